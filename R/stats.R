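#' Exact-match prediction accuracy
#'
#' @param predictions,labels vectors of equal, nonzero length.
#' @return list with `n_test`, `n_correct` and `accuracy` (a fraction).
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) == 0 || length(predictions) != length(labels)) {
    stop("'predictions' and 'labels' must be nonempty and of equal length",
         call. = FALSE)
  }
  n_correct <- sum(as.character(predictions) == as.character(labels))
  list(n_test = length(labels), n_correct = n_correct,
       accuracy = n_correct / length(labels))
}

#' Percent improvement of one accuracy over another
#'
#' `100 * (acc_new / acc_ref - 1)`: the relative accuracy gain, in percent,
#' of (typically) the split-index model over the single-index model. Report
#' to one decimal.
#'
#' @param acc_ref,acc_new accuracies as fractions or percentages (any common
#'   scale); `acc_ref` must be positive.
#' @return percent improvement (possibly negative); `NA` if `acc_ref` is 0.
#' @examples
#' percent_improvement(34.83, 44.03)  # 26.4
#' @export
percent_improvement <- function(acc_ref, acc_new) {
  if (acc_ref < 0 || acc_new < 0) stop("accuracies must be >= 0", call. = FALSE)
  if (acc_ref == 0) return(NA_real_)
  100 * (acc_new / acc_ref - 1)
}

#' One-tailed two-proportion Z-test (unpooled)
#'
#' Tests the difference between two independent proportions with the
#' unpooled (Wald) standard error
#' \deqn{z = \frac{p_2 - p_1}{\sqrt{p_1(1-p_1)/n_1 + p_2(1-p_2)/n_2}}}
#' and reports the one-tailed normal p-value in the observed direction,
#' with a flag indicating whether `p2` improved on, declined from, or equals
#' `p1`. When both proportions are degenerate (both 0 or both 1) the
#' standard error is 0 and the result is `direction = "none"`, `p = 0.5`.
#'
#' @param p1,p2 proportions in \[0, 1\].
#' @param n1,n2 sample sizes (>= 1).
#' @return list of class `ztest`: `p1, p2, n1, n2, z, p_one_tailed,
#'   direction`.
#' @examples
#' two_prop_ztest(0.3199, 1935, 0.3680, 1935)$p_one_tailed  # ~0.0008
#' @export
two_prop_ztest <- function(p1, n1, p2, n2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 >= 1, n2 >= 1)
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  if (se == 0) {
    z <- if (p2 > p1) Inf else if (p2 < p1) -Inf else 0
    direction <- if (p2 > p1) "improvement" else if (p2 < p1) "decline"
      else "none"
    p <- if (direction == "none") 0.5 else 0
  } else {
    z <- (p2 - p1) / se
    direction <- if (z > 0) "improvement" else if (z < 0) "decline" else "none"
    p <- stats::pnorm(abs(z), lower.tail = FALSE)
  }
  structure(list(p1 = p1, p2 = p2, n1 = n1, n2 = n2, z = z,
                 p_one_tailed = p, direction = direction),
            class = "ztest")
}

#' @export
print.ztest <- function(x, ...) {
  cat(sprintf(
    "Two-proportion Z-test (one-tailed, unpooled SE)\n  p1 = %.4f (n = %d), p2 = %.4f (n = %d)\n  z = %.4f, p = %.4f (%s)\n",
    x$p1, x$n1, x$p2, x$n2, x$z, x$p_one_tailed, x$direction))
  invisible(x)
}

#' Fraction of destinations the model ever predicts correctly
#'
#' A destination counts as covered when at least one test case with that
#' label is predicted correctly; coverage is covered / present.
#'
#' @param predictions,labels vectors of equal length.
#' @param present_destinations the dataset's present destinations.
#' @return fraction in \[0, 1\].
#' @export
destination_coverage <- function(predictions, labels, present_destinations) {
  if (length(labels) == 0) stop("empty test set", call. = FALSE)
  correct <- as.character(predictions) == as.character(labels)
  covered <- unique(as.character(labels)[correct])
  length(intersect(covered, present_destinations)) /
    length(present_destinations)
}

#' Recall on the in-hospital death outcome
#'
#' @param predictions,labels vectors of equal length.
#' @return fraction of death-labeled cases predicted as death, or `NA` when
#'   the test set has no death cases.
#' @export
mortality_recall <- function(predictions, labels) {
  is_death <- as.character(labels) == "death"
  if (!any(is_death)) return(NA_real_)
  mean(as.character(predictions)[is_death] == "death")
}

#' Select the beta multiplier by composite accuracy
#'
#' @param per_beta_accuracies named numeric vector: names are candidate beta
#'   values, entries the composite-set accuracy achieved with each.
#' @return the best beta (numeric); exact accuracy ties go to the smaller
#'   beta.
#' @examples
#' select_beta(c("1.5" = 0.35, "1.667" = 0.37, "2" = 0.34))
#' @export
select_beta <- function(per_beta_accuracies) {
  if (length(per_beta_accuracies) == 0) stop("no candidates", call. = FALSE)
  betas <- as.numeric(names(per_beta_accuracies))
  if (anyNA(betas)) stop("names must be numeric beta values", call. = FALSE)
  ord <- order(-per_beta_accuracies, betas)
  betas[ord[1]]
}

#' Compare high-impact-only vs low-impact-only contributions
#'
#' For each specialty in an accuracy table, flags whether the
#' high-impact-only model out-predicted the low-impact-only model and
#' whether the joint split model did at least as well as both single-group
#' models — the leave-one-out reading of variable importance.
#'
#' @param accuracies data frame with columns `specialty`, `variant`,
#'   `accuracy` (variants `high_only`, `low_only` and optionally
#'   `split_mfi`).
#' @return data frame with one row per specialty: `high_only`, `low_only`,
#'   `verdict` (`"high_dominant"`, `"low_dominant"`, `"tie"` or
#'   `"incomparable"`), and `split_at_least_both` (logical, `NA` when the
#'   split model is absent).
#' @export
leave_one_out_compare <- function(accuracies) {
  stopifnot(all(c("specialty", "variant", "accuracy") %in% names(accuracies)))
  out <- lapply(unique(accuracies$specialty), function(sp) {
    sub <- accuracies[accuracies$specialty == sp, ]
    get <- function(v) {
      a <- sub$accuracy[sub$variant == v]
      if (length(a) == 1) a else NA_real_
    }
    hi <- get("high_only"); lo <- get("low_only"); sp_acc <- get("split_mfi")
    verdict <- if (is.na(hi) || is.na(lo)) "incomparable"
      else if (hi > lo) "high_dominant"
      else if (hi < lo) "low_dominant" else "tie"
    data.frame(specialty = sp, high_only = hi, low_only = lo,
               verdict = verdict,
               split_at_least_both = if (is.na(sp_acc) || is.na(hi) ||
                                         is.na(lo)) NA
                 else sp_acc >= max(hi, lo),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
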