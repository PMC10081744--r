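#' Canonical frailty indicators and the high/low-impact partition
#'
#' The 13-item modified frailty index (mFI) used throughout this package is
#' built from 13 binary preoperative indicators. Seven of them — the
#' "high-impact" group — were singled out by their influence on 30-day
#' postoperative mortality; the remaining six form the "low-impact" group.
#'
#' Canonical snake-case names are used everywhere inside the package;
#' [normalize_indicator_names()] maps common NSQIP-style column headers onto
#' them.
#'
#' @return `mfi_indicators()` returns a character vector of the 13 canonical
#'   indicator names (high-impact first). `mfi_partition()` returns a list
#'   with components `high_impact` (7 names) and `low_impact` (6 names).
#' @examples
#' mfi_indicators()
#' mfi_partition()$high_impact
#' @export
mfi_indicators <- function() {
  c(.mfi_high_impact, .mfi_low_impact)
}

.mfi_high_impact <- c(
  "ascites",
  "dialysis",             # dialysis within 2 weeks
  "functional_status",    # dependent (partially or totally)
  "copd",                 # history of COPD
  "chf",                  # history of CHF within 1 month
  "renal_failure",        # renal failure within 24 hours
  "ventilator_dependent"
)

.mfi_low_impact <- c(
  "smoker",               # current smoker within 1 year
  "diabetes",
  "disseminated_cancer",
  "dyspnea",
  "hypertension",         # high blood pressure or on hypertensive medication
  "steroid_use"           # steroid use within 1 month
)

#' @rdname mfi_indicators
#' @export
mfi_partition <- function() {
  list(high_impact = .mfi_high_impact, low_impact = .mfi_low_impact)
}

# NSQIP-like header -> canonical name. Keys are matched case-insensitively.
.mfi_aliases <- c(
  ascites   = "ascites",
  dialysis  = "dialysis",
  fnstatus2 = "functional_status",
  fnstatus  = "functional_status",
  functional_status = "functional_status",
  hxcopd    = "copd",
  copd      = "copd",
  hxchf     = "chf",
  chf       = "chf",
  renafail  = "renal_failure",
  renal_failure = "renal_failure",
  ventilat  = "ventilator_dependent",
  ventilator_dependent = "ventilator_dependent",
  smoke     = "smoker",
  smoker    = "smoker",
  diabetes  = "diabetes",
  discancr  = "disseminated_cancer",
  disseminated_cancer = "disseminated_cancer",
  dyspnea   = "dyspnea",
  hypermed  = "hypertension",
  hypertension = "hypertension",
  steroid   = "steroid_use",
  steroid_use = "steroid_use"
)

#' Normalize indicator column names to the canonical vocabulary
#'
#' Maps NSQIP-style headers (e.g. `HXCOPD`, `FNSTATUS2`, `DISCANCR`) onto the
#' canonical snake-case indicator names; names already canonical pass through.
#' Non-indicator names are returned unchanged.
#'
#' @param x character vector of column names.
#' @return character vector of the same length.
#' @examples
#' normalize_indicator_names(c("HXCOPD", "age", "DISCANCR"))
#' @export
normalize_indicator_names <- function(x) {
  key <- tolower(x)
  hit <- key %in% names(.mfi_aliases)
  x[hit] <- unname(.mfi_aliases[key[hit]])
  x
}

# Validate a named flag set: all 13 canonical names, nothing else, no NA.
# Returns the flags as a named numeric 0/1 vector in canonical order.
.check_indicator_vector <- function(flags) {
  nm <- names(flags)
  if (is.null(nm)) {
    stop("indicator flags must be named with the 13 canonical indicator names",
         call. = FALSE)
  }
  canon <- mfi_indicators()
  missing <- setdiff(canon, nm)
  if (length(missing)) {
    stop("missing indicator(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(nm, canon)
  if (length(extra)) {
    stop("unknown indicator(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  v <- as.numeric(flags[canon])
  if (anyNA(v)) {
    stop("indicator(s) with missing value: ",
         paste(canon[is.na(v)], collapse = ", "), call. = FALSE)
  }
  if (!all(v %in% c(0, 1))) {
    stop("indicator values must be logical or 0/1", call. = FALSE)
  }
  names(v) <- canon
  v
}

#' Frailty index arithmetic
#'
#' `compute_mfi()` is the accumulating-deficits index: the number of deficits
#' present divided by the 13 deficits measured. `compute_split_mfi()` returns
#' the pair of group-wise indices (high-impact deficits / 7, low-impact
#' deficits / 6). `compute_mfi_hat()` is the single weighted index
#' \deqn{\widehat{mFI} = \frac{\beta \sum \mathrm{high} + \sum \mathrm{low}}{13},}
#' which up-weights the high-impact deficits by a constant \eqn{\beta \ge 1}
#' and may exceed 1 (its maximum is \eqn{(7\beta + 6)/13}).
#'
#' @param flags named logical (or 0/1) vector over the 13 canonical
#'   indicators; see [mfi_indicators()].
#' @param partition indicator partition, as from [mfi_partition()].
#' @param beta positive multiplier applied to the high-impact deficit count;
#'   default 1.667, the grid value found to predict best on the composite set.
#' @return `compute_mfi()`: a fraction in \[0, 1\]. `compute_split_mfi()`: a
#'   named numeric vector `c(mfi_high =, mfi_low =)`. `compute_mfi_hat()`: a
#'   nonnegative number.
#' @examples
#' v <- setNames(rep(FALSE, 13), mfi_indicators())
#' v["diabetes"] <- TRUE
#' compute_mfi(v)            # 1/13
#' compute_split_mfi(v)      # c(0, 1/6)
#' compute_mfi_hat(v, beta = 2)
#' @export
compute_mfi <- function(flags) {
  v <- .check_indicator_vector(flags)
  sum(v) / 13
}

#' @rdname compute_mfi
#' @export
compute_split_mfi <- function(flags, partition = mfi_partition()) {
  v <- .check_indicator_vector(flags)
  c(mfi_high = sum(v[partition$high_impact]) / 7,
    mfi_low  = sum(v[partition$low_impact]) / 6)
}

#' @rdname compute_mfi
#' @export
compute_mfi_hat <- function(flags, beta = 1.667, partition = mfi_partition()) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("'beta' must be a single positive number", call. = FALSE)
  }
  v <- .check_indicator_vector(flags)
  (beta * sum(v[partition$high_impact]) + sum(v[partition$low_impact])) / 13
}

#' Default beta grid for the weighted single index
#'
#' The candidate multipliers tried when selecting beta on the composite set.
#' @return numeric vector `c(1.5, 1.667, 1.75, 2)`.
#' @export
mfi_beta_grid <- function() c(1.5, 1.667, 1.75, 2.0)

#' Score a cohort table with all frailty indices
#'
#' Appends `mfi`, `mfi_high`, `mfi_low` and `mfi_hat` columns to a data frame
#' holding the 13 indicator columns coded 0/1 (NSQIP-style headers are
#' normalized first). Rows with a missing indicator get `NA` scores.
#'
#' @param data data frame with the 13 indicator columns.
#' @param beta multiplier for the weighted index; see [compute_mfi_hat()].
#' @return `data` with four score columns appended (full floating precision;
#'   round only for reporting).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_records = 5, seed = 1))
#' head(score_frailty(cohort))
#' @export
score_frailty <- function(data, beta = 1.667) {
  stopifnot(is.data.frame(data))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("'beta' must be a single positive number", call. = FALSE)
  }
  names(data) <- normalize_indicator_names(names(data))
  canon <- mfi_indicators()
  missing <- setdiff(canon, names(data))
  if (length(missing)) {
    stop("missing indicator column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(data[canon])
  storage.mode(m) <- "numeric"
  bad <- !is.na(m) & !(m %in% c(0, 1))
  if (any(bad)) {
    stop("non-binary indicator values in column(s): ",
         paste(unique(canon[col(m)[bad]]), collapse = ", "), call. = FALSE)
  }
  p <- mfi_partition()
  nh <- rowSums(m[, p$high_impact, drop = FALSE])
  nl <- rowSums(m[, p$low_impact, drop = FALSE])
  data$mfi      <- (nh + nl) / 13
  data$mfi_high <- nh / 7
  data$mfi_low  <- nl / 6
  data$mfi_hat  <- (beta * nh + nl) / 13
  data
}

#' Batch frailty scoring between CSV files
#'
#' Reads a CSV with an id column and the 13 indicator columns coded 0/1,
#' appends the four score columns and writes the result.
#'
#' @param infile,outfile paths.
#' @inheritParams score_frailty
#' @return invisibly, the scored data frame.
#' @export
score_frailty_csv <- function(infile, outfile, beta = 1.667) {
  data <- utils::read.csv(infile, stringsAsFactors = FALSE)
  out <- score_frailty(data, beta = beta)
  utils::write.csv(out, outfile, row.names = FALSE, quote = FALSE)
  invisible(out)
}
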