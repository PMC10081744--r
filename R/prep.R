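.independent_vars <- function() {
  c(mfi_indicators(), "age", "sex", "wrvu", "asa_class")
}

#' Model variants: which frailty features feed the classifier
#'
#' Five input configurations are compared, all sharing the four covariates
#' (age, sex, wRVU, ASA class) and differing only in the frailty feature(s):
#' `single_mfi` (the traditional index), `split_mfi` (high- and low-impact
#' indices jointly), `high_only`, `low_only`, and `mfi_hat` (the
#' beta-weighted single index).
#'
#' @param name one of `"single_mfi"`, `"split_mfi"`, `"high_only"`,
#'   `"low_only"`, `"mfi_hat"`.
#' @param beta multiplier used only by `mfi_hat`.
#' @return a `model_variant` object (name, index feature columns, beta).
#' @examples
#' model_variant("split_mfi")$index_features
#' @export
model_variant <- function(name = c("single_mfi", "split_mfi", "high_only",
                                   "low_only", "mfi_hat"),
                          beta = 1.667) {
  name <- match.arg(name)
  features <- switch(name,
    single_mfi = "mfi",
    split_mfi  = c("mfi_high", "mfi_low"),
    high_only  = "mfi_high",
    low_only   = "mfi_low",
    mfi_hat    = "mfi_hat")
  structure(list(name = name, index_features = features, beta = beta),
            class = "model_variant")
}

#' Apply the inclusion criteria and build per-specialty datasets
#'
#' Drops records missing any independent variable (the 13 indicators, age,
#' sex, wRVU, ASA class) or the discharge destination, then builds one
#' dataset per specialty plus the pooled composite. Within each dataset,
#' destinations with fewer than 2 records are dropped so that every retained
#' destination can contribute at least one case to both the training and the
#' test set.
#'
#' @param records cohort data frame (see [generate_cohort()]).
#' @return named list of 10 `specialty_dataset` objects (`$specialty`,
#'   `$records`, `$present_destinations`), keys = specialties + `"composite"`.
#' @export
filter_records <- function(records) {
  stopifnot(is.data.frame(records))
  keep <- stats::complete.cases(records[c(.independent_vars(), "destination")])
  complete <- records[keep, , drop = FALSE]
  make_ds <- function(sub, name) {
    counts <- table(factor(sub$destination, levels = destination_taxonomy()))
    present <- names(counts)[counts >= 2]
    sub <- sub[sub$destination %in% present, , drop = FALSE]
    rownames(sub) <- NULL
    structure(list(specialty = name, records = sub,
                   present_destinations = present),
              class = "specialty_dataset")
  }
  out <- lapply(specialty_names(), function(sp) {
    make_ds(complete[complete$specialty == sp, , drop = FALSE], sp)
  })
  names(out) <- specialty_names()
  out$composite <- make_ds(complete, "composite")
  out
}

#' Destination-stratified 50/50 train/test split
#'
#' Within each present destination, a uniformly random half of the records
#' goes to training and the remainder to testing. For odd counts the extra
#' record alternates between train and test across destinations (taxonomy
#' order), so per-destination counts never differ by more than 1; a
#' destination with exactly 2 records contributes one case to each set.
#'
#' @param ds a `specialty_dataset` from [filter_records()].
#' @param seed integer seed; the split is reproducible from it.
#' @return list with data frames `train` and `test` (class `split_dataset`).
#' @export
stratified_split <- function(ds, seed) {
  stopifnot(inherits(ds, "specialty_dataset"))
  counts <- table(ds$records$destination)
  if (any(counts < 2)) {
    stop("destination(s) with < 2 records: ",
         paste(names(counts)[counts < 2], collapse = ", "),
         "; run filter_records() first", call. = FALSE)
  }
  with_seed(seed, {
    train_idx <- integer(0)
    extra_to_train <- TRUE
    for (d in intersect(destination_taxonomy(), ds$present_destinations)) {
      idx <- which(ds$records$destination == d)
      k <- length(idx)
      n_train <- if (k %% 2 == 0) k %/% 2 else {
        n <- k %/% 2 + as.integer(extra_to_train)
        extra_to_train <- !extra_to_train
        n
      }
      train_idx <- c(train_idx, sample(idx, n_train))
    }
    train_idx <- sort(train_idx)
    structure(list(train = ds$records[train_idx, , drop = FALSE],
                   test = ds$records[-train_idx, , drop = FALSE]),
              class = "split_dataset")
  })
}

#' Median-cap partial class balancing
#'
#' Computes the median of the per-destination record counts; destinations
#' with more records than the median are randomly subsampled (uniform,
#' without replacement) to exactly `ceiling(median)` records, destinations at
#' or below the median keep all their cases. This limits over-learning of the
#' dominant classes without discarding the rare ones. The even-count median
#' is the mean of the two middle counts.
#'
#' @param records data frame with a `destination` column.
#' @param seed integer seed for the subsampling.
#' @return the balanced data frame (row order of the input preserved).
#' @examples
#' # counts {10, 4, 2} -> median 4 -> capped to {4, 4, 2}
#' @export
partial_balance <- function(records, seed) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  counts <- table(records$destination)
  m <- stats::median(as.numeric(counts))
  cap <- ceiling(m)
  with_seed(seed, {
    keep <- logical(nrow(records))
    for (d in names(counts)) {
      idx <- which(records$destination == d)
      if (length(idx) > m) idx <- sample(idx, cap)
      keep[idx] <- TRUE
    }
    out <- records[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Encode records into a scaled feature matrix with one-hot labels
#'
#' Computes the variant's frailty feature column(s), min-max scales `age`,
#' `wrvu` and `asa_class` to \[0, 1\] using training-set bounds (recorded in
#' the result so the identical scaling is applied to test data), encodes sex
#' as 0/1 (male = 1), and one-hot encodes the destination over the dataset's
#' present destinations. `mfi_hat` is scaled by its theoretical maximum
#' `(7 beta + 6)/13` so every feature lies in \[0, 1\]. A constant covariate
#' scales to 0 rather than dividing by zero.
#'
#' @param records complete records (post-[filter_records()]).
#' @param variant a [model_variant()].
#' @param destinations label space: the dataset's present destinations
#'   (default: those present in `records`, taxonomy order). A record with a
#'   destination outside this set is an error.
#' @param bounds scaling bounds from a previous (training) encoding, or
#'   `NULL` to compute them from `records`.
#' @return an `mfi_features` object: `$x` numeric feature matrix, `$y` factor
#'   of destinations, `$labels` one-hot matrix, `$destinations`, `$bounds`,
#'   `$variant`.
#' @export
encode_features <- function(records, variant, destinations = NULL,
                            bounds = NULL) {
  stopifnot(inherits(variant, "model_variant"), is.data.frame(records),
            nrow(records) > 0)
  scored <- score_frailty(records, beta = variant$beta)
  if (is.null(destinations)) {
    destinations <- intersect(destination_taxonomy(),
                              unique(records$destination))
  }
  unseen <- setdiff(unique(records$destination), destinations)
  if (length(unseen)) {
    stop("destination(s) outside the label space: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  }
  if (is.null(bounds)) {
    bounds <- lapply(scored[c("age", "wrvu", "asa_class")], range)
  }
  minmax <- function(x, b) {
    if (b[2] > b[1]) pmin(pmax((x - b[1]) / (b[2] - b[1]), 0), 1)
    else rep(0, length(x))
  }
  idx <- as.matrix(scored[variant$index_features])
  if (variant$name == "mfi_hat") {
    idx <- idx / ((7 * variant$beta + 6) / 13)
  }
  x <- cbind(idx,
             age = minmax(scored$age, bounds$age),
             sex = as.numeric(scored$sex == "male"),
             wrvu = minmax(scored$wrvu, bounds$wrvu),
             asa_class = minmax(scored$asa_class, bounds$asa_class))
  y <- factor(records$destination, levels = destinations)
  labels <- diag(length(destinations))[as.integer(y), , drop = FALSE]
  colnames(labels) <- destinations
  structure(list(x = x, y = y, labels = labels, destinations = destinations,
                 bounds = bounds, variant = variant$name),
            class = "mfi_features")
}
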