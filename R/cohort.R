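#' Discharge-destination taxonomy and surgical specialties
#'
#' The nine post-surgery discharge destinations, ordered by care intensity
#' (home first, in-hospital death last). The order is load-bearing: it is the
#' ordinal scale of the synthetic generator's latent model, the class-label
#' order downstream, and the tie-break order for predictions.
#'
#' @return `destination_taxonomy()`: character vector of 9 destinations.
#'   `specialty_names()`: character vector of the 9 surgical specialties.
#' @export
destination_taxonomy <- function() {
  c("home", "home_with_facility", "multi_level_facility",
    "unskilled_facility", "rehab", "skilled_facility",
    "acute_care", "hospice", "death")
}

#' @rdname destination_taxonomy
#' @export
specialty_names <- function() {
  c("cardiac", "general", "gynecology", "neurosurgery", "orthopedics",
    "ent", "thoracic", "urology", "vascular")
}

# Fixed reference constants used to standardize covariates on the latent
# scale (so destination thresholds do not drift with cohort size).
.covariate_ref <- list(
  age  = c(mean = 63, sd = 15),
  asa  = c(mean = 3, sd = 0.9),
  lwrvu = c(mean = log(20.7), sd = 0.45)
)

# Default destination thresholds, calibrated once by simulation (n = 2e5)
# against the population discharge marginals (home-heavy, death rare) at the
# default effect weights; see calibrate_thresholds().
.default_thresholds <- c(2.0350, 2.0751, 2.0768, 2.0847, 2.3622, 3.6082,
                         3.9630, 4.0355)

#' Specification of a synthetic NSQIP-like cohort
#'
#' Bundles every knob of the synthetic-cohort generator: cohort size,
#' specialty mix, per-indicator prevalences, the latent-scale effect weights,
#' noise level, destination thresholds, missingness and seed. Defaults are
#' chosen to emulate an inpatient elective-surgery population: median mFI
#' near 0.08, high-impact-only median 0, low-impact-only median near 0.17,
#' roughly 91% discharged home, death rare, and a stronger dependence of
#' destination on high-impact than low-impact deficits (`w_high = 3 * w_low`).
#'
#' @param n_records number of records to draw.
#' @param specialty_mix named probability vector over [specialty_names()].
#' @param indicator_prevalence named Bernoulli rate per canonical indicator.
#' @param effect_weights named vector `c(w_high, w_low, w_age, w_asa, w_wrvu)`
#'   of latent-scale coefficients (per deficit for the indicator groups, per
#'   standardized unit for the covariates).
#' @param noise_sd standard deviation of the latent Gaussian noise.
#' @param destination_thresholds 8 strictly increasing latent cutpoints
#'   separating the 9 destinations.
#' @param missing_rate probability that any one independent-variable cell is
#'   blanked (missing completely at random); the outcome is never blanked.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return an object of class `cohort_spec` (a validated list).
#' @examples
#' spec <- cohort_spec(n_records = 100, seed = 42)
#' cohort <- generate_cohort(spec)
#' table(cohort$destination)
#' @export
cohort_spec <- function(n_records = 20000,
                        specialty_mix = c(cardiac = 0.04, general = 0.30,
                                          gynecology = 0.10, neurosurgery = 0.08,
                                          orthopedics = 0.20, ent = 0.06,
                                          thoracic = 0.04, urology = 0.10,
                                          vascular = 0.08),
                        indicator_prevalence = c(
                          ascites = 0.005, dialysis = 0.010,
                          functional_status = 0.020, copd = 0.040,
                          chf = 0.010, renal_failure = 0.005,
                          ventilator_dependent = 0.005,
                          smoker = 0.180, diabetes = 0.150,
                          disseminated_cancer = 0.020, dyspnea = 0.070,
                          hypertension = 0.450, steroid_use = 0.030),
                        effect_weights = c(w_high = 1.50, w_low = 0.50,
                                           w_age = 0.30, w_asa = 0.40,
                                           w_wrvu = 0.20),
                        noise_sd = 0.75,
                        destination_thresholds = .default_thresholds,
                        missing_rate = 0.01,
                        seed = 1L) {
  spec <- list(n_records = n_records, specialty_mix = specialty_mix,
               indicator_prevalence = indicator_prevalence,
               effect_weights = effect_weights, noise_sd = noise_sd,
               destination_thresholds = destination_thresholds,
               missing_rate = missing_rate, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.numeric(spec$n_records) || spec$n_records < 1) {
    stop("'n_records' must be >= 1", call. = FALSE)
  }
  mix <- spec$specialty_mix
  if (length(mix) == 0 || is.null(names(mix)) ||
      !setequal(names(mix), specialty_names())) {
    stop("'specialty_mix' must be named over the 9 specialties", call. = FALSE)
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    stop("'specialty_mix' must be nonnegative and sum to 1", call. = FALSE)
  }
  prev <- spec$indicator_prevalence
  if (!setequal(names(prev), mfi_indicators()) ||
      any(prev < 0) || any(prev > 1)) {
    stop("'indicator_prevalence' must cover the 13 indicators with rates in [0,1]",
         call. = FALSE)
  }
  w <- spec$effect_weights
  need <- c("w_high", "w_low", "w_age", "w_asa", "w_wrvu")
  if (!all(need %in% names(w))) {
    stop("'effect_weights' must name ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  th <- spec$destination_thresholds
  if (length(th) != 8 || any(diff(th) <= 0)) {
    stop("'destination_thresholds' must be 8 strictly increasing cutpoints",
         call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (spec$missing_rate < 0 || spec$missing_rate >= 1) {
    stop("'missing_rate' must be in [0, 1)", call. = FALSE)
  }
  invisible(spec)
}

# Evaluate code with a private, restored-after RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Bin a latent severity score into a discharge destination
#'
#' Ordinal binning of the generator's latent scale: values below the first
#' cutpoint map to `home`, above the last to `death`. A value exactly equal
#' to a cutpoint is assigned to the higher (more intensive) category.
#'
#' @param latent numeric vector of latent scores.
#' @param thresholds 8 strictly increasing cutpoints.
#' @return character vector of destinations.
#' @examples
#' assign_destination(c(-10, 10), cohort_spec(seed = 1)$destination_thresholds)
#' @export
assign_destination <- function(latent, thresholds) {
  if (length(thresholds) != 8 || any(diff(thresholds) <= 0)) {
    stop("'thresholds' must be 8 strictly increasing cutpoints", call. = FALSE)
  }
  destination_taxonomy()[findInterval(latent, thresholds) + 1L]
}

#' Generate a synthetic NSQIP-like cohort
#'
#' Draws `n_records` patient records per the spec: indicators are independent
#' Bernoulli draws; age is truncated normal (mean 63, sd 15, 18–100); wRVU is
#' lognormal with median 20.7; ASA class is categorical over 1–5 with mode 3;
#' sex is Bernoulli (44% male). The discharge destination is assigned by
#' [assign_destination()] from a latent score
#' \deqn{s = w_h n_{high} + w_l n_{low} + w_{age} age' + w_{asa} asa' +
#'   w_{wrvu} wrvu' + N(0, \sigma),}
#' where primed covariates are standardized against fixed reference moments.
#' Missingness is then injected completely at random over the independent
#' variables only. Byte-identical output is guaranteed for a given spec.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with columns `record_id`, `specialty`, the 13 indicator
#'   columns (0/1, possibly `NA`), `age`, `sex`, `wrvu`, `asa_class`,
#'   `destination`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- as.integer(spec$n_records)
  with_seed(spec$seed, {
    specialty <- sample(names(spec$specialty_mix), n, replace = TRUE,
                        prob = spec$specialty_mix)
    canon <- mfi_indicators()
    ind <- vapply(canon, function(k) {
      as.integer(stats::runif(n) < spec$indicator_prevalence[[k]])
    }, integer(n))
    ind <- matrix(ind, nrow = n, dimnames = list(NULL, canon))
    # truncated normal age via inverse-CDF
    ref <- .covariate_ref
    plo <- stats::pnorm(18, ref$age["mean"], ref$age["sd"])
    phi <- stats::pnorm(100, ref$age["mean"], ref$age["sd"])
    age <- as.integer(round(stats::qnorm(stats::runif(n, plo, phi),
                                         ref$age["mean"], ref$age["sd"])))
    sex <- ifelse(stats::runif(n) < 0.44, "male", "female")
    wrvu <- round(stats::rlnorm(n, ref$lwrvu["mean"], ref$lwrvu["sd"]), 4)
    asa <- sample(1:5, n, replace = TRUE,
                  prob = c(0.08, 0.25, 0.45, 0.18, 0.04))

    p <- mfi_partition()
    nh <- rowSums(ind[, p$high_impact, drop = FALSE])
    nl <- rowSums(ind[, p$low_impact, drop = FALSE])
    w <- spec$effect_weights
    latent <- w[["w_high"]] * nh + w[["w_low"]] * nl +
      w[["w_age"]] * (age - ref$age[["mean"]]) / ref$age[["sd"]] +
      w[["w_asa"]] * (asa - ref$asa[["mean"]]) / ref$asa[["sd"]] +
      w[["w_wrvu"]] * (log(wrvu) - ref$lwrvu[["mean"]]) / ref$lwrvu[["sd"]] +
      stats::rnorm(n, 0, spec$noise_sd)
    destination <- assign_destination(latent, spec$destination_thresholds)

    out <- data.frame(record_id = sprintf("R%07d", seq_len(n)),
                      specialty = specialty, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(ind))
    out$age <- age
    out$sex <- sex
    out$wrvu <- wrvu
    out$asa_class <- asa
    out$destination <- destination

    if (spec$missing_rate > 0) {
      indep <- c(canon, "age", "sex", "wrvu", "asa_class")
      for (col in indep) {
        blank <- stats::runif(n) < spec$missing_rate
        out[[col]][blank] <- NA
      }
    }
    out
  })
}

#' Calibrate destination thresholds against target marginals
#'
#' Simulates the latent score distribution under a spec (ignoring its
#' thresholds) and returns the latent quantiles at the cumulative target
#' destination probabilities. Used once to fix the package defaults against
#' the home-heavy population marginals; exposed so alternative marginals can
#' be dialed in.
#'
#' @param spec a [cohort_spec()].
#' @param marginals probability vector of length 9 over
#'   [destination_taxonomy()] (summing to 1).
#' @param n_sim simulation size.
#' @return 8 strictly increasing cutpoints.
#' @export
calibrate_thresholds <- function(spec, marginals, n_sim = 200000) {
  stopifnot(length(marginals) == 9, abs(sum(marginals) - 1) < 1e-6)
  sim <- spec
  sim$n_records <- n_sim
  sim$missing_rate <- 0
  cohort <- generate_cohort(sim)
  ref <- .covariate_ref
  p <- mfi_partition()
  ind <- as.matrix(cohort[mfi_indicators()])
  w <- spec$effect_weights
  latent <- w[["w_high"]] * rowSums(ind[, p$high_impact, drop = FALSE]) +
    w[["w_low"]] * rowSums(ind[, p$low_impact, drop = FALSE]) +
    w[["w_age"]] * (cohort$age - ref$age[["mean"]]) / ref$age[["sd"]] +
    w[["w_asa"]] * (cohort$asa_class - ref$asa[["mean"]]) / ref$asa[["sd"]] +
    w[["w_wrvu"]] * (log(cohort$wrvu) - ref$lwrvu[["mean"]]) / ref$lwrvu[["sd"]] +
    with_seed(spec$seed + 1L, stats::rnorm(n_sim, 0, spec$noise_sd))
  q <- stats::quantile(latent, probs = cumsum(marginals)[1:8], names = FALSE)
  # enforce strict increase for near-empty categories
  eps <- 1e-4
  for (i in 2:8) if (q[i] <= q[i - 1]) q[i] <- q[i - 1] + eps
  q
}

.cohort_columns <- function() {
  c("record_id", "specialty", mfi_indicators(),
    "age", "sex", "wrvu", "asa_class", "destination")
}

#' Read and write cohort CSV files
#'
#' The cohort schema is `record_id, specialty, <13 indicator columns>, age,
#' sex, wrvu, asa_class, destination` (UTF-8, comma-separated, header
#' required; missing cells empty). `read_cohort_csv(write_cohort_csv(x))`
#' round-trips exactly, including missing markers. Malformed rows (unknown
#' specialty, sex or destination labels, non-binary indicators) are rejected
#' with their line numbers and offending values.
#'
#' @param records cohort data frame as from [generate_cohort()].
#' @param path file path.
#' @return `read_cohort_csv()` returns the cohort data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(.cohort_columns(), names(records))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(records[.cohort_columns()], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cols <- .cohort_columns()
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = "", colClasses = "character")
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    stop("cohort file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data <- data[cols]
  if (nrow(data) == 0) {
    out <- generate_cohort(cohort_spec(n_records = 1, seed = 1))[0, ]
    return(out)
  }
  line <- seq_len(nrow(data)) + 1L  # header is line 1
  problems <- character(0)
  note <- function(bad, what, vals) {
    if (any(bad)) {
      problems <<- c(problems, sprintf(
        "line %d: %s '%s'", line[bad], what, vals[bad]))
    }
  }
  note(!is.na(data$specialty) & !(data$specialty %in% specialty_names()),
       "unknown specialty", data$specialty)
  note(!is.na(data$sex) & !(data$sex %in% c("male", "female")),
       "unknown sex", data$sex)
  note(!is.na(data$destination) &
         !(data$destination %in% destination_taxonomy()),
       "unknown destination", data$destination)
  for (k in mfi_indicators()) {
    note(!is.na(data[[k]]) & !(data[[k]] %in% c("0", "1")),
         sprintf("non-binary %s", k), data[[k]])
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  for (k in c("age", "wrvu", "asa_class")) {
    note(!is.na(data[[k]]) & is.na(num_or_na(data[[k]])),
         sprintf("non-numeric %s", k), data[[k]])
  }
  if (length(problems)) {
    stop("malformed cohort file:\n  ",
         paste(utils::head(problems, 20), collapse = "\n  "), call. = FALSE)
  }
  for (k in mfi_indicators()) data[[k]] <- as.integer(data[[k]])
  data$age <- as.integer(data$age)
  data$wrvu <- as.numeric(data$wrvu)
  data$asa_class <- as.integer(data$asa_class)
  data
}
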