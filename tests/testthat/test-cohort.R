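test_that("cohort generation is deterministic and schema-complete", {
  spec <- cohort_spec(n_records = 300, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_identical(nrow(a), 300L)
  expect_true(all(c("record_id", "specialty", mfi_indicators(), "age", "sex",
                    "wrvu", "asa_class", "destination") %in% names(a)))
  expect_true(all(a$specialty %in% specialty_names()))
  expect_true(all(a$destination %in% destination_taxonomy()))
  c <- generate_cohort(cohort_spec(n_records = 300, seed = 8))
  expect_false(identical(a$destination, c$destination))
})

test_that("degenerate specs are rejected", {
  expect_error(cohort_spec(n_records = 0), "n_records")
  expect_error(cohort_spec(specialty_mix = c(cardiac = 1)), "specialty_mix")
  th <- cohort_spec()$destination_thresholds
  expect_error(cohort_spec(destination_thresholds = rev(th)), "increasing")
  expect_error(cohort_spec(missing_rate = 1), "missing_rate")
})

test_that("latent binning respects extremes and the cutpoint tie rule", {
  th <- cohort_spec()$destination_thresholds
  expect_identical(assign_destination(-1e6, th), "home")
  expect_identical(assign_destination(th[8] + 10, th), "death")
  # a value exactly on a cutpoint lands in the higher category
  expect_identical(assign_destination(th[1], th), "home_with_facility")
  expect_identical(assign_destination(th[5], th), "skilled_facility")
})

test_that("empirical marginals track the configured rates and targets", {
  spec <- cohort_spec(n_records = 20000, missing_rate = 0, seed = 11)
  cohort <- generate_cohort(spec)
  # indicator prevalences within 3 standard errors
  for (k in mfi_indicators()) {
    p <- spec$indicator_prevalence[[k]]
    se <- sqrt(p * (1 - p) / 20000)
    expect_lt(abs(mean(cohort[[k]]) - p), 3 * se + 1e-9)
  }
  scored <- score_frailty(cohort)
  expect_lt(abs(median(scored$mfi) - 0.08), 0.02)
  expect_identical(median(scored$mfi_high), 0)
  expect_equal(median(scored$mfi_low), 1 / 6, tolerance = 1e-9)
  # home-heavy population, as configured
  expect_gt(mean(cohort$destination == "home"), 0.88)
})

test_that("raising all thresholds raises the home fraction", {
  base <- cohort_spec(n_records = 5000, missing_rate = 0, seed = 3)
  up <- cohort_spec(n_records = 5000, missing_rate = 0, seed = 3,
                    destination_thresholds = base$destination_thresholds + 0.5)
  expect_gt(mean(generate_cohort(up)$destination == "home"),
            mean(generate_cohort(base)$destination == "home"))
})

test_that("the planted high-impact effect is recoverable by a logistic refit", {
  w <- c(w_high = 1.5, w_low = 0.5, w_age = 0.3, w_asa = 0.4, w_wrvu = 0.2)
  cohort <- generate_cohort(cohort_spec(n_records = 20000, missing_rate = 0,
                                        effect_weights = w, seed = 21))
  p <- mfi_partition()
  nh <- rowSums(cohort[p$high_impact])
  nl <- rowSums(cohort[p$low_impact])
  fit <- glm((cohort$destination != "home") ~ nh + nl, family = binomial)
  expect_gt(coef(fit)[["nh"]], coef(fit)[["nl"]])
  expect_gt(coef(fit)[["nl"]], 0)
})

test_that("with equal weights the destination depends on indicators only through their count", {
  w <- c(w_high = 0.75, w_low = 0.75, w_age = 0.3, w_asa = 0.4, w_wrvu = 0.2)
  cohort <- generate_cohort(cohort_spec(n_records = 50000, missing_rate = 0,
                                        effect_weights = w, seed = 31))
  p <- mfi_partition()
  nh <- rowSums(cohort[p$high_impact])
  nl <- rowSums(cohort[p$low_impact])
  one_high <- cohort$destination[nh == 1 & nl == 0] != "home"
  one_low <- cohort$destination[nh == 0 & nl == 1] != "home"
  zt <- two_prop_ztest(mean(one_high), length(one_high),
                       mean(one_low), length(one_low))
  expect_gt(zt$p_one_tailed, 0.01)
})

test_that("cohort CSV round-trips exactly, including missing markers", {
  cohort <- generate_cohort(cohort_spec(n_records = 100, missing_rate = 0.05,
                                        seed = 13))
  expect_true(anyNA(cohort))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  rownames(cohort) <- NULL
  expect_equal(back, cohort)
})

test_that("malformed cohort files are rejected with line numbers and values", {
  cohort <- generate_cohort(cohort_spec(n_records = 5, missing_rate = 0,
                                        seed = 1))
  cohort$destination[3] <- "mars"
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  expect_error(read_cohort_csv(path), "line 4.*mars")
  cohort$destination[3] <- "home"
  cohort$diabetes[2] <- 7L
  write_cohort_csv(cohort, path)
  expect_error(read_cohort_csv(path), "non-binary diabetes")
})

test_that("a header-only file reads as an empty cohort", {
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(generate_cohort(cohort_spec(n_records = 1, seed = 1))[0, ],
                   path)
  empty <- read_cohort_csv(path)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("record_id", "specialty", mfi_indicators(), "age", "sex",
                    "wrvu", "asa_class", "destination") %in% names(empty)))
})
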