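test_that("accuracy is the exact-match fraction", {
  expect_identical(accuracy(c("a", "b"), c("a", "b"))$accuracy, 1)
  expect_identical(accuracy(c("a", "b"), c("b", "a"))$accuracy, 0)
  r <- accuracy(rep(c("x", "y"), c(712, 1935 - 712)), rep("x", 1935))
  expect_identical(r$n_correct, 712L)
  expect_equal(r$accuracy, 0.36796, tolerance = 1e-4)
  expect_error(accuracy(character(0), character(0)), "nonempty")
  expect_error(accuracy("a", c("a", "b")), "equal length")
})

test_that("percent improvement reproduces every published accuracy pair", {
  tab <- published_accuracies()
  for (i in seq_len(nrow(tab))) {
    expect_identical(
      round(percent_improvement(tab$single_mfi_pct[i], tab$split_mfi_pct[i]), 1),
      tab$improvement_pct[i])
  }
  expect_identical(percent_improvement(0.37, 0.37), 0)
  expect_true(is.na(percent_improvement(0, 0.5)))
})

test_that("forward and reverse improvements are reciprocal", {
  set.seed(1)
  for (i in 1:50) {
    a <- runif(1, 0.05, 0.95); b <- runif(1, 0.05, 0.95)
    i1 <- percent_improvement(a, b); i2 <- percent_improvement(b, a)
    expect_equal((1 + i1 / 100) * (1 + i2 / 100), 1, tolerance = 1e-12)
  }
})

test_that("the Z-test reproduces both published p-values", {
  zc <- two_prop_ztest(0.3199, 1935, 0.3680, 1935)
  expect_identical(round(zc$p_one_tailed, 4), 0.0008)
  expect_identical(zc$direction, "improvement")
  zk <- two_prop_ztest(16 / 52, 52, 14 / 52, 52)
  expect_identical(round(zk$p_one_tailed, 4), 0.3324)
  expect_identical(zk$direction, "decline")
  zn <- two_prop_ztest(0.4, 100, 0.4, 100)
  expect_identical(zn$p_one_tailed, 0.5)
  expect_identical(zn$direction, "none")
})

test_that("the Z-test is antisymmetric and monotone in effect and n", {
  set.seed(2)
  for (i in 1:25) {
    p1 <- runif(1, 0.1, 0.9); p2 <- runif(1, 0.1, 0.9)
    n1 <- sample(20:500, 1); n2 <- sample(20:500, 1)
    a <- two_prop_ztest(p1, n1, p2, n2)
    b <- two_prop_ztest(p2, n2, p1, n1)
    expect_equal(a$z, -b$z, tolerance = 1e-12)
    expect_equal(a$p_one_tailed, b$p_one_tailed, tolerance = 1e-12)
    if (p1 != p2) expect_false(a$direction == b$direction)
  }
  gaps <- seq(0.02, 0.2, by = 0.02)
  ps <- vapply(gaps, function(g) {
    two_prop_ztest(0.4, 200, 0.4 + g, 200)$p_one_tailed
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  ns <- c(50, 100, 200, 400, 800)
  ps_n <- vapply(ns, function(n) {
    two_prop_ztest(0.4, n, 0.5, n)$p_one_tailed
  }, numeric(1))
  expect_true(all(diff(ps_n) < 0))
  # degenerate proportions: zero standard error
  expect_identical(two_prop_ztest(0, 10, 0, 10)$direction, "none")
  expect_identical(two_prop_ztest(1, 10, 1, 10)$p_one_tailed, 0.5)
})

test_that("the normal CDF agrees with a high-precision erf oracle", {
  skip_if_not_installed("pracma")
  z <- seq(-6, 6, by = 0.25)
  oracle <- 0.5 * (1 + pracma::erf(z / sqrt(2)))
  expect_equal(pnorm(z), oracle, tolerance = 1e-10)
})

test_that("destination coverage counts destinations with at least one hit", {
  labs <- rep(c("home", "rehab", "death", "hospice"), each = 3)
  expect_identical(destination_coverage(labs, labs,
                                        unique(labs)), 1)
  all_home <- rep("home", 12)
  expect_identical(destination_coverage(all_home, labs, unique(labs)), 0.25)
  # constructed: 7 present, 4 covered
  present <- destination_taxonomy()[1:7]
  labs7 <- rep(present, each = 2)
  preds7 <- labs7
  preds7[labs7 %in% present[5:7]] <- "home"
  preds7[1] <- "rehab"  # one home case missed, the other still correct
  expect_equal(destination_coverage(preds7, labs7, present), 4 / 7,
               tolerance = 1e-9)
  expect_equal(round(destination_coverage(preds7, labs7, present), 3), 0.571)
})

test_that("mortality recall is death-class recall with an NA marker", {
  labs <- c("death", "death", "home")
  expect_identical(mortality_recall(c("death", "death", "home"), labs), 1)
  expect_identical(mortality_recall(c("home", "home", "home"), labs), 0)
  expect_equal(mortality_recall(rep(c("death", "home"), c(78, 22)),
                                rep("death", 100)), 0.78)
  expect_true(is.na(mortality_recall("home", "home")))
})

test_that("beta selection takes the accuracy argmax with ties to the smaller value", {
  expect_identical(select_beta(c("1.5" = 0.35, "1.667" = 0.37,
                                 "1.75" = 0.36, "2" = 0.34)), 1.667)
  expect_identical(select_beta(c("1.75" = 0.2)), 1.75)
  expect_identical(select_beta(c("2" = 0.4, "1.5" = 0.4)), 1.5)
  expect_error(select_beta(numeric(0)), "no candidates")
})

test_that("leave-one-out comparison flags dominance, ties and gaps", {
  acc <- data.frame(
    specialty = rep(c("general", "cardiac", "ent"), each = 3),
    variant = rep(c("high_only", "low_only", "split_mfi"), 3),
    accuracy = c(0.40, 0.30, 0.45,  0.25, 0.25, 0.20,  0.30, 0.35, 0.33))
  out <- leave_one_out_compare(acc)
  expect_identical(out$verdict[out$specialty == "general"], "high_dominant")
  expect_identical(out$verdict[out$specialty == "cardiac"], "tie")
  expect_identical(out$verdict[out$specialty == "ent"], "low_dominant")
  expect_true(out$split_at_least_both[out$specialty == "general"])
  expect_false(out$split_at_least_both[out$specialty == "cardiac"])
  out2 <- leave_one_out_compare(acc[acc$variant != "low_only", ])
  expect_true(all(out2$verdict == "incomparable"))
})
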