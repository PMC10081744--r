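test_that("RMSE matches its closed forms", {
  t1 <- matrix(c(1, 0, 0, 1), 2)
  expect_identical(compute_rmse(t1, t1), 0)
  expect_identical(compute_rmse(matrix(0.5), matrix(1)), 0.5)
  for (k in c(2, 4, 9)) {
    targets <- diag(k)[rep(1:k, 3), ]
    expect_equal(compute_rmse(matrix(0, nrow(targets), k), targets),
                 sqrt(1 / k))
  }
  expect_error(compute_rmse(matrix(0, 1, 2), matrix(0, 2, 2)), "shape")
  expect_error(compute_rmse(matrix(numeric(0)), matrix(numeric(0))), "empty")
})

test_that("backpropagation gradients match central finite differences", {
  set.seed(3)
  x <- matrix(runif(5 * 4), 5, 4)
  targets <- diag(3)[sample(1:3, 5, replace = TRUE), ]
  w <- frailtynet:::.init_weights(c(4, 6, 3, 3), seed = 9)
  g <- frailtynet:::.net_gradient(w, x, targets)
  loss <- function(w) {
    out <- frailtynet:::.net_forward(w, x)[[4]]
    0.5 * sum((out - targets)^2) / nrow(x)
  }
  h <- 1e-6
  for (l in 1:3) {
    for (idx in sample(length(w$W[[l]]), 5)) {
      wp <- w; wp$W[[l]][idx] <- wp$W[[l]][idx] + h
      wm <- w; wm$W[[l]][idx] <- wm$W[[l]][idx] - h
      fd <- (loss(wp) - loss(wm)) / (2 * h)
      expect_equal(g$W[[l]][idx], fd, tolerance = 1e-5)
    }
    wp <- w; wp$b[[l]][1] <- wp$b[[l]][1] + h
    wm <- w; wm$b[[l]][1] <- wm$b[[l]][1] - h
    expect_equal(g$b[[l]][1], (loss(wp) - loss(wm)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("a separable toy trains to RMSE below target and perfect accuracy", {
  toy <- separable_toy(n = 200)
  fit <- mfi_net(toy$x, toy$y, hidden = 4, control = desk_control(seed = 5))
  expect_lt(fit$rmse, 0.05)
  expect_lt(fit$epochs, fit$control$max_epochs + 1)
  expect_identical(as.character(predict(fit, toy$x)), as.character(toy$y))
  # training RMSE non-increasing across checkpoints (1e-6 jitter allowed)
  expect_true(all(diff(fit$log$rmse) < 1e-6))
})

test_that("fitting is deterministic in the seed and rejects bad architectures", {
  toy <- separable_toy(n = 60)
  a <- mfi_net(toy$x, toy$y, hidden = 3,
               control = desk_control(seed = 2, max_epochs = 2000))
  b <- mfi_net(toy$x, toy$y, hidden = 3,
               control = desk_control(seed = 2, max_epochs = 2000))
  expect_identical(a$weights, b$weights)
  expect_identical(a$log, b$log)
  expect_error(mfi_net(toy$x, toy$y, hidden = integer(0)), "hidden")
  expect_error(mfi_net(toy$x, toy$y, hidden = c(4, 4, 4, 4)), "hidden")
  expect_error(mfi_net(toy$x, toy$y, hidden = 0), "hidden")
})

test_that("outputs are sigmoid activations and argmax prediction breaks ties first", {
  toy <- separable_toy(n = 60)
  fit <- mfi_net(toy$x, toy$y, hidden = 3,
                 control = desk_control(seed = 2, min_epochs = 500,
                                        max_epochs = 500))
  out <- predict(fit, toy$x, type = "response")
  expect_true(all(out > 0 & out < 1))
  # prediction is invariant to a common positive rescaling of outputs
  expect_identical(max.col(out, ties.method = "first"),
                   max.col(out * 3.7, ties.method = "first"))
  # exact tie goes to the earliest class
  tie <- matrix(c(0.5, 0.5, 0.2, 0.9), 2, byrow = TRUE)
  expect_identical(max.col(tie, ties.method = "first"), c(1L, 2L))
  expect_error(predict(fit, toy$x[, 1, drop = FALSE]), "columns")
})

test_that("plateau stopping halts a stalled fit before the epoch budget", {
  set.seed(8)
  x <- matrix(runif(40), 20, 2)
  y <- factor(sample(c("a", "b"), 20, replace = TRUE))  # pure noise labels
  fit <- mfi_net(x, y, hidden = 2,
                 control = desk_control(seed = 3, min_epochs = 500,
                                        max_epochs = 50000, epoch_step = 500,
                                        plateau_window = 500,
                                        learning_rate = 0.01))
  expect_true(fit$stopped %in% c("plateau", "rmse_target"))
  expect_lt(fit$epochs, 50000)
})

test_that("greedy architecture search matches an exhaustive sweep on unimodal profiles", {
  toy <- separable_toy(n = 40)
  feats <- structure(list(x = toy$x, y = toy$y), class = "mfi_features")
  # unimodal accuracy profile over hidden sizes 1..8 (input dim 2 -> 4n = 8)
  profile <- c(0.2, 0.4, 0.7, 0.9, 0.8, 0.75, 0.5, 0.4)
  calls <- integer(0)
  res <- search_architecture(feats, feats, max_depth = 1, increment = 1,
                             eval_fn = function(h) {
                               calls <<- c(calls, h[1]); profile[h[1]]
                             })
  expect_identical(res$hidden, which.max(profile))
  expect_identical(res$accuracy, max(profile))
  # stopped after two consecutive degradations past the peak
  expect_identical(max(calls), 6L)
})

test_that("search stops a sweep after two immediate degradations and breaks ties smaller", {
  toy <- separable_toy(n = 40)
  feats <- structure(list(x = toy$x, y = toy$y), class = "mfi_features")
  profile <- c(0.9, 0.5, 0.4, 0.8, 0.8, 0.8, 0.8, 0.8)
  calls <- integer(0)
  res <- search_architecture(feats, feats, max_depth = 1, increment = 1,
                             eval_fn = function(h) {
                               calls <<- c(calls, h[1]); profile[h[1]]
                             })
  expect_identical(calls, 1:3)     # sweep stops after 3 candidates
  expect_identical(res$hidden, 1L)
  # exact tie between two architectures: smaller total node count wins
  res2 <- search_architecture(feats, feats, max_depth = 1, increment = 1,
                              eval_fn = function(h) 0.5)
  expect_identical(res2$hidden, 1L)
})

test_that("search trains and returns a model by default", {
  toy <- separable_toy(n = 80)
  feats <- structure(list(x = toy$x, y = toy$y), class = "mfi_features")
  res <- search_architecture(feats, feats,
                             control = desk_control(seed = 4,
                                                    min_epochs = 500,
                                                    max_epochs = 1000),
                             max_depth = 1, increment = 2)
  expect_s3_class(res$model, "mfi_net")
  expect_identical(res$model$hidden, res$hidden)
  expect_gte(res$accuracy, 0.9)
})

test_that("model JSON serialization round-trips predictions exactly", {
  toy <- separable_toy(n = 60)
  fit <- mfi_net(toy$x, toy$y, hidden = c(4, 3),
                 control = desk_control(seed = 6, min_epochs = 500,
                                        max_epochs = 500))
  path <- tempfile(fileext = ".json")
  write_mfi_net(fit, path)
  back <- read_mfi_net(path)
  expect_identical(predict(back, toy$x), predict(fit, toy$x))
  expect_equal(predict(back, toy$x, type = "response"),
               predict(fit, toy$x, type = "response"), tolerance = 1e-12)
  expect_identical(back$hidden, fit$hidden)
})
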