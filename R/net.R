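#' Training control for the backpropagation classifier
#'
#' Bundles the epoch protocol and learning parameters. The published-scale
#' defaults train for at least 50000 epochs, checking every 10000 up to
#' 150000, stopping early when training RMSE falls below 0.05 or stays flat
#' (|change| < `plateau_tol`) across `plateau_window` epochs.
#' `desk_control()` is the scaled-down profile used for routine runs and the
#' test suite (checkpoints every 500 epochs between 1500 and 4000).
#'
#' @param min_epochs,max_epochs,epoch_step epoch protocol: training runs to
#'   `min_epochs`, then checks RMSE every `epoch_step` up to `max_epochs`.
#' @param rmse_target stop once training RMSE falls below this.
#' @param plateau_window,plateau_tol stop once RMSE changes by less than
#'   `plateau_tol` across `plateau_window` epochs.
#' @param learning_rate,momentum full-batch gradient-descent parameters.
#' @param seed integer seed for weight initialization.
#' @return a `net_control` list.
#' @export
net_control <- function(min_epochs = 50000, max_epochs = 150000,
                        epoch_step = 10000, rmse_target = 0.05,
                        plateau_window = 10000, plateau_tol = 1e-4,
                        learning_rate = 0.3, momentum = 0.9, seed = 1L) {
  stopifnot(min_epochs <= max_epochs, epoch_step > 0, rmse_target > 0,
            plateau_window > 0, learning_rate > 0, momentum >= 0,
            momentum < 1)
  structure(list(min_epochs = as.integer(min_epochs),
                 max_epochs = as.integer(max_epochs),
                 epoch_step = as.integer(epoch_step),
                 rmse_target = rmse_target,
                 plateau_window = as.integer(plateau_window),
                 plateau_tol = plateau_tol,
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "net_control")
}

#' @rdname net_control
#' @export
desk_control <- function(min_epochs = 1500, max_epochs = 4000,
                         epoch_step = 500, plateau_window = 500, ...) {
  net_control(min_epochs = min_epochs, max_epochs = max_epochs,
              epoch_step = epoch_step, plateau_window = plateau_window, ...)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Root-mean-square error between network outputs and targets
#'
#' The square root of the mean, over all rows and output units, of the
#' squared difference — the quantity the stopping rule monitors.
#'
#' @param outputs,targets numeric matrices of identical shape.
#' @return a single number.
#' @examples
#' compute_rmse(matrix(0, 2, 4), diag(4)[1:2, ])  # sqrt(1/4)
#' @export
compute_rmse <- function(outputs, targets) {
  outputs <- as.matrix(outputs); targets <- as.matrix(targets)
  if (length(outputs) == 0) stop("empty input", call. = FALSE)
  if (!all(dim(outputs) == dim(targets))) {
    stop("'outputs' and 'targets' must have identical shape", call. = FALSE)
  }
  sqrt(mean((outputs - targets)^2))
}

# Forward pass; returns list of activations per layer (input first).
.net_forward <- function(weights, x) {
  act <- list(x)
  for (l in seq_along(weights$W)) {
    act[[l + 1]] <- sigmoid(act[[l]] %*% weights$W[[l]] +
                              rep(1, nrow(x)) %*% t(weights$b[[l]]))
  }
  act
}

# Analytic gradient of E = 0.5 * sum((out - targets)^2) / n w.r.t. all
# weights and biases, by backpropagation through the sigmoid layers.
.net_gradient <- function(weights, x, targets) {
  n <- nrow(x)
  act <- .net_forward(weights, x)
  L <- length(weights$W)
  out <- act[[L + 1]]
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (out - targets) * out * (1 - out) / n
  for (l in L:1) {
    gW[[l]] <- t(act[[l]]) %*% delta
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      a <- act[[l]]
      delta <- (delta %*% t(weights$W[[l]])) * a * (1 - a)
    }
  }
  list(W = gW, b = gb)
}

.init_weights <- function(dims, seed) {
  with_seed(seed, {
    L <- length(dims) - 1
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -0.5, 0.5),
                       dims[l], dims[l + 1])
      b[[l]] <- stats::runif(dims[l + 1], -0.5, 0.5)
    }
    list(W = W, b = b)
  })
}

.run_training <- function(weights, x, targets, control, lr) {
  mom <- control$momentum
  vW <- lapply(weights$W, function(w) w * 0)
  vb <- lapply(weights$b, function(w) w * 0)
  checkpoints <- seq(control$min_epochs, control$max_epochs,
                     by = control$epoch_step)
  k_window <- max(1L, ceiling(control$plateau_window / control$epoch_step))
  log <- data.frame(epoch = integer(0), rmse = numeric(0))
  stopped <- "max_epochs"
  epoch <- 0L
  for (cp in checkpoints) {
    while (epoch < cp) {
      g <- .net_gradient(weights, x, targets)
      for (l in seq_along(weights$W)) {
        vW[[l]] <- mom * vW[[l]] - lr * g$W[[l]]
        vb[[l]] <- mom * vb[[l]] - lr * g$b[[l]]
        weights$W[[l]] <- weights$W[[l]] + vW[[l]]
        weights$b[[l]] <- weights$b[[l]] + vb[[l]]
      }
      epoch <- epoch + 1L
    }
    out <- .net_forward(weights, x)[[length(weights$W) + 1]]
    rmse <- compute_rmse(out, targets)
    if (!is.finite(rmse)) return(list(diverged = TRUE, epoch = epoch))
    log <- rbind(log, data.frame(epoch = epoch, rmse = rmse))
    if (rmse < control$rmse_target) { stopped <- "rmse_target"; break }
    i <- nrow(log)
    if (i > k_window &&
        abs(log$rmse[i] - log$rmse[i - k_window]) < control$plateau_tol) {
      stopped <- "plateau"; break
    }
  }
  list(diverged = FALSE, weights = weights, log = log, epochs = epoch,
       stopped = stopped)
}

#' Fit a feed-forward backpropagation classifier
#'
#' The package's core estimator: a fully connected network with 1–3 sigmoid
#' hidden layers and sigmoid output units, trained by full-batch
#' backpropagation (with momentum) against one-hot targets under a squared
#' error loss. Training halts at the first epoch checkpoint where training
#' RMSE drops below the target, plateaus, or the epoch budget is exhausted
#' (see [net_control()]). Fitting is deterministic given the control seed.
#' If the loss turns non-finite the learning rate is halved once and training
#' restarts from the initial weights; a second divergence is an error.
#'
#' @param x numeric feature matrix with values in \[0, 1\] (as produced by
#'   [encode_features()]), or an `mfi_features` object (in which case `y` is
#'   taken from it).
#' @param y factor of class labels (one per row of `x`), or `NULL` when `x`
#'   is an `mfi_features` object.
#' @param hidden integer vector of 1–3 hidden-layer sizes.
#' @param control a [net_control()]; tests and routine runs use
#'   [desk_control()].
#' @return an object of class `mfi_net` with components `dims`, `weights`,
#'   `classes`, `log` (per-checkpoint epoch and training RMSE), `rmse`,
#'   `epochs`, `stopped`, `fitted`, plus the encoding metadata when fitted
#'   from an `mfi_features` object. Methods: [predict.mfi_net()], `print`,
#'   `summary`, `coef`, `residuals`, `plot`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(runif(40, 0, .3), 20), matrix(runif(40, .7, 1), 20))
#' y <- factor(rep(c("a", "b"), each = 20))
#' fit <- mfi_net(x, y, hidden = 4, control = desk_control(seed = 7))
#' mean(predict(fit, x) == y)
#' @export
mfi_net <- function(x, y = NULL, hidden = 8, control = net_control()) {
  bounds <- NULL; variant <- NULL
  if (inherits(x, "mfi_features")) {
    feats <- x
    x <- feats$x
    y <- feats$y
    bounds <- feats$bounds
    variant <- feats$variant
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.factor(y)
  stopifnot(nrow(x) == length(y))
  hidden <- as.integer(hidden)
  if (length(hidden) < 1 || length(hidden) > 3 || any(hidden < 1)) {
    stop("'hidden' must be 1 to 3 layer sizes, each >= 1", call. = FALSE)
  }
  classes <- levels(y)
  targets <- diag(length(classes))[as.integer(y), , drop = FALSE]
  dims <- c(ncol(x), hidden, length(classes))
  weights0 <- .init_weights(dims, control$seed)

  fit <- .run_training(weights0, x, targets, control, control$learning_rate)
  if (fit$diverged) {
    fit <- .run_training(weights0, x, targets, control,
                         control$learning_rate / 2)
    if (fit$diverged) {
      stop(sprintf(
        "training diverged (non-finite loss) at epoch %d even after halving the learning rate to %g",
        fit$epoch, control$learning_rate / 2), call. = FALSE)
    }
  }
  out <- .net_forward(fit$weights, x)[[length(dims)]]
  colnames(out) <- classes
  structure(list(dims = dims, hidden = hidden, weights = fit$weights,
                 classes = classes, feature_names = colnames(x),
                 control = control, log = fit$log,
                 rmse = fit$log$rmse[nrow(fit$log)], epochs = fit$epochs,
                 stopped = fit$stopped, fitted = out, targets = targets,
                 bounds = bounds, variant = variant, call = match.call()),
            class = "mfi_net")
}

#' Predict discharge destinations from a fitted classifier
#'
#' Each row is assigned the class whose output unit has the maximal
#' activation; exact ties go to the earliest class in the label order (the
#' destination taxonomy order, for pipeline fits).
#'
#' @param object an [mfi_net()] fit.
#' @param newdata feature matrix with the training columns, or an
#'   `mfi_features` object.
#' @param type `"class"` (default) for labels, `"response"` for the raw
#'   output activations.
#' @param ... unused.
#' @return factor of predicted classes, or a numeric activation matrix.
#' @export
predict.mfi_net <- function(object, newdata, type = c("class", "response"),
                            ...) {
  type <- match.arg(type)
  if (inherits(newdata, "mfi_features")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$dims[1]) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         object$dims[1], call. = FALSE)
  }
  if (!is.null(colnames(newdata)) &&
      !identical(colnames(newdata), object$feature_names)) {
    stop("feature columns do not match training columns: got ",
         paste(colnames(newdata), collapse = ","), call. = FALSE)
  }
  out <- .net_forward(object$weights, newdata)[[length(object$dims)]]
  colnames(out) <- object$classes
  if (type == "response") return(out)
  idx <- max.col(out, ties.method = "first")
  factor(object$classes[idx], levels = object$classes)
}

#' @export
print.mfi_net <- function(x, ...) {
  cat("Feed-forward classifier (", paste(x$dims, collapse = "-"),
      ")\n", sep = "")
  cat(sprintf("  %d classes, trained %d epochs (%s), training RMSE %.4f\n",
              length(x$classes), x$epochs, x$stopped, x$rmse))
  invisible(x)
}

#' @export
summary.mfi_net <- function(object, ...) {
  pred <- factor(object$classes[max.col(object$fitted, ties.method = "first")],
                 levels = object$classes)
  truth <- factor(object$classes[max.col(object$targets, ties.method = "first")],
                  levels = object$classes)
  res <- list(dims = object$dims, epochs = object$epochs,
              stopped = object$stopped, rmse = object$rmse,
              train_accuracy = mean(pred == truth),
              confusion = table(truth = truth, predicted = pred),
              log = object$log)
  class(res) <- "summary.mfi_net"
  res
}

#' @export
print.summary.mfi_net <- function(x, ...) {
  cat("Feed-forward classifier (", paste(x$dims, collapse = "-"), ")\n",
      sep = "")
  cat(sprintf("  epochs: %d (stopped: %s)\n  training RMSE: %.4f\n  training accuracy: %.4f\n",
              x$epochs, x$stopped, x$rmse, x$train_accuracy))
  cat("  confusion (training):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
coef.mfi_net <- function(object, ...) object$weights

#' @export
residuals.mfi_net <- function(object, ...) object$targets - object$fitted

#' @export
plot.mfi_net <- function(x, ...) {
  plot(x$log$epoch, x$log$rmse, type = "b", xlab = "epoch",
       ylab = "training RMSE", main = "Training trajectory", ...)
  graphics::abline(h = x$control$rmse_target, lty = 2)
  invisible(x)
}

#' Incremental hidden-layer architecture search
#'
#' Grows the network depth-first: for one, then two, then three hidden
#' layers, the newest layer's node count sweeps upward from `ceiling(n/3)`
#' to `4 n` (where `n` is the size of the preceding layer, the input layer
#' for depth 1), training a model per candidate and scoring test-set
#' accuracy. A sweep stops early after two consecutive candidates that are
#' each strictly worse than the best accuracy seen so far. Earlier layers
#' are frozen at their best size when a layer is added. The globally best
#' architecture wins; exact accuracy ties go to the smaller total node
#' count.
#'
#' @param train,test `mfi_features` for the training and test sets.
#' @param control a [net_control()].
#' @param max_depth maximum number of hidden layers (1–3).
#' @param increment node-count step during a sweep.
#' @param eval_fn optional function `hidden -> accuracy` replacing the
#'   default train-and-score evaluation (used for search audits).
#' @return list with `hidden` (best layer sizes), `accuracy`, `model` (the
#'   refit best model, `NULL` when `eval_fn` is supplied) and `trace` (every
#'   candidate with its accuracy).
#' @export
search_architecture <- function(train, test, control = desk_control(),
                                max_depth = 3, increment = 1,
                                eval_fn = NULL) {
  stopifnot(max_depth >= 1, max_depth <= 3, increment >= 1)
  internal_eval <- is.null(eval_fn)
  if (internal_eval) {
    eval_fn <- function(hidden) {
      fit <- mfi_net(train, hidden = hidden, control = control)
      mean(predict(fit, test) == test$y)
    }
  }
  input_dim <- ncol(train$x)
  trace <- data.frame(depth = integer(0), hidden = character(0),
                      accuracy = numeric(0), stringsAsFactors = FALSE)
  best <- list(hidden = NULL, accuracy = -Inf)
  prefix <- integer(0)
  for (depth in seq_len(max_depth)) {
    n_prev <- if (depth == 1) input_dim else prefix[depth - 1]
    sweep_best <- list(hidden = NULL, accuracy = -Inf)
    worse_run <- 0L
    for (h in seq.int(ceiling(n_prev / 3), 4 * n_prev, by = increment)) {
      hidden <- as.integer(c(prefix, h))
      acc <- eval_fn(hidden)
      trace <- rbind(trace, data.frame(
        depth = depth, hidden = paste(hidden, collapse = "-"),
        accuracy = acc, stringsAsFactors = FALSE))
      if (acc_better(list(hidden = hidden, accuracy = acc), sweep_best)) {
        sweep_best <- list(hidden = hidden, accuracy = acc)
      }
      if (acc < sweep_best$accuracy) {
        worse_run <- worse_run + 1L
        if (worse_run >= 2L) break
      } else {
        worse_run <- 0L
      }
    }
    if (acc_better(sweep_best, best)) best <- sweep_best
    prefix <- sweep_best$hidden
  }
  if (!is.finite(best$accuracy)) {
    stop("architecture search found no trainable model", call. = FALSE)
  }
  model <- if (internal_eval) {
    mfi_net(train, hidden = best$hidden, control = control)
  } else NULL
  list(hidden = best$hidden, accuracy = best$accuracy, model = model,
       trace = trace)
}

# Is candidate strictly better, or tied with fewer total nodes?
acc_better <- function(candidate, incumbent) {
  if (is.null(incumbent$hidden)) return(TRUE)
  if (candidate$accuracy > incumbent$accuracy) return(TRUE)
  candidate$accuracy == incumbent$accuracy &&
    sum(candidate$hidden) < sum(incumbent$hidden)
}

#' Serialize a fitted classifier to JSON (and back)
#'
#' Writes the architecture, weights, biases, class labels, scaling bounds,
#' seed and training log to a plain-text JSON file; `read_mfi_net()` restores
#' a model whose predictions are identical to the original's.
#'
#' @param model an [mfi_net()] fit.
#' @param path file path.
#' @return `read_mfi_net()` returns the restored `mfi_net`;
#'   `write_mfi_net()` returns `path` invisibly.
#' @export
write_mfi_net <- function(model, path) {
  stopifnot(inherits(model, "mfi_net"))
  payload <- list(
    dims = model$dims, hidden = model$hidden, classes = model$classes,
    feature_names = model$feature_names,
    W = lapply(model$weights$W, unname),
    b = model$weights$b,
    bounds = model$bounds, variant = model$variant,
    seed = model$control$seed, log = model$log,
    rmse = model$rmse, epochs = model$epochs, stopped = model$stopped)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mfi_net
#' @export
read_mfi_net <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(p$W, function(w) {
    w <- as.matrix(w)
    storage.mode(w) <- "double"
    w
  })
  obj <- list(dims = as.integer(p$dims), hidden = as.integer(p$hidden),
              weights = list(W = W,
                             b = lapply(p$b, as.numeric)),
              classes = p$classes, feature_names = p$feature_names,
              control = net_control(seed = p$seed),
              log = as.data.frame(p$log), rmse = p$rmse, epochs = p$epochs,
              stopped = p$stopped, bounds = p$bounds, variant = p$variant,
              fitted = NULL, targets = NULL, call = NULL)
  class(obj) <- "mfi_net"
  obj
}
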