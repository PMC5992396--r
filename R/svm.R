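#' Configuration of the soft-margin SVM
#'
#' The classifier solves the usual soft-margin problem
#' `min C * sum(xi_i) + ||w||^2 / 2` subject to
#' `y_i (w' phi(x_i) + b) >= 1 - xi_i`, with a radial-basis kernel by
#' default. Two fitting routes are provided: the exact dual solver
#' (`method = "solver"`, via the libsvm implementation in \pkg{e1071}) and a
#' batched hinge-loss subgradient descent (`method = "sgd"`, linear kernel
#' only) that mirrors the 200-step / 20%-batch protocol used for the CNN.
#'
#' @param C regularisation weight of the slack variables.
#' @param kernel `"rbf"` or `"linear"`.
#' @param gamma RBF bandwidth; `"scale"` (default) uses the inverse-variance
#'   convention `1 / (p * var(x))`.
#' @param method `"solver"` (exact dual) or `"sgd"`.
#' @param steps,batch_fraction,lr subgradient-descent parameters (only used
#'   by `method = "sgd"`).
#' @return an object of class `braking_svm_config`.
#' @export
svm_config <- function(C = 1, kernel = c("rbf", "linear"), gamma = "scale",
                       method = c("solver", "sgd"),
                       steps = 200, batch_fraction = 0.2, lr = 0.005) {
  kernel <- match.arg(kernel)
  method <- match.arg(method)
  stopifnot(C > 0)
  if (method == "sgd" && kernel != "linear") {
    stop("the subgradient route supports the linear kernel only")
  }
  structure(list(C = C, kernel = kernel, gamma = gamma, method = method,
                 steps = as.integer(steps), batch_fraction = batch_fraction,
                 lr = lr),
            class = "braking_svm_config")
}

#' Train the soft-margin SVM
#'
#' @param dataset a `braking_dataset` or list with `x` and `y` (+1/-1).
#' @param config a [svm_config()].
#' @param seed integer seed (used by the `"sgd"` route; the dual solver is
#'   deterministic).
#' @return an object of class `braking_svm` holding the fitted model and
#'   the score orientation (positive scores = braking intention).
#' @export
train_svm <- function(dataset, config = svm_config(), seed = 1) {
  stopifnot(inherits(config, "braking_svm_config"))
  x <- dataset$x; y <- dataset$y
  if (length(unique(y)) < 2L) {
    stop("degenerate_classes: training data contain a single class")
  }
  if (config$method == "solver") {
    gamma <- if (identical(config$gamma, "scale")) {
      v <- var(as.vector(x)); if (v <= 0) 1 else 1 / (ncol(x) * v)
    } else config$gamma
    fit <- e1071::svm(x = x, y = factor(y, levels = c(-1, 1)),
                      type = "C-classification",
                      kernel = if (config$kernel == "rbf") "radial"
                               else "linear",
                      cost = config$C, gamma = gamma, scale = FALSE)
    # libsvm orients decision values towards the first class seen in the
    # training data; normalise so positive = braking intention (+1)
    dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
    flip <- if (grepl("^-1", colnames(dv)[1])) -1 else 1
    model <- list(fit = fit, flip = flip, gamma = gamma)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, "svm/sgd"))
    n <- nrow(x); p <- ncol(x)
    w <- numeric(p); b <- 0
    nb <- max(2L, round(config$batch_fraction * n))
    for (step in seq_len(config$steps)) {
      idx <- sample.int(n, nb)
      margins <- drop(x[idx, , drop = FALSE] %*% w + b) * y[idx]
      coef <- y[idx] * as.numeric(margins < 1)
      gw <- w - config$C * colSums(coef * x[idx, , drop = FALSE])
      gb <- -config$C * sum(coef)
      eta <- config$lr / sqrt(step)
      w <- w - eta * gw
      b <- b - eta * gb
    }
    model <- list(w = w, b = b)
  }
  structure(list(model = model, config = config, seed = as.integer(seed),
                 p = ncol(x)),
            class = "braking_svm")
}

#' Predict braking intention with a trained SVM
#'
#' @param object a [train_svm()] model.
#' @param newdata feature matrix or `braking_dataset`.
#' @param ... unused.
#' @return numeric +1/-1 labels with attribute `scores` (signed distance to
#'   the separating hyperplane; positive = braking intention).
#' @export
predict.braking_svm <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "braking_dataset")) newdata$x else
    as.matrix(newdata)
  if (ncol(x) != object$p) {
    stop("dimension_mismatch: model expects ", object$p, " features, got ",
         ncol(x))
  }
  if (object$config$method == "solver") {
    pr <- predict(object$model$fit, x, decision.values = TRUE)
    scores <- object$model$flip *
      as.numeric(attr(pr, "decision.values"))
  } else {
    scores <- as.numeric(x %*% object$model$w + object$model$b)
  }
  labels <- ifelse(scores > 0, 1, -1)
  attr(labels, "scores") <- scores
  labels
}

#' @export
print.braking_svm <- function(x, ...) {
  cat(sprintf("Soft-margin SVM (%s kernel, C = %g, %s)\n",
              x$config$kernel, x$config$C,
              if (x$config$method == "solver") "exact dual solver"
              else "hinge subgradient descent"))
  if (x$config$method == "solver") {
    cat(sprintf("  support vectors: %d\n", nrow(x$model$fit$SV)))
  }
  invisible(x)
}

#' Classifier trainers for the evaluation protocols
#'
#' Thin adapters binding a configuration to a fitting function, so the
#' evaluation protocols can treat both classifiers uniformly.
#'
#' @param config classifier configuration.
#' @param record_history passed to [train_cnn()]; off by default inside the
#'   repeated-evaluation loops.
#' @return a `braking_trainer`: list with `name` and `fit(dataset, seed)`.
#' @export
trainer_cnn <- function(config = cnn_config(), record_history = FALSE) {
  structure(list(name = "cnn",
                 fit = function(dataset, seed)
                   train_cnn(dataset, config, seed,
                             record_history = record_history)),
            class = "braking_trainer")
}

#' @rdname trainer_cnn
#' @export
trainer_svm <- function(config = svm_config()) {
  structure(list(name = "svm",
                 fit = function(dataset, seed)
                   train_svm(dataset, config, seed)),
            class = "braking_trainer")
}
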