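#' Configuration of the braking-intention CNN
#'
#' The study architecture: two convolution/pooling stages (50 then 100
#' kernels of size 4 x 4, rectified-linear activations, non-overlapping
#' 2 x 2 max pooling) followed by a dense hidden layer of 100 sigmoid units
#' and a 2-unit soft-max output. Convolutions use SAME (zero) padding and
#' pooling uses ceiling-mode output sizes -- the unique standard convention
#' under which a 7 x 10 input produces 50 maps of 4 x 5 after stage one and
#' 100 maps of 2 x 3 after stage two (600 dense inputs). Inverted dropout
#' is applied at training time only; the default keeps 85% of the units on
#' both the pooled convolution stages and the dense hidden layer (a 15%
#' drop rate). A 15% *retention* rate on the convolution stages can be
#' configured instead, but empirically stalls learning at this network's
#' scale. Training is plain stochastic gradient descent on the
#' cross-entropy, 200 steps, each step sampling a batch of 20% of the
#' training data, learning rate 0.005.
#'
#' @param input input map size, `c(rows = electrodes, cols = intervals)`.
#' @param kernels kernels per stage.
#' @param kernel_size convolution kernel side.
#' @param hidden dense hidden width.
#' @param retention dropout retention rates `c(conv = , dense = )`;
#'   set both to 1 to disable dropout.
#' @param padding `"same"` (required for training/prediction) or `"valid"`
#'   (supported by [layer_shapes()] for convolution arithmetic only).
#' @param steps,lr,batch_fraction training-protocol parameters.
#' @return an object of class `braking_cnn_config`.
#' @export
cnn_config <- function(input = c(7, 10), kernels = c(50, 100),
                       kernel_size = 4, hidden = 100,
                       retention = c(conv = 0.85, dense = 0.85),
                       padding = c("same", "valid"),
                       steps = 200, lr = 0.005, batch_fraction = 0.2) {
  padding <- match.arg(padding)
  stopifnot(length(input) == 2, length(kernels) == 2,
            all(retention > 0), all(retention <= 1),
            steps >= 1, lr > 0, batch_fraction > 0, batch_fraction <= 1)
  structure(list(input = as.integer(input), kernels = as.integer(kernels),
                 kernel_size = as.integer(kernel_size),
                 hidden = as.integer(hidden),
                 retention = retention, padding = padding,
                 steps = as.integer(steps), lr = lr,
                 batch_fraction = batch_fraction),
            class = "braking_cnn_config")
}

#' Per-stage output shapes of the CNN
#'
#' Computes the (maps, rows, cols) shape after each convolution/pooling
#' stage analytically from the convolution arithmetic: SAME convolutions
#' preserve the spatial size and 2 x 2 pooling outputs `ceiling(size / 2)`;
#' VALID convolutions shrink by `kernel - 1` and pooling floors.
#'
#' @param config a [cnn_config()].
#' @return list of integer vectors `(maps, rows, cols)`, one per stage,
#'   with attribute `flat` = flattened dense input width.
#' @export
#' @examples
#' layer_shapes(cnn_config())  # (50, 4, 5), (100, 2, 3); flat 600
layer_shapes <- function(config = cnn_config()) {
  stopifnot(inherits(config, "braking_cnn_config"))
  h <- config$input[1]; w <- config$input[2]; k <- config$kernel_size
  shapes <- vector("list", length(config$kernels))
  for (s in seq_along(config$kernels)) {
    if (config$padding == "valid") {
      h <- h - k + 1L; w <- w - k + 1L
      if (h < 1L || w < 1L) stop("shape_underflow: stage ", s,
                                 " convolution output is empty")
      h <- h %/% 2L; w <- w %/% 2L
    } else {
      h <- as.integer(ceiling(h / 2)); w <- as.integer(ceiling(w / 2))
    }
    if (h < 1L || w < 1L) stop("shape_underflow: stage ", s,
                               " pooled output is empty")
    shapes[[s]] <- c(maps = config$kernels[s], rows = h, cols = w)
  }
  attr(shapes, "flat") <- as.integer(config$kernels[length(config$kernels)] *
                                       h * w)
  shapes
}

#' 2-D cross-correlation with SAME zero padding
#'
#' The convolution primitive of the network:
#' `S(i, j) = sum_m sum_n I(i + m, j + n) * K(m, n) + b`, evaluated with
#' zero-padded borders so the output has the input's size (for a kernel of
#' side `k`, `floor((k - 1) / 2)` leading and `ceiling((k - 1) / 2)`
#' trailing pad rows/columns).
#'
#' @param input numeric matrix.
#' @param kernel numeric `k x k` matrix.
#' @param bias scalar added to every output element.
#' @return matrix of the input's dimensions.
#' @export
conv2d_same <- function(input, kernel, bias = 0) {
  input <- as.matrix(input); kernel <- as.matrix(kernel)
  k <- nrow(kernel)
  stopifnot(ncol(kernel) == k)
  H <- nrow(input); W <- ncol(input)
  pad <- (k - 1) %/% 2
  if (k > H + 2 * pad || k > W + 2 * pad) {
    stop("kernel_too_large: kernel exceeds the padded input")
  }
  Hp <- H + k - 1; Wp <- W + k - 1
  P <- matrix(0, Hp, Wp)
  P[pad + seq_len(H), pad + seq_len(W)] <- input
  out <- matrix(bias, H, W)
  for (m in seq_len(k)) {
    for (n in seq_len(k)) {
      out <- out + kernel[m, n] * P[(m - 1) + seq_len(H),
                                    (n - 1) + seq_len(W)]
    }
  }
  out
}

.cnn_cpp_cfg <- function(config) {
  list(H = config$input[1], W = config$input[2], k = config$kernel_size,
       K1 = config$kernels[1], K2 = config$kernels[2],
       hidden = config$hidden,
       steps = config$steps, lr = config$lr,
       batch_fraction = config$batch_fraction,
       r_conv = unname(config$retention["conv"]),
       r_dense = unname(config$retention["dense"]))
}

.cnn_init_params <- function(config, seed) {
  k2 <- config$kernel_size^2
  shapes <- layer_shapes(config)
  flat <- attr(shapes, "flat")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "cnn/init"))
  init <- function(nr, nc, fan_in)
    matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  list(W1 = init(k2, config$kernels[1], k2),
       b1 = numeric(config$kernels[1]),
       W2 = init(config$kernels[1] * k2, config$kernels[2],
                 config$kernels[1] * k2),
       b2 = numeric(config$kernels[2]),
       Wd = init(flat, config$hidden, flat),
       bd = numeric(config$hidden),
       Wo = init(config$hidden, 2L, config$hidden),
       bo = numeric(2))
}

#' Train the braking-intention CNN
#'
#' Runs the full training protocol on a labelled dataset: random parameter
#' initialisation from the seed, then `steps` stochastic-gradient steps on
#' the softmax cross-entropy, each on a freshly sampled batch of
#' `batch_fraction` of the data, with inverted dropout at the configured
#' retention rates. When `record_history` is on, the remainder of the
#' training set is scored after every step (validation trace). Identical
#' seeds give bit-identical parameters.
#'
#' @param dataset a `braking_dataset` (balanced, both classes present) or a
#'   list with `x` (n x p matrix) and `y` (+1/-1).
#' @param config a [cnn_config()].
#' @param seed integer seed for initialisation, batches and dropout.
#' @param record_history record per-step loss and validation accuracy
#'   (costs one extra forward pass per step).
#' @return an object of class `braking_cnn` with `params`, `config`,
#'   `history` and the input dimension.
#' @export
train_cnn <- function(dataset, config = cnn_config(), seed = 1,
                      record_history = TRUE) {
  stopifnot(inherits(config, "braking_cnn_config"))
  if (config$padding != "same") {
    stop("training requires SAME padding; VALID is for shape arithmetic only")
  }
  x <- dataset$x; y <- dataset$y
  if (length(unique(y)) < 2L) {
    stop("degenerate_classes: training data contain a single class")
  }
  stopifnot(ncol(x) == prod(config$input))
  # standardise features (training statistics are stored in the model and
  # re-applied at prediction time); gradient descent on raw microvolt
  # magnitudes saturates the dense sigmoid layer
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd); scale_[scale_ == 0] <- 1
  x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  params0 <- .cnn_init_params(config, seed)
  fit <- .cnn_train_cpp(x, as.integer((y + 1) / 2), params0,
                        .cnn_cpp_cfg(config),
                        derive_seed(seed, "cnn/train"), record_history)
  history <- if (record_history) {
    data.frame(step = seq_along(fit$loss), loss = fit$loss,
               val_acc = fit$val_acc)
  } else NULL
  structure(list(params = fit$params, config = config, history = history,
                 center = center, scale = scale_,
                 seed = as.integer(seed), levels = c(-1, 1),
                 p = ncol(x)),
            class = "braking_cnn")
}

#' Predict braking intention with a trained CNN
#'
#' @param object a [train_cnn()] model.
#' @param newdata feature matrix (n x 70) or `braking_dataset`.
#' @param type `"class"` for +1/-1 labels, `"prob"` for the two-column
#'   soft-max output.
#' @param ... unused.
#' @return for `"class"`: numeric labels with attribute `scores` (the
#'   braking-intention class probability, usable as an ROC score); for
#'   `"prob"`: the n x 2 probability matrix (columns: normal driving,
#'   braking intention).
#' @export
predict.braking_cnn <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "braking_dataset")) newdata$x else
    as.matrix(newdata)
  if (ncol(x) != object$p) {
    stop("dimension_mismatch: model expects ", object$p, " features, got ",
         ncol(x))
  }
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  pr <- .cnn_predict_cpp(x, object$params, .cnn_cpp_cfg(object$config))
  colnames(pr) <- c("normal_driving", "braking_intention")
  if (type == "prob") return(pr)
  labels <- ifelse(pr[, 2] > pr[, 1], 1, -1)
  attr(labels, "scores") <- pr[, 2]
  labels
}

#' @export
print.braking_cnn <- function(x, ...) {
  sh <- layer_shapes(x$config)
  n_par <- sum(vapply(x$params, length, 0L))
  cat("Braking-intention CNN\n")
  cat(sprintf("  stage 1: %d kernels %dx%d -> %d maps of %dx%d\n",
              x$config$kernels[1], x$config$kernel_size,
              x$config$kernel_size, sh[[1]][1], sh[[1]][2], sh[[1]][3]))
  cat(sprintf("  stage 2: %d kernels -> %d maps of %dx%d\n",
              x$config$kernels[2], sh[[2]][1], sh[[2]][2], sh[[2]][3]))
  cat(sprintf("  dense: %d -> %d (sigmoid) -> 2 (soft-max); %d parameters\n",
              attr(sh, "flat"), x$config$hidden, n_par))
  if (!is.null(x$history)) {
    cat(sprintf("  final validation accuracy: %.1f%%\n",
                100 * tail(x$history$val_acc, 1)))
  }
  invisible(x)
}

#' Hidden-stage activations of the CNN (diagnostics)
#'
#' Exposes the forward-pass tensors so the shape contract and the
#' convolution arithmetic can be verified against the analytic
#' [layer_shapes()] and the [conv2d_same()] primitive.
#'
#' @param object a `braking_cnn`.
#' @param newdata feature matrix.
#' @return list with stage dimensions, pooled activations, the stage-1
#'   linear (pre-activation) maps, hidden activations and probabilities.
#' @export
cnn_activations <- function(object, newdata) {
  x <- if (inherits(newdata, "braking_dataset")) newdata$x else
    as.matrix(newdata)
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  .cnn_activations_cpp(x, object$params, .cnn_cpp_cfg(object$config))
}
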