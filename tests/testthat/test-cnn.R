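test_that("layer shapes reproduce the published stage dimensions", {
  sh <- layer_shapes(cnn_config())
  expect_equal(unname(sh[[1]]), c(50, 4, 5))
  expect_equal(unname(sh[[2]]), c(100, 2, 3))
  expect_equal(attr(sh, "flat"), 600L)
})

test_that("VALID padding shrinks stage one to 2 x 3, so SAME is required", {
  # convolution arithmetic: a 7 x 10 input under VALID padding leaves
  # (7-4+1) x (10-4+1) = 4 x 7 maps, floored by 2 x 2 pooling to 2 x 3 --
  # not the published 4 x 5, which only SAME padding reproduces
  conv_valid <- function(hw, k) hw - k + 1
  pool_floor <- function(hw) hw %/% 2
  expect_equal(pool_floor(conv_valid(c(7, 10), 4)), c(2, 3))
  # the full two-stage network underflows entirely under VALID padding
  expect_error(layer_shapes(cnn_config(padding = "valid")),
               "shape_underflow")
  # a larger canvas survives both VALID stages with the floored sizes
  sh <- layer_shapes(cnn_config(input = c(16, 18), padding = "valid"))
  expect_equal(unname(sh[[1]]), c(50, 6, 7))
  expect_equal(unname(sh[[2]]), c(100, 1, 2))
})

test_that("the forward pass realises the analytic shapes", {
  ds <- toy_signed_dataset(n = 20)
  m <- train_cnn(ds, cnn_config(steps = 2), seed = 1,
                 record_history = FALSE)
  act <- cnn_activations(m, ds$x[1:3, ])
  sh <- layer_shapes(m$config)
  expect_equal(act$stage1_dims, unname(sh[[1]]))
  expect_equal(act$stage2_dims, unname(sh[[2]]))
  expect_equal(ncol(act$pool1), prod(sh[[1]]))
  expect_equal(ncol(act$pool2), prod(sh[[2]]))
  expect_equal(dim(act$probs), c(3L, 2L))
  # a non-default kernel count still honours the contract
  cfg <- cnn_config(kernels = c(8, 12), hidden = 10, steps = 2)
  m2 <- train_cnn(ds, cfg, seed = 1, record_history = FALSE)
  act2 <- cnn_activations(m2, ds$x[1:2, ])
  sh2 <- layer_shapes(cfg)
  expect_equal(ncol(act2$pool1), prod(sh2[[1]]))
  expect_equal(ncol(act2$pool2), prod(sh2[[2]]))
})

test_that("conv2d_same: identity kernel and pure-bias kernel", {
  x <- matrix(rnorm(70), 7, 10)
  k_id <- matrix(0, 4, 4); k_id[2, 2] <- 1  # anchor under SAME padding 1
  expect_equal(conv2d_same(x, k_id, 0), x)
  expect_equal(conv2d_same(x, matrix(0, 4, 4), 3.5),
               matrix(3.5, 7, 10))
})

test_that("conv2d_same agrees exactly with a quadruple-loop oracle", {
  quadruple_loop <- function(input, kernel, bias) {
    k <- nrow(kernel); H <- nrow(input); W <- ncol(input)
    pad <- (k - 1) %/% 2
    out <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) {
      acc <- bias
      for (m in 1:k) for (n in 1:k) {
        ii <- i + m - 1 - pad; jj <- j + n - 1 - pad
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
          acc <- acc + input[ii, jj] * kernel[m, n]
        }
      }
      out[i, j] <- acc
    }
    out
  }
  set.seed(33)
  for (rep in 1:10) {
    x <- matrix(rnorm(70), 7, 10)
    k <- matrix(rnorm(16), 4, 4)
    b <- rnorm(1)
    expect_equal(conv2d_same(x, k, b), quadruple_loop(x, k, b),
                 tolerance = 1e-12)
  }
  # documented border example: all-ones 2 x 2 kernel on a 2 x 2 input
  x <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(conv2d_same(x, matrix(1, 2, 2), 0),
               quadruple_loop(x, matrix(1, 2, 2), 0))
})

test_that("the network's stage-1 maps equal the conv2d_same oracle", {
  ds <- toy_signed_dataset(n = 20)
  m <- train_cnn(ds, cnn_config(steps = 1), seed = 4,
                 record_history = FALSE)
  x <- ds$x[1, , drop = FALSE]
  act <- cnn_activations(m, x)
  xs <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
  input_map <- matrix(xs, 7, 10, byrow = TRUE)
  for (ko in c(1, 17, 50)) {
    kernel <- matrix(m$params$W1[, ko], 4, 4)  # column-major patch layout
    oracle <- conv2d_same(input_map, kernel, m$params$b1[ko])
    got <- matrix(act$conv1_pre[, ko], 7, 10)  # position p = i + (j-1)*7
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("training is deterministic per seed", {
  ds <- toy_signed_dataset(n = 40)
  m1 <- train_cnn(ds, cnn_config(steps = 20), seed = 6)
  m2 <- train_cnn(ds, cnn_config(steps = 20), seed = 6)
  m3 <- train_cnn(ds, cnn_config(steps = 20), seed = 7)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, ds$x), predict(m2, ds$x))
  expect_false(identical(m1$params$W1, m3$params$W1))
})

test_that("soft-max outputs are probabilities", {
  ds <- toy_signed_dataset(n = 30)
  m <- train_cnn(ds, cnn_config(steps = 5), seed = 2,
                 record_history = FALSE)
  pr <- predict(m, ds$x, type = "prob")
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-9)
  lab <- predict(m, ds$x)
  expect_true(all(lab %in% c(-1, 1)))
  expect_true(all(attr(lab, "scores") >= 0 & attr(lab, "scores") <= 1))
})

test_that("a separable problem is learned to >= 95% training accuracy", {
  toy <- toy_separable(n = 200, shift = 1.5)
  # independent separability oracle: nearest class centroid
  mu_pos <- colMeans(toy$x[toy$y == 1, ])
  mu_neg <- colMeans(toy$x[toy$y == -1, ])
  d_pos <- rowSums(sweep(toy$x, 2, mu_pos)^2)
  d_neg <- rowSums(sweep(toy$x, 2, mu_neg)^2)
  centroid_acc <- mean(ifelse(d_pos < d_neg, 1, -1) == toy$y)
  expect_gte(centroid_acc, 0.95)
  m <- train_cnn(toy, seed = 1)
  expect_gte(mean(predict(m, toy$x) == toy$y), 0.95)
  # the per-step validation trace was recorded
  expect_equal(nrow(m$history), 200)
  expect_gte(tail(m$history$val_acc, 1), 0.9)
})

test_that("degenerate and malformed inputs raise named errors", {
  x <- matrix(rnorm(10 * 70), 10, 70)
  expect_error(train_cnn(list(x = x, y = rep(1, 10)), seed = 1),
               "degenerate_classes")
  ds <- toy_signed_dataset(n = 20)
  m <- train_cnn(ds, cnn_config(steps = 2), seed = 1,
                 record_history = FALSE)
  expect_error(predict(m, matrix(0, 2, 69)), "dimension_mismatch")
})

test_that("swapping the output columns flips every label", {
  ds <- toy_signed_dataset(n = 40)
  m <- train_cnn(ds, cnn_config(steps = 30), seed = 3,
                 record_history = FALSE)
  flipped <- m
  flipped$params$Wo <- m$params$Wo[, c(2, 1)]
  flipped$params$bo <- m$params$bo[c(2, 1)]
  expect_equal(unclass(predict(flipped, ds$x)),
               unclass(-predict(m, ds$x)), ignore_attr = TRUE)
})
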