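# Shared fixtures: small synthetic worlds built once per test run.
# Everything is generated in code from fixed seeds; nothing is stored on disk.

.world_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .world_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .world_cache)
  }
  get(name, envir = .world_cache)
}

# one short session (2 blocks x 15 events) with the default planted signal
small_session <- function() {
  cached("small_session", {
    d <- make_design(seed = 1, n_sessions = 1, blocks_per_session = 2,
                     events_per_block = 15)
    simulate_session(d, brt_model(), signal_model(), "p01", 1, seed = 7)
  })
}

small_pre <- function() {
  cached("small_pre", preprocess_session(small_session()))
}

small_epochs <- function() {
  cached("small_epochs", {
    pre <- small_pre()
    extract_epochs(pre$recording, pre$segments)
  })
}

small_dataset <- function() {
  cached("small_dataset", build_dataset(small_epochs()))
}

# a session with every planted component silenced and no EEG noise removed:
# pure 1/f EEG, baseline EMG only
null_session <- function() {
  cached("null_session", {
    d <- make_design(seed = 2, n_sessions = 1, blocks_per_session = 2,
                     events_per_block = 15)
    sm <- signal_model(pre_movement = list(amplitude = 0),
                       erp_visual = list(amplitude = 0))
    simulate_session(d, brt_model(), sm, "p01", 1, seed = 11)
  })
}

null_dataset <- function(seed = 11) {
  cached(paste0("null_dataset_", seed), {
    d <- make_design(seed = 2, n_sessions = 1, blocks_per_session = 2,
                     events_per_block = 15)
    sm <- signal_model(pre_movement = list(amplitude = 0),
                       erp_visual = list(amplitude = 0))
    s <- simulate_session(d, brt_model(), sm, "p01", 1, seed = seed)
    pre <- preprocess_session(s)
    build_dataset(extract_epochs(pre$recording, pre$segments))
  })
}

# linearly separable 70-dimensional toy problem (two shifted Gaussians)
toy_separable <- function(n = 200, shift = 1.5, seed = 42) {
  set.seed(seed)
  mu <- rep(c(1, -1), each = 35) * shift
  x <- rbind(matrix(rnorm(n / 2 * 70, rep(mu, each = n / 2)), n / 2, 70),
             matrix(rnorm(n / 2 * 70, rep(-mu, each = n / 2)), n / 2, 70))
  list(x = x, y = rep(c(1, -1), each = n / 2))
}

# a synthetic recording holding externally supplied channels, for filter and
# detection tests with analytically known content
toy_recording <- function(eeg, emg = NULL, light = NULL, brake = NULL,
                          fs = 250) {
  T <- ncol(eeg)
  structure(list(eeg = eeg,
                 emg = if (is.null(emg)) numeric(T) else emg,
                 light = if (is.null(light)) numeric(T) else light,
                 brake = if (is.null(brake)) numeric(T) else brake,
                 fs = fs, truth = NULL, block_intervals = NULL,
                 participant_id = "toy", session_id = 1L,
                 filtered = c(eeg = FALSE, emg = FALSE, car = FALSE)),
            class = "braking_recording")
}

# always-correct and coin-flip trainers for evaluation-protocol tests
trainer_perfect <- function() {
  structure(list(name = "oracle",
                 fit = function(dataset, seed) {
                   model <- structure(list(), class = "perfect_clf")
                   model
                 }),
            class = "braking_trainer")
}

predict.perfect_clf <- function(object, newdata, ...) {
  # recovers the label planted in the first feature's sign
  labels <- ifelse(newdata[, 1] > 0, 1, -1)
  attr(labels, "scores") <- newdata[, 1]
  labels
}
registerS3method("predict", "perfect_clf", predict.perfect_clf)

trainer_coin <- function() {
  structure(list(name = "coin",
                 fit = function(dataset, seed) {
                   structure(list(seed = seed), class = "coin_clf")
                 }),
            class = "braking_trainer")
}

predict.coin_clf <- function(object, newdata, ...) {
  set.seed(object$seed)
  labels <- sample(c(-1, 1), nrow(newdata), replace = TRUE)
  attr(labels, "scores") <- runif(nrow(newdata))
  labels
}
registerS3method("predict", "coin_clf", predict.coin_clf)

# dataset whose labels live in the sign of feature 1 (for trainer_perfect)
toy_signed_dataset <- function(n = 80, seed = 5) {
  set.seed(seed)
  x <- matrix(rnorm(n * 70), n, 70)
  y <- ifelse(x[, 1] > 0, 1, -1)
  # force balance by construction
  k <- min(sum(y == 1), sum(y == -1))
  idx <- c(which(y == 1)[seq_len(k)], which(y == -1)[seq_len(k)])
  structure(list(x = x[idx, ], y = y[idx],
                 meta = data.frame(participant = "toy", session = 1L,
                                   event = seq_along(idx),
                                   kind = ifelse(y[idx] == 1, "pre_response",
                                                 "non_braking"))),
            class = "braking_dataset")
}
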