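# Shared fixtures and independent oracles used across the suite.

noiseless_cfg <- function(seed, n_strides = 16, ...) {
  sim_config(n_strides = n_strides, noise_sd_accel = 0, noise_sd_force = 0,
             noise_sd_gyro = 0, seed = seed, ...)
}

test_profile <- function(seed, pattern = NULL) {
  subject_profile(sprintf("T%03d", seed), mass = 60,
                  strike_pattern = pattern %||%
                    (if (seed %% 2) "RFS" else "FFS"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive-search oracle: integer offset minimizing the mean squared
# duration difference over the overlap (overlap >= min_overlap).
oracle_offset <- function(x, y, min_overlap = 3) {
  best <- NULL; best_err <- Inf
  for (o in (-(length(x) - min_overlap)):(length(y) - min_overlap)) {
    i <- seq(max(1, 1 - o), min(length(x), length(y) - o))
    if (length(i) < min_overlap) next
    err <- mean((x[i] - y[i + o])^2)
    if (err < best_err) { best_err <- err; best <- o }
  }
  best
}

# Straight-line scalar re-implementation of the forward pass.
oracle_forward <- function(model, x) {
  act <- switch(model$activation,
                morlet = function(u) exp(-u^2 / 2) * cos(5 * u),
                sigmoid = function(u) 1 / (1 + exp(-u)))
  z <- numeric(model$K)
  for (k in seq_len(model$K)) {
    s <- 0
    for (i in seq_along(x)) s <- s + model$W_hidden[k, i] * x[i]
    z[k] <- act((s - model$b_shift[k]) / model$a_scale[k])
  }
  y <- numeric(101)
  for (i in 1:101) {
    acc <- 0
    for (k in seq_len(model$K)) acc <- acc + model$W_out[i, k] * z[k]
    y[i] <- acc - model$b_out[i]
  }
  y
}

# Central finite-difference gradient at sampled parameter positions.
check_gradients <- function(model, X, Y, lambda, n_check = 20, h = 1e-5) {
  g <- vgrf_grad(model, X, Y, lambda)
  worst <- 0
  params <- c("W_hidden", "b_shift", "a_scale", "W_out", "b_out")
  for (p in params) {
    idx <- sample(length(model[[p]]), min(n_check, length(model[[p]])))
    for (i in idx) {
      mp <- model; mp[[p]][i] <- mp[[p]][i] + h
      mm <- model; mm[[p]][i] <- mm[[p]][i] - h
      fd <- (vgrf_loss(mp, X, Y, lambda) - vgrf_loss(mm, X, Y, lambda)) / (2 * h)
      rel <- abs(fd - g[[p]][i]) / max(abs(fd), abs(g[[p]][i]), 1e-8)
      worst <- max(worst, rel)
    }
  }
  worst
}

# Detect both streams' toe-offs for a generated trial.
trial_events <- function(trial, cfg = event_config()) {
  list(imu = detect_toeoff_imu(trial$imu$gyro[, "coronal"], trial$imu$rate, cfg),
       force = detect_events_force(trial$force$vgrf, trial$force$rate,
                                   cfg$threshold_n, cfg))
}
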