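# Shared fixtures, built once per test run and memoized. The heavy
# study-scale objects (training corpus, fitted detector, closed-loop trials)
# are produced on first use by the acceptance tests.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# Analytic rigidly rotating pinwheel movie: V = cos(atan2(y - y0, x - x0) -
# w t), the canonical single-spiral test pattern.
pinwheel_movie <- function(n = 40, center = c(n / 2 + 0.5, n / 2 + 0.5),
                           n_frames = 30, omega = 2 * pi / 20,
                           chirality = 1) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ang <- atan2(rows - center[1], chirality * (cols - center[2]))
  fr <- array(0, c(n, n, n_frames))
  for (t in seq_len(n_frames)) fr[, , t] <- cos(ang - omega * t)
  voltage_movie(fr, frame_interval_ms = 6, spacing_um = 100)
}

# Random band-limited smooth phase field (no invalid nodes): argument of a
# sum of a few random plane waves plus a constant offset to avoid exact
# zeros.
random_phase_field <- function(n = 24, k_max = 3, seed = 1) {
  set.seed(seed)
  rows <- matrix(seq_len(n), n, n) / n
  cols <- matrix(seq_len(n), n, n, byrow = TRUE) / n
  z <- matrix(0.1 + 0i, n, n)
  for (i in 1:4) {
    kx <- sample(-k_max:k_max, 1); ky <- sample(-k_max:k_max, 1)
    amp <- stats::rnorm(1); ph <- stats::runif(1, 0, 2 * pi)
    z <- z + amp * exp(2i * pi * (kx * cols + ky * rows) + 1i * ph)
  }
  Arg(z)
}

# The desk-scale generator configuration shared by the heavy tests.
desk_config <- function() memo("desk_config", generator_config("desk"))

# Study-scale corpus (50 accepted base simulations, 400 windows) and the
# detector trained on it for 20 epochs.
acceptance_corpus <- function() memo("corpus",
  build_corpus(n_base = 50, seed = 11, config = desk_config(),
               windows_per_base = 1))

acceptance_fit <- function() memo("fit",
  core_cnn(acceptance_corpus(), train = train_config(epochs = 20, seed = 1)))

# Paired closed-loop trials (control ON vs OFF) over spiral fixtures drawn
# from the accepted corpus samples' final states.
# ON runs get a horizon long enough for three full pulse cycles (trigger,
# 3 s settle, 0.5 s pulse, 3 s blanking each); OFF runs cover the 5 s
# comparison horizon.
acceptance_loop_trials <- function(n_fixtures = 20, horizon_on_s = 20,
                                   horizon_off_s = 5) {
  memo("loop_trials", {
    corpus <- acceptance_corpus()
    fit <- acceptance_fit()
    cfg <- desk_config()
    samples <- corpus$samples[seq_len(min(n_fixtures, length(corpus$samples)))]
    lapply(samples, function(s) {
      rig <- virtual_rig(cfg$domain, s$het, cfg$model, s$final_state,
                         dt_ms = cfg$dt_ms)
      on <- run_closed_loop(rig, fit, seed = s$seed, control = TRUE,
                            horizon_s = horizon_on_s)
      off <- run_closed_loop(rig, fit, seed = s$seed, control = FALSE,
                             horizon_s = horizon_off_s)
      list(seed = s$seed, on = on, off = off)
    })
  })
}
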