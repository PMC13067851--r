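#' Sample characterization: conduction velocity, APD, spiral frequency
#'
#' `measure_cv` regresses activation time against distance along a probe line
#' (default: the middle row) and returns the conduction velocity in mm/s.
#' Activation is the upward crossing of the 50% level between the movie's
#' global minimum and maximum, with linear sub-frame interpolation.
#'
#' @param movie a [voltage_movie()].
#' @param probe_row row index of the probe line (default: middle).
#' @param cols optional column range to restrict the fit to.
#' @param min_points minimum activated probe points for a defined measurement.
#' @return conduction velocity, mm/s.
#' @export
measure_cv <- function(movie, probe_row = NULL, cols = NULL, min_points = 10) {
  fr <- movie$frames
  d <- dim(fr)
  if (is.null(probe_row)) probe_row <- round(d[1] / 2)
  level <- robust_level(fr)
  line <- fr[probe_row, , , drop = TRUE]          # [cols, T]
  act <- crossing_times(line, level)              # frames, fractional
  if (is.null(cols)) cols <- seq_len(d[2])
  sel <- cols[!is.na(act[cols])]
  if (length(sel) < min_points)
    stop("measurement undefined: no propagating wave crosses the probe line")
  x_mm <- sel * movie$spacing_um / 1000
  t_ms <- act[sel] * movie$frame_interval_ms
  fit <- stats::lm(x_mm ~ t_ms)
  cv <- abs(stats::coef(fit)[["t_ms"]]) * 1000    # mm/s
  if (!is.finite(cv) || cv <= 0)
    stop("measurement undefined: degenerate activation profile")
  cv
}

# first upward crossing per row of a [points, T] matrix, NA if none
crossing_times <- function(m, level) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  apply(m, 1, function(x) {
    up <- which(x[-length(x)] < level & x[-1] >= level)
    if (!length(up)) return(NA_real_)
    i <- up[1]
    i + (level - x[i]) / (x[i + 1] - x[i])
  })
}

#' @rdname measure_cv
#' @param trace single-node voltage trace (numeric vector, mV).
#' @param dt_ms sample interval of the trace, ms.
#' @param level repolarization level (default 0.8 = APD80).
#' @param min_amplitude_mv minimum AP amplitude for a defined measurement.
#' @export
measure_apd <- function(trace, dt_ms, level = 0.8, min_amplitude_mv = 20) {
  baseline <- min(trace); peak <- max(trace)
  if (peak - baseline < min_amplitude_mv)
    stop("measurement undefined: no action potential in trace")
  thr_act <- baseline + 0.1 * (peak - baseline)
  thr_rep <- peak - level * (peak - baseline)
  up <- which(trace[-length(trace)] < thr_act & trace[-1] >= thr_act)
  if (!length(up)) stop("measurement undefined: no upstroke found")
  i0 <- up[1]
  t_act <- i0 + (thr_act - trace[i0]) / (trace[i0 + 1] - trace[i0])
  ipk <- which.max(trace[i0:length(trace)]) + i0 - 1
  after <- which(trace[-length(trace)] >= thr_rep & trace[-1] < thr_rep)
  after <- after[after >= ipk]
  if (!length(after)) stop("measurement undefined: no full repolarization")
  j <- after[1]
  t_rep <- j + (trace[j] - thr_rep) / (trace[j] - trace[j + 1])
  (t_rep - t_act) * dt_ms
}

#' @rdname measure_cv
#' @param n_probes number of probe points (placed on a small ring around the
#'   domain center).
#' @export
measure_spiral_frequency <- function(movie, n_probes = 5) {
  fr <- movie$frames
  d <- dim(fr)
  level <- robust_level(fr)
  ang <- 2 * pi * seq_len(n_probes) / n_probes
  r <- round(min(d[1], d[2]) / 6)
  rows <- pmin(pmax(round(d[1] / 2 + r * sin(ang)), 1), d[1])
  cols <- pmin(pmax(round(d[2] / 2 + r * cos(ang)), 1), d[2])
  iv <- unlist(lapply(seq_len(n_probes), function(i) {
    x <- fr[rows[i], cols[i], ]
    up <- which(x[-length(x)] < level & x[-1] >= level)
    if (length(up) >= 3) diff(up) else numeric(0)
  }))
  if (!length(iv))
    stop("measurement undefined: fewer than two rotations at every probe")
  1000 / (stats::median(iv) * movie$frame_interval_ms)
}

#' Classify a simulated sample
#'
#' Deterministic label used to filter the synthetic training corpus:
#' `propagation_failure` when no wave ever activates a meaningful fraction of
#' the tissue, `sustained_spiral` when a phase singularity persists through
#' the final part of the recording while the tissue is still active, and
#' `no_sustained_spiral` otherwise (e.g. a single wave that expands and
#' dies out).
#'
#' @param movie a [voltage_movie()].
#' @param thresholds list: `min_range_mv` (global signal range below which the
#'   movie counts as quiescent), `prop_frac` (fraction of pixels that must
#'   ever activate), `tail_frac` (final fraction of frames inspected),
#'   `persist_frac` (fraction of tail frames that must contain a phase
#'   singularity).
#' @return character label, with attributes `ps_tail_frac` and `core` (the
#'   consensus core over the tail, when one exists).
#' @export
classify_sample <- function(movie,
                            thresholds = list(min_range_mv = 20,
                                              prop_frac = 0.3,
                                              tail_frac = 0.5,
                                              persist_frac = 0.8)) {
  fr <- movie$frames
  d <- dim(fr)
  rng <- diff(range(fr))
  if (rng < thresholds$min_range_mv) return("propagation_failure")
  level <- robust_level(fr)
  flat <- matrix(fr, d[1] * d[2], d[3])
  ever_active <- mean(rowSums(flat >= level) > 0)
  if (ever_active < thresholds$prop_frac) return("propagation_failure")

  pm <- compute_phase(movie)
  ps <- detect_ps(pm)
  Tn <- dim(pm$theta)[3]
  tail_start <- ceiling((1 - thresholds$tail_frac) * Tn) + 1
  tail_frames <- tail_start:Tn
  with_ps <- length(intersect(unique(ps$frame), tail_frames)) / length(tail_frames)
  active_end <- any(fr[, , max(1, d[3] - 4):d[3]] >= level)
  label <- if (with_ps >= thresholds$persist_frac && active_end)
    "sustained_spiral" else "no_sustained_spiral"
  core <- if (label == "sustained_spiral")
    consensus_core(ps[ps$frame >= tail_start, ], n_frames = Tn) else NULL
  structure(label, ps_tail_frac = with_ps, core = core)
}

# Half-way activation level between robust quantiles; immune to brief
# stimulus-artifact overshoots in the recording.
robust_level <- function(fr) {
  q <- stats::quantile(fr, c(0.001, 0.999), names = FALSE)
  q[1] + 0.5 * (q[2] - q[1])
}
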