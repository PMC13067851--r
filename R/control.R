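#' Streaming preprocessing of camera frame packs
#'
#' Mirrors the acquisition pipeline of the real-time mapping software: packs
#' of five raw 100 x 100 frames arrive at a fixed interval; the last frame of
#' the previous pack is subtracted from every frame (a high-pass that keeps
#' only dynamic changes), a 3 x 3 Gaussian low-pass suppresses noise, the
#' frames are center-cropped to 86 x 86 to match the detector input, and the
#' window is scaled to unit peak amplitude. The pack's own last raw frame is
#' returned as the background for the next pack.
#'
#' @param pack numeric array \[100, 100, 5\] of raw camera frames.
#' @param background background frame from the previous pack; `NULL` for the
#'   first pack (zeros are used and the result is flagged `warmup`).
#' @param crop_size detector input side (86).
#' @return list with `window` (\[86, 86, 5\]), `background` (raw last frame),
#'   `amplitude` (pre-normalization peak absolute value) and `warmup`.
#' @export
preprocess_pack <- function(pack, background = NULL, crop_size = 86) {
  d <- dim(pack)
  if (length(d) != 3 || d[3] != 5 || d[1] != d[2])
    stop("pack must be a square H x H x 5 array")
  warmup <- is.null(background)
  if (warmup) background <- matrix(0, d[1], d[2])
  win <- array(0, c(crop_size, crop_size, 5))
  for (t in 1:5)
    win[, , t] <- center_crop(gaussian3(pack[, , t] - background), crop_size)
  amp <- max(abs(win))
  if (amp > 0) win <- win / amp
  list(window = win, background = pack[, , 5], amplitude = amp,
       warmup = warmup)
}

#' Core-location histogram and trigger rule
#'
#' The stabilization stage of the decision layer: the argmax coordinate and
#' maximum value of each core-probability map are pushed into a sliding
#' buffer of the last 10 frames. Once the buffer is full and the mean of the
#' 10 maxima exceeds 0.7 (strictly), the modal coordinate of the buffer is
#' returned as the consolidated core location; ties between equally frequent
#' coordinates are resolved in favour of the most recently seen one (the
#' current position of a drifting rotor).
#'
#' @param n buffer length (10 frames).
#' @param threshold trigger threshold on the mean of the buffered maxima.
#' @return `core_histogram` object.
#' @export
core_histogram <- function(n = 10, threshold = 0.7) {
  structure(list(n = n, threshold = threshold,
                 rows = integer(0), cols = integer(0), maxs = numeric(0),
                 dropped = 0L),
            class = "core_histogram")
}

#' @rdname core_histogram
#' @param hist a `core_histogram`.
#' @param prob_map core-probability map in \[0, 1\] (86 x 86).
#' @return list with the updated `hist` and `decision` (`NULL` or
#'   `c(row, col)`).
#' @export
update_and_decide <- function(hist, prob_map) {
  if (anyNA(prob_map) || any(!is.finite(prob_map))) {
    hist$dropped <- hist$dropped + 1L
    return(list(hist = hist, decision = NULL))
  }
  am <- arrayInd(which.max(prob_map), dim(prob_map))
  hist$rows <- c(hist$rows, am[1]); hist$cols <- c(hist$cols, am[2])
  hist$maxs <- c(hist$maxs, max(prob_map))
  if (length(hist$maxs) > hist$n) {
    keep <- seq.int(length(hist$maxs) - hist$n + 1, length(hist$maxs))
    hist$rows <- hist$rows[keep]; hist$cols <- hist$cols[keep]
    hist$maxs <- hist$maxs[keep]
  }
  decision <- NULL
  if (length(hist$maxs) == hist$n && mean(hist$maxs) > hist$threshold) {
    key <- paste(hist$rows, hist$cols)
    cnt <- table(key)
    modal <- names(cnt)[cnt == max(cnt)]
    if (length(modal) > 1) {                  # most recent occupant wins
      last_seen <- vapply(modal, function(k) max(which(key == k)), numeric(1))
      modal <- modal[which.max(last_seen)]
    }
    i <- max(which(key == modal))
    decision <- c(row = hist$rows[i], col = hist$cols[i])
  }
  list(hist = hist, decision = decision)
}

#' Light line from the detected core to the nearest boundary
#'
#' Builds the termination pattern: a straight rasterized segment from the
#' core to the nearest non-conducting pixel (by Euclidean distance; ties
#' broken by the smallest angle from the +x axis), optionally inflated to a
#' width and dotted at a pixel pitch.
#'
#' @param core `c(row, col)` inside the mask.
#' @param mask logical matrix of conducting pixels (camera/crop raster).
#' @param width line width in pixels (odd widths center on the path).
#' @param dot_pitch keep every `dot_pitch`-th pixel along the path
#'   (`NULL` = solid line).
#' @param overshoot_px extend the segment this many pixels beyond the core,
#'   away from the border, so the line covers the rotor's tip orbit (a
#'   consolidated core is the orbit center, and a line ending exactly there
#'   lets the rotor pivot around the line's end).
#' @return data.frame with `row`, `col` of lit pixels (8-connected path
#'   before inflation).
#' @export
nearest_border_line <- function(core, mask, width = 1, dot_pitch = NULL,
                                overshoot_px = 0) {
  core <- round(core)
  if (core[1] < 1 || core[1] > nrow(mask) || core[2] < 1 ||
      core[2] > ncol(mask) || !mask[core[1], core[2]])
    stop("core must lie inside the conducting mask")
  out <- which(!mask, arr.ind = TRUE)
  if (nrow(out) == 0) {                # mask covers everything: use frame edge
    edge <- rbind(cbind(0, seq_len(ncol(mask))),
                  cbind(nrow(mask) + 1, seq_len(ncol(mask))),
                  cbind(seq_len(nrow(mask)), 0),
                  cbind(seq_len(nrow(mask)), ncol(mask) + 1))
    out <- edge
  }
  dr <- out[, 1] - core[1]; dc <- out[, 2] - core[2]
  d2 <- dr^2 + dc^2
  best <- which(d2 == min(d2))
  if (length(best) > 1) {              # smallest angle from the +x (col) axis
    ang <- atan2(dr[best], dc[best]) %% (2 * pi)
    best <- best[which.min(ang)]
  }
  target <- out[best, ]
  start <- core
  if (overshoot_px > 0) {
    v <- core - target
    nv <- sqrt(sum(v^2))
    if (nv > 0) {
      start <- round(core + v / nv * overshoot_px)
      start[1] <- min(max(start[1], 1), nrow(mask))
      start[2] <- min(max(start[2], 1), ncol(mask))
    }
  }
  path <- bresenham(start[1], start[2], target[1], target[2])
  if (!is.null(dot_pitch) && dot_pitch > 1)
    path <- path[seq(1, nrow(path), by = dot_pitch), , drop = FALSE]
  if (width > 1) {
    r <- floor(width / 2)
    off <- expand.grid(dr = -r:r, dc = -r:r)
    off <- off[off$dr^2 + off$dc^2 <= r^2 + 0.1, ]
    path <- unique(data.frame(
      row = rep(path[, 1], each = nrow(off)) + off$dr,
      col = rep(path[, 2], each = nrow(off)) + off$dc))
    path <- path[path$row >= 1 & path$row <= nrow(mask) &
                 path$col >= 1 & path$col <= ncol(mask), ]
    return(path)
  }
  data.frame(row = path[, 1], col = path[, 2])
}

# Integer line rasterization (Bresenham), endpoints included, 8-connected.
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  if (sr == 0) sr <- 1L
  if (sc == 0) sc <- 1L
  err <- dc - dr
  r <- r0; c <- c0
  pts <- matrix(0L, dr + dc + 1, 2)
  k <- 0L
  repeat {
    k <- k + 1L
    pts[k, ] <- c(r, c)
    if (r == r1 && c == c1) break
    e2 <- 2 * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  pts[seq_len(k), , drop = FALSE]
}

#' Multi-well partition of the detector output
#'
#' Splits the probability map into rectangular zones (one per culture well)
#' and applies the stabilization/trigger rule independently in each enabled
#' zone, with a separate core histogram per well. Disabled wells always
#' report no core.
#'
#' @param layout list of wells, each `list(id, rows = c(r1, r2),
#'   cols = c(c1, c2), enabled = TRUE)`; zones must be disjoint.
#' @return a `well_partition` state object.
#' @export
well_partition <- function(layout) {
  occ <- list()
  for (w in layout) {
    stopifnot(!is.null(w$rows), !is.null(w$cols))
    for (v in occ)
      if (w$rows[1] <= v$rows[2] && v$rows[1] <= w$rows[2] &&
          w$cols[1] <= v$cols[2] && v$cols[1] <= w$cols[2])
        stop("config error: well zones overlap")
    occ <- c(occ, list(w))
  }
  structure(list(layout = layout,
                 hists = lapply(layout, function(w) core_histogram())),
            class = "well_partition")
}

#' @rdname well_partition
#' @param state a `well_partition`.
#' @param prob_map full-frame probability map.
#' @return list with updated `state` and `decisions` (named list, one entry
#'   per well: `NULL` or `c(row, col)` in full-frame coordinates).
#' @export
partition_wells <- function(state, prob_map) {
  decisions <- stats::setNames(vector("list", length(state$layout)),
                               vapply(state$layout, function(w)
                                 as.character(w$id), character(1)))
  for (i in seq_along(state$layout)) {
    w <- state$layout[[i]]
    if (!isTRUE(w$enabled %||% TRUE)) next
    sub <- prob_map[w$rows[1]:w$rows[2], w$cols[1]:w$cols[2]]
    res <- update_and_decide(state$hists[[i]], sub)
    state$hists[[i]] <- res$hist
    if (!is.null(res$decision))
      decisions[[i]] <- res$decision + c(w$rows[1], w$cols[1]) - 1
  }
  list(state = state, decisions = decisions)
}

#' Timing policy of the termination loop
#'
#' After a trigger the system waits `settle_ms` for the reentry to stabilize,
#' displays the light pattern for `pulse_ms`, then blanks detections for
#' `blank_ms` to let residual effects of the light decay before re-arming.
#'
#' @param settle_ms,pulse_ms,blank_ms durations in ms (defaults 3000 / 500 /
#'   3000).
#' @export
timing_policy <- function(settle_ms = 3000, pulse_ms = 500, blank_ms = 3000) {
  if (pulse_ms <= 0) stop("config error: pulse duration must be positive")
  if (settle_ms < 0 || blank_ms < 0) stop("config error: negative delay")
  structure(list(settle_ms = settle_ms, pulse_ms = pulse_ms,
                 blank_ms = blank_ms), class = "timing_policy")
}

#' Deterministic pulse schedule from trigger times
#'
#' Pure policy arithmetic: each accepted trigger at time t produces
#' `pulse_on` at `t + settle`, `pulse_off` at `t + settle + pulse`, and a
#' re-arm at `t + settle + pulse + blank`. Triggers arriving before the
#' previous cycle re-arms are ignored (and reported).
#'
#' @param policy a [timing_policy()].
#' @param trigger_times monotone non-decreasing trigger times, ms.
#' @return data.frame of events (`time_ms`, `kind`, `trigger_ms`) with an
#'   attribute `ignored` listing suppressed triggers.
#' @export
schedule_pulses <- function(policy, trigger_times) {
  if (is.unsorted(trigger_times)) stop("trigger times must be monotone")
  ev <- list(); ignored <- numeric(0)
  re_arm <- -Inf
  for (t in trigger_times) {
    if (t < re_arm) { ignored <- c(ignored, t); next }
    on <- t + policy$settle_ms
    off <- on + policy$pulse_ms
    re_arm <- off + policy$blank_ms
    ev[[length(ev) + 1]] <- data.frame(
      time_ms = c(on, off, re_arm),
      kind = c("pulse_on", "pulse_off", "re_arm"),
      trigger_ms = t)
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(time_ms = numeric(0), kind = character(0),
               trigger_ms = numeric(0))
  attr(out, "ignored") <- ignored
  out
}

#' Quiescence-based termination detector
#'
#' Declares the arrhythmia terminated when the high-pass amplitude of the
#' incoming windows stays below `amp_threshold` and no core decision fires
#' for `hold_ms`. A paced rhythm whose planar waves never trigger the core
#' rule but keep the amplitude high is NOT classified as terminated
#' reentry... it simply never terminates the monitor's hold window.
#'
#' Optionally, `no_decision_hold_ms` adds a decision-only criterion: activity
#' that never triggers the core rule for that long (e.g. a paced rhythm of
#' periodic planar waves -- the sinus-rhythm analogue) also counts as
#' "no reentry", regardless of amplitude. The closed-loop driver uses only
#' the quiescence criterion.
#'
#' @param amp_threshold quiescence threshold on the pre-normalization window
#'   amplitude (camera units).
#' @param hold_ms time both conditions must hold.
#' @param no_decision_hold_ms optional decision-only hold (NULL = disabled).
#' @export
termination_monitor <- function(amp_threshold, hold_ms = 1000,
                                no_decision_hold_ms = NULL) {
  structure(list(amp_threshold = amp_threshold, hold_ms = hold_ms,
                 no_decision_hold_ms = no_decision_hold_ms,
                 quiet_since = NA_real_, no_dec_since = NA_real_),
            class = "termination_monitor")
}

#' @rdname termination_monitor
#' @param mon a `termination_monitor`.
#' @param time_ms current time.
#' @param amplitude pre-normalization amplitude of the current window.
#' @param decision_fired whether a core decision fired at this step.
#' @return list with updated `mon` and logical `terminated`.
#' @export
update_termination <- function(mon, time_ms, amplitude, decision_fired) {
  if (amplitude < mon$amp_threshold && !decision_fired) {
    if (is.na(mon$quiet_since)) mon$quiet_since <- time_ms
  } else mon$quiet_since <- NA_real_
  if (!decision_fired) {
    if (is.na(mon$no_dec_since)) mon$no_dec_since <- time_ms
  } else mon$no_dec_since <- NA_real_
  terminated <- (!is.na(mon$quiet_since) &&
                   (time_ms - mon$quiet_since) >= mon$hold_ms) ||
    (!is.null(mon$no_decision_hold_ms) && !is.na(mon$no_dec_since) &&
       (time_ms - mon$no_dec_since) >= mon$no_decision_hold_ms)
  list(mon = mon, terminated = terminated)
}
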