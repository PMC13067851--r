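#' Run the closed-loop termination experiment
#'
#' The full detect--decide--illuminate loop against a virtual rig: the camera
#' emits packs of five frames (8 ms apart), each pack is preprocessed
#' exactly like the real-time stream, the detector produces a core
#' probability map, the 0.7/10-frame histogram rule consolidates a core
#' location, and a trigger starts the timing policy: settle, project the
#' light line (core to nearest boundary, rasterized to the LED matrix and
#' projected back onto the tissue as photocurrent irradiance) for the pulse
#' duration, blank, and re-arm until the reentry terminates. With
#' `control = FALSE` the LED output stays disabled (the no-light control
#' group); acquisition, detection and logging run identically.
#'
#' Phases of one cycle: `armed` (detections update the histogram, a decision
#' triggers), `settle` (detections keep tracking the core, no new trigger),
#' `pulse` and `blank` (detections suppressed; the histogram is cleared on
#' re-arm). The line is generated at pulse onset from the most recent
#' consolidated core. Pattern projection is quantized to camera frames; the
#' schedule arithmetic itself ([schedule_pulses()]) is exact.
#'
#' @param rig a [virtual_rig()] with an induced spiral.
#' @param model a fitted [core_cnn()].
#' @param policy a [timing_policy()].
#' @param seed RNG seed for camera noise; the loop is replayable.
#' @param control enable the LED output.
#' @param horizon_s simulated duration limit, s.
#' @param line_width,dot_pitch,overshoot_px light-line geometry (camera
#'   pixels); the overshoot extends the line past the core to cover the tip
#'   orbit.
#' @param irradiance normalized light-line irradiance.
#' @param amp_threshold termination quiescence threshold (camera units);
#'   default 10x the camera noise floor.
#' @param hold_ms termination hold time.
#' @return A `loop_log`: data.frame of ordered events (`time_ms`, `kind`,
#'   `row`, `col`, `note`) with attributes `terminated`, `n_attempts`,
#'   `termination_time_ms`, `final_state`.
#' @export
run_closed_loop <- function(rig, model, policy = timing_policy(), seed = 1,
                            control = TRUE, horizon_s = 10,
                            line_width = 3, dot_pitch = NULL,
                            overshoot_px = 12,
                            irradiance = 1,
                            amp_threshold = NULL, hold_ms = 1000) {
  if (!inherits(model, "core_cnn")) stop("model must be a fitted core_cnn")
  S <- model$net_config$input_side
  if (rig$camera$raster < S)
    stop("model/rig geometry mismatch: camera raster smaller than detector input")
  set.seed(seed)
  photo <- photo_defaults(rig$model)
  dt <- rig$dt_ms
  frame_ms <- rig$camera$interval_ms
  n_packs <- floor(horizon_s * 1000 / (5 * frame_ms))
  crop_off <- crop_offset(rig$camera$raster, S)
  if (is.null(amp_threshold)) amp_threshold <- 10 * max(rig$camera$noise_sd, 1e-4)

  mask100 <- block_average(rig$domain$conducting_mask * 1, rig$camera$raster) > 0.5
  mask86 <- center_crop(mask100, S)

  state <- rig$state
  background <- NULL
  hist <- core_histogram()
  mon <- termination_monitor(amp_threshold, hold_ms)
  events <- list()
  log_ev <- function(t, kind, row = NA_real_, col = NA_real_, note = "")
    events[[length(events) + 1]] <<- data.frame(time_ms = t, kind = kind,
                                                row = row, col = col,
                                                note = note)
  t_ms <- 0
  term_time <- NA_real_
  cyc_on <- cyc_off <- cyc_rearm <- Inf     # no active cycle
  irr_map <- NULL
  last_core <- NULL
  n_attempts <- 0L
  terminated <- FALSE

  for (k in seq_len(n_packs)) {
    pack <- array(0, c(rig$camera$raster, rig$camera$raster, 5))
    for (f in 1:5) {
      # cycle transitions at frame resolution
      if (is.finite(cyc_on) && t_ms >= cyc_on && is.null(irr_map) &&
          t_ms < cyc_off) {
        if (!mask86[last_core[1], last_core[2]]) {
          # snap a detection on non-conducting pixels to the nearest tissue
          cond <- which(mask86, arr.ind = TRUE)
          j <- which.min((cond[, 1] - last_core[1])^2 +
                           (cond[, 2] - last_core[2])^2)
          last_core <- c(cond[j, 1], cond[j, 2])
        }
        path <- nearest_border_line(last_core, mask86, width = line_width,
                                    dot_pitch = dot_pitch,
                                    overshoot_px = overshoot_px)
        patt <- rasterize(data.frame(row = path$row + crop_off,
                                     col = path$col + crop_off),
                          camera_to_led_transform(rig$reg), rig$led,
                          intensity = irradiance)
        irr_map <- if (control) led_to_tissue(patt, rig$reg, rig$domain, "box")
                   else NULL
        n_attempts <- n_attempts + 1L
        log_ev(t_ms, "pulse_on", last_core[1] + crop_off,
               last_core[2] + crop_off,
               sprintf("%d LEDs%s", sum(patt$on),
                       if (control) "" else " (output disabled)"))
        if (!control) irr_map <- matrix(0, 1, 1)   # placeholder, no light
      }
      if (is.finite(cyc_off) && t_ms >= cyc_off && !is.null(irr_map)) {
        log_ev(t_ms, "pulse_off")
        irr_map <- NULL
      }
      if (is.finite(cyc_rearm) && t_ms >= cyc_rearm) {
        hist <- core_histogram(hist$n, hist$threshold)
        cyc_on <- cyc_off <- cyc_rearm <- Inf
        log_ev(t_ms, "re_arm")
      }
      lit <- control && !is.null(irr_map) && length(irr_map) > 1
      ch <- integrate_chunk(state, rig$domain, rig$het, rig$model, list(),
                            dt, rig$steps_per_frame, round(t_ms / dt), 0L,
                            photo, weights = rig$weights,
                            extra_irr = if (lit) irr_map else NULL)
      state <- ch$state
      t_ms <- t_ms + frame_ms
      pack[, , f] <- camera_frame(state$u, rig$camera, rig$A, rig$B)
    }

    pp <- preprocess_pack(pack, background, S)
    background <- pp$background
    decision_fired <- FALSE
    if (!pp$warmup) {
      armed <- !is.finite(cyc_on)
      in_settle <- is.finite(cyc_on) && t_ms < cyc_on
      # inference only while detections can be used (armed or tracking in
      # the settle window); pulse and blanking suppress detections
      if (armed || in_settle) {
        prob <- predict(model, pp$window)
        res <- update_and_decide(hist, prob)
        hist <- res$hist
        if (!is.null(res$decision)) {
          decision_fired <- TRUE
          last_core <- res$decision
          log_ev(t_ms, "detection", res$decision[1] + crop_off,
                 res$decision[2] + crop_off)
          if (armed) {
            cyc_on <- t_ms + policy$settle_ms
            cyc_off <- cyc_on + policy$pulse_ms
            cyc_rearm <- cyc_off + policy$blank_ms
            log_ev(t_ms, "trigger", res$decision[1] + crop_off,
                   res$decision[2] + crop_off,
                   sprintf("pulse scheduled at %.0f ms", cyc_on))
          }
        }
      }
    }

    upd <- update_termination(mon, t_ms, pp$amplitude, decision_fired)
    mon <- upd$mon
    if (upd$terminated) {
      terminated <- TRUE
      term_time <- mon$quiet_since      # activity ceased here; confirmed now
      log_ev(t_ms, "termination", note = sprintf("quiescent since %.0f ms",
                                                 term_time))
      break
    }
  }

  log <- do.call(rbind, events)
  if (is.null(log)) log <- data.frame(time_ms = numeric(0), kind = character(0),
                                      row = numeric(0), col = numeric(0),
                                      note = character(0))
  structure(log, class = c("loop_log", "data.frame"),
            terminated = terminated, n_attempts = n_attempts,
            termination_time_ms = term_time,
            seed = seed, control = control, final_state = state)
}

#' @export
print.loop_log <- function(x, ...) {
  cat(sprintf("<loop_log> %d events over %.1f s (control %s): %s\n",
              nrow(x), if (nrow(x)) max(x$time_ms) / 1000 else 0,
              ifelse(attr(x, "control"), "ON", "OFF"),
              if (attr(x, "terminated"))
                sprintf("TERMINATED at %.2f s after %d attempt(s)",
                        attr(x, "termination_time_ms") / 1000,
                        attr(x, "n_attempts"))
              else "reentry persisted"))
  invisible(x)
}
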