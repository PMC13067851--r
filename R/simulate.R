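#' Simulation configuration
#'
#' Time stepping and recording cadence of the monodomain integrator. The
#' defaults reproduce the reference recording arithmetic: 1.25 s of activity
#' at dt = 0.005 ms with a frame saved every 1200 steps gives a 208-frame
#' movie at 6 ms resolution. The `"desk"` preset keeps the identical
#' recording arithmetic (6 ms frames, 208 of them) at a coarser step
#' (dt = 0.05 ms, frame every 120 steps), which the phenomenological cell
#' model integrates stably; [check_stability()] verifies the diffusion CFL
#' bound for a given domain/model/step combination.
#'
#' @param dt_ms integration step, ms.
#' @param record_every save a frame every this many steps.
#' @param duration_ms simulated duration, ms; must be an integer number of steps.
#' @param rng_seed integer seed carried in movie metadata.
#' @param preset `"paper"` (0.005 ms / 1200) or `"desk"` (0.05 ms / 120).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(dt_ms = 0.005, record_every = 1200, duration_ms = 1250,
                       rng_seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    if (preset == "desk") { dt_ms <- 0.05; record_every <- 120 }
    else if (preset != "paper") stop("unknown preset")
  }
  if (dt_ms <= 0) stop("dt must be positive")
  if (record_every < 1) stop("record_every must be >= 1")
  n_steps <- duration_ms / dt_ms
  if (abs(n_steps - round(n_steps)) > 1e-6)
    stop("duration must be an integer number of steps")
  structure(list(dt_ms = dt_ms, record_every = as.integer(record_every),
                 duration_ms = duration_ms, n_steps = as.integer(round(n_steps)),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param domain,model,het domain, cell model and heterogeneity to check.
#' @param config a `sim_config`.
#' @export
check_stability <- function(domain, model, config, het = NULL) {
  cmax <- if (is.null(het)) 1 else max(het$coupling_scale)
  h_mm <- domain$spacing_um / 1000
  dt_max <- h_mm^2 / (4 * model$D_mm2_ms * cmax)
  ok <- config$dt_ms <= dt_max && config$dt_ms <= model$pars[["tau_d"]] / 4
  structure(ok, dt_max_diffusion = dt_max)
}

photo_defaults <- function(model = cell_model_fk()) {
  # reversal of the channelrhodopsin photocurrent at 0 mV in normalized units
  list(g = 0.25, u_rev = (0 - model$v_rest_mv) / model$v_amp_mv)
}

#' Channelrhodopsin photocurrent
#'
#' Instantaneous light-gated conductance model: blue light of normalized
#' irradiance `irr` produces a depolarizing current
#' `g * irr * (E_rev - V)` driving the membrane toward the reversal potential
#' `e_rev_mv` (default 0 mV). No channel kinetics are modelled. The returned
#' current is in du/dt units of the normalized cell model; it is zero at zero
#' irradiance and monotone in irradiance for `V < E_rev`.
#'
#' @param v_mv membrane potential(s), mV.
#' @param irradiance normalized irradiance in \[0, 1\] (values outside are
#'   clipped with a warning).
#' @param g peak conductance (du/dt per unit driving force).
#' @param e_rev_mv reversal potential, mV.
#' @param model cell model providing the mV mapping.
#' @export
photocurrent <- function(v_mv, irradiance, g = photo_defaults()$g,
                         e_rev_mv = 0, model = cell_model_fk()) {
  if (any(irradiance < 0 | irradiance > 1)) {
    warning("irradiance outside [0, 1] clipped")
    irradiance <- pmin(pmax(irradiance, 0), 1)
  }
  u <- (v_mv - model$v_rest_mv) / model$v_amp_mv
  u_rev <- (e_rev_mv - model$v_rest_mv) / model$v_amp_mv
  g * irradiance * (u_rev - u)
}

# Internal integrator state helpers -------------------------------------------

rest_state <- function(domain, model) {
  nr <- domain$n_rows; nc <- domain$n_cols
  list(u = matrix(model$rest[["u"]], nr, nc),
       v = matrix(model$rest[["v"]], nr, nc),
       w = matrix(model$rest[["w"]], nr, nc))
}

# Piecewise-constant stimulus maps on [t0, t1): sum of active electrical
# currents and max of active optical irradiances.
stimulus_maps <- function(domain, events, t0, t1) {
  nr <- domain$n_rows; nc <- domain$n_cols
  iext <- 0; irr <- 0
  mid <- (t0 + t1) / 2
  for (ev in events) {
    if (ev$t_on <= mid && mid < ev$t_on + ev$duration) {
      if (ev$kind == "electrical") {
        if (length(iext) == 1) iext <- matrix(0, nr, nc)
        iext <- iext + ev$amplitude * ev$geometry
      } else {
        if (length(irr) == 1) irr <- matrix(0, nr, nc)
        irr <- pmax(irr, ev$amplitude * ev$geometry)
      }
    }
  }
  list(iext = iext, irr = irr)
}

# Core chunked driver shared by run_protocol and the closed-loop rig. Runs the
# state from t_start over n_steps, cutting segments at event boundaries,
# recording frames of u on the global record grid.
integrate_chunk <- function(state, domain, het, model, events, dt, n_steps,
                            step_offset, record_every, photo,
                            reaction = TRUE, diffusion = TRUE,
                            weights = NULL, extra_irr = NULL) {
  if (is.null(weights))
    weights <- domain_edge_weights(domain, model$D_mm2_ms, het$coupling_scale)
  nr <- domain$n_rows; nc <- domain$n_cols
  cond <- matrix(as.integer(domain$conducting_mask), nr, nc)

  bounds <- unlist(lapply(events, function(ev) c(ev$t_on, ev$t_on + ev$duration)))
  t_start <- step_offset * dt
  t_end <- t_start + n_steps * dt
  cuts <- sort(unique(c(t_start, t_end,
                        bounds[bounds > t_start + 1e-9 & bounds < t_end - 1e-9])))
  cut_steps <- round(cuts / dt)

  frames <- vector("list", length(cut_steps) - 1)
  for (si in seq_len(length(cut_steps) - 1)) {
    s0 <- cut_steps[si]; s1 <- cut_steps[si + 1]
    maps <- stimulus_maps(domain, events, s0 * dt, s1 * dt)
    irr <- maps$irr
    if (!is.null(extra_irr)) {
      if (length(irr) == 1) irr <- extra_irr else irr <- pmax(irr, extra_irr)
    }
    res <- fk_segment(state$u, state$v, state$w, nr, nc,
                      weights$wN, weights$wS, weights$wW, weights$wE,
                      cond, het$cell_current_scale, model$pars,
                      if (length(maps$iext) == 1) numeric(1) else maps$iext,
                      if (length(irr) == 1) numeric(1) else irr,
                      photo$g, photo$u_rev,
                      dt, s1 - s0, record_every, s0,
                      reaction, diffusion)
    state <- list(u = matrix(res$u, nr, nc), v = matrix(res$v, nr, nc),
                  w = matrix(res$w, nr, nc))
    if (res$diverged_step >= 0)
      stop(structure(class = c("spiralctl_diverged", "error", "condition"),
                     list(message = sprintf(
                       "integration diverged at step %d (t = %.3f ms)",
                       res$diverged_step, res$diverged_step * dt),
                       call = NULL, step = res$diverged_step)))
    if (res$n_rec > 0)
      frames[[si]] <- array(res$frames, c(nr, nc, res$n_rec))
  }
  frames <- frames[!vapply(frames, is.null, logical(1))]
  list(state = state,
       frames = if (length(frames)) do.call(abind3, frames) else NULL)
}

abind3 <- function(...) {
  xs <- list(...)
  nr <- dim(xs[[1]])[1]; nc <- dim(xs[[1]])[2]
  array(do.call(c, lapply(xs, as.vector)),
        c(nr, nc, sum(vapply(xs, function(x) dim(x)[3], numeric(1)))))
}

#' Advance the simulation state by one (or a few) explicit steps
#'
#' One reaction step plus one masked 5-point diffusion step of the monodomain
#' model; non-conducting nodes never change. Mainly useful for inspecting the
#' integrator; whole protocols run through [run_protocol()].
#'
#' @param state list with matrices `u`, `v`, `w` (see [run_protocol()]).
#' @param domain,het,model geometry, heterogeneity and cell model.
#' @param stimuli list of [stimulus_event()]s.
#' @param t current time, ms.
#' @param dt step, ms.
#' @param n_steps number of steps to take.
#' @param reaction,diffusion switch the reaction and diffusion terms on/off
#'   (diagnostics: pure diffusion conserves the total of `u`).
#' @param photo photocurrent parameters (list with `g`, `u_rev`).
#' @export
step_state <- function(state, domain, het, stimuli = list(), t = 0, dt,
                       n_steps = 1L, model = cell_model_fk(),
                       reaction = TRUE, diffusion = TRUE,
                       photo = photo_defaults(model)) {
  if (!all(is.finite(state$u))) stop("non-finite state")
  res <- integrate_chunk(state, domain, het, model, stimuli, dt, n_steps,
                         round(t / dt), 0L, photo, reaction, diffusion)
  res$state
}

#' Run a stimulation protocol and record a voltage movie
#'
#' Integrates the monodomain model over `config$duration_ms`, applying the
#' given stimulus events, and records membrane-potential frames every
#' `config$record_every` steps. With the default configuration this yields a
#' 208-frame movie at 6 ms resolution from 1.25 s of activity.
#'
#' @param domain a [make_domain()] object.
#' @param het a [sample_heterogeneity()] object.
#' @param events list of [stimulus_event()]s, sorted by onset time.
#' @param config a [sim_config()].
#' @param model cell model (default [cell_model_fk()]).
#' @param init_state optional starting state (list of matrices `u`, `v`, `w`)
#'   to continue from, e.g. an induced spiral; defaults to rest.
#' @param reaction,diffusion term switches (diagnostics).
#' @param photo photocurrent parameters.
#' @return A `voltage_movie`: list with `frames` (\[rows, cols, T\] array in
#'   mV), `frame_interval_ms`, `spacing_um`, `seed` and the final integrator
#'   state in `$final_state`.
#' @export
run_protocol <- function(domain, het, events, config,
                         model = cell_model_fk(), init_state = NULL,
                         reaction = TRUE, diffusion = TRUE,
                         photo = photo_defaults(model)) {
  t_on <- vapply(events, function(e) e$t_on, numeric(1))
  if (length(t_on) > 1 && is.unsorted(t_on)) stop("events must be sorted by t_on")
  state <- if (is.null(init_state)) rest_state(domain, model) else init_state
  res <- withCallingHandlers(
    integrate_chunk(state, domain, het, model, events, config$dt_ms,
                    config$n_steps, 0L, config$record_every, photo,
                    reaction, diffusion),
    spiralctl_diverged = function(e) {
      stop(sprintf("protocol failed: %s", conditionMessage(e)), call. = FALSE)
    })
  frames <- res$frames
  if (is.null(frames)) frames <- array(NA_real_, c(domain$n_rows, domain$n_cols, 0))
  voltage_movie(u_to_mv(frames, model),
                frame_interval_ms = config$dt_ms * config$record_every,
                spacing_um = domain$spacing_um,
                seed = config$rng_seed,
                final_state = res$state)
}

#' Voltage movie container
#'
#' T frames of membrane potential (or camera fluorescence) over an H x W
#' raster with a fixed frame interval and pixel pitch.
#'
#' @param frames numeric array \[rows, cols, T\].
#' @param frame_interval_ms frame spacing, ms.
#' @param spacing_um pixel pitch, micrometers.
#' @param seed seed recorded for provenance.
#' @param final_state optional simulator state snapshot.
#' @export
voltage_movie <- function(frames, frame_interval_ms, spacing_um, seed = NA,
                          final_state = NULL) {
  stopifnot(length(dim(frames)) == 3)
  structure(list(frames = frames, frame_interval_ms = frame_interval_ms,
                 spacing_um = spacing_um, seed = seed,
                 final_state = final_state),
            class = "voltage_movie")
}

#' @export
print.voltage_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<voltage_movie> %d frames of %d x %d, %g ms apart (%.3g s, pitch %g um)\n",
              d[3], d[1], d[2], x$frame_interval_ms,
              d[3] * x$frame_interval_ms / 1000, x$spacing_um))
  invisible(x)
}

#' @export
dim.voltage_movie <- function(x) dim(x$frames)
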