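#' Phenomenological three-variable cardiac cell model
#'
#' The default ionic model: a three-current phenomenological excitable model
#' (fast inward, slow outward, slow inward, each gated by threshold switches)
#' of the Fenton--Karma family, with parameters tuned so that a simulated
#' monolayer shows an action potential duration of roughly 100--200 ms and a
#' conduction velocity of roughly 100--250 mm/s, the range typical of
#' cultured ventricular myocyte monolayers. The transmembrane variable `u` is
#' normalized to \[0, 1\]; movies map it to millivolts as
#' `V = v_rest + v_amp * u`.
#'
#' The cell-model interface is pluggable: any list with the same fields
#' (`pars` in the order consumed by the integrator, `n_state`, `rest`,
#' `v_rest_mv`, `v_amp_mv`, `D_mm2_ms`) can be passed wherever a cell model is
#' accepted, leaving a slot for a detailed ionic model of neonatal rat
#' ventricular myocytes.
#'
#' @param ... named parameter overrides (e.g. `tau_r = 40`).
#' @return An object of class `cell_model`.
#' @export
cell_model_fk <- function(...) {
  p <- list(
    tau_d = 0.25,    # fast inward (depolarization) time scale, ms
    tau_r = 33,      # slow outward repolarization, ms
    tau_si = 29,     # slow inward (plateau) current, ms
    tau_0 = 8.3,     # sub-threshold outward leak, ms
    tau_vp = 3.33,   # fast-gate closing, ms
    tau_v1m = 19.6,  # fast-gate reopening (recovered), ms
    tau_v2m = 1000,  # fast-gate reopening (partially recovered), ms
    tau_wp = 150,    # slow-gate closing, ms
    tau_wm = 41,     # slow-gate reopening, ms
    u_c = 0.13,      # excitation threshold
    u_v = 0.04,      # fast-gate recovery threshold
    u_csi = 0.85,    # slow-inward activation midpoint
    k = 10           # slow-inward activation steepness
  )
  ov <- list(...)
  extra <- setdiff(names(ov), c(names(p), "D_mm2_ms", "v_rest_mv", "v_amp_mv"))
  if (length(extra)) stop("unknown cell-model parameters: ",
                          paste(extra, collapse = ", "))
  for (nm in intersect(names(ov), names(p))) p[[nm]] <- ov[[nm]]
  structure(list(
    name = "fk3",
    pars = unlist(p[c("tau_d", "tau_r", "tau_si", "tau_0", "tau_vp",
                      "tau_v1m", "tau_v2m", "tau_wp", "tau_wm",
                      "u_c", "u_v", "u_csi", "k")]),
    n_state = 3,
    rest = c(u = 0, v = 1, w = 1),
    v_rest_mv = if (is.null(ov$v_rest_mv)) -84 else ov$v_rest_mv,
    v_amp_mv = if (is.null(ov$v_amp_mv)) 100 else ov$v_amp_mv,
    D_mm2_ms = if (is.null(ov$D_mm2_ms)) 0.0025 else ov$D_mm2_ms
  ), class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  cat(sprintf("<cell_model> %s (%d state variables), D = %g mm^2/ms\n",
              x$name, x$n_state, x$D_mm2_ms))
  invisible(x)
}

# Normalized u -> membrane potential in mV.
u_to_mv <- function(u, model) model$v_rest_mv + model$v_amp_mv * u
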