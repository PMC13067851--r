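#' Virtual camera specification
#'
#' The in-silico stand-in for the optical-mapping camera: it renders the
#' simulator's membrane potential to a 100 x 100 raster by exact
#' area-weighted block averaging, applies gain and signal polarity, and adds
#' seeded per-pixel Gaussian noise. Frames are emitted every 8 ms and
#' grouped into packs of five.
#'
#' @param raster pixels per side (100).
#' @param interval_ms frame interval (8 ms; must be an integer number of
#'   simulator steps).
#' @param gain multiplicative gain on the normalized fluorescence.
#' @param noise_sd additive Gaussian noise sd (normalized units).
#' @param polarity +1 or -1 (voltage-dye signals may be inverted).
#' @export
camera_spec <- function(raster = 100, interval_ms = 8, gain = 1,
                        noise_sd = 0.01, polarity = 1) {
  if (interval_ms <= 0) stop("frame interval must be positive")
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1")
  structure(list(raster = raster, interval_ms = interval_ms, gain = gain,
                 noise_sd = noise_sd, polarity = polarity),
            class = "camera_spec")
}

#' Camera / LED / tissue registration
#'
#' Affine registration between the three coordinate frames. The camera
#' raster covers the full tissue square; the LED matrix is centered over the
#' tissue. `offset_mm` injects a deliberate misregistration of the LED frame
#' (for misalignment-tolerance experiments).
#'
#' @param domain tissue domain.
#' @param camera a [camera_spec()].
#' @param led an [led_matrix_spec()].
#' @param offset_mm `c(dy, dx)` LED-frame offset in mm.
#' @export
registration <- function(domain, camera, led, offset_mm = c(0, 0)) {
  px_mm <- domain$side_mm / camera$raster
  origin <- c(domain$side_mm / 2 - led$rows * led$pitch_mm / 2,
              domain$side_mm / 2 - led$cols * led$pitch_mm / 2) + offset_mm
  structure(list(px_mm = px_mm, led_origin_mm = origin,
                 offset_mm = offset_mm, pitch_mm = led$pitch_mm),
            class = "registration")
}

# camera-pixel path -> transform consumed by rasterize()
camera_to_led_transform <- function(reg) {
  list(scale = c(reg$px_mm / reg$pitch_mm, reg$px_mm / reg$pitch_mm),
       offset = c(0.5 - (reg$led_origin_mm[1] + 0.5 * reg$px_mm * 0) / reg$pitch_mm,
                  0.5 - reg$led_origin_mm[2] / reg$pitch_mm) +
         c(-0.5 * reg$px_mm / reg$pitch_mm, -0.5 * reg$px_mm / reg$pitch_mm))
}

#' Render one camera frame from the simulator state
#'
#' Exact area-weighted block average of the normalized membrane variable
#' onto the camera raster, with gain, polarity and (if `noise_sd > 0`)
#' additive Gaussian noise drawn from the current RNG stream.
#'
#' @param u simulator field (matrix, normalized units).
#' @param camera a [camera_spec()].
#' @param A,B precomputed overlap matrices (optional).
#' @export
camera_frame <- function(u, camera, A = NULL, B = NULL) {
  if (is.null(A)) A <- overlap_matrix(camera$raster, nrow(u))
  if (is.null(B)) B <- overlap_matrix(camera$raster, ncol(u))
  f <- camera$polarity * camera$gain * (A %*% u %*% t(B))
  if (camera$noise_sd > 0)
    f <- f + matrix(stats::rnorm(length(f), 0, camera$noise_sd),
                    nrow(f), ncol(f))
  f
}

#' Project an LED pattern onto the simulation grid
#'
#' Converts a boolean LED pattern into a normalized irradiance field on the
#' tissue grid, ready for the photocurrent model. `"box"` mode illuminates
#' each lit LED's pitch-sized footprint uniformly; `"lambertian"` evaluates
#' the physical emitter model ([irradiance_field()]) at the node centers and
#' normalizes by the single-emitter peak.
#'
#' @param pattern a [light_pattern()].
#' @param reg a [registration()].
#' @param domain tissue domain.
#' @param mode `"box"` or `"lambertian"`.
#' @return matrix (grid) of normalized irradiance in \[0, 1\].
#' @export
led_to_tissue <- function(pattern, reg, domain, mode = c("box", "lambertian")) {
  mode <- match.arg(mode)
  nr <- domain$n_rows; nc <- domain$n_cols
  irr <- matrix(0, nr, nc)
  lit <- which(pattern$on, arr.ind = TRUE)
  if (nrow(lit) == 0) return(irr)
  h_mm <- domain$spacing_um / 1000
  if (mode == "box") {
    for (i in seq_len(nrow(lit))) {
      cy <- reg$led_origin_mm[1] + (lit[i, 1] - 0.5) * reg$pitch_mm
      cx <- reg$led_origin_mm[2] + (lit[i, 2] - 0.5) * reg$pitch_mm
      r0 <- max(1, ceiling((cy - reg$pitch_mm / 2) / h_mm + 0.5))
      r1 <- min(nr, floor((cy + reg$pitch_mm / 2) / h_mm + 0.5))
      c0 <- max(1, ceiling((cx - reg$pitch_mm / 2) / h_mm + 0.5))
      c1 <- min(nc, floor((cx + reg$pitch_mm / 2) / h_mm + 0.5))
      if (r1 >= r0 && c1 >= c0) irr[r0:r1, c0:c1] <- pattern$intensity
    }
  } else {
    xs <- ((seq_len(nc) - 0.5) * h_mm) - reg$led_origin_mm[2]
    ys <- ((seq_len(nr) - 0.5) * h_mm) - reg$led_origin_mm[1]
    E <- irradiance_field(pattern, xs, ys)
    irr <- E / pattern$spec$peak_irradiance_mw_cm2
    irr <- pmin(irr, 1)
  }
  irr
}

#' Assemble a virtual rig
#'
#' Couples a tissue simulation (domain, heterogeneity, cell model and an
#' initial state carrying an induced spiral) to the virtual camera and the
#' virtual LED matrix. `rig_with_spiral()` builds the standard single-well
#' rig by running the adaptive S1S2 induction protocol for a seed.
#'
#' @param domain,het,model tissue description.
#' @param state initial simulator state (induced spiral).
#' @param camera a [camera_spec()].
#' @param led an [led_matrix_spec()].
#' @param reg a [registration()] (default: identity-centered).
#' @param dt_ms simulator step.
#' @export
virtual_rig <- function(domain, het, model, state,
                        camera = camera_spec(),
                        led = led_matrix_spec("small"),
                        reg = NULL, dt_ms = 0.1) {
  if (is.null(reg)) reg <- registration(domain, camera, led)
  steps_per_frame <- camera$interval_ms / dt_ms
  if (abs(steps_per_frame - round(steps_per_frame)) > 1e-9)
    stop("config error: camera interval must be an integer number of steps")
  structure(list(domain = domain, het = het, model = model, state = state,
                 camera = camera, led = led, reg = reg, dt_ms = dt_ms,
                 steps_per_frame = as.integer(round(steps_per_frame)),
                 A = overlap_matrix(camera$raster, domain$n_rows),
                 B = overlap_matrix(camera$raster, domain$n_cols),
                 weights = domain_edge_weights(domain, model$D_mm2_ms,
                                               het$coupling_scale)),
            class = "virtual_rig")
}

#' @rdname virtual_rig
#' @param seed induction seed.
#' @param config a [generator_config()].
#' @param camera,led,offset_mm forwarded to the rig.
#' @export
rig_with_spiral <- function(seed, config = generator_config(),
                            camera = camera_spec(),
                            led = led_matrix_spec("small"),
                            offset_mm = c(0, 0)) {
  ind <- induce_spiral(config, seed)
  if (!ind$ok) stop(sprintf("seed %d: induction failed (%s)", seed, ind$reason))
  reg <- registration(config$domain, camera, led, offset_mm)
  virtual_rig(config$domain, ind$het, config$model, ind$state, camera, led,
              reg, dt_ms = config$dt_ms)
}
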