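#' Micro-LED matrix specification
#'
#' Physical description of an addressable mLED matrix: grid size, pixel
#' pitch, emitter footprint, peak irradiance at the culture plane, emission
#' wavelength and the distance to the illuminated plane. Two presets mirror
#' the built devices: `"small"` (48 x 32 pixels, 0.6 mm pitch, 116 mW/cm^2)
#' and `"large"` (160 x 160 pixels, 0.9 mm pitch, 65.4 mW/cm^2), both at
#' 450 nm and roughly 3 mm below the monolayer.
#'
#' @param preset `"small"`, `"large"`, or `NULL` for fully manual.
#' @param rows,cols LED counts.
#' @param pitch_mm center-to-center LED spacing, mm.
#' @param emitter_mm emitter footprint (width, height), mm.
#' @param peak_irradiance_mw_cm2 irradiance directly above a single lit LED.
#' @param wavelength_nm center wavelength.
#' @param plane_distance_mm distance from the emitters to the target plane.
#' @return Object of class `led_matrix_spec`.
#' @export
led_matrix_spec <- function(preset = c("small", "large", "custom"),
                            rows = NULL, cols = NULL, pitch_mm = NULL,
                            emitter_mm = c(0.125, 0.25),
                            peak_irradiance_mw_cm2 = NULL,
                            wavelength_nm = 450, plane_distance_mm = 3) {
  preset <- match.arg(preset)
  if (preset == "small") {
    rows <- rows %||% 48L; cols <- cols %||% 32L
    pitch_mm <- pitch_mm %||% 0.6
    peak_irradiance_mw_cm2 <- peak_irradiance_mw_cm2 %||% 116
  } else if (preset == "large") {
    rows <- rows %||% 160L; cols <- cols %||% 160L
    pitch_mm <- pitch_mm %||% 0.9
    peak_irradiance_mw_cm2 <- peak_irradiance_mw_cm2 %||% 65.4
  }
  if (is.null(rows) || is.null(cols) || rows < 1 || cols < 1)
    stop("rows and cols must be >= 1")
  if (is.null(pitch_mm) || pitch_mm <= 0) stop("pitch must be positive")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch_mm = pitch_mm, emitter_mm = emitter_mm,
                 peak_irradiance_mw_cm2 = peak_irradiance_mw_cm2 %||% 100,
                 wavelength_nm = wavelength_nm,
                 plane_distance_mm = plane_distance_mm),
            class = "led_matrix_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.led_matrix_spec <- function(x, ...) {
  cat(sprintf("<led_matrix_spec> %d x %d LEDs, pitch %g mm, %g mW/cm^2 @ %g nm, H = %g mm\n",
              x$rows, x$cols, x$pitch_mm, x$peak_irradiance_mw_cm2,
              x$wavelength_nm, x$plane_distance_mm))
  invisible(x)
}

#' Boolean LED pattern
#'
#' @param spec an [led_matrix_spec()].
#' @param on logical matrix `rows x cols` (default all off).
#' @param intensity global intensity scale in \[0, 1\].
#' @export
light_pattern <- function(spec, on = NULL, intensity = 1) {
  if (is.null(on)) on <- matrix(FALSE, spec$rows, spec$cols)
  stopifnot(is.logical(on), all(dim(on) == c(spec$rows, spec$cols)),
            intensity >= 0, intensity <= 1)
  structure(list(spec = spec, on = on, intensity = intensity),
            class = "light_pattern")
}

#' Rasterize a camera-space pixel path onto the LED grid
#'
#' Maps each path pixel through the camera-to-LED affine transform and lights
#' the containing LED, guaranteeing that every commanded pixel is covered by
#' a lit LED (the camera raster is finer than the LED raster, so several
#' pixels may share one LED).
#'
#' @param path data.frame or matrix with columns `row`, `col` in camera
#'   pixels.
#' @param transform list with `scale` (length 2) and `offset` (length 2):
#'   `led = cam * scale + offset` in LED index units (row, col).
#' @param spec an [led_matrix_spec()].
#' @param intensity global intensity scale.
#' @return A [light_pattern()]; warns and returns an empty pattern when the
#'   whole path maps off-matrix.
#' @export
rasterize <- function(path, transform, spec, intensity = 1) {
  path <- as.matrix(path)
  r <- round(path[, 1] * transform$scale[1] + transform$offset[1])
  c <- round(path[, 2] * transform$scale[2] + transform$offset[2])
  keep <- r >= 1 & r <= spec$rows & c >= 1 & c <= spec$cols
  on <- matrix(FALSE, spec$rows, spec$cols)
  if (!any(keep)) {
    warning("path maps entirely off the LED matrix; empty pattern")
  } else {
    on[cbind(r[keep], c[keep])] <- TRUE
  }
  light_pattern(spec, on, intensity)
}

#' Driver frame encoding
#'
#' Serializes a boolean pattern for the matrix driver: LEDs scanned row-major
#' from the top-left, eight LEDs per byte, most significant bit first. The
#' byte count is exactly the pixel count divided by eight; `decode_frame`
#' inverts the packing.
#'
#' @param pattern a [light_pattern()].
#' @return raw vector of length `rows * cols / 8`.
#' @export
encode_frame <- function(pattern) {
  bits <- as.integer(t(pattern$on))      # row-major scan
  n <- length(bits)
  if (n %% 8 != 0) stop("pixel count must be divisible by 8")
  bm <- matrix(bits, nrow = 8)
  as.raw(as.integer(2^(7:0)) %*% bm)
}

#' @rdname encode_frame
#' @param bytes raw vector produced by [encode_frame()].
#' @param spec the matrix spec to reshape against.
#' @export
decode_frame <- function(bytes, spec) {
  n <- spec$rows * spec$cols
  if (length(bytes) * 8 != n) stop("byte count does not match the matrix")
  ints <- as.integer(bytes)
  bits <- unlist(lapply(ints, function(b) bitwAnd(b %/% 2^(7:0), 1L)))
  light_pattern(spec, matrix(as.logical(bits), spec$rows, spec$cols,
                             byrow = TRUE))
}

# Irradiance at target points from one Lambertian emitter at (ex, ey):
# E(d) = E_peak * H^4 / (H^2 + d^2)^2 (cosine emission and cosine incidence),
# integrated over the rectangular emitter footprint by a 10-point
# Gauss-Legendre rule per axis (footprint c(0, 0): ideal point emitter).
gl10_nodes <- c(-0.9739065285171717, -0.8650633666889845, -0.6794095682990244,
                -0.4333953941292472, -0.1488743389816312, 0.1488743389816312,
                0.4333953941292472, 0.6794095682990244, 0.8650633666889845,
                0.9739065285171717) / 2
gl10_weights <- c(0.0666713443086881, 0.1494513491505806, 0.2190863625159820,
                  0.2692667193099963, 0.2955242247147529, 0.2955242247147529,
                  0.2692667193099963, 0.2190863625159820, 0.1494513491505806,
                  0.0666713443086881) / 2
lambertian_one <- function(x, y, ex, ey, H, peak, footprint = c(0, 0),
                           nq = NULL) {
  if (all(footprint <= 0)) {
    d2 <- (x - ex)^2 + (y - ey)^2
    return(peak * H^4 / (H^2 + d2)^2)
  }
  acc <- 0
  for (i in 1:10) for (j in 1:10) {
    d2 <- (x - (ex + gl10_nodes[i] * footprint[1]))^2 +
          (y - (ey + gl10_nodes[j] * footprint[2]))^2
    acc <- acc + gl10_weights[i] * gl10_weights[j] * H^4 / (H^2 + d2)^2
  }
  peak * acc
}

#' Irradiance field of a light pattern
#'
#' Superposes the Lambertian irradiance of every lit LED on a target plane at
#' the matrix's plane distance. Each emitter contributes
#' `E_peak * H^4 / (H^2 + d^2)^2` at lateral distance `d` (cosine emission
#' times cosine incidence, inverse square), averaged over its rectangular
#' footprint. The field is additive across patterns and linear in the
#' pattern's intensity scale.
#'
#' @param pattern a [light_pattern()].
#' @param x_mm,y_mm coordinates of the target points (vectors; the field is
#'   evaluated on the outer grid). LED (r, c) sits at
#'   `((c - 0.5) pitch, (r - 0.5) pitch)`.
#' @param nq unused (kept for compatibility; a fixed Gauss-Legendre rule is
#'   used over the footprint).
#' @return matrix `length(y_mm) x length(x_mm)` of irradiance, mW/cm^2.
#' @export
irradiance_field <- function(pattern, x_mm, y_mm, nq = NULL) {
  spec <- pattern$spec
  H <- spec$plane_distance_mm
  if (H <= 0) stop("plane distance must be positive")
  xg <- matrix(x_mm, length(y_mm), length(x_mm), byrow = TRUE)
  yg <- matrix(y_mm, length(y_mm), length(x_mm))
  E <- matrix(0, length(y_mm), length(x_mm))
  lit <- which(pattern$on, arr.ind = TRUE)
  peak <- spec$peak_irradiance_mw_cm2 * pattern$intensity
  for (i in seq_len(nrow(lit))) {
    ex <- (lit[i, 2] - 0.5) * spec$pitch_mm
    ey <- (lit[i, 1] - 0.5) * spec$pitch_mm
    E <- E + lambertian_one(xg, yg, ex, ey, H, peak, spec$emitter_mm, nq)
  }
  E
}

#' Illumination uniformity versus pitch-to-distance ratio
#'
#' Reproduces the design study for the matrices: emitters at pitch
#' `D = sigma * H` illuminate a plane at distance `H`; uniformity is the
#' ratio of the minimum to the maximum irradiance sampled across the central
#' pitch cell of the array (between the two middle emitters), where the
#' inter-emitter ripple governed by sigma is measured without edge falloff.
#' Small `sigma` (dense emitters or a distant plane) approaches perfectly
#' uniform illumination (ratio 1).
#'
#' @param sigma pitch-to-distance ratio D/H (> 0).
#' @param n_leds number of emitters (>= 2).
#' @param geometry `"line"` (a 1D emitter row, the design-study case) or
#'   `"grid"` (square array).
#' @param H plane distance (scale-free: results depend only on sigma).
#' @param n_samples sample points across the central region.
#' @return uniformity ratio in (0, 1].
#' @export
led_uniformity <- function(sigma, n_leds = 32, geometry = c("line", "grid"),
                           H = 1, n_samples = 201) {
  geometry <- match.arg(geometry)
  if (sigma <= 0) stop("sigma must be positive")
  if (n_leds < 2) stop("n_leds must be >= 2")
  D <- sigma * H
  if (geometry == "line") {
    ex <- (seq_len(n_leds) - (n_leds + 1) / 2) * D
    xs <- seq(-D / 2, D / 2, length.out = n_samples)   # central pitch cell
    E <- vapply(xs, function(x)
      sum(H^4 / (H^2 + (x - ex)^2)^2), numeric(1))
  } else {
    m <- round(sqrt(n_leds))
    pos <- (seq_len(m) - (m + 1) / 2) * D
    xs <- seq(-D / 2, D / 2, length.out = min(n_samples, 61))
    E <- matrix(0, length(xs), length(xs))
    for (i in seq_along(xs)) for (j in seq_along(xs)) {
      d2 <- outer((xs[i] - pos)^2, (xs[j] - pos)^2, "+")
      E[i, j] <- sum(H^4 / (H^2 + d2)^2)
    }
  }
  min(E) / max(E)
}
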