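test_that("matrix presets mirror the built devices", {
  small <- led_matrix_spec("small")
  expect_equal(c(small$rows, small$cols), c(48L, 32L))
  expect_equal(small$pitch_mm, 0.6)
  large <- led_matrix_spec("large")
  expect_equal(c(large$rows, large$cols), c(160L, 160L))
  expect_equal(large$pitch_mm, 0.9)
  expect_equal(large$wavelength_nm, 450)
})

test_that("driver frames pack eight LEDs per byte, MSB first", {
  spec <- led_matrix_spec("small")
  off <- light_pattern(spec)
  bytes <- encode_frame(off)
  expect_length(bytes, 48 * 32 / 8)            # 192 = pixels / 8
  expect_true(all(bytes == as.raw(0)))

  one <- light_pattern(spec, {
    m <- matrix(FALSE, 48, 32); m[1, 1] <- TRUE; m })
  b1 <- encode_frame(one)
  expect_equal(b1[1], as.raw(0x80))            # first scan position, MSB
  expect_true(all(b1[-1] == as.raw(0)))

  # round-trip identity over random patterns and several matrix sizes
  set.seed(2)
  for (dims in list(c(48, 32), c(8, 8), c(16, 10))) {
    spec2 <- led_matrix_spec("custom", rows = dims[1], cols = dims[2],
                             pitch_mm = 1)
    for (k in 1:20) {
      patt <- light_pattern(spec2, matrix(stats::runif(prod(dims)) > 0.5,
                                          dims[1], dims[2]))
      expect_identical(decode_frame(encode_frame(patt), spec2)$on, patt$on)
    }
  }
  odd <- led_matrix_spec("custom", rows = 3, cols = 5, pitch_mm = 1)
  expect_error(encode_frame(light_pattern(odd)), "divisible")
})

test_that("rasterization covers the commanded path and shifts with the transform", {
  spec <- led_matrix_spec("small")
  tf <- list(scale = c(0.25, 0.25), offset = c(0, 0))
  p1 <- rasterize(data.frame(row = 40, col = 40), tf, spec)
  expect_equal(sum(p1$on), 1)

  # a diagonal path across the camera frame maps to an 8-connected LED path
  path <- data.frame(row = 1:100, col = 1:100)
  patt <- rasterize(path, tf, spec)
  lit <- which(patt$on, arr.ind = TRUE)
  lit <- lit[order(lit[, 1]), , drop = FALSE]
  expect_true(all(pmax(abs(diff(lit[, 1])), abs(diff(lit[, 2]))) <= 1))

  # a 3-LED offset in the transform shifts the pattern by exactly 3 LEDs
  tf3 <- list(scale = c(0.25, 0.25), offset = c(3, 0))
  p3 <- rasterize(data.frame(row = 40, col = 40), tf3, spec)
  expect_equal(which(p3$on, arr.ind = TRUE)[1, 1],
               which(p1$on, arr.ind = TRUE)[1, 1] + 3)

  expect_warning(rasterize(data.frame(row = 1e4, col = 1e4), tf, spec),
                 "off the LED matrix")
})

test_that("the Lambertian field peaks over the emitter and superposes linearly", {
  spec <- led_matrix_spec("custom", rows = 4, cols = 4, pitch_mm = 1,
                          peak_irradiance_mw_cm2 = 100, emitter_mm = c(0, 0))
  on1 <- matrix(FALSE, 4, 4); on1[2, 2] <- TRUE
  on2 <- matrix(FALSE, 4, 4); on2[3, 4] <- TRUE
  xs <- seq(0, 4, by = 0.1); ys <- xs
  E1 <- irradiance_field(light_pattern(spec, on1), xs, ys)
  peak <- arrayInd(which.max(E1), dim(E1))
  expect_equal(xs[peak[2]], 1.5, tolerance = 0.051)   # directly above (2,2)
  expect_equal(ys[peak[1]], 1.5, tolerance = 0.051)

  E2 <- irradiance_field(light_pattern(spec, on2), xs, ys)
  E12 <- irradiance_field(light_pattern(spec, on1 | on2), xs, ys)
  expect_equal(E12, E1 + E2, tolerance = 1e-12)       # superposition

  Ehalf <- irradiance_field(light_pattern(spec, on1, intensity = 0.5), xs, ys)
  expect_equal(Ehalf, 0.5 * E1, tolerance = 1e-12)    # linear in intensity
})

test_that("the footprint quadrature matches a fine-grid oracle", {
  spec <- led_matrix_spec("custom", rows = 1, cols = 1, pitch_mm = 1,
                          peak_irradiance_mw_cm2 = 1,
                          emitter_mm = c(0.125, 0.25), plane_distance_mm = 3)
  on <- matrix(TRUE, 1, 1)
  xs <- c(0.5, 1.2, 2.5); ys <- c(0.5, 1.5)
  E <- irradiance_field(light_pattern(spec, on), xs, ys)
  # independent oracle: very fine midpoint quadrature over the footprint
  oracle <- function(x, y) {
    n <- 400; H <- 3
    ox <- ((seq_len(n) - 0.5) / n - 0.5) * 0.125
    oy <- ((seq_len(n) - 0.5) / n - 0.5) * 0.25
    acc <- 0
    for (ex in ox) acc <- acc + sum(H^4 / (H^2 + (x - 0.5 - ex)^2 +
                                             (y - 0.5 - oy)^2)^2)
    acc / n^2
  }
  for (i in seq_along(ys)) for (j in seq_along(xs)) {
    ref <- oracle(xs[j], ys[i])
    expect_lt(abs(E[i, j] - ref) / ref, 1e-6)
  }
})

test_that("illumination uniformity improves as sigma shrinks", {
  u1 <- led_uniformity(1, n_leds = 32)
  u10 <- led_uniformity(10, n_leds = 32)
  expect_gt(u1, u10)
  expect_gt(led_uniformity(0.002, 32), 0.999)    # sigma -> 0 limit: ratio -> 1
  sweep <- vapply(c(0.1, 0.5, 1, 2, 4, 7, 10), led_uniformity, numeric(1),
                  n_leds = 32)
  expect_true(all(diff(sweep) <= 1e-4))          # monotone non-increasing
  expect_true(all(sweep > 0 & sweep <= 1))
  # the 2D square-array variant behaves the same way
  expect_gt(led_uniformity(1, 36, geometry = "grid"),
            led_uniformity(8, 36, geometry = "grid"))
  expect_error(led_uniformity(0, 32), "sigma")
})
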