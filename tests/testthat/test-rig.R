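test_that("camera block-averaging reproduces hand-computed cell means", {
  # 4 -> 3 mapping: out cell i covers [ (i-1)*4/3, i*4/3 ) of the input
  x <- matrix(as.numeric(1:16), 4, 4)
  A <- spiralctl:::overlap_matrix(3, 4)
  expect_equal(rowSums(A), rep(1, 3))
  got <- A %*% x %*% t(A)
  # hand-computed first cell: rows/cols 1..(4/3): w = (1, 1/3)/(4/3)
  w <- c(1, 1 / 3) / (4 / 3)
  expect_equal(got[1, 1], sum(outer(w, w) * x[1:2, 1:2]))

  # checkerboard: every aligned 2->1 average is the mean of its 4 pixels
  cb <- matrix(rep(c(0, 1), 50), 100, 100)
  half <- spiralctl:::block_average(cb, 50)
  expect_true(all(abs(half - 0.5) < 1e-12))
})

test_that("the virtual camera is deterministic under a fixed seed", {
  cam <- camera_spec(noise_sd = 0.05)
  u <- matrix(stats::runif(128 * 128), 128, 128)
  set.seed(7); f1 <- camera_frame(u, cam)
  set.seed(7); f2 <- camera_frame(u, cam)
  expect_identical(f1, f2)
  cam0 <- camera_spec(noise_sd = 0)
  f0 <- camera_frame(u, cam0)
  A <- spiralctl:::overlap_matrix(100, 128)
  expect_equal(f0, A %*% u %*% t(A))
  inv <- camera_spec(noise_sd = 0, polarity = -1)
  expect_equal(camera_frame(u, inv), -f0)
})

test_that("LED-to-tissue projection is footprint-accurate and offset-equivariant", {
  d <- make_domain(128, 120, 15)
  cam <- camera_spec()
  led <- led_matrix_spec("small")
  reg <- registration(d, cam, led)
  on <- matrix(FALSE, 48, 32); on[24, 16] <- TRUE
  irr <- led_to_tissue(light_pattern(led, on), reg, d, "box")
  lit <- which(irr > 0, arr.ind = TRUE)
  expect_gt(nrow(lit), 0)
  # footprint is one pitch (0.6 mm = 5 grid nodes at 120 um)
  expect_lte(diff(range(lit[, 1])), 5)
  expect_lte(diff(range(lit[, 2])), 5)

  reg3 <- registration(d, cam, led, offset_mm = c(3 * 0.6, 0))
  irr3 <- led_to_tissue(light_pattern(led, on), reg3, d, "box")
  lit3 <- which(irr3 > 0, arr.ind = TRUE)
  expect_equal(sort(unique(lit3[, 1])), sort(unique(lit[, 1])) + 15)

  # lambertian and box modes deliver comparable total power on a full pattern
  full <- light_pattern(led, matrix(TRUE, 48, 32))
  pb <- sum(led_to_tissue(full, reg, d, "box"))
  pl <- sum(led_to_tissue(full, reg, d, "lambertian"))
  expect_lt(abs(pb - pl) / pb, 0.15)
})

test_that("movies round-trip through TIFF with an enforced metadata sidecar", {
  fr <- array(stats::rnorm(20 * 20 * 6, sd = 30) - 40, c(20, 20, 6))
  mv <- voltage_movie(fr, 6, 120, seed = 5)
  path <- tempfile(fileext = ".tif")
  write_movie(mv, path)
  r1 <- read_movie(path)
  r2 <- read_movie(path)
  expect_identical(r1$frames, r2$frames)          # stable float32 content
  expect_equal(r1$frames, fr, tolerance = 1e-6)   # float32 quantization only
  expect_equal(r1$frame_interval_ms, 6)
  expect_equal(r1$spacing_um, 120)

  rds <- tempfile(fileext = ".rds")
  write_movie_rds(mv, rds)
  r3 <- read_movie_rds(rds)
  expect_identical(r3$frames, fr)                 # exact native round trip
  expect_equal(r1$frames, r3$frames, tolerance = 1e-6)

  file.remove(paste0(path, ".json"))
  expect_error(read_movie(path), "sidecar missing")
})

test_that("a commanded point stimulus activates at the commanded camera pixel", {
  d <- make_domain(128, 120, 15)
  het <- spiralctl:::homogeneous_heterogeneity(d)
  model <- cell_model_fk()
  cam <- camera_spec(noise_sd = 0)
  # command a stimulus at camera pixel (40, 62): identity registration
  px_mm <- d$side_mm / cam$raster
  target <- c(40, 62)
  spot <- stim_disc(d, (target[2] - 0.5) * px_mm, (target[1] - 0.5) * px_mm, 0.4)
  ev <- list(stimulus_event(d, spot, "optical", 0, 30, 1))
  mv <- run_protocol(d, het, ev, sim_config(dt_ms = 0.1, record_every = 20,
                                            duration_ms = 40), model = model)
  # earliest activation on the camera raster
  Tn <- dim(mv$frames)[3]
  act <- matrix(Inf, cam$raster, cam$raster)
  for (t in seq_len(Tn)) {
    f <- camera_frame((mv$frames[, , t] + 84) / 100, cam)
    act[f > 0.4 & !is.finite(act)] <- t
  }
  first <- which(act == min(act), arr.ind = TRUE)
  centroid <- colMeans(first)
  expect_lte(max(abs(centroid - target)), 2)
})

test_that("termination tolerates a three-LED-pitch registration offset", {
  # in-silico analogue of the camera/LED misalignment-tolerance experiment:
  # shift the LED frame by 3 pitches (1.8 mm) and terminate a fixture that
  # the aligned system terminates
  trials <- acceptance_loop_trials(n_fixtures = 20)
  good <- which(vapply(trials, function(tr)
    isTRUE(attr(tr$on, "terminated")) && attr(tr$on, "n_attempts") == 1,
    logical(1)))[1]
  expect_false(is.na(good))
  s <- acceptance_corpus()$samples[[good]]
  cfg <- desk_config()
  led <- led_matrix_spec("small")
  cam <- camera_spec()
  reg <- registration(cfg$domain, cam, led, offset_mm = c(3 * led$pitch_mm, 0))
  rig <- virtual_rig(cfg$domain, s$het, cfg$model, s$final_state,
                     camera = cam, led = led, reg = reg, dt_ms = cfg$dt_ms)
  log <- run_closed_loop(rig, acceptance_fit(), seed = s$seed,
                         control = TRUE, horizon_s = 13)
  expect_true(attr(log, "terminated"))
})
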