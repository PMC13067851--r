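test_that("a spatially uniform oscillation gives a uniform advancing phase", {
  Tn <- 40
  fr <- array(rep(sin(2 * pi * (1:Tn) / 20), each = 64), c(8, 8, Tn))
  pm <- compute_phase(voltage_movie(fr, 6, 100))
  expect_true(all(pm$valid))
  th <- pm$theta
  for (t in seq_len(dim(th)[3])) {
    expect_lt(diff(range(th[, , t])), 1e-9)      # spatially uniform
  }
  # embedding phase advances non-uniformly within a cycle but sums to
  # exactly one turn per oscillation period
  adv <- spiralctl:::wrap_phase(diff(th[4, 4, ]))
  expect_lt(abs(abs(sum(adv[1:20])) - 2 * pi), 1e-6)
  expect_true(all(sign(adv) == sign(adv[1])))  # monotone rotation
})

test_that("constant movies have no valid phase", {
  fr <- array(1, c(8, 8, 20))
  pm <- compute_phase(voltage_movie(fr, 6, 100))
  expect_false(any(pm$valid))
  expect_true(all(is.na(pm$theta)))
})

test_that("a rotating pinwheel yields exactly one singularity at its center", {
  for (chir in c(1, -1)) {
    mv <- pinwheel_movie(n = 41, center = c(21.5, 21.5), chirality = chir)
    pm <- compute_phase(mv)
    ps <- detect_ps(pm)
    mid <- ps[ps$frame == 10, ]
    expect_equal(nrow(mid), 1)
    expect_lt(abs(mid$row - 21.5), 1.5)
    expect_lt(abs(mid$col - 21.5), 1.5)
  }
  # opposite chirality gives opposite charge
  ch1 <- detect_ps(compute_phase(pinwheel_movie(chirality = 1)))$charge[1]
  ch2 <- detect_ps(compute_phase(pinwheel_movie(chirality = -1)))$charge[1]
  expect_equal(ch1, -ch2)
})

test_that("static phase frames carry charge of the expected sign", {
  n <- 21
  rows <- matrix(seq_len(n), n, n); cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  th_pos <- atan2(rows - 10.2, cols - 10.7)
  ps <- detect_ps(th_pos)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$row, 10.5); expect_equal(ps$col, 10.5)
  th_neg <- atan2(rows - 10.2, -(cols - 10.7))
  expect_equal(detect_ps(th_neg)$charge, -ps$charge)
})

test_that("total detected charge equals the boundary winding number", {
  for (s in 1:100) {
    th <- random_phase_field(n = 24, seed = s)
    ps <- detect_ps(th)
    expect_identical(sum(ps$charge), as.numeric(boundary_winding(th)),
                     info = sprintf("field seed %d", s))
  }
})

test_that("detection is translation-equivariant and flips under mirroring", {
  m1 <- pinwheel_movie(n = 41, center = c(16.5, 19.5))
  m2 <- pinwheel_movie(n = 41, center = c(23.5, 27.5))
  p1 <- detect_ps(compute_phase(m1)); p1 <- p1[p1$frame == 8, ]
  p2 <- detect_ps(compute_phase(m2)); p2 <- p2[p2$frame == 8, ]
  expect_equal(p2$row - p1$row, 7)
  expect_equal(p2$col - p1$col, 8)

  # mirroring the movie flips every detected charge
  mm <- m1
  mm$frames <- mm$frames[, rev(seq_len(dim(mm$frames)[2])), , drop = FALSE]
  pm <- detect_ps(compute_phase(mm))
  expect_true(all(pm$charge == -p1$charge[1]))
})

test_that("analytic-signal phase localizes the pinwheel center too", {
  mv <- pinwheel_movie(n = 30, center = c(15.5, 16.5), n_frames = 40)
  ps_h <- detect_ps(compute_phase(mv, method = "hilbert"))
  expect_gt(nrow(ps_h), 0)
  expect_lt(abs(stats::median(ps_h$row) - 15.5), 2)
  expect_lt(abs(stats::median(ps_h$col) - 16.5), 2)
  # uniform oscillation: analytic phase advances exactly omega per frame
  Tn <- 40
  fr <- array(rep(sin(2 * pi * (1:Tn) / 20), each = 36), c(6, 6, Tn))
  pm <- compute_phase(voltage_movie(fr, 6, 100), method = "hilbert")
  adv <- spiralctl:::wrap_phase(diff(pm$theta[3, 3, ]))
  expect_true(all(abs(adv - 2 * pi / 20) < 1e-6))
})

test_that("consensus tracking links detections and prefers long-lived tracks", {
  # stationary singularity
  ps <- data.frame(frame = 1:20, row = 10.5, col = 10.5, charge = 1)
  cc <- consensus_core(ps, 20)
  expect_equal(cc$length, 20)
  expect_true(all(cc$track$row == 10.5))

  # drifting 1 px/frame stays one linked track
  ps <- data.frame(frame = 1:20, row = 5.5 + (1:20) * 0.7, col = 10.5,
                   charge = 1)
  cc <- consensus_core(ps, 20)
  expect_equal(cc$length, 20)
  expect_equal(cc$n_tracks, 1)

  # longevity rule: the 20-frame track beats the 5-frame track
  ps <- rbind(data.frame(frame = 1:20, row = 10.5, col = 10.5, charge = 1),
              data.frame(frame = 1:5, row = 30.5, col = 30.5, charge = -1))
  cc <- consensus_core(ps, 20)
  expect_equal(cc$track$row[1], 10.5)
  expect_equal(cc$length, 20)

  expect_null(consensus_core(ps[0, ], 20))
})
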