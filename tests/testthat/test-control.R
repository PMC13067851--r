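test_that("pack preprocessing is a high-pass + blur + crop pipeline", {
  pack <- array(stats::rnorm(100 * 100 * 5), c(100, 100, 5))
  # a pack identical to its background leaves nothing
  same <- array(rep(pack[, , 1], 5), c(100, 100, 5))
  pp <- preprocess_pack(same, background = pack[, , 1])
  expect_true(all(pp$window == 0))
  expect_equal(dim(pp$window), c(86, 86, 5))
  expect_equal(pp$background, same[, , 5])

  # an interior impulse reproduces the 3x3 Gaussian kernel exactly
  imp <- array(0, c(100, 100, 5)); imp[50, 50, ] <- 16
  pp <- preprocess_pack(imp, background = matrix(0, 100, 100))
  kern <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3)
  got <- pp$window[42:44, 42:44, 1] * pp$amplitude   # undo normalization
  expect_equal(got, kern)
  expect_equal(pp$amplitude, 4)                      # peak of 16 * (4/16)
  expect_error(preprocess_pack(array(0, c(100, 100, 4))), "5")
})

test_that("the 0.7/10-frame trigger rule follows its truth table", {
  mk <- function(val, at = c(20, 30)) {
    m <- matrix(0.01, 86, 86); m[at[1], at[2]] <- val; m
  }
  h <- core_histogram()
  for (i in 1:10) {
    res <- update_and_decide(h, mk(0.75)); h <- res$hist
  }
  expect_equal(unname(res$decision), c(20, 30))

  # mean of maxima 0.69: below threshold, no decision
  h <- core_histogram()
  for (i in 1:10) { res <- update_and_decide(h, mk(0.69)); h <- res$hist }
  expect_null(res$decision)

  # exactly at threshold: strictly-greater semantics, no decision
  h <- core_histogram()
  for (i in 1:10) { res <- update_and_decide(h, mk(0.7)); h <- res$hist }
  expect_null(res$decision)

  # 9 frames at 0.99: buffer not full, no decision
  h <- core_histogram()
  for (i in 1:9) { res <- update_and_decide(h, mk(0.99)); h <- res$hist }
  expect_null(res$decision)

  # NaN map is dropped and logged, not pushed
  h <- core_histogram()
  res <- update_and_decide(h, matrix(NaN, 86, 86))
  expect_equal(res$hist$dropped, 1L)
  expect_length(res$hist$maxs, 0)
})

test_that("histogram ties resolve to the most recent occupant", {
  h <- core_histogram()
  seqpos <- list(c(10, 10), c(40, 40), c(10, 10), c(40, 40), c(10, 10),
                 c(40, 40), c(10, 10), c(40, 40), c(10, 10), c(40, 40))
  for (p in seqpos) {
    m <- matrix(0.01, 86, 86); m[p[1], p[2]] <- 0.9
    res <- update_and_decide(h, m); h <- res$hist
  }
  expect_equal(unname(res$decision), c(40, 40))  # 5-5 tie, (40,40) most recent
})

test_that("the light line runs from the core to the nearest boundary", {
  n <- 101
  rows <- matrix(seq_len(n), n, n); cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  R <- 40
  mask <- (rows - 51)^2 + (cols - 51)^2 <= R^2

  # center core: path length R +/- 1 in some direction
  p <- nearest_border_line(c(51, 51), mask)
  expect_lt(abs(nrow(p) - R), 1.6)
  # with an exactly symmetric square mask the tie resolves along +x
  sq <- matrix(FALSE, 41, 41); sq[6:36, 6:36] <- TRUE
  ps <- nearest_border_line(c(21, 21), sq)
  expect_true(all(ps$row == 21))
  expect_true(all(diff(ps$col) == 1))

  # core 2 px from the border: short path
  p2 <- nearest_border_line(c(51, 51 + R - 2), mask)
  expect_lte(nrow(p2), 3)

  # connectivity and boundary adjacency across 100 random interior cores
  set.seed(1)
  for (k in 1:100) {
    repeat {
      core <- c(sample(15:87, 1), sample(15:87, 1))
      if (mask[core[1], core[2]]) break
    }
    p <- nearest_border_line(core, mask)
    dd <- cbind(diff(p$row), diff(p$col))
    expect_true(all(pmax(abs(dd[, 1]), abs(dd[, 2])) == 1))   # 8-connected
    last <- as.numeric(p[nrow(p), ])
    nb <- expand.grid(dr = -1:1, dc = -1:1)
    adj <- mapply(function(dr, dc) {
      r <- last[1] + dr; c <- last[2] + dc
      r < 1 || r > n || c < 1 || c > n || !mask[r, c]
    }, nb$dr, nb$dc)
    expect_true(any(adj))                     # endpoint touches non-mask
  }
  expect_error(nearest_border_line(c(1, 1), mask), "inside")
})

test_that("line width and dot pitch shape the pattern", {
  mask <- matrix(TRUE, 50, 50); mask[, 45:50] <- FALSE
  thin <- nearest_border_line(c(25, 25), mask)
  wide <- nearest_border_line(c(25, 25), mask, width = 3)
  expect_gt(nrow(wide), nrow(thin))
  dotted <- nearest_border_line(c(25, 25), mask, dot_pitch = 3)
  expect_lt(nrow(dotted), nrow(thin))
})

test_that("well partition applies the rule per zone and honors disabled wells", {
  layout <- list(list(id = 1, rows = c(1, 43), cols = c(1, 43)),
                 list(id = 2, rows = c(1, 43), cols = c(44, 86)),
                 list(id = 3, rows = c(44, 86), cols = c(1, 43),
                      enabled = FALSE),
                 list(id = 4, rows = c(44, 86), cols = c(44, 86)))
  st <- well_partition(layout)
  m <- matrix(0.01, 86, 86)
  m[20, 20] <- 0.9; m[20, 60] <- 0.9; m[60, 20] <- 0.9; m[60, 60] <- 0.9
  for (i in 1:10) { res <- partition_wells(st, m); st <- res$state }
  expect_equal(unname(res$decisions[["1"]]), c(20, 20))
  expect_equal(unname(res$decisions[["2"]]), c(20, 60))
  expect_null(res$decisions[["3"]])           # disabled control well
  expect_equal(unname(res$decisions[["4"]]), c(60, 60))

  # empty map: no decisions anywhere
  st <- well_partition(layout)
  for (i in 1:10) { res <- partition_wells(st, matrix(0, 86, 86)); st <- res$state }
  expect_true(all(vapply(res$decisions, is.null, logical(1))))

  expect_error(well_partition(list(
    list(id = 1, rows = c(1, 50), cols = c(1, 50)),
    list(id = 2, rows = c(40, 86), cols = c(40, 86)))), "overlap")
})

test_that("the pulse schedule follows the 3 s / 0.5 s / 3 s policy", {
  pol <- timing_policy()
  ev <- schedule_pulses(pol, 0)
  expect_equal(ev$time_ms, c(3000, 3500, 6500))
  expect_equal(ev$kind, c("pulse_on", "pulse_off", "re_arm"))

  # a second trigger inside the blanking window is ignored and reported
  ev2 <- schedule_pulses(pol, c(0, 5000, 8000))
  expect_equal(attr(ev2, "ignored"), 5000)
  expect_equal(sum(ev2$kind == "pulse_on"), 2)

  expect_error(timing_policy(pulse_ms = 0), "config error")
})

test_that("termination requires sustained quiescence without decisions", {
  mon <- termination_monitor(amp_threshold = 0.1, hold_ms = 1000)
  t <- 0; done <- FALSE
  while (t <= 1500 && !done) {
    u <- update_termination(mon, t, amplitude = 0, decision_fired = FALSE)
    mon <- u$mon; done <- u$terminated; t <- t + 40
  }
  expect_true(done)
  expect_lte(t, 1200)

  # persistent high-amplitude activity is never "terminated"
  mon <- termination_monitor(0.1, 1000)
  for (t in seq(0, 5000, by = 40)) {
    u <- update_termination(mon, t, amplitude = 5, decision_fired = FALSE)
    mon <- u$mon
  }
  expect_false(u$terminated)

  # paced-rhythm semantics: periodic planar waves that never trigger the
  # core rule count as "no reentry" under the decision-only criterion
  mon <- termination_monitor(0.1, 1000, no_decision_hold_ms = 2000)
  for (t in seq(0, 2500, by = 40)) {
    u <- update_termination(mon, t, amplitude = 5, decision_fired = FALSE)
    mon <- u$mon
  }
  expect_true(u$terminated)
})
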