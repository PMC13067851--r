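test_that("label maps are unit-peak Gaussians with the closed-form mass", {
  L <- render_label(c(43, 43), c(86, 86), sigma = 3)
  expect_equal(L[43, 43], 1)
  expect_equal(which.max(L), which(row(L) == 43 & col(L) == 43))
  expect_equal(L[43, 46], exp(-0.5))          # one sigma from the peak
  expect_equal(L[40, 43], exp(-0.5))

  # total mass equals the separable product of 1D sums (independent closed form)
  sx <- sum(exp(-(seq_len(86) - 43)^2 / 18))
  expect_lt(abs(sum(L) - sx * sx), 1e-6)

  expect_error(render_label(c(0, 10), c(86, 86)), "outside")
})

test_that("window extraction yields the stated counts and spans", {
  fr <- array(stats::rnorm(20 * 20 * 208), c(20, 20, 208))
  mv <- voltage_movie(fr, 6, 100)
  w <- make_windows(mv, preprocess = FALSE)
  expect_length(w, 204)                          # 208 - 5 + 1
  expect_equal(w[[1]]$last_frame, 5)
  # each window spans 5 frames x 6 ms = 30 ms
  expect_equal(dim(w[[1]]$window)[3] * mv$frame_interval_ms, 30)
  short <- voltage_movie(fr[, , 1:4, drop = FALSE], 6, 100)
  expect_warning(w0 <- make_windows(short, preprocess = FALSE), "shorter")
  expect_length(w0, 0)
})

test_that("train/validation split keeps augmentations of a base together", {
  manifest <- expand.grid(base = 1:10, transform = spiralctl:::d4_tags())
  manifest$id <- seq_len(nrow(manifest))
  sp <- split_manifest(manifest, 0.8, seed = 3)
  expect_equal(length(unique(sp$base[sp$split == "train"])), 8)
  expect_equal(length(unique(sp$base[sp$split == "val"])), 2)
  # no base straddles the split
  tab <- table(sp$base, sp$split)
  expect_true(all(rowSums(tab > 0) == 1))
  sp2 <- split_manifest(manifest, 0.8, seed = 3)
  expect_identical(sp$split, sp2$split)
  expect_error(split_manifest(manifest, 1.2), "config error")
})

test_that("dihedral transforms act consistently on frames and coordinates", {
  n <- 41
  tags <- spiralctl:::d4_tags()
  expect_length(unique(tags), 8)
  m <- matrix(stats::rnorm(n * n), n, n)
  expect_identical(spiralctl:::d4_frame(m, "r0"), m)    # identity is exact
  # coordinate map mirrors the frame map for every transform
  for (tag in tags) {
    tm <- spiralctl:::d4_frame(m, tag)
    idx <- c(7, 31)
    val <- m[idx[1], idx[2]]
    new_rc <- spiralctl:::d4_coords(idx, n, tag)
    expect_equal(tm[new_rc[1], new_rc[2]], val, info = tag)
  }
})

test_that("re-detecting the core on a transformed movie finds transformed coordinates", {
  mv <- pinwheel_movie(n = 41, center = c(15.5, 24.5), n_frames = 24)
  base_ps <- detect_ps(compute_phase(mv))
  base <- spiralctl:::consensus_core(base_ps, 24)
  for (tag in spiralctl:::d4_tags()) {
    tf <- mv
    for (t in seq_len(dim(mv$frames)[3]))
      tf$frames[, , t] <- spiralctl:::d4_frame(mv$frames[, , t], tag)
    ps <- detect_ps(compute_phase(tf))
    cc <- consensus_core(ps, 24)
    want <- spiralctl:::d4_coords(c(base$track$row[10], base$track$col[10]),
                                  41, tag)
    got <- spiralctl:::core_at_frame(cc, base$track$frame[10])
    expect_lt(abs(got[1] - want[1]), 0.51, label = tag)
    expect_lt(abs(got[2] - want[2]), 0.51, label = tag)
    # chirality flips under mirror transforms
    if (startsWith(tag, "m"))
      expect_equal(cc$track$charge[1], -base$track$charge[1], info = tag)
  }
})

test_that("augment_sample emits eight tagged variants with exact identity", {
  fr <- array(stats::rnorm(20 * 20 * 10), c(20, 20, 10))
  sample <- structure(list(
    seed = 1,
    movie = voltage_movie(fr, 6, 100),
    movie86 = voltage_movie(fr, 6, 100),
    core = list(track = data.frame(frame = 1:10, row = 7.5, col = 12.5,
                                   charge = 1), length = 10)),
    class = "spiral_sample")
  aug <- augment_sample(sample)
  expect_length(aug, 8)
  expect_identical(aug[[1]]$movie$frames, fr)     # identity is bit-identical
  expect_length(unique(vapply(aug, `[[`, "", "transform")), 8)
  expect_equal(aug[[5]]$core$track$charge[1], -1) # mirrored variants flip
  nonsq <- sample
  nonsq$movie$frames <- array(0, c(20, 30, 10))
  expect_error(augment_sample(nonsq), "square")
})
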