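#' Generator configuration for the synthetic training corpus
#'
#' Bundles the study conditions of the virtual-monolayer generator: grid and
#' disc geometry, cell model, integration step and the 6-ms recording cadence
#' that yields a 208-frame movie from 1.25 s of activity. The `"paper"`
#' preset uses the reference conditions (256 x 256 grid at 60 um, dt =
#' 0.005 ms, a frame every 1200 steps); the `"desk"` preset keeps the same
#' physical geometry and recording arithmetic on a coarser raster (128 x 128
#' at 120 um, dt = 0.1 ms, a frame every 60 steps), which the
#' phenomenological cell model integrates stably (see [check_stability()]).
#'
#' @param preset `"desk"` or `"paper"`.
#' @param model cell model.
#' @param camera_raster camera raster the movies are rendered to.
#' @param crop_size detector input side.
#' @param s2_radius_mm unused for the half-plane premature stimulus; kept for
#'   spot-stimulus experiments.
#' @param stabilize_ms delay between the premature stimulus and the start of
#'   recording, letting the spiral settle.
#' @param label_sigma width (pixels) of the Gaussian target bump.
#' @export
generator_config <- function(preset = c("desk", "paper"),
                             model = cell_model_fk(),
                             camera_raster = 100, crop_size = 86,
                             s2_radius_mm = 2, stabilize_ms = 300,
                             label_sigma = 5) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    n_points <- 256; spacing <- 60; dt <- 0.005; rec <- 1200
  } else {
    n_points <- 128; spacing <- 120; dt <- 0.1; rec <- 60
  }
  domain <- make_domain(n_points, spacing, 15)
  list(preset = preset, domain = domain, model = model,
       dt_ms = dt, record_every = rec, duration_ms = 1250,
       camera_raster = camera_raster, crop_size = crop_size,
       s2_radius_mm = s2_radius_mm, stabilize_ms = stabilize_ms,
       label_sigma = label_sigma)
}

# Induce a spiral with the adaptive S1S2 protocol and return the final state
# plus bookkeeping; shared by generate_sample and the closed-loop fixtures.
# S1 is a strip at the left edge; S2 is a half-plane whose edge passes
# through a random interior site, oriented perpendicular (+/- jitter) to the
# S1 propagation direction, fired a few ms after the site becomes excitable
# again -- i.e. into the vulnerable window of the S1 repolarization tail.
induce_spiral <- function(config, seed) {
  domain <- config$domain; model <- config$model
  het <- sample_heterogeneity(domain, seed)
  set.seed(seed + 500009L)
  coords <- node_centers_mm(domain)
  ang <- stats::runif(1, 0, 2 * pi); rr <- 5 * sqrt(stats::runif(1))
  cx <- domain$side_mm / 2 + rr * cos(ang)
  cy <- domain$side_mm / 2 + rr * sin(ang)
  phi <- sample(c(-1, 1), 1) * pi / 2 + stats::runif(1, -0.3, 0.3)
  s2geom <- matrix((coords$x - cx) * cos(phi) + (coords$y - cy) * sin(phi) > 0,
                   domain$n_rows, domain$n_cols)
  h_mm <- domain$spacing_um / 1000
  site <- c(max(1, round(cy / h_mm)), max(1, round(cx / h_mm)))
  photo <- photo_defaults(model)
  weights <- domain_edge_weights(domain, model$D_mm2_ms, het$coupling_scale)
  s1 <- stimulus_event(domain, stim_edge_strip(domain, "left", 0.5),
                       "electrical", 0, 2, 1.0)
  state <- rest_state(domain, model)
  dt <- config$dt_ms
  t_cur <- 0; seen_up <- FALSE; t_fire <- NA
  repeat {
    ch <- integrate_chunk(state, domain, het, model, list(s1), dt,
                          round(6 / dt), round(t_cur / dt), 0L, photo,
                          weights = weights)
    state <- ch$state; t_cur <- t_cur + 6
    uu <- state$u[site[1], site[2]]
    if (!seen_up && uu > 0.5) seen_up <- TRUE
    if (seen_up && uu < 0.04) { t_fire <- t_cur + 10; break }
    if (t_cur > 900)
      return(list(ok = FALSE, reason = if (seen_up) "no_recovery" else
        "propagation_failure", het = het, seed = seed))
  }
  s2 <- stimulus_event(domain, s2geom, "electrical", t_fire, 2, 0.5)
  ch <- integrate_chunk(state, domain, het, model, list(s2), dt,
                        round((t_fire - t_cur + config$stabilize_ms) / dt),
                        round(t_cur / dt), 0L, photo, weights = weights)
  list(ok = TRUE, state = ch$state, het = het, weights = weights,
       t_fire = t_fire, s2_center = c(cx, cy), seed = seed)
}

#' Generate one labelled training sample
#'
#' Runs the full generator pipeline for one seed: sample heterogeneity,
#' induce a spiral with the adaptive S1S2 protocol, record 1.25 s at 6 ms
#' resolution, render the simulation to the camera raster, classify the
#' recording, and (for sustained spirals) extract the consensus core
#' trajectory with the topological-charge detector. Samples whose tissue
#' fails to propagate, whose spiral dies, or whose core leaves the detector
#' crop are returned as rejection records with the reason; the decision is
#' deterministic per seed.
#'
#' @param seed integer seed (drives heterogeneity, stimulus placement and
#'   timing).
#' @param config a [generator_config()].
#' @return A `spiral_sample` (fields `movie` -- the camera-raster recording
#'   in normalized fluorescence units, `movie86`, `core`, `het`, `seed`,
#'   `final_state`) or a `sample_rejection` (fields `seed`, `reason`).
#' @export
generate_sample <- function(seed, config = generator_config()) {
  ind <- induce_spiral(config, seed)
  if (!ind$ok)
    return(structure(list(seed = seed, reason = ind$reason),
                     class = "sample_rejection"))
  domain <- config$domain; model <- config$model
  dt <- config$dt_ms
  photo <- photo_defaults(model)
  if (max(ind$state$u) < 0.05)
    return(structure(list(seed = seed, reason = "no_sustained_spiral"),
                     class = "sample_rejection"))
  # record in four blocks and stop early if the tissue dies mid-recording
  # (such movies classify as no_sustained_spiral anyway)
  n_total <- round(config$duration_ms / dt)
  block <- ceiling(n_total / 4 / config$record_every) * config$record_every
  state <- ind$state
  frames <- NULL; done <- 0L
  while (done < n_total) {
    nst <- min(block, n_total - done)
    ch <- integrate_chunk(state, domain, ind$het, model, list(), dt,
                          nst, done, config$record_every, photo,
                          weights = ind$weights)
    state <- ch$state; done <- done + nst
    if (!is.null(ch$frames))
      frames <- if (is.null(frames)) ch$frames else abind3(frames, ch$frames)
    if (done < n_total && max(state$u) < 0.05)
      return(structure(list(seed = seed, reason = "no_sustained_spiral"),
                       class = "sample_rejection"))
  }
  ch <- list(frames = frames, state = state)
  if (is.null(ch$frames))
    return(structure(list(seed = seed, reason = "no_sustained_spiral"),
                     class = "sample_rejection"))
  mv100 <- voltage_movie(block_average(ch$frames, config$camera_raster),
                         frame_interval_ms = dt * config$record_every,
                         spacing_um = domain$side_mm * 1000 / config$camera_raster,
                         seed = seed, final_state = NULL)
  mv86 <- voltage_movie(center_crop(mv100$frames, config$crop_size),
                        mv100$frame_interval_ms, mv100$spacing_um, seed)
  label <- classify_sample(voltage_movie(u_to_mv(mv86$frames, model),
                                         mv86$frame_interval_ms,
                                         mv86$spacing_um, seed))
  if (c(label) != "sustained_spiral")
    return(structure(list(seed = seed, reason = c(label)),
                     class = "sample_rejection"))
  core <- attr(label, "core")
  structure(list(seed = seed, movie = mv100, movie86 = mv86, core = core,
                 het = ind$het, t_fire = ind$t_fire,
                 final_state = state, config = config,
                 label = "sustained_spiral"),
            class = "spiral_sample")
}

#' @export
print.spiral_sample <- function(x, ...) {
  cat(sprintf("<spiral_sample> seed %d: sustained spiral, core tracked over %d frames\n",
              x$seed, x$core$length))
  invisible(x)
}

#' @export
print.sample_rejection <- function(x, ...) {
  cat(sprintf("<sample_rejection> seed %d: %s\n", x$seed, x$reason))
  invisible(x)
}

# ---- dihedral-group augmentation ------------------------------------------

rot90_ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
mirror_cols <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

# Apply one of the 8 square-symmetry transforms to a matrix.
d4_frame <- function(m, tag) {
  if (startsWith(tag, "m")) { m <- mirror_cols(m); tag <- sub("^m", "", tag) }
  switch(tag,
         id = , r0 = m,
         r90 = rot90_ccw(m),
         r180 = rot90_ccw(rot90_ccw(m)),
         r270 = rot90_ccw(rot90_ccw(rot90_ccw(m))),
         stop("unknown transform tag"))
}

# The matching map for continuous (row, col) coordinates on an n x n raster
# (centers in [0.5, n + 0.5]); returns c(row, col).
d4_coords <- function(rc, n, tag) {
  r <- rc[1]; c <- rc[2]
  if (startsWith(tag, "m")) { c <- n + 1 - c; tag <- sub("^m", "", tag) }
  for (i in seq_len(switch(tag, id = , r0 = 0, r90 = 1, r180 = 2, r270 = 3))) {
    tmp <- n + 1 - c; c <- r; r <- tmp
  }
  c(r, c)
}

d4_tags <- function() c("r0", "r90", "r180", "r270", "mr0", "mr90", "mr180", "mr270")

#' All eight dihedral-group augmentations of a sample
#'
#' Applies the four 90-degree rotations, with and without mirroring, to the
#' sample's movie and core trajectory. Rotations are exact raster
#' permutations (no interpolation); the spiral chirality metadata flips under
#' mirroring.
#'
#' @param sample a `spiral_sample` (square movie).
#' @return list of 8 samples, each carrying a `transform` tag.
#' @export
augment_sample <- function(sample) {
  fr <- sample$movie$frames
  d <- dim(fr)
  if (d[1] != d[2]) stop("geometry error: augmentation requires a square movie")
  lapply(d4_tags(), function(tag) {
    out <- sample
    tf <- array(0, d)
    for (t in seq_len(d[3])) tf[, , t] <- d4_frame(fr[, , t], tag)
    out$movie$frames <- tf
    if (!is.null(sample$movie86)) {
      f86 <- sample$movie86$frames
      t86 <- array(0, dim(f86))
      for (t in seq_len(dim(f86)[3])) t86[, , t] <- d4_frame(f86[, , t], tag)
      out$movie86$frames <- t86
    }
    if (!is.null(sample$core)) {
      n86 <- dim(sample$movie86$frames)[1]
      tr <- sample$core$track
      rc <- t(vapply(seq_len(nrow(tr)), function(i)
        d4_coords(c(tr$row[i], tr$col[i]), n86, tag), numeric(2)))
      out$core$track$row <- rc[, 1]; out$core$track$col <- rc[, 2]
      if (startsWith(tag, "m"))
        out$core$track$charge <- -out$core$track$charge
    }
    out$transform <- tag
    out
  })
}

#' Gaussian core-probability target
#'
#' The training target for one window: an isotropic Gaussian bump with peak
#' exactly 1 at the pixel containing the core, width `sigma`.
#'
#' @param core `c(row, col)` core location (may be fractional; the peak pixel
#'   is the nearest raster pixel).
#' @param shape `c(rows, cols)` of the map.
#' @param sigma bump width in pixels.
#' @export
render_label <- function(core, shape = c(86, 86), sigma = 3) {
  r0 <- round(core[1]); c0 <- round(core[2])
  if (r0 < 1 || r0 > shape[1] || c0 < 1 || c0 > shape[2])
    stop("core outside the label map")
  d2 <- outer((seq_len(shape[1]) - r0)^2, (seq_len(shape[2]) - c0)^2, "+")
  exp(-d2 / (2 * sigma^2))
}

#' Five-frame training windows from a movie
#'
#' Cuts a movie into overlapping windows of `n_frames` consecutive frames
#' (30 ms of activity at the 6 ms cadence -- less than one rotation), each
#' associated with the frame index of its last frame, whose core position
#' labels the window. When `preprocess = TRUE` each window runs through the
#' same pipeline as the real-time camera stream ([preprocess_pack()]), with
#' the frame immediately before the window as background.
#'
#' @param movie a [voltage_movie()] on the camera raster.
#' @param n_frames frames per window (5).
#' @param stride step between window starts.
#' @param preprocess run the runtime preprocessing pipeline.
#' @param crop_size detector input side.
#' @return list of windows: `list(window, last_frame, amplitude)`; empty
#'   (with a warning) if the movie is shorter than `n_frames`.
#' @export
make_windows <- function(movie, n_frames = 5, stride = 1, preprocess = TRUE,
                         crop_size = 86) {
  fr <- movie$frames
  Tn <- dim(fr)[3]
  if (Tn < n_frames) {
    warning("movie shorter than one window; empty window list")
    return(list())
  }
  starts <- seq(1, Tn - n_frames + 1, by = stride)
  lapply(starts, function(i) {
    if (preprocess) {
      bg <- if (i > 1) fr[, , i - 1] else NULL
      pp <- preprocess_pack(fr[, , i:(i + n_frames - 1)], bg, crop_size)
      list(window = pp$window, last_frame = i + n_frames - 1,
           amplitude = pp$amplitude)
    } else {
      list(window = fr[, , i:(i + n_frames - 1)], last_frame = i + n_frames - 1,
           amplitude = max(abs(fr[, , i:(i + n_frames - 1)])))
    }
  })
}

#' Train/validation split by base sample
#'
#' Assigns base samples (not windows) to the training or validation split so
#' that all augmentations and windows of one simulated monolayer stay on the
#' same side -- the augmentation-aware leakage guard.
#'
#' @param manifest data.frame with a `base` column (one row per corpus item).
#' @param fraction training fraction (0.8).
#' @param seed split seed.
#' @return the manifest with a `split` column (`"train"` / `"val"`).
#' @export
split_manifest <- function(manifest, fraction = 0.8, seed = 1) {
  if (fraction <= 0 || fraction >= 1)
    stop("config error: fraction must be in (0, 1)")
  bases <- unique(manifest$base)
  if (length(bases) < 2) stop("need at least two base samples to split")
  set.seed(seed)
  n_train <- round(fraction * length(bases))
  train <- sample(bases, n_train)
  manifest$split <- ifelse(manifest$base %in% train, "train", "val")
  manifest
}

#' Build an augmented, labelled, split training corpus
#'
#' Runs [generate_sample()] over consecutive seeds until `n_base` sustained
#' spirals are accepted, draws `windows_per_base` window positions from each
#' accepted movie (within the frames covered by the core track), applies all
#' eight dihedral augmentations to every window and its label, adds seeded
#' camera noise before preprocessing, and splits 80/20 by base sample.
#'
#' @param n_base accepted base simulations.
#' @param seed master seed; sample seeds are `seed * 1000 + attempt`.
#' @param config a [generator_config()].
#' @param windows_per_base window positions drawn per base sample.
#' @param noise_sd camera noise (sd, normalized fluorescence units) added to
#'   the raw frames before preprocessing.
#' @param label_sigma Gaussian target width, px (5 px: broad enough to keep
#'   the sparse-target objective trainable at desk scale).
#' @param split_fraction training fraction.
#' @param progress print one line per accepted sample.
#' @return list of class `spiral_corpus`: `windows` (\[86, 86, 5, N\]),
#'   `labels` (\[86, 86, N\]), `manifest` (data.frame), `generation_log`,
#'   `samples` (the accepted `spiral_sample` objects).
#' @export
build_corpus <- function(n_base, seed = 1, config = generator_config(),
                         windows_per_base = 1, noise_sd = 0.01,
                         label_sigma = 5, split_fraction = 0.8,
                         progress = FALSE) {
  samples <- list(); log <- list()
  attempt <- 0
  while (length(samples) < n_base) {
    attempt <- attempt + 1
    s <- generate_sample(seed * 1000 + attempt, config)
    if (inherits(s, "spiral_sample")) {
      samples[[length(samples) + 1]] <- s
      log[[attempt]] <- data.frame(seed = s$seed, accepted = TRUE,
                                   reason = "sustained_spiral")
      if (progress) message(sprintf("accepted %d/%d (seed %d)",
                                    length(samples), n_base, s$seed))
    } else {
      log[[attempt]] <- data.frame(seed = s$seed, accepted = FALSE,
                                   reason = s$reason)
    }
    if (attempt > 40 * n_base)
      stop("generator acceptance rate too low; check configuration")
  }
  crop <- config$crop_size
  win_list <- list(); lab_list <- list(); meta <- list()
  for (s in samples) {
    set.seed(s$seed + 900001L)
    tr <- s$core$track
    ok_frames <- tr$frame[tr$frame >= 6]       # need a background frame
    pos <- sample(ok_frames, min(windows_per_base, length(ok_frames)))
    fr <- s$movie$frames
    for (f in pos) {
      i0 <- f - 4
      pack <- fr[, , i0:f] +
        array(stats::rnorm(length(fr[, , i0:f]), 0, noise_sd), c(dim(fr)[1], dim(fr)[2], 5))
      bg <- fr[, , i0 - 1] + matrix(stats::rnorm(dim(fr)[1] * dim(fr)[2], 0, noise_sd),
                                    dim(fr)[1], dim(fr)[2])
      pp <- preprocess_pack(pack, bg, crop)
      core <- core_at_frame(s$core, f)
      for (tag in d4_tags()) {
        w <- array(0, c(crop, crop, 5))
        for (t in 1:5) w[, , t] <- d4_frame(pp$window[, , t], tag)
        cc <- d4_coords(core, crop, tag)
        win_list[[length(win_list) + 1]] <- w
        lab_list[[length(lab_list) + 1]] <- render_label(cc, c(crop, crop),
                                                         label_sigma)
        meta[[length(meta) + 1]] <- data.frame(
          base = s$seed, frame = f, transform = tag,
          core_row = cc[1], core_col = cc[2])
      }
    }
  }
  N <- length(win_list)
  windows <- array(unlist(win_list), c(crop, crop, 5, N))
  labels <- array(unlist(lab_list), c(crop, crop, N))
  manifest <- do.call(rbind, meta)
  manifest$id <- seq_len(N)
  manifest <- split_manifest(manifest, split_fraction, seed)
  structure(list(windows = windows, labels = labels, manifest = manifest,
                 generation_log = do.call(rbind, log), samples = samples,
                 config = config),
            class = "spiral_corpus")
}

#' @export
print.spiral_corpus <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<spiral_corpus> %d windows (%d base samples x %d aug), %d train / %d val\n",
              nrow(m), length(unique(m$base)), length(unique(m$transform)),
              sum(m$split == "train"), sum(m$split == "val")))
  gl <- x$generation_log
  cat(sprintf("  generator: %d attempts, %.0f%% accepted\n", nrow(gl),
              100 * mean(gl$accepted)))
  invisible(x)
}
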