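#' Phase maps from voltage movies
#'
#' Builds a per-node activation phase from a voltage movie. The default
#' method is time-delay embedding: `theta = atan2(V(t + tau) - Vbar,
#' V(t) - Vbar)` with the per-node temporal mean `Vbar`; the analytic-signal
#' (Hilbert-transform) method is available as an alternative. Nodes whose
#' signal range is below `min_amplitude_frac` of the movie's global range are
#' flagged invalid (their phase is `NA`), which suppresses noise-driven false
#' singularities near the non-conducting boundary.
#'
#' @param movie a [voltage_movie()] or a 3D array \[rows, cols, T\].
#' @param method `"embed"` (time-delay embedding, default) or `"hilbert"`.
#' @param tau embedding delay in frames (default 2).
#' @param min_amplitude_frac validity threshold as a fraction of the global
#'   signal range.
#' @return Object of class `phase_map`: list with `theta` (\[rows, cols, T'\],
#'   radians wrapped to (-pi, pi\]), `valid` (logical matrix), `tau`,
#'   `method`.
#' @export
compute_phase <- function(movie, method = c("embed", "hilbert"), tau = 2,
                          min_amplitude_frac = 0.05) {
  method <- match.arg(method)
  frames <- if (inherits(movie, "voltage_movie")) movie$frames else movie
  d <- dim(frames)
  if (method == "embed" && d[3] < tau + 1)
    stop("movie too short for embedding delay tau")
  flat0 <- matrix(frames, d[1] * d[2], d[3])
  rng <- matrix(do.call(pmax, lapply(seq_len(d[3]), function(t) flat0[, t])) -
                do.call(pmin, lapply(seq_len(d[3]), function(t) flat0[, t])),
                d[1], d[2])
  grange <- max(rng)
  valid <- rng >= min_amplitude_frac * grange & grange > 0
  vbar <- matrix(rowMeans(flat0), d[1], d[2])

  if (method == "embed") {
    Tn <- d[3] - tau
    theta <- array(NA_real_, c(d[1], d[2], Tn))
    for (t in seq_len(Tn)) {
      th <- atan2(frames[, , t + tau] - vbar, frames[, , t] - vbar)
      th[!valid] <- NA_real_
      theta[, , t] <- th
    }
  } else {
    flat <- matrix(frames, d[1] * d[2], d[3])
    flat <- sweep(flat, 1, rowMeans(flat))
    Tlen <- d[3]
    ft <- stats::mvfft(t(flat))
    h <- numeric(Tlen)
    if (Tlen %% 2 == 0) { h[1] <- 1; h[Tlen / 2 + 1] <- 1; h[2:(Tlen / 2)] <- 2 }
    else { h[1] <- 1; h[2:((Tlen + 1) / 2)] <- 2 }
    analytic <- stats::mvfft(ft * h, inverse = TRUE) / Tlen
    theta <- array(atan2(Im(t(analytic)), Re(t(analytic))), d)
    theta[array(!valid, d)] <- NA_real_
  }
  theta <- wrap_phase(theta)
  structure(list(theta = theta, valid = valid, tau = tau, method = method),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  d <- dim(x$theta)
  cat(sprintf("<phase_map> %d x %d x %d (%s method), %d valid nodes\n",
              d[1], d[2], d[3], x$method, sum(x$valid)))
  invisible(x)
}

# Wrap angles to (-pi, pi].
wrap_phase <- function(x) {
  w <- -((-x + pi) %% (2 * pi) - pi)
  w
}

#' Detect phase singularities by topological charge
#'
#' For every 2x2 plaquette of the phase field, sums the four phase
#' differences around the loop, each wrapped to (-pi, pi\]. A plaquette whose
#' circulation equals +/- 2 pi (within `tol`) encloses a phase singularity:
#' the organizing center of a spiral wave. The singularity is reported at the
#' plaquette center, i.e. at half-integer coordinates, with `charge` the sign
#' of the circulation (the spiral's chirality). Plaquettes touching invalid
#' (`NA`) nodes are skipped.
#'
#' @param phase either a `phase_map` (all frames are scanned) or a single
#'   phase frame (matrix, radians).
#' @param tol circulation tolerance around +/- 2 pi.
#' @return data.frame with columns `frame`, `row`, `col` (half-integer
#'   plaquette centers, grid units), `charge` (+1 / -1).
#' @export
detect_ps <- function(phase, tol = 1e-6) {
  if (inherits(phase, "phase_map")) {
    th <- phase$theta
    nr <- dim(th)[1]; nc <- dim(th)[2]
    a <- th[-nr, -nc, , drop = FALSE]; b <- th[-nr, -1, , drop = FALSE]
    cc <- th[-1, -1, , drop = FALSE];  d <- th[-1, -nc, , drop = FALSE]
    circ <- wrap_phase(b - a) + wrap_phase(cc - b) +
            wrap_phase(d - cc) + wrap_phase(a - d)
    hit <- which(!is.na(circ) & abs(abs(circ) - 2 * pi) < tol, arr.ind = TRUE)
    return(data.frame(frame = hit[, 3], row = hit[, 1] + 0.5,
                      col = hit[, 2] + 0.5, charge = sign(circ[hit])))
  }
  th <- phase
  nr <- nrow(th); nc <- ncol(th)
  a <- th[-nr, -nc]; b <- th[-nr, -1]; cc <- th[-1, -1]; d <- th[-1, -nc]
  circ <- wrap_phase(b - a) + wrap_phase(cc - b) +
          wrap_phase(d - cc) + wrap_phase(a - d)
  hit <- which(!is.na(circ) & abs(abs(circ) - 2 * pi) < tol, arr.ind = TRUE)
  data.frame(frame = rep.int(1L, nrow(hit)),
             row = hit[, 1] + 0.5, col = hit[, 2] + 0.5,
             charge = sign(circ[hit]))[, c("frame", "row", "col", "charge")]
}

#' Winding number of a phase field along a rectangular boundary
#'
#' Sums wrapped phase differences along the closed counter-clockwise boundary
#' of the sub-rectangle `rows` x `cols`; divided by 2 pi this is the total
#' topological charge enclosed. Serves as the line-integral cross-check for
#' [detect_ps()].
#'
#' @param theta phase matrix (radians).
#' @param rows,cols index ranges delimiting the rectangle (defaults: whole
#'   matrix).
#' @return integer winding number.
#' @export
boundary_winding <- function(theta, rows = c(1, nrow(theta)),
                             cols = c(1, ncol(theta))) {
  r1 <- rows[1]; r2 <- rows[2]; c1 <- cols[1]; c2 <- cols[2]
  # same loop orientation as the 2x2 plaquette circulation in detect_ps
  path <- rbind(
    cbind(r1, c1:c2),                       # top row, left -> right
    cbind(r1:r2, c2),                       # right edge, top -> bottom
    cbind(r2, c2:c1),                       # bottom row, right -> left
    cbind(r2:r1, c1))                       # left edge, bottom -> top
  vals <- theta[path]
  if (anyNA(vals)) stop("boundary path crosses invalid nodes")
  s <- sum(wrap_phase(diff(vals)))
  round(s / (2 * pi))
}

#' Link per-frame singularities into a consensus core trajectory
#'
#' Associates phase singularities across frames by nearest-neighbour linking
#' (a detection extends a live track if it lies within `link_radius`; tracks
#' survive gaps up to `max_gap` frames). The longest-lived track is the
#' labelled spiral core; ties are broken in favour of the track whose mean
#' distance to the domain boundary is larger (a core well inside the disc).
#'
#' @param ps data.frame from [detect_ps()] with a `frame` column.
#' @param n_frames total number of frames scanned.
#' @param link_radius maximum per-frame jump, grid units.
#' @param max_gap frames a track may miss before it is closed.
#' @param boundary_dist optional function(row, col) giving distance to the
#'   domain boundary, used only for tie-breaking.
#' @return `NULL` when there are no detections; otherwise a list with
#'   `track` (data.frame frame/row/col/charge), `length` (frames covered) and
#'   `n_tracks`.
#' @export
consensus_core <- function(ps, n_frames, link_radius = 5, max_gap = 3,
                           boundary_dist = NULL) {
  if (is.null(ps) || nrow(ps) == 0) return(NULL)
  tracks <- list()   # each: list(rows, cols, frames, charge, last_frame)
  live <- integer(0)
  for (t in sort(unique(ps$frame))) {
    det <- ps[ps$frame == t, ]
    used <- rep(FALSE, nrow(det))
    live <- live[vapply(live, function(i) t - tracks[[i]]$last_frame <= max_gap,
                        logical(1))]
    for (i in live) {
      tr <- tracks[[i]]
      dx <- det$row - tr$rows[length(tr$rows)]
      dy <- det$col - tr$cols[length(tr$cols)]
      dist <- sqrt(dx^2 + dy^2)
      dist[used] <- Inf
      j <- which.min(dist)
      if (length(j) && is.finite(dist[j]) && dist[j] <= link_radius) {
        used[j] <- TRUE
        tracks[[i]]$rows <- c(tr$rows, det$row[j])
        tracks[[i]]$cols <- c(tr$cols, det$col[j])
        tracks[[i]]$frames <- c(tr$frames, t)
        tracks[[i]]$last_frame <- t
      }
    }
    for (j in which(!used)) {
      tracks[[length(tracks) + 1]] <- list(rows = det$row[j], cols = det$col[j],
                                           frames = t, charge = det$charge[j],
                                           last_frame = t)
      live <- c(live, length(tracks))
    }
  }
  lens <- vapply(tracks, function(tr) length(tr$frames), integer(1))
  best <- which(lens == max(lens))
  if (length(best) > 1 && !is.null(boundary_dist)) {
    md <- vapply(tracks[best], function(tr)
      mean(boundary_dist(tr$rows, tr$cols)), numeric(1))
    best <- best[which.max(md)]
  } else best <- best[1]
  tr <- tracks[[best]]
  list(track = data.frame(frame = tr$frames, row = tr$rows, col = tr$cols,
                          charge = tr$charge),
       length = length(tr$frames), n_tracks = length(tracks))
}

# Core position at a given frame: exact match, else nearest tracked frame.
core_at_frame <- function(core, frame) {
  tr <- core$track
  i <- which.min(abs(tr$frame - frame))
  c(row = tr$row[i], col = tr$col[i])
}
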