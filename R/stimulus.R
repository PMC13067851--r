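#' Stimulation events
#'
#' A stimulus event switches an electrical current or an optical irradiance
#' onto a set of nodes for a time window. Electrical amplitudes are in du/dt
#' units of the normalized cell model; optical amplitudes are normalized
#' irradiance in \[0, 1\] driving the channelrhodopsin photocurrent. Geometry
#' is always clipped to the conducting disc.
#'
#' @param domain a [make_domain()] object.
#' @param geometry logical matrix (same dims as the grid) of stimulated nodes.
#' @param kind `"electrical"` or `"optical"`.
#' @param t_on onset time, ms.
#' @param duration duration, ms (> 0).
#' @param amplitude current (du/dt units) or normalized irradiance.
#' @return Object of class `stimulus_event`.
#' @export
stimulus_event <- function(domain, geometry, kind = c("electrical", "optical"),
                           t_on, duration, amplitude) {
  kind <- match.arg(kind)
  if (duration <= 0) stop("stimulus duration must be positive")
  stopifnot(is.logical(geometry), all(dim(geometry) == c(domain$n_rows, domain$n_cols)))
  geometry <- geometry & domain$conducting_mask
  if (!any(geometry)) stop("stimulus geometry contains no conducting nodes")
  if (kind == "optical" && (amplitude < 0 || amplitude > 1)) {
    warning("optical amplitude clipped to [0, 1]")
    amplitude <- min(max(amplitude, 0), 1)
  }
  structure(list(kind = kind, geometry = geometry, t_on = t_on,
                 duration = duration, amplitude = amplitude),
            class = "stimulus_event")
}

#' Stimulus geometry helpers
#'
#' `stim_edge_strip` covers `depth_mm` from one grid edge (the classic S1
#' site); `stim_half_plane` covers half of the monolayer; `stim_disc` a
#' circular spot; `stim_line_mask` a straight line of given width between two
#' points (in mm).
#'
#' @param domain a [make_domain()] object.
#' @param side one of `"left"`, `"right"`, `"top"`, `"bottom"`.
#' @param depth_mm strip depth in mm.
#' @return logical matrix over the grid.
#' @rdname stim-geometry
#' @export
stim_edge_strip <- function(domain, side = "left", depth_mm = 0.6) {
  coords <- node_centers_mm(domain)
  lim <- switch(side,
    left   = coords$x <= min(coords$x[domain$conducting_mask]) + depth_mm,
    right  = coords$x >= max(coords$x[domain$conducting_mask]) - depth_mm,
    top    = coords$y <= min(coords$y[domain$conducting_mask]) + depth_mm,
    bottom = coords$y >= max(coords$y[domain$conducting_mask]) - depth_mm,
    stop("unknown side"))
  matrix(lim, domain$n_rows, domain$n_cols)
}

#' @param frac fraction of the side covered by the half plane.
#' @rdname stim-geometry
#' @export
stim_half_plane <- function(domain, side = "left", frac = 0.5) {
  coords <- node_centers_mm(domain)
  s <- domain$side_mm
  lim <- switch(side,
    left = coords$x <= s * frac, right = coords$x >= s * (1 - frac),
    top = coords$y <= s * frac, bottom = coords$y >= s * (1 - frac),
    stop("unknown side"))
  matrix(lim, domain$n_rows, domain$n_cols)
}

#' @param x_mm,y_mm center of the spot, mm from the grid origin.
#' @param radius_mm spot radius, mm.
#' @rdname stim-geometry
#' @export
stim_disc <- function(domain, x_mm, y_mm, radius_mm) {
  coords <- node_centers_mm(domain)
  matrix((coords$x - x_mm)^2 + (coords$y - y_mm)^2 <= radius_mm^2,
         domain$n_rows, domain$n_cols)
}

# Node-center coordinates in mm; x runs along columns, y along rows, both
# measured from the grid origin (top-left corner), centers at (i + 0.5) h.
node_centers_mm <- function(domain) {
  h <- domain$spacing_um / 1000
  y <- matrix(((seq_len(domain$n_rows) - 1) + 0.5) * h,
              domain$n_rows, domain$n_cols)
  x <- matrix(((seq_len(domain$n_cols) - 1) + 0.5) * h,
              domain$n_rows, domain$n_cols, byrow = TRUE)
  list(x = x, y = y)
}
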