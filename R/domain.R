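#' Build a circular monolayer tissue domain
#'
#' Constructs the grid geometry used by the monodomain simulator: a square
#' grid of `n_points` x `n_points` nodes with spacing `spacing_um`, carrying a
#' centered conducting disc of diameter `conducting_diameter_mm` that mimics
#' the area of a culture-plate well. Nodes outside the disc are non-conducting
#' and all coupling weights crossing the disc boundary are exactly zero
#' (zero-flux / Neumann boundary).
#'
#' Node centers sit at `(i + 0.5) * spacing` for 0-based index `i`, so the
#' physical side length is `n_points * spacing`.
#'
#' @param n_points grid points per side (>= 16).
#' @param spacing_um grid spacing in micrometers.
#' @param conducting_diameter_mm diameter of the conducting disc in mm.
#' @return An object of class `tissue_domain` with fields `n_rows`, `n_cols`,
#'   `spacing_um`, `side_mm`, `conducting_mask` (logical matrix) and
#'   `conducting_diameter_mm`.
#' @examples
#' d <- make_domain(128, 120, 15)
#' d$side_mm
#' @export
make_domain <- function(n_points, spacing_um, conducting_diameter_mm) {
  if (n_points < 16) stop("n_points must be at least 16")
  if (spacing_um <= 0) stop("spacing_um must be positive")
  if (conducting_diameter_mm <= 0)
    stop("invalid geometry: conducting diameter must be positive")
  side_mm <- n_points * spacing_um / 1000
  if (conducting_diameter_mm > side_mm + 1e-9)
    stop("invalid geometry: conducting disc does not fit on the grid")

  h_mm <- spacing_um / 1000
  centers <- ((seq_len(n_points) - 1) + 0.5) * h_mm
  cx <- side_mm / 2
  r <- conducting_diameter_mm / 2
  dx2 <- outer((centers - cx)^2, (centers - cx)^2, "+")
  mask <- dx2 <= r^2
  if (!any(mask)) stop("invalid geometry: conducting mask is empty")

  structure(list(
    n_rows = n_points, n_cols = n_points,
    spacing_um = spacing_um, side_mm = side_mm,
    conducting_diameter_mm = conducting_diameter_mm,
    conducting_mask = mask
  ), class = "tissue_domain")
}

#' @export
print.tissue_domain <- function(x, ...) {
  cat(sprintf("<tissue_domain> %d x %d grid, spacing %g um (side %.4g mm)\n",
              x$n_rows, x$n_cols, x$spacing_um, x$side_mm))
  cat(sprintf("  conducting disc: %g mm diameter, %d nodes (%.1f%% of grid)\n",
              x$conducting_diameter_mm, sum(x$conducting_mask),
              100 * mean(x$conducting_mask)))
  invisible(x)
}

# Edge-weight fields for the 5-point Laplacian. Weight between node i and a
# neighbour is D * mean(coupling_i, coupling_j) / h^2 and exactly zero when
# either endpoint is non-conducting (zero-flux at the disc boundary and the
# grid edge). Symmetry of the edge weights makes the diffusion step conserve
# the total of u over conducting nodes.
domain_edge_weights <- function(domain, D_mm2_ms, coupling = 1) {
  nr <- domain$n_rows; nc <- domain$n_cols
  m <- domain$conducting_mask * 1.0
  cpl <- if (length(coupling) == 1) matrix(coupling, nr, nc) else coupling
  stopifnot(all(dim(cpl) == c(nr, nc)))
  h_mm <- domain$spacing_um / 1000
  base <- D_mm2_ms / h_mm^2
  zero <- matrix(0, nr, nc)

  wN <- zero; wS <- zero; wW <- zero; wE <- zero
  # neighbour up (row - 1)
  wN[-1, ] <- base * 0.5 * (cpl[-1, ] + cpl[-nr, ]) * m[-1, ] * m[-nr, ]
  wS[-nr, ] <- base * 0.5 * (cpl[-nr, ] + cpl[-1, ]) * m[-nr, ] * m[-1, ]
  wW[, -1] <- base * 0.5 * (cpl[, -1] + cpl[, -nc]) * m[, -1] * m[, -nc]
  wE[, -nc] <- base * 0.5 * (cpl[, -nc] + cpl[, -1]) * m[, -nc] * m[, -1]
  list(wN = wN, wS = wS, wW = wW, wE = wE)
}
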