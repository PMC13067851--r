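#' Sample ionic and coupling heterogeneity for one virtual monolayer
#'
#' Draws the three heterogeneity fields that give each simulated monolayer its
#' individuality: a global scaling of all ionic currents (uniform on
#' `global_range`, default 0.83--1.20), an independent per-node multiplier on
#' top of the global value (log-uniform on `cell_range`, default 0.5--2.0, so
#' the median per-node multiplier equals the global value), and a scalar
#' coupling-coefficient multiplier (uniform on `coupling_range`, default
#' 0.25--4). `coupling_spatial = TRUE` instead draws a smooth spatial coupling
#' field spanning the same range.
#'
#' @param domain a [make_domain()] object.
#' @param seed integer seed; the same seed reproduces the fields bit for bit.
#' @param global_range,cell_range,coupling_range numeric length-2 ranges.
#' @param coupling_spatial draw a smooth spatial coupling field instead of a
#'   per-sample scalar.
#' @return Object of class `heterogeneity` with `global_current_scale`,
#'   `cell_current_scale` (matrix, already includes the global factor),
#'   `coupling_scale` (scalar or matrix) and `rng_seed`.
#' @export
sample_heterogeneity <- function(domain, seed,
                                 global_range = c(0.83, 1.20),
                                 cell_range = c(0.5, 2.0),
                                 coupling_range = c(0.25, 4),
                                 coupling_spatial = FALSE) {
  for (r in list(global_range, cell_range, coupling_range))
    if (length(r) != 2 || r[1] > r[2] || r[1] <= 0)
      stop("config error: range bounds must be positive and ordered")
  if (missing(seed) || is.null(seed)) stop("a seed is required")

  nr <- domain$n_rows; nc <- domain$n_cols
  rng <- local({ set.seed(as.integer(seed))
    list(g = stats::runif(1, global_range[1], global_range[2]),
         cell = exp(stats::runif(nr * nc, log(cell_range[1]), log(cell_range[2]))),
         cpl_u = stats::runif(1, coupling_range[1], coupling_range[2]),
         field = stats::rnorm(64)) })

  cell <- matrix(rng$g * rng$cell, nr, nc)

  coupling <- if (!coupling_spatial) rng$cpl_u else {
    # smooth low-order random surface mapped onto the coupling range
    z <- matrix(rng$field[1:36], 6, 6)
    rows <- seq(0, 1, length.out = nr); cols <- seq(0, 1, length.out = nc)
    basis <- function(s, n) outer(s, seq_len(n) - 1, function(x, k) cos(pi * k * x))
    f <- basis(rows, 6) %*% z %*% t(basis(cols, 6))
    f <- (f - min(f)) / max(max(f) - min(f), .Machine$double.eps)
    exp(log(coupling_range[1]) + f * (log(coupling_range[2]) - log(coupling_range[1])))
  }

  structure(list(global_current_scale = rng$g,
                 cell_current_scale = cell,
                 coupling_scale = coupling,
                 rng_seed = as.integer(seed)),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("<heterogeneity> global current scale %.3f, per-cell %.2f-%.2f, coupling %s\n",
              x$global_current_scale,
              min(x$cell_current_scale), max(x$cell_current_scale),
              if (is.matrix(x$coupling_scale))
                sprintf("spatial %.2f-%.2f", min(x$coupling_scale), max(x$coupling_scale))
              else sprintf("%.3f", x$coupling_scale)))
  invisible(x)
}

# Homogeneous stand-in used by fixtures and physics tests.
homogeneous_heterogeneity <- function(domain, coupling = 1) {
  structure(list(global_current_scale = 1,
                 cell_current_scale = matrix(1, domain$n_rows, domain$n_cols),
                 coupling_scale = coupling,
                 rng_seed = NA_integer_),
            class = "heterogeneity")
}
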