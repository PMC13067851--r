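# Geometry pipeline shared by the virtual camera and the dataset generator:
# area-weighted block averaging between rasters, the 3x3 Gaussian low-pass,
# and the centered crop to the detector input size.

# Row/column overlap matrix for exact area-weighted block averaging from
# n_in to n_out samples of the same physical extent (the rasters need not
# nest: fractional coverage is handled exactly).
overlap_matrix <- function(n_out, n_in) {
  A <- matrix(0, n_out, n_in)
  r <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * r; hi <- i * r
    j0 <- floor(lo) + 1; j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) A[i, j] <- ov / r
    }
  }
  A
}

# Block-average a [H,W] frame or [H,W,T] stack onto an n_out^2 raster.
block_average <- function(x, n_out) {
  d <- dim(x)
  A <- overlap_matrix(n_out, d[1])
  B <- overlap_matrix(n_out, d[2])
  if (length(d) == 2) return(A %*% x %*% t(B))
  out <- array(0, c(n_out, n_out, d[3]))
  for (t in seq_len(d[3])) out[, , t] <- A %*% x[, , t] %*% t(B)
  out
}

# 3x3 Gaussian low-pass (separable binomial kernel 1-2-1 / 4) with
# replicated edges.
gaussian3 <- function(m) {
  pad_r <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  v <- (pad_r[-c(nrow(pad_r) - 1, nrow(pad_r)), ] +
        2 * pad_r[-c(1, nrow(pad_r)), ] +
        pad_r[-c(1, 2), ]) / 4
  pad_c <- cbind(v[, 1, drop = FALSE], v, v[, ncol(v), drop = FALSE])
  (pad_c[, -c(ncol(pad_c) - 1, ncol(pad_c))] +
     2 * pad_c[, -c(1, ncol(pad_c))] +
     pad_c[, -c(1, 2)]) / 4
}

# Centered crop of a [H,W] or [H,W,T] array to size n (here 100 -> 86).
center_crop <- function(x, n) {
  d <- dim(x)
  o1 <- floor((d[1] - n) / 2); o2 <- floor((d[2] - n) / 2)
  if (length(d) == 2) x[o1 + seq_len(n), o2 + seq_len(n)]
  else x[o1 + seq_len(n), o2 + seq_len(n), , drop = FALSE]
}

# Offset (in source pixels) of the centered crop, for coordinate transforms.
crop_offset <- function(n_full, n_crop) floor((n_full - n_crop) / 2)
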