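# Internal numerical helpers shared across modules.

# Row-wise Pearson correlation between two conformable matrices.
# Rows with (numerically) zero variance in either input give NA.
.row_pearson <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  ssa <- rowSums(a * a)
  ssb <- rowSums(b * b)
  den <- sqrt(ssa * ssb)
  r <- rowSums(a * b) / den
  bad <- ssa <= .Machine$double.eps * ncol(a) | ssb <= .Machine$double.eps * ncol(b)
  r[bad] <- NA_real_
  pmin(pmax(r, -1), 1)
}

# Voxel (i,j,k) indices (1-based) -> world mm coordinates through a 4x4 affine.
.ijk_to_mm <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk - 1, 1)           # NIfTI voxel indices are 0-based
  t(affine %*% t(h))[, 1:3, drop = FALSE]
}

# Default RAS-like affine for an isotropic grid centred on the origin.
.default_affine <- function(grid_shape, voxel_size_mm) {
  a <- diag(c(rep(voxel_size_mm, 3), 1))
  a[1:3, 4] <- -voxel_size_mm * (grid_shape - 1) / 2
  a
}

# Place a per-voxel vector back into a 3D array over a logical mask.
.vec_to_volume <- function(values, mask, fill = NA_real_) {
  vol <- array(fill, dim = dim(mask))
  vol[mask] <- values
  vol
}

.is_count <- function(x) length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)

# Mid-point times (seconds) of frames 1..n at sampling interval tr.
.frame_midpoints <- function(n_frames, tr_s) (seq_len(n_frames) - 0.5) * tr_s

# Clamp exact-zero p-values (e.g. from a perfect correlation) to the
# smallest representable positive double before FDR correction.
.safe_p <- function(p) pmax(p, .Machine$double.xmin)

# One-sample t statistics down the columns of an n x V matrix.
.col_tstat <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  v <- (colSums(x * x) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  m / sqrt(v / n)
}
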