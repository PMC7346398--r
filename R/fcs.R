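#' Voxel-wise functional connectivity strength (FCS)
#'
#' For every in-mask voxel i, computes the sum over all other in-mask
#' voxels j of the Fisher z-transform `atanh(r_ij)` of Pearson
#' correlations, restricted to `r_ij > r_threshold` (strictly above; weak
#' correlations are treated as noise and excluded). Correlations are
#' clipped to `+/-(1 - 1e-7)` before the transform. With `scale = "mean"`
#' the sum is divided by the number of in-mask voxels minus one.
#' Zero-variance voxels receive FCS 0 and are counted in the
#' `n_zero_variance` field.
#'
#' The V x V correlation matrix is never materialized: correlations are
#' computed in column blocks, so memory stays O(V x block).
#'
#' @param run A preprocessed [bold_run()].
#' @param r_threshold Correlation threshold (default 0.1); strictly
#'   exceeded correlations enter the sum.
#' @param scale `"mean"` (default, per-pair average) or `"sum"` (raw sum of
#'   suprathreshold z-values).
#' @param block_size Number of target voxels per correlation block.
#' @return An `fcs_map`: list with 3D `data`, `mask`, `r_threshold`,
#'   `scale`, `voxel_size_mm`, `n_zero_variance`.
#' @export
compute_fcs <- function(run, r_threshold = 0.1, scale = c("mean", "sum"),
                        block_size = 1024L) {
  stopifnot(inherits(run, "bold_run"))
  scale <- match.arg(scale)
  if (!is.finite(r_threshold) || r_threshold <= -1 || r_threshold >= 1)
    stop_field("r_threshold", "must lie in (-1, 1)")
  nt <- dim(run$data)[4]
  sp <- dim(run$data)[1:3]
  if (!all(is.finite(run$data))) stop_field("data", "contains non-finite values")
  inm <- which(as.vector(run$mask))
  if (length(inm) < 2L) stop_field("mask", "needs at least 2 in-mask voxels")
  Y <- matrix(run$data, ncol = nt)[inm, , drop = FALSE]   # V x t
  mu <- rowMeans(Y)
  Yc <- Y - mu
  ss <- sqrt(rowSums(Yc^2))
  valid <- ss > 0
  nv <- sum(valid)
  if (nv < 2L)
    stop_field("data", "fewer than 2 in-mask voxels with nonzero variance")
  Z <- Yc[valid, , drop = FALSE] / ss[valid]              # unit rows
  clip <- 1 - 1e-7
  fcs_valid <- numeric(nv)
  for (start in seq(1L, nv, by = block_size)) {
    idx <- start:min(start + block_size - 1L, nv)
    R <- Z %*% t(Z[idx, , drop = FALSE])                  # nv x b
    R[cbind(idx, seq_along(idx))] <- -2                   # exclude self
    R[R > clip] <- clip
    R[R < -clip & R > -1.5] <- -clip
    pass <- R > r_threshold
    R[!pass] <- 0
    R[pass] <- atanh(R[pass])
    fcs_valid[idx] <- colSums(R)
  }
  if (scale == "mean") fcs_valid <- fcs_valid / (length(inm) - 1L)
  out <- numeric(prod(sp))
  out[inm[valid]] <- fcs_valid
  structure(list(data = array(out, dim = sp), mask = run$mask,
                 r_threshold = r_threshold, scale = scale,
                 voxel_size_mm = run$voxel_size_mm,
                 n_zero_variance = length(inm) - nv),
            class = "fcs_map")
}

#' @export
print.fcs_map <- function(x, ...) {
  cat(sprintf("<fcs_map> %s, r>%g, scale=%s, %d in mask (%d zero-variance)\n",
              paste(dim(x$data), collapse = "x"), x$r_threshold, x$scale,
              sum(x$mask), x$n_zero_variance))
  invisible(x)
}

# 1D Gaussian kernel for a given sigma (in voxels), truncated at 4 sigma.
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve a 3D array along one axis with a symmetric 1D kernel
# (zero-filled open boundary), by shift-and-add.
convolve_axis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim = dim(a))
  for (o in seq(-r, r))
    out <- out + kernel[o + r + 1L] * shift_array(a, o, axis)
  out
}

#' Mask-renormalized Gaussian smoothing of an FCS map
#'
#' Separable 3D Gaussian convolution with per-axis
#' `sigma = fwhm_mm / (voxel_size_mm * sqrt(8 ln 2))`. Smoothing is
#' restricted to the mask: both `data * mask` and `mask` are convolved and
#' their ratio taken inside the mask, so out-of-mask zeros never bleed in
#' and a constant in-mask map is left unchanged.
#'
#' @param map An `fcs_map` (or list with `data`, `mask`, `voxel_size_mm`).
#' @param fwhm_mm Full width at half maximum in mm (default 4); 0 is the
#'   identity.
#' @return The smoothed `fcs_map`.
#' @export
gaussian_smooth <- function(map, fwhm_mm = 4) {
  if (fwhm_mm < 0) stop_field("fwhm_mm", "must be non-negative")
  if (fwhm_mm == 0) return(map)
  sig <- fwhm_mm / (map$voxel_size_mm * sqrt(8 * log(2)))
  num <- map$data * map$mask
  den <- array(as.numeric(map$mask), dim = dim(map$data))
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sig[ax])
    num <- convolve_axis(num, k, ax)
    den <- convolve_axis(den, k, ax)
  }
  out <- array(0, dim = dim(map$data))
  inm <- map$mask & den > 0
  out[inm] <- num[inm] / den[inm]
  map$data <- out
  map
}

#' Mean map value over a region of interest
#'
#' @param map An `fcs_map` (or any list with 3D `data` and logical `mask`).
#' @param roi Logical 3D array; the mean is taken over `roi & mask`.
#' @return Scalar mean.
#' @export
extract_cluster_mean <- function(map, roi) {
  assert_flag_array(roi, dim(map$data), "roi")
  sel <- roi & map$mask
  if (!any(sel)) stop_field("roi", "does not intersect the mask")
  mean(map$data[sel])
}
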