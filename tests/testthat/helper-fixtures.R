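# Fixtures and independent oracles shared across test files.

# Small deterministic BOLD run of white noise.
make_test_run <- function(dims = c(4, 4, 3), nt = 30, tr = 2.4, seed = 42,
                          mask = NULL) {
  set.seed(seed)
  bold_run(array(rnorm(prod(dims) * nt), dim = c(dims, nt)),
           tr_seconds = tr, voxel_size_mm = c(2, 2, 2), mask = mask)
}

# A run whose in-mask voxel series have EXACT sample correlation matrix R:
# orthonormalize iid columns, then color with chol(R).
make_run_with_corr <- function(R, nt = 24, tr = 2.4, seed = 1) {
  set.seed(seed)
  V <- nrow(R)
  X <- matrix(rnorm(nt * V), nt, V)
  X <- scale(X, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(X))   # orthonormal columns, each orthogonal to the 1-vector
  S <- Q %*% chol(R)
  dims <- c(V, 1, 1)
  bold_run(array(t(S), dim = c(dims, nt)), tr_seconds = tr,
           voxel_size_mm = c(2, 2, 2))
}

# Literal O(V^2) FCS oracle: correlate, threshold, Fisher-z, sum.
fcs_bruteforce <- function(run, r_threshold = 0.1, scale = "mean") {
  nt <- dim(run$data)[4]
  Y <- matrix(run$data, ncol = nt)
  inm <- which(as.vector(run$mask))
  out <- numeric(length(as.vector(run$mask)))
  clip <- 1 - 1e-7
  for (i in inm) {
    acc <- 0
    if (sd(Y[i, ]) == 0) { out[i] <- 0; next }
    for (j in inm) {
      if (i == j || sd(Y[j, ]) == 0) next
      r <- cor(Y[i, ], Y[j, ])
      r <- max(min(r, clip), -clip)
      if (r > r_threshold) acc <- acc + atanh(r)
    }
    out[i] <- if (scale == "mean") acc / (length(inm) - 1) else acc
  }
  array(out, dim = dim(run$data)[1:3])
}

# Wrap a bare 3D array as the fcs_map structure the inference stage needs.
make_fcs_map <- function(data, mask = NULL, voxel_size_mm = c(2, 2, 2)) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(data))
  structure(list(data = data, mask = mask, r_threshold = 0.1,
                 scale = "mean", voxel_size_mm = voxel_size_mm,
                 n_zero_variance = 0L),
            class = "fcs_map")
}

# Smooth white-noise 3D field with an isotropic Gaussian (open boundary).
smooth_noise_field <- function(dims, fwhm_vox) {
  a <- array(rnorm(prod(dims)), dim = dims)
  if (fwhm_vox > 0) {
    m <- make_fcs_map(a)
    m$voxel_size_mm <- c(1, 1, 1)
    a <- gaussian_smooth(m, fwhm_mm = fwhm_vox)$data
  }
  a
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
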