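#' Construct a BOLD run
#'
#' Container for a subject's 4D resting-state BOLD series together with its
#' repetition time, voxel geometry and analysis mask.
#'
#' @param data 4D numeric array (x, y, z, t) of BOLD values; all finite.
#' @param tr_seconds Repetition time in seconds (time between volumes).
#' @param voxel_size_mm Numeric length-3, voxel edge lengths in mm.
#' @param mask Logical 3D array marking in-analysis (gray-matter/brain)
#'   voxels; defaults to all voxels.
#' @return An object of class `bold_run`: a list with elements `data`,
#'   `tr_seconds`, `voxel_size_mm`, `mask`.
#' @export
bold_run <- function(data, tr_seconds, voxel_size_mm = c(3, 3, 3),
                     mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_field("data", "must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L)
    stop_field("data", "needs at least 2 time points")
  if (!all(is.finite(data)))
    stop_field("data", "contains non-finite values")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop_field("tr_seconds", "must be a positive scalar")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop_field("voxel_size_mm", "must be 3 positive values")
  sp <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = sp)
  assert_flag_array(mask, sp, "mask")
  structure(list(data = data, tr_seconds = tr_seconds,
                 voxel_size_mm = as.numeric(voxel_size_mm), mask = mask),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %dx%dx%d voxels, %d volumes, TR=%gs, %d in mask\n",
              d[1], d[2], d[3], d[4], x$tr_seconds, sum(x$mask)))
  invisible(x)
}

#' Discard initial volumes
#'
#' Removes the first `n_discard` volumes of a run (magnetization
#' equilibration period). The caller must trim the matching motion trace
#' identically.
#'
#' @param run A [bold_run()].
#' @param n_discard Number of leading volumes to drop (default 5).
#' @return The trimmed `bold_run`.
#' @export
discard_initial <- function(run, n_discard = 5L) {
  stopifnot(inherits(run, "bold_run"))
  nt <- dim(run$data)[4]
  if (n_discard < 0L) stop_field("n_discard", "must be non-negative")
  if (n_discard >= nt)
    stop_field("n_discard",
               sprintf("cannot discard %d of %d volumes", n_discard, nt))
  if (n_discard == 0L) return(run)
  run$data <- run$data[, , , -seq_len(n_discard), drop = FALSE]
  run
}

#' Friston 24-parameter motion expansion
#'
#' Expands a 6-column rigid-body motion trace R into the canonical 24
#' motion regressors `[R, R^2, R_lag1, R_lag1^2]`, where the one-volume lag
#' is zero-padded at the first row.
#'
#' @param motion t x 6 numeric matrix (3 translations mm, 3 rotations deg)
#'   or a `motion_trace`.
#' @return t x 24 numeric matrix with columns `friston_1` .. `friston_24`.
#' @export
friston24 <- function(motion) {
  m <- as_motion_matrix(motion)
  if (nrow(m) < 2L) stop_field("motion", "needs at least 2 rows")
  if (!all(is.finite(m))) stop_field("motion", "contains non-finite values")
  lag1 <- rbind(0, m[-nrow(m), , drop = FALSE])
  out <- cbind(m, m^2, lag1, lag1^2)
  colnames(out) <- paste0("friston_", seq_len(24L))
  out
}

as_motion_matrix <- function(motion) {
  m <- if (inherits(motion, "motion_trace")) motion$params else as.matrix(motion)
  if (ncol(m) != 6L)
    stop_field("motion", sprintf("expected 6 columns, got %d", ncol(m)))
  storage.mode(m) <- "double"
  m
}

#' Extract nuisance signal time courses
#'
#' Spatial-mean time courses over the white-matter and CSF masks and over
#' the run's own analysis mask (the global signal), each mean-centered.
#'
#' @param run A [bold_run()].
#' @param wm_mask,csf_mask Logical 3D arrays within the volume.
#' @return List with numeric t-vectors `wm`, `csf`, `global`.
#' @export
extract_nuisance_signals <- function(run, wm_mask, csf_mask) {
  stopifnot(inherits(run, "bold_run"))
  sp <- dim(run$data)[1:3]
  assert_flag_array(wm_mask, sp, "wm_mask")
  assert_flag_array(csf_mask, sp, "csf_mask")
  one <- function(mask, name) {
    if (!any(mask)) stop_field(name, "mask is empty")
    Y <- matrix(run$data, ncol = dim(run$data)[4])[as.vector(mask), ,
                                                   drop = FALSE]
    s <- colMeans(Y)
    s - mean(s)
  }
  list(wm = one(wm_mask, "wm_mask"), csf = one(csf_mask, "csf_mask"),
       global = one(run$mask, "mask"))
}

#' Assemble a nuisance design matrix
#'
#' Binds the Friston-24 motion regressors, the tissue/global signals and an
#' intercept into the regression design (28 columns when all components are
#' present).
#'
#' @param friston t x 24 matrix from [friston24()], or NULL.
#' @param signals List with vectors `wm`, `csf`, `global` (any may be
#'   omitted), as from [extract_nuisance_signals()].
#' @return Numeric matrix with named columns, intercept last.
#' @export
nuisance_design <- function(friston = NULL, signals = list()) {
  parts <- list()
  if (!is.null(friston)) parts$friston <- friston
  for (nm in c("wm", "csf", "global"))
    if (!is.null(signals[[nm]])) {
      parts[[nm]] <- matrix(signals[[nm]], ncol = 1,
                            dimnames = list(NULL, nm))
    }
  nt <- unique(vapply(parts, nrow, 1L))
  if (length(nt) > 1L)
    stop_field("design", "components have differing numbers of rows")
  if (length(nt) == 0L) stop_field("design", "no components supplied")
  X <- do.call(cbind, c(unname(parts),
                        list(matrix(1, nt, 1, dimnames = list(NULL, "intercept")))))
  if (!all(is.finite(X))) stop_field("design", "contains non-finite values")
  X
}

#' Regress nuisance design out of a BOLD run
#'
#' Replaces every in-mask voxel series by its ordinary-least-squares
#' residual against the design. Exactly collinear design columns are
#' dropped with a warning. Out-of-mask voxels are set to 0.
#'
#' @param run A [bold_run()].
#' @param design t x k numeric design matrix (see [nuisance_design()]).
#' @return The residualized `bold_run`.
#' @export
regress_out <- function(run, design) {
  stopifnot(inherits(run, "bold_run"))
  X <- as.matrix(design)
  nt <- dim(run$data)[4]
  if (nrow(X) != nt)
    stop_field("design", sprintf("has %d rows but run has %d volumes",
                                 nrow(X), nt))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning(sprintf("design is rank deficient; dropping collinear column(s): %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    qr_x <- qr(X[, keep, drop = FALSE])
  }
  Y <- matrix(run$data, ncol = nt)       # voxels x t
  inm <- as.vector(run$mask)
  res <- qr.resid(qr_x, t(Y[inm, , drop = FALSE]))   # t x V
  Y[] <- 0
  Y[inm, ] <- t(res)
  run$data <- array(Y, dim = dim(run$data))
  run
}

#' Temporal band-pass filter
#'
#' Filters each in-mask voxel series to the `[low_hz, high_hz]` band via an
#' ideal DFT-domain mask on the linearly detrended series: frequency bins
#' with `low_hz <= f <= high_hz` pass with unit gain, all other bins
#' (including DC when `low_hz > 0`) are zeroed. Out-of-mask voxels are set
#' to 0.
#'
#' @param run A [bold_run()].
#' @param low_hz,high_hz Band edges in Hz; `0 <= low < high <= 1/(2 TR)`.
#' @return The filtered `bold_run`.
#' @export
bandpass <- function(run, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(run, "bold_run"))
  nyq <- 1 / (2 * run$tr_seconds)
  if (low_hz < 0 || low_hz >= high_hz)
    stop_field("low_hz", "need 0 <= low_hz < high_hz")
  if (high_hz > nyq + 1e-12)
    stop_field("high_hz", sprintf("exceeds Nyquist frequency %.4f Hz", nyq))
  nt <- dim(run$data)[4]
  Y <- matrix(run$data, ncol = nt)
  inm <- as.vector(run$mask)
  S <- t(Y[inm, , drop = FALSE])         # t x V
  # linear detrend (removes the ramp that the finite DFT represents poorly)
  tt <- seq_len(nt)
  S <- qr.resid(qr(cbind(1, tt)), S)
  f <- seq_len(nt) - 1L
  f <- pmin(f, nt - f) / (nt * run$tr_seconds)   # two-sided frequency axis
  keep <- f >= low_hz & f <= high_hz
  Fc <- stats::mvfft(S)
  Fc[!keep, ] <- 0
  S <- Re(stats::mvfft(Fc, inverse = TRUE)) / nt
  Y[] <- 0
  Y[inm, ] <- t(S)
  run$data <- array(Y, dim = dim(run$data))
  run
}

#' Full preprocessing chain for one subject
#'
#' Applies the fixed stage order: discard initial volumes (trimming the
#' motion trace to match), nuisance regression with the Friston-24 motion
#' expansion plus white-matter, CSF and (optionally) global mean signals
#' and an intercept, then temporal band-pass filtering.
#'
#' @param run A [bold_run()].
#' @param motion t x 6 motion parameters or `motion_trace` (pre-discard
#'   length).
#' @param wm_mask,csf_mask Logical 3D nuisance-tissue masks.
#' @param n_discard Leading volumes to drop (default 5).
#' @param band Length-2 numeric, band edges in Hz (default `c(0.01, 0.1)`).
#' @param gsr Include global signal regression (default TRUE).
#' @return The preprocessed `bold_run`.
#' @export
preprocess_bold <- function(run, motion, wm_mask, csf_mask, n_discard = 5L,
                            band = c(0.01, 0.1), gsr = TRUE) {
  m <- as_motion_matrix(motion)
  if (nrow(m) != dim(run$data)[4])
    stop_field("motion", sprintf("has %d rows but run has %d volumes",
                                 nrow(m), dim(run$data)[4]))
  run <- discard_initial(run, n_discard)
  if (n_discard > 0L) m <- m[-seq_len(n_discard), , drop = FALSE]
  sig <- extract_nuisance_signals(run, wm_mask, csf_mask)
  if (!gsr) sig$global <- NULL
  X <- nuisance_design(friston24(m), sig)
  run <- regress_out(run, X)
  bandpass(run, band[1], band[2])
}
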