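#' Specify a synthetic imaging-genetics cohort
#'
#' Collects every parameter of the synthetic cohort generator: genotype
#' group sizes, BOLD grid geometry and timing, the seeded connectivity hub
#' (location, extent, per-genotype connectivity dose), schizotypal-trait
#' (SPQ) score moments, the within-group brain-behavior coupling, and
#' nuisance/noise levels.
#'
#' `connectivity_dose` is the per-genotype target correlation between each
#' hub voxel's time series and a shared band-limited latent signal, ordered
#' (AA, AG, GG); pairwise correlation between two hub voxels is then the
#' product of their doses. `behavior_coupling` is the realized within-group
#' correlation between subject-level hub strength (the subject's dose) and
#' the SPQ total, imposed exactly in `coupling_group` and exactly 0 in the
#' other groups.
#'
#' @param group_sizes Integer length-3, subjects per genotype (AA, AG, GG).
#' @param grid_shape Integer length-3, voxels per axis.
#' @param n_volumes Volumes per run before discarding.
#' @param tr_seconds Repetition time in seconds.
#' @param hub_center Integer length-3, 1-based voxel index of the hub
#'   center; NULL (default) places it at roughly (1/3, 2/5, 1/2) of the
#'   grid extents (an off-center, occipital-like location).
#' @param hub_radius_vox Hub radius in voxels (Euclidean ball); NULL
#'   (default) uses 2.5 voxels, shrunk if needed so the ball fits the
#'   grid.
#' @param connectivity_dose Numeric length-3 in (-1, 1), mean hub-latent
#'   correlation per genotype; expected non-decreasing AA to GG.
#' @param dose_jitter_sd SD of the subject-level jitter added to the group
#'   dose.
#' @param spq_means,spq_sds SPQ total score moments per genotype.
#' @param behavior_coupling Within-group hub-SPQ correlation in
#'   `coupling_group` (in `[-1, 1]`).
#' @param coupling_group Which genotype carries the coupling (default
#'   "GG").
#' @param noise_sd SD of voxel-level noise (arbitrary BOLD units).
#' @param motion_sd Per-volume random-walk step SD of the motion trace (mm
#'   / degrees).
#' @param seed Integer RNG seed; the cohort is fully reproducible from it.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(group_sizes = c(142L, 188L, 72L),
                        grid_shape = c(16L, 16L, 10L),
                        n_volumes = 217L,
                        tr_seconds = 2.4,
                        hub_center = NULL,
                        hub_radius_vox = NULL,
                        connectivity_dose = c(0.2, 0.45, 0.7),
                        dose_jitter_sd = 0.1,
                        spq_means = c(26.930, 26.553, 31.167),
                        spq_sds = c(13.853, 14.038, 14.470),
                        behavior_coupling = -0.4,
                        coupling_group = "GG",
                        noise_sd = 1,
                        motion_sd = 0.05,
                        seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  auto_center <- is.null(hub_center)
  if (auto_center)
    hub_center <- pmax(2L, pmin(grid_shape - 1L,
                                round(grid_shape * c(1 / 3, 0.4, 0.5))))
  if (is.null(hub_radius_vox)) {
    hub_radius_vox <- 2.5
    if (auto_center)
      hub_radius_vox <- min(2.5, min(pmin(hub_center - 1L,
                                          grid_shape - hub_center)))
  }
  spec <- list(group_sizes = as.integer(group_sizes),
               grid_shape = grid_shape,
               n_volumes = as.integer(n_volumes),
               tr_seconds = tr_seconds, hub_center = as.integer(hub_center),
               hub_radius_vox = hub_radius_vox,
               connectivity_dose = connectivity_dose,
               dose_jitter_sd = dose_jitter_sd,
               spq_means = spq_means, spq_sds = spq_sds,
               behavior_coupling = behavior_coupling,
               coupling_group = coupling_group,
               noise_sd = noise_sd, motion_sd = motion_sd,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(s) {
  if (length(s$group_sizes) != 3L || any(s$group_sizes < 2L))
    stop_field("group_sizes", "must be 3 counts, all >= 2")
  if (length(s$grid_shape) != 3L || prod(s$grid_shape) < 27L)
    stop_field("grid_shape", "must be 3 extents with product >= 27")
  if (s$n_volumes <= 10L) stop_field("n_volumes", "must exceed 10")
  if (s$tr_seconds <= 0) stop_field("tr_seconds", "must be positive")
  if (any(abs(s$connectivity_dose) >= 1) ||
      length(s$connectivity_dose) != 3L)
    stop_field("connectivity_dose", "must be 3 values in (-1, 1)")
  if (s$dose_jitter_sd < 0) stop_field("dose_jitter_sd", "must be >= 0")
  if (any(s$spq_sds <= 0)) stop_field("spq_sds", "must be positive")
  if (abs(s$behavior_coupling) > 1)
    stop_field("behavior_coupling", "must lie in [-1, 1]")
  if (!s$coupling_group %in% c("AA", "AG", "GG"))
    stop_field("coupling_group", "must be one of AA, AG, GG")
  if (s$noise_sd <= 0) stop_field("noise_sd", "must be positive")
  if (s$motion_sd < 0) stop_field("motion_sd", "must be >= 0")
  lo <- s$hub_center - s$hub_radius_vox
  hi <- s$hub_center + s$hub_radius_vox
  if (any(lo < 1) || any(hi > s$grid_shape))
    stop_field("hub_center", "hub sphere extends outside the grid")
  invisible(TRUE)
}

# Tissue partition of the grid: two opposite-corner blocks act as WM and
# CSF compartments; everything else is the gray-matter analysis mask.
cohort_masks <- function(spec) {
  d <- spec$grid_shape
  b <- ifelse(d >= 4L, 2L, 1L)
  wm <- array(FALSE, dim = d); csf <- array(FALSE, dim = d)
  wm[seq_len(b[1]), seq_len(b[2]), seq_len(b[3])] <- TRUE
  csf[seq.int(d[1] - b[1] + 1L, d[1]), seq.int(d[2] - b[2] + 1L, d[2]),
      seq.int(d[3] - b[3] + 1L, d[3])] <- TRUE
  gray <- !(wm | csf)
  co <- grid_coords(d)
  dist2 <- (co[, 1] - spec$hub_center[1])^2 + (co[, 2] - spec$hub_center[2])^2 +
    (co[, 3] - spec$hub_center[3])^2
  hub <- array(dist2 <= spec$hub_radius_vox^2, dim = d) & gray
  list(gray = gray, wm = wm, csf = csf, hub = hub)
}

#' Generate a rigid-body motion trace
#'
#' Six motion parameters (3 translations in mm, 3 rotations in degrees) as
#' a Gaussian random walk with per-volume step SD `motion_sd`, so traces
#' drift smoothly as realignment output does. The maximum absolute
#' translation and rotation are recorded so callers can emulate
#' excessive-motion exclusion rules.
#'
#' @param n_volumes Number of rows (>= 2).
#' @param motion_sd Step standard deviation; 0 yields an all-zero trace.
#' @param seed Integer seed.
#' @return A `motion_trace`: list with `params` (t x 6 matrix),
#'   `max_translation_mm`, `max_rotation_deg`.
#' @export
generate_motion <- function(n_volumes, motion_sd, seed) {
  if (n_volumes < 2L) stop_field("n_volumes", "must be >= 2")
  if (motion_sd < 0) stop_field("motion_sd", "must be >= 0")
  p <- with_seed(seed, {
    steps <- matrix(stats::rnorm(n_volumes * 6L, sd = motion_sd),
                    nrow = n_volumes)
    apply(steps, 2, cumsum)
  })
  colnames(p) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  structure(list(params = p,
                 max_translation_mm = max(abs(p[, 1:3])),
                 max_rotation_deg = max(abs(p[, 4:6]))),
            class = "motion_trace")
}

# Unit-variance band-limited signal via frequency-domain synthesis:
# Gaussian complex coefficients on DFT bins inside [low, high] Hz.
band_limited_signal <- function(n, tr, low = 0.01, high = 0.08) {
  half <- (n - 1L) %/% 2L
  f <- seq_len(half) / (n * tr)
  sel <- which(f >= low & f <= high)
  if (length(sel) == 0L) sel <- which.min(abs(f - (low + high) / 2))
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  co <- complex(real = stats::rnorm(length(sel)),
                imaginary = stats::rnorm(length(sel)))
  spec[sel + 1L] <- co
  spec[n + 1L - sel] <- Conj(co)
  x <- Re(stats::fft(spec, inverse = TRUE))
  x / stats::sd(x)
}

# y with realized sample correlation to x exactly rho (length >= 4);
# falls back to a population draw for tiny groups.
couple_exact <- function(x, rho) {
  n <- length(x)
  zx <- as.numeric(scale(x))
  if (n < 4L || stats::sd(x) == 0)
    return(rho * (if (any(!is.finite(zx))) stats::rnorm(n) else zx) +
             sqrt(1 - rho^2) * stats::rnorm(n))
  e <- stats::rnorm(n)
  e <- e - mean(e) - zx * sum(e * zx) / sum(zx^2)
  e <- e / stats::sd(e)
  rho * zx + sqrt(1 - rho^2) * e
}

# Phenotype stage: cheap, fully determined by spec$seed. Draws genotype
# labels, subject-level doses, demographics, SPQ scores coupled to hub
# strength, and per-subject BOLD/motion seeds.
generate_phenotypes <- function(spec) {
  groups <- c("AA", "AG", "GG")
  g <- factor(rep(groups, spec$group_sizes), levels = groups)
  n <- length(g)
  with_seed(spec$seed, {
    dose <- spec$connectivity_dose[as.integer(g)] +
      stats::rnorm(n, sd = spec$dose_jitter_sd)
    dose <- pmin(0.99, pmax(0.01, dose))
    sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
    age <- round(stats::rnorm(n, mean = 20.9, sd = 1.1), 1)
    spq_z <- numeric(n)
    for (k in seq_along(groups)) {
      idx <- which(g == groups[k])
      rho <- if (groups[k] == spec$coupling_group) spec$behavior_coupling else 0
      spq_z[idx] <- couple_exact(dose[idx], rho)
    }
    spq <- numeric(n)
    for (k in seq_along(groups)) {
      idx <- which(g == groups[k])
      spq[idx] <- spec$spq_means[k] + spec$spq_sds[k] * spq_z[idx]
    }
    spq <- pmin(74, pmax(0, round(spq)))
    cogper <- pmin(33, pmax(0, round(0.45 * spq + stats::rnorm(n, sd = 2))))
    interp <- pmin(33, pmax(0, round(0.45 * spq + stats::rnorm(n, sd = 2))))
    disorg <- pmin(16, pmax(0, round(0.22 * spq + stats::rnorm(n, sd = 1.5))))
    subj_seeds <- sample.int(.Machine$integer.max - 1L, n)
    list(phenotypes = data.frame(
           subject_id = sprintf("sub-%03d", seq_len(n)),
           genotype = as.character(g), sex = sex, age = age,
           spq_total = as.integer(spq), spq_cogper = as.integer(cogper),
           spq_interp = as.integer(interp), spq_disorg = as.integer(disorg),
           stringsAsFactors = FALSE),
         dose = dose, subject_seeds = subj_seeds)
  })
}

# One subject's BOLD run: hub voxels share a band-limited latent at target
# correlation d; all voxels receive global WM/CSF/drift time courses and a
# motion-coupled component on top of independent noise.
generate_subject_bold <- function(spec, d, seed, masks, motion) {
  nt <- spec$n_volumes
  nvox <- prod(spec$grid_shape)
  with_seed(seed, {
    latent <- band_limited_signal(nt, spec$tr_seconds)
    wm_tc <- scale(cumsum(stats::rnorm(nt)))[, 1]
    csf_tc <- scale(cumsum(stats::rnorm(nt)))[, 1]
    glob_tc <- scale(cumsum(stats::rnorm(nt)))[, 1]
    mp <- motion$params
    mot_tc <- if (stats::sd(rowSums(mp)) > 0) {
      as.numeric(scale(rowSums(mp)))
    } else rep(0, nt)
    eps <- matrix(stats::rnorm(nvox * nt), nrow = nvox)   # voxels x t
    hub_idx <- which(as.vector(masks$hub))
    eps[hub_idx, ] <- d * rep(latent, each = length(hub_idx)) +
      sqrt(1 - d^2) * eps[hub_idx, , drop = FALSE]
    nuis <- 0.3 * wm_tc + 0.3 * csf_tc + 0.5 * glob_tc + 0.2 * mot_tc
    Y <- spec$noise_sd * (eps + rep(nuis, each = nvox)) + 100
    bold_run(array(Y, dim = c(spec$grid_shape, nt)),
             tr_seconds = spec$tr_seconds, voxel_size_mm = c(2, 2, 2),
             mask = masks$gray)
  })
}

#' Generate a synthetic cohort
#'
#' Produces one BOLD run and motion trace per subject, a phenotype table,
#' and the ground truth needed for parameter-recovery tests (hub mask,
#' per-subject hub strength, expected group ordering). Identical spec and
#' seed yield identical output.
#'
#' @param spec A [cohort_spec()].
#' @param keep_bold If FALSE, omit the (large) BOLD arrays and return only
#'   phenotypes, motion and truth; per-subject runs can then be
#'   regenerated one at a time with the recorded seeds.
#' @return List with `bold` (list of [bold_run()] or NULL), `motion` (list
#'   of `motion_trace`), `phenotypes` (data frame), `truth` (list:
#'   `hub_mask`, `per_subject_hub_strength`, `genotype_labels`,
#'   `effect_ordering`, `subject_seeds`), `mask`, `wm_mask`, `csf_mask`,
#'   `spec`.
#' @export
generate_cohort <- function(spec, keep_bold = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_cohort_spec(spec)
  masks <- cohort_masks(spec)
  ph <- generate_phenotypes(spec)
  n <- nrow(ph$phenotypes)
  motion <- lapply(seq_len(n), function(i)
    generate_motion(spec$n_volumes, spec$motion_sd, ph$subject_seeds[i]))
  bold <- NULL
  if (keep_bold) {
    bold <- lapply(seq_len(n), function(i)
      generate_subject_bold(spec, ph$dose[i], ph$subject_seeds[i] + 1L,
                            masks, motion[[i]]))
  }
  ord <- order(spec$connectivity_dose)
  truth <- list(hub_mask = masks$hub,
                per_subject_hub_strength = ph$dose,
                genotype_labels = ph$phenotypes$genotype,
                effect_ordering = c("AA", "AG", "GG")[ord],
                subject_seeds = ph$subject_seeds)
  list(bold = bold, motion = motion, phenotypes = ph$phenotypes,
       truth = truth, mask = masks$gray, wm_mask = masks$wm,
       csf_mask = masks$csf, spec = spec)
}

#' Regenerate one subject's BOLD run from a cohort
#'
#' Rebuilds subject `i`'s run from the recorded per-subject seed, allowing
#' memory-bounded streaming over large cohorts (identical to the run
#' `generate_cohort()` would have stored).
#'
#' @param cohort Output of [generate_cohort()] (with or without BOLD kept).
#' @param i Subject index.
#' @return A [bold_run()].
#' @export
cohort_subject_bold <- function(cohort, i) {
  masks <- cohort_masks(cohort$spec)
  generate_subject_bold(cohort$spec, cohort$truth$per_subject_hub_strength[i],
                        cohort$truth$subject_seeds[i] + 1L, masks,
                        cohort$motion[[i]])
}
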