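#' Default pipeline configuration
#'
#' Collects every numeric choice of the analysis in one place: 5 discarded
#' volumes, 0.01-0.1 Hz band, global signal regression on, correlation
#' threshold r = 0.1, mean-scaled FCS, 4 mm FWHM smoothing, additive /
#' dominant / recessive genetic models with voxel p < 0.001 and cluster
#' p < 0.05 under 26-connectivity, sex + age covariates, and the
#' 0.05 / 5 stratified-correlation significance level.
#'
#' @param ... Named overrides of any default entry (nested lists are
#'   replaced wholesale).
#' @return A `pipeline_config` list with entries `cohort` (arguments for
#'   [cohort_spec()]; used when no `input_dir` is given), `input_dir`,
#'   `preprocess`, `fcs`, `inference`, `behavior`, `seed`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cohort = list(),
    input_dir = NULL,
    preprocess = list(n_discard = 5L, band = c(0.01, 0.1), gsr = TRUE),
    fcs = list(r_threshold = 0.1, scale = "mean", fwhm_mm = 4),
    inference = list(models = c("additive", "dominant", "recessive"),
                     voxel_forming_p = 0.001, cluster_alpha = 0.05,
                     connectivity = 26L, covariates = c("sex", "age")),
    behavior = list(alpha_divisor = 5),
    seed = 1L)
  dots <- list(...)
  for (nm in names(dots)) cfg[nm] <- dots[nm]   # keeps NULL entries
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  inf <- cfg$inference
  bad <- setdiff(inf$models, c("additive", "dominant", "recessive"))
  if (length(bad))
    stop_field("inference$models",
               paste("unknown model(s):", paste(bad, collapse = ", ")))
  if (inf$voxel_forming_p <= 0 || inf$voxel_forming_p >= 1)
    stop_field("inference$voxel_forming_p", "must lie in (0, 1)")
  if (inf$cluster_alpha <= 0 || inf$cluster_alpha >= 1)
    stop_field("inference$cluster_alpha", "must lie in (0, 1)")
  if (!cfg$inference$connectivity %in% c(6L, 18L, 26L))
    stop_field("inference$connectivity", "must be 6, 18 or 26")
  pp <- cfg$preprocess
  if (pp$band[1] < 0 || pp$band[1] >= pp$band[2])
    stop_field("preprocess$band", "need 0 <= low < high")
  if (cfg$fcs$r_threshold <= -1 || cfg$fcs$r_threshold >= 1)
    stop_field("fcs$r_threshold", "must lie in (-1, 1)")
  if (cfg$behavior$alpha_divisor < 1)
    stop_field("behavior$alpha_divisor", "must be >= 1")
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#'
#' The on-disk form round-trips losslessly through [pipeline_config()].
#'
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Per-subject FCS computation shared by the pipeline: preprocess then
# correlate-threshold-sum then smooth.
subject_fcs <- function(run, motion, wm_mask, csf_mask, pp, fc) {
  run <- preprocess_bold(run, motion, wm_mask, csf_mask,
                         n_discard = pp$n_discard, band = pp$band,
                         gsr = pp$gsr)
  m <- compute_fcs(run, r_threshold = fc$r_threshold, scale = fc$scale)
  gaussian_smooth(m, fc$fwhm_mm)
}

#' Run the full imaging-genetics pipeline
#'
#' Executes, in order: cohort simulation (or loading from `input_dir`),
#' per-subject preprocessing (volume discard, Friston-24 + WM/CSF/global
#' nuisance regression, band-pass), FCS computation and smoothing,
#' voxel-wise genotype-group statistics under each configured genetic
#' model with GRF cluster-level correction, cluster-mean extraction and
#' one-way ANOVA with LSD post hoc comparisons on the surviving
#' additive-model clusters, cohort demographic tests (Hardy-Weinberg,
#' sex chi-square, age and SPQ ANOVA), and genotype-stratified Spearman
#' correlations between cluster FCS and the SPQ scores.
#'
#' Subjects are processed one at a time, so memory stays bounded by a
#' single BOLD run plus the per-subject FCS maps.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stat maps, cluster
#'   tables, behavior tables and a JSON provenance record are written.
#' @param verbose Narrate stages (default TRUE).
#' @return List with `phenotypes`, `fcs_maps`, `models` (per genetic
#'   model: `stat_map`, `smoothness`, `clusters`), `surviving_models`,
#'   `cluster_values` (per-subject mean FCS over the significant additive
#'   clusters, or NULL), `cluster_anova`, `posthoc`, `demographics`,
#'   `spearman`, `truth` (when simulated).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = TRUE) {
  validate_pipeline_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(config$input_dir)) {
    say("[1/5] simulating cohort (seed %d)", config$seed)
    spec <- do.call(cohort_spec, c(config$cohort,
                                   list(seed = config$seed)))
    cohort <- generate_cohort(spec, keep_bold = FALSE)
    get_run <- function(i) cohort_subject_bold(cohort, i)
    truth <- cohort$truth
  } else {
    say("[1/5] loading cohort from %s", config$input_dir)
    cohort <- load_cohort_dir(config$input_dir)
    get_run <- function(i) {
      run <- read_bold(cohort$bold_files[i])
      run$mask <- cohort$mask
      run
    }
    truth <- NULL
  }
  pheno <- cohort$phenotypes
  n <- nrow(pheno)
  say("[2/5] preprocessing and FCS for %d subjects", n)
  fcs_maps <- vector("list", n)
  for (i in seq_len(n)) {
    fcs_maps[[i]] <- subject_fcs(get_run(i), cohort$motion[[i]],
                                 cohort$wm_mask, cohort$csf_mask,
                                 config$preprocess, config$fcs)
  }
  say("[3/5] voxel-wise group statistics + GRF correction")
  inf <- config$inference
  cov_tab <- if (length(inf$covariates))
    pheno[, inf$covariates, drop = FALSE] else NULL
  models <- list()
  for (mod in inf$models) {
    sm <- voxelwise_group_stat(fcs_maps, pheno$genotype, model = mod,
                               covariates = cov_tab)
    smo <- estimate_smoothness(sm$residuals, sm$mask)
    cl <- grf_cluster_inference(sm, smo,
                                voxel_forming_p = inf$voxel_forming_p,
                                cluster_alpha = inf$cluster_alpha,
                                connectivity = inf$connectivity)
    models[[mod]] <- list(stat_map = sm, smoothness = smo, clusters = cl)
  }
  surviving <- names(models)[vapply(models,
                                    function(m) nrow(m$clusters) > 0L,
                                    logical(1))]
  say("[4/5] cluster extraction and post hoc tests (surviving: %s)",
      if (length(surviving)) paste(surviving, collapse = ", ") else "none")
  cluster_values <- NULL; cluster_anova <- NULL; posthoc <- NULL
  spearman <- NULL
  extract_model <- if ("additive" %in% surviving) "additive" else
    if (length(surviving)) surviving[1] else NULL
  if (!is.null(extract_model)) {
    roi <- attr(models[[extract_model]]$clusters, "cluster_labels") > 0
    cluster_values <- vapply(fcs_maps,
                             function(m) extract_cluster_mean(m, roi),
                             numeric(1))
    cluster_anova <- oneway_anova(cluster_values, pheno$genotype)
    posthoc <- posthoc_lsd(cluster_values, pheno$genotype)
    spearman <- spearman_by_group(
      cluster_values,
      pheno[, c("spq_total", "spq_cogper", "spq_interp", "spq_disorg")],
      pheno$genotype, alpha_divisor = config$behavior$alpha_divisor)
  }
  say("[5/5] cohort demographic statistics")
  counts <- table(factor(pheno$genotype, levels = c("AA", "AG", "GG")))
  sex_tab <- table(factor(pheno$sex, levels = c("male", "female")),
                   factor(pheno$genotype, levels = c("AA", "AG", "GG")))
  demographics <- list(
    genotype_counts = counts,
    hwe = hwe_chi2(counts[["AA"]], counts[["AG"]], counts[["GG"]]),
    sex_chi2 = contingency_chi2(sex_tab),
    age_anova = oneway_anova(pheno$age, pheno$genotype),
    spq_anova = oneway_anova(pheno$spq_total, pheno$genotype))
  res <- list(phenotypes = pheno, fcs_maps = fcs_maps, models = models,
              surviving_models = surviving,
              cluster_values = cluster_values,
              cluster_anova = cluster_anova, posthoc = posthoc,
              demographics = demographics, spearman = spearman,
              truth = truth, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Minimal loader matching write_cohort()'s layout.
load_cohort_dir <- function(dir) {
  pheno <- read_phenotypes(file.path(dir, "phenotypes.tsv"))
  bold_files <- file.path(dir, paste0(pheno$subject_id, "_bold.nii.gz"))
  motion_files <- file.path(dir, paste0(pheno$subject_id, "_motion.txt"))
  missing <- c(bold_files[!file.exists(bold_files)],
               motion_files[!file.exists(motion_files)])
  if (length(missing))
    stop(sprintf("phenotype table lists subjects with no image/motion file: %s",
                 paste(basename(missing), collapse = ", ")), call. = FALSE)
  list(phenotypes = pheno, bold_files = bold_files,
       motion = lapply(motion_files, read_motion),
       mask = read_mask(file.path(dir, "mask_gray.nii.gz")),
       wm_mask = read_mask(file.path(dir, "mask_wm.nii.gz")),
       csf_mask = read_mask(file.path(dir, "mask_csf.nii.gz")))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (mod in names(res$models)) {
    m <- res$models[[mod]]
    write_map(list(data = m$stat_map$data,
                   voxel_size_mm = res$fcs_maps[[1]]$voxel_size_mm),
              file.path(out_dir, paste0("stat_", mod, ".nii.gz")))
    lab <- attr(m$clusters, "cluster_labels")
    write_map(list(data = array(as.numeric(lab), dim = dim(lab)),
                   voxel_size_mm = res$fcs_maps[[1]]$voxel_size_mm),
              file.path(out_dir, paste0("clusters_", mod, ".nii.gz")))
    write_cluster_table(m$clusters,
                        file.path(out_dir, paste0("clusters_", mod, ".tsv")))
  }
  if (!is.null(res$spearman))
    utils::write.table(res$spearman, file.path(out_dir, "spearman.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$posthoc))
    utils::write.table(res$posthoc, file.path(out_dir, "posthoc_lsd.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- res$config
  prov <- list(
    package_version = as.character(utils::packageVersion("fcstrength")),
    seed = cfg$seed,
    preprocess = cfg$preprocess, fcs = cfg$fcs,
    inference = cfg$inference[c("models", "voxel_forming_p",
                                "cluster_alpha", "connectivity")],
    behavior = cfg$behavior,
    smoothness = lapply(res$models, function(m)
      list(fwhm_vox = m$smoothness$fwhm_vox,
           resel_count = m$smoothness$resel_count)),
    surviving_models = res$surviving_models)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
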