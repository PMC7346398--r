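#' Write / read a BOLD run as NIfTI-1
#'
#' Volumes are stored as 4D NIfTI with voxel sizes and TR in `pixdim`.
#' The analysis mask travels as a separate 3D NIfTI (see [write_mask()]).
#'
#' @param run A [bold_run()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_bold <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  a <- run$data
  attr(a, "pixdim") <- c(run$voxel_size_mm, run$tr_seconds)
  RNifti::writeNifti(RNifti::asNifti(a), path)
  invisible(path)
}

#' @rdname write_bold
#' @param mask Optional logical 3D array to attach as the run's mask.
#' @export
read_bold <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4L)
    stop(sprintf("'%s': expected a 4D BOLD image, got %dD", path,
                 length(dim(a))), call. = FALSE)
  pd <- RNifti::pixdim(img)
  tr <- if (length(pd) >= 4L && pd[4] > 0) pd[4] else 1
  bold_run(a, tr_seconds = tr, voxel_size_mm = pd[1:3], mask = mask)
}

#' Write / read a 3D map as NIfTI-1
#'
#' @param map An `fcs_map`, or any list with 3D `data` and
#'   `voxel_size_mm`; a bare 3D array is accepted with `voxel_size_mm`
#'   taken as 1 mm.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  if (is.array(map)) map <- list(data = map, voxel_size_mm = c(1, 1, 1))
  a <- map$data
  attr(a, "pixdim") <- map$voxel_size_mm
  RNifti::writeNifti(RNifti::asNifti(a), path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop(sprintf("'%s': expected a 3D image", path), call. = FALSE)
  list(data = a, voxel_size_mm = RNifti::pixdim(img)[1:3])
}

#' Write / read a binary mask as NIfTI-1
#'
#' @param mask Logical 3D array.
#' @param path Output path.
#' @param voxel_size_mm Voxel sizes recorded in the header.
#' @return `path` invisibly; `read_mask()` returns a logical 3D array
#'   (nonzero voxels).
#' @export
write_mask <- function(mask, path, voxel_size_mm = c(2, 2, 2)) {
  a <- array(as.integer(mask), dim = dim(mask))
  attr(a, "pixdim") <- voxel_size_mm
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "uint8"), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  array(a != 0, dim = dim(a))
}

#' Read / write a 6-column motion parameter file
#'
#' Whitespace- or tab-delimited text, one row per volume, columns in the
#' order 3 translations (mm) then 3 rotations (degrees).
#'
#' @param path File path.
#' @return `read_motion()` returns a `motion_trace`.
#' @export
read_motion <- function(path) {
  m <- tryCatch(as.matrix(utils::read.table(path, header = FALSE)),
                error = function(e)
                  stop(sprintf("'%s': cannot parse motion file (%s)", path,
                               conditionMessage(e)), call. = FALSE))
  if (ncol(m) != 6L)
    stop(sprintf("'%s': expected 6 motion columns (t x 6), got %d", path,
                 ncol(m)), call. = FALSE)
  if (!all(is.finite(m)))
    stop(sprintf("'%s': non-finite motion values", path), call. = FALSE)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  structure(list(params = m,
                 max_translation_mm = max(abs(m[, 1:3])),
                 max_rotation_deg = max(abs(m[, 4:6]))),
            class = "motion_trace")
}

#' @rdname read_motion
#' @param motion A `motion_trace` or t x 6 matrix.
#' @export
write_motion <- function(motion, path) {
  m <- as_motion_matrix(motion)
  utils::write.table(format(m, digits = 10, trim = TRUE), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write the phenotype table
#'
#' Tab-separated with header `subject_id genotype sex age spq_total
#' spq_cogper spq_interp spq_disorg`. Genotype must be AA, AG or GG; the
#' spelling "GA" is accepted and normalized to "AG" with a warning.
#' Validation errors cite the offending line.
#'
#' @param path File path.
#' @return A data frame matching the schema.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "genotype", "sex", "age", "spq_total",
            "spq_cogper", "spq_interp", "spq_disorg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("'%s': missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  ga <- which(df$genotype == "GA")
  if (length(ga)) {
    warning(sprintf("'%s': normalized genotype \"GA\" to \"AG\" on line(s) %s",
                    path, paste(ga + 1L, collapse = ", ")), call. = FALSE)
    df$genotype[ga] <- "AG"
  }
  bad <- which(!df$genotype %in% c("AA", "AG", "GG"))
  if (length(bad))
    stop(sprintf("'%s': invalid genotype \"%s\" on line %d", path,
                 df$genotype[bad[1]], bad[1] + 1L), call. = FALSE)
  badspq <- which(df$spq_total < 0 | df$spq_total > 74)
  if (length(badspq))
    stop(sprintf("'%s': spq_total outside [0, 74] on line %d", path,
                 badspq[1] + 1L), call. = FALSE)
  df
}

#' @rdname read_phenotypes
#' @param phenotypes Data frame matching the phenotype schema.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a cluster table as TSV
#'
#' @param table A `cluster_table` from [grf_cluster_inference()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' BOLD runs as 4D NIfTI (`sub-XXX_bold.nii.gz`), motion as 6-column text,
#' gray/WM/CSF masks as 3D NIfTI, phenotypes as TSV, and ground truth
#' (hub coordinates, per-subject hub strength) as JSON.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(cohort$phenotypes)
  vx <- c(2, 2, 2)
  for (i in seq_len(n)) {
    id <- cohort$phenotypes$subject_id[i]
    run <- if (!is.null(cohort$bold)) cohort$bold[[i]] else
      cohort_subject_bold(cohort, i)
    vx <- run$voxel_size_mm
    write_bold(run, file.path(dir, paste0(id, "_bold.nii.gz")))
    write_motion(cohort$motion[[i]],
                 file.path(dir, paste0(id, "_motion.txt")))
  }
  write_mask(cohort$mask, file.path(dir, "mask_gray.nii.gz"), vx)
  write_mask(cohort$wm_mask, file.path(dir, "mask_wm.nii.gz"), vx)
  write_mask(cohort$csf_mask, file.path(dir, "mask_csf.nii.gz"), vx)
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  truth <- list(
    hub_voxels = which(cohort$truth$hub_mask, arr.ind = TRUE) - 1L,
    per_subject_hub_strength = cohort$truth$per_subject_hub_strength,
    genotype_labels = cohort$truth$genotype_labels,
    effect_ordering = cohort$truth$effect_ordering,
    seed = cohort$spec$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
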