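#' Reduce a labeled volume to per-region values
#'
#' Summarizes an image volume over the voxels of each atlas region in a
#' matching integer label volume. Voxels labeled 0 (background) are ignored.
#' Volumes are treated purely in voxel space; no resampling or registration
#' is performed, so image and labels must already be on the same grid.
#'
#' @param image 3D numeric array (e.g. gray-matter volume map or PET uptake).
#' @param labels 3D integer array of the same dimensions; values are atlas
#'   `region_id`s, 0 = background.
#' @param atlas an `atlas_spec`; every `region_id` must occur in `labels`.
#' @param reduction `"mean"` or `"median"` over the voxels of a region.
#' @return named numeric vector, one value per atlas region in atlas order,
#'   names `region_<id>`.
#' @seealso [parcellate_nifti()] for file-based input, [suvr_normalize()].
#' @export
parcellate_volume <- function(image, labels, atlas = default_atlas(),
                              reduction = c("mean", "median")) {
  reduction <- match.arg(reduction)
  if (!is.numeric(image)) stop("`image` must be numeric", call. = FALSE)
  if (!identical(dim(image), dim(labels)))
    stop("`image` and `labels` have different dimensions (",
         paste(dim(image), collapse = "x"), " vs ",
         paste(dim(labels), collapse = "x"), ")", call. = FALSE)
  lab <- as.integer(round(as.vector(labels)))
  img <- as.vector(image)
  keep <- lab != 0L
  present <- unique(lab[keep])
  absent <- setdiff(atlas$region_id, present)
  if (length(absent))
    stop("atlas region(s) absent from label volume: ",
         paste(absent, collapse = ", "), call. = FALSE)
  fun <- if (reduction == "mean") mean else stats::median
  grouped <- split(img[keep], lab[keep])
  vals <- vapply(as.character(atlas$region_id),
                 function(id) fun(grouped[[id]]), numeric(1))
  names(vals) <- region_columns(atlas)
  vals
}

#' @rdname parcellate_volume
#' @param image_path,labels_path paths to NIfTI volumes (`.nii`/`.nii.gz`).
#' @export
parcellate_nifti <- function(image_path, labels_path, atlas = default_atlas(),
                             reduction = c("mean", "median")) {
  image <- as.array(RNifti::readNifti(image_path))
  labels <- as.array(RNifti::readNifti(labels_path))
  parcellate_volume(image, labels, atlas, reduction)
}

#' Normalize regional PET values to a reference region set
#'
#' Divides every regional value by the unweighted mean of the values in the
#' chosen reference regions, yielding standardized uptake value ratios
#' (SUVR). There is no silent default reference: the caller must name it.
#'
#' @param values named region-value vector as from [parcellate_volume()].
#' @param reference_region_ids integer region ids forming the reference.
#' @return the normalized vector, with attributes `reference_region_ids` and
#'   `reference_mean` recording the normalization.
#' @export
suvr_normalize <- function(values, reference_region_ids) {
  if (missing(reference_region_ids) || !length(reference_region_ids))
    stop("`reference_region_ids` must name at least one region", call. = FALSE)
  ref_cols <- sprintf("region_%d", reference_region_ids)
  missing_ref <- setdiff(ref_cols, names(values))
  if (length(missing_ref))
    stop("reference region(s) not in `values`: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  ref_mean <- mean(values[ref_cols])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference mean must be positive (got ", format(ref_mean), ")",
         call. = FALSE)
  out <- values / ref_mean
  attr(out, "reference_region_ids") <- as.integer(reference_region_ids)
  attr(out, "reference_mean") <- ref_mean
  out
}

#' Read and write feature tables
#'
#' A feature table is one row per subject: a `subject_id` column plus one
#' numeric column per atlas region (`region_<id>`). On read, columns are
#' canonicalized to atlas order; missing or extra region columns and
#' non-numeric cells are hard errors.
#'
#' @param path CSV file path.
#' @param atlas an `atlas_spec` defining the expected column set and order.
#' @return `read_feature_table()`: a data.frame `subject_id` + region columns.
#' @export
read_feature_table <- function(path, atlas = default_atlas()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(tab))
    stop("feature table lacks a subject_id column", call. = FALSE)
  want <- region_columns(atlas)
  have <- setdiff(names(tab), "subject_id")
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  if (length(missing) || length(extra))
    stop("feature table columns do not match the atlas",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  for (cn in want) {
    if (!is.numeric(tab[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[cn]]))))[1]
      stop(sprintf("non-numeric feature cell at row %d, column %s", bad, cn),
           call. = FALSE)
    }
    if (any(!is.finite(tab[[cn]])))
      stop("non-finite feature value in column ", cn, call. = FALSE)
  }
  tab[, c("subject_id", want)]
}

#' @rdname read_feature_table
#' @param table data.frame with `subject_id` and region columns.
#' @export
write_feature_table <- function(table, path, atlas = default_atlas()) {
  want <- c("subject_id", region_columns(atlas))
  missing <- setdiff(want, names(table))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(table[, want], path, row.names = FALSE)
  invisible(path)
}

phenotype_columns <- c(
  "subject_id", "chronological_age", "sex", "education", "apoe4_carrier",
  "diagnosis_group", "progression_status", "memory_composite",
  "executive_composite", "amyloid_pet_suvr", "csf_abeta42",
  "ptau_abeta_ratio", "latent_bag_true")

#' Read a phenotype table
#'
#' @param path CSV with at least `subject_id`, `chronological_age`, `sex`,
#'   `education`, `apoe4_carrier`, `diagnosis_group`; remaining cohort
#'   columns (cognition, pathology, progression, latent ground truth) are
#'   optional and filled with `NA` when absent.
#' @return data.frame with the full phenotype column set.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "chronological_age", "sex", "education",
            "apoe4_carrier", "diagnosis_group")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("phenotype table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (cn in setdiff(phenotype_columns, names(tab))) tab[[cn]] <- NA
  tab[, phenotype_columns]
}
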