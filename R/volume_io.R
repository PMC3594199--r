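#' Grey-matter volume container
#'
#' Wraps a 3D array of grey-matter values (segmentation probabilities or
#' modulated intensities, arbitrary non-negative units) together with voxel
#' dimensions and an inclusion mask marking voxels eligible as grey matter.
#' By default the mask is `data > gm_threshold`; the default threshold of 0
#' treats any positive grey-matter value as eligible.
#'
#' @param data 3D numeric array of grey-matter values.
#' @param voxel_size_mm numeric length-3, voxel edge lengths in mm (all > 0).
#' @param mask optional logical array, same shape as `data`. Defaults to
#'   `data > gm_threshold`.
#' @param gm_threshold scalar used to derive the default mask.
#' @return An object of class `gm_volume` with elements `data`,
#'   `voxel_size_mm`, `mask`, `gm_threshold`.
#' @export
gm_volume <- function(data, voxel_size_mm = c(1, 1, 1), mask = NULL,
                      gm_threshold = 0) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be 3 positive finite numbers")
  }
  if (is.null(mask)) {
    mask <- data > gm_threshold
  }
  if (!identical(dim(mask), dim(data))) {
    stop("`mask` and `data` must have identical shape")
  }
  structure(
    list(data = data, voxel_size_mm = voxel_size_mm,
         mask = mask, gm_threshold = gm_threshold),
    class = "gm_volume"
  )
}

#' @export
print.gm_volume <- function(x, ...) {
  cat("<gm_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size_mm, 4), collapse = " x "),
      " mm; ", sum(x$mask), " in mask\n", sep = "")
  invisible(x)
}

#' Read a grey-matter volume from a NIfTI file
#'
#' Reads a 3D NIfTI-1 image (`.nii` or `.nii.gz`) into a [gm_volume()].
#' Voxel sizes are taken from the header; the data array is in 0-based voxel
#' index space with the x index varying fastest (R array convention).
#'
#' @param path path to a 3D NIfTI file.
#' @param gm_threshold threshold used to derive the default mask
#'   (`data > gm_threshold`).
#' @return A [gm_volume()].
#' @export
read_volume <- function(path, gm_threshold = 0) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3D image, got ", length(d), " dimensions in ", path)
  }
  vox <- RNifti::pixdim(img)
  if (length(vox) < 3L || any(!is.finite(vox[1:3])) || any(vox[1:3] <= 0)) {
    stop("missing or invalid voxel geometry in NIfTI header of ", path)
  }
  gm_volume(array(as.numeric(img), dim = d), voxel_size_mm = vox[1:3],
            gm_threshold = gm_threshold)
}

#' Write a grey-matter volume to a NIfTI file
#'
#' @param vol a [gm_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "gm_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Atlas label volume container
#'
#' A 3D integer array of anatomical region labels co-registered with a
#' subject's grey-matter volume. Label 0 means unlabelled; every nonzero
#' label must have a name.
#'
#' @param labels 3D integer array (0 = unlabelled).
#' @param region_names named character vector or `NULL`; names are label
#'   numbers as strings. Missing names are auto-filled as `"region_<label>"`.
#' @return An object of class `gm_labels`.
#' @export
gm_labels <- function(labels, region_names = NULL) {
  if (length(dim(labels)) != 3L) stop("`labels` must be a 3D array")
  lab <- array(as.integer(round(labels)), dim = dim(labels))
  present <- sort(unique(lab[lab != 0L]))
  if (is.null(region_names)) region_names <- character(0)
  need <- setdiff(as.character(present), names(region_names))
  if (length(need)) {
    auto <- paste0("region_", need)
    names(auto) <- need
    region_names <- c(region_names, auto)
  }
  structure(list(labels = lab, region_names = region_names),
            class = "gm_labels")
}

#' Read an atlas label volume from a NIfTI file
#'
#' @param path path to a 3D integer-valued NIfTI file.
#' @param region_names optional named character vector (label number as
#'   string -> region name).
#' @return A [gm_labels()].
#' @export
read_labels <- function(path, region_names = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) {
    stop("expected a 3D label image, got ", length(dim(img)), " dimensions")
  }
  gm_labels(array(as.numeric(img), dim = dim(img)), region_names)
}

#' Write an atlas label volume to a NIfTI file
#' @param labels a [gm_labels()].
#' @param path output path.
#' @param voxel_size_mm voxel sizes written to the header.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(inherits(labels, "gm_labels"))
  img <- RNifti::asNifti(labels$labels + 0)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort covariate table
#'
#' Reads a delimited text file with one row per subject. Required columns:
#' `id`, `group` (exactly two levels), `age`, `sex`. Optional:
#' `global_gm_volume` (mm^3), `cognitive_score` (missing values permitted),
#' and any number of `gm_<region>` columns holding regional volumes.
#'
#' @param path path to a CSV/TSV file (delimiter inferred from extension).
#' @return A data.frame with `group` as a two-level factor.
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  validate_cohort(tab)
}

#' Write a cohort covariate table
#' @param cohort data.frame as returned by [read_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

validate_cohort <- function(tab) {
  req <- c("id", "group", "age", "sex")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("cohort table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$id)) stop("cohort ids must be unique")
  tab$group <- factor(tab$group)
  if (nlevels(tab$group) != 2L) {
    stop("`group` must have exactly two levels, got ", nlevels(tab$group))
  }
  tab
}
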