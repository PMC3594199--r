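#' Assign cube nodes to atlas regions
#'
#' Each cube is assigned the majority label among its 27 voxels. Unlabelled
#' voxels (label 0) do not vote; ties go to the lowest label; a cube whose
#' voxels are all unlabelled stays unassigned (`NA`).
#'
#' @param cubes a [extract_cubes()] result.
#' @param labels a [gm_labels()] with the same volume shape the cubes were
#'   extracted from.
#' @return Integer vector of region labels per cube (`NA` = unassigned).
#' @export
assign_cubes_to_regions <- function(cubes, labels) {
  stopifnot(inherits(cubes, "gm_cubes"), inherits(labels, "gm_labels"))
  d <- dim(labels$labels)
  corners <- cubes$corners
  if (any(corners + 3L > matrix(d, nrow(corners), 3, byrow = TRUE))) {
    stop("label volume shape does not cover the cube grid")
  }
  cube_lin <- as.matrix(expand.grid(dx = 0:2, dy = 0:2, dz = 0:2))
  lin0 <- (corners[, 1] + 1L) + corners[, 2] * d[1] + corners[, 3] * d[1] * d[2]
  off_lin <- cube_lin[, 1] + cube_lin[, 2] * d[1] + cube_lin[, 3] * d[1] * d[2]
  lab <- matrix(labels$labels[outer(lin0, off_lin, `+`)], nrow = nrow(corners))
  apply(lab, 1, function(v) {
    v <- v[v != 0L]
    if (!length(v)) return(NA_integer_)
    tab <- table(v)
    winners <- as.integer(names(tab)[tab == max(tab)])
    min(winners)                       # tie -> lowest label
  })
}

#' Summarize nodal graph properties per atlas region
#'
#' Arithmetic means of each nodal property over the cubes assigned to each
#' region. Regions present in the label set but containing no cubes are
#' reported with `n_cubes = 0` and `NA` means (missing, not zero).
#'
#' @param report a [graph_report()].
#' @param assignment integer labels per node from
#'   [assign_cubes_to_regions()].
#' @param labels optional [gm_labels()] supplying region names and the full
#'   region set.
#' @param volumes optional named numeric vector of regional grey-matter
#'   volumes in mm^3 (names = label numbers), e.g. from [regional_volume()].
#' @return data.frame with one row per region: `label`, `name`, `n_cubes`,
#'   `mean_degree`, `mean_clustering`, `mean_path_length`,
#'   `mean_betweenness`, `mean_betweenness_norm`, `volume_mm3`.
#' @export
summarize_regions <- function(report, assignment, labels = NULL,
                              volumes = NULL) {
  stopifnot(inherits(report, "gm_report"))
  nodal <- report$nodal
  if (length(assignment) != nrow(nodal)) {
    stop("assignment must cover every node of the report")
  }
  all_labels <- sort(unique(c(
    assignment[!is.na(assignment)],
    if (!is.null(labels)) unique(labels$labels[labels$labels != 0L])
  )))
  region_name <- function(l) {
    if (!is.null(labels) && as.character(l) %in% names(labels$region_names))
      labels$region_names[[as.character(l)]] else paste0("region_", l)
  }
  rows <- lapply(all_labels, function(l) {
    sel <- !is.na(assignment) & assignment == l
    m <- function(col) if (any(sel)) mean(nodal[[col]][sel]) else NA_real_
    data.frame(
      label = l, name = region_name(l), n_cubes = sum(sel),
      mean_degree = m("degree"),
      mean_clustering = m("clustering"),
      mean_path_length = m("path_length"),
      mean_betweenness = m("betweenness"),
      mean_betweenness_norm = m("betweenness_norm"),
      volume_mm3 = if (!is.null(volumes) &&
                       as.character(l) %in% names(volumes))
        unname(volumes[[as.character(l)]]) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_unassigned") <- sum(is.na(assignment))
  out
}

#' Regional grey-matter volume
#'
#' Volume of each atlas region in mm^3. In `"value"` mode (the modulated-VBM
#' convention, default) the in-mask grey-matter values are summed and scaled
#' by the voxel volume; in `"count"` mode in-mask voxels are counted and
#' multiplied by the voxel volume.
#'
#' @param vol a [gm_volume()].
#' @param labels a [gm_labels()] with the same shape.
#' @param mode `"value"` or `"count"`.
#' @return Named numeric vector (names = label numbers) of volumes in mm^3;
#'   regions with no in-mask voxels get 0.
#' @export
regional_volume <- function(vol, labels, mode = c("value", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, "gm_volume"), inherits(labels, "gm_labels"))
  if (!identical(dim(vol$data), dim(labels$labels))) {
    stop("volume and label shapes differ")
  }
  voxvol <- prod(vol$voxel_size_mm)
  lab <- labels$labels
  present <- sort(unique(lab[lab != 0L]))
  sel <- vol$mask & lab != 0L
  contrib <- if (mode == "value") vol$data[sel] else rep(1, sum(sel))
  sums <- tapply(contrib, lab[sel], sum)
  out <- stats::setNames(rep(0, length(present)), as.character(present))
  out[names(sums)] <- as.numeric(sums) * voxvol
  out
}
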