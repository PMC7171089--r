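#' Quantification configuration
#'
#' Holds the constants of the 2D-to-3D counting arithmetic: detected cells
#' on sparse 2D sections are scaled by the conversion factor `k3d` (1.4) to
#' estimate total 3D counts, and regional volumes come from voxel counts
#' times the physical voxel volume (20 x 20 x 50 um^3 = 20000 um^3 at the
#' working resolution).
#'
#' @param k3d 2D-to-3D conversion factor (> 0), default 1.4.
#' @param voxel_volume_um3 voxel volume in um^3; default `NULL` takes it
#'   from the label volume's spacing.
#' @param background_id background label id, default 0.
#' @return object of class `quant_config`.
#' @export
quant_config <- function(k3d = 1.4, voxel_volume_um3 = NULL,
                         background_id = 0L) {
  if (k3d <= 0) stop("k3d must be > 0", call. = FALSE)
  if (!is.null(voxel_volume_um3) && voxel_volume_um3 <= 0)
    stop("voxel volume must be > 0", call. = FALSE)
  structure(list(k3d = k3d, voxel_volume_um3 = voxel_volume_um3,
                 background_id = as.integer(background_id)),
            class = "quant_config")
}

#' Assign detected cells to anatomical regions
#'
#' Each cell is assigned the label of the voxel containing it under the
#' half-open floor convention (a cell exactly on a boundary plane belongs to
#' the higher-index voxel). Cells in background voxels are retained and
#' flagged; cells outside the grid are retained, flagged `out_of_grid`, and
#' excluded from regional counts.
#'
#' @param cells cell tibble (`x_um`, `y_um`, `z_um`, ...).
#' @param labels a [label_volume()] in the same physical space.
#' @param config a [quant_config()].
#' @return the cell tibble with `region_id`, `background` and `out_of_grid`
#'   columns.
#' @export
assign_cells <- function(cells, labels, config = quant_config()) {
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels$data)
  idx <- points_to_voxels(labels, as.matrix(cells[, c("x_um", "y_um", "z_um")]))
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  region <- rep(NA_integer_, nrow(cells))
  if (any(inside)) {
    lin <- (idx[inside, 1] - 1) + d[1] * (idx[inside, 2] - 1) +
      d[1] * d[2] * (idx[inside, 3] - 1) + 1
    region[inside] <- labels$data[lin]
  }
  cells$region_id <- region
  cells$out_of_grid <- !inside
  cells$background <- !is.na(region) & region == config$background_id
  cells
}

#' Per-region counts, volumes and densities
#'
#' One record per region id present in the label volume (zero-count regions
#' included with density 0): the 2D-detected count `n2d`, the 3D estimate
#' `n3d = k3d x n2d`, the voxel count, the regional volume in mm^3
#' (`voxels x voxel volume x 1e-9`) and the density `n3d / volume_mm3` in
#' cells per mm^3. Background and out-of-grid cells are excluded from the
#' regional records and reported in the attributes `"n_background"` and
#' `"n_out_of_grid"`.
#'
#' @param assignments output of [assign_cells()].
#' @param labels the [label_volume()] used for assignment.
#' @param config a [quant_config()].
#' @param metadata optional named list (age, sex, subject, ...) recycled
#'   onto every row.
#' @return tibble of region statistics.
#' @export
region_stats <- function(assignments, labels, config = quant_config(),
                         metadata = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  vv <- if (is.null(config$voxel_volume_um3)) voxel_volume_um3(labels)
        else config$voxel_volume_um3
  lab_vec <- as.vector(labels$data)
  vox <- table(lab_vec[lab_vec != config$background_id])
  ids <- as.integer(names(vox))
  counted <- assignments[!assignments$out_of_grid & !assignments$background &
                           !is.na(assignments$region_id), , drop = FALSE]
  bad <- setdiff(unique(counted$region_id), c(ids, config$background_id))
  if (length(bad))
    stop("cells assigned to region(s) with zero voxels: ",
         paste(bad, collapse = ", "), call. = FALSE)
  n2d <- table(factor(counted$region_id, levels = ids))
  out <- tibble::tibble(
    region_id = ids,
    n2d = as.integer(n2d),
    n3d = config$k3d * as.integer(n2d),
    n_voxels = as.integer(vox),
    volume_mm3 = as.integer(vox) * vv * 1e-9
  )
  out$density_mm3 <- ifelse(out$volume_mm3 > 0, out$n3d / out$volume_mm3, 0)
  if (!is.null(labels$ontology)) {
    out <- dplyr::left_join(
      out, labels$ontology[, c("id", "acronym", "name")],
      by = c(region_id = "id"))
    out <- out[, c("region_id", "acronym", "name", "n2d", "n3d", "n_voxels",
                   "volume_mm3", "density_mm3")]
  }
  if (!is.null(metadata)) for (nm in names(metadata)) out[[nm]] <- metadata[[nm]]
  attr(out, "n_background") <- sum(assignments$background, na.rm = TRUE)
  attr(out, "n_out_of_grid") <- sum(assignments$out_of_grid)
  attr(out, "k3d") <- config$k3d
  out
}

#' Aggregate region statistics up an ontology
#'
#' Produces one record for *every* ontology node: counts and voxel numbers
#' are summed over all descendants plus any voxels labeled directly at the
#' node itself, and the density is recomputed from the summed quantities
#' (never averaged over child densities, which would break
#' `density x volume = n3d`).
#'
#' @param stats leaf-level tibble from [region_stats()].
#' @param ontology validated ontology tibble.
#' @return tibble of region statistics at every ontology node, ordered as
#'   the ontology.
#' @export
aggregate_regions <- function(stats, ontology) {
  unknown <- setdiff(stats$region_id, ontology$id)
  if (length(unknown))
    stop("stats carry region id(s) absent from the ontology: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  k3d <- attr(stats, "k3d")
  if (is.null(k3d)) {
    k3d <- if (any(stats$n2d > 0)) {
      i <- which(stats$n2d > 0)[1]
      stats$n3d[i] / stats$n2d[i]
    } else 1.4
  }
  vv_per_mm3 <- if (any(stats$n_voxels > 0)) {
    i <- which(stats$n_voxels > 0)[1]
    stats$volume_mm3[i] / stats$n_voxels[i]
  } else 0
  rows <- lapply(seq_len(nrow(ontology)), function(i) {
    id <- ontology$id[i]
    fam <- c(id, ontology_descendants(ontology, id))
    sub <- stats[stats$region_id %in% fam, , drop = FALSE]
    n2d <- sum(sub$n2d)
    nvox <- sum(sub$n_voxels)
    tibble::tibble(region_id = id, acronym = ontology$acronym[i],
                   name = ontology$name[i], n2d = n2d, n3d = k3d * n2d,
                   n_voxels = nvox, volume_mm3 = nvox * vv_per_mm3)
  })
  out <- dplyr::bind_rows(rows)
  out$density_mm3 <- ifelse(out$volume_mm3 > 0, out$n3d / out$volume_mm3, 0)
  meta <- setdiff(names(stats), names(out))
  for (nm in meta) if (length(unique(stats[[nm]])) == 1)
    out[[nm]] <- stats[[nm]][1]
  attr(out, "k3d") <- k3d
  out
}

#' Full quantification of one subject
#'
#' Convenience chain: assign cells, compute leaf region statistics, then
#' aggregate over the ontology.
#'
#' @inheritParams assign_cells
#' @inheritParams region_stats
#' @param ontology optional ontology (defaults to the label volume's).
#' @return tibble of region statistics at every ontology node.
#' @export
quantify_cells <- function(cells, labels, config = quant_config(),
                           ontology = NULL, metadata = NULL) {
  if (is.null(ontology)) ontology <- labels$ontology
  if (is.null(ontology)) stop("no ontology available", call. = FALSE)
  asg <- assign_cells(cells, labels, config)
  st <- region_stats(asg, labels, config, metadata)
  aggregate_regions(st, ontology)
}
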