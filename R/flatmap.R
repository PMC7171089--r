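#' Evenly spaced cortical bins for a flatmap
#'
#' Partitions the cortical shell of a labeled reference volume into an
#' `n_u x n_v` grid of bins over the shell's angular parameterization
#' (azimuth around the dorsoventral axis x polar angle from dorsal), the
#' package's stand-in for a precomputed cortical flattening: each bin is a
#' contiguous set of cortical voxels summarizing one cortical column
#' segment.
#'
#' @param labels [label_volume()] of the reference brain.
#' @param cortex_ids label ids forming the cortex mask (default: ids of the
#'   ontology subtree rooted at acronym "CTX", else all labels 101-106).
#' @param n_u,n_v bins along azimuth / polar axes (default 8 x 6).
#' @return object of class `flatmap_bins`: `bin_volume` (integer volume,
#'   0 outside bins), `bins` tibble (bin_id, grid_x, grid_y), `n_u`, `n_v`,
#'   `layer` ("full").
#' @export
flatmap_bins <- function(labels, cortex_ids = NULL, n_u = 8, n_v = 6) {
  stopifnot(inherits(labels, "label_volume"))
  if (is.null(cortex_ids)) {
    if (!is.null(labels$ontology) && "CTX" %in% labels$ontology$acronym) {
      ctx <- labels$ontology$id[labels$ontology$acronym == "CTX"]
      cortex_ids <- c(ctx, ontology_descendants(labels$ontology, ctx))
    } else cortex_ids <- 101:106
  }
  lab <- as.vector(labels$data)
  brain <- lab != 0
  if (!any(brain)) stop("empty label volume", call. = FALSE)
  pts <- grid_centers(labels)
  ctr <- colMeans(pts[brain, , drop = FALSE])
  semi <- apply(abs(sweep(pts[brain, , drop = FALSE], 2, ctr, "-")), 2, max)
  in_ctx <- lab %in% cortex_ids
  xn <- (pts[in_ctx, 1] - ctr[1]) / semi[1]
  yn <- (pts[in_ctx, 2] - ctr[2]) / semi[2]
  zn <- (pts[in_ctx, 3] - ctr[3]) / semi[3]
  r <- sqrt(xn^2 + yn^2 + zn^2)
  u <- atan2(yn, xn)                      # azimuth in (-pi, pi]
  vang <- acos(pmin(pmax(zn / r, -1), 1)) # polar angle from dorsal (+z)
  vmax <- max(vang) * (1 + 1e-9)
  gu <- pmin(pmax(floor((u + pi) / (2 * pi) * n_u) + 1, 1), n_u)
  gv <- pmin(pmax(floor(vang / vmax * n_v) + 1, 1), n_v)
  bin_id <- gu + n_u * (gv - 1)
  bv <- integer(length(lab))
  bv[in_ctx] <- bin_id
  bins <- tidyr::expand_grid(grid_y = seq_len(n_v), grid_x = seq_len(n_u))
  bins <- tibble::tibble(bin_id = seq_len(n_u * n_v),
                         grid_x = bins$grid_x, grid_y = bins$grid_y)
  structure(list(
    bin_volume = volume(array(bv, dim(labels$data)), labels$spacing,
                        labels$origin),
    bins = bins, n_u = n_u, n_v = n_v, layer = "full"),
    class = "flatmap_bins")
}

#' Restrict flatmap bins to superficial or deep cortical layers
#'
#' Intersects the bin volume with the layer mask: layers 1-3 for the
#' superficial map, layers 5 and 6 for the deep map (layer 4 belongs to
#' neither restricted map; the full-cortex bins include it). Layer ids are
#' resolved from the ontology acronyms `L1`..`L6` unless given explicitly.
#' Bins whose intersection is empty are retained with zero voxels (their
#' density is later reported as missing, not zero).
#'
#' @param bins a [flatmap_bins()].
#' @param labels the [label_volume()] the bins were built from.
#' @param which `"superficial"` or `"deep"`.
#' @param layer_ids optional explicit label ids for the layer mask.
#' @return a `flatmap_bins` restricted to the layer mask.
#' @export
layer_restrict <- function(bins, labels, which = c("superficial", "deep"),
                           layer_ids = NULL) {
  which <- match.arg(which)
  stopifnot(inherits(bins, "flatmap_bins"))
  if (is.null(layer_ids)) {
    acr <- if (which == "superficial") paste0("L", 1:3) else paste0("L", 5:6)
    if (!is.null(labels$ontology) && all(acr %in% labels$ontology$acronym)) {
      layer_ids <- labels$ontology$id[labels$ontology$acronym %in% acr]
    } else {
      layer_ids <- if (which == "superficial") 101:103 else 105:106
    }
  }
  mask <- array(as.vector(labels$data) %in% layer_ids,
                dim(labels$data))
  out <- bins
  out$bin_volume$data <- bins$bin_volume$data * mask
  out$layer <- which
  out
}

#' Per-bin counts, volumes and densities on a cortical flatmap
#'
#' Assigns reference-space cells to bins by voxel lookup, converts 2D counts
#' to 3D (`x k3d`) and divides by each bin's *age-specific* volume: the bin
#' volume is carried onto the age's template grid through `age_transform`
#' (the transform that resamples reference-space content onto the age grid,
#' i.e. the reverse registration of the reference to that age), where voxels
#' are counted at the age grid's voxel volume. Pass
#' [transform_identity()] for the reference age itself; a missing transform
#' is an error — there is no silent fallback to reference-age bin volumes.
#'
#' @param cells cell tibble registered into reference space.
#' @param bins a [flatmap_bins()] (possibly layer-restricted).
#' @param age_transform a `brain_transform` (see above).
#' @param config a [quant_config()].
#' @param age_grid optional [volume()] defining the age template grid
#'   (defaults to the transform's fixed domain, else the reference grid).
#' @return tibble: bin_id, grid_x, grid_y, n2d, n3d, n_voxels, volume_mm3,
#'   density_mm3 (NA for bins with zero age-specific volume).
#' @export
bin_densities <- function(cells, bins, age_transform, config = quant_config(),
                          age_grid = NULL) {
  stopifnot(inherits(bins, "flatmap_bins"))
  if (missing(age_transform) || is.null(age_transform))
    stop("age_transform is required (use transform_identity() for the ",
         "reference age)", call. = FALSE)
  bv <- bins$bin_volume
  nbin <- nrow(bins$bins)
  # 2D counts per bin in reference space
  idx <- points_to_voxels(bv, as.matrix(cells[, c("x_um", "y_um", "z_um")]))
  d <- dim(bv$data)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
    idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  bin_of_cell <- integer(nrow(cells))
  if (any(inside)) {
    lin <- (idx[inside, 1] - 1) + d[1] * (idx[inside, 2] - 1) +
      d[1] * d[2] * (idx[inside, 3] - 1) + 1
    bin_of_cell[inside] <- bv$data[lin]
  }
  n2d <- tabulate(bin_of_cell[bin_of_cell > 0], nbins = nbin)
  # age-specific bin volumes via the reverse registration
  blab <- label_volume(bv$data, bv$spacing, bv$origin)
  warped <- apply_to_labels(age_transform, blab, grid = age_grid)
  nvox <- tabulate(as.vector(warped$data)[as.vector(warped$data) > 0],
                   nbins = nbin)
  vol_mm3 <- nvox * voxel_volume_um3(warped) * 1e-9
  out <- bins$bins
  out$n2d <- n2d
  out$n3d <- config$k3d * n2d
  out$n_voxels <- nvox
  out$volume_mm3 <- vol_mm3
  out$density_mm3 <- ifelse(vol_mm3 > 0, out$n3d / vol_mm3, NA_real_)
  out
}

#' Render a flatmap density table as a heat map
#'
#' Deterministic tile map of per-bin densities on the `grid_x x grid_y`
#' layout; bins with missing density (zero age-specific volume) are drawn in
#' a distinct missing-data colour, never as zero. The table itself is the
#' source of truth; write it with [readr::write_tsv()].
#'
#' @param density_table output of [bin_densities()].
#' @param title optional plot title.
#' @return a ggplot object.
#' @export
render_flatmap <- function(density_table, title = NULL) {
  ggplot2::ggplot(density_table,
                  ggplot2::aes(x = .data$grid_x, y = .data$grid_y,
                               fill = .data$density_mm3)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_viridis_c(name = "cells / mm³",
                                  na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "azimuthal bin", y = "polar bin", title = title) +
    ggplot2::theme_minimal()
}
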