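#' Create a 3D volume
#'
#' A `volume` is the package's container for a scalar 3D image: a numeric
#' array in `(x, y, z)` axis order together with physical voxel spacing in
#' micrometres. The z axis is the sectioning axis (50 um steps at the working
#' resolution used throughout, with 20 um in-plane).
#'
#' Coordinate convention: physical coordinates are in micrometres with the
#' origin at the *corner* of voxel `(1,1,1)` (0-based corner at 0 um). A point
#' with coordinate `c` on an axis with spacing `s` falls in voxel
#' `floor(c / s) + 1` (1-based), i.e. voxel intervals are half-open
#' `[ (i-1)*s, i*s )`. The centre of voxel `i` is at `(i - 0.5) * s`.
#'
#' @param data numeric 3D array, axis order (x, y, z).
#' @param spacing numeric length-3, voxel spacing in um; all > 0.
#'   Default `c(20, 20, 50)`.
#' @param origin numeric length-3, physical position (um) of the corner of the
#'   first voxel. Default `c(0, 0, 0)`.
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = c(20, 20, 50), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (x, y, z)", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (um)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (um)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume")
}

#' Create a label volume
#'
#' A `label_volume` is an integer-valued [volume()] whose voxel values are
#' anatomical region ids (0 = background), optionally linked to a region
#' ontology (see [read_ontology()]).
#'
#' @param data integer 3D array of region ids; 0 is background.
#' @param spacing,origin as in [volume()].
#' @param ontology optional ontology tibble; when given, every nonzero label
#'   must appear in `ontology$id`.
#' @return An object of class `label_volume` (inherits `volume`).
#' @export
label_volume <- function(data, spacing = c(20, 20, 50), origin = c(0, 0, 0),
                         ontology = NULL) {
  if (any(data %% 1 != 0, na.rm = TRUE))
    stop("label data must be integer-valued", call. = FALSE)
  v <- volume(data, spacing, origin)
  storage.mode(v$data) <- "integer"
  if (!is.null(ontology)) {
    labs <- setdiff(unique(as.vector(v$data)), 0L)
    missing <- setdiff(labs, ontology$id)
    if (length(missing))
      stop("labels absent from ontology: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  v$ontology <- ontology
  class(v) <- c("label_volume", "volume")
  v
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %g x %g x %g um\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (inherits(x, "label_volume"))
    cat(sprintf("  %d distinct nonzero labels\n",
                length(setdiff(unique(as.vector(x$data)), 0L))))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Physical volume of one voxel in cubic micrometres
#' @param v a [volume()].
#' @return scalar, um^3 (default spacing gives 20 * 20 * 50 = 20000).
#' @export
voxel_volume_um3 <- function(v) prod(v$spacing)

#' Map physical points to voxel indices
#'
#' Applies the half-open floor convention: coordinate `c` maps to 1-based
#' index `floor((c - origin) / spacing) + 1`, so a point exactly on a voxel
#' boundary belongs to the higher-index voxel.
#'
#' @param v a [volume()].
#' @param pts numeric matrix (n x 3) of physical coordinates in um.
#' @return integer matrix (n x 3) of 1-based voxel indices; indices outside
#'   the grid are returned as-is (callers flag them).
#' @export
points_to_voxels <- function(v, pts) {
  pts <- as.matrix(pts)
  idx <- floor(sweep(sweep(pts, 2, v$origin, "-"), 2, v$spacing, "/")) + 1
  storage.mode(idx) <- "integer"
  idx
}

#' Physical coordinates of voxel centres
#' @param v a [volume()].
#' @param idx integer matrix (n x 3) of 1-based voxel indices.
#' @return numeric matrix (n x 3), um.
#' @export
voxel_centers <- function(v, idx) {
  idx <- as.matrix(idx)
  sweep(sweep(idx - 0.5, 2, v$spacing, "*"), 2, v$origin, "+")
}

# index grid of all voxel centres as an n x 3 matrix (x fastest), cached order
# matches as.vector(v$data)
grid_centers <- function(v) {
  d <- dim(v$data)
  idx <- cbind(
    rep.int(seq_len(d[1]), d[2] * d[3]),
    rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
    rep(seq_len(d[3]), each = d[1] * d[2])
  )
  voxel_centers(v, idx)
}

#' Mirror a volume about the mid-x plane
#'
#' Left-right mirroring is always about the midplane of the x extent; the
#' grid, spacing and origin are unchanged.
#'
#' @param v a [volume()].
#' @return mirrored volume of the same class.
#' @export
mirror_x <- function(v) {
  v$data <- v$data[dim(v$data)[1]:1, , , drop = FALSE]
  v
}

#' Trilinear / nearest-neighbour sampling of a volume at physical points
#'
#' Samples outside the grid return `outside` (default `NA`). Interpolation is
#' carried out in voxel-centre coordinates: the value at a voxel's centre is
#' its array value.
#'
#' @param v a [volume()].
#' @param pts n x 3 matrix of physical coordinates (um).
#' @param interpolation "linear" or "nearest" (labels must use nearest).
#' @param outside value for out-of-grid samples.
#' @return numeric vector of length n.
#' @export
sample_volume <- function(v, pts, interpolation = c("linear", "nearest"),
                          outside = NA_real_) {
  interpolation <- match.arg(interpolation)
  pts <- as.matrix(pts)
  d <- dim(v$data)
  # continuous voxel coordinate: voxel centre i is at coordinate i
  cc <- sweep(sweep(pts, 2, v$origin, "-"), 2, v$spacing, "/") + 0.5
  if (interpolation == "nearest") {
    idx <- round(cc)
    ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
      idx[, 2] >= 1 & idx[, 2] <= d[2] &
      idx[, 3] >= 1 & idx[, 3] <= d[3]
    out <- rep(outside, nrow(pts))
    if (any(ok)) {
      lin <- (idx[ok, 1] - 1) + d[1] * (idx[ok, 2] - 1) +
        d[1] * d[2] * (idx[ok, 3] - 1) + 1
      out[ok] <- v$data[lin]
    }
    return(out)
  }
  i0 <- floor(cc)
  f <- cc - i0
  out <- rep(as.numeric(outside), nrow(pts))
  ok <- cc[, 1] >= 1 & cc[, 1] <= d[1] &
    cc[, 2] >= 1 & cc[, 2] <= d[2] &
    cc[, 3] >= 1 & cc[, 3] <= d[3]
  if (!any(ok)) return(out)
  i0 <- pmin(pmax(i0[ok, , drop = FALSE], 1), rep(d - 1, each = sum(ok)))
  fx <- cc[ok, 1] - i0[, 1]; fy <- cc[ok, 2] - i0[, 2]; fz <- cc[ok, 3] - i0[, 3]
  dat <- v$data
  n12 <- d[1] * d[2]
  base <- (i0[, 1] - 1) + d[1] * (i0[, 2] - 1) + n12 * (i0[, 3] - 1) + 1
  v000 <- dat[base];            v100 <- dat[base + 1]
  v010 <- dat[base + d[1]];     v110 <- dat[base + d[1] + 1]
  v001 <- dat[base + n12];      v101 <- dat[base + n12 + 1]
  v011 <- dat[base + d[1] + n12]; v111 <- dat[base + d[1] + n12 + 1]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

# gradient volumes (central differences, per-axis, in intensity per um)
volume_gradient <- function(v) {
  d <- dim(v$data)
  g <- lapply(1:3, function(ax) {
    arr <- v$data
    up <- arr; dn <- arr
    if (ax == 1) { up[-d[1], , ] <- arr[-1, , ]; dn[-1, , ] <- arr[-d[1], , ] }
    if (ax == 2) { up[, -d[2], ] <- arr[, -1, ]; dn[, -1, ] <- arr[, -d[2], ] }
    if (ax == 3) { up[, , -d[3]] <- arr[, , -1]; dn[, , -1] <- arr[, , -d[3]] }
    (up - dn) / (2 * v$spacing[ax])
  })
  lapply(g, function(arr) volume(arr, v$spacing, v$origin))
}

# block-mean downsample by integer factors (pads by edge replication implicitly
# via truncation); used by the registration pyramids
downsample_volume <- function(v, factor) {
  factor <- as.integer(factor)
  d <- dim(v$data)
  nd <- pmax(d %/% factor, 1L)
  arr <- v$data[seq_len(nd[1] * factor[1]), seq_len(nd[2] * factor[2]),
                seq_len(nd[3] * factor[3]), drop = FALSE]
  dim(arr) <- c(factor[1], nd[1], factor[2], nd[2], factor[3], nd[3])
  out <- apply(arr, c(2, 4, 6), mean)
  volume(out, v$spacing * factor, v$origin)
}
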