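#' Spatial transforms
#'
#' A `brain_transform` is an ordered list of stages, each an affine map or a
#' cubic-B-spline free-form deformation. Internally the stages store the
#' *resampling* map (output/fixed space -> input/moving space), the
#' convention under which [register()] naturally produces its result:
#' `apply_to_volume()` evaluates the moving image at mapped grid positions,
#' while `apply_to_points()` applies the inverse map so that image content
#' and point sets move together (warping an impulse image and the matching
#' point lands both in the same voxel).
#'
#' User-facing constructors take the *motion* map (how points move), which is
#' what one writes down for a translation: `transform_translation(c(40,0,0))`
#' moves a point at x = 100 um to x = 140 um and shifts image content the
#' same way.
#'
#' @name brain_transform
NULL

new_transform <- function(stages, fixed_domain = NULL) {
  structure(list(stages = stages, fixed_domain = fixed_domain),
            class = "brain_transform")
}

#' @export
print.brain_transform <- function(x, ...) {
  cat("<brain_transform> ", length(x$stages), " stage(s): ",
      paste(vapply(x$stages, `[[`, "", "type"), collapse = " -> "), "\n",
      sep = "")
  invisible(x)
}

#' @rdname brain_transform
#' @return identity transform.
#' @export
transform_identity <- function() new_transform(list())

#' @rdname brain_transform
#' @param A 3x3 matrix (motion map, `y = A x + t`); must be invertible.
#' @param t length-3 translation in um.
#' @export
transform_affine <- function(A = diag(3), t = c(0, 0, 0)) {
  A <- as.matrix(A)
  if (abs(det(A)) < 1e-12)
    stop("affine matrix is singular", call. = FALSE)
  # store the resampling (inverse) map
  Ai <- solve(A)
  new_transform(list(list(type = "affine", A = Ai, t = as.numeric(-Ai %*% t))))
}

#' @rdname brain_transform
#' @param shift length-3 displacement in um applied to points.
#' @export
transform_translation <- function(shift) {
  transform_affine(diag(3), shift)
}

#' @rdname brain_transform
#' @param ctrl 4D array `[n1, n2, n3, 3]` of control-point displacements (um)
#'   defining the *resampling* displacement field `R(x) = x + u(x)`.
#' @param ctrl_spacing control lattice spacing (um, length 3).
#' @param ctrl_origin physical position of control point (1,1,1) (um).
#' @export
transform_bspline <- function(ctrl, ctrl_spacing, ctrl_origin = c(0, 0, 0)) {
  stopifnot(length(dim(ctrl)) == 4L, dim(ctrl)[4] == 3L)
  new_transform(list(list(type = "bspline", ctrl = ctrl,
                          spacing = as.numeric(ctrl_spacing),
                          origin = as.numeric(ctrl_origin))))
}

# cubic B-spline basis at fractional positions f in [0,1): 4 weights for
# control offsets -1, 0, +1, +2
bspline_weights <- function(f) {
  f2 <- f * f; f3 <- f2 * f
  cbind((1 - 3 * f + 3 * f2 - f3) / 6,
        (4 - 6 * f2 + 3 * f3) / 6,
        (1 + 3 * f + 3 * f2 - 3 * f3) / 6,
        f3 / 6)
}

# displacement of a B-spline stage at physical points (n x 3), um
bspline_displacement <- function(stage, pts) {
  ctrl <- stage$ctrl
  dcp <- dim(ctrl)[1:3]
  n <- nrow(pts)
  tt <- sweep(sweep(pts, 2, stage$origin, "-"), 2, stage$spacing, "/")
  i0 <- floor(tt)
  fr <- tt - i0
  W <- list(bspline_weights(fr[, 1]), bspline_weights(fr[, 2]),
            bspline_weights(fr[, 3]))
  # 1-based index of the offset-0 control point, clamped per-offset below
  base <- i0 + 1
  u <- matrix(0, n, 3)
  n12 <- dcp[1] * dcp[2]
  cm <- matrix(ctrl, nrow = prod(dcp), ncol = 3)
  for (a in 1:4) {
    ia <- pmin(pmax(base[, 1] + a - 2, 1), dcp[1])
    wa <- W[[1]][, a]
    for (b in 1:4) {
      ib <- pmin(pmax(base[, 2] + b - 2, 1), dcp[2])
      wab <- wa * W[[2]][, b]
      for (cc in 1:4) {
        ic <- pmin(pmax(base[, 3] + cc - 2, 1), dcp[3])
        w <- wab * W[[3]][, cc]
        lin <- ia + dcp[1] * (ib - 1) + n12 * (ic - 1)
        u <- u + w * cm[lin, , drop = FALSE]
      }
    }
  }
  u
}

stage_map <- function(stage, pts) {
  switch(stage$type,
    affine = sweep(pts %*% t(stage$A), 2, stage$t, "+"),
    bspline = pts + bspline_displacement(stage, pts),
    inv_bspline = invert_bspline_points(stage$inner, pts, stage$tol_um),
    stop("unknown stage type ", stage$type)
  )
}

# resampling map: fixed-space points -> moving-space points
map_points_resample <- function(t, pts) {
  pts <- as.matrix(pts)
  for (s in t$stages) pts <- stage_map(s, pts)
  pts
}

# motion map: moving-space points -> fixed-space points (inverse resample)
map_points_motion <- function(t, pts) {
  map_points_resample(invert_transform(t), pts)
}

# fixed-point inversion of y = x + u(x): find x given y
invert_bspline_points <- function(stage, pts, tol_um = 1, max_iter = 100) {
  x <- pts
  for (k in seq_len(max_iter)) {
    xn <- pts - bspline_displacement(stage, x)
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol_um) break
  }
  x
}

#' Invert a transform
#'
#' Affine stages invert in closed form; B-spline stages invert numerically by
#' fixed-point iteration at application time (tolerance `tol_um`, default a
#' tenth of the smallest fixed-grid voxel edge when known, else 1 um).
#'
#' @param t a `brain_transform`.
#' @param tol_um fixed-point tolerance for B-spline stages, um.
#' @return the inverse `brain_transform`.
#' @export
invert_transform <- function(t, tol_um = NULL) {
  if (is.null(tol_um)) {
    tol_um <- if (!is.null(t$fixed_domain)) 0.1 * min(t$fixed_domain$spacing)
              else 1
  }
  inv_stage <- function(s) {
    switch(s$type,
      affine = {
        Ai <- solve(s$A)
        list(type = "affine", A = Ai, t = as.numeric(-Ai %*% s$t))
      },
      bspline = list(type = "inv_bspline", inner = s, tol_um = tol_um),
      inv_bspline = s$inner,
      stop("unknown stage type ", s$type))
  }
  new_transform(rev(lapply(t$stages, inv_stage)), fixed_domain = NULL)
}

#' Compose transforms
#'
#' `compose_transforms(t1, t2)` is the transform that moves points first by
#' `t1`, then by `t2` (so for label propagation source -> mid -> target, pass
#' the source->mid transform first). Composition is associative.
#'
#' @param ... `brain_transform` objects, applied to points left to right.
#' @return composed `brain_transform`.
#' @export
compose_transforms <- function(...) {
  ts <- list(...)
  stopifnot(all(vapply(ts, inherits, TRUE, "brain_transform")))
  # resample map applies the later motion's stages first
  stages <- do.call(c, lapply(rev(ts), `[[`, "stages"))
  last <- ts[[length(ts)]]
  new_transform(stages, fixed_domain = last$fixed_domain)
}

#' Resample a volume through a transform
#'
#' Evaluates the moving volume at transform-mapped positions of the output
#' grid. The output grid defaults to the transform's recorded fixed domain
#' (when produced by [register()]) and falls back to the input's own grid.
#'
#' @param t a `brain_transform`.
#' @param v the moving [volume()].
#' @param interpolation "linear" (intensities) or "nearest".
#' @param grid optional [volume()] whose grid/spacing define the output.
#' @param outside fill value for unmapped voxels (default 0).
#' @return resampled [volume()] on the output grid.
#' @export
apply_to_volume <- function(t, v, interpolation = c("linear", "nearest"),
                            grid = NULL, outside = 0) {
  interpolation <- match.arg(interpolation)
  out <- resample_grid(t, v, grid)
  vals <- sample_volume(v, out$pts, interpolation, outside = outside)
  volume(array(vals, out$dim), spacing = out$spacing, origin = out$origin)
}

resample_grid <- function(t, v, grid) {
  if (is.null(grid) && !is.null(t$fixed_domain)) {
    fd <- t$fixed_domain
    grid <- volume(array(0, fd$dim), fd$spacing, fd$origin)
  }
  if (is.null(grid)) grid <- v
  pts <- map_points_resample(t, grid_centers(grid))
  list(pts = pts, dim = dim(grid$data), spacing = grid$spacing,
       origin = grid$origin)
}

#' Resample a label volume (nearest-neighbour only)
#'
#' Nearest-neighbour interpolation guarantees that no label absent from the
#' input can appear in the output.
#'
#' @inheritParams apply_to_volume
#' @param lv a [label_volume()].
#' @return warped [label_volume()] carrying the same ontology.
#' @export
apply_to_labels <- function(t, lv, grid = NULL) {
  stopifnot(inherits(lv, "label_volume"))
  out <- resample_grid(t, lv, grid)
  vals <- sample_volume(lv, out$pts, "nearest", outside = 0L)
  label_volume(array(as.integer(vals), out$dim), spacing = out$spacing,
               origin = out$origin, ontology = lv$ontology)
}

#' Map a cell table through a transform
#'
#' Applies the motion map (points move with image content). When the
#' transform records a fixed domain, cells landing outside its bounding box
#' are retained and flagged in the logical column `out_of_domain`.
#'
#' @param t a `brain_transform`.
#' @param cells tibble with `x_um`, `y_um`, `z_um` (other columns pass
#'   through).
#' @return tibble with transformed coordinates and an `out_of_domain` column.
#' @export
apply_to_points <- function(t, cells) {
  pts <- as.matrix(cells[, c("x_um", "y_um", "z_um")])
  mapped <- map_points_motion(t, pts)
  cells$x_um <- mapped[, 1]
  cells$y_um <- mapped[, 2]
  cells$z_um <- mapped[, 3]
  if (!is.null(t$fixed_domain)) {
    fd <- t$fixed_domain
    hi <- fd$origin + fd$dim * fd$spacing
    cells$out_of_domain <-
      mapped[, 1] < fd$origin[1] | mapped[, 1] >= hi[1] |
      mapped[, 2] < fd$origin[2] | mapped[, 2] >= hi[2] |
      mapped[, 3] < fd$origin[3] | mapped[, 3] >= hi[3]
  } else {
    cells$out_of_domain <- FALSE
  }
  cells
}

#' Serialise / restore a transform
#'
#' Affine stages are stored in a JSON file; each B-spline stage's control
#' lattice is written as a 4D NIfTI displacement volume next to it
#' (`<path>_stage<k>.nii.gz`).
#'
#' @param t a `brain_transform`.
#' @param path JSON path (`.json`).
#' @return `path` (write) or a `brain_transform` (read).
#' @export
write_transform <- function(t, path) {
  stages <- lapply(seq_along(t$stages), function(k) {
    s <- t$stages[[k]]
    if (s$type == "affine")
      return(list(type = "affine", A = as.vector(s$A), t = s$t))
    if (s$type == "bspline") {
      f <- sub("\\.json$", sprintf("_stage%d.nii.gz", k), path)
      img <- RNifti::asNifti(s$ctrl * 1)
      RNifti::writeNifti(img, f)
      return(list(type = "bspline", ctrl_file = basename(f),
                  spacing = s$spacing, origin = s$origin))
    }
    stop("cannot serialise stage type ", s$type)
  })
  jsonlite::write_json(list(stages = stages, fixed_domain = t$fixed_domain),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(obj$stages$type)
  stages <- lapply(seq_len(n), function(k) {
    type <- obj$stages$type[k]
    if (type == "affine") {
      return(list(type = "affine",
                  A = matrix(obj$stages$A[[k]], 3, 3),
                  t = obj$stages$t[[k]]))
    }
    f <- file.path(dirname(path), obj$stages$ctrl_file[k])
    ctrl <- as.array(RNifti::readNifti(f))
    list(type = "bspline", ctrl = ctrl,
         spacing = obj$stages$spacing[[k]],
         origin = obj$stages$origin[[k]])
  })
  fd <- obj$fixed_domain
  if (!is.null(fd)) fd <- lapply(fd, as.numeric)
  new_transform(stages, fixed_domain = fd)
}

#' Mean displacement magnitude of a transform over a grid
#'
#' Average Euclidean distance between grid points and their mapped positions,
#' a summary of how far a transform moves content (used for identity and
#' inverse-consistency checks).
#'
#' @param t a `brain_transform`.
#' @param v a [volume()] supplying the evaluation grid.
#' @return scalar, um.
#' @export
mean_displacement <- function(t, v) {
  pts <- grid_centers(v)
  mapped <- map_points_resample(t, pts)
  mean(sqrt(rowSums((mapped - pts)^2)))
}
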