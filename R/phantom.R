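#' Specification of a synthetic phantom brain
#'
#' The phantom emulates the geometry and statistical structure the pipeline
#' operates on: an ellipsoidal "brain" whose dorsal shell is a 6-layer
#' "cortex" (outermost shell = layer 1), an interior "subcortex" holding a
#' grid of box-shaped nuclei, smooth random deformations and a global scale
#' factor per pseudo-age, and per-region cell counts drawn from a negative
#' binomial distribution. Everything is mirror-symmetric about the mid-x
#' plane unless `asymmetry > 0`.
#'
#' Regional expected cell counts are NB with mean `density x volume(mm^3)`
#' and dispersion `dispersion` (the `size` parameter; `Inf` gives the
#' Poisson limit).
#'
#' @param grid_shape voxels per axis (x, y, z); each >= 8.
#' @param spacing_um voxel spacing, default `c(20, 20, 50)` um.
#' @param n_nuclei number of box nuclei in the subcortical core (a symmetric
#'   x-y-z grid; default 50).
#' @param densities named numeric vector, cells per mm^3 by region id.
#'   Defaults are scaled so that per-region *expected counts* land in the
#'   realistic hundreds-to-thousands range despite the phantom's miniature
#'   physical volume: layer counts ~100-750, nucleus counts ~50-250.
#' @param dispersion NB size parameter (scalar or named by region id);
#'   default 20, i.e. ~22% between-subject coefficient of variation for
#'   well-sampled regions.
#' @param deformation_um magnitude of the per-subject random smooth
#'   deformation (um at the control points; 0 = none).
#' @param age_deformation_um magnitude of each age-to-age incremental
#'   deformation (um; increments accumulate across ages, so age-adjacent
#'   geometries stay closer than age-distant ones). Default 60.
#' @param age_scale numeric vector of global scale factors, one per age,
#'   age 1 = the base/reference age (default generated as
#'   `1, 0.92, 0.84, ...`).
#' @param asymmetry nonnegative level of left-right intensity asymmetry
#'   (0 = perfectly mirror-symmetric).
#' @param seed integer master seed; all phantom randomness derives from it
#'   (per-subject streams use `seed + 1000 * age + subject`).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 28),
                         spacing_um = c(20, 20, 50),
                         n_nuclei = 50,
                         densities = NULL,
                         dispersion = 20,
                         deformation_um = 40,
                         age_deformation_um = 60,
                         age_scale = NULL,
                         asymmetry = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 8L))
    stop("phantom grid too small: every dimension must be >= 8 voxels",
         call. = FALSE)
  if (any(spacing_um <= 0)) stop("spacing must be positive", call. = FALSE)
  if (asymmetry < 0) stop("asymmetry must be >= 0", call. = FALSE)
  if (any(dispersion <= 0)) stop("dispersion must be > 0", call. = FALSE)
  if (is.null(densities)) {
    layer_ids <- 101:106
    nuc_ids <- seq_len(n_nuclei) + 200L
    densities <- c(
      stats::setNames(c(3000, 22500, 18000, 12000, 15000, 9000), layer_ids),
      stats::setNames(25000 + (seq_len(n_nuclei) - 1) %% 10 * 10000, nuc_ids)
    )
  }
  if (any(densities < 0)) stop("densities must be >= 0", call. = FALSE)
  ids <- as.integer(names(densities))
  if (anyDuplicated(ids) || any(ids == 0L))
    stop("region ids must be unique and nonzero", call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing_um = as.numeric(spacing_um),
                 n_nuclei = as.integer(n_nuclei), densities = densities,
                 dispersion = dispersion, deformation_um = deformation_um,
                 age_deformation_um = age_deformation_um,
                 age_scale = age_scale, asymmetry = asymmetry,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# run code under a derived, restored RNG stream
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Phantom ontology
#'
#' Root (id 999) with two children: cortex (100, layers 101-106 as children
#' named L1..L6) and subcortex (200, nuclei 201.. as children). Some interior
#' voxels are labeled directly at the subcortex parent (id 200), exercising
#' aggregation of voxels carried by non-leaf nodes.
#'
#' @param n_nuclei number of subcortical nuclei.
#' @return validated ontology tibble.
#' @export
phantom_ontology <- function(n_nuclei = 50) {
  nuc <- seq_len(n_nuclei) + 200L
  ont <- tibble::tibble(
    id = c(999L, 100L, 101:106, 200L, nuc),
    acronym = c("BR", "CTX", paste0("L", 1:6), "SUB", paste0("NU", seq_len(n_nuclei))),
    name = c("brain", "cortex", paste("cortical layer", 1:6), "subcortex",
             paste("nucleus", seq_len(n_nuclei))),
    parent_id = c(NA_integer_, 999L, rep(100L, 6), 999L, rep(200L, n_nuclei))
  )
  validate_ontology(ont)
}

# analytic phantom fields (intensity + label) at arbitrary physical points;
# evaluating the closed-form fields at warped coordinates gives subject
# volumes free of interpolation smoothing, so registration is tested
# against exact image content
phantom_fields <- function(spec, pts) {
  d <- spec$grid_shape
  sp <- spec$spacing_um
  ext <- d * sp
  ctr <- ext / 2
  semi <- ext * c(0.44, 0.44, 0.42)
  xn <- (pts[, 1] - ctr[1]) / semi[1]
  yn <- (pts[, 2] - ctr[2]) / semi[2]
  zn <- (pts[, 3] - ctr[3]) / semi[3]
  r <- sqrt(xn^2 + yn^2 + zn^2)
  inside <- r <= 1
  labels <- integer(nrow(pts))
  # dorsal cortical shell: 6 layers between r = 0.72 and 1, upper z half
  shell <- inside & r > 0.72 & zn > 0
  layer <- pmin(floor((1 - r[shell]) / (0.28 / 6)) + 1, 6)
  labels[shell] <- 100L + as.integer(layer)
  # interior: subcortex, with a symmetric grid of box nuclei
  interior <- inside & !shell
  labels[interior] <- 200L
  # nucleus grid inside the core box |xn|,|yn|,|zn| < 0.5
  nx <- 5L; ny <- 5L; nz <- ceiling(spec$n_nuclei / (nx * ny))
  gx <- pmin(pmax(floor((xn + 0.5) * nx), 0), nx - 1)
  gy <- pmin(pmax(floor((yn + 0.5) * ny), 0), ny - 1)
  gz <- pmin(pmax(floor((zn + 0.5) * nz), 0), nz - 1)
  core <- interior & abs(xn) < 0.5 & abs(yn) < 0.5 & abs(zn) < 0.5
  nid <- gx + nx * gy + nx * ny * gz + 1
  sel <- core & nid <= spec$n_nuclei
  labels[sel] <- 200L + as.integer(nid[sel])
  # intensity: radial + layer contrast, anisotropic texture, and distinct
  # per-nucleus brightness (mirror-symmetric: paired nuclei share offsets) —
  # the anatomical contrast registration needs to pin down correspondence
  tex <- cos(3 * pi * xn) * cos(2 * pi * yn) +
    sin(2 * pi * zn) * cos(pi * yn) +
    cos(2.5 * pi * xn) * sin(1.5 * pi * zn)
  inten <- ifelse(inside, 100 + 60 * cos(6 * r) + 30 * tex, 0)
  inten[shell] <- inten[shell] + 14 * layer
  sym_gx <- pmin(gx, nx - 1 - gx)
  nuc_off <- 14 * ((sym_gx + 2 * gy + 3 * gz) %% 8)
  inten[sel] <- inten[sel] + nuc_off[sel]
  if (spec$asymmetry > 0) {
    bump <- exp(-(((xn - 0.45) / 0.25)^2 + (yn / 0.35)^2 + (zn / 0.35)^2))
    inten <- inten + spec$asymmetry * 100 * bump * inside
  }
  list(inten = inten, labels = labels)
}

# base geometry: returns list(volume, labels, ontology)
phantom_base <- function(spec) {
  d <- spec$grid_shape
  v <- volume(array(0, d), spec$spacing_um)
  fl <- phantom_fields(spec, grid_centers(v))
  ont <- phantom_ontology(spec$n_nuclei)
  list(volume = volume(array(fl$inten, d), spec$spacing_um),
       labels = label_volume(array(fl$labels, d), spec$spacing_um,
                             ontology = ont),
       ontology = ont)
}

# smooth random deformation as a B-spline transform over the grid domain
random_deformation <- function(spec, magnitude_um, seed, n_ctrl = 5L) {
  d <- spec$grid_shape * spec$spacing_um
  ctrl_spacing <- d / (n_ctrl - 3)
  ctrl_origin <- -ctrl_spacing
  ctrl <- local_seed(seed, array(stats::runif(3 * n_ctrl^3, -magnitude_um,
                                              magnitude_um),
                                 c(n_ctrl, n_ctrl, n_ctrl, 3)))
  transform_bspline(ctrl, ctrl_spacing, ctrl_origin)
}

#' Generate a phantom age series with ground truth
#'
#' Builds the base brain once, then for each pseudo-age and subject applies
#' the age's global scale plus a smooth random subject deformation. Age 1 is
#' the base (reference/adult analogue); later ages shrink by `age_scale` and
#' drift geometrically away from the base, so age-adjacent shapes are more
#' similar than age-distant ones (the rationale for sequential label
#' propagation).
#'
#' @param spec a [phantom_spec()].
#' @param n_ages number of pseudo-ages (>= 1).
#' @param n_subjects_per_age subjects per age (>= 1).
#' @return list with `base` (volume, labels, ontology) and `subjects`, a
#'   tibble with columns age, subject, volume, labels, truth (the
#'   ground-truth `brain_transform` mapping the subject grid into base
#'   space, i.e. exactly what registering base -> subject recovers).
#' @export
make_phantom_series <- function(spec, n_ages = 1, n_subjects_per_age = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n_ages < 1 || n_subjects_per_age < 1)
    stop("need n_ages >= 1 and n_subjects_per_age >= 1", call. = FALSE)
  base <- phantom_base(spec)
  scales <- spec$age_scale
  if (is.null(scales)) scales <- 1 - 0.08 * (seq_len(n_ages) - 1)
  if (length(scales) < n_ages)
    stop("age_scale must supply one factor per age", call. = FALSE)
  ctr <- spec$grid_shape * spec$spacing_um / 2
  rows <- list()
  # cumulative age drift: each age adds a fresh smooth increment on top of
  # the previous age's deformation, so age-adjacent shapes stay closer than
  # age-distant ones (development is cumulative, not resampled)
  age_stages <- list()
  age_def <- spec$age_deformation_um
  if (is.null(age_def)) age_def <- 60
  if (age_def > 0 && n_ages > 1) {
    for (a in 2:n_ages) {
      inc <- random_deformation(spec, age_def, spec$seed + 7L * a)
      prev <- if (a > 2) age_stages[[a - 1L]] else list()
      age_stages[[a]] <- c(prev, inc$stages)
    }
  }
  for (a in seq_len(n_ages)) {
    for (s in seq_len(n_subjects_per_age)) {
      seed_s <- spec$seed + 1000L * a + s
      stages <- list()
      if (a > 1 && length(age_stages) >= a && length(age_stages[[a]]))
        stages <- c(stages, age_stages[[a]])
      if (spec$deformation_um > 0) {
        t_sub <- random_deformation(spec, spec$deformation_um, seed_s)
        stages <- c(stages, t_sub$stages)
      }
      if (scales[a] != 1) {
        sc <- 1 / scales[a]
        A <- diag(3) * sc
        stages <- c(stages,
                    list(list(type = "affine", A = A,
                              t = as.numeric(ctr - A %*% ctr))))
      }
      truth <- new_transform(stages,
                             fixed_domain = list(dim = spec$grid_shape,
                                                 spacing = spec$spacing_um,
                                                 origin = c(0, 0, 0)))
      if (length(stages)) {
        # evaluate the analytic fields at warped coordinates: exact subject
        # volumes and labels, no interpolation smoothing
        mapped <- map_points_resample(truth, grid_centers(base$volume))
        fl <- phantom_fields(spec, mapped)
        d <- spec$grid_shape
        vol <- volume(array(fl$inten, d), spec$spacing_um)
        labs <- label_volume(array(fl$labels, d), spec$spacing_um,
                             ontology = base$ontology)
      } else {
        vol <- base$volume
        labs <- base$labels
      }
      rows[[length(rows) + 1]] <-
        tibble::tibble(age = a, subject = s, volume = list(vol),
                       labels = list(labs), truth = list(truth))
    }
  }
  list(base = base, subjects = dplyr::bind_rows(rows))
}

#' Simulate cells in a labeled phantom volume
#'
#' For every region id with nonzero expected density, a total 3D cell count
#' is drawn from NB(mean = density x region volume in mm^3, size =
#' dispersion); cells are placed uniformly within the region's voxels. Each
#' cell carries the 0-based z index of its section (`section_index`). Use
#' [thin_cells_2d()] to emulate the sparse 2D counting convention.
#'
#' @param labels a [label_volume()].
#' @param spec a [phantom_spec()] supplying densities and dispersion.
#' @param seed integer seed for this draw.
#' @param density_scale optional named multiplier per region id (e.g. a
#'   planted group effect); regions not named are unscaled.
#' @return cell tibble (`x_um`, `y_um`, `z_um`, `section_index`, `channel`,
#'   `true_region`).
#' @export
simulate_cells <- function(labels, spec, seed = spec$seed,
                           density_scale = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  dens <- spec$densities[spec$densities > 0]
  ids <- as.integer(names(dens))
  lab_vec <- as.vector(labels$data)
  present <- ids %in% lab_vec
  if (!all(present))
    stop("density specified for region id(s) absent from the label volume: ",
         paste(ids[!present], collapse = ", "), call. = FALSE)
  if (!length(ids))
    return(tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                          z_um = numeric(0), section_index = integer(0),
                          channel = integer(0), true_region = integer(0)))
  vox_mm3 <- voxel_volume_um3(labels) * 1e-9
  d <- dim(labels$data)
  local_seed(seed, {
    out <- lapply(ids, function(id) {
      vox <- which(lab_vec == id)
      mu <- dens[[as.character(id)]] * length(vox) * vox_mm3
      if (!is.null(density_scale) && as.character(id) %in% names(density_scale))
        mu <- mu * density_scale[[as.character(id)]]
      disp <- if (length(spec$dispersion) > 1)
        spec$dispersion[[as.character(id)]] else spec$dispersion
      n <- if (is.infinite(disp)) stats::rpois(1, mu)
           else stats::rnbinom(1, size = disp, mu = mu)
      if (n == 0)
        return(tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                              z_um = numeric(0), section_index = integer(0),
                              channel = integer(0), true_region = integer(0)))
      pick <- vox[sample.int(length(vox), n, replace = TRUE)]
      k0 <- pick - 1L
      ix <- k0 %% d[1]
      iy <- (k0 %/% d[1]) %% d[2]
      iz <- k0 %/% (d[1] * d[2])
      tibble::tibble(
        x_um = (ix + stats::runif(n)) * labels$spacing[1] + labels$origin[1],
        y_um = (iy + stats::runif(n)) * labels$spacing[2] + labels$origin[2],
        z_um = (iz + stats::runif(n)) * labels$spacing[3] + labels$origin[3],
        section_index = as.integer(iz),
        channel = 1L,
        true_region = as.integer(id))
    })
    dplyr::bind_rows(out)
  })
}

#' Thin a 3D cell set to emulate sparse 2D counting
#'
#' Downstream quantification converts 2D-detected counts to 3D estimates by
#' multiplying with the conversion factor `k3d` (1.4 by default). The phantom
#' emulates the 2D counting convention by keeping each true 3D cell with
#' probability `1 / k3d`, so the correction exactly inverts the thinning in
#' expectation.
#'
#' @param cells cell tibble from [simulate_cells()].
#' @param k3d conversion factor (> 1), default 1.4.
#' @param seed integer seed.
#' @return thinned cell tibble.
#' @export
thin_cells_2d <- function(cells, k3d = 1.4, seed = 1L) {
  stopifnot(k3d >= 1)
  local_seed(seed, {
    keep <- stats::runif(nrow(cells)) < 1 / k3d
    cells[keep, , drop = FALSE]
  })
}
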