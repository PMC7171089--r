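#' Registration configuration
#'
#' Mirrors the registration contract used throughout: a multi-resolution 3D
#' affine stage (default 4 pyramid levels) followed by a multi-resolution 3D
#' cubic-B-spline stage (default 6 levels). The similarity metric is
#' minimized over the fixed-image grid. The default `"ncc"` is a normalized
#' -correlation metric: each evaluation profiles out the optimal global
#' intensity gain/offset before squaring residuals, making it robust to
#' acquisition gain differences and to shifts of the foreground/background
#' mix; `"mse"` compares raw intensities for strictly same-modality
#' problems. Levels use Gaussian-smoothed full-resolution images with
#' decimated sample grids (so fixed and moving are always smoothed at the
#' same physical scale, the moving one matched through the affine).
#'
#' @param affine_levels pyramid levels for the affine stage (>= 1).
#' @param bspline_levels pyramid levels for the B-spline stage (0 disables
#'   the deformable stage).
#' @param metric "ncc" or "mse".
#' @param iterations optimizer iteration cap per level,
#'   `c(affine, bspline)`.
#' @param sampling_fraction fraction of fixed voxels used for the metric in
#'   (0, 1]; values < 1 subsample deterministically from `seed`.
#' @param bspline_spacing_um coarsest control-point spacing (um, length 3);
#'   default a third of the fixed extent, halved per level and floored at 2
#'   voxels.
#' @param regularization L2 weight on control-point displacements (um^-2
#'   scale; small values stabilize low-contrast areas).
#' @param seed integer seed (only consumed when `sampling_fraction < 1`).
#' @return object of class `registration_config`.
#' @export
registration_config <- function(affine_levels = 4, bspline_levels = 6,
                                metric = c("ncc", "mse"),
                                iterations = c(80, 60),
                                sampling_fraction = 1,
                                bspline_spacing_um = NULL,
                                regularization = 1e-6,
                                seed = 1L) {
  metric <- match.arg(metric)
  if (affine_levels < 1 || bspline_levels < 0)
    stop("need affine_levels >= 1 and bspline_levels >= 0", call. = FALSE)
  if (sampling_fraction <= 0 || sampling_fraction > 1)
    stop("sampling_fraction must be in (0, 1]", call. = FALSE)
  structure(list(affine_levels = as.integer(affine_levels),
                 bspline_levels = as.integer(bspline_levels),
                 metric = metric, iterations = iterations,
                 sampling_fraction = sampling_fraction,
                 bspline_spacing_um = bspline_spacing_um,
                 regularization = regularization, seed = as.integer(seed)),
            class = "registration_config")
}

zscore_volume <- function(v) {
  mu <- mean(v$data); sd <- stats::sd(as.vector(v$data))
  if (sd == 0) stop("cannot register a constant-intensity volume",
                    call. = FALSE)
  volume((v$data - mu) / sd, v$spacing, v$origin)
}

# per-level decimation factors, coarsest first; factors keep >= 8 samples
# per axis
pyramid_factors <- function(d, levels) {
  lapply(seq_len(levels), function(l) {
    f <- 2^(levels - l)
    pmax(pmin(rep(f, 3), d %/% 8L), 1L)
  })
}

# separable Gaussian smoothing (sigma in voxels per axis) with edge
# renormalization; both images of a level are smoothed at the same physical
# scale in their own grids, the standard multi-resolution construction
smooth_volume_gauss <- function(v, sigma_vox) {
  arr <- v$data
  d <- dim(arr)
  wsum <- array(1, d)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 0.3) next
    rad <- ceiling(3 * s)
    w <- stats::dnorm(-rad:rad, sd = s)
    acc <- array(0, d)
    accw <- array(0, d)
    for (j in seq_along(w)) {
      off <- j - rad - 1L
      src <- seq_len(d[ax]) + off
      okk <- src >= 1 & src <= d[ax]
      dst <- which(okk); src <- src[okk]
      if (ax == 1) {
        acc[dst, , ] <- acc[dst, , ] + w[j] * arr[src, , ]
        accw[dst, , ] <- accw[dst, , ] + w[j] * wsum[src, , ]
      } else if (ax == 2) {
        acc[, dst, ] <- acc[, dst, ] + w[j] * arr[, src, ]
        accw[, dst, ] <- accw[, dst, ] + w[j] * wsum[, src, ]
      } else {
        acc[, , dst] <- acc[, , dst] + w[j] * arr[, , src]
        accw[, , dst] <- accw[, , dst] + w[j] * wsum[, , src]
      }
    }
    arr <- acc
    wsum <- accw
  }
  volume(arr / wsum, v$spacing, v$origin)
}

# decimated sample points + smoothed fixed values for one level
metric_samples <- function(fixed_smooth, f3, cfg) {
  d <- dim(fixed_smooth$data)
  ix <- lapply(1:3, function(ax)
    seq.int(1L + (f3[ax] - 1L) %/% 2L, d[ax], by = f3[ax]))
  idx <- as.matrix(expand.grid(ix[[1]], ix[[2]], ix[[3]]))
  fv <- fixed_smooth$data[idx]
  pts <- voxel_centers(fixed_smooth, idx)
  if (cfg$sampling_fraction < 1) {
    keep <- local_seed(cfg$seed, sample.int(
      nrow(pts), max(100L, round(cfg$sampling_fraction * nrow(pts)))))
    pts <- pts[keep, , drop = FALSE]; fv <- fv[keep]
  }
  list(pts = pts, f = fv)
}

# one-pass trilinear value + analytic interpolant gradient at physical pts;
# residuals masked (zeroed) outside the physical extent. The valid band
# extends half a voxel beyond the outermost centres (edge-clamped there) so
# that grids of identical extent never sit exactly on the mask boundary,
# which would make the metric discontinuous at the identity.
sample_res_grad <- function(mov, mpts) {
  d <- dim(mov$data)
  cc <- sweep(sweep(mpts, 2, mov$origin, "-"), 2, mov$spacing, "/") + 0.5
  n <- nrow(mpts)
  r <- numeric(n)
  g <- matrix(0, n, 3)
  ok <- cc[, 1] >= 0.5 & cc[, 1] <= d[1] + 0.5 &
    cc[, 2] >= 0.5 & cc[, 2] <= d[2] + 0.5 &
    cc[, 3] >= 0.5 & cc[, 3] <= d[3] + 0.5
  nok <- sum(ok)
  if (nok == 0) return(list(val = r, g = g, ok = ok, n = 1L))
  cc_raw <- cc[ok, , drop = FALSE]
  cc <- pmin(pmax(cc_raw, 1), rep(d, each = nok))
  clamped <- cc_raw != cc          # flat directions: interpolant gradient 0
  i0 <- pmin(floor(cc), rep(d - 1, each = nok))
  fx <- cc[, 1] - i0[, 1]; fy <- cc[, 2] - i0[, 2]; fz <- cc[, 3] - i0[, 3]
  dat <- mov$data
  n12 <- d[1] * d[2]
  base <- (i0[, 1] - 1) + d[1] * (i0[, 2] - 1) + n12 * (i0[, 3] - 1) + 1
  v000 <- dat[base];              v100 <- dat[base + 1]
  v010 <- dat[base + d[1]];       v110 <- dat[base + d[1] + 1]
  v001 <- dat[base + n12];        v101 <- dat[base + n12 + 1]
  v011 <- dat[base + d[1] + n12]; v111 <- dat[base + d[1] + n12 + 1]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  val <- c0 * (1 - fz) + c1 * fz
  r[ok] <- val
  # exact gradient of the trilinear interpolant (per um)
  dx0 <- (v100 - v000) * (1 - fy) + (v110 - v010) * fy
  dx1 <- (v101 - v001) * (1 - fy) + (v111 - v011) * fy
  gx <- (dx0 * (1 - fz) + dx1 * fz) / mov$spacing[1]
  gy <- ((c10 - c00) * (1 - fz) + (c11 - c01) * fz) / mov$spacing[2]
  gz <- (c1 - c0) / mov$spacing[3]
  gx[clamped[, 1]] <- 0; gy[clamped[, 2]] <- 0; gz[clamped[, 3]] <- 0
  g[ok, 1] <- gx; g[ok, 2] <- gy; g[ok, 3] <- gz
  list(val = r, g = g, ok = ok, n = nok)
}

# residuals after the metric's intensity model: "ncc" fits the optimal
# gain/offset over the valid samples each evaluation (the least-squares
# profile of a normalized-correlation metric; by the envelope theorem the
# spatial gradient stays a * grad M), "mse" compares raw intensities
metric_residual <- function(sr, fvals, metric) {
  r <- numeric(length(fvals))
  if (sr$n <= 2) return(list(r = r, a = 1))
  mo <- sr$val[sr$ok]; fo <- fvals[sr$ok]
  if (metric == "ncc") {
    vm <- stats::var(mo)
    a <- if (vm > 0) stats::cov(mo, fo) / vm else 1
    b <- mean(fo) - a * mean(mo)
  } else { a <- 1; b <- 0 }
  r[sr$ok] <- a * mo + b - fo
  list(r = r, a = a)
}

affine_stage_fit <- function(f, m, cfg, center) {
  theta <- c(as.vector(diag(3)), 0, 0, 0)
  trace <- list()
  factors <- pyramid_factors(dim(f$data), cfg$affine_levels)
  for (l in seq_along(factors)) {
    f3 <- factors[[l]]
    sig <- 0.5 * f3
    fs <- smooth_volume_gauss(f, sig)
    mov <- smooth_volume_gauss(m, sig)
    sm <- metric_samples(fs, f3, cfg)
    xc <- sweep(sm$pts, 2, center, "-")
    fn <- function(p) {
      A <- matrix(p[1:9], 3, 3)
      mpts <- sweep(xc %*% t(A), 2, center + p[10:12], "+")
      sr <- sample_res_grad(mov, mpts)
      mr <- metric_residual(sr, sm$f, cfg$metric)
      sum(mr$r^2) / sr$n
    }
    gr <- function(p) {
      A <- matrix(p[1:9], 3, 3)
      mpts <- sweep(xc %*% t(A), 2, center + p[10:12], "+")
      sr <- sample_res_grad(mov, mpts)
      mr <- metric_residual(sr, sm$f, cfg$metric)
      P <- sr$g * (mr$a * mr$r)             # n x 3, rows a * r * grad
      dA <- 2 / sr$n * crossprod(P, xc)     # 3 x 3
      dt <- 2 / sr$n * colSums(P)
      c(as.vector(dA), dt)
    }
    start <- fn(theta)
    opt <- stats::optim(theta, fn, gr, method = "BFGS",
                        control = list(maxit = cfg$iterations[1],
                                       reltol = 1e-9,
                                       parscale = c(rep(0.01, 9), rep(10, 3))))
    theta <- opt$par
    trace[[l]] <- c(level = l, start = start, value = opt$value,
                    conv = opt$convergence)
  }
  A <- matrix(theta[1:9], 3, 3)
  list(stage = list(type = "affine", A = A,
                    t = as.numeric(center + theta[10:12] - A %*% center)),
       trace = trace)
}

# evaluation structure for one B-spline level: n x 64 weight and clamped
# control-index matrices over the fixed sample points
bspline_eval_struct <- function(pts, spacing, origin, dcp) {
  tt <- sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/")
  i0 <- floor(tt)
  fr <- tt - i0
  W3 <- list(bspline_weights(fr[, 1]), bspline_weights(fr[, 2]),
             bspline_weights(fr[, 3]))
  base <- i0 + 1
  n <- nrow(pts)
  Wm <- matrix(0, n, 64)
  Lm <- matrix(0L, n, 64)
  k <- 1
  n12 <- dcp[1] * dcp[2]
  for (a in 1:4) {
    ia <- pmin(pmax(base[, 1] + a - 2, 1), dcp[1])
    for (b in 1:4) {
      ib <- pmin(pmax(base[, 2] + b - 2, 1), dcp[2])
      wab <- W3[[1]][, a] * W3[[2]][, b]
      for (cc in 1:4) {
        ic <- pmin(pmax(base[, 3] + cc - 2, 1), dcp[3])
        Wm[, k] <- wab * W3[[3]][, cc]
        Lm[, k] <- as.integer(ia + dcp[1] * (ib - 1) + n12 * (ic - 1))
        k <- k + 1
      }
    }
  }
  list(W = Wm, L = Lm, Lvec = as.vector(Lm), n = n)
}

bs_field <- function(es, cm) {
  u <- matrix(0, es$n, 3)
  for (k in 1:64) {
    idx <- es$L[, k]; w <- es$W[, k]
    u[, 1] <- u[, 1] + w * cm[idx, 1]
    u[, 2] <- u[, 2] + w * cm[idx, 2]
    u[, 3] <- u[, 3] + w * cm[idx, 3]
  }
  u
}

bs_backproject <- function(es, P, ncp) {
  # adjoint of bs_field: scatter-add weighted residual gradients into bins
  out <- matrix(0, ncp, 3)
  for (ax in 1:3) {
    vals <- as.vector(P[, ax] * es$W)
    acc <- rowsum(vals, es$Lvec, reorder = FALSE)
    out[as.integer(rownames(acc)), ax] <- acc[, 1]
  }
  out
}

bspline_stage_fit <- function(f, m, cfg, fixed_full, aff_stage) {
  A <- aff_stage$A
  tA <- aff_stage$t
  ext <- dim(fixed_full$data) * fixed_full$spacing
  start_sp <- if (!is.null(cfg$bspline_spacing_um)) cfg$bspline_spacing_um
              else ext / 3
  min_sp_final <- 2 * fixed_full$spacing
  ctrl <- NULL; ctrl_meta <- NULL
  trace <- list()
  prev_key <- ""
  factors <- pyramid_factors(dim(f$data), cfg$bspline_levels)
  for (l in seq_along(factors)) {
    f3 <- factors[[l]]
    # control resolution tied to the level's sampling: never finer than 2
    # sample steps at that level, floored at 2 full-resolution voxels
    sp <- pmax(start_sp / 2^(l - 1), 2 * f3 * fixed_full$spacing,
               min_sp_final)
    origin <- -sp
    dcp <- pmax(ceiling(ext / sp), 1) + 3L
    key <- paste(c(round(sp, 3), f3), collapse = ",")
    if (key == prev_key) next
    prev_key <- key
    # carry the previous level's field onto the new lattice
    new_ctrl <- matrix(0, prod(dcp), 3)
    if (!is.null(ctrl)) {
      cp_idx <- as.matrix(expand.grid(seq_len(dcp[1]), seq_len(dcp[2]),
                                      seq_len(dcp[3])))
      cp_pos <- sweep(sweep(cp_idx - 1, 2, sp, "*"), 2, origin, "+")
      stage_prev <- list(type = "bspline",
                         ctrl = array(ctrl, c(ctrl_meta$dcp, 3)),
                         spacing = ctrl_meta$sp, origin = ctrl_meta$origin)
      new_ctrl <- bspline_displacement(stage_prev, cp_pos)
    }
    ctrl <- new_ctrl; ctrl_meta <- list(dcp = dcp, sp = sp, origin = origin)
    sig <- 0.5 * f3
    fs <- smooth_volume_gauss(f, sig)
    # match the moving image's effective smoothing scale through the affine
    # (a fixed-space kernel corresponds to an A-scaled kernel in moving
    # space); unmatched scales induce scale-space drift that the field
    # would absorb as a spurious deformation
    ax_scale <- sqrt(colSums(A^2))
    mov <- smooth_volume_gauss(m, sig * ax_scale)
    sm <- metric_samples(fs, f3, cfg)
    es <- bspline_eval_struct(sm$pts, sp, origin, dcp)
    lam <- cfg$regularization
    # the deformable stage optimizes the composed map M(A(x + u(x)) + t):
    # no intermediate resampled volume, so masking and background handling
    # stay consistent with the final transform
    fn <- function(p) {
      cm <- matrix(p, ncol = 3)
      mpts <- sweep((sm$pts + bs_field(es, cm)) %*% t(A), 2, tA, "+")
      sr <- sample_res_grad(mov, mpts)
      mr <- metric_residual(sr, sm$f, cfg$metric)
      sum(mr$r^2) / sr$n + lam * mean(cm^2)
    }
    gr <- function(p) {
      cm <- matrix(p, ncol = 3)
      mpts <- sweep((sm$pts + bs_field(es, cm)) %*% t(A), 2, tA, "+")
      sr <- sample_res_grad(mov, mpts)
      mr <- metric_residual(sr, sm$f, cfg$metric)
      P <- (sr$g %*% A) * (mr$a * mr$r)   # chain rule through the affine
      g <- 2 / sr$n * bs_backproject(es, P, prod(dcp)) +
        2 * lam / length(cm) * cm
      as.vector(g)
    }
    start <- fn(as.vector(ctrl))
    opt <- stats::optim(as.vector(ctrl), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = cfg$iterations[2],
                                       factr = 1e9))
    ctrl <- matrix(opt$par, ncol = 3)
    trace[[length(trace) + 1]] <- c(level = l, start = start,
                                    value = opt$value,
                                    conv = opt$convergence)
  }
  list(stage = list(type = "bspline",
                    ctrl = array(ctrl, c(ctrl_meta$dcp, 3)),
                    spacing = ctrl_meta$sp, origin = ctrl_meta$origin),
       trace = trace)
}

#' Register a moving volume to a fixed volume
#'
#' Intensity-based registration: a 3D affine stage over a 4-level (default)
#' image pyramid, followed by a 3D cubic-B-spline free-form stage over a
#' 6-level (default) pyramid with a coarse-to-fine control lattice. Both
#' stages minimize the configured similarity metric with analytic gradients
#' (BFGS for the affine parameters, L-BFGS-B for the control-point
#' displacements). Deterministic given inputs, config and seed.
#'
#' The result maps content of `moving` onto the grid of `fixed`:
#' `apply_to_volume(t, moving)` resamples onto the fixed grid, and
#' `apply_to_points(t, cells)` carries points detected in the moving volume
#' into fixed space.
#'
#' @param fixed,moving [volume()] objects sharing physical-space semantics.
#' @param config a [registration_config()].
#' @return a `brain_transform` with the per-level metric trace in attribute
#'   `"trace"`; a final metric above its starting value triggers a
#'   non-convergence warning carrying the trace.
#' @export
register <- function(fixed, moving, config = registration_config()) {
  stopifnot(inherits(fixed, "volume"), inherits(moving, "volume"))
  f <- fixed; m <- moving
  if (config$metric == "ncc") { f <- zscore_volume(f); m <- zscore_volume(m) }
  center <- dim(f$data) * f$spacing / 2 + f$origin
  aff <- affine_stage_fit(f, m, config, center)
  stages <- list(aff$stage)
  traces <- list(affine = aff$trace)
  if (config$bspline_levels > 0) {
    # deformable stage matches the affinely warped moving image, then the
    # affine is appended so the composite applies bspline first
    bsp <- bspline_stage_fit(f, m, config, f, aff$stage)
    stages <- list(bsp$stage, aff$stage)
    traces$bspline <- bsp$trace
  }
  out <- new_transform(stages,
                       fixed_domain = list(dim = dim(fixed$data),
                                           spacing = fixed$spacing,
                                           origin = fixed$origin))
  attr(out, "trace") <- traces
  # per-level metric values are not comparable across resolutions; flag
  # non-convergence when any level ends above where it started
  last <- traces[[length(traces)]]
  worse <- vapply(last, function(tr) tr[["value"]] > tr[["start"]] + 1e-12,
                  logical(1))
  if (any(worse)) {
    msg <- vapply(last, function(tr)
      sprintf("L%d: %.4g -> %.4g", tr[["level"]], tr[["start"]],
              tr[["value"]]), "")
    warning("registration did not reduce the metric at every level; trace: ",
            paste(msg, collapse = "; "), call. = FALSE)
  }
  out
}

#' Dice overlap of a label between two label volumes
#'
#' @param a,b [label_volume()] objects on the same grid.
#' @param id region id (default: all nonzero voxels as one mask).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b, id = NULL) {
  ma <- if (is.null(id)) a$data != 0 else a$data == id
  mb <- if (is.null(id)) b$data != 0 else b$data == id
  s <- sum(ma) + sum(mb)
  if (s == 0) return(NA_real_)
  2 * sum(ma & mb) / s
}

#' Mean landmark error between two transforms
#'
#' Maps the same physical points through both transforms (resampling
#' direction) and returns the mean Euclidean discrepancy — the standard way
#' to score a recovered registration against a known ground-truth
#' deformation.
#'
#' @param t_est,t_true `brain_transform` objects.
#' @param pts n x 3 matrix of physical points (um) in the fixed space.
#' @return mean error in um.
#' @export
landmark_error <- function(t_est, t_true, pts) {
  a <- map_points_resample(t_est, as.matrix(pts))
  b <- map_points_resample(t_true, as.matrix(pts))
  mean(sqrt(rowSums((a - b)^2)))
}
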