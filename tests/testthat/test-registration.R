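test_that("identity transform leaves labels bitwise unchanged", {
  b <- base_phantom()
  out <- apply_to_labels(transform_identity(), b$labels)
  expect_identical(out$data, b$labels$data)
})

test_that("a pure translation moves points by the stated offset", {
  tr <- transform_translation(c(40, 0, 0))
  cells <- tibble::tibble(x_um = 100, y_um = 30, z_um = 75)
  out <- apply_to_points(tr, cells)
  expect_equal(out$x_um, 140)
  expect_equal(out$y_um, 30)
})

test_that("warping an impulse image and its point lands in the same voxel", {
  v <- volume(array(0, c(16, 16, 8)), c(20, 20, 50))
  v$data[8, 9, 4] <- 1
  pt <- voxel_centers(v, cbind(8, 9, 4))
  tr <- transform_translation(c(45, -20, 50))
  w <- apply_to_volume(tr, v, "nearest")
  hit <- which(w$data == 1, arr.ind = TRUE)
  cells <- apply_to_points(tr, tibble::tibble(
    x_um = pt[1], y_um = pt[2], z_um = pt[3]))
  idx <- points_to_voxels(v, as.matrix(cells[, 1:3]))
  expect_equal(as.integer(hit[1, ]), as.integer(idx[1, ]))
})

test_that("warped label sets are subsets of the input label set", {
  b <- base_phantom()
  spec <- phantom_spec(seed = 9)
  tr <- devbrainmap:::random_deformation(spec, 60, seed = 21)
  out <- apply_to_labels(tr, b$labels)
  expect_true(all(unique(as.vector(out$data)) %in%
                    c(0L, unique(as.vector(b$labels$data)))))
})

test_that("composition is associative and matches sequential application", {
  t1 <- transform_translation(c(10, 0, 0))
  t2 <- transform_affine(diag(3) * 1.1, c(0, 5, 0))
  t3 <- transform_translation(c(0, 0, -20))
  pts <- matrix(rnorm(30, 200, 50), 10, 3)
  colnames(pts) <- c("x_um", "y_um", "z_um")
  cells <- tibble::as_tibble(pts)
  a <- apply_to_points(compose_transforms(compose_transforms(t1, t2), t3), cells)
  b <- apply_to_points(compose_transforms(t1, compose_transforms(t2, t3)), cells)
  c3 <- apply_to_points(t3, apply_to_points(t2, apply_to_points(t1, cells)))
  expect_equal(a$x_um, b$x_um, tolerance = 1e-9)
  expect_equal(a$x_um, c3$x_um, tolerance = 1e-9)
  expect_equal(a$z_um, c3$z_um, tolerance = 1e-9)
})

test_that("B-spline inversion reaches fixed-point tolerance", {
  spec <- phantom_spec(seed = 4)
  tr <- devbrainmap:::random_deformation(spec, 50, seed = 13)
  pts <- matrix(runif(60, 200, 700), 20, 3)
  fwd <- devbrainmap:::map_points_resample(tr, pts)
  back <- devbrainmap:::map_points_resample(invert_transform(tr, tol_um = 0.5),
                                            fwd)
  expect_lt(max(abs(back - pts)), 2)
})

test_that("transforms serialize and restore through JSON + NIfTI", {
  spec <- phantom_spec(seed = 6)
  tr <- compose_transforms(
    devbrainmap:::random_deformation(spec, 30, seed = 2),
    transform_affine(diag(3) * 0.95, c(12, -4, 8)))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "t.json")
  write_transform(tr, path)
  tr2 <- read_transform(path)
  pts <- matrix(runif(30, 100, 800), 10, 3)
  expect_equal(devbrainmap:::map_points_resample(tr, pts),
               devbrainmap:::map_points_resample(tr2, pts),
               tolerance = 1e-6)
})

test_that("registering a volume to itself recovers near-identity", {
  b <- base_phantom()
  t_id <- register(b$volume, b$volume, light_reg())
  expect_lt(mean_displacement(t_id, b$volume) / min(b$volume$spacing), 1)
  labs <- apply_to_labels(t_id, b$labels)
  expect_gt(dice(labs, b$labels), 0.99)
})

test_that("registration is deterministic given inputs, config and seed", {
  spec <- phantom_spec(grid_shape = c(24, 24, 12), deformation_um = 20,
                       seed = 3)
  ser <- make_phantom_series(spec, 1, 1)
  cfg <- light_reg()
  t1 <- register(ser$subjects$volume[[1]], ser$base$volume, cfg)
  t2 <- register(ser$subjects$volume[[1]], ser$base$volume, cfg)
  expect_identical(t1$stages, t2$stages)
})

test_that("constant volumes are rejected by the similarity metric", {
  v <- volume(array(1, c(16, 16, 8)))
  expect_error(register(v, v, light_reg()), "constant")
})
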