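test_that("symmetric phantom equals its mirror voxelwise; asymmetry breaks it", {
  b <- base_phantom()
  expect_identical(mirror_x(b$volume)$data, b$volume$data)
  ba <- devbrainmap:::phantom_base(phantom_spec(asymmetry = 0.5))
  expect_false(identical(mirror_x(ba$volume)$data, ba$volume$data))
})

test_that("zero deformation and unit scale reproduce the base exactly", {
  ser <- make_phantom_series(tiny_spec(), n_ages = 1, n_subjects_per_age = 2)
  for (i in 1:2) {
    expect_identical(ser$subjects$volume[[i]]$data, ser$base$volume$data)
    expect_identical(ser$subjects$labels[[i]]$data, ser$base$labels$data)
  }
})

test_that("phantom generation is deterministic given the seed", {
  spec <- phantom_spec(grid_shape = c(24, 24, 12), seed = 7)
  a <- make_phantom_series(spec, n_ages = 2, n_subjects_per_age = 2)
  b <- make_phantom_series(spec, n_ages = 2, n_subjects_per_age = 2)
  expect_identical(a$subjects$volume[[3]]$data, b$subjects$volume[[3]]$data)
  c1 <- simulate_cells(a$base$labels, spec, seed = 11)
  c2 <- simulate_cells(b$base$labels, spec, seed = 11)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("degenerate grids are rejected with a sizing error", {
  expect_error(phantom_spec(grid_shape = c(4, 24, 24)), "8 voxels")
})

test_that("zero density everywhere yields an empty cell table", {
  spec <- tiny_spec()
  spec$densities[] <- 0
  cells <- simulate_cells(base_phantom()$labels, spec, seed = 1)
  expect_equal(nrow(cells), 0)
})

test_that("density for a region absent from the volume is an error", {
  spec <- tiny_spec()
  spec$densities <- c(spec$densities, "777" = 100)
  expect_error(simulate_cells(base_phantom()$labels, spec, seed = 1),
               "absent")
})

test_that("every simulated cell falls inside a voxel of its region", {
  b <- base_phantom()
  cells <- simulate_cells(b$labels, phantom_spec(), seed = 5)
  asg <- assign_cells(cells, b$labels)
  expect_true(all(!asg$out_of_grid))
  expect_identical(asg$region_id, asg$true_region)
})

test_that("simulated counts match the NB mean in the Poisson limit", {
  # a single region close to 1 mm^3 at density 1400, dispersion -> Inf:
  # the replicate mean must sit within Monte-Carlo error of density x volume
  d <- c(10, 10, 10)
  arr <- array(0L, d); arr[2:9, 2:9, 2:9] <- 1L
  ont <- tibble::tibble(id = 1L, acronym = "R", name = "region",
                        parent_id = NA_integer_)
  lv <- label_volume(arr, spacing = c(25, 25, 80), ontology = ont)
  vol_mm3 <- sum(arr) * prod(c(25, 25, 80)) * 1e-9   # 1.024 mm^3
  spec <- tiny_spec()
  spec$densities <- c("1" = 1400)
  spec$dispersion <- Inf
  counts <- vapply(1:500, function(s)
    nrow(simulate_cells(lv, spec, seed = s)), numeric(1))
  mu <- 1400 * vol_mm3
  se <- sqrt(mu / 500)
  expect_lt(abs(mean(counts) - mu), 4 * se)
  # Poisson limit: variance/mean near 1
  expect_lt(var(counts) / mean(counts), 1.25)
})

test_that("finite dispersion produces overdispersed counts", {
  d <- c(10, 10, 10)
  arr <- array(0L, d); arr[2:9, 2:9, 2:9] <- 1L
  ont <- tibble::tibble(id = 1L, acronym = "R", name = "region",
                        parent_id = NA_integer_)
  lv <- label_volume(arr, spacing = c(25, 25, 80), ontology = ont)
  spec <- tiny_spec()
  spec$densities <- c("1" = 1400)
  spec$dispersion <- 4
  counts <- vapply(1:300, function(s)
    nrow(simulate_cells(lv, spec, seed = 4000 + s)), numeric(1))
  expect_gt(var(counts) / mean(counts), 1.5)
})

test_that("thinning keeps ~1/k3d of cells so the 1.4 correction inverts it", {
  b <- base_phantom()
  cells <- simulate_cells(b$labels, phantom_spec(), seed = 2)
  thin <- thin_cells_2d(cells, k3d = 1.4, seed = 3)
  frac <- nrow(thin) / nrow(cells)
  se <- sqrt((1 / 1.4) * (1 - 1 / 1.4) / nrow(cells))
  expect_lt(abs(frac - 1 / 1.4), 4 * se)
})
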