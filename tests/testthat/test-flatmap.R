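test_that("layer-restricted bins are disjoint subsets of the full bins", {
  b <- base_phantom()
  bins <- flatmap_bins(b$labels)
  sup <- layer_restrict(bins, b$labels, "superficial")
  deep <- layer_restrict(bins, b$labels, "deep")
  full_mask <- bins$bin_volume$data > 0
  expect_true(all(sup$bin_volume$data[!full_mask] == 0))
  expect_true(all(deep$bin_volume$data[!full_mask] == 0))
  # a voxel can be superficial or deep, never both
  expect_equal(sum(sup$bin_volume$data > 0 & deep$bin_volume$data > 0), 0)
  # full = superficial + deep + layer-4 remainder
  n_l4 <- sum(as.vector(b$labels$data) == 104L)
  expect_equal(sum(full_mask),
               sum(sup$bin_volume$data > 0) + sum(deep$bin_volume$data > 0) +
                 n_l4)
})

test_that("restricted voxel counts match brute-force mask arithmetic", {
  b <- base_phantom()
  bins <- flatmap_bins(b$labels)
  sup <- layer_restrict(bins, b$labels, "superficial")
  lab <- as.vector(b$labels$data)
  bv <- as.vector(bins$bin_volume$data)
  for (id in c(3L, 17L, 25L)) {
    brute <- sum(bv == id & lab %in% 101:103)
    expect_equal(sum(sup$bin_volume$data == id), brute)
  }
})

test_that("restricting to absent layers yields all-zero bins", {
  b <- base_phantom()
  bins <- flatmap_bins(b$labels)
  none <- layer_restrict(bins, b$labels, "superficial", layer_ids = 888L)
  expect_equal(sum(none$bin_volume$data), 0)
  fm <- bin_densities(tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                                     z_um = numeric(0)),
                      none, transform_identity())
  expect_true(all(is.na(fm$density_mm3)))
})

test_that("bin counts conserve cortical cells; identity keeps volumes", {
  b <- base_phantom()
  spec <- phantom_spec()
  bins <- flatmap_bins(b$labels)
  cells <- simulate_cells(b$labels, spec, seed = 41)
  fm <- bin_densities(cells, bins, transform_identity())
  # conservation: binned 2D counts equal cells landing in any binned voxel
  asg <- assign_cells(cells, b$labels)
  in_ctx <- asg$region_id %in% 101:106
  expect_equal(sum(fm$n2d), sum(in_ctx))
  # identity transform: bin volumes equal reference bin volumes
  expect_equal(fm$n_voxels,
               tabulate(bins$bin_volume$data[bins$bin_volume$data > 0],
                        nbins = nrow(bins$bins)))
  # missing transform is an error, not a fallback
  expect_error(bin_densities(cells, bins, NULL), "age_transform")
})

test_that("a uniform cortical density field maps to a flat map", {
  b <- base_phantom()
  spec <- phantom_spec()
  spec$densities[] <- 0
  spec$densities[paste(101:106)] <- 1200
  cells <- thin_cells_2d(simulate_cells(b$labels, spec, seed = 43),
                         1.4, seed = 44)
  bins <- flatmap_bins(b$labels)
  fm <- bin_densities(cells, bins, transform_identity())
  occ <- fm[!is.na(fm$density_mm3) & fm$n_voxels >= 50, ]
  mu <- occ$volume_mm3 * 1200 / 1.4       # expected 2D count per bin
  z <- (occ$n2d - mu) / sqrt(mu)          # Poisson placement noise per bin
  expect_lt(max(abs(z)), 4)
  # and in aggregate the recovered cortical density is unbiased
  z_tot <- (sum(occ$n2d) - sum(mu)) / sqrt(sum(mu))
  expect_lt(abs(z_tot), 4)
})

test_that("age-specific bin volumes follow the age transform", {
  b <- base_phantom()
  bins <- flatmap_bins(b$labels)
  # a global shrink of content: warped bins occupy fewer voxels
  ctr <- dim(b$labels$data) * b$labels$spacing / 2
  shrink <- transform_affine(diag(3) * 0.8, as.numeric(ctr - 0.8 * ctr))
  fm_ref <- bin_densities(tibble::tibble(x_um = numeric(0),
                                         y_um = numeric(0),
                                         z_um = numeric(0)),
                          bins, transform_identity())
  fm_age <- bin_densities(tibble::tibble(x_um = numeric(0),
                                         y_um = numeric(0),
                                         z_um = numeric(0)),
                          bins, shrink)
  expect_lt(sum(fm_age$n_voxels), sum(fm_ref$n_voxels))
  expect_gt(sum(fm_age$n_voxels), 0.35 * sum(fm_ref$n_voxels))
})

test_that("rendering is deterministic from the density table", {
  tbl <- tibble::tibble(bin_id = 1:4, grid_x = c(1, 2, 1, 2),
                        grid_y = c(1, 1, 2, 2),
                        density_mm3 = c(100, 200, NA, 400))
  g1 <- render_flatmap(tbl)
  g2 <- render_flatmap(tbl)
  expect_s3_class(g1, "ggplot")
  expect_identical(ggplot2::layer_data(g1), ggplot2::layer_data(g2))
  # missing bins get the missing-data colour, distinct from any real fill
  ld <- ggplot2::layer_data(g1)
  na_fill <- ld$fill[is.na(tbl$density_mm3[order(tbl$bin_id)])]
  expect_equal(na_fill, "grey80")
})
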