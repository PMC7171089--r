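make_small_labels <- function() {
  # 10x10x10 grid at default spacing: two regions under one parent
  arr <- array(0L, c(10, 10, 10))
  arr[2:5, 2:9, 2:9] <- 1L
  arr[6:9, 2:9, 2:9] <- 2L
  ont <- tibble::tibble(id = c(9L, 1L, 2L),
                        acronym = c("P", "A", "B"),
                        name = c("parent", "a", "b"),
                        parent_id = c(NA, 9L, 9L))
  label_volume(arr, spacing = c(20, 20, 50), ontology = validate_ontology(ont))
}

test_that("cells are assigned by containing voxel, boundaries half-open", {
  lv <- make_small_labels()
  # centre of voxel (2,2,2) -> region 1
  ctr <- voxel_centers(lv, cbind(2, 2, 2))
  cells <- tibble::tibble(x_um = ctr[1], y_um = ctr[2], z_um = ctr[3])
  expect_equal(assign_cells(cells, lv)$region_id, 1L)
  # x = 100 um is the boundary between voxels 5 and 6 -> higher voxel, region 2
  cells <- tibble::tibble(x_um = 100, y_um = 50, z_um = 125)
  expect_equal(assign_cells(cells, lv)$region_id, 2L)
  # outside the grid: flagged, not dropped
  cells <- tibble::tibble(x_um = -5, y_um = 50, z_um = 125)
  asg <- assign_cells(cells, lv)
  expect_true(asg$out_of_grid)
  expect_equal(nrow(asg), 1)
})

test_that("n3d applies the 1.4 conversion and volumes use voxel arithmetic", {
  lv <- make_small_labels()
  # 1000 cells in region 1
  ctr <- voxel_centers(lv, cbind(3, 5, 5))
  cells <- tibble::tibble(x_um = rep(ctr[1], 1000), y_um = ctr[2],
                          z_um = ctr[3], section_index = 4L, channel = 1L)
  st <- region_stats(assign_cells(cells, lv), lv)
  r1 <- st[st$region_id == 1L, ]
  expect_equal(r1$n2d, 1000L)
  expect_equal(r1$n3d, 1400)
  # region volumes: n_voxels x 20000 um^3 x 1e-9
  expect_equal(r1$volume_mm3, r1$n_voxels * 20000 * 1e-9)
  # zero-count region present with density 0
  r2 <- st[st$region_id == 2L, ]
  expect_equal(r2$n2d, 0L)
  expect_equal(r2$density_mm3, 0)
  # identity: density x volume == n3d
  expect_equal(r1$density_mm3 * r1$volume_mm3, r1$n3d)
})

test_that("50,000 voxels at 20 x 20 x 50 um give exactly 1 mm^3", {
  arr <- array(0L, c(50, 50, 20))
  arr[1:50, 1:50, 1:20] <- 1L            # 50000 voxels
  ont <- tibble::tibble(id = 1L, acronym = "R", name = "r",
                        parent_id = NA_integer_)
  lv <- label_volume(arr, spacing = c(20, 20, 50), ontology = ont)
  cells <- tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                          z_um = numeric(0))
  st <- region_stats(assign_cells(cells, lv), lv)
  expect_equal(st$n_voxels, 50000L)
  expect_equal(st$volume_mm3, 1.0)
})

test_that("ontology aggregation recomputes parent density from sums", {
  # two children: n3d 140 and 280 over 0.1 and 0.2 mm^3 -> parent 420 / 0.3
  st <- tibble::tibble(
    region_id = c(1L, 2L),
    n2d = c(100L, 200L),
    n3d = c(140, 280),
    n_voxels = c(5000L, 10000L),          # 0.1 / 0.2 mm^3 at 20000 um^3
    volume_mm3 = c(0.1, 0.2))
  st$density_mm3 <- st$n3d / st$volume_mm3
  attr(st, "k3d") <- 1.4
  ont <- validate_ontology(tibble::tibble(
    id = c(9L, 1L, 2L), acronym = c("P", "A", "B"),
    name = c("p", "a", "b"), parent_id = c(NA, 9L, 9L)))
  agg <- aggregate_regions(st, ont)
  p <- agg[agg$region_id == 9L, ]
  expect_equal(p$n3d, 420)
  expect_equal(p$volume_mm3, 0.3)
  expect_equal(p$density_mm3, 1400)
  # single child: parent stats equal child stats
  ont1 <- validate_ontology(tibble::tibble(
    id = c(9L, 1L), acronym = c("P", "A"), name = c("p", "a"),
    parent_id = c(NA, 9L)))
  agg1 <- aggregate_regions(st[1, ], ont1)
  expect_equal(agg1$n3d[agg1$region_id == 9L], st$n3d[1])
  # aggregation is idempotent with respect to child order
  agg_rev <- aggregate_regions(st[2:1, ], ont)
  expect_equal(agg[order(agg$region_id), ]$n3d,
               agg_rev[order(agg_rev$region_id), ]$n3d)
  # unknown region id is an error
  bad <- st; bad$region_id[1] <- 77L
  expect_error(aggregate_regions(bad, ont), "absent")
})

test_that("counts are conserved from cell table to aggregated root", {
  b <- base_phantom()
  spec <- phantom_spec()
  cells <- simulate_cells(b$labels, spec, seed = 31)
  asg <- assign_cells(cells, b$labels)
  st <- region_stats(asg, b$labels)
  n_bg <- attr(st, "n_background")
  n_out <- attr(st, "n_out_of_grid")
  expect_equal(sum(st$n2d) + n_bg + n_out, nrow(cells))
  agg <- aggregate_regions(st, b$ontology)
  root <- agg[agg$region_id == 999L, ]
  expect_equal(root$n2d, sum(st$n2d))
  expect_equal(root$n3d, 1.4 * sum(st$n2d))
})

test_that("phantom cells all recover their generating region", {
  b <- base_phantom()
  cells <- simulate_cells(b$labels, phantom_spec(), seed = 8)
  asg <- assign_cells(cells, b$labels)
  expect_identical(asg$region_id, asg$true_region)
})

test_that("recovered densities match generation within NB error", {
  # full quantification chain on thinned (2D-convention) counts
  b <- base_phantom()
  spec <- phantom_spec()
  cells <- simulate_cells(b$labels, spec, seed = 17)
  thin <- thin_cells_2d(cells, 1.4, seed = 18)
  st <- quantify_cells(thin, b$labels)
  leaf <- st[st$region_id %in% as.integer(names(spec$densities)), ]
  mu <- spec$densities[as.character(leaf$region_id)] * leaf$volume_mm3
  sd_nb <- sqrt(mu + mu^2 / spec$dispersion)
  z <- (leaf$n3d - mu) / sd_nb
  expect_lt(max(abs(z)), 3.5)
})
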