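gaussian_spot_section <- function(nx, ny, centers, sigma = 1.5, amp = 100) {
  img <- matrix(0, nx, ny)
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  for (i in seq_len(nrow(centers))) {
    img <- img + amp * exp(-((xs - centers[i, 1])^2 +
                               (ys - centers[i, 2])^2) / (2 * sigma^2))
  }
  img
}

test_that("a blank section yields zero cells (with a range warning)", {
  img <- matrix(0, 32, 32)
  expect_warning(out <- detect_cells_2d(img, threshold = 10), "range")
  expect_equal(nrow(out), 0)
})

test_that("disjoint Gaussian spots are counted exactly, centroids < 1 px", {
  set.seed(5)
  centers <- as.matrix(expand.grid(seq(8, 72, by = 16), seq(8, 72, by = 16)))
  centers <- centers + matrix(runif(50, -1, 1), 25, 2)    # 25 spots
  img <- gaussian_spot_section(80, 80, centers)
  out <- detect_cells_2d(img, threshold = 30, spacing_um = c(1, 1),
                         section_index = 3L)
  expect_equal(nrow(out), 25)
  # match each detection to its nearest true centre (physical = px - 0.5)
  det <- cbind(out$x_um + 0.5, out$y_um + 0.5)
  err <- vapply(seq_len(25), function(i)
    min(sqrt(rowSums(sweep(det, 2, centers[i, ], "-")^2))), numeric(1))
  expect_lt(max(err), 1)
  expect_equal(unique(out$section_index), 3L)
})

test_that("components below the minimum area are excluded", {
  img <- matrix(0, 40, 40)
  img[10:13, 10:13] <- 100      # 16 px blob
  img[30, 30] <- 100            # 1 px speck
  out <- detect_cells_2d(img, threshold = 50, min_area = 4)
  expect_equal(nrow(out), 1)
  expect_equal(out$area_px, 16)
  # two spots merged above threshold count as one component
  img2 <- matrix(0, 40, 40)
  img2[10:12, 10:20] <- 100     # single merged bar
  out2 <- detect_cells_2d(img2, threshold = 50, min_area = 1)
  expect_equal(nrow(out2), 1)
})

test_that("volume-wise detection stamps section geometry", {
  v <- volume(array(0, c(32, 32, 4)), c(20, 20, 50))
  v$data[16, 16, 2] <- 100
  v$data[8, 24, 4] <- 100
  out <- detect_cells(v, threshold = 50)
  expect_equal(nrow(out), 2)
  expect_setequal(out$section_index, c(1L, 3L))
  expect_equal(sort(out$z_um), c(75, 175))
  # detection feeding assignment: the cell lands in its source voxel
  lv <- label_volume(array(7L, c(32, 32, 4)), c(20, 20, 50),
                     ontology = tibble::tibble(id = 7L, acronym = "R",
                                               name = "r",
                                               parent_id = NA_integer_))
  asg <- assign_cells(out, lv)
  expect_equal(asg$region_id, c(7L, 7L))
})
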