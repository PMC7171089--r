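test_that("BH adjustment matches the hand-computed step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  # random vectors against the brute-force step-up definition
  set.seed(99)
  for (m in 2:6) {
    for (r in 1:25) {
      p <- round(runif(m), 2)
      expect_equal(bh_adjust(p), bh_oracle(p))
    }
  }
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("identical groups give a null result", {
  y <- c(120L, 95L, 140L, 88L, 103L)
  r <- nb_group_test(y, y)
  expect_gt(r$p_value, 0.9)
  expect_lt(abs(r$log_fc), 1e-8)
})

test_that("all-zero regions are degenerate with p = 1 by convention", {
  r <- nb_group_test(c(0L, 0L, 0L), c(0L, 0L, 0L))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
})

test_that("count and group-size preconditions are enforced", {
  expect_error(nb_group_test(5L, c(1L, 2L)), "2 subjects")
  expect_error(nb_group_test(c(-1L, 2L), c(1L, 2L)), "nonnegative")
  expect_error(nb_group_test(c(1.5, 2), c(1L, 2L)), "integers")
})

test_that("volume offsets shift the comparison onto densities", {
  # same counts, group B measured over twice the volume: significant deficit
  a <- c(200L, 190L, 210L, 205L, 195L)
  r_no <- nb_group_test(a, a)
  r_off <- nb_group_test(a, a, offsets_a = rep(1, 5), offsets_b = rep(2, 5))
  expect_gt(r_no$p_value, 0.9)
  expect_lt(r_off$log_fc, -0.5)
  expect_lt(r_off$p_value, 0.05)
})

test_that("a strong planted effect is detected", {
  set.seed(7)
  a <- rnbinom(5, size = 8, mu = 100)
  b <- rnbinom(5, size = 8, mu = 1000)
  r <- nb_group_test(a, b)
  expect_lt(r$p_value, 0.01)
  expect_gt(r$log_fc, 1)
})

test_that("compare_groups adjusts across regions and flags dimorphism", {
  set.seed(11)
  rows <- list()
  for (reg in 1:20) {
    mu <- 150
    scale_b <- if (reg <= 2) 4 else 1
    for (grp in c("F", "M")) {
      n <- rnbinom(5, size = 10, mu = mu * if (grp == "M") scale_b else 1)
      rows[[length(rows) + 1]] <- tibble::tibble(
        region_id = reg, group = grp, n3d = n,
        subject = 1:5, volume_mm3 = 0.5)
    }
  }
  cmp <- compare_groups(dplyr::bind_rows(rows))
  td <- tidy(cmp)
  expect_true(all(td$region_id[td$significant] %in% 1:2))
  expect_true(all(cmp$q_value >= cmp$p_value, na.rm = TRUE))
  gl <- glance(cmp)
  expect_equal(gl$n_regions, 20L)
})

test_that("power is ~alpha at zero effect and ~1 at huge effect", {
  cfg0 <- stats_config(effect_size = 1e-9, seed = 21)
  p0 <- power_regions(means = 200, dispersions = 8, n_per_group = 5,
                      config = cfg0, n_sim = 300)
  expect_lt(p0$power[1], 0.12)
  cfg_big <- stats_config(effect_size = log(10), seed = 22)
  p1 <- power_regions(means = 500, dispersions = 10, n_per_group = 5,
                      config = cfg_big, n_sim = 100)
  expect_gt(p1$power[1], 0.95)
})

test_that("power is monotone nondecreasing in group size", {
  cfg <- stats_config(effect_size = 0.85, seed = 23)
  pw <- vapply(c(3, 5, 10), function(n)
    power_regions(500, 5, n, cfg, n_sim = 150)$power[1], numeric(1))
  expect_true(all(diff(pw) >= -0.05))
  expect_error(power_regions(500, 5, 1, cfg), ">= 2")
})

test_that("colocalization percentages reproduce the worked examples", {
  expect_equal(colocalization_percent(321, 383, 1), 83.8)
  expect_equal(colocalization_percent(99, 576, 0), 17)
  expect_equal(colocalization_percent(0, 50), 0)
  expect_error(colocalization_percent(5, 0), "undefined")
  expect_error(colocalization_percent(60, 50), "<=")
})

test_that("puncta positivity exposes both comparators", {
  expect_false(puncta_positive(0))
  expect_true(puncta_positive(4))                       # default >=
  expect_false(puncta_positive(4, comparator = ">"))
  expect_true(puncta_positive(10))
  expect_true(puncta_positive(10, comparator = ">"))
})

test_that("spine density matches the textbook pooled-variance t-test", {
  spines_a <- c(20, 18, 25, 22)
  len_a <- c(10, 12, 11, 10)
  spines_b <- c(12, 10, 14, 9)
  len_b <- c(10, 11, 12, 9)
  r <- spine_density_test(spines_a, len_a, spines_b, len_b)
  # 20 spines on 10 um -> 20 per 10 um
  expect_equal(r$density_a[1], 20)
  # hand-computed pooled-variance t
  da <- 10 * spines_a / len_a; db <- 10 * spines_b / len_b
  sp2 <- (3 * var(da) + 3 * var(db)) / 6
  t_hand <- (mean(da) - mean(db)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 6)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), 6), tolerance = 1e-12)
  # identical groups: p ~ 1
  ri <- spine_density_test(spines_a, len_a, spines_a, len_a)
  expect_gt(ri$p_value, 0.99)
  expect_error(spine_density_test(1, 10, spines_b, len_b), "2 segments")
  expect_error(spine_density_test(spines_a, c(10, 0, 11, 10),
                                  spines_b, len_b), "> 0")
})
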