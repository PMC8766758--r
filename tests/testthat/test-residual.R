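square_hull <- function(x0 = 5, x1 = 15, y0 = 5, y1 = 15) {
  scotoma_hull(cbind(c(x0, x0, x1, x1), c(y0, y1, y0, y1)))
}

test_that("mirror flip is an isometric involution fixing the meridian", {
  h <- scotoma_hull(cbind(c(-10, -10, -1, 0), c(-8, 8, 5, -2)))
  f <- mirror_flip(h)
  expect_equal(hull_area(f), hull_area(h))
  ff <- mirror_flip(f)
  expect_setequal(paste(ff$vertices[, 1], ff$vertices[, 2]),
                  paste(h$vertices[, 1], h$vertices[, 2]))
  # a vertex on the vertical meridian is a fixed point
  expect_true(any(f$vertices[, 1] == 0 & f$vertices[, 2] == -2))
  # flipped x coordinates change sign
  expect_equal(sort(f$vertices[, 1]), sort(-h$vertices[, 1]))
})

test_that("disc-hull intersection handles the easy cases and errors", {
  h <- square_hull()
  expect_true(circle_intersects_hull(c(10, 10), 0, h))
  expect_true(circle_intersects_hull(c(10, 10), 5, h))
  expect_false(circle_intersects_hull(c(0, 10), 1, h))   # 5 deg away
  expect_true(circle_intersects_hull(c(0, 10), 5, h))    # tangent counts
  expect_error(circle_intersects_hull(c(0, 0), -1, h), "non-negative")
  # degenerate hulls use point/segment distance
  pt <- scotoma_hull(cbind(3, 4))
  expect_true(circle_intersects_hull(c(0, 0), 5, pt))
  expect_false(circle_intersects_hull(c(0, 0), 4.9, pt))
  seg <- scotoma_hull(cbind(c(0, 10), c(5, 5)))
  expect_true(circle_intersects_hull(c(5, 7), 2, seg))
  expect_false(circle_intersects_hull(c(5, 7), 1.9, seg))
  # the empty sentinel intersects nothing
  empty <- scotoma_hull(data.frame(x = 0, y = 0, seen = TRUE))
  expect_false(circle_intersects_hull(c(0, 0), 100, empty))
})

test_that("disc-hull intersection agrees with a rasterization oracle", {
  set.seed(31)
  for (case in 1:120) {
    h <- scotoma_hull(cbind(runif(6, -6, 6), runif(6, -6, 6)))
    center <- runif(2, -8, 8)
    radius <- runif(1, 0, 3)
    got <- circle_intersects_hull(center, radius, h)
    want <- oracle_circle_hull(center, radius, h, step = 0.02)
    if (got != want) {
      # disagreement is only tolerable within one raster cell of tangency
      gap <- abs(strokefield:::dist_points_boundary(
        matrix(center, 1), h$vertices) - radius)
      expect_lt(gap, 0.02 * sqrt(2))
    } else {
      succeed()
    }
  }
})

test_that("supersampling replicates native voxels with recoverable identity", {
  fits <- toy_fits(c(1, 2), c(0, 0), 1, r2 = c(0.3, 0.9))
  ss <- supersample_fits(fits, factor = 3)
  expect_equal(nrow(ss), 2 * 27)
  expect_equal(sum(ss$native_voxel == 1), 27)
  expect_equal(unique(ss$r2[ss$native_voxel == 2]), 0.9)
  expect_equal(max(ss$replicate), 27)
})

test_that("scotoma pRF counts follow construction arithmetic and thresholds", {
  h <- square_hull()
  # 5 of 10 native voxels intersect; 3 mm -> 1 mm replication gives 135
  fits <- toy_fits(x0 = c(rep(10, 5), rep(-30, 5)),
                   y0 = rep(10, 10), sigma = 1, r2 = 0.9)
  ss <- supersample_fits(fits, factor = 3)
  expect_equal(as.integer(count_scotoma_prfs(ss, h, threshold = 0.5)), 135)
  # counts are monotone non-increasing in the threshold
  fits2 <- toy_fits(x0 = rep(10, 6), y0 = rep(10, 6), sigma = 1,
                    r2 = seq(0.1, 0.6, by = 0.1))
  counts <- vapply(c(0, 0.25, 0.45, 0.65, 1.1),
                   function(th) as.integer(count_scotoma_prfs(fits2, h, th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 6)
  # no reliable fits and the empty-scotoma sentinel
  expect_equal(as.integer(count_scotoma_prfs(fits, h, threshold = 0.95)), 0)
  empty <- scotoma_hull(data.frame(x = 0, y = 0, seen = TRUE))
  res <- count_scotoma_prfs(fits, empty, threshold = 0)
  expect_equal(as.integer(res), 0)
  expect_equal(attr(res, "status"), "empty_scotoma")
})

test_that("coverage maps combine pRF profiles by pointwise maximum", {
  gx <- seq(-10, 10, length.out = 81)
  one <- coverage_map(toy_fits(2, 2, 1), gx, gx)
  expect_equal(max(one$values), 1, tolerance = 1e-3)
  peak <- which(one$values == max(one$values), arr.ind = TRUE)
  expect_equal(gx[peak[1]], 2, tolerance = 0.3)
  expect_equal(gx[peak[2]], 2, tolerance = 0.3)
  # empty fit set gives an all-zero map
  none <- coverage_map(toy_fits(numeric(0), numeric(0), numeric(0)), gx, gx)
  expect_true(all(none$values == 0))
  # two disjoint pRFs: map equals the pointwise max of the single maps
  a <- toy_fits(-5, -5, 0.8)
  b <- toy_fits(5, 5, 1.2)
  both <- coverage_map(rbind(a, b), gx, gx)
  expect_equal(both$values,
               pmax(coverage_map(a, gx, gx)$values,
                    coverage_map(b, gx, gx)$values))
  # permutation invariance and monotonicity under added fits
  expect_equal(coverage_map(rbind(b, a), gx, gx)$values, both$values)
  expect_true(all(both$values >= coverage_map(a, gx, gx)$values))
  # non-normalized mode scales by amplitude
  a$amplitude <- 3
  nn <- coverage_map(a, gx, gx, mode = "non_normalized")
  expect_equal(max(nn$values), 3, tolerance = 1e-3)
})

test_that("KS statistic matches the brute-force pooled sweep", {
  x <- c(0.1, 0.4, 0.7)
  y <- c(0.2, 0.5)
  r <- ks_compare(x, y)
  expect_equal(r$D, oracle_ks_d(x, y), tolerance = 1e-15)
  set.seed(33)
  for (i in 1:30) {
    x <- runif(sample(3:40, 1))
    y <- runif(sample(3:40, 1))
    r <- ks_compare(x, y)
    expect_equal(r$D, oracle_ks_d(x, y), tolerance = 1e-12)
    # independent reference implementation
    expect_equal(r$D, suppressWarnings(stats::ks.test(x, y)$statistic[[1]]),
                 tolerance = 1e-12)
  }
})

test_that("KS extremes, invariances, and the no-overlap sentinel behave", {
  s <- c(0.2, 0.4, 0.9)
  r <- ks_compare(s, s)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  expect_equal(ks_compare(1:5, 6:10)$D, 1)
  # D is invariant under strictly monotone transforms of both samples
  set.seed(34)
  x <- rnorm(25)
  y <- rnorm(30, mean = 0.5)
  d0 <- ks_compare(x, y)$D
  expect_equal(ks_compare(exp(x), exp(y))$D, d0)
  expect_equal(ks_compare(x^3, y^3)$D, d0)
  # asymptotic p agrees with the reference implementation at large n
  set.seed(35)
  xl <- rnorm(250)
  yl <- rnorm(300, mean = 0.25)
  ref <- suppressWarnings(stats::ks.test(xl, yl, exact = FALSE)$p.value)
  expect_equal(ks_compare(xl, yl)$p, ref, tolerance = 0.02)
  none <- ks_compare(numeric(0), y)
  expect_equal(none$status, "no_overlap")
  expect_true(is.na(none$D))
})

test_that("per-ROI residual summary counts both hemispheres correctly", {
  h <- scotoma_hull(cbind(c(-12, -12, -2, -2), c(-12, 12, 12, -12)))
  fits <- rbind(
    toy_fits(c(-6, -7, -30), c(0, 2, 30), 1, r2 = c(0.9, 0.8, 0.9),
             hemisphere = "lesioned"),
    toy_fits(c(6, 7, 30), c(0, 2, 30), 1, r2 = c(0.7, 0.85, 0.9),
             hemisphere = "healthy"))
  fits$voxel <- seq_len(nrow(fits))
  out <- residual_summary(fits, h, threshold = 0.75, factor = 3)
  expect_equal(out$count_mm3, 2 * 27)          # r2 0.9 and 0.8 inside
  expect_equal(out$control_count_mm3, 1 * 27)  # only r2 0.85 passes
  expect_equal(out$n1, 2)
  expect_equal(out$n2, 2)
  r2s <- unique_voxel_r2(supersample_fits(fits, 3))
  expect_equal(r2s, fits$r2)
})
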