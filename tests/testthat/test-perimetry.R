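flat_normals <- normative_field(peak_db = 30, slope_db_per_deg = 0)

grid_points <- function(xs, ys, db = 30, seen = TRUE) {
  g <- expand.grid(x = xs, y = ys)
  data.frame(x = g$x, y = g$y, eye = "OD",
             threshold_db = rep_len(db, nrow(g)),
             seen = rep_len(seen, nrow(g)))
}

test_that("a defect deeper than 6 dB recruits its four grid neighbors", {
  tested <- grid_points(0, 0, db = 23)  # 7 dB below the flat 30 dB normal
  new <- adaptive_expand(tested, flat_normals, grid_step = 5)
  # enumeration oracle: the 4-neighborhood of the flagged point
  expect_setequal(paste(new$x, new$y),
                  c("5 0", "-5 0", "0 5", "0 -5"))
  # already-tested neighbors are not re-queued
  tested2 <- rbind(tested, grid_points(5, 0, db = 30))
  new2 <- adaptive_expand(tested2, flat_normals, grid_step = 5)
  expect_setequal(paste(new2$x, new2$y), c("-5 0", "0 5", "0 -5"))
})

test_that("the 6 dB criterion is a strict inequality", {
  tested <- grid_points(0, 0, db = 24)  # exactly 6 dB below normal
  expect_equal(nrow(adaptive_expand(tested, flat_normals, 5)), 0)
  expect_equal(nrow(adaptive_expand(grid_points(0, 0, db = 29),
                                    flat_normals, 5)), 0)
})

test_that("expansion respects the test extent, grid, and is idempotent", {
  tested <- grid_points(48, 0, db = 10)
  new <- adaptive_expand(tested, flat_normals, grid_step = 2,
                         max_extent = 50)
  # (50, 0) is on the boundary and stays; (52, 0) falls outside
  expect_setequal(paste(new$x, new$y), c("50 0", "46 0", "48 2", "48 -2"))
  expect_error(adaptive_expand(grid_points(1.3, 0), flat_normals, 2),
               "off the grid")
  # once the new points test normal, nothing further is added
  follow <- rbind(tested,
                  data.frame(x = new$x, y = new$y, eye = "OD",
                             threshold_db = 30, seen = TRUE))
  again <- adaptive_expand(follow, flat_normals, grid_step = 2,
                           max_extent = 50)
  expect_equal(nrow(again), 0)
})

test_that("mean deviation is the signed mean departure from the normal hill", {
  tested <- grid_points(c(-10, 0, 10), c(-10, 0, 10))
  expect_equal(mean_deviation(tested, flat_normals), 0)
  tested$threshold_db <- 25
  expect_equal(mean_deviation(tested, flat_normals), -5)
  expect_equal(abs(mean_deviation(tested, flat_normals)), 5)
  expect_equal(mean_deviation(tested, flat_normals,
                              sign = "normal_minus_measured"), 5)
  # linearity in a uniform shift
  tested$threshold_db <- tested$threshold_db + 3
  expect_equal(mean_deviation(tested, flat_normals), -2)
  # unseen points enter at the floor sensitivity
  tested$seen <- FALSE
  expect_equal(mean_deviation(tested, flat_normals), -30)
  expect_equal(mean_deviation(tested, flat_normals, floor_db = 10), -20)
})

test_that("tabulated normals must cover every tested location", {
  tab <- data.frame(x = 0, y = 0, normal_db = 30)
  tested <- grid_points(c(0, 5), 0)
  expect_error(mean_deviation(tested, tab), "\\(5, 0\\)")
  expect_equal(mean_deviation(grid_points(0, 0), tab), 0)
})

test_that("BCEA follows the closed form and its scaling laws", {
  # sigma_h = sigma_v = 1, rho = 0 at 63.21% containment: k = 1, BCEA = 2*pi
  p63 <- 1 - exp(-1)
  cloud <- make_fixation_cloud(1, 1, 0, n = 5000, seed = 3)
  # normalize the sample so the sample statistics are exactly the targets
  cloud <- scale(cloud)
  s <- bcea(cloud, containment_p = p63)
  expect_equal(s$bcea, 2 * pi * sqrt(1 - s$rho^2), tolerance = 1e-12)
  expect_equal(s$bcea, 2 * pi, tolerance = 0.01)
  # quadratic scaling
  s2 <- bcea(cloud * 2, containment_p = p63)
  expect_equal(s2$bcea, 4 * s$bcea, tolerance = 1e-9)
  # collinear cloud collapses the ellipse
  line <- cbind(1:10, 2 * (1:10))
  expect_warning(s0 <- bcea(line), "collinear")
  expect_equal(s0$bcea, 0)
  expect_warning(bcea(matrix(1, 5, 2)), "degenerate")
  expect_error(bcea(cloud[1:2, ]))
  expect_error(bcea(cloud, containment_p = 1.2))
})

test_that("BCEA ellipse contains close to the requested fraction", {
  cloud <- make_fixation_cloud(1.2, 0.7, 0.4, n = 20000, seed = 5)
  s <- bcea(cloud, containment_p = 0.632)
  expect_equal(mean(bcea_contains(s, cloud)), 0.632, tolerance = 0.03)
})

test_that("scotoma hull matches squares, oracles, and degeneracies", {
  sq <- data.frame(x = c(5, 5, 15, 15, 10), y = c(5, 15, 5, 15, 10),
                   seen = FALSE)
  h <- scotoma_hull(sq)
  expect_equal(hull_area(h), 100)
  expect_equal(nrow(h$vertices), 4)  # the interior point is dropped
  # adding another interior point leaves the hull unchanged
  h2 <- scotoma_hull(rbind(sq, data.frame(x = 7, y = 8, seen = FALSE)))
  expect_setequal(paste(h2$vertices[, 1], h2$vertices[, 2]),
                  paste(h$vertices[, 1], h$vertices[, 2]))
  # empty, point, and segment sentinels
  none <- scotoma_hull(data.frame(x = 1, y = 1, seen = TRUE))
  expect_true(none$empty)
  expect_equal(hull_area(none), 0)
  pt <- scotoma_hull(cbind(3, 4))
  expect_equal(nrow(pt$vertices), 1)
  seg <- scotoma_hull(cbind(c(0, 1, 2, 3), c(0, 1, 2, 3)))
  expect_equal(nrow(seg$vertices), 2)
  expect_equal(hull_area(seg), 0)
})

test_that("random hull area agrees with the rasterization oracle", {
  set.seed(21)
  pts <- cbind(runif(50, -20, 20), runif(50, -20, 20))
  h <- scotoma_hull(pts)
  expect_equal(hull_area(h), oracle_hull_area(h, step = 0.05),
               tolerance = 0.01)
})

test_that("hull area is invariant under rigid rotation", {
  set.seed(22)
  pts <- cbind(runif(30, -10, 10), runif(30, -10, 10))
  a0 <- hull_area(scotoma_hull(pts))
  for (th in c(0.3, 1.1, 2.5)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    expect_equal(hull_area(scotoma_hull(pts %*% R)), a0, tolerance = 1e-9)
  }
})

test_that("discordant monocular outcomes are reported, concordant are not", {
  pts <- rbind(
    data.frame(x = c(0, 5), y = 0, eye = "OD", threshold_db = 30,
               seen = c(FALSE, TRUE)),
    data.frame(x = c(0, 5), y = 0, eye = "OS", threshold_db = 30,
               seen = c(FALSE, FALSE)))
  rep <- homonymous_agreement(pts)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$x, 5)
})
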