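small_cfg <- function(...) {
  args <- list(field_radius = 8, n_voxels = 8, n_control = 4,
               grid_n = 41, aperture_kinds = c("wedge", "bar"))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

test_that("generators are pure functions of config and seed", {
  a <- make_sheet(small_cfg(), seed = 9)
  b <- make_sheet(small_cfg(), seed = 9)
  expect_identical(a$truth, b$truth)
  expect_identical(a$series, b$series)
  c <- make_sheet(small_cfg(), seed = 10)
  expect_false(identical(a$series, c$series))
  expect_identical(make_fixation_cloud(1, 1, 0.2, 100, seed = 4),
                   make_fixation_cloud(1, 1, 0.2, 100, seed = 4))
  sch <- make_gradient_scheme(12)
  expect_identical(make_dwi_phantom(list(diag(3) * 1e-3), sch,
                                    noise_sd = 1, seed = 2),
                   make_dwi_phantom(list(diag(3) * 1e-3), sch,
                                    noise_sd = 1, seed = 2))
  # generators do not disturb the caller's RNG stream
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(make_sheet(small_cfg(), seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("a zero-noise sheet is recovered essentially perfectly", {
  cfg <- small_cfg(noise_sd = 0)
  sh <- make_sheet(cfg, seed = 2)
  vis <- sh$truth$hemisphere != "control"
  fits <- fit_prf(sh$series[, vis], sh$apertures, search = tiny_search())
  expect_true(all(fits$r2 > 0.999))
  expect_lt(max(abs(fits$x0 - sh$truth$x0[vis])), 0.05)
  expect_lt(max(abs(fits$sigma - sh$truth$sigma[vis]) /
                  sh$truth$sigma[vis]), 0.05)
})

test_that("lesioned voxels carry no trace of their silenced response", {
  cfg <- small_cfg(n_voxels = 40)
  poly <- rbind(c(30, -30), c(30, 30), c(-30, 30), c(-30, -30))
  sh <- make_sheet(cfg, scotoma = poly, seed = 6)
  les <- which(sh$truth$lesion)
  expect_gt(length(les), 20)  # whole lesioned hemisphere silenced
  expect_true(all(sh$truth$hemisphere[les] == "lesioned"))
  cors <- vapply(les, function(v) {
    truth <- as.list(sh$truth[v, c("x0", "y0", "sigma")])
    pred <- predict_timeseries(truth, sh$apertures, hrf = sh$hrf)
    abs(cor(sh$series[, v], pred))
  }, numeric(1))
  expect_gte(mean(cors < 0.3), 0.95)
})

test_that("the scotoma polygon must overlap the mapped field", {
  far <- rbind(c(30, 30), c(40, 30), c(40, 40), c(30, 40))
  expect_error(make_sheet(small_cfg(), scotoma = far, seed = 1),
               "outside the mapped field")
})

test_that("a symmetric sheet mirrors ground truth across the meridian", {
  sh <- make_sheet(small_cfg(n_voxels = 30), seed = 3, symmetric = TRUE)
  les <- sh$truth[sh$truth$hemisphere == "lesioned", ]
  hea <- sh$truth[sh$truth$hemisphere == "healthy", ]
  expect_equal(hea$x0, -les$x0)
  expect_equal(hea$y0, les$y0)
  expect_equal(hea$sigma, les$sigma)
})

test_that("perimetry responder marks exactly the strict polygon interior", {
  # intact field
  all_seen <- make_perimetry_responder(NULL, grid_step = 5, extent = 20)
  expect_true(all(all_seen$seen))
  expect_true(all(!is.na(all_seen$threshold_db)))
  # lower-left quadrant scotoma
  quad <- rbind(c(0, 0), c(0, -30), c(-30, -30), c(-30, 0))
  resp <- make_perimetry_responder(quad, grid_step = 5, extent = 20)
  # enumeration oracle: strictly inside means x < 0 and y < 0
  expect_setequal(paste(resp$x[!resp$seen], resp$y[!resp$seen]),
                  paste(resp$x[resp$x < 0 & resp$y < 0],
                        resp$y[resp$x < 0 & resp$y < 0]))
  # the hull of the responder covers the unseen grid points
  h <- scotoma_hull(resp)
  unseen <- cbind(resp$x[!resp$seen], resp$y[!resp$seen])
  expect_true(all(circle_intersects_hull(unseen, 0, h)))
  # seen thresholds follow the normative hill
  nf <- normative_field()
  expect_equal(resp$threshold_db[resp$seen],
               normal_db(nf, resp$x[resp$seen], resp$y[resp$seen]))
})

test_that("fixation clouds match their generating covariance", {
  s <- make_fixation_cloud(1.5, 0.8, 0.35, n = 10000, seed = 8)
  expect_lt(abs(cor(s[, 1], s[, 2]) - 0.35), 0.02)
  expect_equal(sd(s[, 1]), 1.5, tolerance = 0.05)
  swapped <- make_fixation_cloud(0.8, 1.5, 0.35, n = 10000, seed = 8)
  expect_equal(sd(swapped[, 2]), 1.5, tolerance = 0.05)
  expect_error(make_fixation_cloud(1, 1, 1, 10), "covariance")
  expect_error(make_fixation_cloud(-1, 1, 0, 10), "covariance")
  expect_error(make_fixation_cloud(1, 1, 0, 2), "n >= 3")
})

test_that("DWI phantoms are exact forward models", {
  sch <- make_gradient_scheme(20)
  D <- diag(c(1.2, 0.4, 0.2)) * 1e-3
  s <- make_dwi_phantom(list(D), sch, s0 = 90)
  expect_equal(s[1, 1], 90)  # b = 0 volume is S0 exactly when noiseless
  f <- fit_tensor(s[1, ], sch)
  expect_equal(f$eigenvalues, c(1.2, 0.4, 0.2) * 1e-3, tolerance = 1e-9)
  bad <- diag(c(1, 1, -1)) * 1e-3
  expect_error(make_dwi_phantom(list(bad), sch), "positive definite")
})

test_that("FA-targeted tensor rescaling hits the requested ratio", {
  D <- diag(c(1.7, 0.3, 0.3)) * 1e-3
  D2 <- make_fa_scaled_tensor(D, 0.6)
  ev <- eigen(D2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fa(ev), 0.6 * fa(c(1.7, 0.3, 0.3) * 1e-3), tolerance = 1e-9)
  # mean diffusivity is preserved by the shrinkage
  expect_equal(md(ev), md(c(1.7, 0.3, 0.3) * 1e-3), tolerance = 1e-12)
})
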