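# Radial foveal pit morphometry: LOESS smoothing, rim detection, slope
# computation and whole-macula aggregation.

test_that("LOESS smoothing reproduces local polynomials and its WLS oracle", {
  r <- seq(0, 2, by = 0.1)
  # quadratic data: local quadratic smoothing is an identity
  quad <- 230 + 40 * r - 12 * r^2
  expect_lt(max(abs(loess_smooth(r, quad) - quad)), 1e-9)
  # span = 1 on quadratic data equals the global quadratic fit
  global <- unname(stats::fitted(stats::lm(quad ~ r + I(r^2))))
  expect_lt(max(abs(loess_smooth(r, quad, span = 1) - global)), 1e-8)
  # brute-force per-point weighted-least-squares oracle
  set.seed(42)
  for (k in 1:5) {
    v <- 250 + cumsum(stats::rnorm(length(r), 0, 5))
    expect_lt(max(abs(loess_smooth(r, v) - loess_oracle(r, v))), 1e-9)
  }
  # cross-check against stats::loess with a matching neighbourhood
  v <- 250 + 30 * sin(2 * r) + 5 * r
  ref <- stats::fitted(stats::loess(v ~ r, span = 11 / 21, degree = 2,
                                    family = "gaussian",
                                    surface = "direct"))
  expect_lt(max(abs(loess_smooth(r, v) - ref)), 1e-6)
  expect_error(loess_smooth(c(0, 0.1), c(1, 2)), "at least 5")
  expect_error(loess_smooth(c(0, 0.1, 0.1, 0.2, 0.3), rep(1, 5)),
               "strictly increasing")
})

test_that("pit parameters recover a noiseless closed-form pit", {
  p <- default_pit()  # CFT 230.3, rim 350.8 um, radius 1.134 mm
  prof <- analytic_profile(function(theta, r) pit_surface(r, theta, p))
  res <- pit_params(prof)
  agg <- aggregate_pit(res)
  expect_lt(abs(agg$cft_um - 230.3), 0.5)
  expect_lt(abs(agg$rim_height_um - 350.8), 1)
  expect_lt(abs(agg$rim_radius_mm - 1.134), 0.1 + 1e-9)
  expect_false(agg$rim_at_boundary)
})

test_that("mean slope matches the arctangent closed form on a linear ramp", {
  # T = 230 + 100*r up to the rim: every forward step has slope
  # atan(100 um/mm / 1000) = 5.71 degrees
  ramp <- function(theta, r) 230 + 100 * pmin(r, 1.5) - 100 * pmax(r - 1.5, 0)
  prof <- analytic_profile(ramp)
  res <- pit_params(prof)
  expect_equal(res$directions$rim_radius_mm, rep(1.5, 24), tolerance = 0.11)
  slope <- atan(0.1) * 180 / pi
  expect_equal(mean(res$directions$mean_slope_deg), slope, tolerance = 0.02)
  # monotone decreasing profile: arg-max lands on the first step
  dec <- analytic_profile(function(theta, r) 300 - 20 * r)
  rd <- pit_params(dec)
  expect_true(all(rd$directions$rim_radius_mm == 0.1))
  # monotone increasing to the boundary: flagged
  inc <- analytic_profile(function(theta, r) 230 + 50 * r)
  ri <- pit_params(inc)
  expect_true(all(ri$directions$rim_at_boundary))
  expect_true(aggregate_pit(ri)$rim_at_boundary)
})

test_that("aggregation is the arithmetic mean over directions", {
  p <- default_pit()
  prof <- analytic_profile(function(theta, r) pit_surface(r, theta, p))
  res <- pit_params(prof)
  agg <- aggregate_pit(res)
  # radially symmetric: aggregate equals any single direction
  expect_equal(agg$rim_height_um, res$directions$rim_height_um[1])
  # shifting one direction's rim radius moves the mean by delta/24
  res2 <- res
  res2$directions$rim_radius_mm[3] <- res$directions$rim_radius_mm[3] + 0.2
  expect_equal(aggregate_pit(res2)$rim_radius_mm,
               agg$rim_radius_mm + 0.2 / 24)
  # elliptical modulation R(theta) = 1.0 + 0.2*cos^2(theta): angular mean 1.1
  pe <- list(cft = 230, rim_height = 350, rim_radius = 1, shape = 2,
             radius_mod = 0, height_mod = 0)
  prof_e <- analytic_profile(function(theta, r) {
    pe$rim_radius <- 1 + 0.2 * cos(theta)^2
    pit_surface(r, theta, pe)
  })
  agg_e <- aggregate_pit(pit_params(prof_e))
  expect_lt(abs(agg_e$rim_radius_mm - 1.1), 0.1 + 1e-9)
})

test_that("thickness scaling maps pit metrics as expected", {
  p <- default_pit()
  prof <- analytic_profile(function(theta, r) pit_surface(r, theta, p))
  k <- 1.3
  prof_k <- prof
  prof_k$trt <- prof$trt * k
  a <- aggregate_pit(pit_params(prof))
  b <- aggregate_pit(pit_params(prof_k))
  expect_equal(b$cft_um, k * a$cft_um)
  expect_equal(b$rim_height_um, k * a$rim_height_um, tolerance = 1e-9)
  expect_equal(b$rim_radius_mm, a$rim_radius_mm)
  # slopes transform through atan(k * tan(.)) per step; check direction 1
  s_a <- pit_params(prof)$directions$mean_slope_deg[1]
  d <- prof$trt[1, ]
  r <- prof$radii_mm
  i <- which(r == pit_params(prof)$directions$rim_radius_mm[1])
  manual_k <- mean(atan(k * diff(d[1:i]) / diff(r[1:i]) / 1000) * 180 / pi)
  expect_equal(pit_params(prof_k)$directions$mean_slope_deg[1], manual_k,
               tolerance = 1e-9)
  expect_gt(b$mean_slope_deg, a$mean_slope_deg)
})

test_that("generated eyes have a horizontally broader pit", {
  cfg <- tiny_config(mode = "pit", noise_scale = 1)
  subs <- sample_demographics(cfg, seed = 21)
  for (i in seq_len(nrow(subs))) {
    scan <- sample_eye(subs[i, ], "OD", cfg, seed = 30 + i)
    norm <- normalize_eye(scan, find_fovea(scan))
    pit <- fovea_pit_metrics(norm)
    d <- pit$directions
    horiz <- d$rim_radius_mm[d$angle_deg %in% c(0, 180)]
    vert <- d$rim_radius_mm[d$angle_deg %in% c(90, 270)]
    expect_gt(mean(horiz), mean(vert))
    # rim height never below the smoothed center for rising profiles
    expect_true(all(d$rim_height_um >= pit$cft_um - 1))
  }
})
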