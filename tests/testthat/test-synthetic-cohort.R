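# Synthetic cohort generator: demographics, mean models, pit surface and
# eye sampling.

test_that("demographic sampling respects structure, determinism and edge cases", {
  cfg <- oct_config(n_subjects = 4000L)
  d <- sample_demographics(cfg, seed = 11)
  expect_equal(nrow(d), 4000L)
  expect_true(all(d$age >= 21 & d$age <= 88))
  # bucket counts close to expectation (5 sigma binomial bands)
  counts <- table(cut(d$age, cfg$age_breaks, right = FALSE,
                      include.lowest = TRUE))
  expv <- 4000 * cfg$age_bucket_weights
  expect_true(all(abs(as.numeric(counts) - expv) <
                    5 * sqrt(expv * (1 - cfg$age_bucket_weights)) + 5))
  pf <- mean(d$sex == "female")
  expect_lt(abs(pf - cfg$female_fraction), 0.04)
  # determinism and empty case
  expect_identical(d, sample_demographics(cfg, seed = 11))
  expect_equal(nrow(sample_demographics(oct_config(n_subjects = 0L), 1)), 0L)
  # invalid weights rejected
  expect_error(oct_config(age_bucket_weights = c(0.5, 0.5, 0.2, -0.2)),
               "weights")
})

test_that("layer mean model reproduces its closed form", {
  cfg <- tiny_config()
  s40 <- ref_subject(age = 40)
  le <- cfg$layer_effects
  for (l in ALL_LAYERS) {
    expect_equal(layer_mean_model(s40, l, cfg),
                 le$mean[le$parameter == l], tolerance = 1e-12)
  }
  # age difference: 10*b1 + 100*b2 in the centered parameterization
  s50 <- ref_subject(age = 50)
  for (l in c("GCIPL", "ONPL")) {
    row <- le[le$parameter == l, ]
    b1 <- if (row$quadratic) 0.9 * row$age else row$age
    b2 <- if (row$quadratic) 0.0025 * row$age else 0
    expect_equal(layer_mean_model(s50, l, cfg) - layer_mean_model(s40, l, cfg),
                 10 * b1 + 100 * b2, tolerance = 1e-10)
  }
  # sex difference is the sex coefficient; TRT difference is the layer sum
  sm <- ref_subject(age = 57, sex = "male")
  sf <- ref_subject(age = 57, sex = "female")
  expect_equal(layer_mean_model(sm, "TRT", cfg) -
                 layer_mean_model(sf, "TRT", cfg),
               sum(le$sex[le$parameter != "TRT"]), tolerance = 1e-10)
  expect_equal(layer_mean_model(sm, "INL", cfg) -
                 layer_mean_model(sf, "INL", cfg),
               le$sex[le$parameter == "INL"], tolerance = 1e-10)
  expect_error(layer_mean_model(s40, "LGN", cfg), "unknown layer")
})

test_that("pit surface matches an independent closed-form evaluation", {
  p <- default_pit()
  expect_equal(pit_surface(0, 0, p), p$cft)
  expect_equal(pit_surface(p$rim_radius, 0.7, p), p$rim_height)
  # independent evaluation of T = CFT + (H - CFT) * u^a exp(a(1-u))
  r <- seq(0, 2, by = 0.05)
  u <- r / p$rim_radius
  expected <- p$cft + (p$rim_height - p$cft) * u^p$shape *
    exp(p$shape * (1 - u))
  expect_equal(pit_surface(r, 1.2, p), expected, tolerance = 1e-12)
  # angular modulation moves the rim
  pm <- default_pit(radius_mod = 0.1)
  expect_equal(pit_surface(pm$rim_radius * 1.1, 0, pm), pm$rim_height)
  expect_error(pit_surface(1, 0, default_pit(shape = -1)), "shape")
  expect_error(pit_surface(-0.1, 0, p), ">= 0")
})

test_that("sampled eyes satisfy raster, additivity and mirroring invariants", {
  cfg <- tiny_config()
  s <- ref_subject(age = 55, sex = "male", scan_focus = 0.5)
  scan <- sample_eye(s, "OD", cfg, seed = 3)
  expect_equal(nrow(scan), 25L * 512L)
  expect_lt(max(abs(scan$TRT - rowSums(scan[, LAYERS]))), 1e-6)
  expect_true(all(scan[, c(LAYERS, "TRT")] >= 0))
  # OS eye of the same subject/seed is the x-mirrored field
  os <- sample_eye(s, "OS", cfg, seed = 3)
  m <- os[order(-os$x_mm, os$y_mm), c(LAYERS, "TRT")]
  o <- scan[order(scan$x_mm, scan$y_mm), c(LAYERS, "TRT")]
  expect_equal(unname(as.matrix(m)), unname(as.matrix(o)), tolerance = 1e-9)
  # determinism
  expect_equal(sample_eye(s, "OD", cfg, seed = 3), scan)
  # highres raster size
  cfg2 <- tiny_config(protocol = "highres")
  expect_equal(nrow(sample_eye(s, "OD", cfg2, seed = 1)), 97L * 1024L)
})

test_that("noiseless centered eyes reproduce the layer mean model within discretization", {
  cfg <- tiny_config()
  s <- ref_subject(age = 63, sex = "female", scan_focus = -0.4)
  scan <- sample_eye(s, "OD", cfg, seed = 7)
  vals <- analyze_eye(scan, cfg, what = "whole")
  for (l in ALL_LAYERS) {
    expect_lt(abs(vals[[l]] - layer_mean_model(s, l, cfg)), 0.5)
  }
})

test_that("generated cohorts have the expected eye counts and are reproducible", {
  cfg <- tiny_config(n_subjects = 2L, both_eyes_prob = 1)
  dir <- file.path(tempdir(), "cohort_a")
  unlink(dir, recursive = TRUE)
  meta <- generate_cohort(cfg, dir, seed = 5)
  expect_equal(nrow(meta), 4L)
  expect_length(list.files(file.path(dir, "scans")), 4L)
  # regeneration is byte-identical
  dir2 <- file.path(tempdir(), "cohort_b")
  unlink(dir2, recursive = TRUE)
  generate_cohort(cfg, dir2, seed = 5)
  expect_identical(readLines(file.path(dir, "metadata.csv")),
                   readLines(file.path(dir2, "metadata.csv")))
  f <- list.files(file.path(dir, "scans"))[1]
  expect_identical(readLines(file.path(dir, "scans", f)),
                   readLines(file.path(dir2, "scans", f)))
  # expected eye count: 444 subjects with p = 411/444 -> 855 expected
  co <- simulate_cohort(oct_config(), seed = 2)
  expect_lt(abs(nrow(co$eyes) - 855), 5 * sqrt(444 * (411 / 444) * (33 / 444)) + 1)
})

test_that("layer reference means are internally consistent", {
  le <- default_layer_effects()
  mu <- le$mean[le$parameter != "TRT"]
  trt <- le$mean[le$parameter == "TRT"]
  # renormalization makes the sum exact; raw derived means agree within 1%
  expect_equal(sum(mu), trt, tolerance = 1e-12)
  raw <- c(0.22 / 0.0069, 1.77 / 0.0241, 0.45 / 0.0131, 0.66 / 0.0073,
           0.45 / 0.0056)
  expect_lt(abs(sum(raw) - trt) / trt, 0.01)
})
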