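# Shared fixtures: tiny configurations and analytic surfaces built in code.

# A small, fast configuration (few subjects, noiseless and centered unless
# overridden) for unit tests that exercise the machinery rather than the
# statistics.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 3L, noise_scale = 0, fixation_offset_max = 0)
  do.call(oct_config, utils::modifyList(defaults, args))
}

# One synthetic subject with fixed covariates.
ref_subject <- function(age = 40, sex = "female", scan_focus = 0) {
  s <- data.frame(subject_id = "S0001", age = age, sex = sex,
                  scan_focus = scan_focus, stringsAsFactors = FALSE)
  for (p in c(octmorph::LAYERS, "cft", "rim_height", "rim_radius")) {
    s[[paste0("intercept_", p)]] <- 0
  }
  s
}

# Build a scan data.frame from an analytic thickness function f(x, y) -> um,
# sampled on a protocol raster. All thickness goes into ONPL plus a flat
# ELM_BM floor so the additivity invariant holds.
analytic_scan <- function(f, protocol = "standard", eye = "OD") {
  p <- list(standard = c(25L, 512L), highres = c(97L, 1024L))[[protocol]]
  x <- seq(-3, 3, length.out = p[2])
  y <- seq(-3, 3, length.out = p[1])
  d <- expand.grid(x_mm = x, y_mm = y)
  trt <- f(d$x_mm, d$y_mm)
  stopifnot(all(trt >= 0))
  floor_um <- min(80, min(trt))
  d$RNFL <- 0; d$GCIPL <- 0; d$INL <- 0
  d$ONPL <- trt - floor_um
  d$ELM_BM <- floor_um
  d$TRT <- trt
  attr(d, "eye") <- eye
  attr(d, "protocol") <- protocol
  d
}

# Default pit-surface parameters matching the generator's reference values.
default_pit <- function(...) {
  utils::modifyList(list(cft = 230.3, rim_height = 350.8,
                         rim_radius = 1.134, shape = 2,
                         radius_mod = 0, height_mod = 0), list(...))
}

# Radial profile object built directly from an analytic radial function
# g(r, theta) -> um (no raster, no interpolation).
analytic_profile <- function(g, n_angles = 24L, r_max = 2, dr = 0.1) {
  angles <- seq(0, 360, length.out = n_angles + 1L)[seq_len(n_angles)]
  radii <- seq(0, r_max, by = dr)
  trt <- outer(angles * pi / 180, radii, g)
  trt[, 1] <- trt[1, 1]
  structure(list(angles_deg = angles, radii_mm = radii, trt = trt),
            class = "radial_profile")
}

# Independent brute-force LOESS oracle: per-point weighted least squares
# with tricube weights over the nearest ceil(span*n) neighbours.
loess_oracle <- function(r, v, span = 0.5, degree = 2L) {
  n <- length(r)
  q <- max(ceiling(span * n), degree + 1L)
  sapply(seq_len(n), function(i) {
    d <- abs(r - r[i])
    dq <- sort(d)[q]
    w <- (1 - pmin(d / dq, 1)^3)^3
    keep <- w > 0
    fit <- stats::lm(v[keep] ~ poly(d2 <- (r[keep] - r[i]), degree,
                                    raw = TRUE), weights = w[keep])
    unname(stats::coef(fit)[1])
  })
}

# True centered age-model coefficients (b1, b2) injected by the generator
# for a thickness parameter; TRT is the sum of the five layers' models
# (which mix linear and quadratic forms).
true_centered_coefs <- function(cfg, parameter) {
  le <- cfg$layer_effects
  one <- function(row) {
    if (row$quadratic) c(0.9 * row$age, 0.0025 * row$age)
    else c(row$age, 0)
  }
  if (parameter == "TRT") {
    rows <- le[le$parameter != "TRT", ]
    Reduce(`+`, lapply(seq_len(nrow(rows)), function(i) one(rows[i, ])))
  } else {
    one(le[le$parameter == parameter, ])
  }
}
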