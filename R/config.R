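#' Retinal layers analyzed by the package
#'
#' The five non-overlapping segmented layers (their sum is the total retinal
#' thickness, TRT): retinal nerve fiber layer (RNFL), ganglion cell-inner
#' plexiform layer (GCIPL), inner nuclear layer (INL), outer nuclear and
#' plexiform layer (ONPL), and external limiting membrane-Bruch's membrane
#' complex (ELM_BM).
#' @export
LAYERS <- c("RNFL", "GCIPL", "INL", "ONPL", "ELM_BM")

#' @rdname LAYERS
#' @export
ALL_LAYERS <- c("TRT", LAYERS)

#' Foveal pit morphology parameters
#' @export
PIT_PARAMS <- c("cft", "rim_height", "rim_radius", "mean_slope")

# Reference age (years) at which the age effect is centered. Layer reference
# means are therefore the expected values at age 40, which keeps the percent
# normalization against the young group (age <= 40) consistent by design.
REF_AGE <- 40

# Acquisition raster protocols: B-scans are horizontal lines (constant y),
# A-scans are samples along x. Both cover a 6 x 6 mm field.
PROTOCOLS <- list(
  standard = list(n_bscans = 25L, n_ascans = 512L),
  highres  = list(n_bscans = 97L, n_ascans = 1024L)
)

# Default fixed-effect configuration for the six thickness parameters.
# Reference means (um, at age 40) are derived as the ratio of the absolute to
# the percent effect coefficient of the normative tables this generator
# emulates; the five layer means are renormalized so they sum exactly to the
# TRT mean. `age` is the combined 40-80 effect in um per YEAR; layers flagged
# quadratic split it as b1 = 0.9*age, b2 = 0.0025*age (centered at age 40)
# so the quadratic term carries 10% of the combined effect. `sex` is the
# male - female difference in um; `sf` the scan-focus slope in um/diopter
# (1 um/D in total, allocated proportionally to the layer means). `r2` is the
# marginal R-squared (percent) that the noise calibration targets.
default_layer_effects <- function() {
  mu_raw <- c(RNFL = 0.22 / 0.0069, GCIPL = 1.77 / 0.0241,
              INL = 0.45 / 0.0131, ONPL = 0.66 / 0.0073,
              ELM_BM = 0.45 / 0.0056)
  mu_trt <- 3.25 / 0.0105
  mu <- mu_raw * mu_trt / sum(mu_raw)
  d <- data.frame(
    parameter = LAYERS,
    mean = as.numeric(mu),
    age = c(0.022, -0.177, -0.045, -0.066, -0.045),
    quadratic = c(FALSE, TRUE, TRUE, FALSE, TRUE),
    sex = c(-0.03, 0.57, 0.87, 1.80, 0.93),
    sf = as.numeric(mu / mu_trt),
    r2 = c(0.2, 11.9, 7.1, 2.6, 6.0),
    stringsAsFactors = FALSE
  )
  trt <- data.frame(
    parameter = "TRT", mean = mu_trt, age = sum(d$age),
    quadratic = TRUE, sex = sum(d$sex), sf = 1, r2 = 8.2,
    stringsAsFactors = FALSE
  )
  rbind(trt, d)
}

# Default effect configuration for the foveal pit surface parameters.
# Units: cft and rim_height in um, rim_radius in um (converted to mm when
# building surfaces). Means again derived as absolute/percent coefficient
# ratios. The mean slope is not listed: it is an emergent property of the
# surface, not an injectable parameter.
default_pit_effects <- function() {
  data.frame(
    parameter = c("cft", "rim_height", "rim_radius"),
    mean = c(7.99 / 0.0347, 8.63 / 0.0246, 59.4 / 0.0524),
    age = c(-0.144, -0.342, -0.766),
    quadratic = c(TRUE, TRUE, FALSE),
    sex = c(7.99, 8.63, -59.4),
    sf = c(1, 1, 1),
    r2 = c(4.8, 11.9, 8.4),
    stringsAsFactors = FALSE
  )
}

# Centered age-model coefficients (b1, b2) for one effect row.
age_coefs <- function(row) {
  if (row$quadratic) c(b1 = 0.9 * row$age, b2 = 0.0025 * row$age)
  else c(b1 = row$age, b2 = 0)
}

# Raw moments E[(age - 40)^k], k = 1..4, of the bucket-uniform age mixture.
age_moments <- function(breaks, weights) {
  w <- weights / sum(weights)
  mom <- numeric(4)
  for (k in 1:4) {
    per <- mapply(function(lo, hi) {
      ((hi - REF_AGE)^(k + 1) - (lo - REF_AGE)^(k + 1)) / ((k + 1) * (hi - lo))
    }, breaks[-length(breaks)], breaks[-1])
    mom[k] <- sum(w * per)
  }
  mom
}

# Variance of the fixed-effect predictor for one parameter under the
# generator's demographic structure (used to calibrate noise to a target
# marginal R-squared).
fixed_effect_variance <- function(row, config) {
  m <- age_moments(config$age_breaks, config$age_bucket_weights)
  b <- age_coefs(row)
  var_age <- b["b1"]^2 * (m[2] - m[1]^2) +
    b["b2"]^2 * (m[4] - m[2]^2) +
    2 * b["b1"] * b["b2"] * (m[3] - m[1] * m[2])
  p_male <- 1 - config$female_fraction
  unname(var_age + row$sex^2 * p_male * (1 - p_male) +
           row$sf^2 * config$scan_focus_sd^2)
}

# Solve intercept/residual SDs so the parameter's marginal R-squared equals
# its target, keeping the 196:36 intercept:residual variance split (the
# ratio of the TRT defaults). Used for the pit parameters, whose noise
# levels are not pinned directly.
calibrate_noise <- function(row, config) {
  vf <- fixed_effect_variance(row, config)
  noise <- vf * (100 / row$r2 - 1)
  c(intercept_sd = sqrt(noise * 196 / 232), resid_sd = sqrt(noise * 36 / 232))
}

# TRT noise defaults (um): subject random intercept and eye-level residual.
TRT_INTERCEPT_SD <- 14
TRT_RESID_SD <- 6

#' Build a synthetic cohort generator configuration
#'
#' Assembles demographic structure, per-parameter effect models, calibrated
#' noise levels and acquisition options for [simulate_cohort()] and friends.
#' Defaults emulate the normative study conditions this package validates
#' against: 444 subjects (855 eyes expected), ages 21-88 drawn uniformly
#' within four buckets weighted 51/212/161/8, 63% female, and effect sizes
#' encoding the documented ground-truth age/sex coefficients.
#'
#' @param n_subjects number of subjects to simulate.
#' @param mode `"grid"` builds each eye's six layers from radial anatomical
#'   templates scaled to the layer mean model (used for thickness analyses);
#'   `"pit"` builds the TRT surface directly from a parametric foveal pit
#'   whose parameters follow their own effect models (used for pit
#'   morphometry analyses).
#' @param protocol acquisition raster: `"standard"` (25 B-scans x 512
#'   A-scans) or `"highres"` (97 x 1024).
#' @param noise_scale multiplier applied to all calibrated noise SDs
#'   (subject intercepts and eye-level residuals); `0` gives a noiseless
#'   cohort for exact-recovery checks.
#' @param fixation_offset_max maximum fixation error radius (mm); per-eye
#'   offsets are uniform in this disc. Set to `0` for perfectly centered
#'   scans.
#' @param both_eyes_prob probability that a subject contributes both eyes
#'   (default 411/444, giving 855 expected eyes for 444 subjects).
#' @param female_fraction,age_bucket_weights,age_breaks demographic
#'   structure; weights must be non-negative and sum to 1 (after the default
#'   normalization).
#' @param scan_focus_sd SD (diopters) of the scan-focus covariate.
#' @param layer_effects,pit_effects effect tables as produced by the
#'   defaults; replace to inject different ground truth.
#' @param grid_nodes,grid_extent_mm analysis grid: `grid_nodes` nodes per
#'   axis spanning `[-grid_extent_mm, grid_extent_mm]`.
#' @param pit_shape shape exponent `a` of the radial pit profile
#'   (must be > 0).
#' @param pit_radius_mod,pit_height_mod amplitude of the `cos(2*theta)`
#'   angular modulation of rim radius and rim height (the pit is broader
#'   horizontally).
#' @param loess_span,loess_degree smoothing options for the radial profiles.
#' @param alpha significance level for corrected tests.
#' @return an object of class `"oct_config"` (a named list).
#' @export
oct_config <- function(n_subjects = 444L,
                       mode = c("grid", "pit"),
                       protocol = c("standard", "highres"),
                       noise_scale = 1,
                       fixation_offset_max = 0.3,
                       both_eyes_prob = 411 / 444,
                       female_fraction = 281 / 444,
                       age_bucket_weights = c(51, 212, 161, 8) / 432,
                       age_breaks = c(21, 40, 60, 80, 88),
                       scan_focus_sd = 1.5,
                       layer_effects = default_layer_effects(),
                       pit_effects = default_pit_effects(),
                       grid_nodes = 300L,
                       grid_extent_mm = 3,
                       pit_shape = 2,
                       pit_radius_mod = 0.10,
                       pit_height_mod = 0.01,
                       loess_span = 0.5,
                       loess_degree = 2L,
                       alpha = 0.05) {
  mode <- match.arg(mode)
  protocol <- match.arg(protocol)
  if (n_subjects < 0) stop("n_subjects must be >= 0")
  if (any(age_bucket_weights < 0) ||
      abs(sum(age_bucket_weights) - 1) > 1e-9) {
    stop("age_bucket_weights must be non-negative and sum to 1")
  }
  for (p in c(both_eyes_prob, female_fraction)) {
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]")
  }
  if (pit_shape <= 0) stop("pit_shape must be > 0")
  if (any(layer_effects$mean <= 0)) stop("reference means must be > 0")
  pe <- pit_effects
  if (pe$mean[pe$parameter == "rim_height"] <=
      pe$mean[pe$parameter == "cft"]) {
    stop("rim height mean must exceed CFT mean")
  }
  rr <- pe$mean[pe$parameter == "rim_radius"] / 1000
  if (rr <= 0 || rr > 2) stop("rim radius mean must lie in (0, 2] mm")
  cfg <- list(
    n_subjects = as.integer(n_subjects), mode = mode, protocol = protocol,
    noise_scale = noise_scale, fixation_offset_max = fixation_offset_max,
    both_eyes_prob = both_eyes_prob, female_fraction = female_fraction,
    age_bucket_weights = age_bucket_weights, age_breaks = age_breaks,
    scan_focus_sd = scan_focus_sd,
    layer_effects = layer_effects, pit_effects = pit_effects,
    grid_nodes = as.integer(grid_nodes), grid_extent_mm = grid_extent_mm,
    pit_shape = pit_shape, pit_radius_mod = pit_radius_mod,
    pit_height_mod = pit_height_mod,
    loess_span = loess_span, loess_degree = as.integer(loess_degree),
    alpha = alpha
  )
  class(cfg) <- "oct_config"
  # Thickness noise: the TRT subject intercept (14 um) and eye residual
  # (6 um) are fixed defaults; each layer's SDs scale with its reference
  # mean, normalized so the five independent layer noises sum (in variance)
  # exactly to the TRT values (TRT is structurally the layer sum).
  le <- cfg$layer_effects
  lay_i <- which(le$parameter != "TRT")
  share <- le$mean / sqrt(sum(le$mean[lay_i]^2))
  le$intercept_sd <- TRT_INTERCEPT_SD * share * noise_scale
  le$resid_sd <- TRT_RESID_SD * share * noise_scale
  le$intercept_sd[le$parameter == "TRT"] <- TRT_INTERCEPT_SD * noise_scale
  le$resid_sd[le$parameter == "TRT"] <- TRT_RESID_SD * noise_scale
  cfg$layer_effects <- le
  pcal <- t(vapply(seq_len(nrow(pe)),
                   function(i) calibrate_noise(pe[i, ], cfg), numeric(2)))
  pe$intercept_sd <- pcal[, 1] * noise_scale
  pe$resid_sd <- pcal[, 2] * noise_scale
  cfg$pit_effects <- pe
  cfg
}

#' @export
print.oct_config <- function(x, ...) {
  cat("<oct_config>", x$mode, "mode,", x$n_subjects, "subjects,",
      x$protocol, "protocol\n")
  cat("  grid:", x$grid_nodes, "x", x$grid_nodes, "nodes over +/-",
      x$grid_extent_mm, "mm\n")
  cat("  noise_scale:", x$noise_scale,
      " fixation offset <=", x$fixation_offset_max, "mm\n")
  invisible(x)
}

#' Write / read a generator configuration as YAML
#'
#' Only the scalar and effect-table fields are serialized; [read_config()]
#' rebuilds the object through [oct_config()] so validation and noise
#' calibration are re-applied.
#' @param config an `oct_config` object.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  keep <- setdiff(names(config), c("layer_effects", "pit_effects"))
  out <- config[keep]
  out$layer_effects <- as.list(
    config$layer_effects[, c("parameter", "mean", "age", "quadratic",
                             "sex", "sf", "r2")])
  out$pit_effects <- as.list(
    config$pit_effects[, c("parameter", "mean", "age", "quadratic",
                           "sex", "sf", "r2")])
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  le <- as.data.frame(raw$layer_effects, stringsAsFactors = FALSE)
  pe <- as.data.frame(raw$pit_effects, stringsAsFactors = FALSE)
  raw$layer_effects <- le
  raw$pit_effects <- pe
  raw$age_bucket_weights <- as.numeric(raw$age_bucket_weights)
  raw$age_breaks <- as.numeric(raw$age_breaks)
  do.call(oct_config, raw)
}
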