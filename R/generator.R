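# Synthetic cohort generator: segmented-OCT eyes with known ground-truth
# age and sex effects, for end-to-end validation of the analysis pipeline.

#' Sample subject demographics
#'
#' Draws ages uniformly within the age bucket selected by the configured
#' bucket weights, sex as Bernoulli(female_fraction), scan focus as
#' Normal(0, scan_focus_sd), and one subject-level random intercept per
#' noise-bearing parameter (five layers in grid mode; CFT, rim height and
#' rim radius in pit mode).
#'
#' @param config an [oct_config()] object.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a data.frame with one row per subject: `subject_id`, `age`
#'   (years), `sex` (`"female"`/`"male"`), `scan_focus` (diopters) and one
#'   `intercept_*` column per parameter (um).
#' @export
sample_demographics <- function(config, seed = 1L) {
  n <- config$n_subjects
  noise_rows <- if (config$mode == "grid") {
    config$layer_effects[config$layer_effects$parameter != "TRT", ]
  } else {
    config$pit_effects
  }
  with_seed(seed, {
    if (n == 0L) {
      d <- data.frame(subject_id = character(0), age = numeric(0),
                      sex = character(0), scan_focus = numeric(0),
                      stringsAsFactors = FALSE)
      for (p in noise_rows$parameter) d[[paste0("intercept_", p)]] <- numeric(0)
      return(d)
    }
    nb <- length(config$age_bucket_weights)
    bucket <- sample.int(nb, n, replace = TRUE,
                         prob = config$age_bucket_weights)
    lo <- config$age_breaks[bucket]
    hi <- config$age_breaks[bucket + 1L]
    age <- stats::runif(n, lo, hi)
    sex <- ifelse(stats::runif(n) < config$female_fraction,
                  "female", "male")
    sf <- stats::rnorm(n, 0, config$scan_focus_sd)
    d <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex, scan_focus = sf, stringsAsFactors = FALSE
    )
    for (i in seq_len(nrow(noise_rows))) {
      p <- noise_rows$parameter[i]
      d[[paste0("intercept_", p)]] <-
        stats::rnorm(n, 0, noise_rows$intercept_sd[i])
    }
    d
  })
}

#' Expected whole-macula layer mean for one subject
#'
#' Implements the forward mean model
#' `mu + b1*(age - 40) + b2*(age - 40)^2 + beta_sex*isMale +
#'  beta_sf*scanFocus + subject_intercept`,
#' with age centered at 40 years so `mu` is the young-reference mean.
#'
#' @param subject one row of [sample_demographics()] output (or a list with
#'   `age`, `sex`, `scan_focus` and optionally `intercept_<layer>`).
#' @param layer one of `r paste(ALL_LAYERS, collapse = ", ")`. The TRT value
#'   is the sum of the five layer models.
#' @param config an [oct_config()] object.
#' @return expected whole-macula mean thickness (um).
#' @export
layer_mean_model <- function(subject, layer, config) {
  if (layer == "TRT") {
    return(sum(vapply(LAYERS, layer_mean_model, numeric(1),
                      subject = subject, config = config)))
  }
  le <- config$layer_effects
  row <- le[le$parameter == layer, ]
  if (nrow(row) != 1L) stop("unknown layer: ", layer)
  effect_model(subject, row, paste0("intercept_", layer))
}

# Shared fixed-effect + intercept evaluation for one effect-table row.
effect_model <- function(subject, row, intercept_col) {
  b <- age_coefs(row)
  a <- subject$age - REF_AGE
  gamma <- subject[[intercept_col]]
  if (is.null(gamma)) gamma <- 0
  row$mean + b[["b1"]] * a + b[["b2"]] * a^2 +
    row$sex * (subject$sex == "male") +
    row$sf * subject$scan_focus + gamma
}

#' Parametric foveal pit surface
#'
#' Total retinal thickness as a function of polar position:
#' `T(r, theta) = CFT + (RimHeight(theta) - CFT) * g(r / RimRadius(theta))`
#' with the radial template `g(u) = u^a * exp(a * (1 - u))`, which satisfies
#' `g(0) = 0`, `g(1) = 1`, has its unique maximum at `u = 1` and decays
#' smoothly beyond it. Rim height and rim radius may carry a `cos(2*theta)`
#' modulation making the pit broader horizontally (`theta = 0` is the
#' horizontal/nasal direction in the right-eye frame).
#'
#' @param r radial distance from the foveal center (mm, `>= 0`).
#' @param theta angular direction (radians).
#' @param params list with `cft` (um), `rim_height` (um), `rim_radius` (mm),
#'   `shape` (`a > 0`), and optional `radius_mod`, `height_mod` modulation
#'   amplitudes.
#' @return TRT values (um) of the same length as `r`.
#' @export
pit_surface <- function(r, theta, params) {
  if (is.null(params$shape) || params$shape <= 0) {
    stop("pit shape parameter must be > 0")
  }
  if (any(r < 0)) stop("r must be >= 0")
  rmod <- if (is.null(params$radius_mod)) 0 else params$radius_mod
  hmod <- if (is.null(params$height_mod)) 0 else params$height_mod
  R <- params$rim_radius * (1 + rmod * cos(2 * theta))
  H <- params$rim_height * (1 + hmod * cos(2 * theta))
  a <- params$shape
  u <- r / R
  g <- ifelse(u == 0, 0, exp(a * log(u) + a * (1 - u)))
  params$cft + (H - params$cft) * g
}

# Per-eye ground-truth pit parameters (pit mode): each of CFT, rim height
# and rim radius follows its own effect model plus subject intercept; the
# eye-level residual is added by sample_eye.
pit_truth <- function(subject, config) {
  pe <- config$pit_effects
  vals <- vapply(seq_len(nrow(pe)), function(i) {
    effect_model(subject, pe[i, ],
                 paste0("intercept_", pe$parameter[i]))
  }, numeric(1))
  names(vals) <- pe$parameter
  vals
}

# ---- Radial layer templates (grid mode) -----------------------------------
# Invented anatomical stand-ins: inner layers (RNFL, GCIPL, INL) are near
# zero centrally with annular maxima; ONPL is centrally peaked; ELM_BM is
# near flat. Each template is normalized so its unweighted mean over the
# 3 mm radius disc is 1; an eye's layer field is the template times the
# eye's target whole-macula mean.

layer_template_raw <- function(layer, r) {
  # smooth step from 0 to 1 around `at` (inner layers vanish centrally)
  rise <- function(r, at, width = 0.08) 0.5 * (1 + tanh((r - at) / width))
  switch(layer,
    RNFL   = (r / 3)^3,
    GCIPL  = rise(r, 0.52) * (0.55 + 0.9 * exp(-((r - 1.0) / 1.1)^2)),
    INL    = rise(r, 0.55) * (0.60 + 0.8 * exp(-((r - 1.2) / 1.2)^2)),
    ONPL   = 1 + 0.75 * exp(-((r - 0.45) / 0.8)^2),
    ELM_BM = 1 + 0.05 * exp(-(r / 1.2)^2),
    stop("unknown layer: ", layer)
  )
}

# Disc means (r <= 3 mm) of the raw templates, computed once by radial
# quadrature with the 2*pi*r area weight.
template_disc_means <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      r <- seq(0, 3, length.out = 3001L)
      cache <<- vapply(LAYERS, function(l) {
        f <- layer_template_raw(l, r)
        sum((f * r)[-1] + (f * r)[-length(r)]) / 2 * diff(r)[1] * 2 / 9
      }, numeric(1))
    }
    cache
  }
})

# Normalized template value (disc mean 1).
layer_template <- function(layer, r) {
  layer_template_raw(layer, r) / template_disc_means()[[layer]]
}

# Raster sample positions (device frame, mm) for a protocol.
raster_positions <- function(protocol) {
  p <- PROTOCOLS[[protocol]]
  if (is.null(p)) stop("unknown protocol: ", protocol)
  x <- seq(-3, 3, length.out = p$n_ascans)
  y <- seq(-3, 3, length.out = p$n_bscans)
  list(x = rep(x, times = p$n_bscans), y = rep(y, each = p$n_ascans))
}

# Evaluate an eye's true thickness fields at device-frame positions.
# `truth` holds the fovea offset, laterality sign and either per-layer
# target means (grid mode) or pit parameters (pit mode).
eval_eye_surface <- function(xs, ys, truth, config) {
  # anatomical (right-eye, fovea-centered) coordinates
  ax <- truth$mirror_sign * (xs - truth$offset[1])
  ay <- ys - truth$offset[2]
  r <- sqrt(ax^2 + ay^2)
  out <- matrix(0, length(xs), length(LAYERS),
                dimnames = list(NULL, LAYERS))
  if (truth$mode == "grid") {
    for (l in LAYERS) {
      out[, l] <- truth$layer_means[[l]] * layer_template(l, r)
    }
  } else {
    theta <- atan2(ay, ax)
    trt <- pit_surface(r, theta, truth$pit)
    # Synthetic layer decomposition keeping TRT = sum(layers) and all >= 0:
    # flat ELM_BM floor, remainder in ONPL, inner layers zero.
    floor_um <- min(80, min(trt))
    out[, "ELM_BM"] <- floor_um
    out[, "ONPL"] <- trt - floor_um
  }
  out
}

#' Simulate one eye's segmented scan
#'
#' Builds the eye's true thickness surface (layer templates scaled to the
#' subject's layer mean model plus an eye-level residual in grid mode, or a
#' parametric pit surface in pit mode), applies a random fixation offset
#' (uniform in a disc of radius `fixation_offset_max`), mirrors OS eyes in
#' x, and samples the surface on the protocol raster.
#'
#' @param subject one row of [sample_demographics()].
#' @param eye `"OD"` (right) or `"OS"` (left).
#' @param config an [oct_config()] object.
#' @param seed integer seed for the eye-level random draws.
#' @return a `data.frame` scan with columns `x_mm`, `y_mm`, the five layers
#'   and `TRT` (um), and attributes `subject_id`, `eye`, `protocol` and
#'   `truth` (the generating parameters, used by [resample_protocol()]).
#' @export
sample_eye <- function(subject, eye = "OD", config, seed = 1L) {
  stopifnot(eye %in% c("OD", "OS"))
  truth <- with_seed(seed, {
    off <- c(0, 0)
    if (config$fixation_offset_max > 0) {
      repeat {
        off <- stats::runif(2, -config$fixation_offset_max,
                            config$fixation_offset_max)
        if (sum(off^2) <= config$fixation_offset_max^2) break
      }
    }
    tr <- list(mode = config$mode, offset = off,
               mirror_sign = if (eye == "OS") -1 else 1)
    if (config$mode == "grid") {
      le <- config$layer_effects[config$layer_effects$parameter != "TRT", ]
      means <- lapply(seq_len(nrow(le)), function(i) {
        layer_mean_model(subject, le$parameter[i], config) +
          stats::rnorm(1, 0, le$resid_sd[i])
      })
      names(means) <- le$parameter
      if (any(unlist(means) <= 0)) stop("negative layer mean generated")
      tr$layer_means <- means
    } else {
      pe <- config$pit_effects
      pv <- pit_truth(subject, config) +
        stats::rnorm(nrow(pe), 0, pe$resid_sd)
      tr$pit <- list(cft = pv[["cft"]], rim_height = pv[["rim_height"]],
                     rim_radius = pv[["rim_radius"]] / 1000,
                     shape = config$pit_shape,
                     radius_mod = config$pit_radius_mod,
                     height_mod = config$pit_height_mod)
      if (tr$pit$rim_height <= tr$pit$cft || tr$pit$rim_radius <= 0) {
        stop("degenerate pit parameters generated")
      }
    }
    tr
  })
  build_scan(truth, subject$subject_id, eye, config$protocol, config)
}

# Evaluate a truth object on a protocol raster and package it as a scan.
build_scan <- function(truth, subject_id, eye, protocol, config) {
  pos <- raster_positions(protocol)
  vals <- eval_eye_surface(pos$x, pos$y, truth, config)
  scan <- data.frame(x_mm = pos$x, y_mm = pos$y)
  for (l in LAYERS) scan[[l]] <- vals[, l]
  scan$TRT <- rowSums(vals)
  attr(scan, "subject_id") <- subject_id
  attr(scan, "eye") <- eye
  attr(scan, "protocol") <- protocol
  attr(scan, "truth") <- truth
  scan
}

#' Simulate a full cohort in memory
#'
#' Samples demographics, assigns each subject two eyes with probability
#' `both_eyes_prob` (one eye, OD or OS at random, otherwise), and returns
#' the scan-generation plan. Scans themselves are built lazily by
#' [analyze_cohort()] / [generate_cohort()] via [sample_eye()] so a full
#' cohort never needs to be held in memory at once.
#'
#' @param config an [oct_config()] object.
#' @param seed integer seed.
#' @return a list with `subjects` (demographics data.frame), `eyes`
#'   (data.frame with `subject_id`, `eye`, `eye_seed`), and `config`.
#' @export
simulate_cohort <- function(config, seed = 1L) {
  subjects <- sample_demographics(config, seed = seed)
  eyes <- with_seed(sub_seed(seed, 1L), {
    n <- nrow(subjects)
    if (n == 0L) {
      data.frame(subject_id = character(0), eye = character(0),
                 stringsAsFactors = FALSE)
    } else {
      both <- stats::runif(n) < config$both_eyes_prob
      single <- ifelse(stats::runif(n) < 0.5, "OD", "OS")
      do.call(rbind, lapply(seq_len(n), function(i) {
        ee <- if (both[i]) c("OD", "OS") else single[i]
        data.frame(subject_id = subjects$subject_id[i], eye = ee,
                   stringsAsFactors = FALSE)
      }))
    }
  })
  if (nrow(eyes)) {
    eyes$eye_seed <- vapply(seq_len(nrow(eyes)), function(i) {
      sub_seed(seed, 100L + i)
    }, integer(1))
  } else {
    eyes$eye_seed <- integer(0)
  }
  list(subjects = subjects, eyes = eyes, config = config, seed = seed)
}

#' Write a synthetic cohort to disk
#'
#' Writes `metadata.csv` (one row per eye), one scan CSV per eye under
#' `scans/`, and `ground_truth.yaml` logging the generator configuration.
#'
#' @param config an [oct_config()] object.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, the metadata table.
#' @export
generate_cohort <- function(config, out_dir, seed = 1L) {
  cohort <- simulate_cohort(config, seed = seed)
  dir.create(file.path(out_dir, "scans"), recursive = TRUE,
             showWarnings = FALSE)
  meta <- cohort_metadata(cohort)
  write_cohort_metadata(meta, file.path(out_dir, "metadata.csv"))
  write_config(config, file.path(out_dir, "ground_truth.yaml"))
  for (i in seq_len(nrow(cohort$eyes))) {
    e <- cohort$eyes[i, ]
    subject <- cohort$subjects[cohort$subjects$subject_id == e$subject_id, ]
    scan <- sample_eye(subject, e$eye, config, seed = e$eye_seed)
    write_scan(scan, file.path(out_dir, "scans",
                               paste0(e$subject_id, "_", e$eye, ".csv")))
  }
  invisible(meta)
}

# Per-eye metadata table (one row per eye).
cohort_metadata <- function(cohort) {
  eyes <- cohort$eyes
  sub <- cohort$subjects[match(eyes$subject_id, cohort$subjects$subject_id), ]
  data.frame(
    subject_id = eyes$subject_id, eye = eyes$eye,
    age_years = sub$age, sex = sub$sex, scan_focus_D = sub$scan_focus,
    protocol = cohort$config$protocol, stringsAsFactors = FALSE
  )
}

#' Simulate eye-level parameter values without rasterization
#'
#' Draws the same ground-truth eye-level parameter values that
#' [sample_eye()] injects (mean model + subject intercept + eye residual)
#' but skips surface construction and measurement entirely. Used for
#' statistics-level simulations (noiseless recovery, type-I calibration)
#' where the measurement stage is not under study.
#'
#' @param config an [oct_config()] object.
#' @param seed integer seed.
#' @return a long-format parameter table (see [analyze_cohort()]): columns
#'   `subject_id`, `eye`, `age_years`, `sex`, `scan_focus_D`, `protocol`,
#'   `parameter`, `value`.
#' @export
simulate_parameter_table <- function(config, seed = 1L) {
  cohort <- simulate_cohort(config, seed = seed)
  eyes <- cohort$eyes
  sub <- cohort$subjects[match(eyes$subject_id, cohort$subjects$subject_id), ]
  rows <- if (config$mode == "grid") {
    config$layer_effects[config$layer_effects$parameter != "TRT", ]
  } else {
    config$pit_effects
  }
  vals <- with_seed(sub_seed(cohort$seed, 2L), {
    sapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      mu <- vapply(seq_len(nrow(eyes)), function(k) {
        effect_model(sub[k, ], r, paste0("intercept_", r$parameter))
      }, numeric(1))
      mu + stats::rnorm(nrow(eyes), 0, r$resid_sd)
    })
  })
  vals <- matrix(vals, nrow = nrow(eyes))
  colnames(vals) <- rows$parameter
  out <- data.frame(
    subject_id = rep(eyes$subject_id, times = ncol(vals)),
    eye = rep(eyes$eye, times = ncol(vals)),
    age_years = rep(sub$age, times = ncol(vals)),
    sex = rep(sub$sex, times = ncol(vals)),
    scan_focus_D = rep(sub$scan_focus, times = ncol(vals)),
    protocol = config$protocol,
    parameter = rep(colnames(vals), each = nrow(eyes)),
    value = as.numeric(vals), stringsAsFactors = FALSE
  )
  if (config$mode == "grid") {
    trt <- stats::aggregate(value ~ subject_id + eye, data = out, FUN = sum)
    trt_rows <- out[out$parameter == out$parameter[1], ]
    key <- paste(trt_rows$subject_id, trt_rows$eye)
    trt_rows$parameter <- "TRT"
    trt_rows$value <- trt$value[match(key, paste(trt$subject_id, trt$eye))]
    out <- rbind(out, trt_rows)
  }
  rownames(out) <- NULL
  out
}
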