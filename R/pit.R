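# Foveal pit morphometry: LOESS-smoothed radial profiles, per-direction
# rim detection, and whole-macula aggregation.

#' Locally weighted quadratic smoothing (LOESS) of a radial profile
#'
#' At each radius the fitted value of a weighted polynomial regression
#' (degree 2 by default) over the nearest `ceiling(span * n)` neighbours,
#' with tricube weights on distance scaled by the furthest included
#' neighbour. With `span = 1` and degree 2 this reduces to a global
#' quadratic fit; polynomials up to the local degree are reproduced
#' exactly.
#'
#' @param r radii (mm), strictly increasing.
#' @param values thickness values (um) at `r`.
#' @param span fraction of points in each local neighbourhood (default 0.5).
#' @param degree local polynomial degree.
#' @return smoothed values at `r`.
#' @export
loess_smooth <- function(r, values, span = 0.5, degree = 2L) {
  n <- length(r)
  stopifnot(length(values) == n)
  if (n < 5L) stop("need at least 5 points per direction")
  if (any(diff(r) <= 0)) stop("radii must be strictly increasing")
  q <- ceiling(span * n)
  q <- max(q, degree + 1L)
  vapply(seq_len(n), function(i) {
    d <- abs(r - r[i])
    dq <- sort(d, partial = q)[q]
    if (dq == 0) stop("duplicated radii give a singular local fit")
    w <- (1 - pmin(d / dq, 1)^3)^3
    keep <- w > 0
    X <- outer(r[keep] - r[i], 0:degree, "^")
    fit <- stats::lm.wfit(X, values[keep], w[keep])
    if (anyNA(fit$coefficients)) stop("singular local design in LOESS fit")
    fit$coefficients[[1L]]
  }, numeric(1))
}

#' Per-direction foveal pit parameters
#'
#' For each angular direction of a radial TRT profile:
#' * CFT: the raw (unsmoothed) TRT at r = 0, shared across directions;
#' * rim: the arg-max of the LOESS-smoothed TRT over r in (0, 2] (ties go
#'   to the smallest radius); `rim_height` is the smoothed TRT there and
#'   `rim_radius` the corresponding radius;
#' * mean slope: the mean over the forward-difference steps between r = 0
#'   and the rim of `atan(dT/dr)` in degrees (thickness converted to mm),
#'   computed on the unsmoothed profile.
#'
#' Directions whose arg-max falls on the outermost radius are flagged
#' `rim_at_boundary`.
#'
#' @param profile a [radial_resample()] object.
#' @param span,degree LOESS options (see [loess_smooth()]).
#' @return an object of class `"pit_result"`: list with `cft_um` and a
#'   per-direction data.frame `directions` (`angle_deg`, `rim_height_um`,
#'   `rim_radius_mm`, `mean_slope_deg`, `rim_at_boundary`), plus the
#'   smoothed profile matrix.
#' @export
pit_params <- function(profile, span = 0.5, degree = 2L) {
  r <- profile$radii_mm
  nd <- length(profile$angles_deg)
  smoothed <- t(vapply(seq_len(nd), function(i) {
    loess_smooth(r, profile$trt[i, ], span = span, degree = degree)
  }, numeric(length(r))))
  cft <- profile$trt[1L, 1L]
  dirs <- lapply(seq_len(nd), function(i) {
    sm <- smoothed[i, ]
    k <- which.max(sm[-1L]) + 1L  # arg-max over r > 0; ties -> smallest r
    raw <- profile$trt[i, ]
    steps <- atan(diff(raw[1:k]) / diff(r[1:k]) / 1000) * 180 / pi
    data.frame(angle_deg = profile$angles_deg[i],
               rim_height_um = sm[k], rim_radius_mm = r[k],
               mean_slope_deg = mean(steps),
               rim_at_boundary = k == length(r))
  })
  structure(list(cft_um = cft, directions = do.call(rbind, dirs),
                 smoothed = smoothed, radii_mm = r),
            class = "pit_result")
}

#' Whole-macula foveal pit aggregates
#'
#' Unweighted means of rim height, rim radius and mean slope across the 24
#' directions; the CFT does not vary radially and is passed through. If any
#' direction was flagged `rim_at_boundary` the aggregate carries the flag.
#'
#' @param pit a [pit_params()] result.
#' @return named list: `cft_um`, `rim_height_um`, `rim_radius_mm`,
#'   `mean_slope_deg`, `rim_at_boundary`.
#' @export
aggregate_pit <- function(pit) {
  d <- pit$directions
  list(cft_um = pit$cft_um,
       rim_height_um = mean(d$rim_height_um),
       rim_radius_mm = mean(d$rim_radius_mm),
       mean_slope_deg = mean(d$mean_slope_deg),
       rim_at_boundary = any(d$rim_at_boundary))
}

#' Foveal pit metrics for one normalized scan
#'
#' Convenience wrapper: radial resampling, LOESS smoothing, per-direction
#' pit parameters and whole-macula aggregation.
#'
#' @param samples a normalized (fovea-centered) scan.
#' @param span,degree LOESS options.
#' @return the per-direction `pit_result` with the aggregate attached as
#'   `$aggregate`.
#' @export
fovea_pit_metrics <- function(samples, span = 0.5, degree = 2L) {
  prof <- radial_resample(samples)
  pit <- pit_params(prof, span = span, degree = degree)
  pit$aggregate <- aggregate_pit(pit)
  pit
}

#' Export pit parameters as a tidy table
#'
#' One row per direction plus an `"ALL"` row for the whole-macula
#' aggregate, matching the on-disk pit parameter schema.
#'
#' @param pit a [pit_params()] result (with aggregate).
#' @param subject_id,eye identifiers for the exported rows.
#' @return data.frame with columns `subject_id`, `eye`, `direction_deg`,
#'   `cft_um`, `rim_height_um`, `rim_radius_mm`, `mean_slope_deg`, `flags`.
#' @export
pit_table <- function(pit, subject_id = "", eye = "") {
  if (is.null(pit$aggregate)) pit$aggregate <- aggregate_pit(pit)
  d <- pit$directions
  agg <- pit$aggregate
  rbind(
    data.frame(subject_id = subject_id, eye = eye,
               direction_deg = as.character(d$angle_deg),
               cft_um = pit$cft_um, rim_height_um = d$rim_height_um,
               rim_radius_mm = d$rim_radius_mm,
               mean_slope_deg = d$mean_slope_deg,
               flags = ifelse(d$rim_at_boundary, "rim_at_boundary", ""),
               stringsAsFactors = FALSE),
    data.frame(subject_id = subject_id, eye = eye, direction_deg = "ALL",
               cft_um = agg$cft_um, rim_height_um = agg$rim_height_um,
               rim_radius_mm = agg$rim_radius_mm,
               mean_slope_deg = agg$mean_slope_deg,
               flags = ifelse(agg$rim_at_boundary, "rim_at_boundary", ""),
               stringsAsFactors = FALSE)
  )
}
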