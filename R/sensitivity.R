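# Acquisition-protocol sensitivity analysis: bias of the standard raster
# (25 x 512) relative to the high-resolution raster (97 x 1024).

#' Re-sample an eye's true surface under another protocol
#'
#' Evaluates the same per-eye ground-truth surface (same layer targets or
#' pit parameters, same fixation offset and laterality) on the requested
#' raster, emulating a second acquisition of the same eye.
#'
#' @param scan a generated scan (from [sample_eye()]) carrying its `truth`
#'   attribute.
#' @param protocol `"standard"` or `"highres"`.
#' @param config the [oct_config()] used to generate the scan.
#' @return a scan data.frame on the new raster.
#' @export
resample_protocol <- function(scan, protocol, config) {
  truth <- attr(scan, "truth")
  if (is.null(truth)) stop("scan carries no ground-truth surface")
  if (!protocol %in% names(PROTOCOLS)) stop("unknown protocol: ", protocol)
  build_scan(truth, attr(scan, "subject_id"), attr(scan, "eye"),
             protocol, config)
}

#' Simulate a paired two-protocol cohort and measure it
#'
#' Generates `n_subjects` subjects (both eyes each), acquires every eye
#' under both the standard and the high-resolution protocol from the same
#' true surface, runs the full measurement pipeline on each acquisition,
#' and returns the combined long parameter table.
#'
#' @param config an [oct_config()] object (its `protocol` field is ignored;
#'   both protocols are acquired).
#' @param n_subjects number of subjects (default 12, both eyes).
#' @param seed integer seed.
#' @param what parameter groups to measure (see [analyze_eye()]).
#' @return long parameter table with a `protocol` column distinguishing the
#'   paired acquisitions.
#' @export
simulate_paired_cohort <- function(config, n_subjects = 12L, seed = 1L,
                                   what = c("whole", "pit")) {
  cfg <- config
  cfg$n_subjects <- as.integer(n_subjects)
  cfg$both_eyes_prob <- 1
  cohort <- simulate_cohort(cfg, seed = seed)
  out <- list()
  for (i in seq_len(nrow(cohort$eyes))) {
    e <- cohort$eyes[i, ]
    subject <- cohort$subjects[cohort$subjects$subject_id == e$subject_id, ]
    base <- sample_eye(subject, e$eye, cfg, seed = e$eye_seed)
    for (prot in c("standard", "highres")) {
      scan <- resample_protocol(base, prot, cfg)
      vals <- analyze_eye(scan, cfg, what = what)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = e$subject_id, eye = e$eye,
        age_years = subject$age, sex = subject$sex,
        scan_focus_D = subject$scan_focus, protocol = prot,
        parameter = names(vals), value = as.numeric(vals),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Protocol bias estimates
#'
#' For each parameter, fits the mixed model
#' `value ~ isStandard + (1 | subject)` on the paired table and reports the
#' standard-protocol bias with Wald CI and p-value, plus the percent bias
#' (bias divided by the model intercept, i.e. the high-resolution level).
#'
#' @param paired_table output of [simulate_paired_cohort()] (every eye must
#'   appear under both protocols).
#' @param parameters parameters to analyze.
#' @return data.frame with one row per parameter: `parameter`,
#'   `intercept`, `bias_abs`, `bias_lo`, `bias_hi`, `bias_pct`,
#'   `bias_pct_lo`, `bias_pct_hi`, `p`.
#' @export
fit_bias <- function(paired_table,
                     parameters = unique(paired_table$parameter)) {
  rows <- lapply(parameters, function(p) {
    d <- paired_table[paired_table$parameter == p, ]
    tab <- table(paste(d$subject_id, d$eye), d$protocol)
    if (!all(tab == 1L) || ncol(tab) != 2L) {
      stop("unpaired data for parameter ", p,
           ": every eye needs exactly one measurement per protocol")
    }
    d$is_standard <- as.numeric(d$protocol == "standard")
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(value ~ is_standard + (1 | subject_id), data = d,
                 REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    ))
    beta <- lme4::fixef(fit)
    V <- safe_vcov(fit)
    b <- beta[["is_standard"]]
    se <- sqrt(V["is_standard", "is_standard"])
    z <- stats::qnorm(0.975)
    b0 <- beta[["(Intercept)"]]
    data.frame(
      parameter = p, intercept = b0, bias_abs = b,
      bias_lo = b - z * se, bias_hi = b + z * se,
      bias_pct = 100 * b / b0,
      bias_pct_lo = 100 * (b - z * se) / b0,
      bias_pct_hi = 100 * (b + z * se) / b0,
      p = 2 * stats::pnorm(-abs(b / se)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
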