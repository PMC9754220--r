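# Readers and writers for on-disk artifacts. All writers are deterministic
# (stable row and column order, 6 significant digits); readers validate the
# schema and reject malformed rows instead of coercing.

SCAN_COLS <- c("x_mm", "y_mm", LAYERS, "TRT")

fmt6 <- function(x) signif(x, 6)

#' Write / read a segmented scan
#'
#' Scans are CSV files with columns `x_mm`, `y_mm`, `RNFL`, `GCIPL`, `INL`,
#' `ONPL`, `ELM_BM`, `TRT` (thicknesses in um). On read, the layer
#' additivity invariant (`TRT` equals the layer sum within 0.01 um) and
#' non-negativity are enforced.
#'
#' @param scan a scan data.frame (see [sample_eye()]).
#' @param path file path.
#' @return `read_scan()` returns the validated scan data.frame (generator
#'   attributes are not persisted).
#' @export
write_scan <- function(scan, path) {
  stopifnot(all(SCAN_COLS %in% names(scan)))
  out <- scan[SCAN_COLS]
  for (cl in SCAN_COLS) out[[cl]] <- fmt6(out[[cl]])
  # re-impose additivity after rounding
  out$TRT <- fmt6(rowSums(out[LAYERS]))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_scan <- function(path) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  d <- as.data.frame(data.table::fread(path))
  missing <- setdiff(SCAN_COLS, names(d))
  if (length(missing)) {
    stop("scan file ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  }
  d <- d[SCAN_COLS]
  for (cl in SCAN_COLS) {
    if (!is.numeric(d[[cl]])) stop("non-numeric column ", cl, " in ", path)
  }
  bad <- which(as.matrix(d[c(LAYERS, "TRT")]) < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative thickness at row ", bad[1, 1], " of ", path)
  }
  mism <- abs(d$TRT - rowSums(d[LAYERS])) > 0.01
  if (any(mism)) {
    stop("TRT does not equal the layer sum at row ", which(mism)[1],
         " of ", path)
  }
  d
}

#' Write / read the cohort metadata table
#'
#' One row per eye: `subject_id`, `eye`, `age_years`, `sex`,
#' `scan_focus_D`, `protocol`.
#' @param meta metadata data.frame.
#' @param path file path.
#' @export
write_cohort_metadata <- function(meta, path) {
  cols <- c("subject_id", "eye", "age_years", "sex", "scan_focus_D",
            "protocol")
  stopifnot(all(cols %in% names(meta)))
  out <- meta[cols]
  out <- out[order(out$subject_id, out$eye), ]
  out$age_years <- fmt6(out$age_years)
  out$scan_focus_D <- fmt6(out$scan_focus_D)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_cohort_metadata
#' @export
read_cohort_metadata <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  cols <- c("subject_id", "eye", "age_years", "sex", "scan_focus_D",
            "protocol")
  missing <- setdiff(cols, names(d))
  if (length(missing)) {
    stop("metadata is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(d[c("subject_id", "eye")])) {
    stop("duplicate (subject_id, eye) rows in metadata")
  }
  d
}

#' Write a sector summary table
#'
#' Sector summaries (see [sector_table()]) are written with a stable
#' ordering by (layer, scheme, sector_id). Sector identifiers: ETDRS uses
#' `C0`, `N1`/`S1`/`T1`/`I1` (inner ring), `N2`/`S2`/`T2`/`I2` (outer
#' ring); the 20x20 grid uses `g<row>_<col>` with row 0 the most superior
#' row and column 0 the most temporal column (right-eye frame).
#'
#' @param summaries data.frame with columns `scheme`, `sector_id`, `layer`,
#'   `mean_um`, `n_nodes`, `excluded`, `reason`.
#' @param path file path.
#' @export
write_sector_table <- function(summaries, path) {
  cols <- c("scheme", "sector_id", "layer", "mean_um", "n_nodes",
            "excluded", "reason")
  stopifnot(all(cols %in% names(summaries)))
  ok <- summaries$scheme %in% c("whole", "etdrs", "grid20")
  if (!all(ok)) stop("unknown scheme: ", summaries$scheme[!ok][1])
  out <- summaries[cols]
  out <- out[order(out$layer, out$scheme, out$sector_id), ]
  out$mean_um <- fmt6(out$mean_um)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_sector_table
#' @export
read_sector_table <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write / read a long-format parameter table
#'
#' The eye-by-parameter table consumed by [estimate_effects()]; columns
#' `subject_id`, `eye`, `age_years`, `sex`, `scan_focus_D`, `protocol`,
#' `parameter`, `value`. Duplicate (subject, eye, parameter, protocol)
#' entries are rejected.
#' @param table parameter table data.frame.
#' @param path file path.
#' @export
write_parameter_table <- function(table, path) {
  cols <- c("subject_id", "eye", "age_years", "sex", "scan_focus_D",
            "protocol", "parameter", "value")
  stopifnot(all(cols %in% names(table)))
  out <- table[cols]
  out <- out[order(out$parameter, out$subject_id, out$eye, out$protocol), ]
  out$value <- fmt6(out$value)
  out$age_years <- fmt6(out$age_years)
  out$scan_focus_D <- fmt6(out$scan_focus_D)
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  if (anyDuplicated(d[c("subject_id", "eye", "parameter", "protocol")])) {
    stop("duplicate (eye, parameter) rows in parameter table")
  }
  d
}
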