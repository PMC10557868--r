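#' Double-reference subtraction of a sensorgram
#'
#' Removes bulk refractive-index and systematic instrument contributions:
#' output = (sample - reference) - mean over blanks of
#' (blank sample - blank reference), pointwise on the shared time grid.
#'
#' @param sample `sensorgram` recorded on the active (protein) spot.
#' @param reference `sensorgram` of the same cycle on the empty reference spot.
#' @param blanks List of buffer-only blank cycles, each a
#'   `list(sample = , reference = )` pair of sensorgrams on the same spots.
#' @return A `sensorgram` with the sample's phase metadata.
#' @export
double_reference <- function(sample, reference, blanks) {
  stopifnot(inherits(sample, "sensorgram"), inherits(reference, "sensorgram"))
  if (length(blanks) < 1) stop_data("at least one blank cycle is required")
  same_grid <- function(a, b) length(a$time) == length(b$time) &&
    all(a$time == b$time)
  if (!same_grid(sample, reference))
    stop_data("sample and reference time grids differ; resample first")
  ref_sub <- sample$response - reference$response
  blank_mean <- 0
  for (b in blanks) {
    if (!same_grid(sample, b$sample) || !same_grid(sample, b$reference))
      stop_data("blank cycle time grid differs from sample; resample first")
    blank_mean <- blank_mean + (b$sample$response - b$reference$response)
  }
  blank_mean <- blank_mean / length(blanks)
  out <- sample
  out$response <- ref_sub - blank_mean
  out
}

#' Scalar report point of a sensorgram
#'
#' Mean response over a window at the end of the association phase, minus the
#' mean over a pre-injection baseline window. Offsets are in seconds relative
#' to the end of injection (report window) and the start of injection
#' (baseline window).
#'
#' @param s A `sensorgram`.
#' @param window Report window `(start_offset, end_offset)` relative to
#'   `inject_end`; the default is the last 5 s of association.
#' @param baseline_window Baseline window relative to `inject_start`; the
#'   default is the 10 s immediately before injection. Use `NULL` to skip
#'   baseline subtraction.
#' @return Report point, RU.
#' @export
report_point <- function(s, window = c(-5, 0), baseline_window = c(-10, 0)) {
  stopifnot(inherits(s, "sensorgram"))
  if (window[2] <= window[1]) stop_domain("report window must be non-empty")
  sel <- s$time >= s$inject_end + window[1] & s$time <= s$inject_end + window[2]
  if (!any(sel)) stop_domain("report window contains no samples")
  if (any(s$time[sel] < s$inject_start))
    stop_domain("report window must lie within the association phase")
  rp <- mean(s$response[sel])
  if (!is.null(baseline_window)) {
    bsel <- s$time >= s$inject_start + baseline_window[1] &
      s$time <= s$inject_start + baseline_window[2] & s$time < s$inject_start
    if (!any(bsel)) stop_domain("baseline window contains no samples")
    rp <- rp - mean(s$response[bsel])
  }
  rp
}

#' Fit a DMSO solvent-correction curve
#'
#' Monotone piecewise-linear interpolant through (reference-spot excess,
#' observed correction) pairs measured on a ladder of DMSO solvent standards.
#' Queries outside the calibrated range raise an error rather than
#' extrapolating.
#'
#' @param standards data.frame with columns `reference_excess_RU` and
#'   `correction_RU`; at least 3 standards spanning the expected mismatch
#'   range.
#' @return An object of class `solvent_curve`.
#' @export
fit_solvent_curve <- function(standards) {
  need <- c("reference_excess_RU", "correction_RU")
  if (!all(need %in% names(standards)))
    stop_data(paste("standards must have columns:", paste(need, collapse = ", ")))
  if (nrow(standards) < 3)
    stop_data("at least 3 solvent standards are required")
  o <- order(standards$reference_excess_RU)
  x <- standards$reference_excess_RU[o]
  y <- standards$correction_RU[o]
  if (any(diff(x) <= 0))
    stop_data("solvent-standard reference excesses must be distinct (non-monotone ladder)")
  structure(list(x = x, y = y, range = range(x)), class = "solvent_curve")
}

#' Evaluate a solvent-correction curve
#'
#' @param curve A `solvent_curve`.
#' @param reference_excess Reference-spot excess response, RU (vectorized).
#' @return Correction, RU.
#' @export
solvent_correction <- function(curve, reference_excess) {
  stopifnot(inherits(curve, "solvent_curve"))
  if (any(reference_excess < curve$range[1] - 1e-9) ||
      any(reference_excess > curve$range[2] + 1e-9))
    stop_data(sprintf(
      "reference excess outside calibrated solvent range [%.3g, %.3g] RU; refusing to extrapolate",
      curve$range[1], curve$range[2]))
  stats::approx(curve$x, curve$y, xout = reference_excess, rule = 2)$y
}

#' Apply a solvent correction to a report point
#'
#' corrected = report_point - curve(reference_excess).
#'
#' @param rp Double-referenced report point, RU.
#' @param reference_excess Reference-spot excess of the same cycle, RU.
#' @param curve A `solvent_curve` for the same spot.
#' @return Corrected report point, RU.
#' @export
apply_solvent_correction <- function(rp, reference_excess, curve) {
  rp - solvent_correction(curve, reference_excess)
}

#' @export
print.solvent_curve <- function(x, ...) {
  cat(sprintf("Solvent-correction curve: %d standards over [%.3g, %.3g] RU\n",
              length(x$x), x$range[1], x$range[2]))
  invisible(x)
}

# report point of each row of a cycles x time response matrix (vectorized
# counterpart of report_point(); same window conventions)
matrix_report_points <- function(m, tt, inject_start, inject_end,
                                 window = c(-5, 0),
                                 baseline_window = c(-10, 0)) {
  sel <- tt >= inject_end + window[1] & tt <= inject_end + window[2]
  bsel <- tt >= inject_start + baseline_window[1] &
    tt <= inject_start + baseline_window[2] & tt < inject_start
  if (!any(sel) || !any(bsel)) stop_domain("empty report or baseline window")
  rowMeans(m[, sel, drop = FALSE]) - rowMeans(m[, bsel, drop = FALSE])
}

# report point against a per-cycle linear baseline fit over the baseline
# window, extrapolated to the report window (removes linear drift exactly)
drift_corrected_report_points <- function(m, tt, inject_start, inject_end,
                                          window = c(-5, 0),
                                          baseline_window = c(-10, 0)) {
  sel <- tt >= inject_end + window[1] & tt <= inject_end + window[2]
  bsel <- tt >= inject_start + baseline_window[1] &
    tt <= inject_start + baseline_window[2] & tt < inject_start
  if (!any(sel) || sum(bsel) < 2)
    stop_domain("empty report window or fewer than 2 baseline samples")
  xb <- tt[bsel]
  yb <- m[, bsel, drop = FALSE]
  xc <- xb - mean(xb)
  slope <- as.vector(yb %*% xc) / sum(xc^2)
  intercept <- rowMeans(yb) - slope * mean(xb)
  rowMeans(m[, sel, drop = FALSE]) - (intercept + slope * mean(tt[sel]))
}

#' Preprocess a full screen dataset to report points
#'
#' Runs the complete referencing chain over every compound cycle and protein
#' spot: double-reference subtraction against the empty reference spot and
#' the averaged blank cycles, scalar report-point extraction, and per-spot
#' DMSO solvent correction calibrated on the dataset's solvent standards.
#'
#' @param x An `spr_screen_data` object.
#' @param window,baseline_window Report-point windows; see [report_point()].
#' @return A list with `report_points` (data.frame: cycle_id, compound_id,
#'   spot_id, raw_RU, corrected_RU, reference_excess_RU) and the fitted
#'   per-spot `solvent_curves`.
#' @export
preprocess_screen <- function(x, window = c(-5, 0), baseline_window = c(-10, 0)) {
  stopifnot(inherits(x, "spr_screen_data"))
  tt <- x$time
  sch <- x$schedule
  ref_id <- x$reference_spot
  blank_rows <- which(x$cycles$cycle_type == "blank")
  if (length(blank_rows) < 1) stop_data("dataset contains no blank cycles")
  sol_rows <- which(x$cycles$cycle_type == "solvent")
  cpd_rows <- which(x$cycles$cycle_type == "compound")
  ref_m <- x$traces[[ref_id]]
  ref_blank <- colMeans(ref_m[blank_rows, , drop = FALSE])
  # reference-spot excess per cycle: blank-subtracted reference trace, read
  # against a linear baseline fit extrapolated into the report window so the
  # cycle's drift does not leak into the solvent-correction axis; the fit
  # uses the whole pre-injection baseline to keep the extrapolation stable
  ref_excess <- drift_corrected_report_points(
    sweep(ref_m, 2, ref_blank), tt, sch$inject_start, sch$inject_end,
    window, c(tt[1] - sch$inject_start, 0))
  protein_spots <- x$spots$spot_id[x$spots$protein != "empty_reference"]
  curves <- list()
  rp_list <- list()
  for (sp in protein_spots) {
    d <- x$traces[[sp]] - ref_m
    d <- sweep(d, 2, colMeans(d[blank_rows, , drop = FALSE]))
    rps <- matrix_report_points(d, tt, sch$inject_start, sch$inject_end,
                                window, baseline_window)
    curves[[sp]] <- fit_solvent_curve(data.frame(
      reference_excess_RU = ref_excess[sol_rows],
      correction_RU = rps[sol_rows]))
    corrected <- apply_solvent_correction(rps[cpd_rows], ref_excess[cpd_rows],
                                          curves[[sp]])
    rp_list[[sp]] <- data.frame(
      cycle_id = x$cycles$cycle_id[cpd_rows],
      compound_id = x$cycles$compound_id[cpd_rows],
      spot_id = sp, raw_RU = rps[cpd_rows], corrected_RU = corrected,
      reference_excess_RU = ref_excess[cpd_rows],
      stringsAsFactors = FALSE)
  }
  list(report_points = do.call(rbind, c(rp_list, list(make.row.names = FALSE))),
       solvent_curves = curves)
}
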