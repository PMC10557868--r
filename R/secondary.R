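#' Normalize reporter wells to the vehicle (DMSO) control
#'
#' Activity = well luminescence divided by the mean vehicle luminescence,
#' optionally after per-well total-protein normalization; inhibition is
#' 1 - activity (negative values indicate activation).
#'
#' @param luminescence Well luminescence values (arbitrary units).
#' @param vehicle Vehicle-well luminescence values (>= 1 well, mean > 0).
#' @param protein_mass Optional per-well protein masses for `luminescence`.
#' @param vehicle_protein_mass Optional protein masses for the vehicle wells.
#' @return data.frame with `activity` and `inhibition` per well.
#' @export
normalize_to_vehicle <- function(luminescence, vehicle, protein_mass = NULL,
                                 vehicle_protein_mass = NULL) {
  if (length(vehicle) < 1) stop_data("at least one vehicle well is required")
  if (!is.null(protein_mass)) luminescence <- luminescence / protein_mass
  if (!is.null(vehicle_protein_mass)) vehicle <- vehicle / vehicle_protein_mass
  v <- mean(vehicle)
  if (!is.finite(v) || v <= 0)
    stop_data("vehicle mean luminescence must be positive")
  activity <- luminescence / v
  data.frame(activity = activity, inhibition = 1 - activity)
}

#' Summarize a secondary reporter plate to per-compound inhibitions
#'
#' Normalizes each reporter's wells to that reporter's DMSO wells and
#' averages replicate wells per compound.
#'
#' @param plate Long well table as produced by [generate_secondary_plate()]
#'   (columns reporter, compound_id, luminescence; DMSO rows are vehicle).
#' @return data.frame: compound_id, target_inhibition, control_inhibition,
#'   target_activity, control_activity.
#' @export
summarize_secondary_plate <- function(plate) {
  need <- c("reporter", "compound_id", "luminescence")
  if (!all(need %in% names(plate)))
    stop_data(paste("plate must have columns:", paste(need, collapse = ", ")))
  per_reporter <- function(rep_nm) {
    w <- plate[plate$reporter == rep_nm, , drop = FALSE]
    veh <- w$luminescence[w$compound_id == "DMSO"]
    cpd <- w[w$compound_id != "DMSO", , drop = FALSE]
    norm <- normalize_to_vehicle(cpd$luminescence, veh)
    agg <- stats::aggregate(norm$activity, list(compound_id = cpd$compound_id),
                            mean)
    names(agg)[2] <- "activity"
    agg
  }
  tgt <- per_reporter("target_responsive")
  ctl <- per_reporter("control_responsive")
  m <- merge(tgt, ctl, by = "compound_id", suffixes = c("_target", "_control"))
  data.frame(compound_id = m$compound_id,
             target_inhibition = 1 - m$activity_target,
             control_inhibition = 1 - m$activity_control,
             target_activity = m$activity_target,
             control_activity = m$activity_control,
             stringsAsFactors = FALSE)
}

#' Secondary-screen pass criterion
#'
#' A compound passes if it inhibits the target-responsive reporter by
#' strictly more than `target_min` (default 70 percent) without inhibiting
#' the constitutive control reporter, quantified as control inhibition
#' strictly below `control_max`.
#'
#' @param target_inhibition,control_inhibition Inhibition fractions
#'   (vectorized).
#' @param target_min Minimum target inhibition, exclusive (default 0.70).
#' @param control_max Maximum tolerated control inhibition, exclusive
#'   (default 0.20; the conventional counter-screen tolerance, configurable).
#' @return Logical vector of passes.
#' @export
secondary_hit_filter <- function(target_inhibition, control_inhibition,
                                 target_min = 0.70, control_max = 0.20) {
  target_inhibition > target_min & control_inhibition < control_max
}

#' Fusion-positive vs fusion-negative reporter specificity test
#'
#' Two-sample t test comparing treated normalized reporter activities between
#' a fusion-positive-like and a fusion-negative-like line. Pooled-variance
#' (Student) by default; set `var_equal = FALSE` for Welch.
#'
#' @param fp_activities,fn_activities Normalized activities, >= 2 replicates
#'   each.
#' @param var_equal Pooled-variance Student test (default TRUE).
#' @return List with `t`, `df`, `p_value`, group means, and the method label.
#' @export
reporter_specificity_test <- function(fp_activities, fn_activities,
                                      var_equal = TRUE) {
  if (length(fp_activities) < 2 || length(fn_activities) < 2)
    stop_data("at least 2 replicates per group are required")
  ht <- stats::t.test(fp_activities, fn_activities, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_fp = mean(fp_activities), mean_fn = mean(fn_activities),
       method = if (var_equal) "Student" else "Welch")
}

#' Reporter activators
#'
#' Compounds whose target-reporter activity is at least `fold` times the
#' vehicle level without comparable activation of the control reporter;
#' exported as a candidate-activator list, no statistics beyond the ratio.
#'
#' @param results Per-compound summary from [summarize_secondary_plate()].
#' @param fold Activation fold threshold (inclusive; default 5).
#' @return Subset of `results`, sorted by descending target activity.
#' @export
find_activators <- function(results, fold = 5) {
  act <- results[results$target_activity >= fold &
                   results$control_activity < fold, , drop = FALSE]
  act <- act[order(-act$target_activity, act$compound_id), , drop = FALSE]
  rownames(act) <- NULL
  act
}
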