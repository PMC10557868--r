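#' Expected 1:1 Rmax for every compound/spot pair
#'
#' Tabulates the stoichiometric binding capacity
#' [theoretical_rmax()] for each compound on each protein spot
#' (reference spots are excluded).
#'
#' @param library Compound table with `compound_id` and `mw_Da`.
#' @param spots Spot table with `spot_id`, `protein`, `R_L_RU`,
#'   `ligand_mw_Da`.
#' @return data.frame: compound_id, spot_id, expected_rmax_RU.
#' @export
expected_rmax_table <- function(library, spots) {
  if (any(is.na(library$mw_Da)))
    stop_data(paste("missing molecular weight for compound(s):",
                    paste(library$compound_id[is.na(library$mw_Da)],
                          collapse = ", ")))
  sp <- spots[spots$protein != "empty_reference", , drop = FALSE]
  g <- expand.grid(compound_id = library$compound_id, spot_id = sp$spot_id,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mw <- library$mw_Da[match(g$compound_id, library$compound_id)]
  i <- match(g$spot_id, sp$spot_id)
  g$expected_rmax_RU <- theoretical_rmax(sp$R_L_RU[i], mw, sp$ligand_mw_Da[i])
  g
}

#' Stoichiometry/density elimination rules for one compound
#'
#' Evaluates the three primary-screen elimination rules on the target-protein
#' surfaces: (i) a higher raw signal on the LD than the HD target surface,
#' (ii) HD target binding above 200 percent of the expected Rmax
#' (superstoichiometric), (iii) HD target binding below 50 percent of the
#' expected Rmax (weak or partial activity). Rule (i) compares raw RU
#' (strict >); rules (ii)/(iii) compare percent Rmax on the HD surface
#' (strict > 200, strict < 50).
#'
#' @param target_hd_RU,target_ld_RU Observed report points on the HD/LD
#'   target spots, RU.
#' @param target_hd_pct Observed HD target binding as percent of expected
#'   Rmax.
#' @param over_pct,under_pct Percent-Rmax gates (defaults 200 and 50).
#' @return Character vector of elimination codes (possibly empty), a subset
#'   of `LD_EXCEEDS_HD`, `OVER_200_PCT`, `UNDER_50_PCT`.
#' @export
apply_elimination_rules <- function(target_hd_RU, target_ld_RU, target_hd_pct,
                                    over_pct = 200, under_pct = 50) {
  if (anyNA(c(target_hd_RU, target_ld_RU, target_hd_pct)))
    stop_data("missing target-surface observation")
  out <- character(0)
  if (target_ld_RU > target_hd_RU) out <- c(out, "LD_EXCEEDS_HD")
  if (target_hd_pct > over_pct) out <- c(out, "OVER_200_PCT")
  if (target_hd_pct < under_pct) out <- c(out, "UNDER_50_PCT")
  out
}

#' Target/control specificity fold ratio
#'
#' Ratio of percent-Rmax binding on the HD target surface to the HD control
#' surface. A control value of zero or below (possible after referencing
#' noise) yields +Inf: a non-binding control is the strongest specificity
#' evidence, and such compounds are retained for ranking but flagged.
#'
#' @param target_hd_pct,control_hd_pct Percent-Rmax values (vectorized).
#' @return Fold ratio (dimensionless), +Inf where the control is <= 0.
#' @export
specificity_ratio <- function(target_hd_pct, control_hd_pct) {
  if (anyNA(target_hd_pct) || anyNA(control_hd_pct))
    stop_data("specificity ratio requires finite percent-Rmax values")
  ifelse(control_hd_pct <= 0, Inf, target_hd_pct / control_hd_pct)
}

#' Run the primary-hit triage cascade
#'
#' Converts corrected report points into per-compound triage records:
#' percent-Rmax normalization against the expected 1:1 capacity of each spot,
#' the three elimination rules on the target surfaces, and the
#' target-vs-control specificity fold ratio. Negative corrected report points
#' are floored at zero before normalization.
#'
#' @param report_points data.frame from [preprocess_screen()] (columns
#'   compound_id, spot_id, corrected_RU).
#' @param library,spots Tables as in [expected_rmax_table()].
#' @param threshold Specificity fold-ratio threshold for a primary hit
#'   (inclusive; default 5).
#' @param over_pct,under_pct Elimination gates, percent of expected Rmax.
#' @return data.frame of triage records, one row per compound, with observed
#'   RU and percent Rmax per spot, `eliminations` (semicolon-joined codes),
#'   `specificity_ratio`, `control_nonpositive` flag and `is_primary_hit`.
#' @export
triage_screen <- function(report_points, library, spots, threshold = 5,
                          over_pct = 200, under_pct = 50) {
  need_spot <- function(protein, density) {
    id <- spots$spot_id[spots$protein == protein &
                          !is.na(spots$density_class) &
                          spots$density_class == density]
    if (length(id) != 1L)
      stop_data(sprintf("spot table must contain exactly one %s %s spot",
                        density, protein))
    id
  }
  tgt_hd <- need_spot("target", "HD"); tgt_ld <- need_spot("target", "LD")
  ctl_hd <- need_spot("control", "HD")
  exp_tab <- expected_rmax_table(library, spots)
  get_col <- function(df, value, spot) {
    v <- df[[value]][df$spot_id == spot]
    id <- df$compound_id[df$spot_id == spot]
    v[match(library$compound_id, id)]
  }
  obs <- list(tgt_hd = get_col(report_points, "corrected_RU", tgt_hd),
              tgt_ld = get_col(report_points, "corrected_RU", tgt_ld),
              ctl_hd = get_col(report_points, "corrected_RU", ctl_hd))
  if (anyNA(obs$tgt_hd) || anyNA(obs$tgt_ld))
    stop_data("missing target-surface report point for some compound")
  # negative corrected responses are referencing noise: floor at zero
  obs <- lapply(obs, pmax, 0)
  exp_rmax <- list(tgt_hd = get_col(exp_tab, "expected_rmax_RU", tgt_hd),
                   tgt_ld = get_col(exp_tab, "expected_rmax_RU", tgt_ld),
                   ctl_hd = get_col(exp_tab, "expected_rmax_RU", ctl_hd))
  pct <- mapply(function(o, e) 100 * o / e, obs, exp_rmax, SIMPLIFY = FALSE)
  elim <- vapply(seq_len(nrow(library)), function(i) {
    paste(apply_elimination_rules(obs$tgt_hd[i], obs$tgt_ld[i],
                                  pct$tgt_hd[i], over_pct, under_pct),
          collapse = ";")
  }, "")
  ratio <- specificity_ratio(pct$tgt_hd, pct$ctl_hd)
  rec <- data.frame(
    compound_id = library$compound_id,
    target_hd_RU = obs$tgt_hd, target_ld_RU = obs$tgt_ld,
    control_hd_RU = obs$ctl_hd,
    expected_rmax_hd_RU = exp_rmax$tgt_hd,
    target_hd_pct_rmax = pct$tgt_hd, target_ld_pct_rmax = pct$tgt_ld,
    control_hd_pct_rmax = pct$ctl_hd,
    eliminations = elim,
    specificity_ratio = ratio,
    control_nonpositive = pct$ctl_hd <= 0,
    stringsAsFactors = FALSE)
  rec$is_primary_hit <- rec$eliminations == "" & rec$specificity_ratio >= threshold
  rec
}

#' Select and rank primary hits
#'
#' Hits are the triage records with no elimination flag and a specificity
#' fold ratio at or above the threshold (inclusive), sorted by descending
#' ratio with a stable compound-id tie-break.
#'
#' @param records Triage table from [triage_screen()].
#' @param threshold Fold-ratio threshold (inclusive; default 5).
#' @return The hit subset of `records`, ranked.
#' @export
select_primary_hits <- function(records, threshold = 5) {
  hits <- records[records$eliminations == "" &
                    records$specificity_ratio >= threshold, , drop = FALSE]
  hits <- hits[order(-hits$specificity_ratio, hits$compound_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
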