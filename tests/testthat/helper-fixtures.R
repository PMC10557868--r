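# Shared fixtures and independent oracles for the test suite. Oracles here
# re-derive expected values from first principles (direct arithmetic, ODE
# integration, single-pass rule evaluation) and never call the pipeline code
# they check.

# a library with exact per-class counts (the multinomial generator cannot
# guarantee counts); blocks are generated class-pure and re-identified
fixed_count_library <- function(counts, seed = 1L, ...) {
  blocks <- lapply(seq_along(counts), function(i) {
    cls <- names(counts)[i]
    if (counts[i] == 0) return(NULL)
    mix <- setNames(as.numeric(names(counts) == cls), names(counts))
    generate_library(counts[i], mix, seed = seed + i, ...)
  })
  lib <- do.call(rbind, blocks)
  lib$compound_id <- sprintf("CPD%05d", seq_len(nrow(lib)))
  rownames(lib) <- NULL
  lib
}

all_classes <- c(non_binder = 0, specific_binder = 0, superstoichiometric = 0,
                 weak_substoichiometric = 0, density_artifact = 0)

# noiseless simulated series for kinetic-fit round trips
noiseless_series <- function(params, concentrations, cycle_end = 360) {
  lapply(concentrations, function(C)
    simulate_cycle(injection_schedule(analyte_concentration = C,
                                      cycle_end = cycle_end), params))
}

add_trace_noise <- function(series, sigma, seed) {
  set.seed(seed)
  lapply(series, function(s) {
    s$response <- s$response + rnorm(length(s$response), 0, sigma)
    s
  })
}

# independent single-pass evaluation of the published triage rules over a
# report-point table (brute-force oracle; plain loops, no pipeline calls)
brute_force_triage <- function(report_points, library, spots, threshold = 5) {
  rl <- function(spot) spots$R_L_RU[spots$spot_id == spot]
  lmw <- function(spot) spots$ligand_mw_Da[spots$spot_id == spot]
  obs <- function(cpd, spot) {
    v <- report_points$corrected_RU[report_points$compound_id == cpd &
                                      report_points$spot_id == spot]
    max(v, 0)
  }
  out <- lapply(library$compound_id, function(cpd) {
    mw <- library$mw_Da[library$compound_id == cpd]
    hd <- obs(cpd, "TGT_HD"); ld <- obs(cpd, "TGT_LD")
    chd <- obs(cpd, "CTL_HD")
    pct_hd <- 100 * hd / (rl("TGT_HD") * mw / lmw("TGT_HD"))
    pct_chd <- 100 * chd / (rl("CTL_HD") * mw / lmw("CTL_HD"))
    elim <- character(0)
    if (ld > hd) elim <- c(elim, "LD_EXCEEDS_HD")
    if (pct_hd > 200) elim <- c(elim, "OVER_200_PCT")
    if (pct_hd < 50) elim <- c(elim, "UNDER_50_PCT")
    ratio <- if (pct_chd <= 0) Inf else pct_hd / pct_chd
    list(compound_id = cpd, eliminations = paste(elim, collapse = ";"),
         ratio = ratio, hit = length(elim) == 0 && ratio >= threshold)
  })
  data.frame(compound_id = vapply(out, `[[`, "", "compound_id"),
             eliminations = vapply(out, `[[`, "", "eliminations"),
             ratio = vapply(out, `[[`, 0, "ratio"),
             hit = vapply(out, `[[`, TRUE, "hit"),
             stringsAsFactors = FALSE)
}

# textbook pooled-variance two-sample t test (independent oracle)
student_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}
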