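#' Noise and artifact model for synthetic sensorgrams
#'
#' Describes the systematic and stochastic artifacts added to simulated
#' sensorgrams. Baseline drift is shared across the spots of a cycle. Every
#' injection plug (compound, blank buffer, or solvent standard) produces a
#' bulk refractive-index response equal to the constant `bulk_offset_ru`
#' plus the cycle's DMSO mismatch, attenuated on protein-coated spots by
#' `protein_dmso_sensitivity` relative to the empty reference spot (the
#' excluded-volume effect). Double referencing removes the constant part;
#' the solvent-correction calibration measures and removes the
#' mismatch-dependent remainder.
#'
#' @param sigma_ru Gaussian point noise SD, RU.
#' @param drift_ru_per_s SD of the per-cycle linear baseline drift rate, RU/s.
#' @param bulk_offset_ru Constant bulk refractive-index jump of the injection
#'   plug relative to running buffer, RU; present in every injection
#'   (including buffer blanks) so double referencing removes it.
#' @param dmso_mismatch_ru Scale of the per-cycle DMSO mismatch, RU; per-cycle
#'   mismatches are drawn uniformly in +/- 2.5 times this value.
#' @param protein_dmso_sensitivity DMSO response of protein spots relative to
#'   the empty reference spot (reference = 1).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_ru = 0.2, drift_ru_per_s = 0.005,
                        bulk_offset_ru = 10, dmso_mismatch_ru = 2,
                        protein_dmso_sensitivity = 0.85) {
  if (sigma_ru < 0) stop_config("sigma_ru must be >= 0")
  if (dmso_mismatch_ru < 0) stop_config("dmso_mismatch_ru must be >= 0")
  structure(list(sigma_ru = sigma_ru, drift_ru_per_s = drift_ru_per_s,
                 bulk_offset_ru = bulk_offset_ru,
                 dmso_mismatch_ru = dmso_mismatch_ru,
                 protein_dmso_sensitivity = protein_dmso_sensitivity),
            class = "noise_model")
}

#' Zero-noise, zero-artifact model
#' @return A `noise_model` with every component set to zero (sensitivity 1).
#' @export
noiseless <- function() noise_model(0, 0, 0, 0, 1)

default_class_mix <- c(non_binder = 0.94, specific_binder = 0.02,
                       superstoichiometric = 0.015,
                       weak_substoichiometric = 0.015,
                       density_artifact = 0.01)

compound_classes <- names(default_class_mix)

#' Generate a synthetic compound library
#'
#' Draws a screening library with hidden true binding classes. Molecular
#' weights are log-uniform in `mw_range`; binder-like compounds receive a KD
#' log-uniform in `kd_range` and an association rate log-uniform in
#' `ka_range`. Superstoichiometric compounds bind with `super_multiplier`
#' times the 1:1 capacity, weak substoichiometric binders with
#' `weak_fraction` of it, and density-artifact compounds carry an extra
#' nonspecific signal on low-density surfaces scaled by `ld_artifact_factor`
#' relative to their high-density level.
#'
#' @param n Library size (>= 1).
#' @param class_mix Named proportions over the five compound classes
#'   (non_binder, specific_binder, superstoichiometric,
#'   weak_substoichiometric, density_artifact); must sum to 1.
#' @param seed Integer seed; identical seeds give byte-identical libraries.
#' @param concentration Injected concentration, M (screen default 50e-6).
#' @param mw_range Molecular-weight range, Da.
#' @param kd_range KD range for binders, M.
#' @param ka_range Association-rate range, 1/(M*s).
#' @param super_multiplier Stoichiometry multiplier for superstoichiometric
#'   compounds (> 2 so the 200 percent capacity gate has planted violators).
#' @param weak_fraction Effective capacity fraction for weak binders.
#' @param ld_artifact_factor LD nonspecific excess of density artifacts,
#'   relative to their HD response level.
#' @return A data.frame with one row per compound.
#' @export
generate_library <- function(n, class_mix = default_class_mix, seed = 1L,
                             concentration = 50e-6,
                             mw_range = c(150, 800),
                             kd_range = c(0.1e-6, 20e-6),
                             ka_range = c(1e3, 1e6),
                             super_multiplier = 3, weak_fraction = 0.3,
                             ld_artifact_factor = 1.5) {
  if (n < 1) stop_config("library size n must be >= 1")
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% compound_classes))
    stop_config(paste("class_mix must be named with classes:",
                      paste(compound_classes, collapse = ", ")))
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8)
    stop_config("class_mix proportions must be non-negative and sum to 1")
  mix <- setNames(rep(0, length(compound_classes)), compound_classes)
  mix[names(class_mix)] <- class_mix
  with_seed(seed, {
    # documented draw order: classes, MW, ka, KD (full-length vectors)
    cls <- sample(compound_classes, n, replace = TRUE, prob = mix)
    mw <- 10^stats::runif(n, log10(mw_range[1]), log10(mw_range[2]))
    ka <- 10^stats::runif(n, log10(ka_range[1]), log10(ka_range[2]))
    KD <- 10^stats::runif(n, log10(kd_range[1]), log10(kd_range[2]))
    kd <- ka * KD
    binderlike <- cls != "non_binder"
    ka[!binderlike] <- NA_real_
    kd[!binderlike] <- NA_real_
    stoich <- c(non_binder = 0, specific_binder = 1,
                superstoichiometric = super_multiplier,
                weak_substoichiometric = weak_fraction,
                density_artifact = 1)[cls]
    data.frame(compound_id = sprintf("CPD%05d", seq_len(n)),
               mw_Da = mw, concentration_M = concentration,
               true_class = cls, true_ka = ka, true_kd = kd,
               stoichiometry = unname(stoich),
               ld_artifact_factor = ifelse(cls == "density_artifact",
                                           ld_artifact_factor, 0),
               stringsAsFactors = FALSE)
  })
}

#' Generate the multi-spot sensor surface layout
#'
#' One CM5-style flow cell: target protein and a negative-control protein
#' each immobilized at high (HD) and low (LD) density in neighboring spots,
#' plus one empty reference spot. Densities are drawn uniformly from the
#' stated ranges.
#'
#' @param seed Integer seed.
#' @param target_mw,control_mw Ligand molecular weights, Da.
#' @param target_hd,target_ld,control_hd,control_ld Density ranges, RU.
#' @param dmso_sensitivity DMSO response of protein spots relative to the
#'   reference spot.
#' @return A data.frame with one row per spot (reference has R_L = 0).
#' @export
generate_spots <- function(seed = 1L, target_mw = 105000, control_mw = 25000,
                           target_hd = c(2700, 4200), target_ld = c(400, 700),
                           control_hd = c(1800, 3200), control_ld = c(500, 800),
                           dmso_sensitivity = 0.85) {
  with_seed(seed, {
    rl <- c(stats::runif(1, target_hd[1], target_hd[2]),
            stats::runif(1, target_ld[1], target_ld[2]),
            stats::runif(1, control_hd[1], control_hd[2]),
            stats::runif(1, control_ld[1], control_ld[2]),
            0)
    data.frame(spot_id = c("TGT_HD", "TGT_LD", "CTL_HD", "CTL_LD", "REF"),
               protein = c("target", "target", "control", "control",
                           "empty_reference"),
               density_class = c("HD", "LD", "HD", "LD", NA),
               R_L_RU = rl,
               ligand_mw_Da = c(target_mw, target_mw, control_mw, control_mw, NA),
               dmso_sensitivity = c(rep(dmso_sensitivity, 4), 1),
               stringsAsFactors = FALSE)
  })
}

# noiseless specific binding component of one compound on one spot,
# evaluated on the full cycle time grid
specific_component <- function(tt, schedule, compound, spot) {
  r <- numeric(length(tt))
  if (spot$protein == "empty_reference") return(r)
  if (compound$true_class == "non_binder") return(r)
  # specific, weak and artifact compounds are control-inert;
  # superstoichiometric compounds bind promiscuously on both proteins
  if (spot$protein == "control" &&
      compound$true_class != "superstoichiometric") return(r)
  rmax_eff <- theoretical_rmax(spot$R_L_RU, compound$mw_Da, spot$ligand_mw_Da) *
    compound$stoichiometry
  if (rmax_eff <= 0) return(r)
  p <- kinetic_params(compound$true_ka, compound$true_kd, rmax_eff)
  C <- compound$concentration_M
  assoc <- tt >= schedule$inject_start & tt <= schedule$inject_end
  dissoc <- tt > schedule$inject_end
  r[assoc] <- association_response(tt[assoc] - schedule$inject_start, C, p)
  R0 <- association_response(schedule$inject_end - schedule$inject_start, C, p)
  r[dissoc] <- dissociation_response(tt[dissoc] - schedule$inject_end, R0, p$kd)
  r
}

#' Simulate a full primary-screen dataset
#'
#' For every compound, one injection cycle is recorded on every spot of the
#' surface layout. Blank (buffer-only) cycles and a ladder of DMSO solvent
#' standards are included, and every systematic artifact (drift, bulk jump,
#' DMSO mismatch) is shared across the spots of a cycle apart from the
#' spot-specific DMSO sensitivity and the specific binding component.
#' Density-artifact compounds additionally carry a nonspecific square-pulse
#' signal on the LD target spot exceeding their HD response.
#'
#' @param library Compound table from [generate_library()].
#' @param spots Spot table from [generate_spots()]; must contain exactly one
#'   empty reference spot.
#' @param schedule An [injection_schedule()].
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param n_blanks Number of buffer-only blank cycles (>= 1).
#' @param solvent_ladder Planted DMSO mismatches of the solvent standards, RU;
#'   defaults to 8 values spanning +/- 4 times the model's mismatch scale.
#' @return An object of class `spr_screen_data` holding the cycle table and
#'   one response matrix (cycles x time) per spot.
#' @export
generate_screen_dataset <- function(library, spots,
                                    schedule = injection_schedule(),
                                    noise = noise_model(), seed = 1L,
                                    n_blanks = 3, solvent_ladder = NULL) {
  ref <- spots$spot_id[spots$protein == "empty_reference"]
  if (length(ref) != 1L)
    stop_config("spots must contain exactly one empty_reference spot")
  if (n_blanks < 1) stop_config("n_blanks must be >= 1")
  if (is.null(solvent_ladder))
    solvent_ladder <- seq(-4, 4, length.out = 8) *
      max(noise$dmso_mismatch_ru, 1)
  tt <- schedule_times(schedule)
  n_cpd <- nrow(library)
  n_sol <- length(solvent_ladder)
  n_cyc <- n_blanks + n_sol + n_cpd
  cycles <- data.frame(
    cycle_id = sprintf("CYC%05d", seq_len(n_cyc)),
    cycle_type = c(rep("blank", n_blanks), rep("solvent", n_sol),
                   rep("compound", n_cpd)),
    compound_id = c(rep(NA_character_, n_blanks + n_sol),
                    library$compound_id),
    stringsAsFactors = FALSE)
  with_seed(seed, {
    # documented draw order: drift rates, compound mismatches, then one
    # Gaussian noise matrix per spot in spot-table order
    drift <- stats::rnorm(n_cyc, 0, noise$drift_ru_per_s)
    mism <- numeric(n_cyc)
    mism[cycles$cycle_type == "solvent"] <- solvent_ladder
    mism[cycles$cycle_type == "compound"] <-
      stats::runif(n_cpd, -2.5, 2.5) * noise$dmso_mismatch_ru
    cycles$dmso_mismatch_RU <- mism
    inj <- as.numeric(tt >= schedule$inject_start & tt <= schedule$inject_end)
    # plug response on each spot: sensitivity * (constant bulk + mismatch)
    plug <- noise$bulk_offset_ru + mism
    shared <- outer(drift, tt - tt[1])
    traces <- vector("list", nrow(spots))
    names(traces) <- spots$spot_id
    cpd_rows <- which(cycles$cycle_type == "compound")
    for (s in seq_len(nrow(spots))) {
      spot <- spots[s, ]
      m <- shared + outer(plug * spot$dmso_sensitivity, inj)
      if (spot$protein != "empty_reference") {
        for (i in seq_len(n_cpd)) {
          cpd <- library[i, ]
          sp <- specific_component(tt, schedule, cpd, spot)
          if (spot$protein == "target" && spot$density_class == "LD" &&
              cpd$ld_artifact_factor > 0) {
            hd <- spots[spots$protein == "target" &
                          spots$density_class == "HD", ][1, ]
            hd_level <- specific_component(schedule$inject_end, schedule,
                                           cpd, hd)
            sp <- sp + cpd$ld_artifact_factor * hd_level * inj
          }
          m[cpd_rows[i], ] <- m[cpd_rows[i], ] + sp
        }
      }
      if (noise$sigma_ru > 0)
        m <- m + matrix(stats::rnorm(length(m), 0, noise$sigma_ru), nrow(m))
      traces[[s]] <- m
    }
    structure(list(library = library, spots = spots, schedule = schedule,
                   noise = noise, seed = seed, time = tt, cycles = cycles,
                   traces = traces, reference_spot = ref),
              class = "spr_screen_data")
  })
}

#' @export
print.spr_screen_data <- function(x, ...) {
  cat(sprintf("SPR screen dataset: %d compounds, %d spots, %d cycles x %d timepoints\n",
              nrow(x$library), nrow(x$spots), nrow(x$cycles), length(x$time)))
  cat(sprintf("  blanks: %d, solvent standards: %d\n",
              sum(x$cycles$cycle_type == "blank"),
              sum(x$cycles$cycle_type == "solvent")))
  invisible(x)
}

#' Extract one cycle/spot trace as a sensorgram
#'
#' @param x An `spr_screen_data` object.
#' @param cycle_id,spot_id Identifiers of the trace.
#' @return A [sensorgram()] object.
#' @export
get_trace <- function(x, cycle_id, spot_id) {
  stopifnot(inherits(x, "spr_screen_data"))
  i <- match(cycle_id, x$cycles$cycle_id)
  if (is.na(i)) stop_data(paste("unknown cycle:", cycle_id))
  if (!spot_id %in% names(x$traces)) stop_data(paste("unknown spot:", spot_id))
  sensorgram(x$time, x$traces[[spot_id]][i, ],
             inject_start = x$schedule$inject_start,
             inject_end = x$schedule$inject_end,
             analyte_concentration =
               if (x$cycles$cycle_type[i] == "compound")
                 x$library$concentration_M[match(x$cycles$compound_id[i],
                                                 x$library$compound_id)]
               else 0,
             cycle_id = cycle_id,
             compound_id = x$cycles$compound_id[i], spot_id = spot_id)
}

#' Generate a secondary reporter-screen plate
#'
#' Luminescence wells for a target-responsive reporter line and a
#' constitutive (control) reporter line, treated with each primary hit plus
#' vehicle (DMSO) wells. Luminescence is `plate_scale * (1 - true inhibition)`
#' with mean-one multiplicative lognormal noise.
#'
#' @param truth data.frame with columns compound_id, target_inhibition,
#'   control_inhibition (fractions; negative = activation).
#' @param n_wells Replicate wells per compound per reporter.
#' @param n_vehicle Vehicle wells per reporter.
#' @param noise_cv Coefficient of variation of the well noise.
#' @param plate_scale Mean vehicle luminescence, arbitrary units.
#' @param dose Treatment concentration, M.
#' @param seed Integer seed.
#' @return Long data.frame of wells.
#' @export
generate_secondary_plate <- function(truth, n_wells = 6, n_vehicle = 16,
                                     noise_cv = 0.05, plate_scale = 1e6,
                                     dose = 10e-6, seed = 1L) {
  need <- c("compound_id", "target_inhibition", "control_inhibition")
  if (!all(need %in% names(truth)))
    stop_config(paste("truth must have columns:", paste(need, collapse = ", ")))
  with_seed(seed, {
    out <- list()
    for (rep_nm in c("target_responsive", "control_responsive")) {
      line <- if (rep_nm == "target_responsive") "fusion_reporter_line"
              else "constitutive_reporter_line"
      inh_col <- if (rep_nm == "target_responsive") "target_inhibition"
                 else "control_inhibition"
      ids <- c(rep("DMSO", n_vehicle), rep(truth$compound_id, each = n_wells))
      inh <- c(rep(0, n_vehicle), rep(truth[[inh_col]], each = n_wells))
      ds <- c(rep(0, n_vehicle), rep(dose, n_wells * nrow(truth)))
      lum <- plate_scale * (1 - inh) * lognoise(length(inh), noise_cv)
      out[[rep_nm]] <- data.frame(cell_line = line, reporter = rep_nm,
                                  compound_id = ids, dose_M = ds,
                                  luminescence = lum,
                                  stringsAsFactors = FALSE)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

# mean-one multiplicative lognormal noise at a given CV (exact 1 at CV 0)
lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic thermal-shift (CETSA) melt table
#'
#' Soluble fraction follows a descending logistic in temperature with
#' aggregation midpoint `tagg_control` for the vehicle arm and
#' `tagg_control + delta_tagg` for the treated arm, with mean-one
#' multiplicative noise per band.
#'
#' @param temps Strictly increasing heating temperatures, deg C.
#' @param tagg_control Vehicle aggregation midpoint, deg C.
#' @param delta_tagg Treatment-induced midpoint shift, deg C.
#' @param slope Logistic width parameter, deg C.
#' @param noise_cv Coefficient of variation of the band noise.
#' @param replicates Replicate experiments per arm (>= 1).
#' @param seed Integer seed.
#' @return data.frame: treatment, replicate, temperature_C, soluble_fraction.
#' @export
generate_cetsa <- function(temps = seq(40, 64, by = 3), tagg_control = 48,
                           delta_tagg = 3, slope = 2.5, noise_cv = 0.1,
                           replicates = 3, seed = 1L) {
  if (any(diff(temps) <= 0)) stop_domain("temps must be strictly increasing")
  if (replicates < 1) stop_config("replicates must be >= 1")
  with_seed(seed, {
    out <- list()
    for (arm in c("vehicle", "treated")) {
      tagg <- tagg_control + if (arm == "treated") delta_tagg else 0
      for (r in seq_len(replicates)) {
        frac <- 1 / (1 + exp((temps - tagg) / slope)) *
          lognoise(length(temps), noise_cv)
        out[[paste(arm, r)]] <- data.frame(treatment = arm, replicate = r,
                                           temperature_C = temps,
                                           soluble_fraction = frac,
                                           stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Generate paired viability/reporter dose-response tables
#'
#' Four-parameter logistic responses (top 1, bottom 0 by default) for each
#' cell line's viability and reporter assays with mean-one multiplicative
#' noise. Fusion-positive-like lines have a reporter IC50 below the viability
#' IC50; negative-control lines have them equal.
#'
#' @param lines data.frame with columns cell_line, ic50_viability_M,
#'   ic50_reporter_M.
#' @param doses Treatment doses, M (> 0); the default 8-point ladder spans
#'   0.2-1000 uM so both assay transitions are bracketed.
#' @param hill Hill slope.
#' @param replicates Replicates per dose.
#' @param noise_cv Coefficient of variation.
#' @param top,bottom Response plateaus.
#' @param seed Integer seed.
#' @return Long data.frame: cell_line, assay, dose_M, replicate, response.
#' @export
generate_dose_response <- function(lines,
                                   doses = 10^seq(log10(0.2e-6),
                                                  log10(1000e-6),
                                                  length.out = 8),
                                   hill = 1, replicates = 3, noise_cv = 0.05,
                                   top = 1, bottom = 0, seed = 1L) {
  need <- c("cell_line", "ic50_viability_M", "ic50_reporter_M")
  if (!all(need %in% names(lines)))
    stop_config(paste("lines must have columns:", paste(need, collapse = ", ")))
  if (any(doses <= 0)) stop_domain("doses must be > 0")
  if (any(lines$ic50_viability_M <= 0) || any(lines$ic50_reporter_M <= 0))
    stop_domain("IC50s must be > 0")
  with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(lines))) {
      for (assay in c("viability", "reporter")) {
        ic50 <- if (assay == "viability") lines$ic50_viability_M[i]
                else lines$ic50_reporter_M[i]
        for (r in seq_len(replicates)) {
          resp <- (bottom + (top - bottom) / (1 + (doses / ic50)^hill)) *
            lognoise(length(doses), noise_cv)
          out[[paste(i, assay, r)]] <-
            data.frame(cell_line = lines$cell_line[i], assay = assay,
                       dose_M = doses, replicate = r, response = resp,
                       stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}
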