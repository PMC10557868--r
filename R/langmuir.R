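#' Kinetic parameters of a 1:1 interaction
#'
#' Container for the rate constants of a 1:1 (Langmuir) surface interaction.
#' The equilibrium dissociation constant is always derived as `kd / ka` and is
#' never stored independently.
#'
#' @param ka Association rate constant, 1/(M*s). Must be positive.
#' @param kd Dissociation rate constant, 1/s. Must be positive.
#' @param Rmax Maximal analyte response, RU. Must be positive.
#' @param chi2 Optional residual goodness-of-fit (reduced SSR), RU^2.
#' @return An object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params(ka = 1e5, kd = 1e-3, Rmax = 100)
#' equilibrium_kd(p)  # 1e-8 M
#' @export
kinetic_params <- function(ka, kd, Rmax, chi2 = NA_real_) {
  for (nm in c("ka", "kd", "Rmax")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_domain(sprintf("'%s' must be a single positive finite number", nm))
  }
  structure(list(ka = ka, kd = kd, Rmax = Rmax, chi2 = chi2),
            class = "kinetic_params")
}

#' Equilibrium dissociation constant
#'
#' @param object An object carrying 1:1 rate constants (e.g. `kinetic_params`
#'   or a fitted `spr_kinetic_fit`).
#' @return KD = kd / ka, in molar.
#' @export
equilibrium_kd <- function(object) UseMethod("equilibrium_kd")

#' @export
equilibrium_kd.kinetic_params <- function(object) object$kd / object$ka

#' @export
print.kinetic_params <- function(x, ...) {
  cat("1:1 interaction parameters\n")
  cat(sprintf("  ka   = %.4g 1/(M*s)\n", x$ka))
  cat(sprintf("  kd   = %.4g 1/s\n", x$kd))
  cat(sprintf("  KD   = %.4g M (kd/ka)\n", x$kd / x$ka))
  cat(sprintf("  Rmax = %.4g RU\n", x$Rmax))
  if (is.finite(x$chi2)) cat(sprintf("  chi2 = %.4g RU^2\n", x$chi2))
  invisible(x)
}

#' Injection schedule for one sensorgram cycle
#'
#' Defines the phase boundaries (baseline, association, dissociation) and time
#' grid of one injection cycle. All times in seconds, concentration in molar.
#'
#' @param baseline_start Start of the recorded baseline, s.
#' @param inject_start Start of the analyte injection (association phase), s.
#' @param inject_end End of the injection (start of dissociation), s.
#' @param cycle_end End of the recorded cycle, s.
#' @param analyte_concentration Injected analyte concentration, M.
#' @param sampling_interval Sampling interval of the time grid, s.
#' @return An object of class `injection_schedule`.
#' @export
injection_schedule <- function(baseline_start = 0, inject_start = 60,
                               inject_end = 120, cycle_end = 240,
                               analyte_concentration = 50e-6,
                               sampling_interval = 1) {
  if (!(baseline_start <= inject_start && inject_start < inject_end &&
        inject_end < cycle_end))
    stop_domain("schedule must satisfy baseline_start <= inject_start < inject_end < cycle_end")
  if (sampling_interval <= 0) stop_domain("sampling_interval must be > 0")
  if (analyte_concentration < 0) stop_domain("analyte_concentration must be >= 0")
  structure(list(baseline_start = baseline_start, inject_start = inject_start,
                 inject_end = inject_end, cycle_end = cycle_end,
                 analyte_concentration = analyte_concentration,
                 sampling_interval = sampling_interval),
            class = "injection_schedule")
}

#' Time grid of an injection schedule
#'
#' @param schedule An `injection_schedule`.
#' @return Numeric vector of sampling times, s.
#' @export
schedule_times <- function(schedule) {
  seq(schedule$baseline_start, schedule$cycle_end,
      by = schedule$sampling_interval)
}

#' Association-phase response of the 1:1 Langmuir model
#'
#' Closed-form response during analyte injection:
#' R(t) = (ka C Rmax / (ka C + kd)) (1 - exp(-(ka C + kd) t)).
#'
#' @param t Time since injection start, s (vectorized). Must be >= 0.
#' @param C Analyte concentration, M. Must be >= 0.
#' @param params A `kinetic_params` object.
#' @return Response in RU, bounded by \[0, Rmax).
#' @export
association_response <- function(t, C, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(t < 0)) stop_domain("association time must be >= 0")
  if (length(C) != 1L || C < 0) stop_domain("concentration must be a single value >= 0")
  if (C == 0) return(rep(0, length(t)))
  kobs <- params$ka * C + params$kd
  Req <- params$ka * C * params$Rmax / kobs
  Req * (1 - exp(-kobs * t))
}

#' Dissociation-phase response of the 1:1 Langmuir model
#'
#' R(t) = R0 exp(-kd t), with t measured from the end of injection.
#'
#' @param t Time since injection end, s (vectorized). Must be >= 0.
#' @param R0 Response at the end of injection, RU. Must be >= 0.
#' @param kd Dissociation rate constant, 1/s. Must be > 0.
#' @return Response in RU, non-increasing in `t`.
#' @export
dissociation_response <- function(t, R0, kd) {
  if (any(t < 0)) stop_domain("dissociation time must be >= 0")
  if (length(R0) != 1L || R0 < 0) stop_domain("R0 must be a single value >= 0")
  if (length(kd) != 1L || kd <= 0) stop_domain("kd must be a single value > 0")
  R0 * exp(-kd * t)
}

#' Steady-state (equilibrium) response of the 1:1 model
#'
#' Req = C Rmax / (C + KD), the binding isotherm used for steady-state
#' affinity analysis.
#'
#' @param C Analyte concentration, M (vectorized). Must be >= 0.
#' @param KD Equilibrium dissociation constant, M. Must be > 0.
#' @param Rmax Maximal response, RU. Must be > 0.
#' @return Equilibrium response in RU, bounded by \[0, Rmax\].
#' @export
steady_state_response <- function(C, KD, Rmax) {
  if (any(C < 0)) stop_domain("concentration must be >= 0")
  if (length(KD) != 1L || KD <= 0) stop_domain("KD must be a single value > 0")
  if (length(Rmax) != 1L || Rmax <= 0) stop_domain("Rmax must be a single value > 0")
  C * Rmax / (C + KD)
}

#' Theoretical maximal response for 1:1 stoichiometry
#'
#' The stoichiometric binding capacity of a surface spot,
#' Rmax = R_L * MW_analyte / MW_ligand, where R_L is the immobilization level
#' of the ligand (the surface-bound protein) and the molecular weights are
#' those of the injected analyte and the ligand.
#'
#' @param R_L Immobilized ligand level, RU (vectorized). Must be > 0.
#' @param mw_analyte Analyte molecular weight, Da. Must be > 0.
#' @param mw_ligand Ligand molecular weight, Da. Must be > 0.
#' @return Expected maximal response in RU assuming 1:1 binding.
#' @examples
#' theoretical_rmax(3000, 400, 120000)  # 10 RU
#' @export
theoretical_rmax <- function(R_L, mw_analyte, mw_ligand) {
  if (any(R_L <= 0) || any(mw_analyte <= 0) || any(mw_ligand <= 0))
    stop_domain("R_L, mw_analyte and mw_ligand must all be positive")
  R_L * mw_analyte / mw_ligand
}

#' Simulate one noiseless sensorgram cycle
#'
#' Composes the closed-form association and dissociation responses on the
#' schedule's time grid: zero through the baseline, the association form
#' during injection, and exponential dissociation afterwards. The trace is
#' continuous at the end of injection by construction.
#'
#' @param schedule An `injection_schedule`.
#' @param params A `kinetic_params` object.
#' @return A `sensorgram` object.
#' @export
simulate_cycle <- function(schedule, params) {
  stopifnot(inherits(schedule, "injection_schedule"),
            inherits(params, "kinetic_params"))
  tt <- schedule_times(schedule)
  r <- numeric(length(tt))
  C <- schedule$analyte_concentration
  assoc <- tt >= schedule$inject_start & tt <= schedule$inject_end
  dissoc <- tt > schedule$inject_end
  r[assoc] <- association_response(tt[assoc] - schedule$inject_start, C, params)
  R0 <- association_response(schedule$inject_end - schedule$inject_start, C, params)
  r[dissoc] <- dissociation_response(tt[dissoc] - schedule$inject_end, R0, params$kd)
  sensorgram(time = tt, response = r,
             inject_start = schedule$inject_start,
             inject_end = schedule$inject_end,
             analyte_concentration = C)
}

#' Sensorgram: one injection cycle's time/response trace
#'
#' @param time Strictly increasing sampling times, s.
#' @param response Responses, RU (same length as `time`).
#' @param inject_start,inject_end Association-phase boundaries, s.
#' @param analyte_concentration Injected analyte concentration, M.
#' @param cycle_id,compound_id,spot_id Optional identifiers.
#' @return An object of class `sensorgram`.
#' @export
sensorgram <- function(time, response, inject_start, inject_end,
                       analyte_concentration = NA_real_,
                       cycle_id = NA_character_, compound_id = NA_character_,
                       spot_id = NA_character_) {
  if (length(time) != length(response))
    stop_data("time and response must have the same length")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop_data("sensorgram time must be strictly increasing")
  structure(list(time = as.numeric(time), response = as.numeric(response),
                 inject_start = inject_start, inject_end = inject_end,
                 analyte_concentration = analyte_concentration,
                 cycle_id = cycle_id, compound_id = compound_id,
                 spot_id = spot_id),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("Sensorgram: %d points over [%g, %g] s", length(x$time),
              min(x$time), max(x$time)))
  if (!is.na(x$analyte_concentration))
    cat(sprintf(", C = %.3g M", x$analyte_concentration))
  cat(sprintf("\n  injection [%g, %g] s, peak response %.3g RU\n",
              x$inject_start, x$inject_end, max(x$response)))
  invisible(x)
}

#' @export
plot.sensorgram <- function(x, ..., xlab = "time (s)", ylab = "response (RU)") {
  plot(x$time, x$response, type = "l", xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = c(x$inject_start, x$inject_end), lty = 3, col = "grey50")
  invisible(x)
}

# condition helpers: classed errors so the CLI can map failure modes to
# distinct exit codes (config 2, data 3, fit 4)
stop_domain <- function(msg) {
  stop(structure(class = c("sprscreen_domain_error", "sprscreen_data_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
stop_data <- function(msg) {
  stop(structure(class = c("sprscreen_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
stop_config <- function(msg) {
  stop(structure(class = c("sprscreen_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
stop_fit <- function(msg) {
  stop(structure(class = c("sprscreen_fit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stable per-stage substream derivation from one run seed (kept below 2^31)
derive_seed <- function(seed, stage) {
  offsets <- c(library = 1L, spots = 2L, screen = 3L, secondary = 4L,
               cetsa = 5L, dose_response = 6L)
  if (!stage %in% names(offsets)) stop_config(paste("unknown stage:", stage))
  as.integer((as.numeric(seed) * 48271 + offsets[[stage]]) %% 2147483629)
}
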