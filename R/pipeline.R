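#' Default screen configuration
#'
#' Assembles a fully defaulted, validated configuration for [run_screen()].
#' The triage constants default to the screen's published gates: elimination
#' above 200 percent and below 50 percent of the expected Rmax, a 5-fold
#' (inclusive) specificity threshold for primary hits, and a secondary
#' criterion of target-reporter inhibition strictly above 70 percent with
#' control inhibition below 20 percent.
#'
#' @param seed Run seed; all stage substreams derive from it.
#' @param n_compounds Library size.
#' @param class_mix Named class proportions (see [generate_library()]).
#' @param concentration Injected screening concentration, M.
#' @param schedule List of [injection_schedule()] arguments.
#' @param noise List of [noise_model()] arguments.
#' @param spots List of [generate_spots()] arguments (seed excluded).
#' @param report_window,baseline_window Report-point windows, s.
#' @param triage List with over_pct, under_pct, fold_threshold.
#' @param secondary List with target_min, control_max, n_wells, n_vehicle,
#'   noise_cv.
#' @param n_blanks Blank cycles per run.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(seed = 1L, n_compounds = 500,
                          class_mix = default_class_mix,
                          concentration = 50e-6,
                          schedule = list(), noise = list(), spots = list(),
                          report_window = c(-5, 0),
                          baseline_window = c(-10, 0),
                          triage = list(), secondary = list(),
                          n_blanks = 3) {
  cfg <- list(
    seed = as.integer(seed), n_compounds = n_compounds,
    class_mix = as.list(class_mix), concentration = concentration,
    schedule = utils::modifyList(
      list(baseline_start = 0, inject_start = 60, inject_end = 120,
           cycle_end = 240, sampling_interval = 1), schedule),
    noise = utils::modifyList(
      list(sigma_ru = 0.2, drift_ru_per_s = 0.005, bulk_offset_ru = 10,
           dmso_mismatch_ru = 2, protein_dmso_sensitivity = 0.85), noise),
    spots = utils::modifyList(
      list(target_mw = 105000, control_mw = 25000,
           target_hd = c(2700, 4200), target_ld = c(400, 700),
           control_hd = c(1800, 3200), control_ld = c(500, 800),
           dmso_sensitivity = 0.85), spots),
    report_window = report_window, baseline_window = baseline_window,
    triage = utils::modifyList(
      list(over_pct = 200, under_pct = 50, fold_threshold = 5), triage),
    secondary = utils::modifyList(
      list(target_min = 0.70, control_max = 0.20, n_wells = 6,
           n_vehicle = 16, noise_cv = 0.05), secondary),
    n_blanks = n_blanks)
  validate_config(cfg)
}

#' Validate a raw screen configuration
#'
#' Accepts a list or a path to a JSON/YAML file, merges it over the
#' documented defaults, and returns a `screen_config` or raises one
#' aggregated error listing every offending key.
#'
#' @param x List of configuration overrides, a file path, or an existing
#'   `screen_config`.
#' @return A validated `screen_config`.
#' @export
validate_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop_config(paste("config file not found:", x))
    x <- if (grepl("\\.ya?ml$", x)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop_config("YAML configs require the 'yaml' package")
      yaml::read_yaml(x)
    } else jsonlite::read_json(x, simplifyVector = TRUE)
    if (is.null(x)) x <- list()
  }
  if (inherits(x, "screen_config")) x <- unclass(x)
  if (!is.list(x)) stop_config("config must be a list or a JSON/YAML file")
  defaults <- list(
    seed = 1L, n_compounds = 500, class_mix = as.list(default_class_mix),
    concentration = 50e-6,
    schedule = list(baseline_start = 0, inject_start = 60, inject_end = 120,
                    cycle_end = 240, sampling_interval = 1),
    noise = list(sigma_ru = 0.2, drift_ru_per_s = 0.005, bulk_offset_ru = 10,
                 dmso_mismatch_ru = 2, protein_dmso_sensitivity = 0.85),
    spots = list(target_mw = 105000, control_mw = 25000,
                 target_hd = c(2700, 4200), target_ld = c(400, 700),
                 control_hd = c(1800, 3200), control_ld = c(500, 800),
                 dmso_sensitivity = 0.85),
    report_window = c(-5, 0), baseline_window = c(-10, 0),
    triage = list(over_pct = 200, under_pct = 50, fold_threshold = 5),
    secondary = list(target_min = 0.70, control_max = 0.20, n_wells = 6,
                     n_vehicle = 16, noise_cv = 0.05),
    n_blanks = 3)
  unknown <- setdiff(names(x), names(defaults))
  cfg <- utils::modifyList(defaults, x[intersect(names(x), names(defaults))])
  errs <- character(0)
  if (length(unknown))
    errs <- c(errs, paste("unknown config key(s):",
                          paste(unknown, collapse = ", ")))
  if (!is.numeric(cfg$n_compounds) || cfg$n_compounds < 1)
    errs <- c(errs, "n_compounds: must be >= 1")
  mix <- unlist(cfg$class_mix)
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    errs <- c(errs, "class_mix: proportions must be non-negative and sum to 1")
  if (!all(names(mix) %in% compound_classes))
    errs <- c(errs, "class_mix: unknown class name")
  if (cfg$concentration <= 0)
    errs <- c(errs, "concentration: must be > 0")
  for (k in c("over_pct", "under_pct", "fold_threshold"))
    if (!is.numeric(cfg$triage[[k]]) || cfg$triage[[k]] <= 0)
      errs <- c(errs, sprintf("triage$%s: must be > 0", k))
  for (k in c("target_min", "control_max"))
    if (!is.numeric(cfg$secondary[[k]]) || cfg$secondary[[k]] <= 0)
      errs <- c(errs, sprintf("secondary$%s: must be > 0", k))
  if (cfg$noise$sigma_ru < 0) errs <- c(errs, "noise$sigma_ru: must be >= 0")
  if (cfg$n_blanks < 1) errs <- c(errs, "n_blanks: must be >= 1")
  sch <- cfg$schedule
  if (!(sch$baseline_start <= sch$inject_start &&
        sch$inject_start < sch$inject_end && sch$inject_end < sch$cycle_end))
    errs <- c(errs, "schedule: phase boundaries out of order")
  if (length(errs))
    stop_config(paste0("invalid configuration:\n  - ",
                       paste(errs, collapse = "\n  - ")))
  structure(cfg, class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf("Screen config: %d compounds at %.3g M, seed %d\n",
              x$n_compounds, x$concentration, x$seed))
  cat(sprintf("  triage gates: >%g%% / <%g%% of expected Rmax, %g-fold specificity\n",
              x$triage$over_pct, x$triage$under_pct, x$triage$fold_threshold))
  cat(sprintf("  secondary: target > %g, control < %g\n",
              x$secondary$target_min, x$secondary$control_max))
  invisible(x)
}

config_json <- function(cfg) {
  as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}

md5_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

#' Run the full screening pipeline
#'
#' simulate -> preprocess -> triage -> secondary, as one seeded reproducible
#' run. Stage substreams are derived from the run seed, every stage output is
#' written as CSV, and a manifest JSON records the configuration hash, the
#' compound funnel counts and per-file checksums. Rerunning with the same
#' configuration is byte-identical.
#'
#' @param config A `screen_config` (or overrides accepted by
#'   [validate_config()]).
#' @param out_dir Output directory.
#' @param write_sensorgrams Also write the full long-form sensorgram tables
#'   (large; default FALSE).
#' @param verbose Log per-stage counts with [message()].
#' @return Invisibly, the manifest list.
#' @export
run_screen <- function(config = screen_config(), out_dir,
                       write_sensorgrams = FALSE, verbose = TRUE) {
  cfg <- validate_config(config)
  if (missing(out_dir)) stop_config("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- "simulate"
  res <- tryCatch({
    library <- generate_library(
      cfg$n_compounds, unlist(cfg$class_mix),
      seed = derive_seed(cfg$seed, "library"),
      concentration = cfg$concentration)
    spots <- do.call(generate_spots,
                     c(list(seed = derive_seed(cfg$seed, "spots")), cfg$spots))
    schedule <- do.call(injection_schedule,
                        c(cfg$schedule,
                          list(analyte_concentration = cfg$concentration)))
    noise <- do.call(noise_model, cfg$noise)
    ds <- generate_screen_dataset(library, spots, schedule, noise,
                                  seed = derive_seed(cfg$seed, "screen"),
                                  n_blanks = cfg$n_blanks)
    log(stage, "%d compounds, %d cycles", nrow(library), nrow(ds$cycles))

    stage <- "preprocess"
    pp <- preprocess_screen(ds, cfg$report_window, cfg$baseline_window)
    log(stage, "%d report points", nrow(pp$report_points))

    stage <- "triage"
    tri <- triage_screen(pp$report_points, library, spots,
                         threshold = cfg$triage$fold_threshold,
                         over_pct = cfg$triage$over_pct,
                         under_pct = cfg$triage$under_pct)
    hits <- select_primary_hits(tri, cfg$triage$fold_threshold)
    log(stage, "screened %d -> %d primary hits", nrow(tri), nrow(hits))

    stage <- "secondary"
    truth <- secondary_truth(library, hits$compound_id,
                             seed = derive_seed(cfg$seed, "secondary"))
    plate <- generate_secondary_plate(
      truth, n_wells = cfg$secondary$n_wells,
      n_vehicle = cfg$secondary$n_vehicle,
      noise_cv = cfg$secondary$noise_cv,
      seed = derive_seed(cfg$seed, "secondary") + 1L)
    sec <- if (nrow(truth) > 0) summarize_secondary_plate(plate)
           else data.frame(compound_id = character(0),
                           target_inhibition = numeric(0),
                           control_inhibition = numeric(0),
                           target_activity = numeric(0),
                           control_activity = numeric(0))
    sec$passes <- secondary_hit_filter(sec$target_inhibition,
                                       sec$control_inhibition,
                                       cfg$secondary$target_min,
                                       cfg$secondary$control_max)
    sec_hits <- sec[sec$passes, , drop = FALSE]
    log(stage, "%d primary hits -> %d secondary hits", nrow(truth),
        nrow(sec_hits))

    stage <- "write"
    p <- function(f) file.path(out_dir, f)
    files <- c(write_table(library, p("compounds.csv")),
               write_table(spots, p("spots.csv")),
               write_table(pp$report_points, p("report_points.csv")),
               write_table(tri, p("triage.csv")),
               write_table(hits, p("hits.csv")),
               write_table(plate, p("reporter_plate.csv")),
               write_table(sec, p("secondary_results.csv")),
               write_table(sec_hits, p("secondary_hits.csv")),
               write_table(find_activators(sec), p("activators.csv")))
    if (write_sensorgrams)
      files <- c(files, write_screen_dataset(ds, file.path(out_dir, "raw")))
    cjson <- config_json(cfg)
    manifest <- list(
      package = "sprscreen",
      version = as.character(utils::packageVersion("sprscreen")),
      seed = cfg$seed, config = unclass(cfg),
      config_hash = md5_string(cjson),
      funnel = list(screened = nrow(tri), primary_hits = nrow(hits),
                    secondary_hits = nrow(sec_hits)),
      checksums = as.list(tools::md5sum(sort(files))))
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    writeLines(c(paste("FAILED at stage:", stage), conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop_wrapped(e, stage)
  })
  invisible(res)
}

stop_wrapped <- function(e, stage) {
  cls <- class(e)
  msg <- sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e))
  stop(structure(class = unique(c(cls[cls != "simpleError"], "error",
                                  "condition")),
                 list(message = msg, call = NULL)))
}

# planted secondary-assay truth: specific binders are strong, clean target
# inhibitors; everything else is inert-to-weak on both reporters
secondary_truth <- function(library, hit_ids, seed) {
  idx <- match(hit_ids, library$compound_id)
  cls <- library$true_class[idx]
  with_seed(seed, {
    specific <- cls == "specific_binder"
    tgt <- ifelse(specific, stats::runif(length(idx), 0.75, 0.95),
                  stats::runif(length(idx), 0, 0.30))
    ctl <- ifelse(specific, stats::runif(length(idx), 0, 0.05),
                  stats::runif(length(idx), 0, 0.10))
    data.frame(compound_id = hit_ids, target_inhibition = tgt,
               control_inhibition = ctl, stringsAsFactors = FALSE)
  })
}
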