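# CSV writers/readers for the screen's table dialects. All tables are UTF-8
# CSV with header rows and unit-suffixed column names (time_s, response_RU).

phase_labels <- function(tt, schedule) {
  ifelse(tt < schedule$inject_start, "baseline",
         ifelse(tt <= schedule$inject_end, "association", "dissociation"))
}

long_traces <- function(x, cycle_rows) {
  tt <- x$time
  ph <- phase_labels(tt, x$schedule)
  n_t <- length(tt)
  out <- vector("list", length(x$traces))
  for (sp in names(x$traces)) {
    m <- x$traces[[sp]][cycle_rows, , drop = FALSE]
    out[[sp]] <- data.frame(
      cycle_id = rep(x$cycles$cycle_id[cycle_rows], each = n_t),
      compound_id = rep(x$cycles$compound_id[cycle_rows], each = n_t),
      spot_id = sp,
      time_s = rep(tt, length(cycle_rows)),
      response_RU = as.vector(t(m)),
      phase = rep(ph, length(cycle_rows)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Write a screen dataset to CSV files
#'
#' Writes compounds.csv, spots.csv, sensorgrams.csv (compound cycles, long
#' form), blanks.csv, solvent_standards.csv and a manifest.json recording the
#' seed and the planted truth.
#'
#' @param x An `spr_screen_data` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_screen_dataset <- function(x, dir) {
  stopifnot(inherits(x, "spr_screen_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  files <- c(
    write_table(x$library, p("compounds.csv")),
    write_table(x$spots, p("spots.csv")),
    write_table(long_traces(x, which(x$cycles$cycle_type == "compound")),
                p("sensorgrams.csv")),
    write_table(long_traces(x, which(x$cycles$cycle_type == "blank")),
                p("blanks.csv")),
    write_table(cbind(long_traces(x, which(x$cycles$cycle_type == "solvent")),
                      planted_mismatch_RU = rep(
                        rep(x$cycles$dmso_mismatch_RU[
                          x$cycles$cycle_type == "solvent"],
                          each = length(x$time)),
                        times = length(x$traces))),
                p("solvent_standards.csv")))
  manifest <- list(seed = x$seed,
                   schedule = unclass(x$schedule),
                   noise = unclass(x$noise),
                   n_compounds = nrow(x$library),
                   truth = table_to_list(x$library[, c("compound_id",
                                                      "true_class")]))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, p("manifest.json")))
}

table_to_list <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))

#' Read a screen dataset written by [write_screen_dataset()]
#'
#' @param dir Directory containing the CSV files.
#' @return An `spr_screen_data` object.
#' @export
read_screen_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("compounds.csv", "spots.csv", "sensorgrams.csv", "blanks.csv",
              "solvent_standards.csv", "manifest.json"))
    if (!file.exists(p(f))) stop_data(paste("missing dataset file:", f))
  library <- utils::read.csv(p("compounds.csv"), stringsAsFactors = FALSE)
  spots <- utils::read.csv(p("spots.csv"), stringsAsFactors = FALSE)
  man <- jsonlite::read_json(p("manifest.json"), simplifyVector = TRUE)
  schedule <- do.call(injection_schedule, man$schedule[
    c("baseline_start", "inject_start", "inject_end", "cycle_end",
      "analyte_concentration", "sampling_interval")])
  noise <- do.call(noise_model, man$noise)
  parts <- list(
    blank = utils::read.csv(p("blanks.csv"), stringsAsFactors = FALSE),
    solvent = utils::read.csv(p("solvent_standards.csv"),
                              stringsAsFactors = FALSE),
    compound = utils::read.csv(p("sensorgrams.csv"), stringsAsFactors = FALSE))
  parts$solvent$planted_mismatch_RU <- NULL
  tt <- sort(unique(parts$blank$time_s))
  cyc_ids <- unlist(lapply(parts, function(d) unique(d$cycle_id)),
                    use.names = FALSE)
  cycles <- data.frame(
    cycle_id = cyc_ids,
    cycle_type = rep(names(parts), vapply(parts, function(d)
      length(unique(d$cycle_id)), 0L)),
    compound_id = NA_character_, stringsAsFactors = FALSE)
  cpd <- parts$compound
  cmap <- unique(cpd[, c("cycle_id", "compound_id")])
  cycles$compound_id <- cmap$compound_id[match(cycles$cycle_id, cmap$cycle_id)]
  traces <- list()
  for (sp in spots$spot_id) {
    m <- matrix(NA_real_, nrow(cycles), length(tt))
    for (nm in names(parts)) {
      d <- parts[[nm]][parts[[nm]]$spot_id == sp, , drop = FALSE]
      rows <- match(d$cycle_id, cycles$cycle_id)
      cols <- match(d$time_s, tt)
      m[cbind(rows, cols)] <- d$response_RU
    }
    traces[[sp]] <- m
  }
  structure(list(library = library, spots = spots, schedule = schedule,
                 noise = noise, seed = man$seed, time = tt, cycles = cycles,
                 traces = traces,
                 reference_spot = spots$spot_id[spots$protein == "empty_reference"]),
            class = "spr_screen_data")
}
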