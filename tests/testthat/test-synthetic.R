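test_that("library generation is seeded, classed and validated", {
  mix0 <- all_classes; mix0["non_binder"] <- 1
  lib <- generate_library(10, mix0, seed = 1)
  expect_equal(nrow(lib), 10)
  expect_true(all(is.na(lib$true_ka)) && all(is.na(lib$true_kd)))
  expect_true(all(lib$stoichiometry == 0))
  expect_identical(generate_library(50, seed = 7), generate_library(50, seed = 7))
  expect_false(identical(generate_library(50, seed = 7),
                         generate_library(50, seed = 8)))
  expect_error(generate_library(10, c(non_binder = 0.6)), "sum to 1")
  expect_error(generate_library(0), "n must be")
  # planted class counts match an independent redraw of the same stream
  lib3 <- generate_library(1000, seed = 3)
  set.seed(3)
  cls <- sample(c("non_binder", "specific_binder", "superstoichiometric",
                  "weak_substoichiometric", "density_artifact"),
                1000, replace = TRUE,
                prob = c(0.94, 0.02, 0.015, 0.015, 0.01))
  expect_identical(lib3$true_class, cls)
})

test_that("library draws respect the declared ranges", {
  lib <- generate_library(500, seed = 2)
  expect_true(all(lib$mw_Da >= 150 & lib$mw_Da <= 800))
  kds <- (lib$true_kd / lib$true_ka)[lib$true_class != "non_binder"]
  expect_true(all(kds >= 0.1e-6 & kds <= 20e-6))
  expect_true(all(lib$concentration_M == 50e-6))
  expect_true(all(lib$stoichiometry[lib$true_class == "superstoichiometric"] > 2))
})

test_that("screen datasets are deterministic and reference-checked", {
  lib <- generate_library(5, seed = 1)
  spots <- generate_spots(seed = 2)
  d1 <- generate_screen_dataset(lib, spots, seed = 9)
  d2 <- generate_screen_dataset(lib, spots, seed = 9)
  expect_identical(d1$traces, d2$traces)
  expect_error(generate_screen_dataset(lib, spots[spots$protein != "empty_reference", ],
                                       seed = 1),
               "empty_reference")
})

test_that("noiseless non-binders vanish after double referencing", {
  mix0 <- all_classes; mix0["non_binder"] <- 1
  lib <- generate_library(3, mix0, seed = 4)
  spots <- generate_spots(seed = 2)
  ds <- generate_screen_dataset(lib, spots, noise = noiseless(), seed = 5)
  blanks_rows <- ds$cycles$cycle_id[ds$cycles$cycle_type == "blank"]
  blanks <- lapply(blanks_rows, function(cid)
    list(sample = get_trace(ds, cid, "TGT_HD"),
         reference = get_trace(ds, cid, "REF")))
  cid <- ds$cycles$cycle_id[ds$cycles$cycle_type == "compound"][1]
  out <- double_reference(get_trace(ds, cid, "TGT_HD"),
                          get_trace(ds, cid, "REF"), blanks)
  expect_true(max(abs(out$response)) < 1e-9)
})

test_that("noiseless ideal binders reproduce the closed-form signal", {
  mix0 <- all_classes; mix0["specific_binder"] <- 1
  lib <- generate_library(1, mix0, seed = 6)
  spots <- generate_spots(seed = 2)
  nm <- noise_model(0, 0, 0, 0, 1)
  ds <- generate_screen_dataset(lib, spots, noise = nm, seed = 5)
  pp <- preprocess_screen(ds)
  hd <- pp$report_points[pp$report_points$spot_id == "TGT_HD", ]
  rm_hd <- theoretical_rmax(spots$R_L_RU[1], lib$mw_Da, spots$ligand_mw_Da[1])
  p <- kinetic_params(lib$true_ka, lib$true_kd, rm_hd)
  expected <- mean(association_response(seq(55, 60, 1), 50e-6, p))
  expect_equal(hd$corrected_RU, expected, tolerance = 1e-9)
  # at 50 uM against low-micromolar KD the plateau is near equilibrium
  expect_equal(hd$corrected_RU,
               steady_state_response(50e-6, lib$true_kd / lib$true_ka, rm_hd),
               tolerance = 0.01)
})

test_that("secondary plates encode planted inhibition exactly without noise", {
  truth <- data.frame(compound_id = c("A", "B"),
                      target_inhibition = c(1, 0.25),
                      control_inhibition = c(0, 0))
  plate <- generate_secondary_plate(truth, noise_cv = 0, seed = 1)
  a_t <- plate$luminescence[plate$reporter == "target_responsive" &
                              plate$compound_id == "A"]
  expect_true(all(a_t == 0))
  dmso <- plate$luminescence[plate$compound_id == "DMSO" &
                               plate$reporter == "target_responsive"]
  sec <- summarize_secondary_plate(plate)
  expect_equal(sec$target_activity[sec$compound_id == "B"], 0.75)
  expect_equal(mean(dmso), 1e6)
})

test_that("noisy secondary plates recover planted inhibition within sampling error", {
  truth <- data.frame(compound_id = "X", target_inhibition = 0.80,
                      control_inhibition = 0)
  hits <- replicate(40, {
    plate <- generate_secondary_plate(truth, n_wells = 6, noise_cv = 0.05,
                                      seed = sample.int(1e6, 1))
    summarize_secondary_plate(plate)$target_inhibition
  })
  se <- 0.2 * 0.05 / sqrt(6)  # CV of the (1-inh) level over 6 wells
  expect_lt(abs(mean(hits) - 0.80), 3 * se)
})

test_that("melt tables follow the planted logistic", {
  cet <- generate_cetsa(delta_tagg = 0, noise_cv = 0, replicates = 2, seed = 1)
  tr <- cet[cet$treatment == "treated", ]
  ve <- cet[cet$treatment == "vehicle", ]
  expect_equal(tr$soluble_fraction, ve$soluble_fraction)
  cet2 <- generate_cetsa(temps = c(40, 44, 48, 52, 56), tagg_control = 48,
                         delta_tagg = 0, noise_cv = 0, replicates = 1, seed = 1)
  expect_equal(cet2$soluble_fraction[cet2$temperature_C == 48], c(0.5, 0.5))
  expect_error(generate_cetsa(temps = c(50, 45, 55)), "increasing")
})

test_that("dose-response tables follow the planted 4PL", {
  lines <- data.frame(cell_line = "FP", ic50_viability_M = 40e-6,
                      ic50_reporter_M = 10e-6)
  d <- generate_dose_response(lines, doses = c(1e-7, 10e-6, 40e-6, 1e-3),
                              replicates = 1, noise_cv = 0, seed = 1)
  rep_at_ic50 <- d$response[d$assay == "reporter" & d$dose_M == 10e-6]
  via_at_ic50 <- d$response[d$assay == "viability" & d$dose_M == 40e-6]
  expect_equal(rep_at_ic50, 0.5)
  expect_equal(via_at_ic50, 0.5)
  low <- d$response[d$assay == "viability" & d$dose_M == 1e-7]
  expect_equal(low, 1, tolerance = 0.01)
  expect_error(generate_dose_response(lines, doses = c(0, 1e-6)), "doses")
})
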