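make_sg <- function(y, tt = seq(0, 240, 1)) {
  sensorgram(tt, y, inject_start = 60, inject_end = 120,
             analyte_concentration = 1e-6)
}

test_that("double referencing removes shared artifacts and validates grids", {
  tt <- seq(0, 240, 1)
  art <- 0.01 * tt + 5 * (tt >= 60 & tt <= 120)
  specific <- ifelse(tt >= 60 & tt <= 120, 3, 0)
  blanks <- list(list(sample = make_sg(art), reference = make_sg(art)))
  out <- double_reference(make_sg(art + specific), make_sg(art), blanks)
  expect_equal(out$response, specific)
  # a blank processed against itself is identically zero
  z <- double_reference(make_sg(art), make_sg(art), blanks)
  expect_true(all(z$response == 0))
  expect_error(double_reference(make_sg(art), make_sg(art[-1], tt[-1]), blanks),
               "grid")
  expect_error(double_reference(make_sg(art), make_sg(art), list()), "blank")
})

test_that("double referencing is linear and blank-order invariant", {
  tt <- seq(0, 240, 1)
  sig <- ifelse(tt >= 60 & tt <= 120, 7, 0)
  zero <- make_sg(numeric(length(tt)))
  blanks <- list(list(sample = make_sg(0.1 * tt), reference = make_sg(0.1 * tt)),
                 list(sample = make_sg(rep(2, length(tt))),
                      reference = make_sg(rep(2, length(tt)))))
  o1 <- double_reference(make_sg(sig), zero, blanks)
  o2 <- double_reference(make_sg(3 * sig), zero, blanks)
  expect_equal(o2$response, 3 * o1$response)
  o3 <- double_reference(make_sg(sig), zero, rev(blanks))
  expect_equal(o1$response, o3$response)
})

test_that("report points average the association plateau minus baseline", {
  tt <- seq(0, 240, 1)
  expect_equal(report_point(make_sg(rep(7, length(tt)))), 0)
  expect_equal(report_point(make_sg(rep(7, length(tt))), baseline_window = NULL), 7)
  expect_equal(report_point(make_sg(numeric(length(tt)))), 0)
  ramp <- ifelse(tt >= 60 & tt <= 120, 10, 0) + 2
  expect_equal(report_point(make_sg(ramp)), 10)
  expect_error(report_point(make_sg(rep(1, length(tt))), window = c(0, -5)),
               "window")
})

test_that("solvent curves interpolate standards and refuse extrapolation", {
  std <- data.frame(reference_excess_RU = c(-6, -2, 0, 2, 6),
                    correction_RU = c(0, 0, 0, 0, 0))
  cv <- fit_solvent_curve(std)
  expect_equal(solvent_correction(cv, c(-5, 0, 3)), c(0, 0, 0))
  expect_equal(apply_solvent_correction(10, 3, cv), 10)
  # exactly linear mismatch reproduces the line everywhere in range
  std2 <- data.frame(reference_excess_RU = seq(-6, 6, length.out = 8))
  std2$correction_RU <- -0.15 * std2$reference_excess_RU
  cv2 <- fit_solvent_curve(std2)
  q <- seq(-5.5, 5.5, 0.7)
  expect_equal(solvent_correction(cv2, q), -0.15 * q, tolerance = 1e-12)
  expect_equal(apply_solvent_correction(10, 4, cv2), 10 - (-0.15 * 4),
               tolerance = 1e-12)
  expect_error(fit_solvent_curve(std2[1:2, ]), "3 solvent standards")
  expect_error(fit_solvent_curve(data.frame(reference_excess_RU = c(1, 1, 2),
                                            correction_RU = c(0, 0, 0))),
               "non-monotone")
  expect_error(solvent_correction(cv2, 7), "extrapolate")
})

test_that("the full noiseless chain inverts the planted artifacts exactly", {
  nm <- noise_model(sigma_ru = 0, drift_ru_per_s = 0.01, bulk_offset_ru = 15,
                    dmso_mismatch_ru = 3, protein_dmso_sensitivity = 0.8)
  mix <- all_classes
  mix[c("non_binder", "specific_binder")] <- c(0.5, 0.5)
  lib <- generate_library(30, mix, seed = 11)
  spots <- generate_spots(seed = 3)
  ds <- generate_screen_dataset(lib, spots, noise = nm, seed = 12)
  pp <- preprocess_screen(ds)
  for (spot in c("TGT_HD", "TGT_LD", "CTL_HD", "CTL_LD")) {
    got <- pp$report_points[pp$report_points$spot_id == spot, ]
    got <- got[match(lib$compound_id, got$compound_id), ]
    i <- match(spot, spots$spot_id)
    expected <- vapply(seq_len(nrow(lib)), function(k) {
      if (lib$stoichiometry[k] == 0 || spots$protein[i] == "control") return(0)
      rm <- theoretical_rmax(spots$R_L_RU[i], lib$mw_Da[k],
                             spots$ligand_mw_Da[i]) * lib$stoichiometry[k]
      p <- kinetic_params(lib$true_ka[k], lib$true_kd[k], rm)
      mean(association_response(seq(55, 60, 1), lib$concentration_M[k], p))
    }, 0)
    expect_lt(max(abs(got$corrected_RU - expected)), 1e-6)
  }
})

test_that("a planted DMSO mismatch is removed by the solvent correction", {
  mix <- all_classes; mix["specific_binder"] <- 1
  lib <- generate_library(4, mix, seed = 21)
  spots <- generate_spots(seed = 3)
  with_mism <- noise_model(0, 0, 10, 5, 0.8)
  no_mism <- noise_model(0, 0, 10, 0, 0.8)
  pp1 <- preprocess_screen(generate_screen_dataset(lib, spots,
                                                   noise = with_mism, seed = 2))
  pp0 <- preprocess_screen(generate_screen_dataset(lib, spots,
                                                   noise = no_mism, seed = 2))
  expect_lt(max(abs(pp1$report_points$corrected_RU -
                      pp0$report_points$corrected_RU)), 1e-6)
  # without the correction the mismatch contaminates the raw report points
  expect_gt(max(abs(pp1$report_points$raw_RU -
                      pp0$report_points$raw_RU)), 0.1)
})
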