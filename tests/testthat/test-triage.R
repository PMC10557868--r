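test_that("expected Rmax tables reproduce the mass-ratio arithmetic", {
  lib <- data.frame(compound_id = c("A", "B"), mw_Da = c(300, 300),
                    stringsAsFactors = FALSE)
  spots <- data.frame(spot_id = c("S1", "REF"),
                      protein = c("target", "empty_reference"),
                      density_class = c("HD", NA),
                      R_L_RU = c(3000, 0), ligand_mw_Da = c(100000, NA),
                      stringsAsFactors = FALSE)
  tab <- expected_rmax_table(lib, spots)
  expect_equal(nrow(tab), 2)  # reference excluded
  expect_equal(tab$expected_rmax_RU, c(9, 9))
  lib$mw_Da[2] <- NA
  expect_error(expected_rmax_table(lib, spots), "B")
  # row-by-row recomputation on a full synthetic library
  lib500 <- generate_library(500, seed = 13)
  sp <- generate_spots(seed = 4)
  tab500 <- expected_rmax_table(lib500, sp)
  for (i in sample(nrow(tab500), 50)) {
    mw <- lib500$mw_Da[lib500$compound_id == tab500$compound_id[i]]
    j <- match(tab500$spot_id[i], sp$spot_id)
    expect_equal(tab500$expected_rmax_RU[i],
                 sp$R_L_RU[j] * mw / sp$ligand_mw_Da[j])
  }
})

test_that("elimination rules flag exactly the stated conditions", {
  expect_identical(apply_elimination_rules(10, 5, 100), character(0))
  expect_identical(apply_elimination_rules(10, 5, 250), "OVER_200_PCT")
  expect_identical(apply_elimination_rules(10, 5, 40), "UNDER_50_PCT")
  expect_identical(apply_elimination_rules(10, 12, 100), "LD_EXCEEDS_HD")
  # boundaries are strict
  expect_identical(apply_elimination_rules(10, 10, 200), character(0))
  expect_identical(apply_elimination_rules(10, 10, 50), character(0))
  expect_setequal(apply_elimination_rules(10, 12, 250),
                  c("LD_EXCEEDS_HD", "OVER_200_PCT"))
  expect_error(apply_elimination_rules(NA, 5, 100), "missing")
})

test_that("specificity ratios divide target by control percent Rmax", {
  expect_equal(specificity_ratio(80, 16), 5)
  expect_equal(specificity_ratio(37, 37), 1)
  expect_identical(specificity_ratio(80, 0), Inf)
  expect_identical(specificity_ratio(80, -2), Inf)
})

test_that("primary-hit selection is inclusive at the fold threshold and ranked", {
  rec <- data.frame(compound_id = c("A", "B", "C", "D"),
                    eliminations = c("", "OVER_200_PCT", "", ""),
                    specificity_ratio = c(5, 10, 7, 5),
                    stringsAsFactors = FALSE)
  hits <- select_primary_hits(rec, threshold = 5)
  expect_identical(hits$compound_id, c("C", "A", "D"))  # ratio desc, id tie-break
  expect_false("B" %in% hits$compound_id)  # eliminated despite high ratio
  expect_identical(select_primary_hits(rec, threshold = 5.1)$compound_id, "C")
})

test_that("the cascade equals a brute-force evaluation of the published rules", {
  for (s in c(101, 202)) {
    lib <- generate_library(300, seed = s)
    spots <- generate_spots(seed = s + 1)
    ds <- generate_screen_dataset(lib, spots, seed = s + 2)
    pp <- preprocess_screen(ds)
    tri <- triage_screen(pp$report_points, lib, spots)
    oracle <- brute_force_triage(pp$report_points, lib, spots)
    expect_identical(tri$eliminations, oracle$eliminations)
    expect_equal(tri$specificity_ratio, oracle$ratio)
    oh <- oracle[oracle$hit, ]
    oh <- oh[order(-oh$ratio, oh$compound_id), ]
    expect_identical(select_primary_hits(tri)$compound_id, oh$compound_id)
  }
})

test_that("a noiseless planted library yields exactly the specific binders", {
  counts <- c(non_binder = 170, specific_binder = 10,
              superstoichiometric = 10, weak_substoichiometric = 5,
              density_artifact = 5)
  lib <- fixed_count_library(counts, seed = 31)
  spots <- generate_spots(seed = 7)
  ds <- generate_screen_dataset(lib, spots, noise = noiseless(), seed = 9)
  tri <- triage_screen(preprocess_screen(ds)$report_points, lib, spots)
  hits <- select_primary_hits(tri)
  expect_setequal(hits$compound_id,
                  lib$compound_id[lib$true_class == "specific_binder"])
  elim_of <- function(cls) tri$eliminations[lib$true_class == cls]
  expect_true(all(grepl("OVER_200_PCT", elim_of("superstoichiometric"))))
  expect_true(all(grepl("LD_EXCEEDS_HD", elim_of("density_artifact"))))
  expect_true(all(grepl("UNDER_50_PCT", elim_of("weak_substoichiometric"))))
  expect_true(all(elim_of("non_binder") != ""))  # auditability
})

test_that("percent Rmax and hit membership are density invariant for ideal binders", {
  counts <- c(non_binder = 20, specific_binder = 10, superstoichiometric = 0,
              weak_substoichiometric = 0, density_artifact = 0)
  lib <- fixed_count_library(counts, seed = 41)
  spots <- generate_spots(seed = 7)
  spots2 <- spots
  spots2$R_L_RU <- 2 * spots2$R_L_RU
  t1 <- triage_screen(preprocess_screen(
    generate_screen_dataset(lib, spots, noise = noiseless(),
                            seed = 1))$report_points, lib, spots)
  t2 <- triage_screen(preprocess_screen(
    generate_screen_dataset(lib, spots2, noise = noiseless(),
                            seed = 1))$report_points, lib, spots2)
  expect_equal(t1$target_hd_pct_rmax, t2$target_hd_pct_rmax, tolerance = 1e-9)
  expect_identical(t1$is_primary_hit, t2$is_primary_hit)
})

test_that("raising the control signal never creates a hit", {
  lib <- data.frame(compound_id = "A", mw_Da = 400, stringsAsFactors = FALSE)
  spots <- generate_spots(seed = 7)
  mk_rp <- function(ctl) data.frame(
    compound_id = "A", spot_id = c("TGT_HD", "TGT_LD", "CTL_HD", "CTL_LD"),
    corrected_RU = c(12, 1, ctl, 0), stringsAsFactors = FALSE)
  hit_at <- vapply(seq(0, 5, 0.25), function(ctl) {
    tr <- triage_screen(mk_rp(ctl), lib, spots)
    tr$is_primary_hit
  }, TRUE)
  expect_true(all(diff(as.integer(hit_at)) <= 0))
})
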