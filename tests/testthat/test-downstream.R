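logistic_frac <- function(tt, tagg, slope = 2.5) 1 / (1 + exp((tt - tagg) / slope))

test_that("melt-curve fits recover exact logistic data", {
  tt <- seq(40, 64, 3)
  fit <- fit_melt_curve(tt, logistic_frac(tt, 48))
  expect_lt(abs(fit$tagg - 48), 1e-6)
  expect_lt(abs(fit$slope - 2.5), 1e-5)
  # temperature-shift equivariance
  fit2 <- fit_melt_curve(tt + 2, logistic_frac(tt, 48))
  expect_equal(fit2$tagg, fit$tagg + 2, tolerance = 1e-6)
  expect_error(fit_melt_curve(tt, rep(1, length(tt))), "flat")
  expect_error(fit_melt_curve(c(40, 50, 60), c(1, 0.5, 0)), "4 distinct")
})

test_that("melt summaries report replicate mean and SE per temperature", {
  cet <- generate_cetsa(noise_cv = 0.1, replicates = 3, seed = 2)
  s <- melt_curve_summary(cet)
  one <- cet$soluble_fraction[cet$treatment == "vehicle" &
                                cet$temperature_C == 46]
  expect_equal(s$mean_fraction[s$treatment == "vehicle" &
                                 s$temperature_C == 46], mean(one))
  expect_equal(s$se_fraction[s$treatment == "vehicle" &
                               s$temperature_C == 46],
               sd(one) / sqrt(3))
})

test_that("thermal shifts are antisymmetric and zero for identical arms", {
  cet <- generate_cetsa(delta_tagg = 0, noise_cv = 0, replicates = 2, seed = 1)
  tr <- cet[cet$treatment == "treated", ]
  ve <- cet[cet$treatment == "vehicle", ]
  dt <- delta_tagg(tr, ve, n_boot = 29, seed = 5)
  expect_equal(dt$delta_tagg, 0, tolerance = 1e-8)
  expect_true(dt$ci[1] <= 0 && 0 <= dt$ci[2])
  cet2 <- generate_cetsa(delta_tagg = 2, noise_cv = 0.05, replicates = 3,
                         seed = 3)
  tr2 <- cet2[cet2$treatment == "treated", ]
  ve2 <- cet2[cet2$treatment == "vehicle", ]
  expect_equal(delta_tagg(tr2, ve2, n_boot = 19, seed = 5)$delta_tagg,
               -delta_tagg(ve2, tr2, n_boot = 19, seed = 5)$delta_tagg)
})

test_that("4PL fits recover exact dose-response data", {
  d <- 10^seq(-6.5, -4, length.out = 8)
  y <- 1 / (1 + (d / 15e-6)^1)
  fit <- fit_4pl(d, y)
  expect_lt(abs(fit$ic50 / 15e-6 - 1), 1e-6)
  expect_lt(abs(fit$hill - 1), 1e-5)
  # the fitted curve passes through (IC50, midpoint) by construction
  expect_equal(predict(fit, fit$ic50), (fit$top + fit$bottom) / 2)
  # dose-axis equivariance
  fit10 <- fit_4pl(10 * d, y)
  expect_equal(fit10$ic50, 10 * fit$ic50, tolerance = 1e-6)
  expect_equal(fit10$hill, fit$hill, tolerance = 1e-5)
  expect_error(fit_4pl(c(1, 2, 4) * 1e-6, c(1, 0.5, 0)), "4 distinct")
  expect_error(fit_4pl(c(0, 1e-6, 1e-5, 1e-4), rep(0.5, 4)), "doses")
})

test_that("selectivity index is the viability/reporter IC50 ratio", {
  d <- 10^seq(-7, -3.5, length.out = 8)
  fv <- fit_4pl(d, 1 / (1 + d / 30e-6), assay = "viability")
  fr <- fit_4pl(d, 1 / (1 + d / 10e-6), assay = "reporter")
  expect_equal(selectivity_index(fv, fr), 3, tolerance = 1e-5)
  expect_equal(selectivity_index(fv, fv), 1, tolerance = 1e-9)
  # invariant under a common dose-axis rescaling
  fv2 <- fit_4pl(7 * d, 1 / (1 + d / 30e-6), assay = "viability")
  fr2 <- fit_4pl(7 * d, 1 / (1 + d / 10e-6), assay = "reporter")
  expect_equal(selectivity_index(fv2, fr2), 3, tolerance = 1e-5)
})

test_that("group IC50 comparison reports percent difference and Student p", {
  same <- compare_group_ic50(c(10, 10), c(10, 10))
  expect_equal(same$percent_difference, 0)
  g <- compare_group_ic50(c(5.7, 5.9), c(9.9, 10.1))
  expect_equal(g$percent_difference, 100 * (10 - 5.8) / 10)
  set.seed(8)
  a <- rlnorm(5, log(5e-6), 0.3); b <- rlnorm(6, log(9e-6), 0.3)
  got <- compare_group_ic50(a, b)
  want <- student_t_oracle(a, b)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_error(compare_group_ic50(5, c(1, 2)), "2 IC50s")
})

test_that("bootstrap thermal-shift intervals hold nominal coverage", {
  hits <- vapply(1:60, function(r) {
    cet <- generate_cetsa(delta_tagg = 3, noise_cv = 0.1, replicates = 3,
                          seed = 5000 + r)
    dt <- delta_tagg(cet[cet$treatment == "treated", ],
                     cet[cet$treatment == "vehicle", ],
                     n_boot = 59, seed = r)
    dt$ci[1] <= 3 && 3 <= dt$ci[2]
  }, TRUE)
  expect_gte(mean(hits), 0.88)
})
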