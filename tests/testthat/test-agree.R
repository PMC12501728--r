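test_that("linear_fit reproduces hand-computed OLS", {
  # exact-line inputs: slope p-value is degenerate, summary.lm warns
  r <- suppressWarnings(linear_fit(1:3, c(2, 4, 6)))
  expect_equal(r$slope, 2); expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)
  r2 <- linear_fit(1:4, c(2, 1, 4, 3))
  expect_equal(r2$slope, 0.6)
  expect_equal(r2$intercept, 1.0)
  expect_equal(r2$r_squared, 0.36)
  # identity data
  r3 <- suppressWarnings(linear_fit(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(r3$slope, 1); expect_equal(r3$intercept, 0)
  expect_error(linear_fit(rep(2, 4), 1:4), "degenerate")
})

test_that("bland_altman matches hand computation and is translation-equivariant", {
  a <- c(100, 200, 300); b <- c(110, 190, 310)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, 10 / 3, tolerance = 1e-12)
  expect_equal(ba$sd_diff, sd(c(10, -10, 10)))
  expect_equal(ba$loa_low, -19.297, tolerance = 1e-3)
  expect_equal(ba$loa_high, 25.964, tolerance = 1e-3)
  # LoA half-width / 1.96 equals the sample SD exactly
  expect_equal((ba$loa_high - ba$loa_low) / 2 / 1.96, ba$sd_diff)
  # a == b
  z <- bland_altman(a, a)
  expect_equal(c(z$bias, z$loa_high - z$loa_low), c(0, 0))
  # adding a constant shifts bias, not the width
  bc <- bland_altman(a, b + 50)
  expect_equal(bc$bias, ba$bias + 50)
  expect_equal(bc$loa_high - bc$loa_low, ba$loa_high - ba$loa_low)
  expect_error(bland_altman(a, b[1:2]), "equal length")
})

test_that("REML equals closed-form ANOVA components on a balanced one-way design", {
  # 8 participants x 4 replicate scans, single modality, intercept only
  set.seed(13)
  np <- 8; nr <- 4
  p_eff <- rnorm(np, 0, 12)
  tab <- expand.grid(participant = 1:np, scan = 1:nr)
  tab$kidney <- "left"; tab$day <- 1; tab$modality <- "ASL"
  tab$perfusion_ml_min_100ml <- 250 + p_eff[tab$participant] +
    rnorm(nrow(tab), 0, 7)
  fit <- fit_mixed_model(tab, terms = "participant", fixed = ~1)
  # one-way ANOVA closed form
  gm <- tapply(tab$perfusion_ml_min_100ml, tab$participant, mean)
  msb <- nr * var(gm)
  msw <- mean(tapply(tab$perfusion_ml_min_100ml, tab$participant, var))
  expect_rel_equal(fit$sds["residual"]^2, msw, 1e-3)
  expect_rel_equal(fit$sds["participant"]^2, (msb - msw) / nr, 1e-3)
})

test_that("REML agrees with lme4 on a nested single-modality model", {
  skip_if_not_installed("lme4")
  vc <- variance_components(c(ASL = 50, PET = 50), 20, c(ASL = 10, PET = 10),
                            c(ASL = 30, PET = 30))
  tab <- simulate_agreement_dataset(agreement_design(n_participants = 40),
                                    vc, seed = 17)
  asl <- tab[tab$modality == "ASL", ]
  fit <- fit_mixed_model(asl, fixed = ~ factor(scan))
  m <- lme4::lmer(perfusion_ml_min_100ml ~ factor(scan) + (1 | participant) +
                    (1 | participant:kidney) + (1 | participant:kidney:day),
                  data = asl, REML = TRUE)
  vcs <- as.data.frame(lme4::VarCorr(m))
  ref <- c(participant = vcs$sdcor[vcs$grp == "participant"],
           kidney = vcs$sdcor[vcs$grp == "participant:kidney"],
           day = vcs$sdcor[vcs$grp == "participant:kidney:day"],
           residual = vcs$sdcor[vcs$grp == "Residual"])
  # absolute SD scale (both fits may pin the day SD at the zero boundary)
  expect_lt(max(abs(fit$sds[c("participant", "kidney", "day", "residual")] -
                      ref[c("participant", "kidney", "day", "residual")])),
            0.1)
})

test_that("pure fixed-effect data yields zero SDs and exact coefficients", {
  des <- agreement_design(n_participants = 4)
  vc0 <- variance_components(c(ASL = 0, PET = 0), 0, c(ASL = 0, PET = 0),
                             c(ASL = 0, PET = 0))
  tab <- simulate_agreement_dataset(des, vc0, seed = 3)
  fit <- fit_mixed_model(tab)
  expect_true(all(fit$sds <= 1e-6))
  expect_equal(unname(fit$fixed["(Intercept)"]), 286, tolerance = 1e-8)
  expect_equal(unname(fit$fixed["modalityPET"]), 13, tolerance = 1e-8)
})

test_that("REML value at the optimum does not degrade from the starting point", {
  vc <- variance_components(c(ASL = 50, PET = 50), 20, c(ASL = 10, PET = 10),
                            c(ASL = 30, PET = 30))
  tab <- simulate_agreement_dataset(agreement_design(n_participants = 20),
                                    vc, seed = 19)
  fit <- fit_mixed_model(tab)
  expect_lte(fit$reml_neg2ll, fit$start_value)
  expect_true(fit$converged)
})

test_that("agreement derivation applies the variance-summation rule", {
  vc <- variance_components(sd_participant = c(ASL = 40, PET = 35),
                            sd_kidney = 20, sd_day = c(ASL = 8, PET = 9),
                            sd_residual = c(ASL = 30.81, PET = 25))
  # same-day repeatability: residual only, twice
  rep_asl <- derive_agreement(vc, comparison_repeatability("ASL"),
                              reference_mean = 283.5)
  expect_equal(rep_asl$loa, 1.96 * sqrt(2 * 30.81^2), tolerance = 1e-9)
  expect_equal(rep_asl$loa, 85.4, tolerance = 0.05)
  expect_equal(rep_asl$cov_percent, 10.9, tolerance = 0.05)
  # between-day reproducibility: day + residual, each twice
  rpd <- derive_agreement(vc, comparison_reproducibility("PET"),
                          reference_mean = 304.5)
  expect_equal(rpd$loa, 1.96 * sqrt(2 * 9^2 + 2 * 25^2), tolerance = 1e-9)
  # cross-modality: participant + day + residual from both sides
  cx <- derive_agreement(vc, comparison_cross_modality(),
                         reference_mean = 292.7)
  expect_equal(cx$loa,
               1.96 * sqrt(40^2 + 35^2 + 8^2 + 9^2 + 30.81^2 + 25^2),
               tolerance = 1e-9)
  # degenerate variances
  vc0 <- variance_components(c(ASL = 0, PET = 0), 0, c(ASL = 0, PET = 0),
                             c(ASL = 0, PET = 0))
  d0 <- derive_agreement(vc0, comparison_repeatability("ASL"),
                         reference_mean = 100)
  expect_equal(d0$loa, 0)
  expect_error(comparison_spec("ASL", "ASL", 1, 1), "differ")
})

test_that("derived LoA matches simulated paired differences", {
  vc <- variance_components(sd_participant = c(ASL = 40, PET = 35),
                            sd_kidney = 20, sd_day = c(ASL = 8, PET = 9),
                            sd_residual = c(ASL = 30, PET = 25))
  n <- 1e5
  set.seed(23)
  # reproducibility ASL: shared participant/kidney cancel; day and residual differ
  d_rep <- (rnorm(n, 0, 8) + rnorm(n, 0, 30)) - (rnorm(n, 0, 8) + rnorm(n, 0, 30))
  loa_emp <- 1.96 * sd(d_rep)
  loa_rule <- derive_agreement(vc, comparison_reproducibility("ASL"),
                               reference_mean = 280)$loa
  expect_rel_equal(loa_emp, loa_rule, 0.02)
  # cross-modality: participant, day, residual all differ per side
  d_cx <- (rnorm(n, 0, 40) + rnorm(n, 0, 8) + rnorm(n, 0, 30)) -
    (rnorm(n, 0, 35) + rnorm(n, 0, 9) + rnorm(n, 0, 25))
  expect_rel_equal(1.96 * sd(d_cx),
                   derive_agreement(vc, comparison_cross_modality(),
                                    reference_mean = 292)$loa, 0.02)
})

test_that("cov_from_loa applies the paired-difference convention", {
  expect_equal(cov_from_loa(1.96 * sqrt(2), 100), 1.0)
  expect_equal(cov_from_loa(85.4, 283.5), 10.9, tolerance = 0.05)
  expect_equal(cov_from_loa(136, 292.7), 16.8, tolerance = 0.05)
  expect_error(cov_from_loa(-1, 100), "positive")
})
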