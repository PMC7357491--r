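test_that("a two-level one-factor design is fitted exactly", {
  df <- tibble::tibble(g = rep(c("a", "b"), each = 3), value = rep(c(1, 3), each = 3))
  fit <- fit_assay_model(df, model_spec("value", fixed_factors = "g"))
  expect_equal(unname(fit$coefficients["gb"]), 2)
  expect_equal(fit$sigma2, 0)
  expect_equal(fit$residual_df, 4)
})

test_that("the OLS path matches the normal-equations oracle and lm()", {
  df <- two_factor_fixture()
  expect_lte(nrow(df), 50)
  spec <- model_spec("value", fixed_factors = c("f", "g"),
                     interactions = list(c("f", "g")))
  fit <- fit_assay_model(df, spec)
  X <- model.matrix(~ f + g + f:g, df)
  expect_equal(unname(fit$coefficients), ols_normal_equations(X, df$value),
               tolerance = 1e-8)
  lmfit <- lm(value ~ f + g + f:g, df)
  expect_equal(unname(fit$coefficients), unname(coef(lmfit)), tolerance = 1e-8)
  expect_equal(fit$sigma2, summary(lmfit)$sigma^2, tolerance = 1e-8)
  expect_equal(unname(fit$vcov), unname(vcov(lmfit)), tolerance = 1e-8)
})

test_that("design pathologies raise classed errors", {
  df <- two_factor_fixture()
  expect_error(
    fit_assay_model(dplyr::filter(df, f == "a"),
                    model_spec("value", fixed_factors = "f")),
    class = "rhizorank_design_error"
  )
  # aliased copy of a factor
  df$f2 <- df$f
  expect_error(
    fit_assay_model(df, model_spec("value", fixed_factors = c("f", "f2"))),
    class = "rhizorank_singular_error"
  )
  expect_error(model_spec("value", fixed_factors = "u", random_intercept = "u"),
               class = "rhizorank_design_error")
})

test_that("marginal means average cells equally, not by cell counts", {
  df <- two_factor_fixture()
  spec <- model_spec("value", fixed_factors = c("f", "g"),
                     interactions = list(c("f", "g")))
  fit <- fit_assay_model(df, spec)
  mm <- marginal_means(fit, "f")
  # with the interaction model, fitted cell means are raw cell means:
  cell <- dplyr::summarise(dplyr::group_by(df, f, g), m = mean(value),
                           .groups = "drop")
  byhand <- dplyr::summarise(dplyr::group_by(cell, f), m = mean(m),
                             .groups = "drop")
  expect_equal(mm$estimate, byhand$m, tolerance = 1e-10)
  # not the raw (count-weighted) means in this unbalanced design
  raw <- dplyr::summarise(dplyr::group_by(df, f), m = mean(value), .groups = "drop")
  expect_gt(max(abs(mm$estimate - raw$m)), 1e-3)
  # balanced one-factor design: marginal means are the group means
  bal <- tibble::tibble(g = rep(c("a", "b"), each = 4),
                        value = c(1, 2, 3, 4, 2, 4, 6, 8))
  fitb <- fit_assay_model(bal, model_spec("value", fixed_factors = "g"))
  mmb <- marginal_means(fitb, "g")
  expect_equal(mmb$estimate, c(2.5, 5), tolerance = 1e-12)
  # intercept-only model: the grand mean
  fit0 <- fit_assay_model(bal, model_spec("value"))
  expect_equal(marginal_means(fit0)$estimate, mean(bal$value), tolerance = 1e-12)
  expect_error(marginal_means(fitb, "nope"), class = "rhizorank_key_error")
})

test_that("marginal means agree with emmeans on an unbalanced fixture", {
  library(emmeans)
  df <- two_factor_fixture()
  fit <- fit_assay_model(df, model_spec("value", fixed_factors = c("f", "g"),
                                        interactions = list(c("f", "g"))))
  mm <- marginal_means(fit, "f")
  em <- as.data.frame(emmeans(lm(value ~ f * g, df), "f"))
  expect_equal(mm$estimate, em$emmean, tolerance = 1e-8)
  expect_equal(mm$se, em$SE, tolerance = 1e-8)
  expect_equal(mm$df, em$df, tolerance = 1e-6)
})

test_that("the REML engine recovers variance components and matches lme4", {
  library(lme4)
  df <- lmm_fixture(seed = 7, sigma2_b = 0.5, sigma2_e = 0.1)
  fit <- fit_assay_model(df, model_spec("value", covariates = "x",
                                        random_intercept = "u"))
  expect_lt(abs(fit$group_variance - 0.5) / 0.5, 0.3)
  expect_lt(abs(fit$sigma2 - 0.1) / 0.1, 0.3)
  lfit <- lmer(value ~ x + (1 | u), df, REML = TRUE)
  expect_equal(unname(fit$coefficients), unname(fixef(lfit)), tolerance = 1e-5)
  vc <- as.data.frame(VarCorr(lfit))
  expect_equal(fit$group_variance, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2, vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(coef(summary(lfit))[, "Std. Error"]), tolerance = 1e-4)
})

test_that("Satterthwaite degrees of freedom track lmerTest", {
  library(lmerTest)
  df <- lmm_fixture(seed = 21, n_units = 8, n_per = 4,
                    sigma2_b = 0.3, sigma2_e = 0.2)
  fit <- fit_assay_model(df, model_spec("value", covariates = "x",
                                        random_intercept = "u"))
  ltfit <- lmerTest::lmer(value ~ x + (1 | u), df, REML = TRUE)
  co <- coef(summary(ltfit))
  idx <- which(names(fit$coefficients) == "x")
  L <- as.numeric(seq_along(fit$coefficients) == idx)
  expect_equal(rhizorank:::contrast_df(fit, L), co["x", "df"], tolerance = 0.02)
})

test_that("Tukey comparisons behave at the boundary cases", {
  # identical groups: p = 1, shared letter
  df <- tibble::tibble(g = rep(c("a", "b"), each = 3), value = rep(2, 6))
  tp <- tukey_pairwise(fit_assay_model(df, model_spec("value", fixed_factors = "g")), "g")
  expect_equal(tp$p_adjusted, 1)
  expect_equal(cld_letters(tp)$letters, c("A", "A"))
  # k = 2: Tukey p equals the pooled two-sample t-test p
  set.seed(5)
  df2 <- tibble::tibble(g = rep(c("a", "b"), each = 6),
                        value = rnorm(12) + rep(c(0, 1), each = 6))
  tp2 <- tukey_pairwise(fit_assay_model(df2, model_spec("value", fixed_factors = "g")), "g")
  tt <- t.test(value ~ g, df2, var.equal = TRUE)
  expect_equal(tp2$p_adjusted, tt$p.value, tolerance = 1e-6)
  expect_error(
    tukey_pairwise(fit_assay_model(df2, model_spec("value", fixed_factors = "g")),
                   "g", alpha = 1.2),
    class = "rhizorank_domain_error"
  )
})

test_that("Tukey p-values and letters match emmeans on a three-group design", {
  library(emmeans)
  set.seed(12)
  df <- tibble::tibble(g = rep(c("a", "b", "c"), each = 5),
                       value = rnorm(15, sd = 0.1) + rep(c(0, 0, 10), each = 5))
  fit <- fit_assay_model(df, model_spec("value", fixed_factors = "g"))
  tp <- tukey_pairwise(fit, "g", alpha = 0.05)
  em <- summary(contrast(emmeans(lm(value ~ g, df), "g"), method = "pairwise",
                         adjust = "tukey"))
  expect_equal(tp$p_adjusted, em$p.value, tolerance = 1e-6)
  letters <- cld_letters(tp)$letters
  expect_equal(letters[1], letters[2])   # a and b indistinguishable
  expect_false(letters[3] %in% letters[1:2])  # c distinct
})

test_that("degradation velocities recover slopes and gate correctly", {
  # noiseless line: exact slope, significant
  tbl <- od_series(slope = 0.01)
  vel <- degradation_velocities(tbl)
  expect_equal(vel$velocity, 0.01, tolerance = 1e-12)
  expect_equal(vel$flag, "significant_slope")
  # flat series: gated to zero
  flat <- od_series(slope = 0)
  velf <- degradation_velocities(flat)
  expect_equal(velf$velocity, 0)
  expect_equal(velf$flag, "gated_to_zero")
  # noisy recovery within +/- 0.002 of the 0.008 truth
  noisy <- od_series(slope = 0.008, noise_sd = 0.01, plate_sd = 0.02, seed = 42)
  veln <- degradation_velocities(noisy)
  expect_lt(abs(veln$slope - 0.008), 0.002)
  # too few time points
  short <- od_series(slope = 0.01, times = c(12, 24))
  expect_error(degradation_velocities(short),
               class = "rhizorank_insufficient_data_error")
})

test_that("velocity gating is monotone in alpha", {
  set.seed(33)
  tables <- lapply(1:12, function(i) {
    od_series(slope = sample(c(0, 0.004, 0.01), 1), noise_sd = 0.01,
              plate_sd = 0.02, substrate = sprintf("s%02d", i))
  })
  tbl <- assay_table(dplyr::bind_rows(lapply(tables, tibble::as_tibble)))
  counts <- vapply(c(0.01, 0.05, 0.2), function(a) {
    sum(degradation_velocities(tbl, alpha = a)$flag == "significant_slope")
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("siderophore percent applies the x100 rule with clipping", {
  expect_equal(siderophore_percent(0), 0)
  expect_equal(siderophore_percent(0.594), 59.4)
  expect_warning(pct <- siderophore_percent(1.2), "clipped")
  expect_equal(pct, 100)
  expect_error(siderophore_percent(-0.1), class = "rhizorank_domain_error")
  # conventional reference formula behind the switch
  expect_equal(siderophore_percent(0.25, method = "reference", reference = 1), 75)
})

test_that("capture contrast is the group-mean difference in percent", {
  expect_equal(capture_contrast(c(86.1, 88.4), 59.4), 27.85)
  expect_equal(round(capture_contrast(c(86.1, 88.4), 59.4)), 28)
  expect_equal(capture_contrast(50, 50), 0)
  expect_equal(capture_contrast(c(10, 30), 0), 20)
  expect_error(capture_contrast(numeric(0), 50), class = "rhizorank_domain_error")
  expect_error(capture_contrast(c(50, 120), 10), class = "rhizorank_domain_error")
})

test_that("the Levene check flags heteroscedastic groups", {
  df_eq <- tibble::tibble(g = rep(c("a", "b"), each = 4),
                          value = c(1, 2, 3, 4, 11, 12, 13, 14))
  out <- levene_check(df_eq, "value", "g")
  expect_gt(out$p_value, 0.9)
  set.seed(8)
  df_ne <- tibble::tibble(g = rep(c("a", "b"), each = 20),
                          value = c(rnorm(20, sd = 1), rnorm(20, sd = 10)))
  expect_lt(levene_check(df_ne, "value", "g")$p_value, 0.05)
  df_deg <- tibble::tibble(g = c("a", "b"), value = c(1, 2))
  expect_error(levene_check(df_deg, "value", "g"),
               class = "rhizorank_design_error")
})

test_that("the performance matrix is complete, back-transformed and gated", {
  mm_halo <- tibble::tibble(strain = c("A", "B"), attribute = "Pca",
                            value = expm1(c(0.5, 0.9)))
  vel <- tibble::tibble(strain = c("A", "B"), attribute = "S01",
                        value = c(0, 0.01))
  perf <- build_performance_matrix(mm_halo, vel)
  expect_equal(nrow(perf), 4)
  expect_equal(perf$value[perf$strain == "A" & perf$attribute == "S01"], 0)
  expect_equal(perf$value[perf$strain == "A" & perf$attribute == "Pca"],
               expm1(0.5))
  err <- expect_error(
    build_performance_matrix(mm_halo, vel[1, ],
                             attributes = c("Pca", "S01")),
    class = "rhizorank_completeness_error"
  )
  expect_match(conditionMessage(err), "B/S01")
  expect_error(build_performance_matrix(mm_halo, mm_halo),
               class = "rhizorank_integrity_error")
})
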