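test_that("with no random terms the engine reproduces the IRLS optimum", {
  g <- gen_glmm_data(4000, beta = c("(Intercept)" = 0.4, dam_age = -0.3,
                                    offspring_f = -0.5), seed = 21)
  spec <- model_spec(fixed_terms = c("dam_age", "offspring_f"),
                     random_intercepts = character(0))
  fit <- fit_glmm(spec, g$data)
  X <- cbind("(Intercept)" = 1, dam_age = g$data$dam_age,
             offspring_f = g$data$offspring_f)
  oracle <- irls_logistic(X, g$data$survival)
  expect_equal(unname(fit$beta), unname(oracle), tolerance = 1e-6)
  expect_length(fit$sigma2, 0)
  expect_equal(fit$k_params, 3)
})

test_that("intercept-only fit on balanced outcomes is near zero", {
  d <- data.frame(survival = rep(0:1, each = 500), species = "sp1")
  fit <- fit_glmm(model_spec(fixed_terms = character(0),
                             random_intercepts = character(0)), d)
  expect_lt(abs(fit$beta[["(Intercept)"]]), 3 * fit$se[["(Intercept)"]] + 1e-9)
})

test_that("mixed-model fit recovers variance structure and is order-invariant", {
  g <- gen_glmm_data(2500, beta = c("(Intercept)" = 0.3, offspring_f = -0.4),
                     sd_sp = 0.5, sd_prog = 0.2, sd_year = 0.2,
                     n_sp = 4, seed = 31)
  spec <- model_spec(fixed_terms = "offspring_f")
  fit <- suppressWarnings(fit_glmm(spec, g$data))
  expect_true(all(fit$sigma2 >= 0))
  expect_equal(fit$k_params, 2 + 3)
  # Wald CI covers the true slope here
  expect_lt(abs(fit$beta[["offspring_f"]] - (-0.4)),
            2.5 * fit$se[["offspring_f"]])
  # invariance to row order and to relabeling of grouping-factor levels
  perm <- sample(nrow(g$data))
  d2 <- g$data[perm, ]
  d2$birth_program <- paste0("relabel_", d2$birth_program)
  fit2 <- suppressWarnings(fit_glmm(spec, d2))
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-6)
  expect_equal(fit$loglik, fit2$loglik, tolerance = 1e-6)
})

test_that("Wald 95% CIs for a fixed effect cover the truth (Laplace, scaled run)", {
  # property stated at n=5000 x 50 replicates; run at n=1200 for runtime,
  # same >= 80% coverage bar
  covered <- logical(40)
  for (r in seq_along(covered)) {
    g <- gen_glmm_data(1200, beta = c("(Intercept)" = 0.3,
                                      offspring_f = -0.3),
                       sd_sp = 0.3, sd_prog = 0.2, sd_year = 0.15,
                       n_sp = 3, seed = 1000 + r)
    fit <- suppressWarnings(fit_glmm(model_spec(fixed_terms = "offspring_f"),
                                     g$data))
    b <- fit$beta[["offspring_f"]]; s <- fit$se[["offspring_f"]]
    covered[r] <- (b - 1.96 * s) <= -0.3 && -0.3 <= (b + 1.96 * s)
  }
  expect_gte(mean(covered), 0.8)
})

test_that("random-slope models recover species-level heterogeneity", {
  # heterogeneous slopes across 15 species
  set.seed(1)
  sl <- setNames(rnorm(15, 0.2, 0.3), sprintf("sp%02d", 1:15))
  g <- gen_glmm_data(12000, beta = c("(Intercept)" = 0.3, dam_age = 0),
                     sd_sp = 0.3, n_sp = 15, n_prog = 2, n_year = 5,
                     seed = 55, slope_pred = "dam_age",
                     slope_by_species = sl)
  rs <- suppressWarnings(fit_random_slope("dam_age", g$data,
                                          spec = model_spec(
                                            fixed_terms = "dam_age")))
  expect_length(rs$species_effects, 15)
  expect_gt(rs$slope_variance, 0)
  # sign recovery for clearly non-zero species effects
  strong <- names(sl)[abs(sl) > 0.3]
  agree <- sign(rs$species_effects[strong]) == sign(sl[strong])
  expect_gte(mean(agree), 0.8)
  # BLUPs centred: mean species effect close to the fixed slope
  expect_lt(abs(mean(rs$species_effects) - rs$beta[["dam_age"]]), 0.05)
})

test_that("random-slope variance collapses when species share one slope", {
  sl <- setNames(rep(0.25, 6), sprintf("sp%02d", 1:6))
  g <- gen_glmm_data(6000, beta = c("(Intercept)" = 0.2, dam_age = 0),
                     sd_sp = 0.3, n_sp = 6, n_prog = 2, n_year = 5,
                     seed = 77, slope_pred = "dam_age",
                     slope_by_species = sl)
  rs <- suppressWarnings(fit_random_slope("dam_age", g$data,
                                          spec = model_spec(
                                            fixed_terms = "dam_age")))
  expect_lt(rs$slope_variance, 0.02)
  expect_true(all(abs(rs$species_effects - rs$beta[["dam_age"]]) <
                    2 * rs$se[["dam_age"]] + 0.05))
})

test_that("simulation from a fit matches its fitted probabilities", {
  g <- gen_glmm_data(800, beta = c("(Intercept)" = 0.2, dam_age = -0.6),
                     seed = 9)
  fit <- fit_glmm(model_spec(fixed_terms = "dam_age",
                             random_intercepts = character(0)), g$data)
  expect_equal(dim(simulate_from_fit(fit, 0)), c(800, 0))
  sims <- simulate_from_fit(fit, 1000, seed = 4)
  expect_true(all(sims %in% 0:1))
  expect_lt(max(abs(rowMeans(sims) - fit$fit$fitted.values)), 0.05)
  # deterministic under the seed
  expect_identical(sims, simulate_from_fit(fit, 1000, seed = 4))
  # degenerate all-survivors data: fitted p ~ 1, so all simulations are 1
  d1 <- data.frame(survival = rep(1L, 30), species = "sp1")
  fit1 <- suppressWarnings(fit_glmm(model_spec(fixed_terms = character(0),
                                               random_intercepts = character(0)),
                                    d1))
  expect_true(all(simulate_from_fit(fit1, 50, seed = 1) == 1L))
})

test_that("residual diagnostics are calibrated and detect injected zeros", {
  # calibration: data generated by the fitted model family should rarely fail
  # the KS uniformity test (<= 10% at alpha = 0.05; scaled-down 100-run check)
  reject <- logical(100)
  for (r in seq_along(reject)) {
    g <- gen_glmm_data(400, beta = c("(Intercept)" = 0.4, dam_age = -0.4),
                       seed = 2000 + r)
    fit <- fit_glmm(model_spec(fixed_terms = "dam_age",
                               random_intercepts = character(0)), g$data)
    di <- residual_diagnostics(fit, g$data, n_sims = 100, seed = 3000 + r)
    reject[r] <- di$ks_uniformity_p < 0.05
  }
  expect_lte(mean(reject), 0.10)

  # dispersion ratio ~ 1 for correctly specified Bernoulli data
  g <- gen_glmm_data(1500, beta = c("(Intercept)" = 0.3, dam_age = -0.4),
                     seed = 71)
  fit <- fit_glmm(model_spec(fixed_terms = "dam_age",
                             random_intercepts = character(0)), g$data)
  d0 <- residual_diagnostics(fit, g$data, n_sims = 200, seed = 8)
  expect_gt(d0$dispersion_p, 0.05)
  expect_lt(abs(d0$dispersion_ratio - 1), 0.25)
  expect_gt(d0$outlier_p, 0.05)

  # inject extra zeros: 20% of responses forced to 0
  d_zi <- g$data
  set.seed(99)
  d_zi$survival[sample(nrow(d_zi), 0.2 * nrow(d_zi))] <- 0L
  # diagnose the corrupted responses against the clean model's simulations
  di_zi <- residual_diagnostics(fit, d_zi, n_sims = 200, seed = 12)
  expect_gt(di_zi$zero_inflation_ratio, 1)
  expect_lt(di_zi$zero_inflation_p, 0.05)
})

test_that("VIFs follow the closed form", {
  # exactly orthogonal predictors via QR
  set.seed(5)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(50 * 3), 50, 3))))
  d <- data.frame(a = Q[, 2], b = Q[, 3], c = Q[, 4])
  v <- variance_inflation(d, c("a", "b", "c"))
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-10)
  expect_false(any(v$flag))

  # sample correlation exactly 0.6 -> VIF = 1/(1 - 0.36) = 1.5625
  x1 <- sqrt(49) * Q[, 2] # unit sample variance after scaling below
  e <- sqrt(49) * Q[, 3]
  d2 <- data.frame(x1 = x1, x2 = 0.6 * x1 + 0.8 * e)
  v2 <- variance_inflation(d2, c("x1", "x2"))
  expect_equal(v2$vif, c(1.5625, 1.5625), tolerance = 1e-10)

  # duplicated column -> infinite VIF, flagged
  d3 <- data.frame(a = rnorm(20))
  d3$b <- d3$a
  v3 <- variance_inflation(d3, c("a", "b"))
  expect_true(all(is.infinite(v3$vif)))
  expect_true(all(v3$flag))
  expect_error(variance_inflation(d3, "a"), "at least 2")
})
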