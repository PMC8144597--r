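test_that("AICc follows its formula and limits", {
  # hand computation: loglik -5, k 2, n 10 -> AIC 14, AICc 14 + 12/7
  expect_equal(aicc(-5, k = 2, n = 10), 14 + 12 / 7)
  # converges to AIC for large n
  expect_lt(abs(aicc(-100, k = 5, n = 10000) - (2 * 100 + 2 * 5)), 0.01)
  # undefined when n <= k + 1
  expect_error(aicc(-5, k = 9, n = 10), "AICc undefined")
})

test_that("dredge enumerates all subsets and normalizes weights", {
  g <- gen_glmm_data(600, beta = c("(Intercept)" = 0.3, dam_age = -0.5,
                                   sire_age = 0, offspring_f = 0),
                     sd_sp = 0.2, n_sp = 3, n_prog = 2, n_year = 5, seed = 13)
  spec <- model_spec(fixed_terms = c("dam_age", "sire_age", "offspring_f"))
  ms <- suppressWarnings(dredge(spec, g$data, nAGQ = 0))
  expect_equal(nrow(ms$table), 2^3)
  expect_equal(sum(ms$table$weight), 1, tolerance = 1e-12)
  expect_equal(min(ms$table$delta), 0)
  expect_true(all(diff(ms$table$aicc) >= 0))
  # intercept-only model present
  expect_true("(intercept)" %in% ms$table$terms)
  # the active predictor appears in the top model
  expect_match(ms$table$terms[1], "dam_age")
  # aicc consistent with each fit's own loglik/k/n
  expect_equal(ms$table$aicc,
               vapply(ms$fits, aicc, numeric(1)))
})

test_that("conditional averaging has the stated degenerate behaviour", {
  g <- gen_glmm_data(600, beta = c("(Intercept)" = 0.3, dam_age = -0.5,
                                   sire_age = 0), sd_sp = 0.2, n_sp = 3,
                     n_prog = 2, n_year = 5, seed = 14)
  spec <- model_spec(fixed_terms = c("dam_age", "sire_age"))
  ms <- suppressWarnings(dredge(spec, g$data, nAGQ = 0))

  # single retained model: averaged estimates equal that model exactly
  avg1 <- retain_and_average(ms, delta_cutoff = 1e-9)
  top <- ms$fits[[1]]
  for (pr in names(top$beta)) {
    row <- avg1$estimates[avg1$estimates$predictor == pr, ]
    expect_equal(row$estimate, unname(top$beta[pr]))
    expect_equal(row$se, unname(top$se[pr]))
    expect_equal(row$relative_importance, 1)
  }
  # predictors absent from the single retained model: NA estimate, RI 0
  absent <- setdiff(spec$fixed_terms, names(top$beta))
  for (pr in absent) {
    row <- avg1$estimates[avg1$estimates$predictor == pr, ]
    expect_true(is.na(row$estimate))
    expect_equal(row$relative_importance, 0)
  }

  # averaged estimate lies within the range of component estimates, and
  # adding models beyond the cutoff never changes the result
  avg2 <- retain_and_average(ms, delta_cutoff = 2)
  for (pr in spec$fixed_terms) {
    comp <- vapply(avg2$retained$model, function(m) {
      f <- ms$fits[[which(ms$table$model == m)]]
      if (pr %in% names(f$beta)) unname(f$beta[pr]) else NA_real_
    }, numeric(1))
    est <- avg2$estimates$estimate[avg2$estimates$predictor == pr]
    if (!is.na(est)) {
      expect_gte(est, min(comp, na.rm = TRUE) - 1e-12)
      expect_lte(est, max(comp, na.rm = TRUE) + 1e-12)
    }
  }
  # two-model hand check with equal weights
  w <- c(0.5, 0.5); b <- c(0.1, 0.3)
  expect_equal(sum(w * b), 0.2)
})

test_that("pooling averages replicates and applies the CI significance rule", {
  mk_avg <- function(est, se) {
    structure(list(estimates = data.frame(
      predictor = c("(Intercept)", "offspring_f"),
      estimate = c(0.4, est), se = c(0.1, se),
      ci_low = NA, ci_high = NA, relative_importance = 1,
      stringsAsFactors = FALSE), retained = NULL, n_retained = 1,
      delta_cutoff = 2), class = "averaged_estimates")
  }
  reps <- list(mk_avg(0.1, 0.05), mk_avg(0.2, 0.05), mk_avg(0.3, 0.05),
               mk_avg(0.2, 0.05), mk_avg(0.2, 0.05))
  pooled <- pool_replicates(reps)
  row <- pooled[pooled$predictor == "offspring_f", ]
  expect_equal(row$mean_estimate, 0.2)
  expect_equal(row$mean_se, 0.05)
  expect_equal(row$ci_low, 0.2 - 1.96 * 0.05)
  # significance iff |mean estimate| > 1.96 * mean SE
  expect_true(row$significant)
  weak <- pool_replicates(list(mk_avg(0.05, 0.05)))
  expect_false(weak[weak$predictor == "offspring_f", "significant"])
  # single replicate pools to itself
  one <- pool_replicates(list(mk_avg(0.1, 0.02)))
  expect_equal(one$mean_estimate[2], 0.1)
  # mismatched predictor sets -> error
  bad <- mk_avg(0.1, 0.05)
  bad$estimates$predictor[2] <- "dam_age"
  expect_error(pool_replicates(list(mk_avg(0.1, 0.05), bad)), "mismatched")
})

test_that("a strong true predictor dominates relative importance", {
  # scaled-down version of the selection-consistency property
  wins <- logical(6)
  for (r in seq_along(wins)) {
    g <- gen_glmm_data(900, beta = c("(Intercept)" = 0.3, offspring_f = -0.5,
                                     sire_f = 0), sd_sp = 0.2, n_sp = 3,
                       n_prog = 2, n_year = 5, seed = 400 + r)
    ms <- suppressWarnings(dredge(model_spec(
      fixed_terms = c("offspring_f", "sire_f")), g$data, nAGQ = 0))
    avg <- retain_and_average(ms)
    ri <- setNames(avg$estimates$relative_importance,
                   avg$estimates$predictor)
    wins[r] <- ri[["offspring_f"]] >= ri[["sire_f"]]
  }
  expect_gte(mean(wins), 0.9)
})
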