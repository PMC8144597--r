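#' Specify the binomial survival mixed model
#'
#' The global model is
#' `survival ~ dam_generation + sire_generation + dam_age + sire_age +
#' dam_f + sire_f + offspring_f` with nested random intercepts for species,
#' birth program within species, and birth year within species. The nesting is
#' expanded into three independent intercept terms (`Species`,
#' `Species:BirthProgram`, `Species:Year`); a random slope, when present, is a
#' species-level slope uncorrelated with the species intercept.
#'
#' @param fixed_terms character vector of fixed-effect predictors (subset of
#'   the seven; the intercept is always included).
#' @param random_intercepts grouping factors among `"species"`,
#'   `"species:birth_program"`, `"species:year"`; empty vector fits a plain
#'   logistic regression (all random-effect variances constrained to zero).
#' @param random_slope optional predictor name to give an (uncorrelated)
#'   species-level random slope.
#' @param response response column (default `"survival"`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(fixed_terms = PREDICTORS,
                       random_intercepts = c("species",
                                             "species:birth_program",
                                             "species:year"),
                       random_slope = NULL,
                       response = "survival") {
  bad <- setdiff(random_intercepts,
                 c("species", "species:birth_program", "species:year"))
  if (length(bad))
    stopf("unknown random intercept term(s): %s", paste(bad, collapse = ", "))
  if (!is.null(random_slope) && length(random_slope) != 1L)
    stopf("`random_slope` must be a single predictor name")
  structure(list(response = response,
                 fixed_terms = as.character(fixed_terms),
                 random_intercepts = random_intercepts,
                 random_slope = random_slope),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", deparse(spec_formula(x)), "\n")
  invisible(x)
}

# grouping-factor columns used in model frames
RE_VARS <- c("species" = ".sp", "species:birth_program" = ".sp_prog",
             "species:year" = ".sp_year")

spec_formula <- function(spec) {
  fixed <- if (length(spec$fixed_terms))
    paste(spec$fixed_terms, collapse = " + ") else "1"
  re <- character(0)
  if (length(spec$random_intercepts))
    re <- sprintf("(1 | %s)", RE_VARS[spec$random_intercepts])
  if (!is.null(spec$random_slope))
    re <- c(re, sprintf("(0 + %s | .sp)", spec$random_slope))
  rhs <- paste(c(fixed, re), collapse = " + ")
  as.formula(paste(spec$response, "~", rhs))
}

# add grouping-factor columns for the nested random design
model_frame <- function(spec, data) {
  d <- as.data.frame(data)
  need <- unique(c(spec$response, spec$fixed_terms, spec$random_slope))
  missing <- setdiff(need, names(d))
  if (length(missing))
    stopf("column(s) missing from data: %s", paste(missing, collapse = ", "))
  if ("species" %in% names(d)) d$.sp <- factor(d$species)
  if ("birth_program" %in% names(d))
    d$.sp_prog <- factor(paste(d$species, d$birth_program, sep = ":"))
  if ("birth_year" %in% names(d))
    d$.sp_year <- factor(paste(d$species, d$birth_year, sep = ":"))
  for (term in spec$random_intercepts) {
    v <- RE_VARS[[term]]
    if (!v %in% names(d))
      stopf("grouping columns for '%s' missing from data", term)
    if (nlevels(d[[v]]) < 2L)
      stopf("grouping factor '%s' has fewer than 2 levels", term)
  }
  d
}

#' Fit the binomial survival GLMM
#'
#' Maximum likelihood via the Laplace approximation (lme4). With an empty
#' random structure the model reduces to plain logistic regression (all
#' random-effect variances constrained to zero) and is fit by Fisher scoring;
#' the two routes agree in log-likelihood when the variances vanish. Fitting
#' is deterministic given the data.
#'
#' @param spec a [model_spec()].
#' @param data a [standardized_table][standardize_within_species()] (or any
#'   data frame with the response, predictors and grouping columns).
#' @param nAGQ integer passed to [lme4::glmer()]; 1 (default) is the Laplace
#'   approximation, 0 uses the faster penalized-least-squares step only
#'   (useful for large all-subsets screens).
#' @param ... further arguments to [lme4::glmer()].
#' @return An object of class `glmm_fit`: fixed-effect estimates (`beta`,
#'   logit scale) and standard errors (`se`), random-effect variances
#'   (`sigma2`), `loglik`, `n_obs`, `k_params` (fixed effects + variance
#'   components), `converged`, accumulated `messages`, and the underlying
#'   `fit` object.
#' @export
fit_glmm <- function(spec, data, nAGQ = 1L, ...) {
  d <- model_frame(spec, data)
  form <- spec_formula(spec)
  msgs <- character(0)
  if (length(spec$random_intercepts) || !is.null(spec$random_slope)) {
    fit <- withCallingHandlers(
      lme4::glmer(form, data = d, family = binomial(), nAGQ = nAGQ, ...),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    vc <- lme4::VarCorr(fit)
    sigma2 <- vapply(vc, function(m) unname(diag(m))[1], numeric(1))
    conv <- length(fit@optinfo$conv$lme4) == 0L &&
      !any(grepl("failed to converge", msgs, fixed = TRUE))
  } else {
    fit <- glm(form, data = d, family = binomial())
    beta <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    sigma2 <- numeric(0)
    conv <- fit$converged
  }
  if (any(abs(beta) > 15))
    warnf("possible separation: |standardized coefficient| > 15 (%s)",
          paste(names(beta)[abs(beta) > 15], collapse = ", "))
  out <- structure(list(
    spec = spec,
    beta = beta,
    se = setNames(as.numeric(se), names(beta)),
    sigma2 = sigma2,
    loglik = as.numeric(logLik(fit)),
    n_obs = nrow(d),
    k_params = length(beta) + length(sigma2),
    converged = conv,
    messages = msgs,
    fit = fit), class = "glmm_fit")
  out
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %s | n=%d, k=%d, logLik=%.2f%s\n",
              paste(deparse(spec_formula(x$spec)), collapse = " "),
              x$n_obs, x$k_params, x$loglik,
              if (x$converged) "" else " [check convergence]"))
  print(round(cbind(estimate = x$beta, se = x$se), 4))
  if (length(x$sigma2)) {
    cat("random-effect variances:\n")
    print(round(x$sigma2, 4))
  }
  invisible(x)
}

#' Species-level random-slope model for one predictor
#'
#' Refits the global model with an additional species-level random slope for
#' `predictor`, uncorrelated with the species random intercept. The fixed
#' coefficient is the mean effect across species; the species-level effect of
#' each species is the fixed coefficient plus that species' BLUP, and the
#' slope variance quantifies between-species heterogeneity in the response to
#' the predictor.
#'
#' @inheritParams fit_glmm
#' @param predictor one of the fixed-effect predictors.
#' @param spec the global [model_spec()] whose fixed structure is reused.
#' @return A `glmm_fit` with extra elements `slope_predictor`,
#'   `slope_variance` and `species_effects` (named vector, one per species).
#' @export
fit_random_slope <- function(predictor, data, spec = model_spec(),
                             nAGQ = 1L, ...) {
  if (!predictor %in% spec$fixed_terms)
    stopf("`predictor` must be one of the fixed terms of the global model")
  rs_spec <- model_spec(fixed_terms = spec$fixed_terms,
                        random_intercepts = spec$random_intercepts,
                        random_slope = predictor,
                        response = spec$response)
  fit <- tryCatch(
    fit_glmm(rs_spec, data, nAGQ = nAGQ, ...),
    error = function(e) stopf(paste(
      "random-slope model for '%s' could not be fitted (%s);",
      "convergence failure is a known behaviour of species-level slope",
      "models when between-species variation in the slope is negligible"),
      predictor, conditionMessage(e)))
  re <- lme4::ranef(fit$fit)$.sp
  blup <- setNames(re[[predictor]], rownames(re))
  fit$slope_predictor <- predictor
  # variance of the (0 + predictor | .sp) term
  vc <- lme4::VarCorr(fit$fit)
  slope_idx <- which(vapply(vc, function(m)
    predictor %in% rownames(m), logical(1)))
  fit$slope_variance <- unname(diag(vc[[slope_idx[1]]])[
    match(predictor, rownames(vc[[slope_idx[1]]]))])
  fit$species_effects <- fit$beta[[predictor]] + blup
  fit
}

#' Simulate responses from a fitted model
#'
#' Draws new random effects from their estimated distributions and Bernoulli
#' responses from the implied probabilities (unconditional simulation, the
#' substrate for simulation-based residual diagnostics).
#'
#' @param fit a `glmm_fit`.
#' @param n_sims number of simulated response vectors.
#' @param seed integer seed.
#' @return Integer matrix, `n_obs` rows by `n_sims` columns.
#' @export
simulate_from_fit <- function(fit, n_sims, seed = 1L) {
  if (n_sims == 0L) return(matrix(integer(0), nrow = fit$n_obs, ncol = 0L))
  with_seed(seed, {
    if (inherits(fit$fit, "merMod")) {
      sims <- simulate(fit$fit, nsim = n_sims, use.u = FALSE)
      matrix(as.integer(as.matrix(sims)), nrow = fit$n_obs)
    } else {
      p <- fit$fit$fitted.values
      matrix(rbinom(fit$n_obs * n_sims, 1L, rep(p, n_sims)),
             nrow = fit$n_obs)
    }
  })
}

#' Simulation-based residual diagnostics
#'
#' Randomized-quantile residual checks in the style of simulation-based GLMM
#' diagnostics: each observation's scaled residual is its (tie-randomized)
#' position within `n_sims` simulations from the fitted model; under a correct
#' model the residuals are standard uniform.
#'
#' Reports a Kolmogorov-Smirnov uniformity test, a non-parametric dispersion
#' test (ratio of the observed residual variance around simulated means to its
#' simulation distribution), an outlier test (observations outside the
#' simulated range, against the binomial expectation `2/(n_sims+1)`), and a
#' zero-inflation test (observed zeros over mean simulated zeros, with a
#' two-sided simulation p-value).
#'
#' @param fit a `glmm_fit`.
#' @param data the data the model was fit to.
#' @param n_sims number of simulations (default 250).
#' @param seed integer seed (simulation and tie randomization).
#' @return A list of class `diagnostics_report` with elements
#'   `ks_uniformity_p`, `dispersion_ratio`, `dispersion_p`, `outlier_p`,
#'   `zero_inflation_ratio`, `zero_inflation_p` and `scaled_residuals`.
#' @export
residual_diagnostics <- function(fit, data, n_sims = 250L, seed = 1L) {
  obs <- model_frame(fit$spec, data)[[fit$spec$response]]
  sims <- simulate_from_fit(fit, n_sims, seed = seed)
  n <- length(obs)
  res <- with_seed(seed + 1L, {
    below <- rowMeans(sims < obs)
    equal <- rowMeans(sims == obs)
    below + runif(n) * equal
  })
  ks <- suppressWarnings(ks.test(res, "punif"))

  mu <- rowMeans(sims)
  disp_obs <- var(obs - mu)
  disp_sim <- vapply(seq_len(ncol(sims)), function(j) var(sims[, j] - mu),
                     numeric(1))
  dispersion_ratio <- disp_obs / mean(disp_sim)
  dispersion_p <- min(1, 2 * min(mean(disp_sim >= disp_obs),
                                 mean(disp_sim <= disp_obs)) +
                        1 / n_sims)

  # one-sided: only an excess of observations outside the simulated range is
  # diagnostic (with a bounded response, outliers are near-impossible under a
  # correct model, so a deficit carries no signal)
  n_out <- sum(obs < apply(sims, 1, min) | obs > apply(sims, 1, max))
  outlier_p <- stats::binom.test(n_out, n, p = 2 / (n_sims + 1),
                                 alternative = "greater")$p.value

  zero_obs <- sum(obs == 0)
  zero_sim <- colSums(sims == 0)
  zero_ratio <- zero_obs / mean(zero_sim)
  zero_p <- min(1, 2 * min(mean(zero_sim >= zero_obs),
                           mean(zero_sim <= zero_obs)) + 1 / n_sims)

  structure(list(ks_uniformity_p = unname(ks$p.value),
                 dispersion_ratio = dispersion_ratio,
                 dispersion_p = dispersion_p,
                 outlier_p = outlier_p,
                 zero_inflation_ratio = zero_ratio,
                 zero_inflation_p = zero_p,
                 n_sims = n_sims,
                 scaled_residuals = res),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report>\n")
  cat(sprintf("  KS uniformity p        = %.3f\n", x$ks_uniformity_p))
  cat(sprintf("  dispersion ratio       = %.3f (p = %.3f)\n",
              x$dispersion_ratio, x$dispersion_p))
  cat(sprintf("  outlier test p         = %.3f\n", x$outlier_p))
  cat(sprintf("  zero-inflation ratio   = %.3f (p = %.3f)\n",
              x$zero_inflation_ratio, x$zero_inflation_p))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from the linear regression (with intercept) of
#' predictor `j` on the remaining predictors. Values below 2 are the
#' conventional requirement for the survival model's predictors. Perfectly
#' collinear predictors are reported as `Inf` and flagged.
#'
#' @param data data frame containing the predictors.
#' @param predictors character vector (>= 2) of predictor columns.
#' @return Data frame with columns `predictor`, `vif`, `flag` (`TRUE` when
#'   `vif >= 2`).
#' @export
variance_inflation <- function(data, predictors = PREDICTORS) {
  if (length(predictors) < 2L) stopf("need at least 2 predictors")
  x <- as.data.frame(data)[predictors]
  vif <- vapply(predictors, function(pr) {
    f <- as.formula(paste(pr, "~",
                          paste(setdiff(predictors, pr), collapse = " + ")))
    m <- lm(f, data = x)
    r2 <- suppressWarnings(summary(m)$r.squared) # perfect fits warn
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = predictors, vif = unname(vif),
             flag = unname(vif) >= 2, row.names = NULL,
             stringsAsFactors = FALSE)
}
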