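#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param object a `glmm_fit`, or a numeric log-likelihood.
#' @param k,n parameter count and sample size (only when `object` is numeric).
#' @param ... unused.
#' @return AICc value.
#' @export
aicc <- function(object, ...) UseMethod("aicc")

#' @rdname aicc
#' @export
aicc.glmm_fit <- function(object, ...)
  aicc(object$loglik, k = object$k_params, n = object$n_obs)

#' @rdname aicc
#' @export
aicc.numeric <- function(object, k, n, ...) {
  if (n - k - 1 <= 0)
    stopf("AICc undefined: n - k - 1 = %g must be positive", n - k - 1)
  -2 * object + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' All-subsets model enumeration and AICc ranking
#'
#' Fits every subset of the global model's fixed terms (the intercept and the
#' random structure are always included): `2^p` candidate models for `p`
#' predictors. Models are ranked by AICc; Akaike weights
#' `exp(-delta/2) / sum(exp(-delta/2))` are computed over the converged set.
#' Sub-models that fail to fit are recorded and excluded from the weights.
#'
#' @inheritParams fit_glmm
#' @param global_spec the global [model_spec()] (all seven predictors by
#'   default).
#' @param progress print a model counter while fitting.
#' @return An object of class `model_set`: a ranking table (`$table` with
#'   columns `model`, `terms`, `k`, `loglik`, `aicc`, `delta`, `weight`), the
#'   fits themselves (`$fits`, in table order) and failed models (`$failed`).
#' @export
dredge <- function(global_spec, data, nAGQ = 1L, progress = FALSE, ...) {
  terms <- global_spec$fixed_terms
  p <- length(terms)
  subsets <- lapply(0:(2^p - 1), function(bits) terms[bitwAnd(
    bits, 2^(seq_len(p) - 1)) > 0])
  fits <- vector("list", length(subsets))
  failed <- character(0)
  for (m in seq_along(subsets)) {
    if (progress) cat(sprintf("\rfitting model %d/%d", m, length(subsets)))
    sp <- model_spec(fixed_terms = subsets[[m]],
                     random_intercepts = global_spec$random_intercepts,
                     random_slope = global_spec$random_slope,
                     response = global_spec$response)
    fits[[m]] <- tryCatch(suppressWarnings(fit_glmm(sp, data, nAGQ = nAGQ, ...)),
                          error = function(e) conditionMessage(e))
    if (is.character(fits[[m]]))
      failed <- c(failed, setNames(fits[[m]],
                                   paste(subsets[[m]], collapse = "+")))
  }
  if (progress) cat("\n")
  ok <- vapply(fits, inherits, logical(1), what = "glmm_fit")
  if (!any(ok)) stopf("no sub-model could be fitted")
  if (any(!ok))
    warnf("%d of %d sub-models failed to fit and were excluded",
          sum(!ok), length(fits))
  fits <- fits[ok]
  subsets <- subsets[ok]
  tab <- data.frame(
    model = seq_along(fits),
    terms = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = "+") else "(intercept)", character(1)),
    k = vapply(fits, function(f) f$k_params, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aicc = vapply(fits, aicc, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(tab$aicc)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta <- tab$aicc - tab$aicc[1]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, failed = failed,
                 global_spec = global_spec),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set> %d models (+%d failed)\n",
              nrow(x$table), length(x$failed)))
  print(head(x$table, 10))
  invisible(x)
}

#' Retain the top model set and model-average (conditional method)
#'
#' Retains models within `delta_cutoff` AICc units of the best model
#' (boundary ties retained) and renormalizes their Akaike weights. For each
#' predictor, the conditional average is the weighted mean of its estimate
#' over the retained models that contain it, with weights renormalized over
#' those models; the averaged standard error uses the revised
#' Burnham-Anderson estimator, which adds the between-model spread of the
#' estimates to the within-model variances:
#' `se = sum_m w_m * sqrt(se_m^2 + (b_m - b_avg)^2)`.
#' Relative importance is the sum of retained-set weights of the models
#' containing the predictor.
#'
#' @param ms a [model_set][dredge].
#' @param delta_cutoff AICc window (default 2).
#' @return An object of class `averaged_estimates`: a table with columns
#'   `predictor`, `estimate`, `se`, `ci_low`, `ci_high` (Wald 95%),
#'   `relative_importance`, plus the retained ranking table (`$retained`).
#' @export
retain_and_average <- function(ms, delta_cutoff = 2) {
  keep <- ms$table$delta <= delta_cutoff
  tab <- ms$table[keep, , drop = FALSE]
  fits <- ms$fits[keep]
  w <- tab$weight / sum(tab$weight)

  preds <- c("(Intercept)", ms$global_spec$fixed_terms)
  rows <- lapply(preds, function(pr) {
    has <- vapply(fits, function(f) pr %in% names(f$beta), logical(1))
    if (!any(has))
      # predictor absent from every retained model: no conditional average
      return(data.frame(predictor = pr, estimate = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        relative_importance = 0, stringsAsFactors = FALSE))
    wc <- w[has] / sum(w[has])
    b <- vapply(fits[has], function(f) unname(f$beta[pr]), numeric(1))
    s <- vapply(fits[has], function(f) unname(f$se[pr]), numeric(1))
    est <- sum(wc * b)
    se <- sum(wc * sqrt(s^2 + (b - est)^2))
    data.frame(predictor = pr, estimate = est, se = se,
               ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
               relative_importance = sum(w[has]),
               stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, rows)
  rownames(est) <- NULL
  structure(list(estimates = est, retained = tab, n_retained = nrow(tab),
                 delta_cutoff = delta_cutoff),
            class = "averaged_estimates")
}

#' @export
print.averaged_estimates <- function(x, ...) {
  cat(sprintf("<averaged_estimates> %d retained model(s), delta <= %g\n",
              x$n_retained, x$delta_cutoff))
  print(transform(x$estimates,
                  estimate = round(estimate, 4), se = round(se, 4),
                  ci_low = round(ci_low, 4), ci_high = round(ci_high, 4),
                  relative_importance = round(relative_importance, 3)))
  invisible(x)
}

#' Pool model-averaged estimates across litter-sampling replicates
#'
#' Per predictor: the mean of the replicate estimates, the mean of the
#' replicate standard errors, and the 95% CI `mean_estimate +/- 1.96 *
#' mean_se`. A predictor whose pooled CI excludes zero is flagged as a
#' statistically significant trend (alpha = 0.05).
#'
#' @param results list of [averaged_estimates][retain_and_average] (one per
#'   replicate) with identical predictor sets.
#' @return Data frame of class `pooled_estimates` with columns `predictor`,
#'   `mean_estimate`, `mean_se`, `ci_low`, `ci_high`, `relative_importance`
#'   (mean across replicates), `significant`.
#' @export
pool_replicates <- function(results) {
  if (!length(results)) stopf("no replicate results to pool")
  preds <- results[[1]]$estimates$predictor
  for (r in results)
    if (!identical(r$estimates$predictor, preds))
      stopf("replicates have mismatched predictor sets")
  est <- sapply(results, function(r) r$estimates$estimate)
  se <- sapply(results, function(r) r$estimates$se)
  ri <- sapply(results, function(r) r$estimates$relative_importance)
  if (is.null(dim(est))) { # single predictor edge case
    est <- matrix(est, nrow = 1); se <- matrix(se, nrow = 1)
    ri <- matrix(ri, nrow = 1)
  }
  # a predictor absent from every retained model of some replicate is pooled
  # over the replicates where it was estimable
  me <- rowMeans(est, na.rm = TRUE)
  ms <- rowMeans(se, na.rm = TRUE)
  out <- data.frame(predictor = preds,
                    mean_estimate = me,
                    mean_se = ms,
                    ci_low = me - 1.96 * ms,
                    ci_high = me + 1.96 * ms,
                    relative_importance = rowMeans(ri),
                    stringsAsFactors = FALSE)
  out$mean_estimate[is.nan(out$mean_estimate)] <- NA_real_
  out$mean_se[is.nan(out$mean_se)] <- NA_real_
  out$significant <- !is.na(out$ci_low) & (out$ci_low > 0 | out$ci_high < 0)
  attr(out, "n_replicates") <- length(results)
  class(out) <- c("pooled_estimates", "data.frame")
  out
}
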