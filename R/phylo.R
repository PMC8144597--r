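#' Read a phylogeny in Newick format
#'
#' Wraps [ape::read.tree()] with the checks the signal tests need: unique tip
#' labels, and branch lengths (trees distributed as topologies only, e.g. from
#' large synthesis trees, get unit branch lengths with a warning).
#'
#' @param path path to a Newick file (or a Newick string via `text`).
#' @param text optional Newick string instead of a file.
#' @return An [ape::phylo] tree with branch lengths.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tree <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) stopf("malformed Newick: %s", conditionMessage(e)))
  if (is.null(tree)) stopf("malformed Newick: no tree could be parsed")
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate tip label(s): %s",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  if (is.null(tree$edge.length)) {
    warnf("tree has no branch lengths; unit lengths substituted")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  tree
}

#' Lambda-transformed Brownian-motion covariance
#'
#' The Brownian-motion covariance of a rooted tree (shared root-to-tip path
#' lengths) with all off-diagonal entries multiplied by `lambda`; `lambda = 1`
#' is pure Brownian motion, `lambda = 0` removes all phylogenetic covariance.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param lambda value in `[0, 1]`.
#' @return Symmetric positive semi-definite species covariance matrix.
#' @export
lambda_covariance <- function(tree, lambda) {
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stopf("`lambda` must be in [0, 1]")
  V <- ape::vcv(tree)
  d <- diag(V)
  V <- V * lambda
  diag(V) <- d
  V
}

# Gaussian profile log-likelihood at a given lambda: mean and BM rate
# analytic (GLS), lambda concentrated out.
lambda_loglik <- function(tree, trait, lambda) {
  V <- lambda_covariance(tree, lambda)
  n <- length(trait)
  ch <- tryCatch(chol(V), error = function(e)
    stopf("singular phylogenetic covariance at lambda = %g", lambda))
  Li <- backsolve(ch, diag(n), transpose = TRUE) # t(ch)^-1
  y <- Li %*% trait
  one <- Li %*% rep(1, n)
  mu <- sum(one * y) / sum(one * one)
  r <- y - mu * one
  s2 <- sum(r^2) / n
  logdet <- 2 * sum(log(diag(ch)))
  -n / 2 * log(2 * pi) - n / 2 * log(s2) - logdet / 2 - n / 2
}

#' Estimate Pagel's lambda and test phylogenetic signal
#'
#' Profiles the Gaussian likelihood of a species-level trait over
#' `lambda` in `[0, 1]` (mean and Brownian rate analytic, lambda by bounded
#' 1-D optimization), and tests `lambda = 0` by likelihood ratio with the
#' boundary-corrected null (an equal mixture of a point mass at zero and
#' chi-square with 1 df), since `lambda = 0` lies on the parameter boundary.
#'
#' @param tree an `ape::phylo` tree whose tips cover the trait's species.
#' @param trait named numeric vector of species values (names matching tips).
#' @param tol optimization tolerance (default 1e-8).
#' @return A list of class `phylo_signal`: `lambda` (ML estimate),
#'   `loglik_ml`, `loglik_lambda0`, `lrt_stat`, `p_value`, and
#'   `identifiable` (`FALSE` on a star phylogeny or other flat likelihood,
#'   in which case `lambda` is `NA`).
#' @export
fit_lambda <- function(tree, trait, tol = 1e-8) {
  if (is.null(names(trait)))
    stopf("`trait` must be a named vector (species names)")
  unmatched <- setdiff(names(trait), tree$tip.label)
  if (length(unmatched))
    stopf("species not among tree tips: %s", paste(unmatched, collapse = ", "))
  if (length(trait) < 4) stopf("need >= 4 species")
  tree <- ape::keep.tip(tree, names(trait))
  trait <- trait[tree$tip.label]
  if (sd(trait) == 0)
    stopf("trait is constant across species; lambda is unidentifiable")

  ll0 <- lambda_loglik(tree, trait, 0)
  V1 <- ape::vcv(tree)
  if (max(abs(V1[upper.tri(V1)])) < 1e-12) {
    # star phylogeny: likelihood flat in lambda
    return(structure(list(lambda = NA_real_, loglik_ml = ll0,
                          loglik_lambda0 = ll0, lrt_stat = 0, p_value = 1,
                          identifiable = FALSE), class = "phylo_signal"))
  }
  opt <- optimize(function(l) lambda_loglik(tree, trait, l),
                  interval = c(0, 1), maximum = TRUE, tol = tol)
  ll1 <- lambda_loglik(tree, trait, 1)
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll0, ll1)
  best <- which.max(lls)
  lambda_hat <- cand[best]
  ll_ml <- lls[best]
  if (diff(range(lls)) < 1e-10 && abs(ll_ml - ll0) < 1e-10) {
    # flat likelihood: unidentifiable
    return(structure(list(lambda = NA_real_, loglik_ml = ll_ml,
                          loglik_lambda0 = ll0, lrt_stat = 0, p_value = 1,
                          identifiable = FALSE), class = "phylo_signal"))
  }
  lrt <- max(0, 2 * (ll_ml - ll0))
  p <- if (lrt <= 1e-12) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(lambda = lambda_hat, loglik_ml = ll_ml,
                 loglik_lambda0 = ll0, lrt_stat = lrt, p_value = p,
                 identifiable = TRUE), class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  if (!x$identifiable)
    cat("<phylo_signal> lambda unidentifiable (flat likelihood)\n")
  else
    cat(sprintf("<phylo_signal> lambda = %.4g, LRT = %.3f, p = %.4g\n",
                x$lambda, x$lrt_stat, x$p_value))
  invisible(x)
}

#' Phylogenetic signal of species-level random-slope effects
#'
#' Fits Pagel's lambda to each column of a species-by-predictor matrix of
#' random-slope (species-level) effects. Predictors whose random-slope model
#' failed (all-`NA` columns) are skipped with a note rather than an error --
#' convergence failures do occur (typically for sire age at breeding).
#'
#' @param slopes matrix or data frame, rows = species (rownames matching tree
#'   tips), columns = predictors.
#' @param tree an `ape::phylo` tree.
#' @return Data frame with one row per predictor: `predictor`, `lambda`,
#'   `loglik_ml`, `loglik_lambda0`, `lrt_stat`, `p_value`, `note`.
#' @export
signal_for_random_slopes <- function(slopes, tree) {
  slopes <- as.matrix(slopes)
  if (is.null(rownames(slopes)))
    stopf("`slopes` must have species rownames")
  unmatched <- setdiff(rownames(slopes), tree$tip.label)
  if (length(unmatched))
    stopf("species not among tree tips: %s", paste(unmatched, collapse = ", "))
  rows <- lapply(colnames(slopes), function(pr) {
    x <- setNames(slopes[, pr], rownames(slopes))
    if (anyNA(x))
      return(data.frame(predictor = pr, lambda = NA_real_,
                        loglik_ml = NA_real_, loglik_lambda0 = NA_real_,
                        lrt_stat = NA_real_, p_value = NA_real_,
                        note = "skipped: random-slope model unavailable",
                        stringsAsFactors = FALSE))
    fit <- tryCatch(fit_lambda(tree, x), error = function(e)
      conditionMessage(e))
    if (is.character(fit))
      return(data.frame(predictor = pr, lambda = NA_real_,
                        loglik_ml = NA_real_, loglik_lambda0 = NA_real_,
                        lrt_stat = NA_real_, p_value = NA_real_,
                        note = paste("skipped:", fit),
                        stringsAsFactors = FALSE))
    data.frame(predictor = pr, lambda = fit$lambda,
               loglik_ml = fit$loglik_ml, loglik_lambda0 = fit$loglik_lambda0,
               lrt_stat = fit$lrt_stat, p_value = fit$p_value,
               note = if (fit$identifiable) "" else "lambda unidentifiable",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
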