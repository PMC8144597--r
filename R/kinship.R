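#' Pedigree kinship coefficient
#'
#' Probability that alleles drawn at random, one from each individual, are
#' identical by descent. Computed by memoized recursion over the pedigree,
#' under the studbook conventions that wild-born founders are unrelated and
#' non-inbred and that each unknown parent is a unique unrelated wild founder
#' ("set unknown parents to wild"). `kinship(i, i)` equals `0.5 * (1 + f(i))`.
#'
#' @param p a [pedigree][as_pedigree].
#' @param i,j individual ids.
#' @param wild_as_founder if `TRUE` (default) the recorded ancestry of
#'   wild-born individuals is ignored, so wild-born animals are exact pedigree
#'   founders for kinship and inbreeding.
#' @return Kinship coefficient in `[0, 1]`.
#' @seealso [inbreeding()], [kinship_matrix()], [gene_drop_kinship()]
#' @export
kinship <- function(p, i, j, wild_as_founder = TRUE) {
  ctx <- kinship_context(p, wild_as_founder)
  ii <- resolve_id(p, i)
  jj <- resolve_id(p, j)
  ctx$kin(ii, jj)
}

resolve_id <- function(p, id) {
  idx <- match(as.character(id), p$records$id)
  if (anyNA(idx)) stopf("unknown individual id: %s",
                        paste(as.character(id)[is.na(idx)], collapse = ", "))
  idx
}

# Shared state for recursive kinship: effective parent maps, topological
# depths (error on cycles) and a string-keyed memo table.
kinship_context <- function(p, wild_as_founder = TRUE) {
  par <- parent_indices(p, wild_as_founder)
  depth <- topo_depth(par$sire, par$dam, nrow(p$records))
  if (anyNA(depth))
    stopf("pedigree contains a parent-link cycle (see validate_pedigree())")
  memo <- new.env(parent = emptyenv(), size = 4L * nrow(p$records))
  sire <- par$sire; dam <- par$dam

  kin <- function(a, b) {
    key <- if (a <= b) paste0(a, ".", b) else paste0(b, ".", a)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (a == b) {
      s <- sire[a]; d <- dam[a]
      f <- if (is.na(s) || is.na(d)) 0 else kin(s, d)
      0.5 * (1 + f)
    } else {
      # recurse through the deeper individual's parents; with
      # depth(a) >= depth(b), a cannot be a proper ancestor of b
      if (depth[a] < depth[b]) { tmp <- a; a <- b; b <- tmp }
      s <- sire[a]; d <- dam[a]
      0.5 * ((if (is.na(s)) 0 else kin(s, b)) +
               (if (is.na(d)) 0 else kin(d, b)))
    }
    memo[[key]] <- val
    val
  }
  list(kin = kin, sire = sire, dam = dam, depth = depth)
}

#' Full kinship matrix (tabular algorithm)
#'
#' Computes the complete pairwise kinship matrix by the standard tabular
#' method in topological order; an independent path to the same quantities as
#' the recursive [kinship()], used for full-matrix output and cross-checks.
#'
#' @inheritParams kinship
#' @return A symmetric numeric matrix with individual ids as dimnames; the
#'   diagonal is `0.5 * (1 + f)`.
#' @export
kinship_matrix <- function(p, wild_as_founder = TRUE) {
  n <- nrow(p$records)
  par <- parent_indices(p, wild_as_founder)
  depth <- topo_depth(par$sire, par$dam, n)
  if (anyNA(depth))
    stopf("pedigree contains a parent-link cycle (see validate_pedigree())")
  ord <- order(depth)
  K <- matrix(0, n, n, dimnames = list(p$records$id, p$records$id))
  for (i in ord) {
    s <- par$sire[i]; d <- par$dam[i]
    prev <- ord[seq_len(which(ord == i) - 1L)]
    if (length(prev)) {
      row <- 0.5 * ((if (is.na(s)) 0 else K[s, prev]) +
                      (if (is.na(d)) 0 else K[d, prev]))
      K[i, prev] <- row
      K[prev, i] <- row
    }
    f <- if (is.na(s) || is.na(d)) 0 else K[s, d]
    K[i, i] <- 0.5 * (1 + f)
  }
  K
}

#' Pedigree inbreeding coefficient
#'
#' `f(x)` is the kinship of the parents of `x`. Founders (wild-born animals
#' and individuals with unknown parents) have `f = 0` by convention.
#'
#' @inheritParams kinship
#' @param i individual id(s); default all individuals.
#' @return Named numeric vector of inbreeding coefficients in `[0, 1)`.
#' @export
inbreeding <- function(p, i = NULL, wild_as_founder = TRUE) {
  ctx <- kinship_context(p, wild_as_founder)
  idx <- if (is.null(i)) seq_len(nrow(p$records)) else resolve_id(p, i)
  out <- vapply(idx, function(k) {
    s <- ctx$sire[k]; d <- ctx$dam[k]
    if (is.na(s) || is.na(d)) 0 else ctx$kin(s, d)
  }, numeric(1))
  setNames(out, p$records$id[idx])
}

#' Generations in captivity
#'
#' Wild-born individuals are generation 0; an unknown parent counts as
#' generation 0; a captive-born individual's generation is the mean of its
#' parents' generations plus 1 (so values may be non-integer, e.g. an
#' offspring of a G0 and a G1 parent is G1.5).
#'
#' @inheritParams inbreeding
#' @return Named numeric vector of generations (non-negative, possibly
#'   fractional).
#' @export
generation <- function(p, i = NULL) {
  r <- p$records
  n <- nrow(r)
  par <- parent_indices(p, wild_as_founder = TRUE)
  depth <- topo_depth(par$sire, par$dam, n)
  if (anyNA(depth))
    stopf("pedigree contains a parent-link cycle (see validate_pedigree())")
  g <- rep(NA_real_, n)
  for (k in order(depth)) {
    if (r$origin[k] == "wild") { g[k] <- 0; next }
    gs <- if (is.na(par$sire[k])) 0 else g[par$sire[k]]
    gd <- if (is.na(par$dam[k])) 0 else g[par$dam[k]]
    g[k] <- (gs + gd) / 2 + 1
  }
  idx <- if (is.null(i)) seq_len(n) else resolve_id(p, i)
  setNames(g[idx], r$id[idx])
}

#' Wright's effective population size
#'
#' `Ne = 4 * Nm * Nf / (Nm + Nf)` over the numbers of distinct breeding males
#' (individuals recorded as sire of at least one offspring) and breeding
#' females (recorded as dam). An approximation to the effective size reported
#' by studbook-management software.
#'
#' @inheritParams kinship
#' @return A single number (individuals).
#' @export
effective_size <- function(p) {
  r <- p$records
  nm <- length(unique(r$sire[!is.na(r$sire)]))
  nf <- length(unique(r$dam[!is.na(r$dam)]))
  if (nm == 0L || nf == 0L)
    stopf("no recorded breeders of %s",
          paste(c("male", "female")[c(nm == 0L, nf == 0L)], collapse = " and "))
  4 * nm * nf / (nm + nf)
}

#' Summary pedigree metrics
#'
#' Convenience wrapper computing per-individual inbreeding coefficients and
#' generations in captivity, plus Wright's effective population size (if any
#' breeders of both sexes are on file).
#'
#' @inheritParams kinship
#' @param kinship_matrix if `TRUE`, also return the full kinship matrix.
#' @return A list with elements `f`, `generation`, `Ne` (NA when undefined)
#'   and optionally `kinship`.
#' @export
pedigree_metrics <- function(p, wild_as_founder = TRUE, kinship_matrix = FALSE) {
  out <- list(
    f = inbreeding(p, wild_as_founder = wild_as_founder),
    generation = generation(p),
    Ne = tryCatch(effective_size(p), error = function(e) NA_real_)
  )
  if (kinship_matrix)
    out$kinship <- kinship_matrix(p, wild_as_founder = wild_as_founder)
  out
}

#' Write a kinship matrix in long format
#'
#' @param K matrix from [kinship_matrix()].
#' @param path output CSV path; columns `id_i`, `id_j`, `kinship` (upper
#'   triangle including the diagonal).
#' @return `path`, invisibly.
#' @export
write_kinship_long <- function(K, path) {
  ut <- which(upper.tri(K, diag = TRUE), arr.ind = TRUE)
  long <- data.frame(id_i = rownames(K)[ut[, 1]],
                     id_j = colnames(K)[ut[, 2]],
                     kinship = K[ut])
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

# ---- gene dropping ----------------------------------------------------------

# Drop founder alleles down the pedigree: every (effective) founder gets two
# unique allele labels, every unknown-parent slot a unique phantom label, and
# each individual inherits one random allele per parent per replicate.
# Returns integer matrices A1, A2 of dimension n x replicates.
gene_drop_alleles <- function(p, replicates, wild_as_founder = TRUE) {
  n <- nrow(p$records)
  par <- parent_indices(p, wild_as_founder)
  depth <- topo_depth(par$sire, par$dam, n)
  if (anyNA(depth))
    stopf("pedigree contains a parent-link cycle (see validate_pedigree())")
  A1 <- matrix(0L, n, replicates)
  A2 <- matrix(0L, n, replicates)
  for (i in order(depth)) {
    s <- par$sire[i]; d <- par$dam[i]
    A1[i, ] <- if (is.na(s)) {
      # phantom sire: a unique never-shared allele label
      rep.int(2L * n + 2L * i - 1L, replicates)
    } else {
      pick <- runif(replicates) < 0.5
      ifelse(pick, A1[s, ], A2[s, ])
    }
    A2[i, ] <- if (is.na(d)) {
      rep.int(2L * n + 2L * i, replicates)
    } else {
      pick <- runif(replicates) < 0.5
      ifelse(pick, A1[d, ], A2[d, ])
    }
    if (is.na(s) && is.na(d)) {
      # true founder: two unique founder alleles
      A1[i, ] <- rep.int(2L * i - 1L, replicates)
      A2[i, ] <- rep.int(2L * i, replicates)
    }
  }
  list(A1 = A1, A2 = A2)
}

#' Monte Carlo kinship by gene dropping
#'
#' Independent simulation oracle for [kinship()] and [inbreeding()]: founder
#' alleles are transmitted down the pedigree by Mendelian sampling, and the
#' kinship of `(i, j)` is estimated as the proportion of replicates in which a
#' random allele from `i` is identical by descent to an independently drawn
#' random allele from `j`.
#'
#' @inheritParams kinship
#' @param replicates number of Monte Carlo replicates (>= 1).
#' @param seed integer seed; the estimate is reproducible given the seed.
#' @return A list with `estimate`, `se` (binomial standard error) and
#'   `replicates`.
#' @export
gene_drop_kinship <- function(p, i, j, replicates = 10000L, seed = 1L,
                              wild_as_founder = TRUE) {
  res <- gene_drop_kinship_pairs(p, cbind(i, j), replicates = replicates,
                                 seed = seed, wild_as_founder = wild_as_founder)
  list(estimate = res$estimate[1], se = res$se[1], replicates = replicates)
}

#' Monte Carlo kinship for many pairs from a single gene drop
#'
#' @inheritParams gene_drop_kinship
#' @param pairs two-column matrix or data frame of individual ids.
#' @return Data frame with columns `i`, `j`, `estimate`, `se`.
#' @export
gene_drop_kinship_pairs <- function(p, pairs, replicates = 10000L, seed = 1L,
                                    wild_as_founder = TRUE) {
  if (replicates < 1L) stopf("`replicates` must be >= 1")
  pairs <- as.matrix(pairs)
  ii <- resolve_id(p, pairs[, 1])
  jj <- resolve_id(p, pairs[, 2])
  with_seed(seed, {
    al <- gene_drop_alleles(p, replicates, wild_as_founder)
    est <- se <- numeric(length(ii))
    for (k in seq_along(ii)) {
      pick_i <- runif(replicates) < 0.5
      pick_j <- runif(replicates) < 0.5
      ai <- ifelse(pick_i, al$A1[ii[k], ], al$A2[ii[k], ])
      aj <- ifelse(pick_j, al$A1[jj[k], ], al$A2[jj[k], ])
      est[k] <- mean(ai == aj)
      se[k] <- sqrt(est[k] * (1 - est[k]) / replicates)
    }
    data.frame(i = pairs[, 1], j = pairs[, 2], estimate = est, se = se,
               stringsAsFactors = FALSE)
  })
}
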