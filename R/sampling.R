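#' Sample one offspring per litter
#'
#' Litter-mates share a dam and a birth event and are not statistically
#' independent; one offspring per litter key is retained, chosen uniformly at
#' random. Singleton litters are always retained. Reproducible given `seed`.
#'
#' @param table an [offspring_table][assemble_offspring_table].
#' @param seed integer seed.
#' @return The sampled subset, one row per litter, in original row order.
#' @export
sample_one_per_litter <- function(table, seed) {
  groups <- split(seq_len(nrow(table)),
                  factor(table$litter_key, levels = unique(table$litter_key)))
  picked <- with_seed(seed, vapply(groups, function(ix) {
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }, integer(1)))
  out <- table[sort(unname(picked)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Independent litter-sampling replicates
#'
#' Repeats [sample_one_per_litter()] `n_replicates` times with seeds derived
#' deterministically from `base_seed` (`base_seed + 1, ..., base_seed + n`).
#' Five replicates, later pooled, is the conventional choice.
#'
#' @inheritParams sample_one_per_litter
#' @param n_replicates number of replicates (>= 1; default 5).
#' @param base_seed integer base seed.
#' @return A list of `n_replicates` table subsets; the derived seed of each is
#'   stored in its `"seed"` attribute.
#' @export
make_replicates <- function(table, n_replicates = 5L, base_seed = 1L) {
  if (n_replicates < 1L) stopf("`n_replicates` must be >= 1")
  lapply(seq_len(n_replicates), function(r) {
    out <- sample_one_per_litter(table, seed = base_seed + r)
    attr(out, "seed") <- base_seed + r
    out
  })
}

#' Standardize predictors within species
#'
#' Centers and scales each of the seven predictors to mean 0, sample standard
#' deviation 1 within each species, so that species with extreme raw scales do
#' not dominate the multi-species model and coefficients are comparable (per 1
#' within-species SD). A predictor that is constant within a species (e.g.
#' parental inbreeding all zero in a reptile studbook) is centred to 0 but not
#' scaled, with a warning. Raw values are kept in `raw_*` columns and the
#' per-species scaling constants in the `"scaling"` attribute.
#'
#' @param table an [offspring_table][assemble_offspring_table].
#' @param predictors columns to standardize (default the seven predictors).
#' @return The table with standardized predictor columns, of class
#'   `standardized_table`.
#' @export
standardize_within_species <- function(table, predictors = PREDICTORS) {
  missing <- setdiff(predictors, names(table))
  if (length(missing))
    stopf("predictor column(s) not in table: %s", paste(missing, collapse = ", "))
  tab <- table
  for (pr in predictors) tab[[paste0("raw_", pr)]] <- tab[[pr]]
  scaling <- list()
  const <- character(0)
  for (sp in unique(tab$species)) {
    rows <- which(tab$species == sp)
    if (length(rows) < 2L)
      warnf("species '%s' has fewer than 2 records; predictors set to 0", sp)
    for (pr in predictors) {
      x <- tab[[pr]][rows]
      m <- mean(x)
      s <- if (length(rows) >= 2L) sd(x) else 0
      if (is.na(s) || s == 0) {
        const <- c(const, paste0(sp, ":", pr))
        tab[[pr]][rows] <- x - m
        scaling[[length(scaling) + 1L]] <-
          data.frame(species = sp, predictor = pr, mean = m, sd = NA_real_)
      } else {
        tab[[pr]][rows] <- (x - m) / s
        scaling[[length(scaling) + 1L]] <-
          data.frame(species = sp, predictor = pr, mean = m, sd = s)
      }
    }
  }
  if (length(const))
    warnf("zero-variance predictor(s) centred but not scaled: %s",
          paste(const, collapse = ", "))
  attr(tab, "scaling") <- do.call(rbind, scaling)
  class(tab) <- unique(c("standardized_table", class(table)))
  tab
}

#' Back-transform standardized predictors
#'
#' Recovers raw predictor values from a [standardize_within_species()] result
#' using the stored per-species scaling constants.
#'
#' @param table a `standardized_table`.
#' @return The table with predictor columns on their raw scales.
#' @export
destandardize <- function(table) {
  scaling <- attr(table, "scaling")
  if (is.null(scaling)) stopf("no scaling constants attached")
  out <- table
  for (k in seq_len(nrow(scaling))) {
    sp <- scaling$species[k]; pr <- scaling$predictor[k]
    rows <- which(out$species == sp)
    s <- scaling$sd[k]
    out[[pr]][rows] <- out[[pr]][rows] * (if (is.na(s)) 1 else s) +
      scaling$mean[k]
  }
  class(out) <- setdiff(class(out), "standardized_table")
  out
}

#' Subset to multi-generational (G2+) offspring
#'
#' Retains only offspring both of whose parents are captive-born (parental
#' generation >= 1), removing every offspring with one or both wild-born
#' parents. Used to separate first-generation effects from ongoing
#' multi-generational change.
#'
#' @param table an offspring table (raw or standardized; standardized tables
#'   use their retained `raw_*` generation columns).
#' @return The G2+ subset.
#' @export
subset_g2plus <- function(table) {
  dg <- if ("raw_dam_generation" %in% names(table))
    table$raw_dam_generation else table$dam_generation
  sg <- if ("raw_sire_generation" %in% names(table))
    table$raw_sire_generation else table$sire_generation
  out <- table[dg >= 1 & sg >= 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}
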