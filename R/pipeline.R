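#' Configuration for a full pipeline run
#'
#' @param studbooks a single [pedigree][as_pedigree], a list of pedigrees, or
#'   a character vector of studbook CSV paths.
#' @param species_cfg a [species_config] covering every species.
#' @param tree optional `ape::phylo` tree (or Newick path) for the
#'   phylogenetic-signal step.
#' @param n_replicates independent litter-sampling replicates (default 5).
#' @param base_seed integer seed; replicate seeds are derived as
#'   `base_seed + 1, ..., base_seed + n_replicates`.
#' @param delta_cutoff AICc retention window (default 2).
#' @param mode `"all_offspring"`, `"g2plus"` or `"both"`.
#' @param truncate_days trailing days dropped from the studbook (default 364).
#' @param nAGQ passed to the GLMM fits (1 = Laplace; 0 = faster
#'   penalized-least-squares step, useful for large all-subsets screens).
#' @param n_sims_diag simulations for residual diagnostics (default 250).
#' @param random_slopes fit per-predictor species-level random-slope models
#'   on the representative replicate (default TRUE).
#' @param out_dir optional directory; when given, result tables and the run
#'   manifest are written as CSV/JSON.
#' @return A list of class `run_config`.
#' @export
run_config <- function(studbooks, species_cfg, tree = NULL,
                       n_replicates = 5L, base_seed = 1L, delta_cutoff = 2,
                       mode = c("both", "all_offspring", "g2plus"),
                       truncate_days = 364L, nAGQ = 1L, n_sims_diag = 250L,
                       random_slopes = TRUE, out_dir = NULL) {
  mode <- match.arg(mode)
  if (n_replicates < 1L) stopf("n_replicates must be >= 1")
  if (delta_cutoff <= 0) stopf("delta_cutoff must be > 0")
  if (inherits(studbooks, "pedigree")) studbooks <- list(studbooks)
  structure(list(studbooks = studbooks, species_cfg = species_cfg,
                 tree = tree, n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed),
                 delta_cutoff = delta_cutoff, mode = mode,
                 truncate_days = as.integer(truncate_days),
                 nAGQ = as.integer(nAGQ),
                 n_sims_diag = as.integer(n_sims_diag),
                 random_slopes = isTRUE(random_slopes),
                 out_dir = out_dir),
            class = "run_config")
}

load_studbooks <- function(cfg) {
  lapply(cfg$studbooks, function(s) {
    if (inherits(s, "pedigree")) s else read_studbook(s)
  })
}

# truncate + exclusions + per-offspring table for one studbook
build_one <- function(p, species_cfg, truncate_days, manifest) {
  pt <- truncate_recent(p, truncate_days)
  excl <- apply_exclusions(pt, species_cfg)
  tab <- suppressWarnings(assemble_offspring_table(pt, species_cfg, excl))
  list(table = tab, tally = excl$tally,
       n_raw = nrow(p$records), n_truncated = nrow(pt$records),
       n_retained = nrow(tab))
}

#' Build the combined analysis table from studbooks
#'
#' Runs truncation, exclusion filtering and table assembly for each studbook
#' and binds the per-offspring rows of all species.
#'
#' @param cfg a [run_config()].
#' @return A list: `table` (combined [offspring_table]) and `filter_counts`
#'   (per-studbook raw/truncated/retained counts and exclusion tallies).
#' @export
build_analysis_table <- function(cfg) {
  peds <- load_studbooks(cfg)
  built <- lapply(peds, build_one, species_cfg = cfg$species_cfg,
                  truncate_days = cfg$truncate_days)
  tab <- do.call(rbind, lapply(built, `[[`, "table"))
  class(tab) <- c("offspring_table", "data.frame")
  counts <- lapply(built, function(b)
    c(n_raw = b$n_raw, n_truncated = b$n_truncated,
      n_retained = b$n_retained, b$tally))
  list(table = tab, filter_counts = counts)
}

analyse_replicates <- function(replicates, cfg, g2plus = FALSE) {
  spec <- model_spec()
  per_rep <- lapply(replicates, function(rep_tab) {
    if (g2plus) rep_tab <- subset_g2plus(rep_tab)
    std <- suppressWarnings(standardize_within_species(rep_tab))
    ms <- dredge(spec, std, nAGQ = cfg$nAGQ)
    avg <- retain_and_average(ms, cfg$delta_cutoff)
    list(std = std, model_set = ms, averaged = avg, n = nrow(std),
         seed = attr(rep_tab, "seed"))
  })
  pooled <- pool_replicates(lapply(per_rep, `[[`, "averaged"))
  # representative replicate: averaged estimates closest (summed absolute
  # deviation) to the pooled means
  dev <- vapply(per_rep, function(r)
    sum(abs(r$averaged$estimates$estimate - pooled$mean_estimate),
        na.rm = TRUE),
    numeric(1))
  rep_idx <- which.min(dev)
  list(per_replicate = per_rep, pooled = pooled,
       representative = rep_idx)
}

random_slope_matrix <- function(std, spec = model_spec(), nAGQ = 1L) {
  species <- sort(unique(std$species))
  out <- matrix(NA_real_, nrow = length(species), ncol = length(PREDICTORS),
                dimnames = list(species, PREDICTORS))
  notes <- character(0)
  for (pr in PREDICTORS) {
    fit <- tryCatch(suppressWarnings(
      fit_random_slope(pr, std, spec = spec, nAGQ = nAGQ)),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      notes <- c(notes, setNames(fit, pr))
    } else {
      out[names(fit$species_effects), pr] <- fit$species_effects
    }
  }
  list(effects = out, failures = notes)
}

#' Run the full survival analysis pipeline
#'
#' Composes the whole procedure: truncation, exclusion filters, per-offspring
#' table, independent litter-sampling replicates, within-species
#' standardization (per replicate), the global binomial GLMM with residual
#' diagnostics and VIFs (on the first replicate), all-subsets AICc model
#' selection with conditional averaging per replicate, pooling across
#' replicates, per-predictor species-level random slopes on the
#' representative replicate, and (when a tree is supplied) Pagel's lambda on
#' species mean survival and on each predictor's species-level effects. Runs
#' the all-offspring analysis, the multi-generational (G2+) subset analysis,
#' or both.
#'
#' @param cfg a [run_config()].
#' @return A list of class `pipeline_result` with elements `all_offspring`
#'   and/or `g2plus` (each: `pooled`, `per_replicate`, `representative`,
#'   `slopes`, `lambda`), `diagnostics`, `vif`, `survival_lambda`, and
#'   `manifest` (seeds, versions, filter counts, replicate sizes).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  tree <- cfg$tree
  if (is.character(tree)) tree <- read_newick(tree)

  built <- build_analysis_table(cfg)
  tab <- built$table
  replicates <- make_replicates(tab, cfg$n_replicates, cfg$base_seed)

  manifest <- list(
    package_version = as.character(packageVersion("studsurv")),
    base_seed = cfg$base_seed,
    replicate_seeds = vapply(replicates, attr, numeric(1), which = "seed"),
    truncate_days = cfg$truncate_days,
    delta_cutoff = cfg$delta_cutoff,
    nAGQ = cfg$nAGQ,
    mode = cfg$mode,
    filter_counts = built$filter_counts,
    n_table = nrow(tab),
    n_litters = length(unique(tab$litter_key)))

  out <- list(manifest = manifest)
  modes <- switch(cfg$mode, both = c("all_offspring", "g2plus"),
                  all_offspring = "all_offspring", g2plus = "g2plus")

  for (m in modes) {
    res <- analyse_replicates(replicates, cfg, g2plus = (m == "g2plus"))
    manifest[[paste0(m, "_replicate_sizes")]] <-
      vapply(res$per_replicate, `[[`, numeric(1), "n")
    manifest[[paste0(m, "_representative_replicate")]] <- res$representative

    if (m == "all_offspring") {
      std1 <- res$per_replicate[[1]]$std
      global_fit <- suppressWarnings(fit_glmm(model_spec(), std1,
                                              nAGQ = cfg$nAGQ))
      out$diagnostics <- residual_diagnostics(global_fit, std1,
                                              n_sims = cfg$n_sims_diag,
                                              seed = cfg$base_seed)
      out$vif <- variance_inflation(std1)
      out$global_fit <- global_fit
    }

    slopes <- NULL
    lam <- NULL
    if (cfg$random_slopes) {
      rep_std <- res$per_replicate[[res$representative]]$std
      slopes <- random_slope_matrix(rep_std, nAGQ = cfg$nAGQ)
      if (!is.null(tree))
        lam <- signal_for_random_slopes(slopes$effects, tree)
      if (m == "all_offspring" && !is.null(tree)) {
        surv_mean <- tapply(rep_std$survival, rep_std$species, mean)
        out$survival_lambda <- fit_lambda(tree,
                                          setNames(as.numeric(surv_mean),
                                                   names(surv_mean)))
      }
    }
    out[[m]] <- list(pooled = res$pooled,
                     per_replicate = res$per_replicate,
                     representative = res$representative,
                     slopes = slopes, lambda = lam)
  }
  out$manifest <- manifest
  class(out) <- "pipeline_result"
  if (!is.null(cfg$out_dir)) write_pipeline_result(out, cfg$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (m in intersect(c("all_offspring", "g2plus"), names(x))) {
    cat(sprintf("-- %s (pooled over %d replicate(s)) --\n", m,
                attr(x[[m]]$pooled, "n_replicates")))
    print(x[[m]]$pooled, digits = 4)
  }
  invisible(x)
}

#' Sensitivity run on the extended (no litter sampling) dataset
#'
#' Re-runs the global model and model selection on the full analysis table,
#' ignoring litter-mate non-independence (all offspring retained; no
#' replicates to pool). Emitted as a sensitivity report for qualitative
#' comparison with the pooled litter-sampling run.
#'
#' @param cfg a [run_config()].
#' @return A list of class `extended_result`: `averaged`, `model_set`, `n`,
#'   and a manifest labelled `"extended_no_litter_sampling"`.
#' @export
extended_dataset_run <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  built <- build_analysis_table(cfg)
  tab <- built$table
  if (cfg$mode == "g2plus") tab <- subset_g2plus(tab)
  std <- suppressWarnings(standardize_within_species(tab))
  ms <- dredge(model_spec(), std, nAGQ = cfg$nAGQ)
  avg <- retain_and_average(ms, cfg$delta_cutoff)
  structure(list(averaged = avg, model_set = ms, n = nrow(std),
                 manifest = list(label = "extended_no_litter_sampling",
                                 mode = cfg$mode,
                                 filter_counts = built$filter_counts,
                                 n_table = nrow(std))),
            class = "extended_result")
}

#' Write pipeline outputs to a directory
#'
#' Writes the pooled estimate tables (Table-2-style layout), the species-level
#' random-slope effect matrices, the lambda results, the diagnostics summary
#' and the JSON run manifest.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in intersect(c("all_offspring", "g2plus"), names(result))) {
    write.csv(as.data.frame(result[[m]]$pooled),
              file.path(dir, paste0("pooled_estimates_", m, ".csv")),
              row.names = FALSE)
    if (!is.null(result[[m]]$slopes)) {
      eff <- result[[m]]$slopes$effects
      write.csv(data.frame(species = rownames(eff), eff,
                           check.names = FALSE),
                file.path(dir, paste0("species_effects_", m, ".csv")),
                row.names = FALSE)
    }
    if (!is.null(result[[m]]$lambda))
      write.csv(result[[m]]$lambda,
                file.path(dir, paste0("lambda_", m, ".csv")),
                row.names = FALSE)
  }
  if (!is.null(result$diagnostics)) {
    d <- result$diagnostics
    write.csv(data.frame(statistic = c("ks_uniformity_p", "dispersion_ratio",
                                       "dispersion_p", "outlier_p",
                                       "zero_inflation_ratio",
                                       "zero_inflation_p"),
                         value = c(d$ks_uniformity_p, d$dispersion_ratio,
                                   d$dispersion_p, d$outlier_p,
                                   d$zero_inflation_ratio,
                                   d$zero_inflation_p)),
              file.path(dir, "diagnostics.csv"), row.names = FALSE)
  }
  if (!is.null(result$vif))
    write.csv(result$vif, file.path(dir, "vif.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
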