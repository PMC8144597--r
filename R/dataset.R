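#' Truncate the most recent days of a studbook
#'
#' Removes individuals born within `days` days of the studbook's current
#' date, to guard against recent deaths not yet entered, and moves the
#' current date back by the same amount for downstream age arithmetic.
#'
#' @param p a [pedigree][as_pedigree].
#' @param days number of trailing days to drop (default 364).
#' @return A pedigree whose current date is `days` earlier.
#' @export
truncate_recent <- function(p, days = 364L) {
  cutoff <- p$current_date - days
  keep <- p$records$birth_date <= cutoff
  as_pedigree(p$records[keep, , drop = FALSE], current_date = cutoff,
              check = FALSE)
}

#' Label survival to reproductive maturity
#'
#' For each individual: 1 if it survived to its sex-specific age at
#' reproductive maturity (unknown sex uses the shorter of the two maturity
#' ages), 0 if it died younger, and `NA` if it was born within the maturity
#' window of the cutoff date and so has not had the opportunity to reach
#' maturity (such individuals are excluded from analysis, dead or alive).
#'
#' @param p a [pedigree][as_pedigree].
#' @param cfg a [species_config] covering every species in `p`.
#' @param cutoff_date reference date; defaults to the pedigree current date
#'   (apply [truncate_recent()] first so this is 364 days before the raw
#'   studbook date).
#' @return Named integer vector (1, 0 or `NA` = too young to assess).
#' @export
label_survival <- function(p, cfg, cutoff_date = p$current_date) {
  r <- p$records
  if (anyNA(r$birth_date)) stopf("missing birth date")
  mat <- maturity_days(r$sex, r$species, cfg)
  age_possible <- as.numeric(cutoff_date - r$birth_date)
  lab <- rep(NA_integer_, nrow(r))
  assessable <- age_possible >= mat
  dead <- !is.na(r$death_date)
  age_death <- as.numeric(r$death_date - r$birth_date)
  lab[assessable & dead] <- as.integer(age_death[assessable & dead] >=
                                         mat[assessable & dead])
  lab[assessable & !dead] <- 1L
  setNames(lab, r$id)
}

#' Apply the analysis exclusion filters
#'
#' Identifies the offspring usable as analysis rows, removing (in order, each
#' individual tallied under the first matching reason):
#' 1. `too_young` -- born within the maturity window of the cutoff date;
#' 2. `hybrid` -- flagged hybrids;
#' 3. `wild_or_released` -- wild-born individuals, and individuals released to
#'    the wild before maturity (via an optional `release_date` column; absent
#'    column leaves this part of the filter inert);
#' 4. `unknown_parent` -- missing sire or dam (or both).
#'
#' Excluded individuals remain in the pedigree as ancestors: the filter
#' selects analysis rows, it does not delete pedigree nodes (deleting them
#' would corrupt descendants' inbreeding and generation values).
#'
#' @inheritParams label_survival
#' @return A list of class `exclusion_result`: `ids` (retained offspring),
#'   `survival` (named 0/1 vector for retained ids), `tally` (named counts per
#'   reason) and `pedigree` (the input pedigree, unchanged).
#' @export
apply_exclusions <- function(p, cfg, cutoff_date = p$current_date) {
  r <- p$records
  lab <- label_survival(p, cfg, cutoff_date)
  reason <- rep(NA_character_, nrow(r))
  reason[is.na(lab)] <- "too_young"
  reason[is.na(reason) & r$hybrid] <- "hybrid"

  released_young <- rep(FALSE, nrow(r))
  if ("release_date" %in% names(r)) {
    mat <- maturity_days(r$sex, r$species, cfg)
    released_young <- !is.na(r$release_date) &
      as.numeric(r$release_date - r$birth_date) < mat
  }
  reason[is.na(reason) & (r$origin == "wild" | released_young)] <-
    "wild_or_released"
  reason[is.na(reason) & (is.na(r$sire) | is.na(r$dam))] <- "unknown_parent"

  keep <- is.na(reason)
  tally <- vapply(c("too_young", "hybrid", "wild_or_released",
                    "unknown_parent"),
                  function(x) sum(reason == x, na.rm = TRUE), integer(1))
  structure(list(ids = r$id[keep],
                 survival = lab[keep],
                 tally = tally,
                 pedigree = p),
            class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  cat(sprintf("<exclusion_result> %d retained analysis offspring\n",
              length(x$ids)))
  cat("  excluded:", paste(names(x$tally), x$tally, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Assemble the per-offspring analysis table
#'
#' One row per retained offspring with the survival outcome and the seven
#' predictors of the global model: dam and sire generations in captivity, dam
#' and sire age at the offspring's birth (days), and dam, sire and offspring
#' inbreeding coefficients; plus the grouping factors (species, birth program,
#' birth year) and the litter key. Inbreeding and generations are computed on
#' the full pedigree, so excluded ancestors still contribute.
#'
#' @inheritParams label_survival
#' @param exclusions result of [apply_exclusions()]; computed if omitted.
#' @param metrics optional result of [pedigree_metrics()] on `p` (recomputed
#'   if omitted).
#' @return A data frame of class `offspring_table`. Rows whose parental age
#'   is not positive are rejected with a warning and reported in the
#'   `"rejected"` attribute.
#' @export
assemble_offspring_table <- function(p, cfg, exclusions = NULL, metrics = NULL) {
  if (is.null(exclusions)) exclusions <- apply_exclusions(p, cfg)
  if (is.null(metrics)) metrics <- pedigree_metrics(p)
  r <- p$records
  idx <- match(exclusions$ids, r$id)
  di <- match(r$dam[idx], r$id)
  si <- match(r$sire[idx], r$id)
  lr <- cfg$litter_rule[match(r$species[idx], cfg$species)]
  birth <- r$birth_date[idx]
  tab <- data.frame(
    offspring_id = r$id[idx],
    species = r$species[idx],
    survival = as.integer(exclusions$survival),
    dam_generation = unname(metrics$generation[di]),
    sire_generation = unname(metrics$generation[si]),
    dam_age = as.numeric(birth - r$birth_date[di]),
    sire_age = as.numeric(birth - r$birth_date[si]),
    dam_f = unname(metrics$f[di]),
    sire_f = unname(metrics$f[si]),
    offspring_f = unname(metrics$f[idx]),
    birth_program = r$birth_program[idx],
    birth_year = as.integer(format(birth, "%Y")),
    dam_id = r$dam[idx],
    sire_id = r$sire[idx],
    stringsAsFactors = FALSE)
  tab$litter_key <- ifelse(lr == "same_year",
                           paste(tab$species, tab$dam_id, tab$birth_year,
                                 sep = "|"),
                           paste(tab$species, tab$dam_id, format(birth),
                                 sep = "|"))
  bad <- tab$dam_age <= 0 | tab$sire_age <= 0
  if (any(bad)) {
    warnf("%d offspring rejected: parent age at birth not positive (%s)",
          sum(bad), paste(head(tab$offspring_id[bad], 5), collapse = ", "))
    rejected <- tab[bad, , drop = FALSE]
    tab <- tab[!bad, , drop = FALSE]
    attr(tab, "rejected") <- rejected
  }
  rownames(tab) <- NULL
  class(tab) <- c("offspring_table", "data.frame")
  tab
}

#' Write / read an offspring analysis table
#'
#' @param table an `offspring_table`.
#' @param path CSV path.
#' @return `path` (writer) or the table (reader).
#' @export
write_offspring_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_offspring_table
#' @export
read_offspring_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("offspring_table", "data.frame")
  tab
}
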