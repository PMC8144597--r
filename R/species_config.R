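#' Species configuration table
#'
#' Per-species settings used to label survival and identify litters: age at
#' reproductive maturity for each sex (days) and the litter-grouping rule
#' (`"same_day"` for mammal litters, `"same_year"` for reptile clutches).
#'
#' @param species character vector of species labels.
#' @param maturity_female_days,maturity_male_days ages at reproductive
#'   maturity in days (> 0), recycled to the length of `species`.
#' @param litter_rule `"same_day"` or `"same_year"`, recycled.
#' @param first_record_year optional informational first-record year.
#' @return A data frame of class `species_config`.
#' @export
species_config <- function(species, maturity_female_days, maturity_male_days,
                           litter_rule = "same_day",
                           first_record_year = NA_integer_) {
  cfg <- data.frame(species = as.character(species),
                    maturity_female_days = as.numeric(maturity_female_days),
                    maturity_male_days = as.numeric(maturity_male_days),
                    litter_rule = as.character(litter_rule),
                    first_record_year = as.integer(first_record_year),
                    stringsAsFactors = FALSE)
  if (any(cfg$maturity_female_days <= 0) || any(cfg$maturity_male_days <= 0))
    stopf("maturity ages must be positive (days)")
  bad <- !cfg$litter_rule %in% c("same_day", "same_year")
  if (any(bad))
    stopf("litter_rule must be 'same_day' or 'same_year' (species %s)",
          paste(cfg$species[bad], collapse = ", "))
  if (anyDuplicated(cfg$species))
    stopf("duplicate species in configuration")
  class(cfg) <- c("species_config", "data.frame")
  cfg
}

#' Read a species configuration file
#'
#' YAML files hold a list of per-species mappings with the [species_config()]
#' fields; CSV files hold the same columns.
#'
#' @param path path to a `.yaml`/`.yml` or `.csv` file.
#' @return A [species_config] data frame.
#' @export
read_species_config <- function(path) {
  if (!file.exists(path)) stopf("species config not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("reading YAML species configs requires the 'yaml' package")
    raw <- yaml::read_yaml(path)
    if (!is.null(raw$species) && is.list(raw$species)) raw <- raw$species
    df <- do.call(rbind, lapply(raw, function(x)
      data.frame(species = x$species,
                 maturity_female_days = x$maturity_female_days,
                 maturity_male_days = x$maturity_male_days,
                 litter_rule = x$litter_rule %||% "same_day",
                 first_record_year = x$first_record_year %||% NA_integer_,
                 stringsAsFactors = FALSE)))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  species_config(df$species, df$maturity_female_days, df$maturity_male_days,
                 df$litter_rule,
                 df$first_record_year %||% NA_integer_)
}

# maturity age in days for each record given its sex; unknown sex uses the
# shorter of the two sexes' maturity ages
maturity_days <- function(sex, species, cfg) {
  m <- match(species, cfg$species)
  if (anyNA(m))
    stopf("species missing from configuration: %s",
          paste(unique(species[is.na(m)]), collapse = ", "))
  fe <- cfg$maturity_female_days[m]
  ma <- cfg$maturity_male_days[m]
  ifelse(sex == "female", fe, ifelse(sex == "male", ma, pmin(fe, ma)))
}
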