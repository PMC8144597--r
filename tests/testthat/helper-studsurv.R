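# Shared fixtures, built once per test session.

FIX <- toy_fixtures()
TOY_CFG <- toy_species_config()

# a mid-sized 3-species simulated studbook reused across test files
TEST_CFG <- simulation_config(n_species = 3, founders_per_species = 20,
                              n_years = 30, max_litters_per_year = 15,
                              seed = 42)
TEST_SIM <- simulate_studbook(TEST_CFG)
TEST_SCFG <- species_config_from_simulation(TEST_CFG)
TEST_PED <- TEST_SIM$pedigree
TEST_TRUNC <- truncate_recent(TEST_PED)
TEST_TAB <- suppressWarnings(assemble_offspring_table(TEST_TRUNC, TEST_SCFG))
TEST_STD <- suppressWarnings(standardize_within_species(TEST_TAB))

# a small random single-species pedigree for property tests
small_pedigree <- function(seed, n_years = 10, founders = 10) {
  cfg <- simulation_config(n_species = 1, founders_per_species = founders,
                           n_years = n_years, max_litters_per_year = 6,
                           litter_rule = "same_day", wild_intake_rate = 0.1,
                           unknown_sire_rate = 0, hybrid_rate = 0,
                           unknown_sex_rate = 0, seed = seed)
  suppressWarnings(simulate_studbook(cfg))$pedigree
}

# quick builder for hand-made pedigrees
mini_ped <- function(id, sire, dam, sex = "female",
                     birth = "2000-01-01", death = NA,
                     origin = "captive", hybrid = FALSE, species = "toy",
                     program = "Europe", current = "2020-01-01") {
  as_pedigree(data.frame(id = id, sire = sire, dam = dam,
                         sex = rep_len(sex, length(id)),
                         birth_date = rep_len(birth, length(id)),
                         death_date = rep_len(death, length(id)),
                         birth_program = rep_len(program, length(id)),
                         origin = rep_len(origin, length(id)),
                         hybrid = rep_len(hybrid, length(id)),
                         species = rep_len(species, length(id)),
                         stringsAsFactors = FALSE),
              current_date = as.Date(current))
}

# direct generator for GLMM-structured survival data (bypasses the studbook
# simulator; used to test the model engine against known coefficients)
gen_glmm_data <- function(n, beta, sd_sp = 0, sd_prog = 0, sd_year = 0,
                          n_sp = 3, n_prog = 3, n_year = 10, seed = 1,
                          slope_pred = NULL, slope_by_species = NULL) {
  stopifnot("(Intercept)" %in% names(beta))
  preds <- setdiff(names(beta), "(Intercept)")
  set.seed(seed)
  species <- sprintf("sp%02d", sample.int(n_sp, n, replace = TRUE))
  prog <- sprintf("pr%d", sample.int(n_prog, n, replace = TRUE))
  year <- 2000L + sample.int(n_year, n, replace = TRUE)
  X <- matrix(rnorm(n * length(preds)), n, length(preds),
              dimnames = list(NULL, preds))
  re_sp <- setNames(rnorm(n_sp, 0, sd_sp), sprintf("sp%02d", 1:n_sp))
  key_prog <- paste(species, prog); upr <- unique(key_prog)
  re_prog <- setNames(rnorm(length(upr), 0, sd_prog), upr)
  key_year <- paste(species, year); uyr <- unique(key_year)
  re_year <- setNames(rnorm(length(uyr), 0, sd_year), uyr)
  eta <- beta[["(Intercept)"]] + drop(X %*% beta[preds]) +
    re_sp[species] + re_prog[key_prog] + re_year[key_year]
  if (!is.null(slope_pred))
    eta <- eta + slope_by_species[species] * X[, slope_pred]
  y <- rbinom(n, 1, plogis(eta))
  d <- data.frame(survival = y, species = species, birth_program = prog,
                  birth_year = year, X, stringsAsFactors = FALSE)
  list(data = d, beta = beta, re_sp = re_sp)
}

# independent iteratively-reweighted-least-squares logistic oracle
irls_logistic <- function(X, y, tol = 1e-12, maxit = 100) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    b_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(b_new - b)) < tol) { b <- drop(b_new); break }
    b <- drop(b_new)
  }
  setNames(b, colnames(X))
}
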