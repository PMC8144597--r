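#' Configuration for the forward studbook simulator
#'
#' Encodes the generative world the survival analysis assumes: multi-species
#' pedigrees founded by wild intakes, litters/clutches, accumulating
#' inbreeding under a mating policy, regional programs and year effects, and
#' Bernoulli survival whose logit is linear in the seven standardized
#' predictors with species-level random intercepts and slopes.
#'
#' Defaults describe a large managed multi-species dataset: 15 species (a
#' fifth of them reptile-like, with same-year clutch grouping), weak
#' generation effects, modest opposing parental-age effects, near-zero
#' parental-inbreeding effects and substantial offspring inbreeding
#' depression (about -0.16 per within-species SD), with kin avoidance in
#' pairings as practiced by managed programs.
#'
#' @param n_species number of species.
#' @param founders_per_species wild founders at program start per species.
#' @param n_years simulated years of breeding.
#' @param start_year calendar year of day 0 (cosmetic).
#' @param litter_mean,litter_max mean and cap of litter size (recycled per
#'   species; sizes are `1 + Poisson(litter_mean - 1)` truncated at
#'   `litter_max`).
#' @param litter_rule `"same_day"` (mammal litters) or `"same_year"`
#'   (reptile clutches spread over weeks), recycled per species; the default
#'   makes the last fifth of species same-year.
#' @param maturity_female_days,maturity_male_days ages at reproductive
#'   maturity (days), recycled per species.
#' @param intercept grand intercept of the survival logit.
#' @param true_beta named vector of the seven logit-scale coefficients (per 1
#'   within-species SD of the predictor).
#' @param species_sd named vector of SDs of species-level slope deviations.
#' @param intercept_sd_species,sd_program,sd_year random-intercept SDs for
#'   species, program-within-species and year-within-species.
#' @param programs region labels births are assigned to.
#' @param wild_intake_rate per species-year probability of a new wild pair.
#' @param max_litters_per_year cap on litters per species-year (holding
#'   capacity).
#' @param mating_policy `"random"`, `"avoid_kin"` (default; choose the least
#'   related of the candidate males) or `"prefer_kin"`.
#' @param hybrid_rate,unknown_sire_rate,unknown_sex_rate,release_rate rates of
#'   hybrid flags, masked sires, unknown sex, and pre-maturity release to the
#'   wild among captive-born offspring.
#' @param seed integer seed; the simulation is deterministic given the seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 15L,
                              founders_per_species = 30L,
                              n_years = 60L,
                              start_year = 1960L,
                              litter_mean = 2.5,
                              litter_max = 6L,
                              litter_rule = NULL,
                              maturity_female_days = 730L,
                              maturity_male_days = 730L,
                              intercept = 0.46,
                              true_beta = c(dam_generation = 0.005,
                                            sire_generation = 0.022,
                                            dam_age = -0.062,
                                            sire_age = 0.058,
                                            dam_f = 0.002,
                                            sire_f = 0.009,
                                            offspring_f = -0.163),
                              species_sd = c(dam_generation = 0.15,
                                             sire_generation = 0.15,
                                             dam_age = 0.08,
                                             sire_age = 0.02,
                                             dam_f = 0.05,
                                             sire_f = 0.05,
                                             offspring_f = 0.08),
                              intercept_sd_species = 0.5,
                              sd_program = 0.2,
                              sd_year = 0.2,
                              programs = c("Europe", "North America",
                                           "Australasia", "Africa"),
                              wild_intake_rate = 0.15,
                              max_litters_per_year = 30L,
                              mating_policy = c("avoid_kin", "random",
                                                "prefer_kin"),
                              hybrid_rate = 0.01,
                              unknown_sire_rate = 0.02,
                              unknown_sex_rate = 0.02,
                              release_rate = 0,
                              seed = 1L) {
  mating_policy <- match.arg(mating_policy)
  if (is.null(litter_rule)) {
    litter_rule <- rep("same_day", n_species)
    if (n_species >= 5L)
      litter_rule[(n_species - ceiling(n_species / 5) + 1L):n_species] <-
        "same_year"
  }
  true_beta <- true_beta[PREDICTORS]
  species_sd <- species_sd[PREDICTORS]
  if (anyNA(true_beta) || anyNA(species_sd))
    stopf("true_beta and species_sd must name all seven predictors")
  if (any(species_sd < 0) || intercept_sd_species < 0 || sd_program < 0 ||
      sd_year < 0)
    stopf("random-effect SDs must be >= 0")
  if (litter_max < 1L) stopf("litter_max must be >= 1")
  rates <- c(wild_intake_rate, hybrid_rate, unknown_sire_rate,
             unknown_sex_rate, release_rate)
  if (any(rates < 0 | rates > 1)) stopf("rates must be probabilities")
  cfg <- list(n_species = as.integer(n_species),
              founders_per_species = as.integer(founders_per_species),
              n_years = as.integer(n_years),
              start_year = as.integer(start_year),
              litter_mean = rep_len(litter_mean, n_species),
              litter_max = as.integer(rep_len(litter_max, n_species)),
              litter_rule = rep_len(litter_rule, n_species),
              maturity_female_days = as.integer(rep_len(maturity_female_days,
                                                        n_species)),
              maturity_male_days = as.integer(rep_len(maturity_male_days,
                                                      n_species)),
              intercept = intercept,
              true_beta = true_beta,
              species_sd = species_sd,
              intercept_sd_species = intercept_sd_species,
              sd_program = sd_program,
              sd_year = sd_year,
              programs = programs,
              wild_intake_rate = wild_intake_rate,
              max_litters_per_year = as.integer(max_litters_per_year),
              mating_policy = mating_policy,
              hybrid_rate = hybrid_rate,
              unknown_sire_rate = unknown_sire_rate,
              unknown_sex_rate = unknown_sex_rate,
              release_rate = release_rate,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Species configuration matching a simulation
#'
#' @param cfg a [simulation_config()].
#' @return The [species_config] the analysis of the simulated studbook needs.
#' @export
species_config_from_simulation <- function(cfg) {
  species_config(species = sprintf("species_%02d", seq_len(cfg$n_species)),
                 maturity_female_days = cfg$maturity_female_days,
                 maturity_male_days = cfg$maturity_male_days,
                 litter_rule = cfg$litter_rule,
                 first_record_year = cfg$start_year)
}

#' Simulate a multi-species studbook with known ground truth
#'
#' Forward simulation per species and year: wild intakes found and replenish
#' the pedigree (G0), mature living animals are paired under the mating
#' policy, litters share a dam and a birth event, and each offspring survives
#' to maturity with probability `plogis(eta)` where `eta` is linear in the
#' seven predictors (standardized on the fly against running within-species
#' moments) with species-level random intercepts and slopes plus program and
#' year effects. Death dates are assigned so that the analysis pipeline's
#' survival labels recover the simulated outcomes exactly; inbreeding
#' bookkeeping uses the same unknown-parent-phantom convention as the
#' pipeline, so pedigree-computed `f` reproduces the simulator's internal
#' values.
#'
#' @param cfg a [simulation_config()].
#' @return A list with elements `pedigree` (a [pedigree][as_pedigree]),
#'   `truth` (per-offspring `eta`, `p`, `survived`, plus realized per-species
#'   slopes/intercepts and program/year effects) and `config`.
#' @export
simulate_studbook <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, simulate_studbook_impl(cfg))
}

simulate_studbook_impl <- function(cfg) {
  end_day <- cfg$n_years * 365L
  origin <- as.Date(sprintf("%d-01-01", cfg$start_year))
  all_records <- list()
  truth_list <- list()
  species_names <- sprintf("species_%02d", seq_len(cfg$n_species))

  # realized species-level effects
  slope_dev <- sapply(PREDICTORS, function(pr)
    rnorm(cfg$n_species, 0, cfg$species_sd[[pr]]))
  if (is.null(dim(slope_dev))) slope_dev <- matrix(
    slope_dev, nrow = 1, dimnames = list(NULL, PREDICTORS))
  rownames(slope_dev) <- species_names
  species_intercept <- setNames(rnorm(cfg$n_species, 0,
                                      cfg$intercept_sd_species),
                                species_names)
  prog_eff <- matrix(rnorm(cfg$n_species * length(cfg$programs), 0,
                           cfg$sd_program),
                     nrow = cfg$n_species,
                     dimnames = list(species_names, cfg$programs))
  year_eff_all <- matrix(rnorm(cfg$n_species * cfg$n_years, 0, cfg$sd_year),
                         nrow = cfg$n_species,
                         dimnames = list(species_names,
                                         as.character(cfg$start_year +
                                                        seq_len(cfg$n_years) - 1L)))
  extinct <- character(0)

  for (s in seq_len(cfg$n_species)) {
    sp <- species_names[s]
    mat_f <- cfg$maturity_female_days[s]
    mat_m <- cfg$maturity_male_days[s]
    cap <- as.integer(cfg$founders_per_species + 256L)
    # per-individual state, grown geometrically as the population grows
    id <- character(cap); sex <- character(cap)
    birth <- integer(cap); death <- rep(NA_integer_, cap)
    sire <- rep(NA_character_, cap); dam <- rep(NA_character_, cap)
    orig <- character(cap); hyb <- logical(cap)
    prog <- character(cap); gen <- numeric(cap); fcoef <- numeric(cap)
    released <- rep(NA_integer_, cap)
    K <- matrix(0, cap, cap)
    n <- 0L

    grow <- function(need) {
      if (need <= cap) return(invisible())
      new_cap <- max(need, 2L * cap)
      pad <- new_cap - cap
      id <<- c(id, character(pad)); sex <<- c(sex, character(pad))
      birth <<- c(birth, integer(pad))
      death <<- c(death, rep(NA_integer_, pad))
      sire <<- c(sire, rep(NA_character_, pad))
      dam <<- c(dam, rep(NA_character_, pad))
      orig <<- c(orig, character(pad)); hyb <<- c(hyb, logical(pad))
      prog <<- c(prog, character(pad)); gen <<- c(gen, numeric(pad))
      fcoef <<- c(fcoef, numeric(pad))
      released <<- c(released, rep(NA_integer_, pad))
      K2 <- matrix(0, new_cap, new_cap)
      K2[seq_len(cap), seq_len(cap)] <- K
      K <<- K2
      cap <<- new_cap
      invisible()
    }

    add_wild <- function(sx, bday, entry_day = 0L) {
      grow(n + 1L)
      n <<- n + 1L
      id[n] <<- sprintf("%s_%05d", sp, n)
      sex[n] <<- sx; birth[n] <<- as.integer(bday)
      orig[n] <<- "wild"; gen[n] <<- 0; fcoef[n] <<- 0
      prog[n] <<- sample(cfg$programs, 1L)
      mat <- if (sx == "female") mat_f else mat_m
      # wild intakes enter as adults and live 1-3 maturities in the program
      death[n] <<- as.integer(entry_day + mat * runif(1, 1, 3))
      K[n, n] <<- 0.5
      n
    }

    for (k in seq_len(cfg$founders_per_species))
      add_wild(if (k %% 2L == 0L) "female" else "male",
               -sample.int(3000L, 1L) - max(mat_f, mat_m))

    # running within-species moments of the raw predictors (Welford)
    w_n <- 0; w_mean <- setNames(numeric(7), PREDICTORS)
    w_m2 <- setNames(numeric(7), PREDICTORS)
    zscore <- function(x) {
      if (w_n < 10) return(setNames(numeric(7), PREDICTORS))
      sds <- sqrt(w_m2 / (w_n - 1))
      z <- ifelse(sds > 0, (x - w_mean) / sds, 0)
      pmin(pmax(z, -4), 4)
    }
    w_update <- function(x) {
      w_n <<- w_n + 1
      d <- x - w_mean
      w_mean <<- w_mean + d / w_n
      w_m2 <<- w_m2 + d * (x - w_mean)
    }

    # per-species ground-truth accumulators
    t_id <- character(0); t_eta <- numeric(0); t_p <- numeric(0)
    t_surv <- logical(0)

    last_birth_year <- NA_integer_
    for (y in seq_len(cfg$n_years)) {
      day0 <- (y - 1L) * 365L
      if (runif(1) < cfg$wild_intake_rate) {
        add_wild("male", day0 - mat_m - sample.int(2000L, 1L),
                 entry_day = day0)
        add_wild("female", day0 - mat_f - sample.int(2000L, 1L),
                 entry_day = day0)
      }
      alive <- seq_len(n)[is.na(released[seq_len(n)]) &
                            death[seq_len(n)] > day0 + 365L]
      fem <- alive[sex[alive] == "female" & birth[alive] + mat_f <= day0]
      mal <- alive[sex[alive] == "male" & birth[alive] + mat_m <= day0]
      if (!length(fem) || !length(mal)) next
      n_lit <- min(length(fem), cfg$max_litters_per_year)
      dams <- if (length(fem) == 1L) fem else sample(fem, n_lit)
      for (dm in dams) {
        cand <- if (length(mal) <= 5L) mal else sample(mal, 5L)
        sr <- switch(cfg$mating_policy,
                     random = cand[sample.int(length(cand), 1L)],
                     avoid_kin = cand[which.min(K[dm, cand])],
                     prefer_kin = cand[which.max(K[dm, cand])])
        lsize <- min(1L + rpois(1L, max(0, cfg$litter_mean[s] - 1)),
                     cfg$litter_max[s])
        base_day <- day0 + sample.int(300L, 1L) - 1L
        days <- if (cfg$litter_rule[s] == "same_year")
          base_day + sample.int(46L, lsize, replace = TRUE) - 1L
        else rep(base_day, lsize)
        grow(n + lsize)
        for (o in seq_len(lsize)) {
          n <- n + 1L
          i <- n
          id[i] <- sprintf("%s_%05d", sp, i)
          sex[i] <- if (runif(1) < cfg$unknown_sex_rate) "unknown"
          else if (runif(1) < 0.5) "female" else "male"
          birth[i] <- as.integer(days[o])
          orig[i] <- "captive"
          hyb[i] <- runif(1) < cfg$hybrid_rate
          prog[i] <- prog[dm]
          mask_sire <- runif(1) < cfg$unknown_sire_rate
          dam[i] <- id[dm]
          sire[i] <- if (mask_sire) NA_character_ else id[sr]
          # masked-pedigree bookkeeping: an unknown sire is a phantom
          # unrelated wild founder, exactly as the pipeline computes f and G
          if (mask_sire) {
            fcoef[i] <- 0
            gen[i] <- (0 + gen[dm]) / 2 + 1
            K[i, seq_len(i - 1L)] <- 0.5 * K[dm, seq_len(i - 1L)]
          } else {
            fcoef[i] <- K[sr, dm]
            gen[i] <- (gen[sr] + gen[dm]) / 2 + 1
            K[i, seq_len(i - 1L)] <- 0.5 * (K[sr, seq_len(i - 1L)] +
                                              K[dm, seq_len(i - 1L)])
          }
          K[seq_len(i - 1L), i] <- K[i, seq_len(i - 1L)]
          K[i, i] <- 0.5 * (1 + fcoef[i])

          x <- c(dam_generation = gen[dm],
                 sire_generation = if (mask_sire) 0 else gen[sr],
                 dam_age = as.numeric(days[o] - birth[dm]),
                 sire_age = as.numeric(days[o] - birth[sr]),
                 dam_f = fcoef[dm],
                 sire_f = if (mask_sire) 0 else fcoef[sr],
                 offspring_f = fcoef[i])
          z <- zscore(x)
          eta <- cfg$intercept + species_intercept[s] +
            prog_eff[s, prog[i]] +
            year_eff_all[s, y] +
            sum((cfg$true_beta + slope_dev[s, ]) * z)
          p <- plogis(eta)
          surv <- runif(1) < p
          w_update(x)

          mat_i <- if (sex[i] == "female") mat_f
          else if (sex[i] == "male") mat_m else min(mat_f, mat_m)
          death[i] <- if (surv)
            as.integer(birth[i] + mat_i + floor(runif(1, 0, 3 * mat_i)))
          else as.integer(birth[i] + floor(runif(1, 0, mat_i)))
          if (cfg$release_rate > 0 && runif(1) < cfg$release_rate)
            released[i] <- as.integer(birth[i] +
                                        floor(runif(1, 0, 0.8 * mat_i)))
          t_id <- c(t_id, id[i]); t_eta <- c(t_eta, unname(eta))
          t_p <- c(t_p, unname(p)); t_surv <- c(t_surv, surv)
          last_birth_year <- y
        }
      }
    }
    if (is.na(last_birth_year) || last_birth_year < cfg$n_years)
      extinct <- c(extinct, sp)

    keep <- seq_len(n)
    death_keep <- death[keep]
    death_keep[!is.na(death_keep) & death_keep > end_day] <- NA_integer_
    rel <- released[keep]
    rec <- data.frame(id = id[keep], sire = sire[keep], dam = dam[keep],
                      sex = sex[keep],
                      birth_date = origin + birth[keep],
                      death_date = origin + death_keep,
                      birth_program = prog[keep],
                      origin = orig[keep],
                      hybrid = hyb[keep],
                      species = sp,
                      stringsAsFactors = FALSE)
    if (cfg$release_rate > 0) rec$release_date <- origin + rel
    rec$.internal_f <- fcoef[keep]
    rec$.internal_gen <- gen[keep]
    all_records[[s]] <- rec
    truth_list[[s]] <- data.frame(id = t_id,
                                  species = rep_len(sp, length(t_id)),
                                  eta = t_eta, p = t_p, survived = t_surv,
                                  stringsAsFactors = FALSE)
  }

  if (length(extinct))
    warnf("population ran out of breeders before the final year: %s",
          paste(extinct, collapse = ", "))

  records <- do.call(rbind, all_records)
  internal <- records[c("id", ".internal_f", ".internal_gen")]
  names(internal) <- c("id", "f", "generation")
  records$.internal_f <- NULL
  records$.internal_gen <- NULL
  ped <- as_pedigree(records, current_date = origin + end_day, check = TRUE)

  truth <- list(offspring = do.call(rbind, truth_list),
                species_slopes = sweep(slope_dev[, PREDICTORS, drop = FALSE],
                                       2, cfg$true_beta[PREDICTORS], "+"),
                species_intercepts = species_intercept,
                program_effects = prog_eff,
                year_effects = year_eff_all,
                internal = internal)
  list(pedigree = ped, truth = truth, config = cfg)
}

#' Write a studbook CSV in the package dialect
#'
#' @param p a [pedigree][as_pedigree].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_studbook <- function(p, path) {
  r <- p$records
  r$sire[is.na(r$sire)] <- "UNKNOWN"
  r$dam[is.na(r$dam)] <- "UNKNOWN"
  r$birth_date <- format(r$birth_date)
  r$death_date <- ifelse(is.na(r$death_date), "ALIVE", format(r$death_date))
  if ("release_date" %in% names(r))
    r$release_date <- ifelse(is.na(r$release_date), "",
                             format(r$release_date))
  r$hybrid <- ifelse(r$hybrid, "TRUE", "FALSE")
  write.csv(r, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a species tree and a trait with chosen phylogenetic signal
#'
#' Random coalescent tree plus a species trait drawn from the
#' lambda-transformed Brownian covariance -- the test bed for the lambda
#' estimator.
#'
#' @param n_species number of tips (>= 4).
#' @param seed integer seed.
#' @param lambda generative Pagel's lambda in `[0, 1]`.
#' @param sigma2 Brownian rate.
#' @param mean trait grand mean.
#' @return A list: `tree` (tips `species_01`, ...), `trait` (named vector),
#'   `lambda`, `sigma2`.
#' @export
simulate_species_tree <- function(n_species, seed = 1L, lambda = 1,
                                  sigma2 = 1, mean = 0) {
  if (n_species < 4L) stopf("need >= 4 species")
  with_seed(seed, {
    tree <- ape::rcoal(n_species,
                       tip.label = sprintf("species_%02d", seq_len(n_species)))
    V <- sigma2 * lambda_covariance(tree, lambda)
    ch <- chol(V + diag(1e-10, n_species))
    trait <- setNames(as.numeric(mean + t(ch) %*% rnorm(n_species)),
                      rownames(V))
    list(tree = tree, trait = trait, lambda = lambda, sigma2 = sigma2)
  })
}

#' Hand-constructed toy pedigrees with known answers
#'
#' Small fixtures with analytically known inbreeding, kinship and generation
#' values:
#' * `founders`: two unrelated wild founders (every f = 0, generation 0).
#' * `fullsib`: offspring of a full-sib mating, `f = 0.25`.
#' * `parent_offspring`: offspring of a parent-offspring mating, `f = 0.25`.
#' * `g_mix`: offspring of a G0 x G1 pairing, generation 1.5.
#' * `litters_mix`: a mammal same-day litter and a reptile same-year clutch
#'   (use [toy_species_config()]).
#' * `exclusions`: 2 wild founders + 10 captive offspring of which 2 hybrids,
#'   1 unknown sire, 1 too young and 6 clean analysis rows.
#'
#' @return Named list of [pedigree][as_pedigree] objects.
#' @export
toy_fixtures <- function() {
  mk <- function(df, current) {
    df$birth_program <- "Europe"
    if (is.null(df$hybrid)) df$hybrid <- FALSE
    if (is.null(df$species)) df$species <- "toy"
    as_pedigree(df, current_date = as.Date(current))
  }
  founders <- mk(data.frame(
    id = c("W1", "W2"), sire = NA, dam = NA, sex = c("male", "female"),
    birth_date = "2000-01-01", death_date = NA, origin = "wild",
    stringsAsFactors = FALSE), "2020-01-01")

  fullsib <- mk(data.frame(
    id = c("W1", "W2", "C1", "C2", "X"),
    sire = c(NA, NA, "W1", "W1", "C1"),
    dam = c(NA, NA, "W2", "W2", "C2"),
    sex = c("male", "female", "male", "female", "female"),
    birth_date = c("2000-01-01", "2000-01-01", "2005-01-01", "2005-01-01",
                   "2010-01-01"),
    death_date = NA,
    origin = c("wild", "wild", "captive", "captive", "captive"),
    stringsAsFactors = FALSE), "2020-01-01")

  parent_offspring <- mk(data.frame(
    id = c("W1", "W2", "C", "X"),
    sire = c(NA, NA, "W1", "W1"),
    dam = c(NA, NA, "W2", "C"),
    sex = c("male", "female", "female", "male"),
    birth_date = c("2000-01-01", "2000-01-01", "2005-01-01", "2010-01-01"),
    death_date = NA,
    origin = c("wild", "wild", "captive", "captive"),
    stringsAsFactors = FALSE), "2020-01-01")

  g_mix <- mk(data.frame(
    id = c("W1", "W2", "W3", "P", "C"),
    sire = c(NA, NA, NA, "W1", "W3"),
    dam = c(NA, NA, NA, "W2", "P"),
    sex = c("male", "female", "male", "female", "female"),
    birth_date = c("2000-01-01", "2000-01-01", "2000-01-01", "2005-01-01",
                   "2010-01-01"),
    death_date = NA,
    origin = c("wild", "wild", "wild", "captive", "captive"),
    stringsAsFactors = FALSE), "2020-01-01")

  litters_mix <- as_pedigree(data.frame(
    id = c("MD", "MS", "M1", "M2", "M3", "RD", "RS", "R1", "R2"),
    sire = c(NA, NA, "MS", "MS", "MS", NA, NA, "RS", "RS"),
    dam = c(NA, NA, "MD", "MD", "MD", NA, NA, "RD", "RD"),
    sex = c("female", "male", "female", "male", "female",
            "female", "male", "female", "male"),
    birth_date = c("2000-01-01", "2000-01-01", "2010-03-05", "2010-03-05",
                   "2011-06-10", "2000-01-01", "2000-01-01", "2010-03-05",
                   "2010-08-20"),
    death_date = NA,
    birth_program = "Europe",
    origin = c("wild", "wild", "captive", "captive", "captive",
               "wild", "wild", "captive", "captive"),
    hybrid = FALSE,
    species = c(rep("mammal_sp", 5), rep("reptile_sp", 4)),
    stringsAsFactors = FALSE), current_date = as.Date("2020-01-01"))

  excl <- data.frame(
    id = c("W1", "W2", sprintf("C%d", 1:10)),
    # C7 has no recorded sire
    sire = c(NA, NA, rep("W1", 6), NA, rep("W1", 3)),
    dam = c(NA, NA, rep("W2", 10)),
    sex = rep(c("male", "female"), 6),
    # C10 born within maturity (365 d) of the 2021-01-01 cutoff
    birth_date = c("2005-01-01", "2005-01-01", rep("2012-06-01", 9),
                   "2020-08-01"),
    death_date = c(NA, NA, "2012-07-01", "2012-08-01", "2012-09-01",
                   NA, NA, NA, NA, NA, NA, NA),
    origin = c("wild", "wild", rep("captive", 10)),
    # C5 and C6 are hybrids
    hybrid = c(rep(FALSE, 6), TRUE, TRUE, rep(FALSE, 4)),
    stringsAsFactors = FALSE)
  exclusions <- mk(excl, "2021-01-01")

  list(founders = founders, fullsib = fullsib,
       parent_offspring = parent_offspring, g_mix = g_mix,
       litters_mix = litters_mix, exclusions = exclusions)
}

#' Species configuration for the toy fixtures
#'
#' @return A [species_config] covering the [toy_fixtures()] species
#'   (maturity 365 days; mammal `same_day`, reptile `same_year`).
#' @export
toy_species_config <- function() {
  species_config(species = c("toy", "mammal_sp", "reptile_sp"),
                 maturity_female_days = 365,
                 maturity_male_days = 365,
                 litter_rule = c("same_day", "same_day", "same_year"))
}
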