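#' Simulation configuration for a synthetic food-consumption survey
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate a
#' national 7-day food-record survey of adults: 2600 individuals, 66 analysis
#' food groups, 7 latent consumption systems (CS) combined into 7 dietary
#' patterns, a high fraction of structural zeros from non-consumption, and
#' survey weights with mean 1 and standard deviation 0.7.
#'
#' @param n_individuals Number of individuals.
#' @param n_food_groups Number of food groups (columns of the consumption
#'   matrix).
#' @param n_cs Number of planted latent consumption systems.
#' @param zero_inflation Probability that any consumption cell is masked to
#'   zero (non-consumption), independent of intake level. Must lie in `[0, 1)`.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise applied to each consumption cell (0 disables noise).
#' @param n_patterns Number of planted dietary patterns.
#' @param pattern_separation Separation of the pattern centroids in CS-score
#'   space: each pattern's signature-CS score is displaced from the
#'   background level by `pattern_separation` within-pattern standard
#'   deviations along that axis. 0 plants no cluster signal; values must stay
#'   below `1 / 0.15` (the reciprocal of the within-pattern coefficient of
#'   variation).
#' @param weight_sd Standard deviation of the survey weights (their mean is
#'   always rescaled to 1).
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 200, n_food_groups = 30, seed = 7)
sim_config <- function(n_individuals = 2600,
                       n_food_groups = 66,
                       n_cs = 7,
                       zero_inflation = 0.3,
                       noise_cv = 0.2,
                       n_patterns = 7,
                       pattern_separation = 6,
                       weight_sd = 0.7,
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_food_groups = as.integer(n_food_groups),
    n_cs = as.integer(n_cs),
    zero_inflation = zero_inflation,
    noise_cv = noise_cv,
    n_patterns = as.integer(n_patterns),
    pattern_separation = pattern_separation,
    weight_sd = weight_sd,
    seed = as.integer(seed)
  )
  counts <- c("n_individuals", "n_food_groups", "n_cs", "n_patterns")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1) stop_dp("`", nm, "` must be a count >= 1")
  }
  if (cfg$n_cs > cfg$n_food_groups) {
    stop_dp("invalid config: n_cs (", cfg$n_cs, ") exceeds n_food_groups (",
            cfg$n_food_groups, ")")
  }
  if (cfg$zero_inflation < 0 || cfg$zero_inflation >= 1) {
    stop_dp("`zero_inflation` must lie in [0, 1)")
  }
  if (cfg$noise_cv < 0) stop_dp("`noise_cv` must be >= 0")
  if (cfg$weight_sd < 0) stop_dp("`weight_sd` must be >= 0")
  if (cfg$pattern_separation < 0 ||
      cfg$pattern_separation >= 1 / .sim_within_cv) {
    stop_dp("`pattern_separation` must lie in [0, ", round(1 / .sim_within_cv, 2),
            ") under the within-pattern CV of ", .sim_within_cv)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Names of the 20 nutrients entering the mean adequacy ratio
#'
#' Proteins, fibres, vitamins A, C, E, D, B1, B2, B3, B6, B9, B12 and the
#' minerals Ca, K, Fe, Mg, Zn, Cu, I, Se.
#'
#' @return Character vector of length 20.
#' @export
mar_nutrients <- function() {
  c("protein_g", "fibre_g",
    "vit_a_ug", "vit_c_mg", "vit_e_mg", "vit_d_ug",
    "vit_b1_mg", "vit_b2_mg", "vit_b3_mg", "vit_b6_mg",
    "vit_b9_ug", "vit_b12_ug",
    "calcium_mg", "potassium_mg", "iron_mg", "magnesium_mg",
    "zinc_mg", "copper_mg", "iodine_ug", "selenium_ug")
}

#' Substances tracked by the synthetic total-diet contamination table
#' @return Character vector of substance identifiers.
#' @export
tds_substances <- function() {
  c("lead", "aluminium", "cadmium", "inorganic_arsenic", "organic_mercury",
    "acrylamide", "deoxynivalenol", "ndl_pcb", "dioxins", "sulphites")
}

# Named food-group catalogue: beverage flag (excluded from energy density)
# and the macro group used by the dietary diversity score (NA = none).
.food_catalog <- function() {
  d <- function(group, bev, dds) data.frame(group = group, beverage = bev,
                                            dds_group = dds,
                                            stringsAsFactors = FALSE)
  rbind(
    d("milk", TRUE,  "dairy"), d("yogurt", FALSE, "dairy"),
    d("cheese", FALSE, "dairy"),
    d("red_meat", FALSE, "meat"), d("poultry", FALSE, "meat"),
    d("fish_crustaceans", FALSE, "meat"),
    d("rice", FALSE, "cereals"), d("pasta", FALSE, "cereals"),
    d("wheat_products", FALSE, "cereals"),
    d("fresh_fruit", FALSE, "fruits"), d("processed_fruit", FALSE, "fruits"),
    d("fresh_vegetables", FALSE, "vegetables"),
    d("prepared_vegetables", FALSE, "vegetables"),
    d("water", TRUE, NA), d("soft_drinks", TRUE, NA),
    d("fruit_juice", TRUE, NA), d("coffee", TRUE, NA), d("tea", TRUE, NA),
    d("wine", TRUE, NA), d("beer", TRUE, NA), d("spirits", TRUE, NA),
    d("bread", FALSE, NA), d("breakfast_cereals", FALSE, NA),
    d("croissant_pastries", FALSE, NA), d("cakes_biscuits", FALSE, NA),
    d("potatoes", FALSE, NA), d("pulses", FALSE, NA),
    d("eggs", FALSE, NA), d("processed_meat", FALSE, NA),
    d("offal", FALSE, NA), d("butter", FALSE, NA),
    d("margarine", FALSE, NA), d("vegetable_oil", FALSE, NA),
    d("sauces_condiments", FALSE, NA), d("sugar_confectionery", FALSE, NA),
    d("chocolate", FALSE, NA), d("ice_cream", FALSE, NA),
    d("pizza_quiche", FALSE, NA), d("sandwiches", FALSE, NA),
    d("soups", FALSE, NA), d("ready_meals", FALSE, NA),
    d("salted_snacks", FALSE, NA), d("nuts_seeds", FALSE, NA),
    d("crackers", FALSE, NA)
  )
}

#' Food-group metadata used by the generator
#'
#' The first groups carry survey-style names with beverage flags and the
#' mapping onto the five macro groups of the dietary diversity score (dairy,
#' meat/fish, cereals, fruits, vegetables); any remainder are generic
#' non-beverage groups.
#'
#' @param n_food_groups Number of groups required.
#' @return A data frame with columns `group`, `beverage`, `dds_group`.
#' @export
food_groups <- function(n_food_groups) {
  cat <- .food_catalog()
  if (n_food_groups <= nrow(cat)) return(cat[seq_len(n_food_groups), ])
  extra <- n_food_groups - nrow(cat)
  pad <- data.frame(group = sprintf("other_food_%02d", seq_len(extra)),
                    beverage = FALSE, dds_group = NA_character_,
                    stringsAsFactors = FALSE)
  out <- rbind(cat, pad)
  rownames(out) <- NULL
  out
}

# Frozen design constants of the score model (documented in the methods
# vignette): within-pattern coefficient of variation of CS usage, background
# CS score (g/d), shared baseline mass of each loading row, and the range of
# dominant food groups per CS.
.sim_within_cv <- 0.15
.sim_background_score <- 50
.sim_baseline_mass <- 0.2
.sim_n_dominant <- c(10L, 15L)

#' Plant the ground truth of a synthetic survey population
#'
#' Draws sparse non-negative CS loadings — the food groups are partitioned
#' among the CS and each CS concentrates 80% of its mass on 10-15 dominant
#' groups of its block, the rest spread uniformly — and individual CS scores
#' from a gamma model: within a pattern, the score on CS `j` has mean given
#' by the pattern centroid and coefficient of variation 0.15. Centroids sit
#' at a background level of 50 g/d on every axis except the pattern's
#' signature axis, which is displaced upwards by `pattern_separation`
#' within-pattern standard deviations — each dietary pattern over-uses its
#' own consumption system, the structure dietary surveys report.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_truth`: list with `true_loadings`
#'   (CS x foods, rows sum to 1), `true_scores` (individuals x CS, g/d),
#'   `true_pattern` (integer labels), `true_covariate_effects`
#'   (data frame: covariate, pattern, log_or), `centroids`, `within_cv`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_cs; p <- config$n_food_groups; n <- config$n_individuals
  fg <- food_groups(p)
  with_seed(config$seed, {
    # Loadings: partition the groups among the CS; dominant subsets carry
    # 80% of each row's mass with near-even gamma weights.
    perm <- sample.int(p)
    blocks <- split(perm, rep(seq_len(k), length.out = p))
    L <- matrix(.sim_baseline_mass / p, nrow = k, ncol = p,
                dimnames = list(paste0("CS", seq_len(k)), fg$group))
    for (j in seq_len(k)) {
      ndom <- min(length(blocks[[j]]),
                  sample(.sim_n_dominant[1]:.sim_n_dominant[2], 1))
      dom <- blocks[[j]][seq_len(ndom)]
      wdom <- stats::rgamma(ndom, shape = 4, rate = 1)
      L[j, dom] <- L[j, dom] + (1 - .sim_baseline_mass) * wdom / sum(wdom)
    }
    L <- L / rowSums(L)

    # Centroids: background score everywhere, signature axis displaced by
    # pattern_separation within-pattern standard deviations. Because the
    # within-pattern spread is proportional to the centroid (fixed CV), the
    # signature level solves hi = lo / (1 - cv * separation).
    lo <- .sim_background_score
    hi <- lo / (1 - .sim_within_cv * config$pattern_separation)
    centroids <- matrix(lo, nrow = config$n_patterns, ncol = k)
    for (c_ in seq_len(config$n_patterns)) {
      ax1 <- ((c_ - 1) %% k) + 1
      centroids[c_, ax1] <- hi
      if (config$n_patterns > k) {   # second axis disambiguates collisions
        ax2 <- ((c_ - 1 + (c_ - 1) %/% k) %% k) + 1
        centroids[c_, ax2] <- (lo + hi) / 2
      }
    }

    # Unequal pattern prevalences spanning roughly 8-20%, the range national
    # dietary surveys report for pattern shares.
    prev <- (config$n_patterns:1) + 3
    prev <- prev / sum(prev)
    labels <- sample.int(config$n_patterns, n, replace = TRUE, prob = prev)

    shape <- 1 / .sim_within_cv^2
    mu <- centroids[labels, , drop = FALSE]
    S <- matrix(stats::rgamma(n * k, shape = shape, rate = 1), n, k) *
      mu / shape
    dimnames(S) <- list(sprintf("ind_%04d", seq_len(n)), rownames(L))

    eff <- data.frame(
      covariate = c("age_65plus", "sex_female", "education_low"),
      pattern = c(1L, 2L, 3L),
      log_or = c(log(2), log(1.5), log(1.8)),
      stringsAsFactors = FALSE
    )
    eff <- eff[eff$pattern <= config$n_patterns, , drop = FALSE]

    structure(list(true_loadings = L, true_scores = S,
                   true_pattern = labels, true_covariate_effects = eff,
                   centroids = centroids, within_cv = .sim_within_cv,
                   food_groups = fg),
              class = "synthetic_truth")
  })
}

#' Generate the observed consumption matrix from a planted truth
#'
#' The observed intake is the low-rank signal `scores %*% loadings`, perturbed
#' by multiplicative log-normal noise with mean 1 and coefficient of variation
#' `noise_cv`, then masked to zero independently per cell with probability
#' `zero_inflation` (the non-consumption mechanism).
#'
#' @param truth A [generate_truth()] result.
#' @param config The matching [sim_config()].
#' @return Non-negative individuals x food-groups matrix of mean daily intake
#'   (g/d), with dimnames.
#' @export
generate_consumption <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(config, "sim_config"))
  if (ncol(truth$true_scores) != config$n_cs ||
      ncol(truth$true_loadings) != config$n_food_groups) {
    stop_dp("truth dimensions are inconsistent with config")
  }
  X0 <- truth$true_scores %*% truth$true_loadings
  with_seed(config$seed + 1L, {
    X <- X0
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      noise <- matrix(stats::rlnorm(length(X), meanlog = -sdlog^2 / 2,
                                    sdlog = sdlog), nrow(X), ncol(X))
      X <- X * noise
    }
    if (config$zero_inflation > 0) {
      mask <- matrix(stats::runif(length(X)) >= config$zero_inflation,
                     nrow(X), ncol(X))
      X <- X * mask
    }
    pmax(X, 0)
  })
}

#' Generate synthetic composition, recommended-intake and contamination tables
#'
#' Produces (i) a food-composition table (energy plus the 20 nutrients of the
#' mean adequacy ratio, per 100 g) with a beverage flag per group, (ii) a
#' recommended daily allowance (RDA) table keyed by sex and age band, and
#' (iii) a contamination table with lower/middle/upper-bound concentrations
#' per substance and food group, where values below the limit of detection are
#' substituted by 0 / LOD/2 / LOD.
#'
#' All values are synthetic placeholders on realistic scales; real composition
#' and allowance tables are supplied by the user in applied work.
#'
#' @param config A [sim_config()].
#' @return A list of class `composition_tables` with elements `composition`,
#'   `rda`, `contamination`, `age_bands`.
#' @export
generate_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fg <- food_groups(config$n_food_groups)
  p <- nrow(fg)
  nutr <- mar_nutrients()
  # Typical per-100g scale for each nutrient (synthetic but plausible order
  # of magnitude) and a daily allowance scale per nutrient.
  nutr_scale <- c(protein_g = 8, fibre_g = 2, vit_a_ug = 60, vit_c_mg = 6,
                  vit_e_mg = 1, vit_d_ug = 0.4, vit_b1_mg = 0.1,
                  vit_b2_mg = 0.12, vit_b3_mg = 1.2, vit_b6_mg = 0.12,
                  vit_b9_ug = 20, vit_b12_ug = 0.3, calcium_mg = 60,
                  potassium_mg = 200, iron_mg = 1, magnesium_mg = 20,
                  zinc_mg = 0.8, copper_mg = 0.1, iodine_ug = 10,
                  selenium_ug = 5)
  rda_scale <- c(protein_g = 60, fibre_g = 25, vit_a_ug = 700, vit_c_mg = 110,
                 vit_e_mg = 12, vit_d_ug = 5, vit_b1_mg = 1.2, vit_b2_mg = 1.5,
                 vit_b3_mg = 13, vit_b6_mg = 1.6, vit_b9_ug = 330,
                 vit_b12_ug = 2.4, calcium_mg = 900, potassium_mg = 3500,
                 iron_mg = 11, magnesium_mg = 380, zinc_mg = 11,
                 copper_mg = 1.5, iodine_ug = 150, selenium_ug = 60)
  with_seed(config$seed + 2L, {
    comp <- matrix(0, nrow = p, ncol = length(nutr),
                   dimnames = list(fg$group, nutr))
    for (j in seq_along(nutr)) {
      comp[, j] <- stats::rlnorm(p, meanlog = log(nutr_scale[j]), sdlog = 0.8)
    }
    energy <- stats::rlnorm(p, meanlog = log(150), sdlog = 0.6)  # kcal/100g
    energy[fg$beverage] <- stats::rlnorm(sum(fg$beverage),
                                         meanlog = log(25), sdlog = 0.9)
    composition <- data.frame(food_group = fg$group,
                              beverage = fg$beverage,
                              dds_group = fg$dds_group,
                              energy_kcal = energy,
                              comp, stringsAsFactors = FALSE,
                              check.names = FALSE)
    rownames(composition) <- NULL

    bands <- c("18-24", "25-34", "35-49", "50-64", "65+")
    rda <- expand.grid(sex = c("male", "female"), age_band = bands,
                       stringsAsFactors = FALSE)
    for (nm in nutr) {
      sex_mult <- ifelse(rda$sex == "male", 1.1, 0.95)
      # Pre-menopausal women need more iron.
      if (nm == "iron_mg") {
        sex_mult <- ifelse(rda$sex == "female" &
                             rda$age_band %in% c("18-24", "25-34", "35-49"),
                           1.45, sex_mult)
      }
      age_mult <- 1 + 0.02 * (match(rda$age_band, bands) - 3)
      rda[[nm]] <- rda_scale[nm] * sex_mult * age_mult
    }

    subs <- tds_substances()
    conc <- stats::rlnorm(length(subs) * p, meanlog = log(0.02), sdlog = 1.2)
    contamination <- data.frame(
      substance = rep(subs, each = p),
      food_group = rep(fg$group, times = length(subs)),
      unit = "ug/g",
      conc_true = conc,
      stringsAsFactors = FALSE
    )
    # Fish-borne contaminants are concentrated in fish, the classic
    # risk-benefit tension of fish-rich prudent diets.
    fish <- contamination$food_group == "fish_crustaceans" &
      contamination$substance %in% c("organic_mercury", "inorganic_arsenic")
    contamination$conc_true[fish] <- contamination$conc_true[fish] * 50
    lod <- stats::quantile(contamination$conc_true, 0.25)
    cens <- contamination$conc_true < lod
    contamination$conc_LB <- ifelse(cens, 0, contamination$conc_true)
    contamination$conc_MB <- ifelse(cens, lod / 2, contamination$conc_true)
    contamination$conc_UB <- ifelse(cens, lod, contamination$conc_true)
    contamination$tef <- 1
    contamination$conc_true <- NULL

    structure(list(composition = composition, rda = rda,
                   contamination = contamination, age_bands = bands),
              class = "composition_tables")
  })
}

# Map an age in years onto the reporting age bands.
age_to_band <- function(age) {
  cut(age, breaks = c(18, 25, 35, 50, 65, Inf), right = FALSE,
      labels = c("18-24", "25-34", "35-49", "50-64", "65+"))
}

#' Generate covariates and survey weights tied to the planted patterns
#'
#' Survey weights are log-normal, rescaled to mean exactly 1 with standard
#' deviation about `weight_sd`. Socio-demographic covariates are drawn so the
#' planted covariate-pattern log-odds in `truth$true_covariate_effects` hold:
#' a binary marker generated by logistic tilting of its prevalence within the
#' target pattern has exactly that odds ratio against pattern membership.
#' Household-wealth indicator items are driven by a latent wealth score.
#'
#' @param truth A [generate_truth()] result.
#' @param config The matching [sim_config()].
#' @return A data frame (one row per individual): `individual_id`, `weight`,
#'   demographics, wealth items, `body_weight_kg`.
#' @export
generate_covariates_and_weights <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(config, "sim_config"))
  n <- config$n_individuals
  pat <- truth$true_pattern
  eff <- truth$true_covariate_effects
  beta <- function(cov) {
    i <- match(cov, eff$covariate)
    if (is.na(i)) return(list(b = 0, pattern = 0L))
    list(b = eff$log_or[i], pattern = eff$pattern[i])
  }
  with_seed(config$seed + 3L, {
    if (config$weight_sd > 0) {
      sdlog <- sqrt(log(1 + config$weight_sd^2))
      w <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      w <- w / mean(w)
    } else {
      w <- rep(1, n)
    }

    b_age <- beta("age_65plus")
    p65 <- stats::plogis(stats::qlogis(0.20) + b_age$b * (pat == b_age$pattern))
    is65 <- stats::runif(n) < p65
    age <- ifelse(is65, stats::runif(n, 65, 80), stats::runif(n, 18, 64.999))

    b_sex <- beta("sex_female")
    pfem <- stats::plogis(stats::qlogis(0.52) + b_sex$b * (pat == b_sex$pattern))
    sex <- ifelse(stats::runif(n) < pfem, "female", "male")

    b_edu <- beta("education_low")
    plow <- stats::plogis(stats::qlogis(0.30) + b_edu$b * (pat == b_edu$pattern))
    edu_low <- stats::runif(n) < plow
    education <- ifelse(edu_low, "low",
                        ifelse(stats::runif(n) < 0.55, "middle", "high"))

    occupation <- sample(c("manual", "employee", "intermediate", "executive",
                           "inactive"), n, replace = TRUE,
                         prob = c(0.22, 0.27, 0.2, 0.14, 0.17))
    household_size <- pmin(stats::rpois(n, 1.4) + 1L, 6L)
    household_comp <- sample(c("single", "couple_no_child", "with_children"),
                             n, replace = TRUE, prob = c(0.3, 0.33, 0.37))
    region <- sample(c("north", "east", "south", "west"), n, replace = TRUE)
    season <- sample(c("winter", "spring", "summer", "autumn"), n,
                     replace = TRUE)
    municipality <- sample(c("rural", "small_urban", "large_urban"), n,
                           replace = TRUE, prob = c(0.25, 0.35, 0.4))
    food_insecurity <- stats::runif(n) < 0.07

    # Latent affluence drives the wealth-questionnaire items.
    u <- stats::rnorm(n) + 0.6 * (education == "high") -
      0.5 * (education == "low")
    item <- function(a, b) stats::runif(n) < stats::plogis(a + b * u)
    holiday_4d <- item(0.1, 1.2)
    n_cars <- cut(u + stats::rnorm(n, sd = 0.8), c(-Inf, -0.8, 0.7, Inf),
                  labels = c("none", "one", "two_plus"))
    many_appliances <- item(0.3, 1.0)
    fin_situation_good <- item(0.0, 1.4)
    access_desired_food <- item(0.8, 1.1)
    housing_owner <- item(-0.2, 0.9)

    bw <- ifelse(sex == "male", stats::rnorm(n, 77, 12),
                 stats::rnorm(n, 65, 11))
    bw <- pmax(bw, 40)

    data.frame(
      individual_id = rownames(truth$true_scores),
      weight = w,
      sex = sex,
      age = age,
      age_band = as.character(age_to_band(age)),
      education = education,
      occupation = occupation,
      household_size = household_size,
      household_comp = household_comp,
      region = region,
      season = season,
      municipality = municipality,
      food_insecurity = food_insecurity,
      holiday_4d = holiday_4d,
      n_cars = as.character(n_cars),
      many_appliances = many_appliances,
      fin_situation_good = fin_situation_good,
      access_desired_food = access_desired_food,
      housing_owner = housing_owner,
      body_weight_kg = bw,
      stringsAsFactors = FALSE
    )
  })
}

#' Disaggregate a consumption matrix into a 7-day diary
#'
#' Splits each individual's mean daily intake of each group across the days of
#' a one-week record: each consumed group is eaten on a random subset of days
#' (episodic consumption) and the weekly total `7 * X[i, j]` is divided among
#' those days by normalised gamma shares, so mass is conserved exactly. Days
#' 1-5 are weekdays, days 6-7 weekend days.
#'
#' @param X Consumption matrix (individuals x groups, g/d).
#' @param seed Integer seed.
#' @param n_days Days in the record (default 7).
#' @return Long data frame: `individual_id`, `day_index`, `day_type`,
#'   `food_group`, `amount` (g), containing only positive amounts.
#' @export
generate_diary <- function(X, seed = 1L, n_days = 7L) {
  nz <- which(X > 0, arr.ind = TRUE)
  if (nrow(nz) == 0) {
    return(data.frame(individual_id = character(), day_index = integer(),
                      day_type = character(), food_group = character(),
                      amount = numeric(), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    ndays_eaten <- 1L + stats::rbinom(nrow(nz), n_days - 1L, 0.55)
    reps <- ndays_eaten
    cell <- rep.int(seq_len(nrow(nz)), reps)
    day <- unlist(lapply(reps, function(m) sample.int(n_days, m)),
                  use.names = FALSE)
    share <- stats::rgamma(length(cell), shape = 1.5, rate = 1)
    tot_share <- rowsum(share, cell)[, 1]
    weekly <- n_days * X[nz]
    amount <- weekly[cell] * share / tot_share[cell]
    data.frame(
      individual_id = rownames(X)[nz[cell, 1]],
      day_index = day,
      day_type = ifelse(day <= 5, "weekday", "weekend"),
      food_group = colnames(X)[nz[cell, 2]],
      amount = amount,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a complete synthetic survey bundle
#'
#' Convenience wrapper running [generate_truth()], [generate_consumption()],
#' [generate_tables()], [generate_covariates_and_weights()] and
#' [generate_diary()] under one configuration.
#'
#' @param config A [sim_config()].
#' @param diary Also generate the 7-day diary (needed for the dietary
#'   diversity score)? Default `TRUE`.
#' @return List of class `synthetic_survey` with elements `config`, `truth`,
#'   `consumption`, `tables`, `individuals`, `diary`.
#' @export
generate_survey <- function(config = sim_config(), diary = TRUE) {
  truth <- generate_truth(config)
  X <- generate_consumption(truth, config)
  tables <- generate_tables(config)
  indiv <- generate_covariates_and_weights(truth, config)
  dia <- if (diary) generate_diary(X, seed = config$seed + 4L) else NULL
  structure(list(config = config, truth = truth, consumption = X,
                 tables = tables, individuals = indiv, diary = dia),
            class = "synthetic_survey")
}

#' Write a synthetic survey bundle to a directory of plain-text files
#'
#' Writes `consumption.csv`, `individuals.csv`, `composition.csv`, `rda.csv`,
#' `contamination.csv`, `truth.json` and `config.yaml`.
#'
#' @param survey A [generate_survey()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_survey_bundle <- function(survey, dir) {
  stopifnot(inherits(survey, "synthetic_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Xdf <- data.frame(individual_id = rownames(survey$consumption),
                    survey$consumption, check.names = FALSE)
  utils::write.csv(Xdf, file.path(dir, "consumption.csv"), row.names = FALSE)
  utils::write.csv(survey$individuals, file.path(dir, "individuals.csv"),
                   row.names = FALSE)
  utils::write.csv(survey$tables$composition, file.path(dir, "composition.csv"),
                   row.names = FALSE)
  utils::write.csv(survey$tables$rda, file.path(dir, "rda.csv"),
                   row.names = FALSE)
  utils::write.csv(survey$tables$contamination,
                   file.path(dir, "contamination.csv"), row.names = FALSE)
  if (!is.null(survey$diary)) {
    utils::write.csv(survey$diary, file.path(dir, "diary.csv"),
                     row.names = FALSE)
  }
  truth <- survey$truth
  jsonlite::write_json(
    list(true_loadings = truth$true_loadings,
         true_pattern = truth$true_pattern,
         true_covariate_effects = truth$true_covariate_effects),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  yaml::write_yaml(unclass(survey$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
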