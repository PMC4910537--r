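#' Per-individual nutrient intakes from consumption and composition
#'
#' Matches a food-composition table (per 100 g) to the consumption matrix:
#' `intake_n = sum_j consumption_j * composition_{j,n} / 100`.
#'
#' @param X Consumption matrix (individuals x groups, g/d).
#' @param composition Data frame with `food_group`, `energy_kcal` and one
#'   column per nutrient (amount per 100 g).
#' @param nutrients Nutrient columns to use; default all numeric columns of
#'   `composition` except the key/flag columns.
#' @return Object of class `nutrient_intake`: list with `intakes`
#'   (individuals x nutrients matrix) and `tei` (kcal/d vector).
#' @export
nutrient_intakes <- function(X, composition, nutrients = NULL) {
  X <- as.matrix(X)
  i <- match(colnames(X), composition$food_group)
  if (anyNA(i)) {
    stop_dp("composition table missing food group(s): ",
            paste(colnames(X)[is.na(i)], collapse = ", "))
  }
  if (is.null(nutrients)) {
    drop <- c("food_group", "beverage", "dds_group")
    nutrients <- setdiff(names(composition)[vapply(composition, is.numeric,
                                                   TRUE)], drop)
  }
  M <- as.matrix(composition[i, nutrients, drop = FALSE])
  rownames(M) <- colnames(X)
  intakes <- X %*% M / 100
  tei <- if ("energy_kcal" %in% nutrients) {
    stats::setNames(intakes[, "energy_kcal"], rownames(X))
  }
  structure(list(intakes = intakes, tei = tei), class = "nutrient_intake")
}

#' Mean adequacy ratio (MAR)
#'
#' Mean over 20 key nutrients of the percentage of the recommended daily
#' allowance covered by the individual's intake, each ratio truncated at
#' 100 so a surplus of one nutrient cannot compensate a deficit of another:
#' `MAR = 100/20 * sum_n min(intake_n / RDA_n, 1)`. RDAs are looked up by the
#' individual's sex and age band.
#'
#' @param intake A [nutrient_intakes()] result (or intake matrix).
#' @param rda RDA table: data frame with `sex`, `age_band` and one column per
#'   nutrient.
#' @param sex,age Per-individual sex (`"male"`/`"female"`) and age (years).
#' @param nutrients Nutrient set; default [mar_nutrients()].
#' @return Numeric vector of MAR values in `[0, 100]`.
#' @export
mar <- function(intake, rda, sex, age, nutrients = mar_nutrients()) {
  M <- if (inherits(intake, "nutrient_intake")) intake$intakes else as.matrix(intake)
  miss <- setdiff(nutrients, colnames(M))
  if (length(miss)) stop_dp("intake missing nutrient(s): ",
                            paste(miss, collapse = ", "))
  band <- as.character(age_to_band(age))
  key <- paste(sex, band)
  ri <- match(key, paste(rda$sex, rda$age_band))
  if (anyNA(ri)) stop_dp("no RDA row for: ", paste(unique(key[is.na(ri)]),
                                                   collapse = "; "))
  R <- as.matrix(rda[ri, nutrients, drop = FALSE])
  if (any(R <= 0)) stop_dp("RDA values must be > 0")
  ratios <- pmin(M[, nutrients, drop = FALSE] / R, 1)
  rowMeans(ratios) * 100
}

#' Energy density of the non-beverage diet
#'
#' Energy per gram of all foods consumed, excluding beverages (water, soft
#' drinks, alcohol, milk, coffee, tea, ...): `ED = sum_j E_j / sum_j g_j`
#' over non-beverage groups, in kcal/g (multiply by 4.184 for kJ/g). An
#' individual consuming no non-beverage food gets `NA`, not 0.
#'
#' @param X Consumption matrix (g/d).
#' @param composition Composition table with `energy_kcal` per 100 g.
#' @param beverage Logical flags per food group; default taken from the
#'   `beverage` column of `composition`.
#' @return Numeric vector, kcal/g (NA where undefined).
#' @export
energy_density <- function(X, composition, beverage = NULL) {
  X <- as.matrix(X)
  i <- match(colnames(X), composition$food_group)
  if (anyNA(i)) stop_dp("composition table missing food group(s): ",
                        paste(colnames(X)[is.na(i)], collapse = ", "))
  if (is.null(beverage)) beverage <- composition$beverage[i]
  if (length(beverage) != ncol(X) || anyNA(beverage)) {
    stop_dp("beverage flag must be defined for every food group")
  }
  keep <- !beverage
  energy <- X[, keep, drop = FALSE] %*%
    (composition$energy_kcal[i][keep] / 100)
  grams <- rowSums(X[, keep, drop = FALSE])
  ed <- as.numeric(energy) / grams
  ed[grams == 0] <- NA_real_
  names(ed) <- rownames(X)
  ed
}

#' Dietary diversity score (DDS)
#'
#' For each individual, 3 diary days are sampled at random — 2 weekdays and
#' 1 weekend day — and the score counts how many of the five macro food
#' groups (dairy, meat/fish, cereals, fruits, vegetables) were consumed in a
#' total of at least `min_grams` (default 30 g) over those 3 days. The score
#' ranges from 0 to 5.
#'
#' @param diary Long diary data frame: `individual_id`, `day_index`,
#'   `day_type` (`"weekday"`/`"weekend"`), `food_group`, `amount`.
#' @param dds_mapping Data frame `food_group` -> `dds_group` (one of
#'   `"dairy"`, `"meat"`, `"cereals"`, `"fruits"`, `"vegetables"`, or NA for
#'   groups outside the score).
#' @param seed Integer seed for the day sampling.
#' @param min_grams Consumption threshold over the 3 days. Default 30.
#' @param ids Individuals to score; default all in the diary.
#' @return Named integer vector of scores in `0..5`.
#' @export
dds <- function(diary, dds_mapping, seed = 1L, min_grams = 30, ids = NULL) {
  if (is.null(ids)) ids <- unique(diary$individual_id)
  macro <- dds_mapping$dds_group[match(diary$food_group,
                                       dds_mapping$food_group)]
  groups5 <- c("dairy", "meat", "cereals", "fruits", "vegetables")
  rows_by_id <- split(seq_len(nrow(diary)), diary$individual_id)
  with_seed(seed, {
    score <- stats::setNames(integer(length(ids)), ids)
    for (id in ids) {
      ri <- rows_by_id[[id]]
      if (is.null(ri)) {
        stop_dp("individual ", id, " has no diary days")
      }
      day <- diary$day_index[ri]
      dtype <- diary$day_type[ri]
      wk <- unique(day[dtype == "weekday"])
      we <- unique(day[dtype == "weekend"])
      if (length(wk) < 2 || length(we) < 1) {
        stop_dp("individual ", id, " lacks the 2 weekday + 1 weekend day ",
                "needed for the diversity score")
      }
      days <- c(sample(wk, 2), if (length(we) == 1) we else sample(we, 1))
      sel <- ri[day %in% days & !is.na(macro[ri])]
      if (!length(sel)) next
      tot <- tapply(diary$amount[sel], macro[sel], sum)
      score[id] <- sum(tot[names(tot) %in% groups5] >= min_grams)
    }
    score
  })
}

#' Survey-weighted covariate-adjusted comparison of pattern means
#'
#' Fits a weighted linear model of the outcome on the dietary-pattern factor
#' plus adjustment covariates, and contrasts each pattern's adjusted mean
#' with the overall adjusted mean (the survey-weighted average of the pattern
#' means, so the contrasts are a weighted one-vs-overall ANOVA). Standard
#' errors are design-robust (sandwich) — survey weights are importance
#' weights, not precision weights, so model-based variances would overstate
#' the effective sample size. Each pattern is flagged `"lower"`, `"ns"` or
#' `"higher"` at the two-sided `alpha` level. No multiplicity correction is
#' applied by default; set `p_adjust` to any [stats::p.adjust()] method to
#' add one.
#'
#' @param values Numeric outcome per individual (NAs dropped with their rows).
#' @param labels Pattern labels.
#' @param covariates Data frame of adjustment covariates (factors or
#'   numerics); may be `NULL` for an unadjusted comparison.
#' @param weights Positive survey weights (default all 1).
#' @param alpha Two-sided significance level. Default 0.05.
#' @param p_adjust Multiplicity correction method, default `"none"`.
#' @return Data frame: `pattern`, `adjusted_mean`, `diff` (vs overall),
#'   `se`, `p_value`, `flag`.
#' @export
compare_group_means <- function(values, labels, covariates = NULL,
                                weights = NULL, alpha = 0.05,
                                p_adjust = "none") {
  n <- length(values)
  w <- check_weights(weights, n)
  ok <- !is.na(values)
  values <- values[ok]; labels <- labels[ok]; w <- w[ok]
  if (!is.null(covariates)) covariates <- covariates[ok, , drop = FALSE]
  pat <- factor(labels)
  if (nlevels(pat) < 2) stop_dp("need at least 2 patterns")

  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    mm_cov <- NULL
    dat <- data.frame(y = values, pattern = pat)
    fit <- stats::lm(y ~ 0 + pattern, data = dat, weights = w)
  } else {
    covariates <- as.data.frame(covariates)
    mm_cov <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    dat <- data.frame(y = values, pattern = pat)
    fit <- stats::lm(y ~ 0 + pattern + mm_cov, data = dat, weights = w)
  }
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop_dp("singular fit; collinear column(s): ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  V <- sandwich::sandwich(fit)
  np <- nlevels(pat)
  pat_idx <- seq_len(np)            # pattern coefficients come first
  shares <- as.numeric(tapply(w, pat, sum) / sum(w))

  # Adjusted mean of pattern c = beta_c + xbar' gamma; the covariate part is
  # common to all patterns and cancels in the contrast against the weighted
  # overall mean: diff_c = beta_c - sum_c' pi_c' beta_c'.
  if (!is.null(mm_cov)) {
    xbar <- colSums(w * mm_cov) / sum(w)
    cov_part <- sum(xbar * cf[-pat_idx])
  } else {
    cov_part <- 0
  }
  adj_mean <- cf[pat_idx] + cov_part
  res <- lapply(seq_len(np), function(ci) {
    L <- numeric(length(cf))
    L[pat_idx] <- -shares
    L[ci] <- L[ci] + 1
    est <- sum(L * cf)
    se <- sqrt(drop(t(L) %*% V %*% L))
    p <- if (se == 0) {
      if (est == 0) 1 else 0      # degenerate: constant outcome
    } else {
      2 * stats::pt(-abs(est / se), df = fit$df.residual)
    }
    data.frame(pattern = levels(pat)[ci], adjusted_mean = unname(adj_mean[ci]),
               diff = est, se = se, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$flag <- ifelse(out$p_value >= alpha, "ns",
                     ifelse(out$diff > 0, "higher", "lower"))
  rownames(out) <- NULL
  out
}
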