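#' Aggregate diary records to an individual x food-group intake matrix
#'
#' Sums each individual's diary amounts within food groups and divides by the
#' number of recorded days, yielding mean daily intake in g/d. Food items are
#' mapped to groups through `mapping`; an unmapped item is an error naming the
#' item. Individuals present in `roster` but absent from the diary receive a
#' zero row.
#'
#' @param records Data frame of diary records with columns `individual_id`,
#'   `food_item` (or `food_group`), `amount`.
#' @param mapping Data frame with columns `food_item`, `group`. May be `NULL`
#'   when `records` already carries a `food_group` column.
#' @param n_days Number of diary days the amounts are averaged over.
#' @param roster Optional character vector of individual ids defining the row
#'   set (and order) of the result.
#' @return Numeric matrix, individuals x groups, mean daily intake (g/d).
#' @export
aggregate_to_groups <- function(records, mapping = NULL, n_days = 7,
                                roster = NULL) {
  if (n_days < 1) stop_dp("`n_days` must be >= 1")
  if (any(records$amount < 0)) stop_dp("diary amounts must be >= 0")
  if (!is.null(mapping)) {
    idx <- match(records$food_item, mapping$food_item)
    if (anyNA(idx)) {
      bad <- unique(records$food_item[is.na(idx)])
      stop_dp("unmapped food item(s): ", paste(bad, collapse = ", "))
    }
    grp <- mapping$group[idx]
    groups <- unique(mapping$group)
  } else {
    if (is.null(records$food_group)) {
      stop_dp("records need `food_group` when no mapping is given")
    }
    grp <- records$food_group
    groups <- unique(grp)
  }
  ids <- if (is.null(roster)) unique(records$individual_id) else roster
  X <- matrix(0, nrow = length(ids), ncol = length(groups),
              dimnames = list(ids, groups))
  keep <- records$individual_id %in% ids
  tot <- rowsum(records$amount[keep],
                paste(records$individual_id[keep], grp[keep], sep = "\r"))
  key <- strsplit(rownames(tot), "\r", fixed = TRUE)
  ii <- match(vapply(key, `[`, "", 1), ids)
  jj <- match(vapply(key, `[`, "", 2), groups)
  X[cbind(ii, jj)] <- tot[, 1] / n_days
  X
}

#' Per-group consumption rate
#'
#' Fraction of individuals with strictly positive intake of each group.
#'
#' @param X Consumption matrix.
#' @return Named numeric vector in `[0, 1]`.
#' @export
consumption_rate <- function(X) colMeans(X > 0)

#' Drop rarely consumed food groups
#'
#' A group is retained iff its consumption rate (fraction of individuals with
#' intake > 0) is at least `threshold`; groups strictly below the threshold
#' are excluded, as rare groups inject noise that surfaces as spurious,
#' overly specific consumption systems. Column order is preserved.
#'
#' @param X Consumption matrix.
#' @param threshold Minimum consumption rate, in `(0, 1)`. Default 0.10.
#' @return List with `matrix` (filtered) and `excluded` (data frame of
#'   dropped groups and their rates).
#' @export
filter_rare_groups <- function(X, threshold = 0.10) {
  if (threshold <= 0 || threshold >= 1) stop_dp("`threshold` must be in (0,1)")
  rate <- consumption_rate(X)
  keep <- rate >= threshold
  if (!any(keep)) stop_dp("all food groups fall below the consumption-rate threshold")
  list(matrix = X[, keep, drop = FALSE],
       excluded = data.frame(group = colnames(X)[!keep],
                             consumption_rate = unname(rate[!keep]),
                             stringsAsFactors = FALSE))
}

#' Schofield basal metabolic rate
#'
#' Weight-based Schofield equations for adults, by sex and age class
#' (18-30, 30-60, 60+ years), returned in kcal/d.
#'
#' @param sex Character vector, `"male"`/`"female"`.
#' @param age Age in years.
#' @param weight_kg Body weight in kg.
#' @return BMR in kcal/d.
#' @export
schofield_bmr <- function(sex, age, weight_kg) {
  coef <- function(sex, age) {
    if (sex == "male") {
      if (age < 30) c(0.063, 2.896) else if (age < 60) c(0.048, 3.653)
      else c(0.049, 2.459)
    } else {
      if (age < 30) c(0.062, 2.036) else if (age < 60) c(0.034, 3.538)
      else c(0.038, 2.755)
    }
  }
  mj <- mapply(function(s, a, w) {
    cf <- coef(s, a)
    cf[1] * w + cf[2]
  }, sex, age, weight_kg)
  unname(mj * 239.006)  # MJ/d -> kcal/d
}

#' Exclude individuals with extremely low total energy intake
#'
#' The default rule excludes individuals whose reported total energy intake
#' falls below a fraction (0.45) of their Schofield basal metabolic rate; the
#' rule is configurable because low-energy cut-offs differ between surveys.
#'
#' @param tei Named numeric vector of total energy intake (kcal/d), names =
#'   individual ids.
#' @param covariates Data frame with `individual_id`, `sex`, `age`,
#'   `body_weight_kg` (needed by the BMR-based rule).
#' @param rule List: either `list(type = "bmr_fraction", fraction = 0.45)` or
#'   `list(type = "absolute", kcal = <threshold>)`.
#' @return List with `kept` and `excluded` id vectors and a `report` list
#'   (`n_excluded`, `fraction_excluded`, `rule`).
#' @export
exclude_low_energy <- function(tei, covariates,
                               rule = list(type = "bmr_fraction",
                                           fraction = 0.45)) {
  if (anyNA(tei)) stop_dp("missing TEI value(s)")
  if (any(tei < 0)) stop_dp("TEI must be >= 0")
  ids <- names(tei)
  if (is.null(ids)) stop_dp("`tei` must be named by individual id")
  if (rule$type == "bmr_fraction") {
    i <- match(ids, covariates$individual_id)
    if (anyNA(i)) stop_dp("covariates missing for some individuals")
    bmr <- schofield_bmr(covariates$sex[i], covariates$age[i],
                         covariates$body_weight_kg[i])
    thr <- rule$fraction * bmr
  } else if (rule$type == "absolute") {
    thr <- rep(rule$kcal, length(tei))
  } else {
    stop_dp("unknown exclusion rule type: ", rule$type)
  }
  excl <- tei < thr
  list(kept = ids[!excl], excluded = ids[excl],
       report = list(n_excluded = sum(excl),
                     fraction_excluded = mean(excl),
                     rule = rule))
}

#' Flag likely energy under-reporters (Goldberg-type cut-off)
#'
#' Marks individuals whose ratio of reported energy intake to Schofield basal
#' metabolic rate falls below `cutoff`. Under-reporters are flagged but never
#' removed: they are retained in all downstream analyses.
#'
#' @inheritParams exclude_low_energy
#' @param cutoff Lower Goldberg cut-off on TEI/BMR. Default 1.05.
#' @return Named logical vector (`TRUE` = flagged under-reporter).
#' @export
flag_under_reporters <- function(tei, covariates, cutoff = 1.05) {
  ids <- names(tei)
  i <- match(ids, covariates$individual_id)
  if (anyNA(i)) stop_dp("covariates missing for some individuals")
  bmr <- schofield_bmr(covariates$sex[i], covariates$age[i],
                       covariates$body_weight_kg[i])
  flags <- tei / bmr < cutoff
  names(flags) <- ids
  flags
}
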