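#' Correspondence-analysis wealth index with tertiles
#'
#' Summarises a set of categorical household-wealth variables into a single
#' score: the indicator (complete disjunctive) table is built, the
#' correspondence-analysis standardised-residual matrix
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` is decomposed by SVD, and each
#' individual's coordinate on the first principal axis is the wealth index
#' (multiple correspondence analysis via the indicator matrix). Survey
#' weights, when given, enter as row masses. The score is split into
#' tertiles at the weighted terciles (lower-closed intervals; ties fall in
#' the lower tertile).
#'
#' The axis sign is arbitrary in CA; the score is oriented so that the
#' indicator column named by `positive_level` has a positive column
#' coordinate. By default the orientation makes the last level of the first
#' variable load positively, so variables should be coded with affluence
#' increasing across levels (or pass e.g.
#' `positive_level = "n_cars.two_plus"`).
#'
#' @param items Data frame of categorical variables (factors, characters or
#'   logicals), one row per individual. Variables with a single observed
#'   level are dropped with a warning.
#' @param weights Optional positive survey weights (row masses).
#' @param positive_level Indicator column (format `"variable.level"`) forced
#'   to load positively; `NULL` for the default rule above.
#' @return Object of class `wealth_index`: list with `score`, `tertile`
#'   (integer 1-3), `column_coord` (first-axis column coordinates),
#'   `inertia_share` (first-axis share of total inertia).
#' @export
wealth_index <- function(items, weights = NULL, positive_level = NULL) {
  items <- as.data.frame(items)
  if (ncol(items) < 2) stop_dp("need at least 2 wealth variables")
  n <- nrow(items)
  w <- check_weights(weights, n)
  for (nm in names(items)) {
    items[[nm]] <- factor(items[[nm]])
    if (nlevels(droplevels(items[[nm]])) < 2) {
      warning("dropping wealth variable with a single observed level: ", nm)
      items[[nm]] <- NULL
    }
  }
  if (ncol(items) < 2) stop_dp("fewer than 2 usable wealth variables remain")

  Z <- do.call(cbind, lapply(names(items), function(nm) {
    M <- stats::model.matrix(~ 0 + items[[nm]])
    colnames(M) <- paste(nm, levels(items[[nm]]), sep = ".")
    M
  }))

  # CA of the weighted indicator table.
  Tm <- w * Z
  P <- Tm / sum(Tm)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  # Row principal coordinates on axis 1.
  score <- sv$u[, 1] * sv$d[1] / sqrt(r)
  colco <- sv$v[, 1] * sv$d[1] / sqrt(cc)
  names(colco) <- colnames(Z)

  if (is.null(positive_level)) {
    v1 <- names(items)[1]
    positive_level <- paste(v1, utils::tail(levels(items[[v1]]), 1), sep = ".")
  }
  if (!positive_level %in% names(colco)) {
    stop_dp("unknown positive_level: ", positive_level)
  }
  if (colco[positive_level] < 0) {
    score <- -score
    colco <- -colco
  }

  cuts <- wquantile(score, w, c(1 / 3, 2 / 3))
  tertile <- 1L + (score >= cuts[1]) + (score >= cuts[2])
  structure(list(score = score, tertile = tertile, column_coord = colco,
                 inertia_share = sv$d[1]^2 / sum(sv$d^2)),
            class = "wealth_index")
}

#' Sex-stratified logistic determinants of dietary-pattern membership
#'
#' For each sex stratum and each dietary pattern, fits a survey-weighted
#' binomial logistic regression of membership in that pattern (vs all
#' others) on the socio-demographic covariates, and reports odds ratios with
#' Wald confidence intervals per covariate level against its reference
#' level (reference rows carry OR = 1). Weights are rescaled to mean 1
#' within each stratum and standard errors are design-robust (sandwich), the
#' variance a survey estimator uses for importance weights. Coefficients
#' beyond `abs(log OR) > 15` are flagged as likely separation.
#'
#' @param labels Pattern labels per individual.
#' @param covariates Data frame of covariates (factors/characters become
#'   dummy-coded against their first level; numerics enter linearly).
#' @param weights Positive survey weights.
#' @param stratum Factor splitting the analysis (typically sex); `NULL` for
#'   a single stratum.
#' @param conf_level Confidence level. Default 0.95.
#' @return Data frame: `stratum`, `pattern`, `variable`, `level`, `OR`,
#'   `CI_low`, `CI_high`, `reference`, `separation`.
#' @export
pattern_logit <- function(labels, covariates, weights = NULL, stratum = NULL,
                          conf_level = 0.95) {
  n <- length(labels)
  w <- check_weights(weights, n)
  covariates <- as.data.frame(covariates)
  if (is.null(stratum)) stratum <- rep("all", n)
  stratum <- as.character(stratum)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list()
  for (st in unique(stratum)) {
    in_st <- stratum == st
    covs <- droplevels(as.data.frame(lapply(covariates[in_st, , drop = FALSE],
                                            function(x) {
                                              if (is.character(x) || is.logical(x)) factor(x) else x
                                            })))
    ws <- w[in_st] / mean(w[in_st])
    for (pat in sort(unique(labels))) {
      y <- as.integer(labels[in_st] == pat)
      dat <- cbind(.y = y, covs)
      fit <- suppressWarnings(
        stats::glm(.y ~ ., data = dat, family = stats::quasibinomial(),
                   weights = ws)
      )
      cf <- summary(fit)$coefficients
      rob_se <- sqrt(diag(sandwich::sandwich(fit)))
      cf[, 2] <- rob_se[rownames(cf)]
      for (nm in names(covs)) {
        x <- covs[[nm]]
        if (is.factor(x)) {
          levs <- levels(x)
          for (li in seq_along(levs)) {
            if (li == 1) {
              out[[length(out) + 1]] <- data.frame(
                stratum = st, pattern = pat, variable = nm, level = levs[1],
                OR = 1, CI_low = NA_real_, CI_high = NA_real_,
                reference = TRUE, separation = FALSE,
                stringsAsFactors = FALSE)
            } else {
              cn <- paste0(nm, levs[li])
              if (!cn %in% rownames(cf)) next   # aliased level
              b <- cf[cn, 1]; se <- cf[cn, 2]
              sep <- abs(b) > 15 || se > 15
              if (sep) warning("possible separation: ", cn, " (stratum ", st,
                               ", pattern ", pat, ")")
              out[[length(out) + 1]] <- data.frame(
                stratum = st, pattern = pat, variable = nm, level = levs[li],
                OR = exp(b), CI_low = exp(b - z * se),
                CI_high = exp(b + z * se), reference = FALSE,
                separation = sep, stringsAsFactors = FALSE)
            }
          }
        } else {
          if (!nm %in% rownames(cf)) next
          b <- cf[nm, 1]; se <- cf[nm, 2]
          sep <- abs(b) > 15 || se > 15
          out[[length(out) + 1]] <- data.frame(
            stratum = st, pattern = pat, variable = nm, level = "per_unit",
            OR = exp(b), CI_low = exp(b - z * se), CI_high = exp(b + z * se),
            reference = FALSE, separation = sep, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}
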