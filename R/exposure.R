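#' Dietary exposure to contaminants, per kg body weight
#'
#' Combines individual consumption with substance concentrations per food
#' group: `E_is = sum_j consumption_ij * conc_sj / bw_i`, in ug/kg body
#' weight per day. Left-censored laboratory values are handled upstream by
#' substitution and carried as three concentration columns; `mode` selects
#' the lower (`"LB"`), middle (`"MB"`, default) or upper (`"UB"`) bound.
#' When a `tef` column is present, concentrations are multiplied by the
#' toxicity-equivalency factor before summation, so congener rows sharing a
#' substance label aggregate to toxicity-equivalent exposure.
#'
#' @param X Consumption matrix (individuals x groups, g/d).
#' @param contamination Long data frame: `substance`, `food_group`, `unit`
#'   (`"ug/g"` or `"ug/kg"`), `conc_LB`, `conc_MB`, `conc_UB`, optional
#'   `tef`.
#' @param body_weight_kg Positive body weight per individual.
#' @param mode Censoring bound to use: `"MB"` (default), `"LB"` or `"UB"`.
#' @param assume_zero If `TRUE`, food groups consumed but absent from the
#'   contamination table contribute zero (with a message); otherwise this is
#'   an error.
#' @return Object of class `exposure_table`: list with `exposure`
#'   (individuals x substances matrix, ug/kg bw/d) and `mode`.
#' @export
exposure_levels <- function(X, contamination, body_weight_kg,
                            mode = c("MB", "LB", "UB"), assume_zero = FALSE) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(body_weight_kg) == 1) body_weight_kg <- rep(body_weight_kg, n)
  if (length(body_weight_kg) != n || any(body_weight_kg <= 0)) {
    stop_dp("`body_weight_kg` must be positive, one value per individual")
  }
  col <- paste0("conc_", mode)
  conc <- contamination[[col]]
  if (is.null(conc)) stop_dp("contamination table lacks column ", col)
  unit <- if (is.null(contamination$unit)) "ug/g" else contamination$unit
  scale <- ifelse(unit == "ug/kg", 1e-3, 1)
  tef <- if (is.null(contamination$tef)) 1 else contamination$tef
  conc <- conc * scale * tef

  subs <- unique(contamination$substance)
  C <- matrix(NA_real_, length(subs), ncol(X),
              dimnames = list(subs, colnames(X)))
  si <- match(contamination$substance, subs)
  gj <- match(contamination$food_group, colnames(X))
  inX <- !is.na(gj)
  # duplicated (substance, group) rows (e.g. congeners) sum after TEF scaling
  agg <- rowsum(conc[inX], paste(si[inX], gj[inX]))
  key <- do.call(rbind, strsplit(rownames(agg), " "))
  C[cbind(as.integer(key[, 1]), as.integer(key[, 2]))] <- agg[, 1]

  consumed <- colSums(X > 0) > 0
  missing_cell <- is.na(C) & rep(consumed, each = nrow(C))
  if (any(missing_cell)) {
    grps <- unique(colnames(X)[colSums(missing_cell) > 0])
    if (!assume_zero) {
      stop_dp("no concentration for consumed food group(s): ",
              paste(grps, collapse = ", "),
              " (set assume_zero = TRUE to treat them as uncontaminated)")
    }
    message("assuming zero concentration for ", length(grps),
            " food group(s) absent from the contamination table")
  }
  C[is.na(C)] <- 0
  E <- (X %*% t(C)) / body_weight_kg
  structure(list(exposure = E, mode = mode), class = "exposure_table")
}

#' Covariate-adjusted comparison of pattern mean exposures
#'
#' Runs [compare_group_means()] for every substance of an exposure table.
#'
#' @param exposures An [exposure_levels()] result (or matrix).
#' @param labels Pattern labels.
#' @param covariates Adjustment covariates (see [compare_group_means()]).
#' @param weights Positive survey weights.
#' @param ... Passed to [compare_group_means()].
#' @return Data frame stacking the per-substance comparisons, with a
#'   `substance` column.
#' @export
compare_exposures <- function(exposures, labels, covariates = NULL,
                              weights = NULL, ...) {
  E <- if (inherits(exposures, "exposure_table")) exposures$exposure
       else as.matrix(exposures)
  out <- lapply(colnames(E), function(s) {
    cbind(substance = s,
          compare_group_means(E[, s], labels, covariates, weights, ...),
          stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
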