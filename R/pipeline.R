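#' Configuration for an end-to-end pipeline run
#'
#' Either `simulate` (a [sim_config()]) or `input_dir` (a directory holding
#' the CSV bundle written by [write_survey_bundle()]) must be given.
#'
#' @param simulate A [sim_config()] to generate the inputs, or `NULL`.
#' @param input_dir Directory with `consumption.csv`, `individuals.csv`,
#'   `composition.csv`, `rda.csv`, `contamination.csv` (and optionally
#'   `diary.csv`), or `NULL`.
#' @param k Number of consumption systems; `NULL` to choose by the rank scan
#'   over `k_range`.
#' @param k_range Candidate ranks for [select_rank()] when `k` is `NULL`.
#' @param n_restarts Random restarts for the NMF.
#' @param c Number of dietary patterns; `NULL` to choose by
#'   [select_n_clusters()] over `c_range`.
#' @param c_range Candidate cluster counts.
#' @param rare_threshold Consumption-rate threshold of [filter_rare_groups()].
#' @param contributor_cutoff Main-contributor cutoff of
#'   [loading_contributions()].
#' @param dds_min_grams Gram threshold of [dds()].
#' @param v_threshold Significance threshold of [v_test()].
#' @param censoring_mode `"LB"`, `"MB"` or `"UB"` for [exposure_levels()].
#' @param tol,max_iter NMF convergence controls.
#' @param seed Root seed; every stochastic stage derives its own seed from it.
#' @param out_dir Output directory for artefacts and the report; `NULL`
#'   keeps everything in memory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, input_dir = NULL,
                            k = 7, k_range = 2:10, n_restarts = 5,
                            c = NULL, c_range = 2:12,
                            rare_threshold = 0.10, contributor_cutoff = 0.025,
                            dds_min_grams = 30, v_threshold = 1.96,
                            censoring_mode = "MB",
                            tol = 1e-6, max_iter = 2000L,
                            seed = 1L, out_dir = NULL) {
  if (is.null(simulate) && is.null(input_dir)) {
    stop_dp("give either `simulate` or `input_dir`")
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop_dp("input_dir does not exist: ", input_dir)
  }
  stopifnot(rare_threshold > 0, rare_threshold < 1,
            contributor_cutoff >= 0, contributor_cutoff < 1,
            dds_min_grams >= 0, v_threshold >= 0,
            censoring_mode %in% c("LB", "MB", "UB"))
  structure(list(simulate = simulate, input_dir = input_dir, k = k,
                 k_range = k_range, n_restarts = n_restarts, c = c,
                 c_range = c_range, rare_threshold = rare_threshold,
                 contributor_cutoff = contributor_cutoff,
                 dds_min_grams = dds_min_grams, v_threshold = v_threshold,
                 censoring_mode = censoring_mode, tol = tol,
                 max_iter = max_iter, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

read_survey_bundle <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE,
                                    stringsAsFactors = FALSE)
  Xdf <- rd("consumption.csv")
  X <- as.matrix(Xdf[, -1, drop = FALSE])
  rownames(X) <- Xdf[[1]]
  diary <- if (file.exists(file.path(dir, "diary.csv"))) rd("diary.csv") else NULL
  list(consumption = X,
       individuals = rd("individuals.csv"),
       tables = structure(list(composition = rd("composition.csv"),
                               rda = rd("rda.csv"),
                               contamination = rd("contamination.csv")),
                          class = "composition_tables"),
       diary = diary, truth = NULL)
}

#' Run the full dietary-pattern pipeline
#'
#' Sequences the analysis stages: data acquisition (simulation or CSV
#' bundle), rare-group filtering, weighted LS-NMF (with optional rank scan),
#' factor normalisation and food contributions, mass-weighted Ward
#' clustering with inertia-ratio cluster-count selection, pattern V-tests,
#' relative CS contributions and survey-weighted shares, nutrient intakes
#' and diet-quality scores (MAR, ED, DDS) with covariate-adjusted pattern
#' comparisons, contaminant exposure with comparisons, the
#' correspondence-analysis wealth index, and sex-stratified logistic
#' determinants. When `out_dir` is set, every intermediate artefact plus a
#' JSON summary and a Markdown report are written there.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list with all stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_dp("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  res <- list(config = config)

  data <- stage("acquire", {
    if (!is.null(config$simulate)) generate_survey(config$simulate)
    else read_survey_bundle(config$input_dir)
  })
  indiv <- data$individuals
  weights <- indiv$weight
  res$truth <- data$truth

  pre <- stage("preprocess", filter_rare_groups(data$consumption,
                                                config$rare_threshold))
  X <- pre$matrix
  res$excluded_groups <- pre$excluded

  k <- config$k
  if (is.null(k)) {
    res$rank_diagnostics <- stage("rank_selection",
      select_rank(X, weights, k_range = config$k_range,
                  n_restarts = config$n_restarts, seed = config$seed + 11L,
                  tol = config$tol, max_iter = config$max_iter))
    k <- res$rank_diagnostics$suggested_k
  }
  res$k <- k

  fit <- stage("nmf", {
    f <- ls_nmf(X, weights, k = k, seed = config$seed + 23L,
                tol = config$tol, max_iter = config$max_iter,
                n_restarts = config$n_restarts)
    normalize_factors(f)
  })
  res$nmf <- fit
  res$contributions <- stage("contributions",
    loading_contributions(fit, cutoff = config$contributor_cutoff))

  tree <- stage("clustering", hca_ward(fit$W, weights))
  res$tree <- tree
  if (is.null(config$c)) {
    sel <- stage("cluster_count", select_n_clusters(tree, config$c_range))
    res$inertia_curve <- sel$curve
    cc <- sel$chosen_c
  } else {
    cc <- config$c
  }
  res$c <- cc
  labels <- stage("labels", assign_patterns(tree, cc))
  res$labels <- labels
  res$shares <- stage("shares", weighted_share(labels, weights))
  res$v_tests <- stage("v_tests", v_test(fit$W, labels, weights,
                                         threshold = config$v_threshold))
  res$rel_contrib <- stage("relative_contribution",
                           relative_contribution(fit$W, labels))

  comp <- data$tables$composition
  ni <- stage("nutrients", nutrient_intakes(data$consumption, comp))
  res$nutrients <- ni
  res$mar <- stage("mar", mar(ni, data$tables$rda, indiv$sex, indiv$age))
  res$ed <- stage("energy_density", energy_density(data$consumption, comp))
  if (!is.null(data$diary) && !is.null(comp$dds_group)) {
    res$dds <- stage("dds", {
      map <- comp[, c("food_group", "dds_group")]
      ids <- intersect(rownames(data$consumption),
                       unique(data$diary$individual_id))
      sc <- dds(data$diary, map, seed = config$seed + 31L,
                min_grams = config$dds_min_grams, ids = ids)
      full <- stats::setNames(rep(NA_integer_, nrow(data$consumption)),
                              rownames(data$consumption))
      full[names(sc)] <- sc
      full
    })
  }

  adj_cov <- stage("covariate_frame", {
    cv <- indiv[, intersect(c("age", "sex", "season", "education",
                              "occupation", "household_size",
                              "household_comp", "municipality", "region",
                              "food_insecurity"), names(indiv)),
                drop = FALSE]
    cv$tei <- ni$tei
    cv
  })
  res$score_comparisons <- stage("score_comparisons", {
    scores <- list(MAR = res$mar, ED = res$ed)
    if (!is.null(res$dds)) scores$DDS <- as.numeric(res$dds)
    do.call(rbind, lapply(names(scores), function(nm) {
      cbind(score = nm,
            compare_group_means(scores[[nm]], labels, adj_cov, weights),
            stringsAsFactors = FALSE)
    }))
  })

  if (!is.null(data$tables$contamination) && "body_weight_kg" %in% names(indiv)) {
    res$exposure <- stage("exposure",
      exposure_levels(data$consumption, data$tables$contamination,
                      indiv$body_weight_kg, mode = config$censoring_mode))
    res$exposure_comparisons <- stage("exposure_comparisons",
      compare_exposures(res$exposure, labels, adj_cov, weights))
  }

  wealth_vars <- intersect(c("holiday_4d", "n_cars", "many_appliances",
                             "fin_situation_good", "access_desired_food",
                             "housing_owner"), names(indiv))
  if (length(wealth_vars) >= 2) {
    res$wealth <- stage("wealth_index",
      wealth_index(indiv[, wealth_vars], weights))
    res$determinants <- stage("determinants", {
      covs <- indiv[, intersect(c("age_band", "education", "occupation",
                                  "household_size", "household_comp",
                                  "region", "municipality",
                                  "food_insecurity"), names(indiv)),
                    drop = FALSE]
      covs$wealth_tertile <- factor(res$wealth$tertile)
      pattern_logit(labels, covs, weights, stratum = indiv$sex)
    })
  }

  class(res) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config$out_dir)
  res
}

#' Write pipeline artefacts, JSON summary and Markdown report
#'
#' @param res A `pipeline_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                          row.names = FALSE)
  fit <- res$nmf
  wcsv(data.frame(individual_id = rownames(fit$W), fit$W,
                  check.names = FALSE), "scores_W.csv")
  wcsv(data.frame(cs = rownames(fit$H), fit$H, check.names = FALSE),
       "loadings_H.csv")
  wcsv(data.frame(iteration = seq_along(fit$objective_trace),
                  objective = fit$objective_trace), "objective_trace.csv")
  wcsv(data.frame(individual_id = names(res$labels), pattern = res$labels),
       "labels.csv")
  wcsv(data.frame(pattern = rownames(res$v_tests$v), res$v_tests$v,
                  check.names = FALSE), "v_tests.csv")
  wcsv(data.frame(pattern = rownames(res$rel_contrib), res$rel_contrib,
                  check.names = FALSE), "relative_contributions.csv")
  wcsv(res$score_comparisons, "score_comparisons.csv")
  if (!is.null(res$exposure_comparisons)) {
    wcsv(res$exposure_comparisons, "exposure_comparisons.csv")
  }
  if (!is.null(res$determinants)) wcsv(res$determinants, "determinants.csv")
  if (!is.null(res$inertia_curve)) {
    jsonlite::write_json(res$inertia_curve,
                         file.path(dir, "inertia_curve.json"), digits = NA)
  }
  if (!is.null(res$rank_diagnostics)) {
    jsonlite::write_json(res$rank_diagnostics$curve,
                         file.path(dir, "rank_diagnostics.json"), digits = NA)
  }
  # 4-column merge table: child1, child2, height, size (negative = singleton)
  tree <- res$tree
  sizes <- integer(nrow(tree$merge))
  for (i in seq_len(nrow(tree$merge))) {
    ch <- tree$merge[i, ]
    sizes[i] <- sum(ifelse(ch < 0, 1L, sizes[pmax(ch, 1)]))
  }
  merge_tab <- data.frame(child1 = tree$merge[, 1], child2 = tree$merge[, 2],
                          height = tree$height, size = sizes)
  utils::write.table(merge_tab, file.path(dir, "linkage.txt"),
                     row.names = FALSE, quote = FALSE)

  summary <- list(
    n_individuals = nrow(fit$W),
    n_food_groups = ncol(fit$H),
    k = res$k,
    n_patterns = res$c,
    shares_pct = as.list(round(res$shares, 4)),
    descriptors = res$v_tests$descriptors,
    excluded_groups = res$excluded_groups$group
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(render_report(res), file.path(dir, "report.md"))
  invisible(dir)
}

# Human-readable Markdown report of a pipeline result.
render_report <- function(res) {
  lines <- c("# Dietary pattern report", "",
             sprintf("%d individuals x %d food groups; %d consumption systems; %d dietary patterns.",
                     nrow(res$nmf$W), ncol(res$nmf$H), res$k, res$c), "")
  for (p_ in rownames(res$v_tests$v)) {
    lines <- c(lines, sprintf("## Pattern %s (%.1f%% of the population)",
                              p_, res$shares[p_]))
    desc <- res$v_tests$descriptors[[p_]]
    lines <- c(lines, sprintf("- Descriptor CS (positive significant V-test): %s",
                              if (length(desc)) paste(desc, collapse = ", ")
                              else "none"))
    rc <- res$rel_contrib[p_, ]
    top <- order(rc, decreasing = TRUE)[1:min(3, length(rc))]
    lines <- c(lines, sprintf("- Largest CS contributions: %s",
                              paste(sprintf("%s (%.1f%%)", names(rc)[top],
                                            100 * rc[top]), collapse = ", ")))
    if (!is.null(res$score_comparisons)) {
      sc <- res$score_comparisons
      sig <- sc[sc$pattern == p_ & sc$flag != "ns", ]
      if (nrow(sig)) {
        lines <- c(lines, sprintf("- Diet-quality scores vs overall: %s",
                                  paste(sprintf("%s %s", sig$score, sig$flag),
                                        collapse = ", ")))
      }
    }
    if (!is.null(res$exposure_comparisons)) {
      ec <- res$exposure_comparisons
      sig <- ec[ec$pattern == p_ & ec$flag != "ns", ]
      if (nrow(sig)) {
        lines <- c(lines, sprintf("- Exposures vs overall: %s",
                                  paste(sprintf("%s %s", sig$substance,
                                                sig$flag), collapse = ", ")))
      }
    }
    lines <- c(lines, "")
  }
  if (!is.null(res$contributions)) {
    lines <- c(lines, "## Main food-group contributors per consumption system", "")
    for (nm in names(res$contributions)) {
      d <- res$contributions[[nm]]
      main <- d[d$main_contributor, ]
      lines <- c(lines, sprintf("- %s: %s", nm,
                                paste(sprintf("%s (%.1f%%)", main$food_group,
                                              main$contribution_pct),
                                      collapse = ", ")))
    }
  }
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Dietary-pattern pipeline result\n")
  cat("  ", nrow(x$nmf$W), " individuals, ", ncol(x$nmf$H),
      " food groups, k = ", x$k, ", patterns = ", x$c, "\n", sep = "")
  cat("  survey-weighted shares (%):\n")
  print(round(x$shares, 1))
  invisible(x)
}
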