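`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a prognostic system end-to-end
#'
#' Runs the full pipeline on a case listing: form combinations of the active
#' factors, drop combinations below the minimum size, build the initial
#' Mann-Whitney dissimilarity matrix, learn consensus dissimilarities by the
#' PAM ensemble, cluster by minimax linkage, trace the C-index curve over
#' candidate cuts, pick the group count at the knee (unless overridden) and
#' assemble the ordered prognostic system. With `out_dir` set, all
#' artifacts (cohort table, matrices, merge table, Newick tree, C-index
#' curve, system JSON and a reproducibility manifest) are written to disk;
#' outputs are byte-identical for identical inputs and seed.
#'
#' @param cases Case data frame (see [read_cases()]).
#' @param active_factors Factors to combine over (default T, N, M).
#' @param min_cases Minimum combination size (default 50).
#' @param B Ensemble runs (default 1000).
#' @param k_range Ensemble k interval; default `c(2, ceiling(n/2))`.
#' @param n_groups Optional manual override of the knee rule.
#' @param knee_rel_gain Relative-gain threshold of the knee rule.
#' @param ks Candidate group counts for the C-index curve (default
#'   `1:min(n, 25)`).
#' @param five_year_month Month for group ordering and rates (default 60).
#' @param seed Master seed for the ensemble.
#' @param out_dir Optional output directory.
#' @return An `eaccd_fit`: list with `cohorts`, `initial_d`, `delta`,
#'   `dendrogram`, `curve`, `system` and `config`.
#' @export
run_fit <- function(cases, active_factors = c("T", "N", "M"),
                    min_cases = 50L, B = 1000L, k_range = NULL,
                    n_groups = NULL, knee_rel_gain = 0.05, ks = NULL,
                    five_year_month = 60, seed = 1L, out_dir = NULL) {
  cohorts <- group_into_combinations(cases, active_factors)
  cohorts <- filter_min_cases(cohorts, min_cases)
  if (nrow(cohorts) < 2) {
    stop("fewer than 2 combinations survive the minimum-size filter; ",
         "consider lowering min_cases", call. = FALSE)
  }
  d <- build_initial_matrix(cohorts, cases)
  delta <- ensemble_learn(d, B = B, k_range = k_range, seed = seed)
  dend <- minimax_linkage(delta)
  ks <- ks %||% seq_len(min(nrow(cohorts), 25L))
  curve <- c_index_curve(dend, cohorts, cases, ks = ks,
                         five_year_month = five_year_month)
  n_star <- n_groups %||% knee_point(curve, knee_rel_gain)
  system <- build_system(dend, cohorts, cases, n_star,
                         five_year_month = five_year_month)
  fit <- structure(list(cohorts = cohorts, initial_d = d, delta = delta,
                        dendrogram = dend, curve = curve, system = system,
                        config = list(active_factors = attr(cohorts, "active_factors"),
                                      min_cases = min_cases, B = B,
                                      k_range = attr(delta, "k_range"),
                                      n_groups_override = n_groups,
                                      knee_rel_gain = knee_rel_gain,
                                      ks = ks,
                                      five_year_month = five_year_month,
                                      seed = seed)),
                   class = "eaccd_fit")
  if (!is.null(out_dir)) write_fit_artifacts(fit, out_dir)
  fit
}

#' @export
print.eaccd_fit <- function(x, ...) {
  cat("EACCD fit:", nrow(x$cohorts), "combinations,",
      x$system$n_groups, "prognostic groups, C-index",
      format(x$system$c_index, digits = 4), "\n")
  invisible(x)
}

#' Write the artifacts of a fit to disk
#'
#' @param fit An `eaccd_fit`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fit_artifacts <- function(fit, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  cohort_tab <- fit$cohorts[setdiff(names(fit$cohorts), "member_ids")]
  utils::write.csv(cohort_tab, p("cohorts.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(fit$initial_d, p("initial_d.csv"), quote = FALSE)
  utils::write.csv(fit$delta, p("learned_delta.csv"), quote = FALSE)
  utils::write.csv(dendrogram_merge_table(fit$dendrogram),
                   p("dendrogram_merges.csv"), row.names = FALSE, quote = FALSE)
  if (requireNamespace("ape", quietly = TRUE)) {
    writeLines(as_newick(fit$dendrogram), p("dendrogram.nwk"))
  }
  utils::write.csv(fit$curve, p("c_index_curve.csv"), row.names = FALSE, quote = FALSE)
  sys <- fit$system
  jsonlite::write_json(
    list(n_groups = sys$n_groups,
         assignment = as.list(sys$assignment),
         five_year_rates = as.list(sys$five_year_rates),
         prototypes = as.list(sys$prototypes),
         c_index = sys$c_index),
    p("system.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    c(fit$config,
      list(package_version = as.character(utils::packageVersion("eaccd")),
           r_version = paste(R.version$major, R.version$minor, sep = "."))),
    p("manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Compare a fitted system against AJCC 8th-edition staging
#'
#' Assigns every case its AJCC 8th-edition stage from T, N, M, tabulates
#' stages against the fitted prognostic groups, computes the midrank
#' Spearman correlation of the two assignments, and tests the difference in
#' Harrell C between group-number and stage-number risk scores with the
#' correlated C-index difference test.
#'
#' @param fit An `eaccd_fit` (or a `prognostic_system`).
#' @param cases Case data frame carrying T, N, M columns.
#' @param out_dir Optional directory for the contingency CSV and report
#'   JSON.
#' @return An `eaccd_comparison`: list with `contingency`, `rho`,
#'   `diff_test` (`c_a` = system, `c_b` = AJCC) and `n`.
#' @export
run_compare <- function(fit, cases, out_dir = NULL) {
  system <- if (inherits(fit, "eaccd_fit")) fit$system else fit
  stopifnot(inherits(system, "prognostic_system"))
  labels <- .case_labels(cases, system$active_factors)
  group <- system$assignment[labels]
  keep <- !is.na(group)
  if (!all(keep)) {
    message("run_compare: ", sum(!keep),
            " case(s) in combinations outside the system were ignored")
  }
  cases <- cases[keep, , drop = FALSE]
  group <- as.integer(group[keep])
  stage <- assign_ajcc8_stage(cases$T, cases$N, cases$M)
  tab <- contingency(stage, factor(group, levels = seq_len(system$n_groups)))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  class(tab) <- c("contingency_table", "matrix", "array")
  rho <- spearman_from_contingency(tab)
  diff <- c_index_difference_test(group, as.integer(stage),
                                  cases$survival_months, cases$event)
  out <- structure(list(contingency = tab, rho = rho, diff_test = diff,
                        n = nrow(cases)),
                   class = "eaccd_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(unclass(tab), file.path(out_dir, "contingency.csv"),
                     quote = FALSE)
    jsonlite::write_json(
      list(rho = as.numeric(rho), rho_p_value = attr(rho, "p_value"),
           c_system = diff$c_a, c_ajcc = diff$c_b, delta = diff$delta,
           ci95 = diff$ci95, p_value = diff$p_value, n = nrow(cases)),
      file.path(out_dir, "comparison.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  out
}

#' @export
print.eaccd_comparison <- function(x, ...) {
  cat("Stage/group agreement (midrank Spearman):",
      format(as.numeric(x$rho), digits = 4), "\n")
  print(x$diff_test)
  invisible(x)
}
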