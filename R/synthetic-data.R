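# Default additive log-hazard contributions per factor level, chosen to span
# the prognostic range seen in registry lung-cancer cohorts: with the default
# baseline hazard 0.0018/month the most favourable combination
# (T1a N0 M0 A0 H3) has a five-year cause-specific survival near 90% and the
# least favourable (T4 N3 M1 A1 H2) near 2%.
.default_effects <- function() {
  list(
    T = c(T1a = 0, T1b = 0.15, T1c = 0.3, T2a = 0.45, T2b = 0.6, T3 = 0.85, T4 = 1.1),
    N = c(N0 = 0, N1 = 0.3, N2 = 0.55, N3 = 0.75),
    M = c(M0 = 0, M1 = 1.1),
    A = c(A0 = 0, A1 = 0.3),
    H = c(H1 = 0.15, H2 = 0.6, H3 = 0, H4 = 0.35)
  )
}

.full_grid <- function(active) {
  lv <- factor_levels()[active]
  g <- rev(expand.grid(rev(lv), stringsAsFactors = TRUE))
  names(g) <- active
  g
}

#' Configure a synthetic SEER-like case-listing simulation
#'
#' Defines the generating model for [generate_cases()]: cohorts are the
#' combinations of the active factors; each patient's true survival time is
#' Weibull (exponential by default) with hazard
#' `baseline_hazard * exp(eta)`, where `eta` is the sum of the additive
#' log-hazard effects of the patient's factor levels, or a planted group
#' log-hazard when `planted_groups` is supplied. Censoring is administrative:
#' uniform over `censoring_window_months`, emulating a registry window with a
#' minimum five-year follow-up. Observed times are floored to whole months.
#'
#' @param active_factors Subset of `c("T","N","M","A","H")`.
#' @param combination_sizes Either a single integer (fixed cohort size) or a
#'   range `c(lo, hi)` sampled uniformly per combination.
#' @param effects Named list of per-level log-hazard contributions (defaults
#'   documented in the methods vignette).
#' @param baseline_hazard Baseline hazard, events per month (> 0).
#' @param planted_groups Optional list with `k_true`, `group_log_hazards`
#'   (length `k_true`) and `assignment` (named integer vector, combination
#'   label -> group index) covering every generated combination.
#' @param censoring_window_months Range `c(lo, hi)` in months (default
#'   `c(60, 96)`).
#' @param combinations Optional data frame of factor-level columns overriding
#'   the full grid of active-factor combinations.
#' @param weibull_shape Shape parameter of the survival distribution
#'   (1 = exponential, the default).
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(active_factors = c("T", "N", "M", "A", "H"),
                              combination_sizes = c(30L, 500L),
                              effects = .default_effects(),
                              baseline_hazard = 0.0018,
                              planted_groups = NULL,
                              censoring_window_months = c(60, 96),
                              combinations = NULL,
                              weibull_shape = 1,
                              seed = 1L) {
  active <- intersect(.FACTORS, active_factors)
  stopifnot(length(active) >= 1, baseline_hazard > 0, weibull_shape > 0,
            length(censoring_window_months) == 2,
            censoring_window_months[1] <= censoring_window_months[2])
  if (length(combination_sizes) == 1L) combination_sizes <- rep(combination_sizes, 2L)
  stopifnot(length(combination_sizes) == 2,
            combination_sizes[1] >= 1, combination_sizes[1] <= combination_sizes[2])
  if (is.null(combinations)) combinations <- .full_grid(active)
  stopifnot(all(active %in% names(combinations)))
  for (f in active) {
    combinations[[f]] <- factor(as.character(combinations[[f]]),
                                levels = factor_levels()[[f]])
    stopifnot(!anyNA(combinations[[f]]))
  }
  labels <- do.call(paste0, lapply(active, function(f) as.character(combinations[[f]])))
  stopifnot(!anyDuplicated(labels))
  if (!is.null(planted_groups)) {
    stopifnot(is.list(planted_groups),
              length(planted_groups$group_log_hazards) == planted_groups$k_true,
              all(labels %in% names(planted_groups$assignment)),
              all(planted_groups$assignment %in% seq_len(planted_groups$k_true)))
  } else {
    for (f in active) stopifnot(all(levels(combinations[[f]]) %in% names(effects[[f]])))
  }
  structure(list(active_factors = active,
                 combinations = combinations,
                 labels = labels,
                 combination_sizes = as.integer(combination_sizes),
                 effects = effects,
                 baseline_hazard = baseline_hazard,
                 planted_groups = planted_groups,
                 censoring_window_months = censoring_window_months,
                 weibull_shape = weibull_shape,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Three-tier planted-group simulation config
#'
#' Convenience constructor for recovery experiments: `k_true` prognostic
#' tiers with hazards `baseline_hazard * hazard_ratio^(tier-1)` planted on
#' combinations drawn from the active-factor grid, interleaved so that the
#' planted structure does not follow the factor ordering.
#'
#' @param k_true Number of planted tiers.
#' @param cohorts_per_tier Combinations per tier.
#' @param n_per_cohort Patients per combination.
#' @param hazard_ratio Hazard ratio between adjacent tiers.
#' @param baseline_hazard Tier-1 hazard per month.
#' @param active_factors Factors whose grid supplies combination labels.
#' @param censoring_window_months Administrative censoring window.
#' @param seed Integer seed.
#' @return A `simulation_config`.
#' @export
planted_tiers_config <- function(k_true = 3L, cohorts_per_tier = 10L,
                                 n_per_cohort = 500L, hazard_ratio = 3,
                                 baseline_hazard = 0.005,
                                 active_factors = c("T", "N", "M"),
                                 censoring_window_months = c(60, 96),
                                 seed = 1L) {
  grid <- .full_grid(intersect(.FACTORS, active_factors))
  n_comb <- k_true * cohorts_per_tier
  stopifnot(n_comb <= nrow(grid))
  grid <- grid[seq_len(n_comb), , drop = FALSE]
  labels <- do.call(paste0, lapply(grid, as.character))
  assignment <- stats::setNames(rep_len(seq_len(k_true), n_comb), labels)
  simulation_config(
    active_factors = active_factors,
    combination_sizes = n_per_cohort,
    baseline_hazard = baseline_hazard,
    planted_groups = list(k_true = k_true,
                          group_log_hazards = log(hazard_ratio) * (seq_len(k_true) - 1),
                          assignment = assignment),
    censoring_window_months = censoring_window_months,
    combinations = grid,
    seed = seed)
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic case listing with known ground truth
#'
#' Draws patients per combination according to a [simulation_config()]:
#' survival times Weibull with the configured hazard, censoring uniform over
#' the administrative window, observed time `floor(min(survival, censoring))`
#' months, event = 1 iff death occurred within follow-up. Deterministic given
#' the config seed.
#'
#' @param config A `simulation_config`.
#' @return List with `cases` (a case data frame, see [read_cases()]) and
#'   `truth` (per-combination hazards, linear predictors, planted group
#'   labels and the config).
#' @export
generate_cases <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, {
    comb <- config$combinations
    labels <- config$labels
    k <- nrow(comb)
    sz <- config$combination_sizes
    sizes <- if (sz[1] == sz[2]) rep(sz[1], k) else
      sample(seq(sz[1], sz[2]), k, replace = TRUE)
    if (!is.null(config$planted_groups)) {
      groups <- config$planted_groups$assignment[labels]
      eta <- config$planted_groups$group_log_hazards[groups]
    } else {
      groups <- NULL
      eta <- rowSums(vapply(config$active_factors, function(f)
        config$effects[[f]][as.character(comb[[f]])], numeric(k)))
    }
    hazard <- config$baseline_hazard * exp(eta)
    cw <- config$censoring_window_months
    pieces <- vector("list", k)
    for (i in seq_len(k)) {
      n <- sizes[i]
      true_t <- stats::rweibull(n, shape = config$weibull_shape, scale = 1 / hazard[i])
      cens_t <- if (cw[1] == cw[2]) rep(cw[1], n) else stats::runif(n, cw[1], cw[2])
      obs <- floor(pmin(true_t, cens_t))
      ev <- as.integer(true_t <= cens_t)
      df <- comb[rep(i, n), , drop = FALSE]
      df$case_id <- sprintf("%s-%05d", labels[i], seq_len(n))
      df$survival_months <- as.integer(obs)
      df$event <- ev
      pieces[[i]] <- df
    }
    cases <- do.call(rbind, pieces)
    rownames(cases) <- NULL
    cases <- cases[c("case_id", config$active_factors, "survival_months", "event")]
    truth <- list(labels = labels,
                  hazards = stats::setNames(hazard, labels),
                  eta = stats::setNames(eta, labels),
                  groups = if (is.null(groups)) NULL else stats::setNames(groups, labels),
                  sizes = stats::setNames(sizes, labels),
                  config = config)
    list(cases = cases, truth = truth)
  })
}

#' Published 10 x 11 stage-by-group contingency table
#'
#' The published contingency table cross-tabulating 77,953 lung-cancer
#' patients by their AJCC 8th-edition stage (rows IA1--IV) and their
#' 11-group clustered TNM prognostic system (columns 1--11). Bundled as a
#' worked in-package example for the stratification-agreement machinery.
#'
#' @return A `contingency_table` (integer matrix with stage row labels and
#'   group column labels).
#' @export
table2_fixture <- function() {
  counts <- rbind(
    IA1  = c(1656,    0,    0,    0,    0,    0,    0,    0,    0,    0,     0),
    IA2  = c(7398,    0,    0,    0,    0,    0,    0,    0,    0,    0,     0),
    IA3  = c(   0, 5111,    0,    0,    0,    0,    0,    0,    0,    0,     0),
    IB   = c(   0,    0, 3411,    0,    0,    0,    0,    0,    0,    0,     0),
    IIA  = c(   0,    0,    0, 1603,    0,    0,    0,    0,    0,    0,     0),
    IIB  = c(   0,    0,  407, 5357,  356,    0,    0,    0,    0,    0,     0),
    IIIA = c(   0,    0,    0,   52, 1859, 5804, 1938,    0,    0,    0,     0),
    IIIB = c(   0,    0,    0,    0,    0,    0, 3182, 4140,    0,    0,     0),
    IIIC = c(   0,    0,    0,    0,    0,    0,    0, 1662,    0,    0,     0),
    IV   = c(   0,    0,    0,    0,    0,    0,    0, 1092, 4320, 8553, 20052))
  colnames(counts) <- as.character(1:11)
  structure(counts, class = c("contingency_table", class(counts)))
}
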