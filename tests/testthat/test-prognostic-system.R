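planted_fit_fixture <- function(seed = 41, B = 100) {
  cfg <- planted_tiers_config(k_true = 3, cohorts_per_tier = 4,
                              n_per_cohort = 300, hazard_ratio = 4,
                              baseline_hazard = 0.008, seed = seed)
  sim <- generate_cases(cfg)
  cohorts <- group_into_combinations(sim$cases, cfg$active_factors)
  d <- build_initial_matrix(cohorts, sim$cases)
  delta <- ensemble_learn(d, B = B, k_range = c(2, 6), seed = seed)
  list(sim = sim, cohorts = cohorts, dend = minimax_linkage(delta))
}

test_that("the C-index curve starts at one half and plateaus after the true k", {
  fx <- planted_fit_fixture()
  curve <- c_index_curve(fx$dend, fx$cohorts, fx$sim$cases, ks = 1:8)
  expect_equal(curve$c_index[curve$k == 1], 0.5)
  expect_true(all(curve$c_index >= 0 & curve$c_index <= 1))
  # steep rise to the planted k = 3, then nearly flat
  gains <- diff(curve$c_index)
  expect_gt(min(gains[1:2]), 0.02)
  expect_lt(max(abs(gains[3:7])), 0.005)
})

test_that("the knee rule implements the marginal-gain threshold", {
  mk <- function(cv) structure(data.frame(k = seq_along(cv), c_index = cv),
                               class = c("c_index_curve", "data.frame"))
  expect_equal(knee_point(mk(c(0.50, 0.70, 0.71, 0.712, 0.713))), 2)
  expect_warning(n <- knee_point(mk(c(0.5, 0.6, 0.7, 0.8, 0.9))), "no knee")
  expect_equal(n, 5)
  expect_warning(nf <- knee_point(mk(rep(0.6, 5))), "flat")
  expect_equal(nf, 1)
  expect_error(knee_point(mk(c(0.5, 0.6))))
})

test_that("the fitted system orders groups by decreasing five-year survival", {
  fx <- planted_fit_fixture()
  sys <- build_system(fx$dend, fx$cohorts, fx$sim$cases, n_groups = 3)
  expect_equal(sys$n_groups, 3L)
  # ordering contract: five-year rates non-increasing in group number
  expect_true(all(diff(sys$five_year_rates) <= 0))
  # planted tiers: group 1 must be the lowest-hazard tier
  truth <- fx$sim$truth$groups[names(sys$assignment)]
  expect_equal(unname(sys$assignment), unname(truth))
  # self-consistency: C recomputed independently from the assignment
  labels <- do.call(paste0, lapply(c("T", "N", "M"),
                                   function(f) as.character(fx$sim$cases[[f]])))
  scores <- sys$assignment[labels]
  expect_equal(sys$c_index,
               harrell_c_index(scores, fx$sim$cases$survival_months,
                               fx$sim$cases$event))
  # every combination is assigned, prototypes cover every group
  expect_setequal(names(sys$assignment), fx$cohorts$label)
  expect_length(sys$prototypes, 3)
})

test_that("a single-group system is uninformative by convention", {
  fx <- planted_fit_fixture(seed = 43)
  sys <- build_system(fx$dend, fx$cohorts, fx$sim$cases, n_groups = 1)
  expect_equal(sys$c_index, 0.5)
  expect_length(sys$five_year_rates, 1)
})

test_that("risk-category proportions are per-level distributions", {
  fx <- planted_fit_fixture(seed = 44)
  sys <- build_system(fx$dend, fx$cohorts, fx$sim$cases, n_groups = 3)
  dist <- suppressWarnings(
    risk_category_distribution(sys, fx$sim$cases, split = list(low = 1, high = 2:3)))
  expect_true(all(abs(dist$low + dist$high - 1) < 1e-12))
  expect_true(all(c("T", "N", "M") %in% dist$factor))

  # degenerate split: everything low risk
  dist_all <- suppressWarnings(
    risk_category_distribution(sys, fx$sim$cases,
                               split = list(low = 1:3, high = integer(0))))
  expect_true(all(dist_all$low == 1))
  expect_error(risk_category_distribution(sys, fx$sim$cases,
                                          split = list(low = 1, high = 2)))
})

test_that("a factor level confined to high-hazard groups shows high risk", {
  # construct cases where histology H2 only appears alongside the worst tier
  set.seed(45)
  mk_cohort <- function(tlab, hlab, hazard, n = 250) {
    cohort <- random_cohort(n, hazard = hazard, cens = c(60, 96))
    data.frame(case_id = sprintf("%s%s-%03d", tlab, hlab, 1:n),
               T = factor(tlab, levels = factor_levels()$T),
               H = factor(hlab, levels = factor_levels()$H),
               survival_months = as.integer(cohort$times),
               event = cohort$events)
  }
  cases <- rbind(mk_cohort("T1a", "H3", 0.004), mk_cohort("T1a", "H1", 0.005),
                 mk_cohort("T2a", "H3", 0.006), mk_cohort("T2a", "H1", 0.007),
                 mk_cohort("T4", "H2", 0.08), mk_cohort("T4", "H1", 0.09))
  cohorts <- group_into_combinations(cases, c("T", "H"))
  d <- build_initial_matrix(cohorts, cases)
  delta <- ensemble_learn(d, B = 100, k_range = c(2, 3), seed = 45)
  dend <- minimax_linkage(delta)
  sys <- build_system(dend, cohorts, cases, n_groups = 2)
  dist <- suppressWarnings(
    risk_category_distribution(sys, cases, split = list(low = 1, high = 2)))
  h <- dist[dist$factor == "H", ]
  expect_equal(h$high[h$level == "H2"], 1)
  expect_gt(h$high[h$level == "H2"], max(h$high[h$level != "H2"]))
})
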