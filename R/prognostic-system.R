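# order raw cut groups by prognosis: descending five-year KM survival,
# ties broken by group size (larger first)
.order_groups <- function(raw_group, times, events, five_year_month = 60) {
  ks <- sort(unique(raw_group))
  rates <- vapply(ks, function(g) {
    sel <- raw_group == g
    survival_rate_at(km_estimate(times[sel], events[sel]), five_year_month)
  }, numeric(1))
  sizes <- vapply(ks, function(g) sum(raw_group == g), numeric(1))
  ord <- order(-rates, -sizes, ks)
  # rank[g] = new group number of raw group g
  rank <- match(ks, ks[ord])
  list(rank = stats::setNames(rank, ks),
       rates = stats::setNames(rates[ord], seq_along(ks)),
       ties = any(duplicated(rates)))
}

#' C-index curve over candidate dendrogram cuts
#'
#' For each candidate group count k, cuts the dendrogram into k clusters,
#' orders them by decreasing five-year Kaplan-Meier survival, scores every
#' patient with their group number and computes Harrell's C over all
#' patients.
#'
#' @param dend A `minimax_dendrogram` over the combinations.
#' @param cohorts The `cohort_set` the dendrogram was built on.
#' @param cases Case data frame.
#' @param ks Integer vector of candidate group counts (default all
#'   `1:n_leaves`).
#' @param five_year_month Month at which group survival is read off for
#'   ordering (default 60).
#' @return A `c_index_curve` data frame with columns `k` and `c_index`.
#' @export
c_index_curve <- function(dend, cohorts, cases, ks = NULL,
                          five_year_month = 60) {
  n_leaves <- length(dend$labels)
  if (is.null(ks)) ks <- seq_len(n_leaves)
  stopifnot(all(ks >= 1), all(ks <= n_leaves))
  ks <- sort(unique(as.integer(ks)))
  ci <- .cohort_index(cohorts, cases)
  keep <- !is.na(ci)
  times <- cases$survival_months[keep]
  events <- cases$event[keep]
  ci <- ci[keep]
  cvals <- vapply(ks, function(k) {
    cut <- cut_dendrogram(dend, k)
    raw <- cut[match(cohorts$label, names(cut))][ci]
    if (k == 1) return(0.5)
    ord <- .order_groups(raw, times, events, five_year_month)
    harrell_c_index(ord$rank[as.character(raw)], times, events)
  }, numeric(1))
  structure(data.frame(k = ks, c_index = cvals),
            class = c("c_index_curve", "data.frame"))
}

#' Knee point of a C-index curve
#'
#' Formal marginal-gain rule standing in for the visual knee: the smallest
#' k from which every subsequent one-group gain in C falls below
#' `rel_gain` times the curve's total span. A flat curve (zero span) returns
#' the smallest k with a warning; a curve whose final gain still exceeds the
#' threshold returns the largest k with a warning (no knee).
#'
#' @param curve A `c_index_curve` (at least 3 points).
#' @param rel_gain Relative-gain threshold (default 0.05).
#' @return The selected number of groups n*.
#' @export
knee_point <- function(curve, rel_gain = 0.05) {
  stopifnot(nrow(curve) >= 3)
  ks <- curve$k
  cv <- curve$c_index
  span <- cv[length(cv)] - cv[1]
  if (span <= 0) {
    warning("flat C-index curve; returning the smallest k", call. = FALSE)
    return(ks[1])
  }
  gains <- diff(cv)
  small <- gains < rel_gain * span
  # smallest index t such that all gains from t onwards are below threshold
  ok <- rev(cumprod(rev(small))) == 1
  if (!any(ok)) {
    warning("no knee: the C-index curve is still rising at the largest k",
            call. = FALSE)
    return(ks[length(ks)])
  }
  ks[which(ok)[1]]
}

#' Build an ordered prognostic system from a dendrogram cut
#'
#' Cuts the dendrogram into `n_groups` clusters of combinations, orders the
#' clusters by decreasing five-year Kaplan-Meier survival (so risk increases
#' with the group number; ties broken by size, larger first, with a
#' message), and assembles per-group survival curves, five-year rates and
#' the system's Harrell C-index with group numbers as risk scores.
#'
#' @inheritParams c_index_curve
#' @param n_groups Number of prognostic groups n*.
#' @return A `prognostic_system`: list with `n_groups`, `assignment`
#'   (combination label -> group number), `group_curves`, `five_year_rates`,
#'   `c_index`, `prototypes`, `active_factors` and `five_year_month`.
#' @export
build_system <- function(dend, cohorts, cases, n_groups,
                         five_year_month = 60) {
  cut <- cut_dendrogram(dend, n_groups)
  ci <- .cohort_index(cohorts, cases)
  keep <- !is.na(ci)
  times <- cases$survival_months[keep]
  events <- cases$event[keep]
  raw <- cut[match(cohorts$label, names(cut))][ci[keep]]
  ord <- .order_groups(raw, times, events, five_year_month)
  if (ord$ties) message("build_system: tied five-year rates; ordering ties broken by group size")
  assignment <- stats::setNames(ord$rank[as.character(cut)], names(cut))
  group <- ord$rank[as.character(raw)]
  curves <- lapply(seq_len(n_groups), function(g) {
    sel <- group == g
    km_estimate(times[sel], events[sel])
  })
  names(curves) <- as.character(seq_len(n_groups))
  c_idx <- if (n_groups == 1) 0.5 else harrell_c_index(group, times, events)
  proto <- attr(cut, "prototypes")
  names(proto) <- as.character(ord$rank[names(proto)])
  proto <- proto[as.character(seq_len(n_groups))]
  structure(list(n_groups = as.integer(n_groups),
                 assignment = assignment,
                 group_curves = curves,
                 five_year_rates = ord$rates,
                 c_index = c_idx,
                 prototypes = proto,
                 active_factors = attr(cohorts, "active_factors"),
                 five_year_month = five_year_month),
            class = "prognostic_system")
}

#' @export
print.prognostic_system <- function(x, ...) {
  cat("Prognostic system with", x$n_groups, "groups over",
      length(x$assignment), "combinations\n")
  cat("C-index:", format(x$c_index, digits = 4), "\n")
  cat("Five-year rates by group (risk increases with group number):\n")
  print(round(x$five_year_rates, 3))
  invisible(x)
}

#' Distribution of factor levels over risk categories
#'
#' Splits the ordered groups into a low-risk and a high-risk category and
#' tabulates, for every level of every active factor, the proportion of that
#' level's patients falling in each category.
#'
#' @param system A `prognostic_system`.
#' @param cases Case data frame.
#' @param split List with integer vectors `low` and `high` partitioning
#'   `1:n_groups`.
#' @return Data frame with columns `factor`, `level`, `low`, `high`
#'   (proportions summing to 1 per level).
#' @export
risk_category_distribution <- function(system, cases, split) {
  stopifnot(setequal(c(split$low, split$high), seq_len(system$n_groups)),
            length(intersect(split$low, split$high)) == 0)
  labels <- .case_labels(cases, system$active_factors)
  group <- system$assignment[labels]
  keep <- !is.na(group)
  if (!all(keep)) {
    message("risk_category_distribution: ", sum(!keep),
            " case(s) in combinations outside the system were ignored")
  }
  cases <- cases[keep, , drop = FALSE]
  group <- group[keep]
  high <- group %in% split$high
  rows <- list()
  for (f in system$active_factors) {
    for (lv in levels(cases[[f]])) {
      sel <- cases[[f]] == lv
      if (!any(sel)) {
        warning("level ", lv, " of factor ", f, " absent from the data; omitted",
                call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, level = lv,
        low = mean(!high[sel]), high = mean(high[sel]))
    }
  }
  do.call(rbind, rows)
}
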