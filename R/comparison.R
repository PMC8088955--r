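.STAGE_LEVELS <- c("IA1", "IA2", "IA3", "IB", "IIA", "IIB", "IIIA", "IIIB",
                   "IIIC", "IV")

.ajcc_env <- new.env(parent = emptyenv())

.ajcc_table <- function() {
  if (is.null(.ajcc_env$tab)) {
    path <- system.file("extdata", "ajcc8_lung_stage_grouping.csv",
                        package = "eaccd", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    key <- paste(tab$t, tab$n, tab$m)
    .ajcc_env$tab <- stats::setNames(tab$stage, key)
  }
  .ajcc_env$tab
}

#' AJCC 8th-edition lung stage assignment
#'
#' Looks up the stage group of each (T, N, M) triple in the bundled
#' 8th-edition lung stage-grouping table (`inst/extdata/`). The lookup is
#' total over the 7 x 4 x 2 grid; every M1 maps to stage IV (metastatic
#' subdivisions are not distinguished) and stage 0/occult is out of scope.
#'
#' @param t,n,m Vectors of 8th-edition T, N and M level codes.
#' @return Factor of stages with ordered levels IA1 < IA2 < ... < IV.
#' @export
assign_ajcc8_stage <- function(t, n, m) {
  tab <- .ajcc_table()
  key <- paste(as.character(t), as.character(n), as.character(m))
  stage <- tab[key]
  if (anyNA(stage)) {
    stop("invalid T/N/M combination at position ", which(is.na(stage))[1],
         call. = FALSE)
  }
  factor(stage, levels = .STAGE_LEVELS)
}

#' Stage-by-group contingency table
#'
#' @param stages Per-patient stage (factor, ordered levels).
#' @param groups Per-patient prognostic group (factor or integer).
#' @return A `contingency_table` (integer matrix, stages in rows, groups in
#'   columns).
#' @export
contingency <- function(stages, groups) {
  stopifnot(length(stages) == length(groups))
  counts <- table(stage = stages, group = groups)
  counts <- unclass(counts)
  names(dimnames(counts)) <- NULL
  structure(counts, class = c("contingency_table", class(counts)))
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- unclass(x)
  m <- rbind(m, Total = colSums(m))
  m <- cbind(m, Total = rowSums(m))
  print(m)
  invisible(x)
}

#' Spearman rank correlation from a contingency table
#'
#' Treats every patient in the table as an observation whose row score is
#' the midrank of its stage (shared across all patients of that stage) and
#' whose column score is the midrank of its group, and returns the Pearson
#' correlation of those midranks -- i.e. Spearman's rho with tied ranks --
#' computed directly from the counts without expanding to patient level.
#' A t-approximation p-value at the patient-level sample size is attached
#' as attribute `p_value`.
#'
#' @param tab A `contingency_table` (or plain count matrix) with at least
#'   two nonempty rows and columns.
#' @return Spearman's rho.
#' @export
spearman_from_contingency <- function(tab) {
  counts <- unclass(tab)
  n <- sum(counts)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (n < 2 || sum(rs > 0) < 2 || sum(cs > 0) < 2) {
    stop("degenerate contingency table: need >= 2 nonempty rows and columns",
         call. = FALSE)
  }
  midrank <- function(x) cumsum(x) - (x - 1) / 2
  r <- midrank(rs)
  cmid <- midrank(cs)
  rbar <- (n + 1) / 2
  num <- sum(counts * outer(r - rbar, cmid - rbar))
  den <- sqrt(sum(rs * (r - rbar)^2) * sum(cs * (cmid - rbar)^2))
  rho <- num / den
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  attr(rho, "p_value") <- 2 * stats::pt(-abs(tstat), df = n - 2)
  rho
}

#' Correlated C-index difference test
#'
#' Tests whether two risk scores evaluated on the same patients differ in
#' Harrell concordance. Both concordances are estimated jointly by
#' [survival::concordance()], whose influence-function variance matrix
#' yields the variance of the paired difference
#' (`var_a + var_b - 2 cov_ab`); the p-value is two-sided normal and the
#' 95% CI is `delta +/- 1.96 SE`.
#'
#' @param scores_a,scores_b Risk scores (higher = higher risk) on the same
#'   patients.
#' @param times Observed months.
#' @param events Event indicators.
#' @return A `c_comparison`: list with `c_a`, `c_b`, `delta`, `se`, `ci95`,
#'   `p_value`.
#' @export
c_index_difference_test <- function(scores_a, scores_b, times, events) {
  stopifnot(length(scores_a) == length(times),
            length(scores_b) == length(times),
            length(events) == length(times))
  fit <- survival::concordance(
    survival::Surv(times, events) ~ scores_a + scores_b, reverse = TRUE)
  if (sum(fit$count[, "concordant"] + fit$count[, "discordant"] +
          fit$count[, "tied.x"]) == 0) {
    stop("no permissible pairs", call. = FALSE)
  }
  c_a <- as.numeric(fit$concordance[1])
  c_b <- as.numeric(fit$concordance[2])
  delta <- c_a - c_b
  se <- sqrt(max(fit$var[1, 1] + fit$var[2, 2] - 2 * fit$var[1, 2], 0))
  p <- if (se == 0) {
    if (abs(delta) < .Machine$double.eps^0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(delta) / se)
  }
  structure(list(c_a = c_a, c_b = c_b, delta = delta, se = se,
                 ci95 = delta + c(-1, 1) * stats::qnorm(0.975) * se,
                 p_value = p),
            class = "c_comparison")
}

#' @export
print.c_comparison <- function(x, ...) {
  cat(sprintf("C_a = %.4f, C_b = %.4f, delta = %.4f (95%% CI %.4f to %.4f), p = %.3g\n",
              x$c_a, x$c_b, x$delta, x$ci95[1], x$ci95[2], x$p_value))
  invisible(x)
}
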