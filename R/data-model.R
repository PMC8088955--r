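# Factor-level enumerations for the five staging factors.
# T uses 8th-edition categories; T7 the 7th-edition categories from which
# registry data are recoded.
.T_LEVELS  <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T3", "T4")
.T7_LEVELS <- c("T1a", "T1b", "T2a", "T2b", "T3", "T4")
.N_LEVELS  <- c("N0", "N1", "N2", "N3")
.M_LEVELS  <- c("M0", "M1")
.A_LEVELS  <- c("A0", "A1")
.H_LEVELS  <- c("H1", "H2", "H3", "H4")
.FACTORS   <- c("T", "N", "M", "A", "H")

#' Staging factor levels
#'
#' Returns the level enumerations used throughout the package: primary tumor
#' extent `T` (8th edition, seven levels T1a--T4), regional lymph nodes `N`
#' (N0--N3), distant metastasis `M` (M0/M1), dichotomized age `A` (A0 under
#' 70 years, A1 at 70 or older) and main histological type `H` (H1 squamous
#' cell, H2 small cell, H3 adenocarcinoma, H4 large cell carcinoma).
#'
#' @return Named list of character vectors, one per factor.
#' @export
factor_levels <- function() {
  list(T = .T_LEVELS, N = .N_LEVELS, M = .M_LEVELS, A = .A_LEVELS, H = .H_LEVELS)
}

.required_cols <- function(dialect) {
  switch(dialect,
    recoded8 = c("case_id", "T", "N", "M", "A", "H", "survival_months", "event"),
    raw7 = c("case_id", "T7", "N", "M", "H", "survival_months", "event",
             "cs_tumor_size_mm", "age_years"))
}

.check_levels <- function(x, levels, col) {
  bad <- which(!(x %in% levels))
  if (length(bad)) {
    stop(sprintf("column %s: unparseable level code '%s' at row %d",
                 col, x[bad[1]], bad[1]), call. = FALSE)
  }
  factor(x, levels = levels)
}

#' Read a case-listing CSV
#'
#' Reads a flat case listing of individual patients. Two dialects are
#' supported: `"recoded8"` carries 8th-edition T plus N, M, A, H directly;
#' `"raw7"` carries 7th-edition T (`T7`), the collaborative-stage tumor size
#' in millimetres and age in years, from which 8th-edition T and the age
#' group A are derived (see [recode_t_7to8()]).
#'
#' Rows with a missing required field are dropped (with a message); the drop
#' count is attached as attribute `n_dropped`. `cs_tumor_size_mm` may be
#' missing on rows whose T7 level never consults size.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param dialect `"recoded8"` (default) or `"raw7"`.
#' @return A data frame of cases with columns `case_id`, `T`, `N`, `M`, `A`,
#'   `H` (factors), `survival_months` (integer months) and `event`
#'   (1 = death from the studied cancer, 0 = censored).
#' @export
read_cases <- function(path, dialect = c("recoded8", "raw7")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- .required_cols(dialect)
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  # completeness selection: size may legitimately be missing (checked later,
  # only where a recoding rule consults it)
  must_have <- setdiff(req, "cs_tumor_size_mm")
  complete <- stats::complete.cases(raw[must_have])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message("read_cases: dropped ", n_dropped, " row(s) with incomplete information")
  }
  df <- raw[complete, , drop = FALSE]
  rownames(df) <- NULL

  if (any(df$survival_months < 0)) {
    stop("negative survival_months at row ", which(df$survival_months < 0)[1],
         call. = FALSE)
  }
  if (!all(df$event %in% c(0L, 1L))) {
    stop("event must be 0/1; offending row ",
         which(!(df$event %in% c(0L, 1L)))[1], call. = FALSE)
  }

  if (dialect == "raw7") {
    t7 <- .check_levels(df$T7, .T7_LEVELS, "T7")
    df$T <- recode_t_7to8(as.character(t7), df$cs_tumor_size_mm)
    df$A <- factor(ifelse(df$age_years >= 70, "A1", "A0"), levels = .A_LEVELS)
  } else {
    df$T <- .check_levels(df$T, .T_LEVELS, "T")
    df$A <- .check_levels(df$A, .A_LEVELS, "A")
  }
  df$N <- .check_levels(df$N, .N_LEVELS, "N")
  df$M <- .check_levels(df$M, .M_LEVELS, "M")
  df$H <- .check_levels(df$H, .H_LEVELS, "H")
  df$case_id <- as.character(df$case_id)
  df$survival_months <- as.integer(df$survival_months)
  df$event <- as.integer(df$event)

  out <- df[c("case_id", "T", "N", "M", "A", "H", "survival_months", "event")]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a case listing to CSV
#'
#' @param cases Data frame as returned by [read_cases()] or [generate_cases()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  utils::write.csv(cases, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Recode 7th-edition T to 8th-edition T
#'
#' Applies the reclassification of the 7th-edition primary-tumor category to
#' the 8th edition using collaborative-stage tumor size: 7th T1a splits at
#' 10 mm into 8th T1a/T1b; 7th T1b becomes T1c; 7th T2a splits at 40 mm into
#' T2a/T2b; 7th T2b becomes T3; 7th T3 splits at 70 mm into T3/T4; 7th T4
#' stays T4. Size intervals are half-open `(lower, upper]`, anchored by the
#' closed upper bounds at 10 mm and 70 mm.
#'
#' A 7th-edition T1a above 20 mm or T2a outside (30, 50] mm is inconsistent
#' with the 7th-edition size definitions; such records are mapped to the
#' nearest covered bin and flagged with a warning.
#'
#' @param t7 Character vector of 7th-edition T levels
#'   (`r paste(.T7_LEVELS, collapse = ", ")`).
#' @param size_mm Numeric tumor size in millimetres; may be `NA` for levels
#'   whose rule never consults size (T1b, T2b, T4).
#' @return Factor of 8th-edition T levels.
#' @export
recode_t_7to8 <- function(t7, size_mm = NA_real_) {
  if (!all(t7 %in% .T7_LEVELS)) {
    bad <- which(!(t7 %in% .T7_LEVELS))[1]
    stop("invalid 7th-edition T level '", t7[bad], "' at position ", bad,
         call. = FALSE)
  }
  n <- length(t7)
  size_mm <- rep_len(as.numeric(size_mm), n)
  needs_size <- t7 %in% c("T1a", "T2a", "T3")
  if (any(needs_size & is.na(size_mm))) {
    stop("CS tumor size missing for size-dependent recoding at position(s): ",
         paste(utils::head(which(needs_size & is.na(size_mm)), 5L), collapse = ", "),
         call. = FALSE)
  }
  out <- character(n)
  anomalous <- logical(n)
  for (i in seq_len(n)) {
    s <- size_mm[i]
    out[i] <- switch(t7[i],
      T1a = if (s <= 10) "T1a" else {
        if (s > 20) anomalous[i] <- TRUE
        "T1b"
      },
      T1b = "T1c",
      T2a = if (s <= 40) {
        if (s <= 30) anomalous[i] <- TRUE
        "T2a"
      } else {
        if (s > 50) anomalous[i] <- TRUE
        "T2b"
      },
      T2b = "T3",
      T3 = if (s <= 70) "T3" else "T4",
      T4 = "T4")
  }
  if (any(anomalous)) {
    warning(sum(anomalous), " record(s) with tumor size outside the 7th-edition ",
            "range for their T level; mapped to the nearest covered 8th-edition bin",
            call. = FALSE)
  }
  factor(out, levels = .T_LEVELS)
}

.case_labels <- function(cases, active_factors) {
  do.call(paste0, lapply(active_factors, function(f) as.character(cases[[f]])))
}

#' Group cases into factor-level combinations
#'
#' Partitions cases into cohorts ("combinations"), one per observed
#' combination of levels of the active factors, labelled by concatenating the
#' level codes in canonical T, N, M, A, H order (e.g. `"T1bN1M0A0H1"`).
#'
#' @param cases Case data frame (see [read_cases()]).
#' @param active_factors Subset of `c("T","N","M","A","H")`.
#' @return A `cohort_set`: a data frame with one row per combination, columns
#'   `label`, the active factor levels, `size`, and a list-column
#'   `member_ids` of case ids; rows sorted by factor-level order. The active
#'   factors are attached as attribute `active_factors`.
#' @export
group_into_combinations <- function(cases, active_factors) {
  active <- intersect(.FACTORS, active_factors)
  if (length(active) == 0L) stop("active_factors must be a non-empty subset of T,N,M,A,H")
  if (nrow(cases) == 0L) {
    out <- data.frame(label = character(0), size = integer(0))
    out$member_ids <- list()
    attr(out, "active_factors") <- active
    class(out) <- c("cohort_set", "data.frame")
    return(out)
  }
  labels <- .case_labels(cases, active)
  # sort combinations by the factor-level ordering, not alphabetically
  keys <- lapply(active, function(f) as.integer(cases[[f]]))
  ord_levels <- do.call(order, keys)
  uniq <- !duplicated(labels[ord_levels])
  cohort_labels <- labels[ord_levels][uniq]
  idx <- split(seq_len(nrow(cases)), factor(labels, levels = cohort_labels))
  out <- data.frame(label = cohort_labels, stringsAsFactors = FALSE)
  for (f in active) {
    out[[f]] <- cases[[f]][vapply(idx, `[`, integer(1), 1L)]
  }
  out$size <- lengths(idx)
  out$member_ids <- I(lapply(idx, function(i) cases$case_id[i]))
  rownames(out) <- NULL
  attr(out, "active_factors") <- active
  class(out) <- c("cohort_set", "data.frame")
  out
}

#' Drop combinations below a minimum size
#'
#' Retains exactly the combinations with at least `min_n` cases (the
#' robustness filter applied before any clustering), preserving order.
#'
#' @param cohorts A `cohort_set` from [group_into_combinations()].
#' @param min_n Minimum number of cases per combination (default 50).
#' @return The filtered `cohort_set`.
#' @export
filter_min_cases <- function(cohorts, min_n = 50L) {
  stopifnot(min_n >= 1)
  keep <- cohorts$size >= min_n
  message(sprintf(
    "filter_min_cases: retained %d/%d combinations (%d/%d cases)",
    sum(keep), length(keep), sum(cohorts$size[keep]), sum(cohorts$size)))
  out <- cohorts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "active_factors") <- attr(cohorts, "active_factors")
  class(out) <- c("cohort_set", "data.frame")
  out
}

# Map each case row to its cohort row index (NA when the combination was
# filtered out); used by downstream modules.
.cohort_index <- function(cohorts, cases) {
  labels <- .case_labels(cases, attr(cohorts, "active_factors"))
  match(labels, cohorts$label)
}

# times/events per cohort, as a list of lists
.cohort_surv <- function(cohorts, cases) {
  idx <- .cohort_index(cohorts, cases)
  lapply(seq_len(nrow(cohorts)), function(i) {
    rows <- which(idx == i)
    list(times = cases$survival_months[rows], events = cases$event[rows])
  })
}
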