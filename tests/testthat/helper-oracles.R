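# Independent brute-force oracles and small fixture generators used across
# the suite. These deliberately avoid the package's own code paths.

# Harrell C by exhaustive pair enumeration: anchor on a death at time t_i,
# comparable when t_i < t_j or (t_i == t_j and j censored); ties in the risk
# score count one half.
brute_c_index <- function(score, time, event) {
  n <- length(time)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (event[i] == 1 &&
          (time[i] < time[j] || (time[i] == time[j] && event[j] == 0))) {
        den <- den + 1
        if (score[i] > score[j]) num <- num + 1
        else if (score[i] == score[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

# classical Mann-Whitney count U/(nm) with half weight for ties
classical_mw <- function(x, y) {
  s <- 0
  for (xi in x) s <- s + sum(xi < y) + 0.5 * sum(xi == y)
  s / (length(x) * length(y))
}

# one agglomeration step oracle: recompute every candidate union's minimax
# radius from scratch and return the best pair (smallest radius, ties by
# smallest member indices)
brute_minimax_radius <- function(d, members) {
  worst <- vapply(members, function(c) max(d[c, members]), numeric(1))
  best <- which.min(worst)
  list(radius = worst[best], prototype = members[best])
}

brute_minimax_linkage <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  protos <- integer(0)
  merges <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        cand <- brute_minimax_radius(d, sort(c(clusters[[i]], clusters[[j]])))
        key <- c(cand$radius, min(clusters[[i]]), min(clusters[[j]]))
        if (is.null(best) || cand$radius < best$radius - 1e-15) {
          best <- c(cand, list(i = i, j = j))
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, best$radius)
    protos <- c(protos, best$prototype)
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
    # keep clusters ordered by smallest member for deterministic ties
    clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  }
  list(members = merges, height = heights, prototype = protos)
}

# Spearman with midranks by full expansion to patient level
expanded_spearman <- function(tab) {
  idx <- which(tab > 0, arr.ind = TRUE)
  r <- rep(idx[, 1], tab[idx])
  g <- rep(idx[, 2], tab[idx])
  suppressWarnings(stats::cor(r, g, method = "spearman"))
}

# random censored cohort with integer month times
random_cohort <- function(n, hazard = 0.03, cens = c(24, 96)) {
  true_t <- stats::rexp(n, hazard)
  cens_t <- stats::runif(n, cens[1], cens[2])
  list(times = floor(pmin(true_t, cens_t)),
       events = as.integer(true_t <= cens_t))
}

# random symmetric dissimilarity matrix with zero diagonal
random_dissim <- function(n, labels = sprintf("C%02d", seq_len(n))) {
  m <- matrix(stats::runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  m
}

# small deterministic case table spanning a T x M cross
tiny_cases <- function() {
  data.frame(
    case_id = sprintf("c%02d", 1:6),
    T = factor(c("T1a", "T1a", "T1a", "T4", "T4", "T4"),
               levels = factor_levels()$T),
    N = factor(rep("N0", 6), levels = factor_levels()$N),
    M = factor(c("M0", "M1", "M0", "M0", "M1", "M1"),
               levels = factor_levels()$M),
    A = factor(rep("A0", 6), levels = factor_levels()$A),
    H = factor(rep("H3", 6), levels = factor_levels()$H),
    survival_months = c(10L, 5L, 20L, 8L, 3L, 2L),
    event = c(1L, 1L, 0L, 1L, 1L, 1L))
}
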