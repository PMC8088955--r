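#' Initial dissimilarity matrix over combinations
#'
#' Computes the symmetrized Mann-Whitney parameter between every pair of
#' combination cohorts and maps it through [initial_dissimilarity()]. The
#' per-cohort Kaplan-Meier curves are estimated once and reused across
#' pairs.
#'
#' @param cohorts A `cohort_set` (at least two combinations).
#' @param cases The case data frame the cohorts were formed from.
#' @return Symmetric dissimilarity matrix with zero diagonal, labelled by
#'   combination; the symmetrized theta matrix is attached as attribute
#'   `theta`.
#' @export
build_initial_matrix <- function(cohorts, cases) {
  n <- nrow(cohorts)
  if (n < 2) stop("need at least two combinations", call. = FALSE)
  surv <- .cohort_surv(cohorts, cases)
  curves <- vector("list", n)
  for (i in seq_len(n)) {
    if (length(surv[[i]]$times) == 0L) {
      stop("combination ", cohorts$label[i], " has no cases", call. = FALSE)
    }
    if (sum(surv[[i]]$events) == 0L) {
      warning("combination ", cohorts$label[i],
              " has no events; its Mann-Whitney estimates rest on the censoring tail only",
              call. = FALSE)
    }
    curves[[i]] <- km_estimate(surv[[i]]$times, surv[[i]]$events)
  }
  theta <- matrix(0.5, n, n, dimnames = list(cohorts$label, cohorts$label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      est <- .mw_from_curves(curves[[i]], curves[[j]])
      theta[i, j] <- est$theta
      theta[j, i] <- 1 - est$theta
    }
  }
  d <- initial_dissimilarity(theta)
  diag(d) <- 0
  attr(d, "theta") <- theta
  d
}

#' Partition combinations around medoids
#'
#' Classical two-phase k-medoids: greedy BUILD seeding followed by
#' steepest-descent SWAP until no improving medoid swap remains, minimizing
#' total dissimilarity to the nearest medoid (via [cluster::pam()], which is
#' deterministic for a given dissimilarity matrix). `k = n` is the trivial
#' all-singletons partition with objective zero.
#'
#' @param dissim Symmetric dissimilarity matrix with labels.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer vector of cluster memberships (1..k), with the
#'   attained objective after the BUILD and SWAP phases attached as
#'   attribute `objective`.
#' @export
pam_partition <- function(dissim, k) {
  n <- nrow(dissim)
  if (k < 1 || k > n) stop("k must be between 1 and the number of items", call. = FALSE)
  if (k == n) {
    part <- stats::setNames(seq_len(n), rownames(dissim))
    attr(part, "objective") <- c(build = 0, swap = 0)
    return(part)
  }
  fit <- cluster::pam(stats::as.dist(dissim), k = k, diss = TRUE)
  part <- fit$clustering
  names(part) <- rownames(dissim)
  attr(part, "objective") <- fit$objective
  part
}

#' Ensemble-learned dissimilarities
#'
#' Refines an initial dissimilarity matrix by consensus over repeated PAM
#' partitions: for each of `B` runs a cluster count `k_b` is drawn uniformly
#' from `k_range`, and the learned dissimilarity `delta(i, j)` is the
#' fraction of runs in which i and j fall in different clusters. PAM is
#' deterministic given `k`, so runs sharing a drawn `k` share a partition;
#' the implementation computes one partition per distinct `k` and weights by
#' draw counts, which is identical to the literal loop.
#'
#' @param dissim Initial dissimilarity matrix.
#' @param B Number of ensemble runs (default 1000).
#' @param k_range Integer interval `c(lo, hi)` to draw `k` from; default
#'   `c(2, ceiling(n/2))`.
#' @param seed Integer seed for the k draws.
#' @return Learned dissimilarity matrix in `[0, 1]`, symmetric, zero
#'   diagonal, same labels; `B`, `k_range` and `seed` attached as
#'   attributes.
#' @export
ensemble_learn <- function(dissim, B = 1000L, k_range = NULL, seed = 1L) {
  n <- nrow(dissim)
  if (is.null(k_range)) k_range <- c(2L, max(2L, ceiling(n / 2)))
  stopifnot(B >= 1, length(k_range) == 2,
            2 <= k_range[1], k_range[1] <= k_range[2], k_range[2] <= n - 1)
  kvals <- seq.int(k_range[1], k_range[2])
  ks <- .with_seed(seed, kvals[sample.int(length(kvals), B, replace = TRUE)])
  tab <- table(ks)
  delta <- matrix(0, n, n)
  for (m in seq_along(tab)) {
    k <- as.integer(names(tab)[m])
    part <- pam_partition(dissim, k)
    delta <- delta + as.numeric(tab[m]) * outer(part, part, `!=`)
  }
  delta <- delta / B
  diag(delta) <- 0
  dimnames(delta) <- dimnames(dissim)
  attr(delta, "B") <- B
  attr(delta, "k_range") <- k_range
  attr(delta, "seed") <- seed
  delta
}

# minimax radius of a cluster: the smallest over candidate prototypes of the
# largest dissimilarity from the prototype to any member; members must be
# sorted so prototype ties resolve to the smallest index
.minimax_radius <- function(d, members) {
  sub <- d[members, members, drop = FALSE]
  worst <- apply(sub, 1L, max)
  best <- which.min(worst)
  list(radius = worst[best], prototype = members[best])
}

#' Minimax-linkage hierarchical clustering
#'
#' Agglomerative clustering where the pair of clusters merged at each step
#' is the one whose union has the smallest minimax radius: the radius of the
#' best prototype, i.e. the member minimizing its maximum dissimilarity to
#' all members of the union. The merge height is that radius and the
#' attaining prototype is recorded, so every cluster in the tree carries a
#' representative combination. Ties (equal radii, equal prototypes) resolve
#' to the smallest indices for reproducibility.
#'
#' @param dissim Symmetric labelled dissimilarity matrix (>= 2 items).
#' @return A `minimax_dendrogram`: list with an hclust-style `merge` matrix,
#'   `height`, `prototypes` (one label per merge), `labels` and `order`.
#' @export
minimax_linkage <- function(dissim) {
  n <- nrow(dissim)
  stopifnot(n >= 2, isTRUE(all.equal(dissim, t(dissim), tolerance = 1e-12)))
  labels <- rownames(dissim)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  members <- as.list(seq_len(n))   # member indices per active cluster
  node <- -seq_len(n)              # hclust node code per active cluster
  active <- seq_len(n)
  R <- matrix(Inf, n, n)           # candidate merge radii between active clusters
  P <- matrix(NA_integer_, n, n)   # prototype attaining each candidate radius
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      R[i, j] <- dissim[i, j]
      P[i, j] <- min(i, j)         # either endpoint attains radius d(i,j)
    }
  }

  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  prototypes <- character(n - 1)

  slot <- seq_len(n)               # active slot ids indexing members/node/R
  for (s in seq_len(n - 1)) {
    # find the minimal candidate radius among active pairs (upper triangle)
    sub <- R[slot, slot, drop = FALSE]
    best <- which(sub == min(sub[upper.tri(sub)]), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    a <- slot[best[1]]; b <- slot[best[2]]

    merge[s, ] <- sort(c(node[a], node[b]))
    height[s] <- R[min(a, b), max(a, b)]
    prototypes[s] <- labels[P[min(a, b), max(a, b)]]

    members[[a]] <- sort(c(members[[a]], members[[b]]))
    node[a] <- s
    slot <- setdiff(slot, b)
    for (o in setdiff(slot, a)) {
      cand <- .minimax_radius(dissim, sort(c(members[[a]], members[[o]])))
      R[min(a, o), max(a, o)] <- cand$radius
      P[min(a, o), max(a, o)] <- cand$prototype
    }
  }

  ord <- local({
    walk <- function(k) {
      if (k < 0) return(-k)
      c(walk(merge[k, 1]), walk(merge[k, 2]))
    }
    walk(n - 1)
  })
  structure(list(merge = merge, height = height, prototypes = prototypes,
                 labels = labels, order = ord, method = "minimax"),
            class = "minimax_dendrogram")
}

# member leaf indices of internal node s (1-based merge row)
.node_members <- function(dend, s) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(dend$merge[k, 1]), walk(dend$merge[k, 2]))
  }
  sort(walk(s))
}

#' Cut a minimax dendrogram into groups
#'
#' Undoes the last `n_groups - 1` merges, yielding `n_groups` clusters.
#' Clusters are numbered by the order of their smallest member, and each
#' cluster carries its minimax prototype (the recorded prototype of its top
#' merge; a singleton is its own prototype).
#'
#' @param dend A `minimax_dendrogram`.
#' @param n_groups Number of groups, between 1 and the number of leaves.
#' @return Named integer vector (label -> group), with a named character
#'   vector of per-group prototypes attached as attribute `prototypes`.
#' @export
cut_dendrogram <- function(dend, n_groups) {
  n <- length(dend$labels)
  if (n_groups < 1 || n_groups > n) {
    stop("n_groups must be between 1 and ", n, call. = FALSE)
  }
  assign <- -seq_len(n)            # per-leaf top node code (negative = leaf itself)
  for (s in seq_len(n - n_groups)) {
    assign[.node_members(dend, s)] <- s
  }
  keys <- unique(assign)           # numbered by order of smallest member
  group <- match(assign, keys)
  proto <- vapply(keys, function(k) {
    if (k < 0) dend$labels[-k] else dend$prototypes[k]
  }, character(1))
  names(proto) <- as.character(seq_along(keys))
  out <- stats::setNames(group, dend$labels)
  attr(out, "prototypes") <- proto
  out
}

#' @export
as.hclust.minimax_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "minimax",
                 call = match.call(), dist.method = "mann-whitney"),
            class = "hclust")
}

#' Merge table of a minimax dendrogram
#'
#' Standard linkage-matrix semantics: negative entries are leaves, positive
#' entries reference earlier merges; plus the cluster size and the minimax
#' prototype of every merge.
#'
#' @param dend A `minimax_dendrogram`.
#' @return Data frame with columns `left`, `right`, `height`, `size`,
#'   `prototype`.
#' @export
dendrogram_merge_table <- function(dend) {
  sizes <- vapply(seq_along(dend$height), function(s)
    length(.node_members(dend, s)), integer(1))
  data.frame(left = dend$merge[, 1], right = dend$merge[, 2],
             height = dend$height, size = sizes, prototype = dend$prototypes)
}

#' Newick export of a minimax dendrogram
#'
#' Branch lengths derive from the merge heights (via
#' [ape::as.phylo()] on the hclust representation).
#'
#' @param dend A `minimax_dendrogram`.
#' @return A single Newick string.
#' @export
as_newick <- function(dend) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the ape package is required for Newick export", call. = FALSE)
  }
  ape::write.tree(ape::as.phylo(as.hclust(dend)))
}
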