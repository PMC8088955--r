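# small planted scenario shared by several blocks
three_tier_fixture <- function(n_per = 400, seed = 31) {
  cfg <- planted_tiers_config(k_true = 3, cohorts_per_tier = 3,
                              n_per_cohort = n_per, hazard_ratio = 4,
                              baseline_hazard = 0.01, seed = seed)
  sim <- generate_cases(cfg)
  cohorts <- group_into_combinations(sim$cases, cfg$active_factors)
  list(sim = sim, cohorts = cohorts)
}

test_that("initial matrix is symmetric, zero-diagonal and orders planted tiers", {
  fx <- three_tier_fixture()
  d <- build_initial_matrix(fx$cohorts, fx$sim$cases)
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0, nrow(d)))
  g <- fx$sim$truth$groups[rownames(d)]
  within <- d[g[row(d)] == g[col(d)] & row(d) < col(d)]
  adjacent <- d[abs(g[row(d)] - g[col(d)]) == 1 & row(d) < col(d)]
  far <- d[abs(g[row(d)] - g[col(d)]) == 2 & row(d) < col(d)]
  expect_lt(max(within), min(adjacent))   # tiers separate
  expect_lt(mean(adjacent), mean(far))    # and are ordered
})

test_that("cohorts drawn from one distribution are nearly indistinguishable", {
  set.seed(32)
  df <- data.frame(case_id = sprintf("c%04d", 1:4000),
                   M = factor(rep(c("M0", "M1"), each = 2000),
                              levels = factor_levels()$M))
  cohort <- random_cohort(4000, hazard = 0.03)
  df$survival_months <- as.integer(cohort$times)
  df$event <- cohort$events
  coh <- group_into_combinations(df, "M")
  d <- build_initial_matrix(coh, df)
  expect_lt(d["M0", "M1"], 0.05)
})

test_that("PAM recovers separated blocks and satisfies descent", {
  lab <- sprintf("B%02d", 1:6)
  d <- matrix(0.9, 6, 6, dimnames = list(lab, lab))
  d[1:3, 1:3] <- 0.05; d[4:6, 4:6] <- 0.05
  d <- d + matrix(stats::runif(36, 0, 0.01), 6)  # break exact ties
  d <- (d + t(d)) / 2; diag(d) <- 0
  part <- pam_partition(d, 2)
  expect_equal(unname(part[1:3]), rep(part[[1]], 3))
  expect_equal(unname(part[4:6]), rep(part[[4]], 3))
  expect_false(part[[1]] == part[[4]])

  # k = n: all singletons, zero objective
  pn <- pam_partition(d, 6)
  expect_equal(as.vector(pn), 1:6)
  expect_equal(unname(attr(pn, "objective")["swap"]), 0)
  expect_error(pam_partition(d, 7), "between")

  # SWAP never worsens BUILD
  set.seed(33)
  for (rep in 1:50) {
    m <- random_dissim(sample(5:12, 1))
    obj <- attr(pam_partition(m, sample(2:4, 1)), "objective")
    expect_lte(obj["swap"], obj["build"] + 1e-12)
  }
})

test_that("ensemble dissimilarities are reproducible consensus frequencies", {
  set.seed(34)
  d <- random_dissim(10)
  delta1 <- ensemble_learn(d, B = 150, k_range = c(2, 5), seed = 9)
  delta2 <- ensemble_learn(d, B = 150, k_range = c(2, 5), seed = 9)
  expect_identical(delta1, delta2)                    # bit-for-bit
  expect_true(all(delta1 >= 0 & delta1 <= 1))
  expect_equal(delta1, t(delta1))
  expect_equal(unname(diag(delta1)), rep(0, 10))

  # duplicated item (identical rows, d = 0) is never separated
  d2 <- d
  d2[2, ] <- d2[1, ]; d2[, 2] <- d2[, 1]; d2[1, 2] <- d2[2, 1] <- 0; diag(d2) <- 0
  delta_dup <- ensemble_learn(d2, B = 100, k_range = c(2, 5), seed = 10)
  expect_equal(delta_dup[1, 2], 0)

  # two planted blocks at fixed k = 2: delta is exactly the block indicator
  lab <- sprintf("B%02d", 1:8)
  db <- matrix(0.95, 8, 8, dimnames = list(lab, lab))
  db[1:4, 1:4] <- 0.05; db[5:8, 5:8] <- 0.05; diag(db) <- 0
  delta_b <- ensemble_learn(db, B = 50, k_range = c(2, 2), seed = 11)
  expect_equal(unname(delta_b[1:4, 1:4]), matrix(0, 4, 4))
  expect_equal(unname(delta_b[5:8, 5:8]), matrix(0, 4, 4))
  expect_equal(unname(delta_b[1:4, 5:8]), matrix(1, 4, 4))
})

test_that("monotone transforms preserve the minimax merge sequence", {
  # minimax linkage decides merges by comparing maxima of dissimilarities,
  # so a strictly increasing transform rescales heights without reordering
  # the tree
  set.seed(35)
  for (rep in 1:10) {
    d <- random_dissim(9)
    a <- minimax_linkage(d)
    b <- minimax_linkage(d^2)
    expect_identical(a$merge, b$merge)
    expect_identical(a$prototypes, b$prototypes)
    expect_equal(b$height, a$height^2, tolerance = 1e-12)
  }
})

test_that("monotone transforms preserve PAM partitions of separated structure", {
  # PAM minimizes a sum of dissimilarities, so this invariance is a property
  # of separated data, not of arbitrary matrices
  set.seed(35)
  for (rep in 1:5) {
    lab <- sprintf("B%02d", 1:9)
    d <- matrix(stats::runif(81, 0.7, 0.9), 9, dimnames = list(lab, lab))
    blocks <- split(1:9, rep(1:3, each = 3))
    for (b in blocks) d[b, b] <- stats::runif(9, 0, 0.1)
    d <- (d + t(d)) / 2; diag(d) <- 0
    expect_equal(as.vector(pam_partition(d, 3)), as.vector(pam_partition(d^2, 3)))
  }
})

test_that("minimax linkage reproduces hand-worked merges", {
  # two items: single merge at their distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  dend2 <- minimax_linkage(d2)
  expect_equal(dend2$height, 0.4)

  # three items: {1,2} at 0.1, then all three at 0.9
  lab <- c("x", "y", "z")
  d3 <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3, dimnames = list(lab, lab))
  dend3 <- minimax_linkage(d3)
  expect_equal(dend3$height, c(0.1, 0.9))
  expect_equal(dend3$merge[1, ], c(-2L, -1L))
  cut2 <- cut_dendrogram(dend3, 2)
  expect_equal(as.vector(cut2), c(1L, 1L, 2L))
})

test_that("minimax linkage agrees with brute-force recomputation on small matrices", {
  set.seed(36)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    d <- random_dissim(n)
    dend <- minimax_linkage(d)
    oracle <- brute_minimax_linkage(d)
    expect_equal(dend$height, oracle$height, tolerance = 1e-12)
    expect_equal(dend$prototypes, rownames(d)[oracle$prototype])
    got_members <- lapply(seq_len(n - 1), function(s) eaccd:::.node_members(dend, s))
    expect_equal(got_members, oracle$members)
  }
})

test_that("every recorded prototype certifies its merge height", {
  set.seed(37)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    d <- random_dissim(n)
    dend <- minimax_linkage(d)
    for (s in seq_len(n - 1)) {
      mem <- eaccd:::.node_members(dend, s)
      p <- match(dend$prototypes[s], dend$labels)
      expect_equal(max(d[p, mem]), dend$height[s], tolerance = 1e-12)
      # and no member does better
      radii <- vapply(mem, function(c) max(d[c, mem]), numeric(1))
      expect_equal(min(radii), dend$height[s], tolerance = 1e-12)
    }
  }
})

test_that("cutting undoes merges from the top", {
  set.seed(38)
  d <- random_dissim(7)
  dend <- minimax_linkage(d)
  expect_equal(as.vector(cut_dendrogram(dend, 1)), rep(1L, 7))
  expect_equal(as.vector(cut_dendrogram(dend, 7)), 1:7)
  expect_error(cut_dendrogram(dend, 8), "between")
  expect_error(cut_dendrogram(dend, 0), "between")
  # nested cuts refine: the k-cut never splits a (k-1)-cut class boundary
  for (k in 2:6) {
    coarse <- cut_dendrogram(dend, k)
    fine <- cut_dendrogram(dend, k + 1)
    expect_true(all(tapply(coarse, fine, function(v) length(unique(v))) == 1))
  }
  # prototypes accompany each cluster
  cut3 <- cut_dendrogram(dend, 3)
  expect_length(attr(cut3, "prototypes"), 3)
})

test_that("hclust conversion, merge table and Newick export are consistent", {
  set.seed(39)
  d <- random_dissim(6)
  dend <- minimax_linkage(d)
  h <- as.hclust(dend)
  expect_s3_class(h, "hclust")
  expect_equal(sort(h$order), 1:6)
  tab <- dendrogram_merge_table(dend)
  expect_equal(tab$height, dend$height)
  expect_equal(tab$size[nrow(tab)], 6L)
  skip_if_not_installed("ape")
  nwk <- as_newick(dend)
  expect_match(nwk, "^\\(")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(d))
})
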