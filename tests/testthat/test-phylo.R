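# Likelihood core, tree fitting, exhaustive search, weighted RF, clustering
# and the two-clade topology census.

test_that("single-site stationarity forces logL = log(1/4)", {
  aln <- rbind(a = "A", b = "A")
  tr <- ape::read.tree(text = "(a:0,b:0);")
  p <- gtr_params()
  expect_equal(log_likelihood(aln, tr, p), log(0.25), tolerance = 1e-10)
})

test_that("pruning equals brute-force state summation on 4-taxon trees", {
  set.seed(1)
  for (rep in 1:8) {
    aln <- rand_aln(4, 20)
    tr <- ape::rtree(4, tip.label = rownames(aln))
    tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.6)
    f <- runif(4) + 0.1
    p <- gtr_params(rates = runif(6, 0.3, 3), freqs = f / sum(f))
    expect_lt(abs(log_likelihood(aln, tr, p) - oracle_loglik(aln, tr, p)),
              1e-8)
  }
  # with Gamma rate variation too
  aln <- rand_aln(4, 20)
  tr <- ape::rtree(4, tip.label = rownames(aln))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.4)
  p <- gtr_params(gamma_shape = 0.7)
  rates <- cohesim:::discrete_gamma_rates(0.7, 4)
  by_cat <- vapply(rates, function(r) {
    trr <- tr
    trr$edge.length <- tr$edge.length * r
    exp_ll <- oracle_loglik(aln, trr, gtr_params())
    exp_ll
  }, 0)
  # category-averaged likelihood assembled from the per-category oracle
  site_mix <- function() {
    per_cat <- sapply(rates, function(r) {
      trr <- tr
      trr$edge.length <- tr$edge.length * r
      sapply(seq_len(ncol(aln)), function(s)
        exp(oracle_loglik(aln[, s, drop = FALSE], trr, gtr_params())))
    })
    sum(log(rowMeans(per_cat)))
  }
  expect_lt(abs(log_likelihood(aln, tr, p) - site_mix()), 1e-8)
})

test_that("duplicating all columns doubles the log-likelihood", {
  aln <- rand_aln(5, 30)
  tr <- ape::rtree(5, tip.label = rownames(aln))
  p <- gtr_params()
  expect_equal(log_likelihood(cbind(aln, aln), tr, p),
               2 * log_likelihood(aln, tr, p), tolerance = 1e-9)
})

test_that("gaps act as missing data", {
  aln <- rbind(a = c("A", "-"), b = c("A", "C"))
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  p <- gtr_params()
  expect_equal(log_likelihood(aln, tr, p),
               log_likelihood(aln[, 1, drop = FALSE], tr, p) +
                 log(0.25), tolerance = 1e-9)
  expect_error(log_likelihood(aln, ape::read.tree(text = "(a:1,x:1);"), p),
               "match")
})

test_that("branch-length optimization ascends and recovers simulated lengths", {
  st <- wolbachia_tree()
  p <- sim_params(seed = 6, seq_length = 10000)
  g <- simulate_gene(st, p)
  pp <- gtr_params(p$gtr_rates, p$base_freqs)
  start <- ape::unroot(st$tree)
  start$edge.length <- rep(0.05, nrow(start$edge))
  ll0 <- log_likelihood(g$alignment, start, pp)
  fit <- fit_tree(g$alignment, start, pp, optimize_model = FALSE)
  expect_gt(fit$logL, ll0)
  # recovered internal branch lengths within 15% of truth (10 kb data)
  wtrue <- cohesim:::bipartition_weights(st$tree)
  west <- cohesim:::bipartition_weights(fit$tree)
  for (k in names(wtrue))
    expect_lt(abs(west[[k]] - wtrue[[k]]) / wtrue[[k]], 0.15)
  expect_error(fit_tree(rbind(a = c("-", "-"), b = c("A", "C")),
                        ape::read.tree(text = "(a:1,b:1);"), pp),
               "all-gap")
})

test_that("the exhaustive search enumerates (2n-5)!! topologies", {
  expect_identical(length(cohesim:::all_topologies(paste0("t", 1:6))), 105L)
  expect_identical(length(cohesim:::all_topologies(paste0("t", 1:4))), 3L)
  aln <- rand_aln(9, 10)
  expect_error(exhaustive_ml_search(aln), "8 taxa")
})

test_that("the search recovers a clean 4-taxon tree and reports a full table", {
  st <- wolbachia_tree()
  keep <- c("wMel", "wRi", "wNo", "wPip")
  tr <- ape::keep.tip(st$tree, keep)
  st4 <- species_tree(tr, st$groups[keep])
  g <- simulate_gene(st4, sim_params(seed = 9, seq_length = 2000))
  fit <- exhaustive_ml_search(g$alignment)
  expect_identical(nrow(fit$table), 3L)
  expect_identical(cohesim:::canonical_topology(fit$tree),
                   cohesim:::canonical_topology(tr))
  expect_equal(max(fit$table$logL), fit$logL, tolerance = 1e-3)
})

test_that("weighted RF is a metric-like distance on internal splits", {
  t1 <- census_tree(c("wMel", "wRi"), c("wPip", "wAlbB"))
  expect_identical(weighted_rf(t1, t1), 0)
  t2 <- t1
  # lengthen one internal branch by 0.3
  internal <- which(t2$edge[, 2] > length(t2$tip.label))
  t2$edge.length[internal[2]] <- t2$edge.length[internal[2]] + 0.3
  expect_equal(weighted_rf(t1, t2), 0.3, tolerance = 1e-12)
  set.seed(3)
  for (k in 1:20) {
    a <- ape::rtree(6, tip.label = t1$tip.label)
    b <- ape::rtree(6, tip.label = t1$tip.label)
    expect_equal(weighted_rf(a, b), weighted_rf(b, a))
    expect_gte(weighted_rf(a, b), 0)
  }
  expect_error(weighted_rf(t1, ape::rtree(5)), "leaf set")
})

test_that("weighted RF matches the independent phangorn computation", {
  # equal pendant lengths so the trivial splits phangorn includes cancel
  set.seed(8)
  for (k in 1:5) {
    a <- ape::unroot(ape::rtree(6))
    b <- ape::unroot(ape::rtree(6, tip.label = a$tip.label))
    a$edge.length[a$edge[, 2] <= 6] <- 0.25
    b$edge.length[b$edge[, 2] <= 6] <- 0.25
    expect_equal(weighted_rf(a, b), phangorn::wRF.dist(a, b),
                 tolerance = 1e-9)
  }
})

test_that("tree clustering cuts at the configured height", {
  t1 <- census_tree(c("wMel", "wRi"), c("wPip", "wAlbB"))
  t2 <- census_tree(c("wMel", "wHa"), c("wPip", "wAlbB"))
  same <- cluster_trees(list(t1, t1, t1))
  expect_identical(length(unique(same)), 1L)
  lab <- cluster_trees(list(t1, t1, t2, t2), cutoff = 1.0)
  expect_identical(length(unique(lab)), 2L)
  expect_identical(lab[1], lab[2])
  expect_identical(lab[3], lab[4])
  # label structure invariant under permutation of the input
  lab2 <- cluster_trees(list(t2, t1, t2, t1), cutoff = 1.0)
  expect_identical(lab2[2], lab2[4])
  expect_identical(lab2[1], lab2[3])
  expect_false(lab2[1] == lab2[2])
})

test_that("the census assigns each of the 9 classes and flags incongruence", {
  pairsA <- list(c("wMel", "wRi"), c("wMel", "wHa"), c("wRi", "wHa"))
  pairsB <- list(c("wNo", "wPip"), c("wNo", "wAlbB"), c("wPip", "wAlbB"))
  trees <- list()
  for (pa in pairsA) for (pb in pairsB)
    trees[[length(trees) + 1]] <- census_tree(pa, pb)
  cen <- topology_census(trees, group_A, group_B)
  expect_true(all(cen$counts == 1L))
  expect_identical(cen$incongruent, 0L)
  expect_identical(sum(cen$counts) + cen$incongruent, cen$n)
  # a tree mixing the groups is incongruent
  bad <- ape::read.tree(
    text = "((wMel:1,wNo:1):1,(wRi:1,(wHa:1,(wPip:1,wAlbB:1):1):1):1);")
  cen2 <- topology_census(list(bad), group_A, group_B)
  expect_identical(cen2$incongruent, 1L)
  # support floor: trees without support data fall below the floor
  cen3 <- topology_census(trees[1], group_A, group_B, support_floor = 75)
  expect_identical(cen3$below_floor, 1L)
})

test_that("bootstrap support is high on a long clonal alignment", {
  st <- wolbachia_tree()
  g <- simulate_gene(st, sim_params(seed = 10, seq_length = 5000))
  pp <- gtr_params(sim_params()$gtr_rates, sim_params()$base_freqs)
  fit <- exhaustive_ml_search(g$alignment, p0 = pp, optimize_model = FALSE)
  bt <- bootstrap_support(g$alignment, fit$tree, n_reps = 25, seed = 4,
                          p0 = pp)
  sup <- attr(bt, "support")
  expect_identical(length(sup), 3L)
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(all(sup >= 95))
  # census honours the support floor with real supports attached
  cen <- topology_census(list(bt), group_A, group_B, support_floor = 75)
  expect_identical(cen$below_floor, 0L)
  expect_identical(sum(cen$counts), 1L)
})
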