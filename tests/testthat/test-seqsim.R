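# Synthetic sequence-evolution generator: determinism, limiting behaviour,
# stationarity, tract logging, posterior tracks, proteome fixtures.

test_that("identical seeds reproduce the simulation byte for byte", {
  st <- wolbachia_tree()
  p <- sim_params(seed = 11, rec_rate_within = 2, tract_mean_within = 300)
  g1 <- apply_recombination(simulate_gene(st, p), st, p)
  g2 <- apply_recombination(simulate_gene(st, p), st, p)
  expect_identical(g1$alignment, g2$alignment)
  expect_identical(g1$truth_log, g2$truth_log)
  g3 <- simulate_gene(st, sim_params(seed = 12))
  expect_false(identical(g3$alignment, g1$alignment))
})

test_that("zero branch lengths give identical rows", {
  st <- wolbachia_tree()
  st$tree$edge.length[] <- 0
  g <- simulate_gene(st, sim_params(seed = 1, seq_length = 300))
  expect_true(all(apply(g$alignment, 2, function(col) length(unique(col)) == 1)))
  expect_identical(nrow(g$truth_log), 0L)
})

test_that("saturated branches drive pairwise identity to 1/4", {
  # closed-form GTR saturation limit with equal base frequencies
  tr <- ape::read.tree(text = "(a:10,b:10);")
  st <- species_tree(tr, c(a = "A", b = "B"))
  p <- sim_params(base_freqs = rep(0.25, 4), seq_length = 1e5, seed = 4)
  g <- simulate_gene(st, p)
  ident <- mean(g$alignment["a", ] == g$alignment["b", ])
  expect_lt(abs(ident - 0.25), 0.01)
})

test_that("long simulations converge to the stationary base composition", {
  tr <- ape::read.tree(text = "(a:0.3,b:0.3);")
  st <- species_tree(tr, c(a = "A", b = "B"))
  p <- sim_params(seq_length = 1e5, seed = 8)
  g <- simulate_gene(st, p)
  obs <- table(factor(g$alignment, levels = c("A", "C", "G", "T")))
  chi <- suppressWarnings(stats::chisq.test(obs, p = p$base_freqs))
  expect_gt(chi$p.value, 0.01)
})

test_that("recombination-free params return the gene unchanged", {
  st <- wolbachia_tree()
  p <- sim_params(seed = 3)
  g <- simulate_gene(st, p)
  g2 <- apply_recombination(g, st, p)
  expect_identical(g2$alignment, g$alignment)
  expect_identical(nrow(g2$truth_log), 0L)
})

test_that("logged tract lengths follow the configured geometric mean", {
  # a cheap two-leaf one-group tree: genes much longer than the tracts, so
  # boundary truncation is negligible and the logged lengths estimate the
  # geometric mean directly
  tr <- ape::read.tree(text = "(a:0,b:0);")
  st <- species_tree(tr, c(a = "A", b = "A"))
  lens <- integer()
  for (i in 1:200) {
    p <- sim_params(seed = 100 + i, seq_length = 50000, rec_rate_within = 5,
                    tract_mean_within = 500)
    g <- apply_recombination(simulate_gene(st, p), st, p)
    if (nrow(g$truth_log))
      lens <- c(lens, g$truth_log$end - g$truth_log$start + 1L)
  }
  expect_gt(length(lens), 800)
  expect_lt(abs(mean(lens) - 500) / 500, 0.05)
})

test_that("tract coordinates stay in bounds and are logged 1-based inclusive", {
  st <- wolbachia_tree()
  p <- sim_params(seed = 21, rec_rate_within = 4, rec_rate_between = 2)
  g <- apply_recombination(simulate_gene(st, p), st, p)
  tl <- g$truth_log
  expect_gt(nrow(tl), 0)
  expect_true(all(tl$start >= 1 & tl$end <= p$seq_length & tl$start <= tl$end))
  expect_true(all(tl$type %in% c("within", "between")))
  same_group <- st$groups[tl$donor] == st$groups[tl$recipient]
  expect_identical(unname(same_group), tl$type == "within")
})

test_that("a whole-gene between-clade transfer breaks the two-clade split", {
  st <- wolbachia_tree()
  p <- sim_params(seed = 31)
  g <- simulate_gene(st, p)
  g <- plant_tract(g, st, p, donor = "wNo", recipient = "wRi", start = 1,
                   length = p$seq_length, seed = 1)
  fit <- exhaustive_ml_search(g$alignment,
                              p0 = gtr_params(freqs = p$base_freqs,
                                              rates = p$gtr_rates),
                              optimize_model = FALSE)
  cls <- topology_census(list(fit$tree), group_A, group_B)
  expect_identical(cls$incongruent, 1L)
})

test_that("posterior tracks honour plateaus, backgrounds and bounds", {
  tr <- simulate_posterior_track(100, events = list(c(10, 20, 0.96)),
                                 background_R = 0)
  expect_identical(count_events(tr), 1L)
  expect_true(all(tr$R[c(1:9, 21:100)] == 0))
  expect_true(all(tr$R[10:20] == 0.96))
  tr2 <- simulate_posterior_track(100, events = list(c(10, 20, 0.80)))
  expect_identical(count_events(tr2), 0L)
  tr3 <- simulate_posterior_track(50)
  expect_true(all(tr3$R == 0))
  expect_error(simulate_posterior_track(100,
                                        events = list(c(10, 30, 0.9),
                                                      c(25, 40, 0.9))),
               "overlap")
  # jitter keeps the peak site exactly at the plateau
  tr4 <- simulate_posterior_track(100, events = list(c(10, 20, 0.96)),
                                  jitter = 0.04, seed = 5)
  expect_true(any(tr4$R[10:20] == 0.96))
  expect_true(all(tr4$R[10:20] > 0.91))
})

test_that("proteome fixtures carry a faithful truth table", {
  pr <- simulate_proteomes(n_core = 6, n_specific_per_group = c(A = 4, B = 3),
                           pseudogene_fraction = 0.5, seed = 7)
  expect_identical(sum(pr$truth$class == "core"), 6L)
  expect_identical(sum(pr$truth$class == "A_specific"), 4L)
  expect_identical(sum(pr$truth$class == "B_specific"), 3L)
  # core families present single copy everywhere
  for (fam in pr$truth$family_id[pr$truth$class == "core"]) {
    members <- grep(paste0("\\|", fam, "$"), names(pr$proteins), value = TRUE)
    expect_setequal(sub("\\|.*", "", members), names(pr$genomes))
  }
  # pseudogenized homologs appear only as disrupted cross-hits
  pg <- pr$truth$family_id[pr$truth$pseudogene_in_other]
  for (fam in pg) {
    h <- pr$hits_cross[grepl(fam, pr$hits_cross$gene), ]
    expect_true(all(h$disrupted))
  }
  # proteins translate their CDS (terminal stop dropped)
  i <- sample(seq_along(pr$cds), 5)
  for (k in i) {
    aa <- cohesim:::translate_cds(pr$cds[[k]])
    expect_identical(sub("\\*$", "", aa), pr$proteins[[k]])
  }
})

test_that("zero planted specific families yield zero specific calls", {
  pr <- simulate_proteomes(n_core = 5, n_specific_per_group = 0, seed = 2)
  lens <- setNames(nchar(pr$proteins), names(pr$proteins))
  cl <- mcl_cluster(filter_edges(pr$hits_self, lens),
                    nodes = names(pr$proteins))
  sp <- call_group_specific(cl, presence_from_hits(cl, pr$hits_cross,
                                                   pr$genomes), pr$genomes)
  expect_true(all(sp$counts == 0))
})

test_that("randomized within-group histories keep the A|B split", {
  st <- wolbachia_tree()
  st2 <- randomize_within_groups(st, seed = 5)
  expect_setequal(st2$tree$tip.label, st$tree$tip.label)
  expect_identical(sort(names(st2$groups)[st2$groups == "A"]),
                   sort(group_A))
  # the A|B bipartition is still an edge of the randomized tree
  keys <- cohesim:::bipartition_keys(st2$tree)
  expect_true(cohesim:::split_key(group_A, st2$tree$tip.label) %in% keys)
})
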