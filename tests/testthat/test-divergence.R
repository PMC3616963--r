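# NG86 dN/dS, relative-dS ternary projection, spread, and the rank-sum
# comparison.

test_that("identical sequences give dN = dS = 0", {
  e <- estimate_dn_ds(c("ATGGCTAAATTT", "ATGGCTAAATTT"))
  expect_identical(e$dN, 0)
  expect_identical(e$dS, 0)
})

test_that("NG86 site and difference counting matches hand computation", {
  # TTT (Phe) vs TTA (Leu): one nonsynonymous difference at position 3.
  # Syn sites: TTT -> {TTC syn; TTA, TTG nonsyn} = 1/3; TTA -> third
  # position {TTG syn, TTT/TTC nonsyn} = 1/3 plus first position
  # {CTA syn (Leu)} = 1/3 -> 2/3.
  e <- estimate_dn_ds(c("TTT", "TTA"))
  expect_equal(e$S_sites, (1 / 3 + 2 / 3) / 2)
  expect_equal(e$N_sites, 3 - e$S_sites)
  expect_identical(unname(e$S_diffs), 0)
  expect_identical(unname(e$N_diffs), 1)
  expect_identical(e$dS, 0)
  # the Jukes-Cantor correction at pS = 0.3 (forced by construction):
  # GGT vs GGA is synonymous; S sites for GGN third position = 1 each,
  # plus fractional sites elsewhere - instead check the correction math
  # directly through pS on a long synthetic pair
  expect_equal(-3 / 4 * log(1 - 4 / 3 * 0.3), 0.3831192, tolerance = 1e-6)
})

test_that("estimation is symmetric and path-averaged for multi-hit codons", {
  a <- "ATGACGTGCCTA"
  b <- "ATGGCATGTTTA"
  e1 <- estimate_dn_ds(c(a, b))
  e2 <- estimate_dn_ds(c(b, a))
  expect_equal(e1$dS, e2$dS)
  expect_equal(e1$dN, e2$dN)
  # averaged path counts for a 2-hit codon sum to the number of changes
  d <- cohesim:::ng86_codon_diffs("ACG", "GCA")
  expect_equal(unname(d["syn"] + d["nonsyn"]), 2)
})

test_that("gapped and stop-containing codon columns are excluded pairwise", {
  e <- estimate_dn_ds(rbind(strsplit("ATG---GCT", "")[[1]],
                            strsplit("ATGAAAGCT", "")[[1]]))
  expect_identical(e$dS, 0)
  expect_identical(e$dN, 0)
  e2 <- estimate_dn_ds(c("ATGTAAGCT", "ATGCAAGCT"))  # TAA stop column out
  expect_identical(e2$dN, 0)
})

test_that("relative dS normalizes, embeds and rescales correctly", {
  r <- relative_ds(c(1, 1, 1))
  expect_equal(unname(r$rel), rep(1 / 3, 3))
  expect_equal(unname(r$xy), c(1 / 3 + 1 / 6, sqrt(3) / 6))
  r2 <- relative_ds(c(0.02, 0.01, 0.01))
  expect_equal(unname(r2$rel), c(0.5, 0.25, 0.25))
  r3 <- relative_ds(10 * c(0.02, 0.01, 0.01))
  expect_equal(r2$rel, r3$rel)
  expect_equal(r3$max_abs_dS, 0.2)
  expect_warning(expect_null(relative_ds(c(0, 0, 0))))
})

test_that("spread is zero for coincident points and halves a two-point split", {
  pts <- list(relative_ds(c(1, 2, 3)), relative_ds(c(1, 2, 3)))
  expect_equal(spread(pts), 0)
  m <- rbind(c(0, 0), c(1, 0))
  expect_equal(spread(m, metric = "xy"), 0.5)
  expect_error(spread(list()), "valid")
  # invariant to gene order and global rescaling
  set.seed(2)
  ds <- replicate(30, runif(3, 0.001, 0.2), simplify = FALSE)
  p1 <- lapply(ds, relative_ds)
  p2 <- lapply(rev(ds), function(d) relative_ds(10 * d))
  expect_equal(spread(p1), spread(p2))
})

test_that("clonal genes are less spread than recombining genes", {
  st <- wolbachia_tree()
  clon <- simulate_gene_set(st, sim_params(seed = 5), 40)
  reco <- simulate_gene_set(st, sim_params(seed = 6), 40,
                            history = "randomized_within")
  sA_c <- triple_spread(lapply(clon, `[[`, "alignment"), group_A)$spread
  sA_r <- triple_spread(lapply(reco, `[[`, "alignment"), group_A)$spread
  expect_lt(sA_c, sA_r)
})

test_that("median pairwise dS tracks the true synonymous divergence", {
  # two-taxon trees over a divergence grid: rank correlation ~ 1
  grid <- seq(0.02, 0.4, length.out = 8)
  med <- vapply(seq_along(grid), function(i) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", grid[i] / 2,
                                        grid[i] / 2))
    stg <- species_tree(tr, c(a = "A", b = "B"))
    g <- simulate_gene(stg, sim_params(seed = 50 + i, seq_length = 3000))
    estimate_dn_ds(g$alignment)$dS
  }, 0)
  expect_gt(cor(grid, med, method = "spearman"), 0.95)
})

test_that("the rank-sum comparison matches the exact small-sample law", {
  r <- compare_divergence_by_status(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p.value, 0.1)
  r2 <- compare_divergence_by_status(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r2$p.value, r$p.value)
  same <- compare_divergence_by_status(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)
})
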