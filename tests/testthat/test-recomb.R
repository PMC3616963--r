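# Recombination detectors, ensemble voting, fragment classification, and
# posterior-track post-processing.

test_that("degenerate alignments yield NA or null results", {
  aln <- rbind(a = rep("A", 50), b = rep("A", 50), c = rep("A", 50))
  expect_true(is.na(phi_test(aln)$p.value))
  expect_true(is.na(nss_test(aln)$p.value))
  mc <- maxchi_test(aln, n_perm = 50)
  expect_identical(mc$statistic, 0)
  expect_identical(mc$p.value, 1)
  # a single informative site is not enough
  one <- rbind(a = c("A", "C"), b = c("A", "C"), c = c("A", "A"),
               d = c("A", "A"))
  one[, 1] <- c("C", "C", "A", "A")
  expect_identical(phi_test(one[, 1, drop = FALSE])$n_informative, 1L)
  expect_true(is.na(phi_test(one[, 1, drop = FALSE])$p.value))
})

test_that("permutation p-values respect the add-one bound and fixed seeds", {
  st <- wolbachia_tree()
  g <- simulate_gene(st, sim_params(seed = 3))
  for (f in list(function(s) phi_test(g$alignment, n_perm = 99, seed = s),
                 function(s) nss_test(g$alignment, n_perm = 99, seed = s),
                 function(s) maxchi_test(g$alignment, n_perm = 99, seed = s))) {
    r1 <- f(7); r2 <- f(7); r3 <- f(8)
    expect_identical(r1$p.value, r2$p.value)
    expect_gte(r1$p.value, 1 / 100)
    expect_lte(r1$p.value, 1)
    expect_true(is.numeric(r3$p.value))
  }
})

test_that("a clean mosaic fires NSS and Phi", {
  # two divergent blocks with conflicting binary signal
  set.seed(9)
  blockA <- matrix("A", 4, 60, dimnames = list(c("s1", "s2", "s3", "s4"),
                                               NULL))
  blockA[c("s1", "s2"), seq(1, 60, 2)] <- "T"   # sites split s1s2 | s3s4
  blockB <- matrix("A", 4, 60, dimnames = list(rownames(blockA), NULL))
  blockB[c("s1", "s3"), seq(1, 60, 2)] <- "G"   # sites split s1s3 | s2s4
  aln <- cbind(blockA, blockB)
  expect_lt(nss_test(aln, n_perm = 500, seed = 1)$p.value, 0.01)
  expect_lt(phi_test(aln, n_perm = 500, seed = 1)$p.value, 0.01)
  # perfectly compatible data: NSS is 1 and cannot be exceeded
  nss0 <- nss_test(blockA, n_perm = 200, seed = 2)
  expect_equal(nss0$statistic, 1)
  expect_equal(nss0$p.value, 1)
})

test_that("MaxChi locates the breakpoint of a half-divergent pair", {
  a <- rbind(s1 = strsplit("AAAAAATTTTTT", "")[[1]],
             s2 = strsplit("AAAAAAAAAAAA", "")[[1]])
  mc <- maxchi_test(a, n_perm = 200, seed = 1)
  expect_equal(mc$statistic, 12)     # 2x2 table (6,0 | 0,6) on 12 sites
  expect_identical(mc$best_break, 6L)
  expect_setequal(mc$best_pair, c("s1", "s2"))
})

test_that("MaxChi breakpoints land near planted tract edges", {
  st <- wolbachia_tree()
  hits <- 0; tries <- 0
  for (i in 1:12) {
    p <- sim_params(seed = 800 + i)
    g <- simulate_gene(st, p)
    g <- plant_tract(g, st, p, donor = "wNo", recipient = "wPip",
                     start = 300, length = 500, seed = i)
    mc <- maxchi_test(g$alignment, n_perm = 100, seed = i)
    tries <- tries + 1
    if (min(abs(mc$best_break - c(300, 799))) <= 100) hits <- hits + 1
  }
  expect_gte(hits / tries, 0.7)
})

test_that("identical pairs produce one spanning, non-significant fragment", {
  aln <- rbind(a = strsplit("ACGTACGTACGTACGAACG", "")[[1]],
               b = strsplit("ACGTACGTACGTACGAACG", "")[[1]],
               c = strsplit("ATGTACCTACGAACGAACG", "")[[1]],
               d = strsplit("ACCTACGTAGGTACGTACG", "")[[1]])
  gc <- geneconv_fragments(aln, gscale = 1, n_perm = 300, seed = 1)
  ab <- gc$fragments[gc$fragments$seq1 == "a" & gc$fragments$seq2 == "b", ]
  expect_identical(nrow(ab), 1L)
  poly <- cohesim:::polymorphic_columns(cohesim:::detector_states(aln))
  expect_identical(ab$start, min(poly))
  expect_identical(ab$end, max(poly))
  expect_gte(ab$ka_p, 0.5)  # shared identity everywhere is not localized
})

test_that("gscale 0 breaks fragments at any mismatch", {
  # pair a,b match at polymorphic sites except one interior mismatch
  aln <- rbind(a = strsplit("ACGTTTACGTTTACGTTT", "")[[1]],
               b = strsplit("ACGTTTACCTTTACGTTT", "")[[1]],
               c = strsplit("AAATTTAAATTTAAATTT", "")[[1]])
  gc0 <- geneconv_fragments(aln, gscale = 0, n_perm = 100, seed = 2)
  ab <- gc0$fragments[gc0$fragments$seq1 == "a" & gc0$fragments$seq2 == "b", ]
  expect_identical(nrow(ab), 2L)  # split by the mismatch at column 9
  expect_true(all(ab$end < 9 | ab$start > 9))
  expect_identical(geneconv_fragments(matrix("A", 3, 30,
                                             dimnames = list(c("a", "b", "c"),
                                                             NULL)))$n_polymorphic,
                   0L)
})

test_that("planted tracts are detected and attributed to the right pair", {
  st <- wolbachia_tree()
  det <- 0
  for (i in 1:10) {
    p <- sim_params(seed = 860 + i)
    g <- simulate_gene(st, p)
    g <- plant_tract(g, st, p, donor = "wNo", recipient = "wPip",
                     start = 200, length = 500, seed = i)
    gc <- geneconv_fragments(g$alignment, gscale = 1, n_perm = 1000,
                             seed = i)
    f <- gc$fragments[gc$fragments$ka_p < 0.05, , drop = FALSE]
    if (nrow(f) && any((f$seq1 == "wNo" & f$seq2 == "wPip") |
                       (f$seq1 == "wPip" & f$seq2 == "wNo")))
      det <- det + 1
  }
  expect_gte(det, 8)
})

test_that("ensemble voting counts methods at their own rules", {
  expect_identical(ensemble_vote(0.001, 0.005, 1e-4, TRUE)$tier, 4L)
  expect_identical(ensemble_vote(0.05, 0.005, 1e-4, TRUE)$tier, 3L)
  expect_identical(ensemble_vote(NA, NA, NA, FALSE)$tier, 0L)
})

test_that("fragments classify by the group membership of the pair", {
  frags <- data.frame(seq1 = c("wRi", "wHa", "wPip"),
                      seq2 = c("wHa", "wNo", "wAlbB"),
                      length = c(500L, 120L, 400L))
  groups <- wolbachia_tree()$groups
  cl <- classify_fragments(frags, groups)
  expect_identical(cl$fragments$class, c("within_A", "between", "within_B"))
  expect_identical(sort(cl$summary$class), c("between", "within_A",
                                             "within_B"))
  expect_error(classify_fragments(data.frame(seq1 = "xx", seq2 = "wNo",
                                             length = 1L), groups), "xx")
  empty <- classify_fragments(frags[0, ], groups)
  expect_identical(nrow(empty$summary), 0L)
})

test_that("rm counting applies the (1-R)S and RS rules at 0.95", {
  tr <- data.frame(S = c(1, 1, 1, 0.9), R = c(0.99, 0.01, 0.5, 0.99))
  rc <- rm_counts(tr)
  expect_identical(rc$n_rec, 1L + 0L + 0L + 0L)  # only site 1: RS = 0.99
  expect_identical(rc$n_mut, 1L)                 # only site 2: (1-R)S = 0.99
  tr2 <- data.frame(S = rep(1, 6), R = c(0.99, 0.99, 0.99, 0.99, 0, 0))
  rc2 <- rm_counts(tr2)
  expect_equal(rc2$r_over_m, 2)
  rc3 <- rm_counts(data.frame(S = 0.5, R = 0.5))
  expect_true(is.na(rc3$r_over_m))
  expect_identical(rc3$flags, "undefined_r_over_m")
})

test_that("event counting follows the 0.5-run / 0.95-peak rule", {
  expect_identical(count_events(data.frame(
    R = c(0.2, 0.6, 0.96, 0.7, 0.3, 0.55, 0.8, 0.4))), 1L)
  expect_identical(count_events(data.frame(R = rep(0, 20))), 0L)
  expect_identical(count_events(data.frame(
    R = c(0.96, 0.96, 0.4, 0.96, 0.96))), 2L)
  # brute-force scan comparison over random small tracks
  set.seed(4)
  for (k in 1:30) {
    R <- round(runif(25), 2)
    runs <- 0L
    inrun <- FALSE; peak <- FALSE
    for (x in R) {
      if (x >= 0.5) {
        if (!inrun) { inrun <- TRUE; peak <- FALSE }
        if (x >= 0.95) peak <- TRUE
      } else {
        if (inrun && peak) runs <- runs + 1L
        inrun <- FALSE
      }
    }
    if (inrun && peak) runs <- runs + 1L
    expect_identical(count_events(data.frame(R = R)), runs)
  }
})
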