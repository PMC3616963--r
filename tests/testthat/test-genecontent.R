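# Presence/pseudogene decision rules and group-specific gene calling.

hit <- function(e, fa, id, dis = FALSE)
  data.frame(evalue = e, fraction_aligned = fa, pct_identity = id,
             disrupted = dis)

test_that("presence thresholds follow the two-branch rule", {
  expect_identical(call_presence(hit(1e-6, 0.7, 40)), "present")
  expect_identical(call_presence(hit(1e-22, 0.35, 36)), "present")
  expect_identical(call_presence(hit(1e-22, 0.35, 36, dis = TRUE)),
                   "pseudogene")
  expect_identical(call_presence(hit(1e-6, 0.5, 40)), "absent")   # cov low
  expect_identical(call_presence(hit(1e-4, 0.9, 90)), "absent")   # e high
  expect_identical(call_presence(hit(1e-22, 0.35, 30)), "absent") # id low
  expect_identical(call_presence(NULL), "absent")
  expect_identical(call_presence(hit(1e-6, 0.7, 40)[0, ]), "absent")
  # an intact passing hit wins over a disrupted one
  two <- rbind(hit(1e-6, 0.7, 40, dis = TRUE), hit(1e-8, 0.8, 50))
  expect_identical(call_presence(two), "present")
  expect_error(call_presence(data.frame(evalue = 1)), "malformed")
})

test_that("presence calls are monotone in evalue and coverage", {
  set.seed(5)
  for (k in 1:50) {
    e <- 10^runif(1, -30, 0)
    fa <- runif(1)
    id <- runif(1, 20, 100)
    base <- call_presence(hit(e, fa, id))
    better <- call_presence(hit(e / 10, min(1, fa + 0.1), id))
    if (base == "present") expect_identical(better, "present")
  }
})

test_that("group-specific calling requires absence everywhere outside", {
  groups <- c(A1 = "A", A2 = "A", A3 = "A", B1 = "B", B2 = "B", B3 = "B")
  clusters <- list(paste0(c("A1", "A2", "A3"), "|f1"),
                   paste0(c("A1", "A2", "A3"), "|f2"),
                   paste0(c("A1", "A2"), "|f3"))
  presence <- rbind(
    data.frame(cluster = 1, genome = c("B1", "B2", "B3"),
               status = c("absent", "pseudogene", "absent")),
    data.frame(cluster = 2, genome = c("B1", "B2", "B3"),
               status = c("present", "absent", "absent")),
    data.frame(cluster = 3, genome = c("B1", "B2", "B3"),
               status = "absent"))
  out <- call_group_specific(clusters, presence, groups)
  expect_identical(out$calls$cluster, 1L)        # f2 hit in B1; f3 lacks A3
  expect_identical(unname(out$counts), c(1L, 0L))
  # symmetric under relabelling the groups
  groups2 <- setNames(ifelse(groups == "A", "B", "A"), names(groups))
  out2 <- call_group_specific(clusters, presence, groups2)
  expect_identical(unname(out2$counts), c(0L, 1L))
})

test_that("outgroup genomes must also lack the cluster", {
  groups <- c(A1 = "A", A2 = "A", B1 = "B", D1 = "D")
  clusters <- list(paste0(c("A1", "A2"), "|f1"))
  pres_ok <- data.frame(cluster = 1, genome = c("B1", "D1"),
                        status = c("absent", "pseudogene"))
  pres_bad <- data.frame(cluster = 1, genome = c("B1", "D1"),
                         status = c("absent", "present"))
  expect_identical(call_group_specific(clusters, pres_ok, groups,
                                       focal_groups = c("A", "B"))$counts[["A"]],
                   1L)
  expect_identical(call_group_specific(clusters, pres_bad, groups,
                                       focal_groups = c("A", "B"))$counts[["A"]],
                   0L)
})

test_that("the planted specific counts and pseudogene flags round-trip", {
  for (seed in c(101, 202)) {
    pr <- simulate_proteomes(n_core = 7,
                             n_specific_per_group = c(A = 6, B = 4),
                             pseudogene_fraction = 0.5, seed = seed)
    lens <- setNames(nchar(pr$proteins), names(pr$proteins))
    cl <- mcl_cluster(filter_edges(pr$hits_self, lens),
                      nodes = names(pr$proteins))
    sp <- call_group_specific(cl, presence_from_hits(cl, pr$hits_cross,
                                                     pr$genomes),
                              pr$genomes)
    expect_identical(unname(sp$counts), c(6L, 4L))
    expect_identical(sum(sp$calls$n_pseudogene > 0),
                     sum(pr$truth$pseudogene_in_other))
  }
})

test_that("pseudogene_fraction one annotates every specific call", {
  pr <- simulate_proteomes(n_core = 3, n_specific_per_group = c(A = 5, B = 0),
                           pseudogene_fraction = 1, seed = 9)
  lens <- setNames(nchar(pr$proteins), names(pr$proteins))
  cl <- mcl_cluster(filter_edges(pr$hits_self, lens),
                    nodes = names(pr$proteins))
  sp <- call_group_specific(cl, presence_from_hits(cl, pr$hits_cross,
                                                   pr$genomes), pr$genomes)
  expect_identical(sp$counts[["A"]], 5L)
  expect_true(all(sp$calls$n_pseudogene[sp$calls$group == "A"] > 0))
})

test_that("the combination census partitions k-genome clusters", {
  genomes <- paste0("g", 1:6)
  clusters <- list(paste0(genomes, "|core1"),
                   paste0(c("g1", "g2", "g3"), "|x"),
                   paste0(c("g1", "g2", "g3"), "|y"),
                   paste0(c("g4", "g5", "g6"), "|z"),
                   paste0(c("g1", "g2"), "|two"))
  cc <- combination_census(clusters, genomes, k = 3)
  expect_identical(sum(cc), 3L)
  expect_identical(cc[["g1+g2+g3"]], 2L)
  expect_identical(cc[["g4+g5+g6"]], 1L)
  all_core <- combination_census(clusters[1], genomes, k = 3)
  expect_true(all(all_core == 0L))
})
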