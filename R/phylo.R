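# Maximum-likelihood gene trees for small taxon sets: GTR(+Gamma4) pruning
# likelihood (Rcpp core), per-branch Brent optimization, exhaustive topology
# search, bootstrap support, weighted Robinson-Foulds distances, topology
# clustering, and the two-clade topology census.

# Encode a character alignment matrix (rows = taxa) as pattern-compressed
# integer states (0..3, -1 for gap/ambiguity) plus pattern weights.
encode_alignment <- function(aln) {
  stopifnot(is.matrix(aln), !is.null(rownames(aln)))
  states <- matrix(match(toupper(aln), BASES) - 1L, nrow(aln), ncol(aln))
  states[is.na(states)] <- -1L
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.numeric(table(factor(key, levels = key[first])))
  list(states = states[, first, drop = FALSE], weights = weights,
       labels = rownames(aln))
}

# Order a tree's tips/edges for the C++ core: postorder edge matrix with the
# alignment's row order defining tip numbering.
tree_for_core <- function(tree, labels) {
  if (length(tree$tip.label) > 2) tree <- ape::unroot(tree)
  if (!setequal(tree$tip.label, labels))
    stop("tree leaves do not match alignment rows")
  # renumber tips to match `labels`
  perm <- match(tree$tip.label, labels)
  tree$edge[tree$edge[, 2] <= length(labels), 2] <-
    perm[tree$edge[tree$edge[, 2] <= length(labels), 2]]
  tree$tip.label <- labels
  ape::reorder.phylo(tree, "postorder")
}

#' GTR(+Gamma) log-likelihood of a tree given an alignment
#'
#' Felsenstein pruning over site patterns; discrete-Gamma categories are
#' averaged with equal weights; gaps and ambiguity codes are treated as
#' missing data (all-ones partial likelihood).
#'
#' @param aln Character alignment matrix, rows named by taxa.
#' @param tree [ape::phylo] tree with branch lengths over the same leaves.
#' @param p A [gtr_params] object.
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(aln, tree, p) {
  enc <- encode_alignment(aln)
  tr <- tree_for_core(tree, enc$labels)
  eig <- gtr_eigen(p)
  rates <- discrete_gamma_rates(p$gamma_shape, p$n_categories)
  cpp_gtr_loglik(enc$states, enc$weights, tr$edge, length(enc$labels),
                 tr$edge.length, eig$U, eig$Uinv, eig$values, p$freqs,
                 rates, rep(1 / length(rates), length(rates)))
}

# Internal: optimize branch lengths of one topology. Returns list(tree, logL).
optimize_branch_lengths <- function(enc, tree, p, eig = NULL, rates = NULL,
                                    tol = 1e-6, max_pass = 5) {
  tr <- tree_for_core(tree, enc$labels)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.05, nrow(tr$edge))
  eig <- eig %||% gtr_eigen(p)
  rates <- rates %||% discrete_gamma_rates(p$gamma_shape, p$n_categories)
  fit <- cpp_optimize_blens(enc$states, enc$weights, tr$edge,
                            length(enc$labels), tr$edge.length, eig$U,
                            eig$Uinv, eig$values, p$freqs, rates,
                            rep(1 / length(rates), length(rates)),
                            tol = tol, max_pass = max_pass)
  tr$edge.length <- fit$blen
  list(tree = tr, logL = fit$logL)
}

# Empirical base frequencies of an alignment (gaps ignored), lightly
# regularized away from zero.
empirical_freqs <- function(aln) {
  counts <- table(factor(toupper(aln), levels = BASES))
  f <- (as.numeric(counts) + 1) / (sum(counts) + 4)
  f / sum(f)
}

#' Fit branch lengths and model parameters on a fixed topology
#'
#' Coordinate ascent: per-branch Brent optimization of branch lengths
#' alternating with Nelder-Mead optimization of the GTR exchangeabilities
#' (and Gamma shape when present), until the log-likelihood improves by less
#' than `tol`. Base frequencies are held at their empirical values.
#'
#' @param aln Character alignment matrix.
#' @param tree Fixed topology ([ape::phylo]); branch lengths are used as
#'   starting values when present.
#' @param p0 Starting [gtr_params]; if `NULL`, equal exchangeabilities and
#'   empirical frequencies.
#' @param optimize_model Set `FALSE` to optimize branch lengths only.
#' @param tol Convergence tolerance in log-likelihood units.
#' @return List with `tree` (optimized branch lengths), `params`, `logL`.
#' @export
fit_tree <- function(aln, tree, p0 = NULL, optimize_model = TRUE,
                     tol = 1e-6) {
  if (any(apply(aln, 1, function(r) all(r %in% c("-", "N", "n", "?")))))
    stop("alignment contains an all-gap row")
  enc <- encode_alignment(aln)
  p <- p0 %||% gtr_params(freqs = empirical_freqs(aln))
  fit <- optimize_branch_lengths(enc, tree, p, tol = tol)
  if (optimize_model) {
    for (round in 1:3) {
      before <- fit$logL
      obj <- function(theta) {
        rates <- c(exp(theta[1:5]), 1)
        shape <- if (!is.null(p$gamma_shape)) exp(theta[6]) else NULL
        pp <- gtr_params(rates, p$freqs, shape, p$n_categories)
        -log_likelihood_enc(enc, fit$tree, pp)
      }
      theta0 <- log(p$rates[1:5] / p$rates[6])
      if (!is.null(p$gamma_shape)) theta0 <- c(theta0, log(p$gamma_shape))
      opt <- optim(theta0, obj, method = "Nelder-Mead",
                   control = list(maxit = 300))
      p <- gtr_params(c(exp(opt$par[1:5]), 1), p$freqs,
                      if (!is.null(p$gamma_shape)) exp(opt$par[6]),
                      p$n_categories)
      fit <- optimize_branch_lengths(enc, fit$tree, p, tol = tol)
      if (fit$logL - before < max(tol, 1e-6)) break
    }
  }
  list(tree = fit$tree, params = p, logL = fit$logL)
}

# log-likelihood on an already-encoded alignment (internal fast path)
log_likelihood_enc <- function(enc, tree, p) {
  tr <- tree_for_core(tree, enc$labels)
  eig <- gtr_eigen(p)
  rates <- discrete_gamma_rates(p$gamma_shape, p$n_categories)
  cpp_gtr_loglik(enc$states, enc$weights, tr$edge, length(enc$labels),
                 tr$edge.length, eig$U, eig$Uinv, eig$values, p$freqs,
                 rates, rep(1 / length(rates), length(rates)))
}

# All unrooted binary topologies over the given labels ((2n-5)!! trees).
all_topologies <- function(labels) {
  labels <- sort(labels)
  key <- paste(labels, collapse = ",")
  hit <- .cohesim_cache$topologies[[key]]
  if (!is.null(hit)) return(hit)
  trees <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  if (is.null(.cohesim_cache$topologies))
    .cohesim_cache$topologies <- list()
  .cohesim_cache$topologies[[key]] <- trees
  trees
}

# Postorder edge matrices (tips numbered by sorted label order) for every
# topology over `labels`, cached per leaf set: the exhaustive search hot
# loop uses these directly, bypassing per-call ape reordering.
topology_bank <- function(labels) {
  labels <- sort(labels)
  key <- paste(c("bank", labels), collapse = ",")
  hit <- .cohesim_cache$topologies[[key]]
  if (!is.null(hit)) return(hit)
  trees <- all_topologies(labels)
  bank <- lapply(trees, function(tp) {
    tp <- ape::reorder.phylo(tp, "postorder")
    list(edge = tp$edge, tree = tp)
  })
  .cohesim_cache$topologies[[key]] <- bank
  bank
}

#' Exhaustive maximum-likelihood topology search
#'
#' Enumerates every unrooted binary topology over the alignment's taxa
#' (valid for 4-8 taxa), optimizes branch lengths on each under a shared
#' GTR(+Gamma) model fitted once on a neighbour-joining starting topology,
#' and returns the maximum-likelihood tree plus the full per-topology
#' log-likelihood table. Ties are broken by canonical topology order and
#' flagged.
#'
#' @param aln Character alignment matrix (4-8 rows).
#' @param p0 Optional starting [gtr_params]; when `NULL` the model is
#'   estimated on the NJ topology.
#' @param optimize_model Estimate exchangeabilities on the starting topology
#'   (default `TRUE`); frequencies are always empirical.
#' @param search_pass Branch-length optimization passes per candidate
#'   topology (the best topology is always refitted fully).
#' @return List with `tree`, `logL`, `params`, `table` (topology signature
#'   vs logL), and `tie` (logical).
#' @export
exhaustive_ml_search <- function(aln, p0 = NULL, optimize_model = is.null(p0),
                                 search_pass = 2) {
  n <- nrow(aln)
  if (n < 4 || n > 8) stop("exhaustive search supports 4 to 8 taxa")
  aln <- aln[order(rownames(aln)), , drop = FALSE]
  enc <- encode_alignment(aln)
  if (is.null(p0)) p0 <- gtr_params(freqs = empirical_freqs(aln))
  p <- if (optimize_model)
    fit_tree(aln, nj_start_tree(aln), p0, optimize_model = TRUE)$params
  else p0
  res <- search_encoded(enc, p, search_pass = search_pass, refit = TRUE)
  tab <- data.frame(topology = vapply(all_topologies(enc$labels),
                                      canonical_topology, ""),
                    logL = res$lls, stringsAsFactors = FALSE)
  list(tree = res$tree, logL = res$logL, params = p, table = tab,
       tie = res$tie)
}

# NJ starting topology from JC-corrected distances (ties/zero rows safe).
nj_start_tree <- function(aln) {
  d <- tryCatch({
    D <- ape::dist.dna(ape::as.DNAbin(tolower(aln)), model = "JC69",
                       pairwise.deletion = TRUE)
    D[!is.finite(D)] <- max(D[is.finite(D)], 0.75) + 0.1
    D
  }, error = function(e) NULL)
  if (is.null(d) || any(!is.finite(d)))
    return(all_topologies(rownames(aln))[[1]])
  tr <- ape::njs(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 1e-8
  ape::unroot(tr)
}

#' Bootstrap support by site resampling with exhaustive re-search
#'
#' Resamples alignment columns with replacement, reruns the exhaustive
#' topology search on each replicate (shared model, single optimization
#' pass), and annotates each internal bipartition of `tree` with the
#' percentage of replicate trees containing it.
#'
#' @param aln Character alignment matrix.
#' @param tree The tree to annotate (typically the ML tree); when `NULL` the
#'   ML tree is computed first.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Optional integer seed.
#' @param p0 Optional [gtr_params] shared across replicates.
#' @return `tree` with `node.label` support percentages on internal nodes
#'   and an attribute `support` (named by bipartition key).
#' @export
bootstrap_support <- function(aln, tree = NULL, n_reps = 100, seed = NULL,
                              p0 = NULL) {
  aln <- aln[order(rownames(aln)), , drop = FALSE]
  if (is.null(tree)) tree <- exhaustive_ml_search(aln, p0)$tree
  enc <- encode_alignment(aln)
  if (all(enc$weights == enc$weights[1]) && ncol(enc$states) == 1) {
    # degenerate: identical sequences; star with zero support
    attr(tree, "unresolved") <- TRUE
  }
  p <- p0 %||% fit_tree(aln, tree, optimize_model = TRUE)$params
  keys <- bipartition_keys(tree)
  hits <- setNames(numeric(length(keys)), keys)
  L <- sum(enc$weights)
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      w <- as.numeric(stats::rmultinom(1, L, enc$weights / L))
      enc_b <- list(states = enc$states, weights = w, labels = enc$labels)
      fit_b <- search_encoded(enc_b, p, search_pass = 1)
      kb <- bipartition_keys(fit_b$tree)
      hits[keys %in% kb] <- hits[keys %in% kb] + 1
    }
  })
  support <- 100 * hits / n_reps
  tree <- annotate_support(tree, support)
  attr(tree, "support") <- support
  tree
}

# Exhaustive search over pre-encoded data (rows sorted by label) with a
# fixed model; uses the cached postorder edge bank, so the hot loop is one
# C++ call per topology.
search_encoded <- function(enc, p, search_pass = 1, refit = FALSE,
                           top_k = 8) {
  stopifnot(!is.unsorted(enc$labels))
  eig <- gtr_eigen(p)
  rates <- discrete_gamma_rates(p$gamma_shape, p$n_categories)
  ratew <- rep(1 / length(rates), length(rates))
  bank <- topology_bank(enc$labels)
  ntip <- length(enc$labels)
  opt <- function(i, blen, tol, max_pass, brent_tol) {
    cpp_optimize_blens(enc$states, enc$weights, bank[[i]]$edge, ntip, blen,
                       eig$U, eig$Uinv, eig$values, p$freqs, rates, ratew,
                       tol = tol, max_pass = max_pass, brent_tol = brent_tol)
  }
  # stage 1: coarse ranking of every topology
  lls <- numeric(length(bank))
  blens <- vector("list", length(bank))
  for (i in seq_along(bank)) {
    ne <- nrow(bank[[i]]$edge)
    f <- opt(i, rep(0.05, ne), tol = 0.05, max_pass = 1, brent_tol = 1e-2)
    lls[i] <- f$logL
    blens[[i]] <- f$blen
  }
  # stage 2: refine the leading candidates at search precision
  cand <- order(lls, decreasing = TRUE)[seq_len(min(top_k, length(bank)))]
  for (i in cand) {
    f <- opt(i, blens[[i]], tol = 1e-3, max_pass = max(search_pass, 2),
             brent_tol = 1e-3)
    lls[i] <- f$logL
    blens[[i]] <- f$blen
  }
  best_i <- which.max(lls)
  tie <- sum(abs(lls - lls[best_i]) < 1e-6) > 1
  blen <- blens[[best_i]]
  logL <- lls[best_i]
  if (refit) {
    f <- opt(best_i, blen, tol = 1e-6, max_pass = 5, brent_tol = 1e-4)
    blen <- f$blen
    logL <- f$logL
  }
  tree <- bank[[best_i]]$tree
  tree$edge.length <- blen
  list(tree = tree, logL = logL, lls = lls, tie = tie)
}

# write per-internal-node support values into node.label
annotate_support <- function(tree, support) {
  ntip <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  labs <- rep("", tree$Nnode)
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    side <- desc[[node]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    key <- split_key(side, tree$tip.label)
    if (key %in% names(support))
      labs[node - ntip] <- format(support[[key]], trim = TRUE)
  }
  tree$node.label <- labs
  tree
}

#' Branch-length-weighted Robinson-Foulds distance
#'
#' Sum over the union of internal bipartitions of the absolute difference in
#' bipartition branch lengths, with weight 0 for a bipartition absent from
#' one tree (the unnormalized branch-score variant on internal edges).
#'
#' @param t1,t2 [ape::phylo] trees over identical leaf sets, with branch
#'   lengths.
#' @return Non-negative scalar distance.
#' @export
weighted_rf <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share an identical leaf set")
  w1 <- bipartition_weights(t1)
  w2 <- bipartition_weights(t2)
  keys <- union(names(w1), names(w2))
  a <- ifelse(keys %in% names(w1), w1[keys], 0)
  b <- ifelse(keys %in% names(w2), w2[keys], 0)
  sum(abs(a - b))
}

#' Cluster gene trees by weighted Robinson-Foulds distance
#'
#' Complete-linkage agglomerative clustering on the pairwise weighted-RF
#' matrix, cut at a fixed height.
#'
#' @param trees List of [ape::phylo] trees sharing one leaf set.
#' @param linkage Linkage method (default `"complete"`).
#' @param cutoff Tree height at which the dendrogram is cut (default 1.0).
#' @return Integer cluster labels, one per tree.
#' @export
cluster_trees <- function(trees, linkage = "complete", cutoff = 1.0) {
  n <- length(trees)
  stopifnot(n >= 2)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) D[i, j] <- D[j, i] <- weighted_rf(trees[[i]],
                                                           trees[[j]])
  }
  hc <- hclust(as.dist(D), method = linkage)
  unname(cutree(hc, h = cutoff))
}

#' Topology census over a two-clade (3+3) leaf set
#'
#' Classifies each gene tree by whether the A|B bipartition is present and,
#' if so, which of the three within-A and three within-B resolutions it
#' shows (9 classes), counting all remaining trees as incongruent. With a
#' support floor set, only trees whose internal bipartitions all have
#' support strictly greater than the floor enter the counts; the rest are
#' tallied separately as `below_floor`.
#'
#' @param trees List of [ape::phylo] trees (leaves = `group_A` and `group_B`,
#'   three each). Trees may carry bootstrap supports from
#'   [bootstrap_support()] (attribute `support` or node labels).
#' @param group_A,group_B Character vectors of three leaf labels each.
#' @param support_floor Support percentage floor (strict `>`), or `NULL`.
#' @return Object of class `topology_census`: list with `counts` (named
#'   9-class vector), `incongruent`, `below_floor`, `n`, and per-tree
#'   `classes`.
#' @export
topology_census <- function(trees, group_A, group_B, support_floor = NULL) {
  stopifnot(length(group_A) == 3, length(group_B) == 3)
  class_names <- as.vector(outer(pair_names(group_A), pair_names(group_B),
                                 paste, sep = " & "))
  counts <- setNames(integer(length(class_names)), class_names)
  incongruent <- 0L
  below_floor <- 0L
  classes <- character(length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!setequal(tr$tip.label, c(group_A, group_B)))
      stop("tree leaves must equal group_A union group_B")
    if (!is.null(support_floor)) {
      sup <- attr(tr, "support")
      if (is.null(sup) && !is.null(tr$node.label))
        sup <- suppressWarnings(as.numeric(tr$node.label[tr$node.label != ""]))
      if (is.null(sup) || any(is.na(sup)) || !all(sup > support_floor)) {
        classes[i] <- "below_floor"
        below_floor <- below_floor + 1L
        next
      }
    }
    cl <- classify_topology(tr, group_A, group_B)
    classes[i] <- cl
    if (cl == "incongruent") incongruent <- incongruent + 1L
    else counts[cl] <- counts[cl] + 1L
  }
  structure(list(counts = counts, incongruent = incongruent,
                 below_floor = below_floor, n = length(trees),
                 classes = classes),
            class = "topology_census")
}

pair_names <- function(g) {
  g <- sort(g)
  c(paste(g[1], g[2], sep = "+"), paste(g[1], g[3], sep = "+"),
    paste(g[2], g[3], sep = "+"))
}

# class of one tree: "<pairA> & <pairB>" or "incongruent"
classify_topology <- function(tree, group_A, group_B) {
  tree <- ape::unroot(tree)
  if (!ape::is.binary(tree)) return("incongruent")
  keys <- bipartition_keys(tree)
  all_tips <- tree$tip.label
  split_ab <- split_key(sort(group_A), all_tips)
  if (!(split_ab %in% keys)) return("incongruent")
  sister_pair <- function(group) {
    prs <- combn(sort(group), 2, simplify = FALSE)
    for (pr in prs) {
      if (split_key(pr, all_tips) %in% keys)
        return(paste(pr[1], pr[2], sep = "+"))
    }
    NA_character_
  }
  pa <- sister_pair(group_A)
  pb <- sister_pair(group_B)
  if (is.na(pa) || is.na(pb)) return("incongruent")
  paste(pa, pb, sep = " & ")
}

#' @export
print.topology_census <- function(x, ...) {
  cat("Topology census over", x$n, "trees\n")
  cat("  split-respecting:", sum(x$counts), "\n")
  for (nm in names(x$counts)) cat(sprintf("    %-28s %d\n", nm, x$counts[[nm]]))
  cat("  incongruent:", x$incongruent, "\n")
  if (x$below_floor > 0) cat("  below support floor:", x$below_floor, "\n")
  invisible(x)
}
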