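# Independent oracles and tiny fixture builders shared across the suite.

# Brute-force GTR(+site-independence) log-likelihood: sum over all internal
# state assignments, product of transition probabilities along edges.
# Independent of the pruning core (no shared code path).
oracle_loglik <- function(aln, tree, p) {
  eig <- cohesim:::gtr_eigen(p)
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  states <- match(aln, c("A", "C", "G", "T"))
  dim(states) <- dim(aln)
  states <- states[match(tr$tip.label, rownames(aln)), , drop = FALSE]
  ntip <- nrow(aln)
  nn <- max(tr$edge)
  P <- lapply(seq_len(nrow(tr$edge)), function(i)
    cohesim:::gtr_prob_matrix(eig, tr$edge.length[i]))
  ints <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(1:4), length(ints))))
  ll <- 0
  for (s in seq_len(ncol(states))) {
    tot <- 0
    for (r in seq_len(nrow(grid))) {
      st <- integer(nn)
      st[seq_len(ntip)] <- states[, s]
      st[ints] <- grid[r, ]
      pr <- p$freqs[st[ntip + 1]]
      for (i in seq_len(nrow(tr$edge)))
        pr <- pr * P[[i]][st[tr$edge[i, 1]], st[tr$edge[i, 2]]]
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}

# Exhaustive affine-gap global alignment score by memoized recursion over
# (i, j, state); gap of length L costs open + L * extend, terminal gaps
# included (matching the global pairwise_align contract).
oracle_align_score <- function(a, b, open = 10, extend = 4) {
  B <- cohesim:::blosum62()
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  NEG <- -1e9
  memo <- array(NA_real_, c(n + 1, m + 1, 3))  # 1=match,2=gap in b,3=gap in a
  rec <- function(i, j, st) {
    # only the "start" state is reachable at the origin: a gap ending at
    # (0,0) would have skipped its opening penalty
    if (i == 0 && j == 0) return(if (st == 1) 0 else NEG)
    if (i < 0 || j < 0) return(NEG)
    v <- memo[i + 1, j + 1, st]
    if (!is.na(v)) return(v)
    v <- if (st == 1) {
      if (i == 0 || j == 0) NEG
      else max(rec(i - 1, j - 1, 1), rec(i - 1, j - 1, 2),
               rec(i - 1, j - 1, 3)) + B[va[i], vb[j]]
    } else if (st == 2) {
      if (i == 0) NEG
      else max(rec(i - 1, j, 1) - open - extend, rec(i - 1, j, 2) - extend,
               rec(i - 1, j, 3) - open - extend)
    } else {
      if (j == 0) NEG
      else max(rec(i, j - 1, 1) - open - extend,
               rec(i, j - 1, 2) - open - extend, rec(i, j - 1, 3) - extend)
    }
    memo[i + 1, j + 1, st] <<- v
    v
  }
  max(rec(n, m, 1), rec(n, m, 2), rec(n, m, 3))
}

# Minimal independent MCL (loop-based, no shared code) returning the node
# partition as a list of sorted character vectors.
reference_mcl <- function(A, inflation, iters = 200) {
  ids <- rownames(A)
  n <- nrow(A)
  for (i in seq_len(n)) A[i, i] <- max(A[i, ])
  M <- A
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(iters)) {
    E <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      E[i, j] <- sum(M[i, ] * M[, j])
    E <- E ^ inflation
    for (j in seq_len(n)) E[, j] <- E[, j] / sum(E[, j])
    if (max(abs(E - M)) < 1e-8) { M <- E; break }
    M <- E
  }
  adj <- (M > 1e-6) | t(M > 1e-6)
  seen <- rep(FALSE, n)
  out <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- i
    repeat {
      grow <- which(apply(adj[, comp, drop = FALSE], 1, any) & !seen)
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
      seen[comp] <- TRUE
    }
    seen[comp] <- TRUE
    out[[length(out) + 1]] <- sort(ids[comp])
  }
  out[order(vapply(out, `[`, "", 1))]
}

# fixed 6-taxon two-group labels used throughout
group_A <- c("wMel", "wRi", "wHa")
group_B <- c("wNo", "wPip", "wAlbB")

# small random nucleotide alignment
rand_aln <- function(ntaxa, nsites, labels = paste0("t", seq_len(ntaxa))) {
  matrix(sample(c("A", "C", "G", "T"), ntaxa * nsites, replace = TRUE),
         ntaxa, nsites, dimnames = list(labels, NULL))
}

# one tree per census class: ((pA),(other_a)) vs ((pB),(other_b))
census_tree <- function(pair_a, pair_b) {
  oa <- setdiff(group_A, pair_a)
  ob <- setdiff(group_B, pair_b)
  txt <- sprintf("(((%s:1,%s:1):1,%s:1):1,((%s:1,%s:1):1,%s:1):1);",
                 pair_a[1], pair_a[2], oa, pair_b[1], pair_b[2], ob)
  ape::read.tree(text = txt)
}
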