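# Intragenic recombination detectors (Phi, NSS, MaxChi, GENECONV-style
# inner-fragment scan), ensemble voting, fragment classification, and the
# r/m + event-count post-processing of per-site posterior tracks.

# integer state matrix for detector input (0..3, -1 missing)
detector_states <- function(aln) {
  states <- matrix(match(toupper(aln), BASES) - 1L, nrow(aln), ncol(aln))
  states[is.na(states)] <- -1L
  rownames(states) <- rownames(aln)
  states
}

# parsimony-informative columns: >= 2 states each present in >= 2 sequences
informative_columns <- function(states) {
  which(apply(states, 2, function(col) {
    tab <- table(col[col >= 0])
    sum(tab >= 2) >= 2
  }))
}

# polymorphic columns: >= 2 distinct observed states, no missing data
polymorphic_columns <- function(states) {
  which(apply(states, 2, function(col) {
    all(col >= 0) && length(unique(col)) >= 2
  }))
}

#' Phi test for intragenic recombination
#'
#' Mean pairwise incompatibility of parsimony-informative sites whose
#' alignment positions lie within a window (bp), compared against
#' permutations that shuffle which site sits at which position.
#' Recombination makes nearby sites more compatible than distant ones, so
#' significance is the fraction of permutations with a statistic at most
#' the observed one (add-one corrected).
#'
#' @param aln Character alignment matrix.
#' @param window Window width in alignment positions (default 100 bp).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return List with `statistic`, `p.value`, `n_informative`; `p.value` is
#'   `NA` with fewer than 2 informative sites.
#' @export
phi_test <- function(aln, window = 100, n_perm = 1000, seed = NULL) {
  states <- detector_states(aln)
  inf <- informative_columns(states)
  if (length(inf) < 2)
    return(list(statistic = NA_real_, p.value = NA_real_,
                n_informative = length(inf)))
  M <- cpp_incompat_matrix(states[, inf, drop = FALSE])
  res <- with_seed(seed, cpp_phi_perm(M, as.integer(inf),
                                      as.integer(window), n_perm))
  list(statistic = res$stat, p.value = res$p, n_informative = length(inf))
}

#' Neighbour similarity score test
#'
#' Fraction of adjacent informative-site pairs that are compatible;
#' recombination clusters compatible sites, inflating the score relative to
#' site-order permutations (p = fraction of permutations with a score at
#' least the observed one, add-one corrected).
#'
#' @inheritParams phi_test
#' @return List with `statistic`, `p.value`, `n_informative`.
#' @export
nss_test <- function(aln, n_perm = 1000, seed = NULL) {
  states <- detector_states(aln)
  inf <- informative_columns(states)
  if (length(inf) < 2)
    return(list(statistic = NA_real_, p.value = NA_real_,
                n_informative = length(inf)))
  M <- cpp_incompat_matrix(states[, inf, drop = FALSE])
  res <- with_seed(seed, cpp_nss_perm(M, n_perm))
  list(statistic = res$stat, p.value = res$p, n_informative = length(inf))
}

#' MaxChi breakpoint test
#'
#' For every sequence pair, slides a breakpoint along the alignment and
#' computes the 2x2 chi-square of (differ/match) x (left/right window
#' half), using the `window` columns on each side of the breakpoint (the
#' whole alignment when it is shorter than two windows); the statistic is
#' the maximum over pairs and breakpoints, with significance by global
#' site-order permutation.
#'
#' @inheritParams phi_test
#' @param window Half-window width in alignment columns (default 200;
#'   capped at half the alignment length).
#' @return List with `statistic`, `p.value`, `best_pair` (character pair)
#'   and `best_break` (the breakpoint lies after this column).
#' @export
maxchi_test <- function(aln, window = 200, n_perm = 1000, seed = NULL) {
  stopifnot(nrow(aln) >= 2)
  states <- detector_states(aln)
  prs <- combn(nrow(aln), 2)
  diffs <- matrix(0L, ncol(prs), ncol(states))
  for (k in seq_len(ncol(prs))) {
    a <- states[prs[1, k], ]; b <- states[prs[2, k], ]
    diffs[k, ] <- as.integer(a >= 0 & b >= 0 & a != b)
  }
  if (all(diffs == 0))
    return(list(statistic = 0, p.value = 1, best_pair = NULL,
                best_break = NA_integer_))
  w <- min(as.integer(window), ncol(states) %/% 2L)
  res <- with_seed(seed, cpp_maxchi_perm(diffs, w, n_perm))
  bp <- res$best_pair
  list(statistic = res$stat, p.value = res$p,
       best_pair = rownames(aln)[prs[, bp]],
       best_break = res$best_break)
}

#' GENECONV-style global inner fragment scan
#'
#' For every sequence pair, walks the alignment's polymorphic columns
#' scoring +1 where the pair matches and subtracting the mismatch penalty
#' `(total polymorphisms) * gscale / (pair site differences)` where it does
#' not (`gscale = 0`: mismatches break fragments). Maximal-scoring segments
#' are candidate fragments; significance is by permutation of
#' polymorphic-column order with Bonferroni correction across pairs
#' (KA-style), and fragments are reported in original alignment coordinates
#' (1-based inclusive bp).
#'
#' @param aln Character alignment matrix with at least 3 rows.
#' @param gscale Mismatch-penalty scale (the study used 0, 1 and 3).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @param ka_threshold Bonferroni-corrected KA p-value threshold for calling
#'   the gene significant (default 0.05).
#' @return List with `fragments` (data frame seq1, seq2, start, end, length,
#'   score, ka_p), `global_p`, `pass`, `gscale`, `n_polymorphic`.
#' @export
geneconv_fragments <- function(aln, gscale = 1, n_perm = 10000, seed = NULL,
                               ka_threshold = 0.05) {
  stopifnot(nrow(aln) >= 3)
  states <- detector_states(aln)
  poly <- polymorphic_columns(states)
  empty <- data.frame(seq1 = character(), seq2 = character(),
                      start = integer(), end = integer(), length = integer(),
                      score = numeric(), ka_p = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(poly))
    return(list(fragments = empty, global_p = 1, pass = FALSE,
                gscale = gscale, n_polymorphic = 0L))
  sub <- states[, poly, drop = FALSE]
  prs <- combn(nrow(aln), 2)
  np <- ncol(prs)
  m01 <- matrix(0L, np, length(poly))
  penalty <- numeric(np)
  P <- length(poly)
  for (k in seq_len(np)) {
    a <- sub[prs[1, k], ]; b <- sub[prs[2, k], ]
    m01[k, ] <- as.integer(a == b)
    nd <- sum(a != b)
    penalty[k] <- if (gscale == 0 || nd == 0) 1e9 else P * gscale / nd
  }
  res <- with_seed(seed, cpp_geneconv_scan(m01, penalty, as.integer(n_perm)))
  rows <- list()
  for (k in seq_len(np)) {
    fr <- res$frags[[k]]
    if (!nrow(fr)) next
    for (j in seq_len(nrow(fr))) {
      sc <- fr$score[j]
      praw <- (1 + sum(res$permmax[, k] >= sc - 1e-9)) / (n_perm + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        seq1 = rownames(aln)[prs[1, k]], seq2 = rownames(aln)[prs[2, k]],
        start = poly[fr$start_idx[j] + 1L], end = poly[fr$end_idx[j] + 1L],
        score = sc, ka_p = min(1, praw * np), stringsAsFactors = FALSE)
    }
  }
  frags <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(frags)) {
    frags$length <- frags$end - frags$start + 1L
    frags <- frags[order(frags$ka_p, -frags$score), ]
    frags <- frags[, c("seq1", "seq2", "start", "end", "length", "score",
                       "ka_p")]
    rownames(frags) <- NULL
  }
  global_p <- if (nrow(frags)) min(frags$ka_p) else 1
  list(fragments = frags, global_p = global_p,
       pass = nrow(frags) > 0 && any(frags$ka_p < ka_threshold),
       gscale = gscale, n_polymorphic = P)
}

#' Ensemble vote over the four detectors
#'
#' Counts how many of NSS, MaxChi, Phi (p below `alpha`) and the GENECONV
#' rule (any global inner fragment with Bonferroni-corrected KA p < 0.05)
#' support recombination in a gene; `NA` p-values count as non-significant.
#'
#' @param p_nss,p_maxchi,p_phi Detector p-values (may be `NA`).
#' @param geneconv_pass Logical: did the GENECONV rule fire?
#' @param alpha Significance level for the three p-value methods (default
#'   0.01).
#' @return List with `tier` (0-4) and per-method logical `significant`.
#' @export
ensemble_vote <- function(p_nss, p_maxchi, p_phi, geneconv_pass,
                          alpha = 0.01) {
  sig <- c(NSS = isTRUE(p_nss < alpha), MaxChi = isTRUE(p_maxchi < alpha),
           Phi = isTRUE(p_phi < alpha), GENECONV = isTRUE(geneconv_pass))
  list(tier = sum(sig), significant = sig)
}

#' Classify detected fragments by supergroup membership of the pair
#'
#' @param frags Fragment data frame from [geneconv_fragments()] (columns
#'   `seq1`, `seq2`, `length`).
#' @param groups Named character vector mapping genomes to group labels.
#' @return List with `fragments` (class-annotated) and `summary`
#'   (min/median/max length per class).
#' @export
classify_fragments <- function(frags, groups) {
  if (!nrow(frags)) {
    return(list(fragments = cbind(frags, class = character(0)),
                summary = data.frame(class = character(), n = integer(),
                                     min = numeric(), median = numeric(),
                                     max = numeric())))
  }
  unknown <- setdiff(unique(c(frags$seq1, frags$seq2)), names(groups))
  if (length(unknown))
    stop("unlabelled genome(s): ", paste(unknown, collapse = ", "))
  g1 <- groups[frags$seq1]
  g2 <- groups[frags$seq2]
  frags$class <- ifelse(g1 != g2, "between", paste0("within_", g1))
  summ <- do.call(rbind, lapply(split(frags$length, frags$class), function(x)
    data.frame(n = length(x), min = min(x), median = median(x), max = max(x))))
  summ <- cbind(class = rownames(summ), summ)
  rownames(summ) <- NULL
  list(fragments = frags, summary = summ)
}

#' Mutation and recombination counts from a posterior track
#'
#' Applies the per-site rule: a site is a mutation-derived substitution when
#' `(1-R)*S >= threshold` and a recombination-derived substitution when
#' `R*S >= threshold`, with `r/m` their ratio.
#'
#' @param track Data frame with columns `S` and `R` (per-site posterior
#'   probabilities of substitution and recombination).
#' @param threshold Counting threshold (default 0.95, inclusive).
#' @return List with `n_mut`, `n_rec`, `r_over_m` (`NA` and flagged when no
#'   mutation sites qualify).
#' @export
rm_counts <- function(track, threshold = 0.95) {
  stopifnot(all(c("S", "R") %in% names(track)))
  S <- track$S; R <- track$R
  n_mut <- sum((1 - R) * S >= threshold)
  n_rec <- sum(R * S >= threshold)
  list(n_mut = n_mut, n_rec = n_rec,
       r_over_m = if (n_mut == 0) NA_real_ else n_rec / n_mut,
       flags = if (n_mut == 0) "undefined_r_over_m" else character())
}

#' Count recombination events along a posterior track
#'
#' An event is a maximal run of sites whose posterior probability of
#' recombination never drops below 0.5 and which contains at least one site
#' with probability at least 0.95.
#'
#' @param track Data frame with column `R`.
#' @param run_floor Run threshold (default 0.5).
#' @param peak Peak requirement (default 0.95).
#' @return Integer event count.
#' @export
count_events <- function(track, run_floor = 0.5, peak = 0.95) {
  R <- track$R
  above <- R >= run_floor
  if (!any(above)) return(0L)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  n <- 0L
  for (k in which(runs$values)) {
    if (any(R[starts[k]:ends[k]] >= peak)) n <- n + 1L
  }
  n
}

#' Run all four detectors on one gene alignment
#'
#' Convenience wrapper producing the per-gene recombination report used by
#' the pipeline: the three PhiPack-style p-values, the GENECONV rule, and
#' the ensemble tier.
#'
#' @param aln Character alignment matrix.
#' @param gscale gscale setting passed to [geneconv_fragments()].
#' @param n_perm Permutations for Phi/NSS/MaxChi.
#' @param n_perm_geneconv Permutations for the GENECONV scan.
#' @param seed Optional integer seed (offset per detector).
#' @param alpha Ensemble significance level (default 0.01).
#' @return List with `p_values`, `geneconv`, `tier`, `fragments`.
#' @export
recombination_report <- function(aln, gscale = 1, n_perm = 1000,
                                 n_perm_geneconv = 10000, seed = NULL,
                                 alpha = 0.01) {
  s <- function(k) if (is.null(seed)) NULL else seed + k
  phi <- phi_test(aln, n_perm = n_perm, seed = s(1))
  nss <- nss_test(aln, n_perm = n_perm, seed = s(2))
  mc <- maxchi_test(aln, n_perm = n_perm, seed = s(3))
  gc_ <- geneconv_fragments(aln, gscale = gscale, n_perm = n_perm_geneconv,
                            seed = s(4))
  vote <- ensemble_vote(nss$p.value, mc$p.value, phi$p.value, gc_$pass,
                        alpha = alpha)
  list(p_values = c(NSS = nss$p.value, MaxChi = mc$p.value,
                    Phi = phi$p.value),
       geneconv = gc_, tier = vote$tier, fragments = gc_$fragments)
}
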