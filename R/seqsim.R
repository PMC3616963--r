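#' Species tree with clade (group) labels
#'
#' Couples a leaf-labelled phylogeny in substitutions/site with a mapping of
#' each leaf to a group (clade) label, the unit the downstream topology
#' census and recombination classification operate on.
#'
#' @param tree An [ape::phylo] tree with branch lengths (substitutions/site).
#' @param groups Named character vector mapping every tip label to a group
#'   label (e.g. `"A"` / `"B"`).
#' @return An object of class `species_tree` with elements `tree` and
#'   `groups`.
#' @export
species_tree <- function(tree, groups) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("species tree needs branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (!all(tree$tip.label %in% names(groups)))
    stop("every leaf needs exactly one group label")
  groups <- groups[tree$tip.label]
  structure(list(tree = tree, groups = groups), class = "species_tree")
}

#' Default six-strain two-supergroup scenario
#'
#' A fixed 3+3 two-clade species tree mimicking the divergence scales of the
#' six sequenced *Wolbachia* strains: three supergroup-A strains (wMel, wRi,
#' wHa) and three supergroup-B strains (wNo, wPip, wAlbB). Within-group
#' pairwise distances are ~0.015-0.04 (A) and ~0.03-0.07 (B)
#' substitutions/site, matching the reported median synonymous divergences
#' of the two supergroups, and between-group distances are ~0.15.
#'
#' @return A [species_tree] object.
#' @export
wolbachia_tree <- function() {
  txt <- "((wMel:0.02,(wRi:0.0075,wHa:0.0075):0.01):0.06,(wNo:0.035,(wPip:0.015,wAlbB:0.015):0.02):0.06);"
  tr <- ape::read.tree(text = txt)
  species_tree(tr, c(wMel = "A", wRi = "A", wHa = "A",
                     wNo = "B", wPip = "B", wAlbB = "B"))
}

#' Simulation parameters
#'
#' Parameters of the synthetic sequence-evolution generator: a GTR(+Gamma)
#' substitution model, gene length, and tract-recombination settings. Tract
#' lengths are geometric; the default means contrast long within-group
#' tracts (500 bp) with short between-group tracts (120 bp).
#'
#' @param gtr_rates Six GTR exchangeabilities (AC, AG, AT, CG, CT, GT).
#' @param base_freqs Stationary base frequencies (A, C, G, T); the default is
#'   AT-rich as typical for endosymbiont genomes.
#' @param gamma_shape Gamma shape for across-site rate variation, or `NULL`
#'   (default) for homogeneous rates.
#' @param seq_length Gene length in bp (default 999, a codon multiple).
#' @param rec_rate_within,rec_rate_between Expected number of tract-transfer
#'   events per gene with a donor from the same / the other clade.
#' @param tract_mean_within,tract_mean_between Mean tract length in bp of the
#'   geometric tract-length distribution (must be >= 1).
#' @param tract_divergence Substitutions/site separating the transferred
#'   copy from its donor (recent-transfer divergence; small).
#' @param seed Integer seed; all randomness of a generator call flows from
#'   it through a private RNG stream.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(gtr_rates = c(1, 4, 1, 1, 4, 1),
                       base_freqs = c(0.35, 0.15, 0.15, 0.35),
                       gamma_shape = NULL,
                       seq_length = 999L,
                       rec_rate_within = 0,
                       rec_rate_between = 0,
                       tract_mean_within = 500,
                       tract_mean_between = 120,
                       tract_divergence = 0.005,
                       seed = 1L) {
  if (any(gtr_rates <= 0)) stop("GTR rates must be positive")
  if (abs(sum(base_freqs) - 1) > 1e-12) stop("base frequencies must sum to 1")
  if (tract_mean_within < 1 || tract_mean_between < 1)
    stop("tract means must be >= 1")
  if (rec_rate_within < 0 || rec_rate_between < 0)
    stop("recombination rates must be >= 0")
  structure(list(gtr_rates = as.numeric(gtr_rates),
                 base_freqs = as.numeric(base_freqs),
                 gamma_shape = gamma_shape,
                 seq_length = as.integer(seq_length),
                 rec_rate_within = rec_rate_within,
                 rec_rate_between = rec_rate_between,
                 tract_mean_within = tract_mean_within,
                 tract_mean_between = tract_mean_between,
                 tract_divergence = tract_divergence,
                 seed = as.integer(seed)),
            class = "sim_params")
}

BASES <- c("A", "C", "G", "T")

# Evolve integer states (1..4) for time t (already rate-scaled) under the
# eigen-decomposed GTR generator.
evolve_states <- function(states, t, eig) {
  if (t <= 0) return(states)
  P <- gtr_prob_matrix(eig, t)
  out <- states
  for (x in 1:4) {
    idx <- which(states == x)
    if (length(idx))
      out[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[x, ])
  }
  out
}

#' Simulate one gene alignment along a species tree
#'
#' Sites evolve independently under GTR (optionally discrete-Gamma rate
#' variation) along the given tree; the root state is drawn from the
#' stationary distribution. Identical seeds give identical output. The
#' returned object carries an empty truth log; tract recombination is added
#' by [apply_recombination()].
#'
#' @param stree A [species_tree].
#' @param params A [sim_params]; `params$seed` drives all randomness.
#' @return An object of class `simulated_gene`: list with `alignment`
#'   (character matrix, taxa x sites), `truth_log` (data frame), and
#'   `generating_topology` (canonical topology signature).
#' @export
simulate_gene <- function(stree, params) {
  stopifnot(inherits(stree, "species_tree"), inherits(params, "sim_params"))
  p <- gtr_params(params$gtr_rates, params$base_freqs, params$gamma_shape)
  eig <- gtr_eigen(p)
  tree <- stree$tree
  L <- params$seq_length
  ntip <- length(tree$tip.label)
  with_seed(params$seed, {
    cat_rates <- discrete_gamma_rates(params$gamma_shape, p$n_categories)
    site_rates <- if (length(cat_rates) == 1L) rep(1, L) else
      cat_rates[sample.int(length(cat_rates), L, replace = TRUE)]
    tr <- ape::reorder.phylo(tree, "cladewise")
    nnode <- ntip + tr$Nnode
    states <- matrix(NA_integer_, nnode, L)
    root <- ntip + 1L
    states[root, ] <- sample.int(4, L, replace = TRUE, prob = p$freqs)
    rate_groups <- split(seq_len(L), site_rates)
    for (k in seq_len(nrow(tr$edge))) {
      par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]; b <- tr$edge.length[k]
      for (g in rate_groups) {
        r <- site_rates[g[1]]
        states[ch, g] <- evolve_states(states[par, g], b * r, eig)
      }
    }
    aln <- matrix(BASES[states[seq_len(ntip), , drop = FALSE]],
                  ntip, L, dimnames = list(tr$tip.label, NULL))
    structure(list(alignment = aln,
                   truth_log = empty_truth_log(),
                   generating_topology = canonical_topology(tree),
                   site_rates = site_rates),
              class = "simulated_gene")
  })
}

empty_truth_log <- function() {
  data.frame(donor = character(), recipient = character(),
             start = integer(), end = integer(), type = character(),
             stringsAsFactors = FALSE)
}

#' Overlay tract recombination on a simulated gene
#'
#' Draws Poisson numbers of within-clade and between-clade events. Each
#' event picks a recipient leaf, a donor leaf from the appropriate clade, a
#' uniform start and a geometric tract length, and replaces the recipient's
#' tract with the donor's tract re-evolved for `tract_divergence`
#' substitutions/site - i.e. the recipient lineage is regrafted next to the
#' donor tip over the tract. The truth log records every event with 1-based
#' inclusive coordinates.
#'
#' @param gene A [simulated_gene] produced from the same tree.
#' @param stree The [species_tree] used to simulate `gene`.
#' @param params A [sim_params]; rates, tract means and the seed (offset
#'   internally from the simulation stage) are taken from it.
#' @return The modified `simulated_gene` with an extended truth log.
#' @export
apply_recombination <- function(gene, stree, params) {
  stopifnot(inherits(gene, "simulated_gene"))
  if (params$tract_mean_within < 1 || params$tract_mean_between < 1)
    stop("tract means must be >= 1")
  if (params$rec_rate_within == 0 && params$rec_rate_between == 0)
    return(gene)
  p <- gtr_params(params$gtr_rates, params$base_freqs, params$gamma_shape)
  eig <- gtr_eigen(p)
  groups <- stree$groups
  L <- ncol(gene$alignment)
  aln <- gene$alignment
  # separate stream from the substitution stage, still a pure function of
  # the user seed
  with_seed(params$seed + 1000003L, {
    n_w <- rpois(1, params$rec_rate_within)
    n_b <- rpois(1, params$rec_rate_between)
    types <- c(rep("within", n_w), rep("between", n_b))
    log <- gene$truth_log
    for (type in types) {
      recipient <- sample(rownames(aln), 1)
      pool <- if (type == "within")
        setdiff(names(groups)[groups == groups[recipient]], recipient)
      else names(groups)[groups != groups[recipient]]
      donor <- if (length(pool) == 1L) pool else sample(pool, 1)
      m <- if (type == "within") params$tract_mean_within else
        params$tract_mean_between
      len <- 1L + rgeom(1, prob = 1 / m)
      start <- sample.int(L, 1)
      end <- min(L, start + len - 1L)
      idx <- start:end
      donor_states <- match(aln[donor, idx], BASES)
      rates <- gene$site_rates[idx]
      new_states <- donor_states
      # age of the transferred copy: exponential around the configured mean
      # (transfers sample the donor group's wider population, not only the
      # sequenced strain)
      td <- stats::rexp(1, 1 / params$tract_divergence)
      for (r in unique(rates)) {
        sel <- which(rates == r)
        new_states[sel] <- evolve_states(donor_states[sel], td * r, eig)
      }
      aln[recipient, idx] <- BASES[new_states]
      log <- rbind(log, data.frame(donor = donor, recipient = recipient,
                                   start = as.integer(start),
                                   end = as.integer(end), type = type,
                                   stringsAsFactors = FALSE))
    }
    gene$alignment <- aln
    gene$truth_log <- log
    gene
  })
}

#' Plant a single controlled recombination tract
#'
#' Deterministically replaces the recipient's `[start, end]` region with the
#' donor's region re-evolved for `tract_divergence` substitutions/site, and
#' logs the event. Unlike [apply_recombination()] nothing is drawn at
#' random except the re-evolution of the transferred copy; used for
#' controlled power and fragment-size experiments.
#'
#' @param gene A [simulate_gene()] result.
#' @param stree The [species_tree] used to simulate it.
#' @param params The [sim_params] used to simulate it.
#' @param donor,recipient Leaf labels.
#' @param start,length Tract coordinates (1-based; truncated at gene end).
#' @param seed Optional seed for the re-evolution draw.
#' @return The modified `simulated_gene`.
#' @export
plant_tract <- function(gene, stree, params, donor, recipient, start,
                        length, seed = NULL) {
  stopifnot(inherits(gene, "simulated_gene"),
            donor %in% rownames(gene$alignment),
            recipient %in% rownames(gene$alignment))
  L <- ncol(gene$alignment)
  end <- min(L, start + length - 1L)
  idx <- start:end
  p <- gtr_params(params$gtr_rates, params$base_freqs, params$gamma_shape)
  eig <- gtr_eigen(p)
  with_seed(seed, {
    donor_states <- match(gene$alignment[donor, idx], BASES)
    rates <- gene$site_rates[idx]
    new_states <- donor_states
    for (r in unique(rates)) {
      sel <- which(rates == r)
      new_states[sel] <- evolve_states(donor_states[sel],
                                       params$tract_divergence * r, eig)
    }
    gene$alignment[recipient, idx] <- BASES[new_states]
    type <- if (stree$groups[donor] == stree$groups[recipient])
      "within" else "between"
    gene$truth_log <- rbind(gene$truth_log,
                            data.frame(donor = donor, recipient = recipient,
                                       start = as.integer(start),
                                       end = as.integer(end), type = type,
                                       stringsAsFactors = FALSE))
    gene
  })
}

#' Randomize within-group tree histories
#'
#' Permutes the leaf labels within each group of a two-clade species tree,
#' leaving the between-group split untouched, and (optionally) redraws each
#' within-group branch length from an exponential with the original length
#' as mean. Drawing a fresh permutation (and fresh depths) per gene
#' emulates the whole-gene limit of heavy within-group recombination: under
#' free recombination every gene has its own within-group genealogy - both
#' its topology and its coalescence times - while the supergroup split is
#' preserved.
#'
#' @param stree A [species_tree].
#' @param seed Optional integer seed.
#' @param redraw_depths Redraw within-group branch lengths exponentially
#'   (default `TRUE`), emulating coalescent time variation across genes.
#' @return A [species_tree] with randomized within-group history.
#' @export
randomize_within_groups <- function(stree, seed = NULL,
                                    redraw_depths = TRUE) {
  with_seed(seed, {
    tree <- stree$tree
    labs <- tree$tip.label
    for (g in unique(stree$groups)) {
      members <- names(stree$groups)[stree$groups == g]
      pos <- which(labs %in% members)
      labs[pos] <- sample(labs[pos])
    }
    tree$tip.label <- labs
    if (redraw_depths) {
      # redraw each three-leaf within-group subtree from a Kingman
      # coalescent whose depth matches the group's mean pairwise
      # within-group distance in `stree`: first coalescence t1 ~ Exp(mean
      # m), second t2 ~ Exp(mean 3m), with the group mean pairwise
      # divergence (2m + 8m + 8m)/3 = 6m. Group stems stay fixed (they
      # carry the between-group divergence, which within-group
      # recombination does not erase).
      desc <- descendant_tips(tree)
      for (g in unique(stree$groups)) {
        members <- names(stree$groups)[stree$groups == g]
        if (length(members) != 3) next
        dm <- ape::cophenetic.phylo(stree$tree)[members, members]
        m <- mean(dm[upper.tri(dm)]) / 6
        t1 <- stats::rexp(1, 1 / m)
        t2 <- stats::rexp(1, 1 / (3 * m))
        for (k in seq_len(nrow(tree$edge))) {
          below <- desc[[tree$edge[k, 2]]]
          if (!all(stree$groups[below] == g) ||
              length(below) >= length(members)) next
          tree$edge.length[k] <-
            if (length(below) == 2) t2            # inner edge
            else if (is_sister_leaf(tree, tree$edge[k, 2])) t1
            else t1 + t2                          # outgroup leaf pendant
        }
      }
    }
    species_tree(tree, stree$groups[labs])
  })
}

# TRUE iff `node` is a leaf whose parent has another leaf child of the
# same subtree (i.e. the leaf belongs to the cherry of a 3-leaf subtree)
is_sister_leaf <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node > ntip) return(FALSE)
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  sibs <- tree$edge[tree$edge[, 1] == parent, 2]
  any(sibs <= ntip & sibs != node)
}

#' Simulate a set of genes
#'
#' Convenience wrapper: simulates `n_genes` genes with per-gene seeds derived
#' from `params$seed`, optionally randomizing within-group histories per gene
#' and overlaying tract recombination.
#'
#' @param stree A [species_tree].
#' @param params A [sim_params].
#' @param n_genes Number of genes.
#' @param history `"clonal"` (every gene follows `stree`) or
#'   `"randomized_within"` (per-gene within-group leaf permutation).
#' @param recombination If `TRUE`, [apply_recombination()] is applied to
#'   every gene with the rates in `params`.
#' @return List of [simulate_gene()] objects.
#' @export
simulate_gene_set <- function(stree, params, n_genes,
                              history = c("clonal", "randomized_within"),
                              recombination = FALSE) {
  history <- match.arg(history)
  lapply(seq_len(n_genes), function(i) {
    pi_ <- params
    pi_$seed <- (params$seed + 7919L * i) %% .Machine$integer.max
    st <- if (history == "randomized_within")
      randomize_within_groups(stree, seed = pi_$seed + 31L) else stree
    g <- simulate_gene(st, pi_)
    if (recombination) g <- apply_recombination(g, st, pi_)
    g
  })
}

#' Simulate a per-site posterior track
#'
#' Builds a per-site track of posterior probabilities of substitution (S)
#' and recombination (R) with plateau-shaped recombination events, the input
#' shape the r/m post-processing consumes.
#'
#' @param n_sites Number of sites.
#' @param events List of events, each `c(start, end, plateau_R)` (or a list
#'   with those elements), 1-based inclusive, non-overlapping.
#' @param background_R Baseline R outside events.
#' @param S_values Per-site substitution posteriors (recycled if length 1).
#' @param seed Optional integer seed (used only when `jitter > 0`).
#' @param jitter Maximum downward jitter applied to plateau values (< 0.05);
#'   the midpoint site of each event always keeps the exact plateau value.
#' @return A data frame with columns `site`, `S`, `R`.
#' @export
simulate_posterior_track <- function(n_sites, events = list(),
                                     background_R = 0, S_values = 1,
                                     seed = NULL, jitter = 0) {
  stopifnot(n_sites >= 1, background_R >= 0, background_R <= 1,
            jitter >= 0, jitter < 0.05)
  S <- rep_len(S_values, n_sites)
  if (any(S < 0 | S > 1)) stop("S values must lie in [0, 1]")
  ev <- lapply(events, function(e) {
    e <- as.numeric(unlist(e)[1:3])
    if (e[1] < 1 || e[2] > n_sites || e[1] > e[2])
      stop("event outside track bounds")
    if (e[3] < 0 || e[3] > 1) stop("plateau_R must lie in [0, 1]")
    e
  })
  if (length(ev) > 1) {
    o <- order(vapply(ev, `[`, 0, 1))
    ev <- ev[o]
    starts <- vapply(ev, `[`, 0, 1); ends <- vapply(ev, `[`, 0, 2)
    if (any(starts[-1] <= ends[-length(ends)]))
      stop("overlapping events are not allowed")
  }
  with_seed(seed, {
    R <- rep(background_R, n_sites)
    for (e in ev) {
      idx <- e[1]:e[2]
      val <- rep(e[3], length(idx))
      if (jitter > 0) {
        val <- pmax(0, e[3] - runif(length(idx), 0, jitter))
        val[ceiling(length(idx) / 2)] <- e[3]
      }
      R[idx] <- val
    }
    data.frame(site = seq_len(n_sites), S = S, R = R)
  })
}
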