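#' Simulate labelled proteome sets with planted group-specific genes
#'
#' Generates protein and CDS sequences for two groups of genomes together
#' with the evidence tables the orthology and gene-content modules consume:
#' a 12-column style within-set homology hit table (members of one family
#' hit each other; unrelated families share no hits) and a cross-group
#' search-hit table emulating tblastn evidence against the other group's
#' genomes. Core families are present single-copy in every genome;
#' group-specific families are present only in one group, except that a
#' fraction of them also persists as a disrupted pseudogene (internal stop
#' or frameshift) in the other group's genomes. A truth table records every
#' family's class.
#'
#' @param n_per_group Named counts of genomes per group, e.g. `c(A=3, B=3)`.
#' @param n_core Number of single-copy core families shared by all genomes.
#' @param n_specific_per_group Number of group-specific families per group;
#'   a single count or a named vector like `c(A=33, B=24)`.
#' @param pseudogene_fraction Fraction of group-specific families present as
#'   pseudogenes in the other group.
#' @param seed Integer seed.
#' @param mut_rate Per-codon replacement probability separating family
#'   members (keeps members alignable while unrelated families are random).
#' @return List with `proteins`, `cds` (named character vectors, names
#'   `genome|gene_id`), `truth`, `hits_self`, `hits_cross`, `genomes`.
#' @export
simulate_proteomes <- function(n_per_group = c(A = 3, B = 3),
                               n_core = 20,
                               n_specific_per_group = c(A = 33, B = 24),
                               pseudogene_fraction = 0.25,
                               seed = 1L,
                               mut_rate = 0.03) {
  stopifnot(all(n_per_group >= 0), n_core >= 0,
            pseudogene_fraction >= 0, pseudogene_fraction <= 1)
  grps <- names(n_per_group)
  if (is.null(grps)) stop("n_per_group must be named by group")
  if (length(n_specific_per_group) == 1L)
    n_specific_per_group <- setNames(rep(n_specific_per_group, length(grps)), grps)
  genomes <- unlist(lapply(grps, function(g)
    setNames(rep(g, n_per_group[[g]]), paste0(g, seq_len(n_per_group[[g]])))))
  ct <- codon_table()
  with_seed(seed, {
    fams <- list()
    fam_id <- 0L
    add_family <- function(class, carriers, pseudo_in) {
      fam_id <<- fam_id + 1L
      L <- sample(80:200, 1)
      anc <- c("ATG", sample(ct$sense, L - 1, replace = TRUE))
      fams[[fam_id]] <<- list(id = sprintf("fam%04d", fam_id), class = class,
                              carriers = carriers, pseudo_in = pseudo_in,
                              ancestor = anc)
    }
    for (i in seq_len(n_core)) add_family("core", names(genomes), character())
    for (g in grps) {
      others <- names(genomes)[genomes != g]
      own <- names(genomes)[genomes == g]
      n_spec <- n_specific_per_group[[g]]
      n_pseudo <- round(pseudogene_fraction * n_spec)
      pseudo_flags <- sample(rep(c(TRUE, FALSE),
                                 c(n_pseudo, n_spec - n_pseudo)))
      for (i in seq_len(n_spec))
        add_family(paste0(g, "_specific"), own,
                   if (pseudo_flags[i]) others else character())
    }
    proteins <- character(); cds <- character()
    truth <- do.call(rbind, lapply(fams, function(f)
      data.frame(family_id = f$id, class = f$class,
                 pseudogene_in_other = length(f$pseudo_in) > 0,
                 stringsAsFactors = FALSE)))
    members <- list()  # per family: named list genome -> codon vector
    for (f in fams) {
      mem <- list()
      for (gn in f$carriers) {
        codons <- f$ancestor
        flip <- which(runif(length(codons) - 1) < mut_rate) + 1L
        if (length(flip))
          codons[flip] <- sample(ct$sense, length(flip), replace = TRUE)
        mem[[gn]] <- codons
        gid <- paste0(gn, "|", f$id)
        cds[gid] <- paste(c(codons, "TAA"), collapse = "")
        proteins[gid] <- paste(ct$aa[codons], collapse = "")
      }
      members[[f$id]] <- mem
    }
    # within-set homology hits (12-column tabular dialect)
    hs <- list()
    for (f in fams) {
      ids <- paste0(f$carriers, "|", f$id)
      if (length(ids) < 2) next
      prs <- combn(ids, 2)
      for (k in seq_len(ncol(prs))) {
        a <- prs[1, k]; b <- prs[2, k]
        pa <- strsplit(proteins[[a]], "")[[1]]
        pb <- strsplit(proteins[[b]], "")[[1]]
        pid <- round(100 * mean(pa == pb), 2)
        len <- length(pa)
        row <- data.frame(qseqid = a, sseqid = b, pident = pid, length = len,
                          mismatch = sum(pa != pb), gapopen = 0L,
                          qstart = 1L, qend = len, sstart = 1L, send = len,
                          evalue = 1e-60,
                          bitscore = round(2 * len * pid / 100, 1),
                          stringsAsFactors = FALSE)
        hs[[length(hs) + 1L]] <- row
        rev <- row
        rev$qseqid <- b; rev$sseqid <- a
        hs[[length(hs) + 1L]] <- rev
      }
    }
    hits_self <- if (length(hs)) do.call(rbind, hs) else
      utils::head(data.frame(qseqid = "", sseqid = "", pident = 0, length = 0L,
                             mismatch = 0L, gapopen = 0L, qstart = 0L,
                             qend = 0L, sstart = 0L, send = 0L, evalue = 0,
                             bitscore = 0), 0)
    # cross-group tblastn-style evidence for group-confined families
    hc <- list()
    for (f in fams) {
      if (f$class == "core") next
      grp <- genomes[f$carriers[1]]
      rep_gene <- paste0(f$carriers[1], "|", f$id)
      outside <- names(genomes)[genomes != grp]
      for (gn in outside) {
        if (gn %in% f$pseudo_in) {
          hc[[length(hc) + 1L]] <- data.frame(
            gene = rep_gene, genome = gn, evalue = 1e-30,
            fraction_aligned = round(runif(1, 0.7, 0.95), 2),
            pct_identity = round(runif(1, 60, 90), 1),
            disrupted = TRUE, stringsAsFactors = FALSE)
        } else if (runif(1) < 0.3) {
          # spurious weak hit below every presence threshold
          hc[[length(hc) + 1L]] <- data.frame(
            gene = rep_gene, genome = gn, evalue = 10^runif(1, -4, -1),
            fraction_aligned = round(runif(1, 0.05, 0.25), 2),
            pct_identity = round(runif(1, 20, 30), 1),
            disrupted = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    hits_cross <- if (length(hc)) do.call(rbind, hc) else
      data.frame(gene = character(), genome = character(), evalue = numeric(),
                 fraction_aligned = numeric(), pct_identity = numeric(),
                 disrupted = logical(), stringsAsFactors = FALSE)
    list(proteins = proteins, cds = cds, truth = truth,
         hits_self = hits_self, hits_cross = hits_cross, genomes = genomes)
  })
}
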