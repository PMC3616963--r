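# Codon-level utilities shared by the proteome generator, the
# back-translation step and the NG86 divergence estimator.

codon_table <- function() {
  if (!is.null(.cohesim_cache$codon_table)) return(.cohesim_cache$codon_table)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  sense <- codons[aa != "*"]
  .cohesim_cache$codon_table <- list(codons = codons, aa = setNames(aa, codons),
                                     sense = sense)
  .cohesim_cache$codon_table
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not a multiple of 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

translate_cds <- function(cds) {
  ct <- codon_table()
  paste(ct$aa[split_codons(cds)], collapse = "")
}

# Fraction of the 9 single-nucleotide neighbours of `codon`, per position,
# that are synonymous; changes to stop codons count as nonsynonymous.
# Returns c(syn_sites, nonsyn_sites) for the codon (NG86 site counting).
ng86_codon_sites <- function(codon) {
  ct <- codon_table()
  aa0 <- ct$aa[[codon]]
  syn <- 0
  for (pos in 1:3) {
    for (b in BASES) {
      if (substr(codon, pos, pos) == b) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (ct$aa[[mut]] == aa0 && ct$aa[[mut]] != "*") syn <- syn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

ng86_sites_table <- function() {
  if (!is.null(.cohesim_cache$ng86_sites)) return(.cohesim_cache$ng86_sites)
  ct <- codon_table()
  tab <- t(vapply(ct$sense, ng86_codon_sites, c(syn = 0, nonsyn = 0)))
  .cohesim_cache$ng86_sites <- tab
  tab
}

# Average numbers of synonymous and nonsynonymous differences between two
# codons over all mutational paths (equal weighting), skipping paths that
# pass through stop codons (all-blocked pairs fall back to including them).
ng86_codon_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  key <- paste(sort(c(c1, c2)), collapse = ":")
  cache <- .cohesim_cache$ng86_diffs
  if (is.null(cache)) cache <- .cohesim_cache$ng86_diffs <- new.env(parent = emptyenv())
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  ct <- codon_table()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- if (length(pos) == 1L) list(pos) else
    lapply(seq_len(factorial(length(pos))), function(i) permn_index(pos, i))
  score_path <- function(ord) {
    cur <- c1; s <- 0; n <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (ct$aa[[nxt]] == "*") return(NULL)
      if (ct$aa[[nxt]] == ct$aa[[cur]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  scored <- Filter(Negate(is.null), lapply(paths, score_path))
  if (!length(scored)) {  # all paths pass a stop; score ignoring the block
    scored <- lapply(paths, function(ord) {
      cur <- c1; s <- 0; n <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (ct$aa[[nxt]] == ct$aa[[cur]] && ct$aa[[nxt]] != "*") s <- s + 1
        else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    })
  }
  m <- colMeans(do.call(rbind, scored))
  out <- c(syn = m[1], nonsyn = m[2])
  cache[[key]] <- out
  out
}

# i-th permutation (1-based) of a small vector, lexicographic order.
permn_index <- function(x, i) {
  n <- length(x)
  i <- i - 1L
  out <- integer(0)
  pool <- x
  for (k in n:1) {
    f <- factorial(k - 1)
    j <- i %/% f
    i <- i %% f
    out <- c(out, pool[j + 1])
    pool <- pool[-(j + 1)]
  }
  out
}
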