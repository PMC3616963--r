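# Protein alignment utilities: global pairwise alignment (affine gaps),
# a small progressive profile aligner for desk-scale families, codon
# back-translation, and the inclusive gap-column pruning rule.

aa_alphabet <- function() c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "-")

blosum62 <- function() {
  if (is.null(.cohesim_cache$blosum62)) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    .cohesim_cache$blosum62 <- get("BLOSUM62", envir = environment())
  }
  .cohesim_cache$blosum62
}

#' Global pairwise protein alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh global alignment maximizing the substitution score
#' minus affine gap costs (a gap of length L costs
#' `gap_open + L * gap_extend`), via [Biostrings::pairwiseAlignment()].
#'
#' @param a,b Protein sequences (non-empty character scalars).
#' @param matrix Substitution matrix name or matrix (default BLOSUM62).
#' @param gap_open,gap_extend Positive gap penalties.
#' @return List with `alignment` (two aligned strings), `score`,
#'   `pct_identity` (over columns where both are aligned) and
#'   `aligned_fraction` (non-gap-aligned columns / length of the shorter
#'   sequence).
#' @export
pairwise_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 4) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  sm <- if (is.matrix(matrix)) matrix else blosum62()
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend)
  s1 <- as.character(Biostrings::alignedPattern(pa))
  s2 <- as.character(Biostrings::alignedSubject(pa))
  v1 <- strsplit(s1, "")[[1]]
  v2 <- strsplit(s2, "")[[1]]
  both <- v1 != "-" & v2 != "-"
  list(alignment = c(s1, s2), score = Biostrings::score(pa),
       pct_identity = 100 * sum(v1 == v2 & both) / max(1, sum(both)),
       aligned_fraction = sum(both) / min(nchar(a), nchar(b)))
}

# k-mer (k=3) count distance between two sequences (guide-tree metric)
kmer_distance <- function(a, b, k = 3) {
  km <- function(s) {
    n <- nchar(s)
    if (n < k) return(table(s))
    table(substring(s, 1:(n - k + 1), k:n))
  }
  ta <- km(a); tb <- km(b)
  keys <- union(names(ta), names(tb))
  ca <- as.numeric(ta[keys]); ca[is.na(ca)] <- 0
  cb <- as.numeric(tb[keys]); cb[is.na(cb)] <- 0
  1 - sum(pmin(ca, cb)) / max(1, min(sum(ca), sum(cb)))
}

# profile = alphabet x columns frequency matrix (alphabet from aa_alphabet)
seq_profile <- function(rows) {
  alpha <- aa_alphabet()
  mat <- do.call(rbind, strsplit(rows, ""))
  prof <- apply(mat, 2, function(col) {
    tabulate(match(col, alpha), nbins = length(alpha))
  })
  prof / length(rows)
}

# affine-gap global alignment of two profiles; returns aligned column index
# vectors (0 = gap) for the two sides
profile_align <- function(profA, profB, gap_open = 10, gap_extend = 1) {
  B <- blosum62()
  alpha <- aa_alphabet()
  aa <- setdiff(alpha, "-")
  S <- t(profA[match(aa, alpha), , drop = FALSE]) %*%
    B[aa, aa] %*% profB[match(aa, alpha), , drop = FALSE]
  m <- ncol(profA); n <- ncol(profB)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(n + 1)) Y[1, j] <- -gap_open - gap_extend * (j - 1)
  for (i in 2:(m + 1)) X[i, 1] <- -gap_open - gap_extend * (i - 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        S[i - 1, j - 1]
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
    }
  }
  # traceback (prefer M, then X, then Y for determinism)
  ia <- integer(0); ib <- integer(0)
  i <- m + 1; j <- n + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  while (i > 1 || j > 1) {
    if (state == 1) {
      ia <- c(i - 1, ia); ib <- c(j - 1, ib)
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      i <- i - 1; j <- j - 1
      state <- which.max(prev)
    } else if (state == 2) {
      ia <- c(i - 1, ia); ib <- c(0, ib)
      from_m <- M[i - 1, j] - gap_open - gap_extend
      state <- if (X[i, j] == from_m || i - 1 == 1) 1 else 2
      i <- i - 1
    } else {
      ia <- c(0, ia); ib <- c(j - 1, ib)
      from_m <- M[i, j - 1] - gap_open - gap_extend
      state <- if (Y[i, j] == from_m || j - 1 == 1) 1 else 3
      j <- j - 1
    }
    if (i == 1 && j == 1) break
    if (i == 1) state <- 3
    if (j == 1) state <- 2
  }
  list(ia = ia, ib = ib)
}

expand_rows <- function(rows, idx) {
  vapply(rows, function(r) {
    v <- strsplit(r, "")[[1]]
    paste(ifelse(idx == 0, "-", v[pmax(idx, 1)]), collapse = "")
  }, "", USE.NAMES = TRUE)
}

#' Progressive multiple alignment of a protein family
#'
#' Builds a guide tree from k-mer distances (neighbour joining; UPGMA-free,
#' deterministic under lexicographic input ordering) and merges profiles in
#' postorder with affine-gap profile alignment under BLOSUM62 expected
#' scores. Intended for small families of closely related sequences;
#' externally produced alignments can be supplied anywhere an alignment is
#' consumed.
#'
#' @param seqs Named character vector of protein sequences (>= 1).
#' @param gap_open,gap_extend Gap penalties for the profile merges.
#' @return Character matrix (rows = sequences, columns = alignment sites).
#' @export
progressive_msa <- function(seqs, gap_open = 10, gap_extend = 1) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  seqs <- seqs[order(names(seqs))]
  if (length(seqs) == 1)
    return(matrix(strsplit(seqs, "")[[1]], 1,
                  dimnames = list(names(seqs), NULL)))
  # guide order: complete-linkage agglomeration on k-mer distances
  # (deterministic; ties broken by the lexicographic input ordering)
  items <- lapply(seq_along(seqs), function(i) {
    list(rows = setNames(as.character(seqs[i]), names(seqs)[i]))
  })
  while (length(items) > 1) {
    n <- length(items)
    best <- c(Inf, 1, 2)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- max(vapply(items[[i]]$rows, function(a)
        max(vapply(items[[j]]$rows, function(b)
          kmer_distance(gsub("-", "", a), gsub("-", "", b)), 0)), 0))
      if (d < best[1] - 1e-12) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    pa <- seq_profile(items[[i]]$rows)
    pb <- seq_profile(items[[j]]$rows)
    al <- profile_align(pa, pb, gap_open, gap_extend)
    rows <- c(expand_rows(items[[i]]$rows, al$ia),
              expand_rows(items[[j]]$rows, al$ib))
    items[[i]] <- list(rows = rows)
    items[[j]] <- NULL
  }
  rows <- items[[1]]$rows[order(names(items[[1]]$rows))]
  do.call(rbind, strsplit(rows, ""))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces every amino acid by its source codon (gaps become `---`). A
#' terminal stop codon in a CDS is tolerated and dropped; internal stops or
#' length mismatches are rejected naming the offending member.
#'
#' @param p Protein alignment matrix (rows named by member).
#' @param cds Named character vector of nucleotide CDS, one per row of `p`.
#' @return Character codon alignment matrix (columns = 3 x protein columns).
#' @export
backtranslate <- function(p, cds) {
  stopifnot(is.matrix(p), all(rownames(p) %in% names(cds)))
  ct <- codon_table()
  out <- matrix("-", nrow(p), 3 * ncol(p),
                dimnames = list(rownames(p), NULL))
  for (m in rownames(p)) {
    if (nchar(cds[[m]]) %% 3 != 0)
      stop("CDS length does not match protein for ", m)
    codons <- split_codons(toupper(cds[[m]]))
    aas <- ct$aa[codons]
    if (!is.na(aas[length(aas)]) && aas[length(aas)] == "*") {
      codons <- codons[-length(codons)]
      aas <- aas[-length(aas)]
    }
    if (any(aas == "*", na.rm = TRUE))
      stop("internal stop codon in CDS of ", m)
    prot <- p[m, ]
    if (sum(prot != "-") * 3 != length(codons) * 3 ||
        length(codons) != sum(prot != "-"))
      stop("CDS length does not match protein for ", m)
    k <- 0L
    for (jj in seq_along(prot)) {
      cols <- (3 * (jj - 1) + 1):(3 * jj)
      if (prot[jj] == "-") next
      k <- k + 1L
      out[m, cols] <- strsplit(codons[k], "")[[1]]
    }
  }
  out
}

#' Prune gap-rich columns from an alignment
#'
#' Removes every column whose gap fraction is greater than or equal to the
#' threshold (inclusive: a 50% gap column is removed at the default). For
#' codon alignments the decision is taken per codon column (triplet), so
#' frame is preserved; remaining column order is unchanged.
#'
#' @param a Character alignment matrix.
#' @param threshold Gap-fraction threshold (default 0.5, inclusive).
#' @param codon Treat `a` as a codon alignment and prune whole triplets.
#' @return The pruned alignment matrix.
#' @export
prune_gap_columns <- function(a, threshold = 0.5, codon = FALSE) {
  stopifnot(is.matrix(a))
  if (!codon) {
    frac <- colMeans(a == "-")
    return(a[, frac < threshold, drop = FALSE])
  }
  if (ncol(a) %% 3 != 0) stop("codon alignment length must be divisible by 3")
  nc <- ncol(a) / 3
  keep <- logical(ncol(a))
  for (j in seq_len(nc)) {
    cols <- (3 * (j - 1) + 1):(3 * j)
    frac <- mean(apply(a[, cols, drop = FALSE] == "-", 1, any))
    keep[cols] <- frac < threshold
  }
  a[, keep, drop = FALSE]
}
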