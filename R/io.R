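# File-format I/O: FASTA (via Biostrings), newick (via ape), 12-column
# tabular hits, and per-site posterior tracks.

#' Read a (multi-)FASTA file
#'
#' @param path File path.
#' @return Named character vector of sequences (wrapped lines and CRLF
#'   endings are handled by the underlying Biostrings parser).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences, or an alignment matrix
#'   (rows are written as sequences).
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.matrix(x)) x <- setNames(apply(x, 1, paste, collapse = ""),
                                  rownames(x))
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), filepath = path,
                              width = width)
  invisible(path)
}

#' Convert between named sequence vectors and alignment matrices
#'
#' @param x Named character vector of equal-length aligned sequences.
#' @return Character matrix (rows = sequences).
#' @export
alignment_matrix <- function(x) {
  stopifnot(length(unique(nchar(x))) == 1)
  do.call(rbind, strsplit(x, ""))
}

#' Read / write newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]; internal
#' node labels carry bootstrap supports.
#'
#' @param path File path.
#' @return For `read_newick`, an [ape::phylo] (or multiPhylo) object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree A phylo or multiPhylo object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read 12-column tabular homology hits
#'
#' The BLAST-style tabular dialect: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore. Malformed rows are
#' rejected with their line number.
#'
#' @param path File path (tab-separated, no header, `#` comments skipped).
#' @return Data frame with the 12 named columns.
#' @export
read_hits_tsv <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^#", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (any(nf != 12)) {
    bad <- which(keep)[which(nf != 12)[1]]
    stop("malformed hits row at line ", bad, ": expected 12 columns, got ",
         nf[which(nf != 12)[1]])
  }
  m <- do.call(rbind, fields)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    pident = as.numeric(m[, 3]),
                    length = as.integer(m[, 4]),
                    mismatch = as.integer(m[, 5]),
                    gapopen = as.integer(m[, 6]),
                    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                    evalue = as.numeric(m[, 11]),
                    bitscore = as.numeric(m[, 12]),
                    stringsAsFactors = FALSE)
  if (any(!complete.cases(out)))
    stop("malformed hits row at line ",
         which(keep)[which(!complete.cases(out))[1]])
  out
}

#' Read / write per-site posterior tracks
#'
#' Tab-separated tracks with columns `site`, `S`, `R` (header included).
#'
#' @param path File path.
#' @return Data frame with columns `site`, `S`, `R`.
#' @export
read_track_tsv <- function(path) {
  tr <- read.table(path, header = TRUE, sep = "\t")
  need <- c("site", "S", "R")
  if (!all(need %in% names(tr)))
    stop("track file must have columns site, S, R")
  if (any(tr$S < 0 | tr$S > 1 | tr$R < 0 | tr$R > 1))
    stop("posterior probabilities must lie in [0, 1]")
  tr[need]
}

#' @rdname read_track_tsv
#' @param track Data frame with columns `site`, `S`, `R`.
#' @export
write_track_tsv <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a truth log of recombination events
#'
#' @param genes List of `simulated_gene` objects.
#' @param path Output path.
#' @return The path, invisibly. Columns: gene_id, donor, recipient, start,
#'   end, type.
#' @export
write_truth_log <- function(genes, path) {
  rows <- lapply(seq_along(genes), function(i) {
    tl <- genes[[i]]$truth_log
    if (!nrow(tl)) return(NULL)
    cbind(gene_id = sprintf("gene%04d", i), tl)
  })
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(tab))
    tab <- data.frame(gene_id = character(), donor = character(),
                      recipient = character(), start = integer(),
                      end = integer(), type = character())
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
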