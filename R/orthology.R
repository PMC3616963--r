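# Homology graph construction with the length/coverage filter, Markov
# clustering of the similarity graph, and single-copy core extraction.

# genome label of a gene id in the `genome|gene` header convention
genome_of <- function(ids) sub("\\|.*$", "", ids)

#' Filter homology edges by length ratio and alignment coverage
#'
#' Keeps an edge iff the shorter protein is at least 60% of the length of
#' the longer one and the alignment covers at least 80% of the shorter
#' protein. Reciprocal hit pairs are merged keeping the best bitscore.
#'
#' @param edges Data frame with columns `qseqid`, `sseqid`, `length`
#'   (alignment columns) and `bitscore` (12-column tabular hits work
#'   directly).
#' @param lengths Named numeric vector of protein lengths (aa) covering all
#'   ids in `edges`.
#' @param min_length_ratio,min_coverage The two thresholds (defaults 0.6 and
#'   0.8, inclusive).
#' @return Data frame of undirected edges: `id1`, `id2` (sorted within
#'   row), `weight` (best bitscore).
#' @export
filter_edges <- function(edges, lengths, min_length_ratio = 0.6,
                         min_coverage = 0.8) {
  ids <- unique(c(edges$qseqid, edges$sseqid))
  unknown <- setdiff(ids, names(lengths))
  if (length(unknown))
    stop("unknown protein length for: ", paste(unknown, collapse = ", "))
  edges <- edges[edges$qseqid != edges$sseqid, , drop = FALSE]
  lq <- lengths[edges$qseqid]
  ls <- lengths[edges$sseqid]
  lmin <- pmin(lq, ls)
  keep <- (lmin / pmax(lq, ls) >= min_length_ratio) &
    (edges$length >= min_coverage * lmin)
  edges <- edges[keep, , drop = FALSE]
  if (!nrow(edges))
    return(data.frame(id1 = character(), id2 = character(),
                      weight = numeric(), stringsAsFactors = FALSE))
  id1 <- pmin(edges$qseqid, edges$sseqid)
  id2 <- pmax(edges$qseqid, edges$sseqid)
  key <- paste(id1, id2, sep = "\r")
  best <- tapply(edges$bitscore, key, max)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  data.frame(id1 = vapply(parts, `[`, "", 1),
             id2 = vapply(parts, `[`, "", 2),
             weight = as.numeric(best), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Markov clustering of a similarity graph
#'
#' Dense MCL: the symmetric weighted adjacency matrix receives self-loops
#' (each node's maximum incident weight), columns are normalized to sum to
#' 1, and expansion (matrix squaring) alternates with inflation
#' (elementwise power and column renormalization) until the maximum
#' columnwise change drops below `tol`. Clusters are the weakly connected
#' components of the attractor matrix; every node lands in exactly one
#' cluster.
#'
#' @param edges Undirected edge data frame (`id1`, `id2`, `weight`), e.g.
#'   from [filter_edges()].
#' @param inflation Inflation exponent (> 1; default 1.5).
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence tolerance (default 1e-6).
#' @param nodes Optional character vector of node ids (adds isolated
#'   nodes absent from `edges`).
#' @return List of clusters (character vectors of member ids), ordered by
#'   smallest member id; attribute `converged`.
#' @export
mcl_cluster <- function(edges, inflation = 1.5, max_iter = 100, tol = 1e-6,
                        nodes = NULL) {
  stopifnot(inflation > 1)
  ids <- sort(unique(c(edges$id1, edges$id2, nodes)))
  n <- length(ids)
  if (n == 0) return(structure(list(), converged = TRUE))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges)) {
    i <- match(edges$id1, ids); j <- match(edges$id2, ids)
    A[cbind(i, j)] <- pmax(A[cbind(i, j)], edges$weight)
    A[cbind(j, i)] <- pmax(A[cbind(j, i)], edges$weight)
  }
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    E <- M %*% M
    E <- E ^ inflation
    E[E < 1e-12] <- 0
    E <- sweep(E, 2, colSums(E), "/")
    delta <- max(abs(E - M))
    M <- E
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge within max_iter; returning current state")
  g <- igraph::graph_from_adjacency_matrix(M > 1e-6, mode = "max")
  comp <- igraph::components(g)$membership
  clusters <- split(ids, comp)
  clusters <- lapply(clusters, sort)
  clusters <- clusters[order(vapply(clusters, `[`, "", 1))]
  structure(unname(clusters), converged = converged)
}

#' Per-genome member counts of a cluster
#'
#' @param cluster Character vector of member ids (`genome|gene`).
#' @param genomes Optional character vector of genome labels to tabulate
#'   over.
#' @return Named integer vector of counts.
#' @export
per_genome_count <- function(cluster, genomes = NULL) {
  g <- genome_of(cluster)
  lv <- genomes %||% sort(unique(g))
  table(factor(g, levels = lv))
}

#' Extract the single-copy core
#'
#' Returns the clusters with exactly one member in every genome of the
#' input set, in stable order by smallest member id.
#'
#' @param clusters List of clusters (character vectors of `genome|gene`
#'   ids).
#' @param genomes Character vector of genome labels that must each be hit
#'   exactly once.
#' @return The filtered list of clusters.
#' @export
extract_single_copy_core <- function(clusters, genomes) {
  keep <- vapply(clusters, function(cl) {
    cnt <- per_genome_count(cl, genomes)
    all(cnt == 1L) && length(cl) == length(genomes)
  }, TRUE)
  core <- clusters[keep]
  core[order(vapply(core, `[`, "", 1))]
}
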