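# Shared small helpers for unrooted tree topology handling (ape::phylo).

# Tip labels on the child side of every internal edge of an unrooted tree.
# Returns a list of character vectors (unsorted sides).
internal_edge_sides <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4) return(list())  # no non-trivial bipartitions
  tree <- ape::unroot(tree)
  internal <- which(tree$edge[, 2] > ntip)
  if (!length(internal)) return(list())
  desc <- descendant_tips(tree)
  lapply(internal, function(i) desc[[tree$edge[i, 2]]])
}

# List mapping every node id to the tip labels below it (tree rooted as stored).
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  out <- vector("list", nnode)
  for (i in seq_len(ntip)) out[[i]] <- tree$tip.label[i]
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

# Canonical string for one bipartition of the full leaf set: the side not
# containing the alphabetically first leaf, sorted and comma-joined.
split_key <- function(side, all_tips) {
  ref <- sort(all_tips)[1]
  if (ref %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = ",")
}

# Canonical keys of all non-trivial bipartitions (internal edges) of a tree.
bipartition_keys <- function(tree) {
  if (length(tree$tip.label) < 4) return(character())
  tree <- ape::unroot(tree)
  all_tips <- tree$tip.label
  sides <- internal_edge_sides(tree)
  sides <- Filter(function(s) length(s) >= 2 && length(s) <= length(all_tips) - 2,
                  sides)
  unique(vapply(sides, split_key, "", all_tips = all_tips))
}

# Canonical topology signature of an unrooted tree: leaf set plus the sorted
# set of bipartition keys. Two trees share a signature iff they share an
# unrooted topology.
canonical_topology <- function(tree) {
  paste(c(paste(sort(tree$tip.label), collapse = ","),
          sort(bipartition_keys(tree))), collapse = ";")
}

# Branch-length weights of non-trivial bipartitions, as a named numeric
# vector keyed by split_key.
bipartition_weights <- function(tree) {
  if (length(tree$tip.label) < 4) return(numeric())
  tree <- ape::unroot(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  all_tips <- tree$tip.label
  ntip <- length(all_tips)
  desc <- descendant_tips(tree)
  w <- numeric(0)
  for (i in seq_len(nrow(tree$edge))) {
    node <- tree$edge[i, 2]
    if (node <= ntip) next
    side <- desc[[node]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    key <- split_key(side, all_tips)
    w[key] <- (if (key %in% names(w)) w[key] else 0) + tree$edge.length[i]
  }
  w
}
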