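# Supergroup-specific gene calling from homology-search evidence: the
# presence/pseudogene decision rules and the per-group census.

#' Presence call for one query against one target genome
#'
#' A hit passes the presence thresholds iff `evalue < 1e-5` with at least
#' 60% of the query protein aligned, or `evalue < 1e-20` with at least 30%
#' aligned and identity of at least 35%. The call is `present` when an
#' intact (non-disrupted) hit passes, `pseudogene` when passing hits exist
#' but all are disrupted by a stop codon or frameshift, and `absent`
#' otherwise.
#'
#' @param hits Data frame (possibly empty) with columns `evalue`,
#'   `fraction_aligned`, `pct_identity`, `disrupted` for one query x one
#'   genome.
#' @return One of `"absent"`, `"present"`, `"pseudogene"`.
#' @export
call_presence <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return("absent")
  need <- c("evalue", "fraction_aligned", "pct_identity", "disrupted")
  if (!all(need %in% names(hits)))
    stop("malformed hit table; need columns: ", paste(need, collapse = ", "))
  if (any(is.na(hits[need])) || any(hits$evalue < 0) ||
      any(hits$fraction_aligned < 0 | hits$fraction_aligned > 1))
    stop("malformed hit record")
  passing <- (hits$evalue < 1e-5 & hits$fraction_aligned >= 0.6) |
    (hits$evalue < 1e-20 & hits$fraction_aligned >= 0.3 &
       hits$pct_identity >= 35)
  if (!any(passing)) return("absent")
  if (any(passing & !hits$disrupted)) return("present")
  "pseudogene"
}

#' Presence matrix for group-confined clusters from a cross-search table
#'
#' For every cluster whose members all belong to one group, applies
#' [call_presence()] to the hits of each member gene against each genome
#' outside the group (any member's hit evidence counts for the cluster).
#'
#' @param clusters List of clusters (`genome|gene` ids).
#' @param hits Search-hit data frame with columns `gene`, `genome`,
#'   `evalue`, `fraction_aligned`, `pct_identity`, `disrupted`.
#' @param groups Named character vector genome -> group label.
#' @return Data frame `cluster`, `genome`, `status` for every
#'   (group-confined cluster, outside genome) pair.
#' @export
presence_from_hits <- function(clusters, hits, groups) {
  rows <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    gset <- unique(groups[genome_of(cl)])
    if (length(gset) != 1 || any(is.na(gset))) next
    outside <- names(groups)[groups != gset]
    for (gn in outside) {
      h <- hits[hits$gene %in% cl & hits$genome == gn, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = ci, genome = gn, status = call_presence(h),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cluster = integer(), genome = character(),
                      status = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Call group-specific clusters
#'
#' A cluster is specific to group G iff it has a member in every G genome
#' and its status in every genome outside G (including any configured
#' outgroup genomes) is `absent` or `pseudogene`.
#'
#' @param clusters List of clusters (`genome|gene` ids).
#' @param presence Data frame from [presence_from_hits()] (`cluster`
#'   index, `genome`, `status`).
#' @param groups Named character vector genome -> group label; outgroup
#'   genomes carry their own label and are treated as "must be absent or
#'   pseudogene" for every group.
#' @param focal_groups Groups for which specificity is assessed (default:
#'   all groups with more than one genome, or all groups).
#' @return List with `calls` (data frame cluster, group, n_pseudogene,
#'   statuses) and `counts` (named per-group totals).
#' @export
call_group_specific <- function(clusters, presence, groups,
                                focal_groups = NULL) {
  focal_groups <- focal_groups %||% sort(unique(groups))
  calls <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    member_groups <- unique(groups[genome_of(cl)])
    if (length(member_groups) != 1 || !(member_groups %in% focal_groups))
      next
    g <- member_groups
    own <- names(groups)[groups == g]
    if (!all(own %in% genome_of(cl))) next  # must be present in all own genomes
    st <- presence[presence$cluster == ci, , drop = FALSE]
    outside <- names(groups)[groups != g]
    if (!all(outside %in% st$genome))
      stop("presence status missing for cluster ", ci)
    ok <- all(st$status %in% c("absent", "pseudogene"))
    if (!ok) next
    calls[[length(calls) + 1L]] <- data.frame(
      cluster = ci, group = g,
      n_pseudogene = sum(st$status == "pseudogene"),
      statuses = paste(paste0(st$genome, "=", st$status), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(cluster = integer(), group = character(),
               n_pseudogene = integer(), statuses = character(),
               stringsAsFactors = FALSE)
  counts <- vapply(focal_groups, function(g) sum(calls$group == g), 0L)
  list(calls = calls, counts = counts)
}

#' Census of clusters exclusive to each k-genome combination
#'
#' For each k-subset of genomes, counts the clusters whose member genome
#' set equals exactly that subset.
#'
#' @param clusters List of clusters (`genome|gene` ids).
#' @param genomes Character vector of genome labels.
#' @param k Subset size (default 3).
#' @return Named integer vector, one entry per k-combination
#'   (`g1+g2+g3`-style names).
#' @export
combination_census <- function(clusters, genomes, k = 3) {
  stopifnot(k <= length(genomes))
  subsets <- combn(sort(genomes), k, simplify = FALSE)
  keys <- vapply(subsets, paste, "", collapse = "+")
  counts <- setNames(integer(length(keys)), keys)
  for (cl in clusters) {
    gs <- sort(unique(genome_of(cl)))
    if (length(gs) != k) next
    key <- paste(gs, collapse = "+")
    if (key %in% keys) counts[key] <- counts[key] + 1L
  }
  counts
}
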