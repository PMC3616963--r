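# Pairwise dN/dS (NG86 counting with Jukes-Cantor correction), relative-dS
# ternary projection, the spread cohesion statistic, and the rank-sum
# comparison of divergence by recombination status.

#' Pairwise dN/dS by Nei-Gojobori counting
#'
#' Counts synonymous and nonsynonymous sites and differences over the
#' gap-free codon columns of a two-row codon alignment (pairwise deletion;
#' codon columns containing stop codons are also excluded), averaging
#' mutational paths for multi-hit codons, and applies the Jukes-Cantor
#' correction `d = -3/4 log(1 - 4/3 p)`. Saturated proportions (argument of
#' the log non-positive) yield `NA` with a flag.
#'
#' @param aln Character codon alignment matrix with exactly 2 rows (columns
#'   a multiple of 3), or a character vector of two equal-length strings.
#' @return List with `dN`, `dS`, `pN`, `pS`, site counts and a `flags`
#'   character vector (may include `"saturated_dS"`, `"saturated_dN"`,
#'   `"no_synonymous_sites"`).
#' @export
estimate_dn_ds <- function(aln) {
  if (is.character(aln) && is.null(dim(aln))) {
    aln <- do.call(rbind, strsplit(toupper(aln), ""))
  }
  stopifnot(nrow(aln) == 2)
  if (ncol(aln) %% 3 != 0) stop("codon alignment length must be divisible by 3")
  s1 <- paste(aln[1, ], collapse = "")
  s2 <- paste(aln[2, ], collapse = "")
  c1 <- split_codons(s1)
  c2 <- split_codons(s2)
  ct <- codon_table()
  ok <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2) &
    ct$aa[c1] != "*" & ct$aa[c2] != "*"
  ok[is.na(ok)] <- FALSE
  c1 <- c1[ok]; c2 <- c2[ok]
  flags <- character()
  if (!length(c1)) {
    return(list(dN = NA_real_, dS = NA_real_, pN = NA_real_, pS = NA_real_,
                S_sites = 0, N_sites = 0, S_diffs = 0, N_diffs = 0,
                flags = "no_codons"))
  }
  sites <- ng86_sites_table()
  S <- (sum(sites[c1, "syn"]) + sum(sites[c2, "syn"])) / 2
  N <- (sum(sites[c1, "nonsyn"]) + sum(sites[c2, "nonsyn"])) / 2
  diffs <- c(syn = 0, nonsyn = 0)
  for (k in which(c1 != c2)) diffs <- diffs + ng86_codon_diffs(c1[k], c2[k])
  if (S <= 0) {
    return(list(dN = NA_real_, dS = NA_real_, pN = NA_real_, pS = NA_real_,
                S_sites = S, N_sites = N, S_diffs = diffs[["syn"]],
                N_diffs = diffs[["nonsyn"]], flags = "no_synonymous_sites"))
  }
  pS <- diffs[["syn"]] / S
  pN <- diffs[["nonsyn"]] / N
  jc <- function(p) {
    arg <- 1 - 4 / 3 * p
    if (arg <= 0) return(NA_real_)
    -3 / 4 * log(arg)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  if (is.na(dS)) flags <- c(flags, "saturated_dS")
  if (is.na(dN)) flags <- c(flags, "saturated_dN")
  list(dN = dN, dS = dS, pN = pN, pS = pS, S_sites = S, N_sites = N,
       S_diffs = diffs[["syn"]], N_diffs = diffs[["nonsyn"]], flags = flags)
}

#' Relative dS triple and its ternary embedding
#'
#' Normalizes the three pairwise dS values of a strain triple to sum to 1
#' and maps them into the standard equilateral-triangle coordinates
#' `x = rel2 + rel3/2`, `y = rel3 * sqrt(3)/2`; the maximum absolute dS is
#' retained (the figure colour channel).
#'
#' @param ds Numeric vector of three pairwise dS values (optionally named
#'   by pair); at least one must be positive and none `NA`.
#' @return List with `rel`, `xy`, `max_abs_dS`; `NULL` (with a warning) when
#'   all three values are zero or any is `NA`.
#' @export
relative_ds <- function(ds) {
  stopifnot(length(ds) == 3)
  if (any(is.na(ds)) || sum(ds) <= 0 || any(ds < 0)) {
    warning("undefined relative dS point (zero, negative or NA values); excluded")
    return(NULL)
  }
  rel <- ds / sum(ds)
  xy <- c(x = unname(rel[2] + rel[3] / 2), y = unname(rel[3] * sqrt(3) / 2))
  list(rel = rel, xy = xy, max_abs_dS = max(ds))
}

#' Spread: median distance from the mean ternary point
#'
#' The cohesion statistic of the relative-dS ternary plot: the componentwise
#' mean point of the per-gene relative-dS values is taken and the spread is
#' the median Euclidean distance of the points from that mean. Near 0 under
#' clonal evolution; large when recombination decouples gene histories. The
#' default distance acts on the raw 3-component relative triple, under
#' which a gene whose closest pair is locally identical (relative values
#' 0, 1/2, 1/2) lies 0.408 from the simplex centre - the geometry that
#' accommodates the spreads reported for recombining bacterial groups
#' (0.3-0.45); `metric = "xy"` instead measures distances in the 2-D
#' plotted coordinates.
#'
#' @param points List of [relative_ds()] results (NULL entries dropped), or
#'   a matrix with 3 (rel triples) or 2 (xy) columns.
#' @param metric `"rel"` (default) or `"xy"`.
#' @return The spread (scalar).
#' @export
spread <- function(points, metric = c("rel", "xy")) {
  metric <- match.arg(metric)
  if (is.list(points) && !is.matrix(points)) {
    points <- Filter(Negate(is.null), points)
    if (!length(points)) stop("no valid ternary points")
    m <- if (metric == "rel")
      do.call(rbind, lapply(points, function(p) unname(p$rel)))
    else do.call(rbind, lapply(points, `[[`, "xy"))
  } else {
    m <- points
    if (metric == "rel" && ncol(m) != 3 || metric == "xy" && ncol(m) != 2)
      stop("point matrix has the wrong number of columns for the metric")
  }
  if (!nrow(m)) stop("no valid ternary points")
  ctr <- colMeans(m)
  median(sqrt(rowSums(sweep(m, 2, ctr)^2)))
}

#' Compare synonymous divergence by recombination status
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test between the dS values of
#' recombining and non-recombining genes: exact enumeration when both
#' samples have at most 8 observations and no ties, normal approximation
#' with tie correction otherwise.
#'
#' @param ds_recombined,ds_other Non-empty numeric vectors.
#' @return List with `U` (statistic for the first sample) and `p.value`.
#' @export
compare_divergence_by_status <- function(ds_recombined, ds_other) {
  stopifnot(length(ds_recombined) > 0, length(ds_other) > 0)
  exact <- length(ds_recombined) <= 8 && length(ds_other) <= 8
  wt <- suppressWarnings(wilcox.test(ds_recombined, ds_other,
                                     alternative = "two.sided",
                                     exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p.value = wt$p.value)
}

#' Per-gene pairwise divergence table
#'
#' Applies [estimate_dn_ds()] to every pair of rows of a codon alignment.
#'
#' @param aln Character codon alignment matrix with named rows.
#' @param gene_id Optional gene identifier recorded in the table.
#' @return Data frame with columns `gene_id`, `seq1`, `seq2`, `dN`, `dS`,
#'   `flags`.
#' @export
pairwise_divergence <- function(aln, gene_id = NA_character_) {
  prs <- combn(rownames(aln), 2, simplify = FALSE)
  do.call(rbind, lapply(prs, function(pr) {
    est <- estimate_dn_ds(aln[pr, , drop = FALSE])
    data.frame(gene_id = gene_id, seq1 = pr[1], seq2 = pr[2],
               dN = est$dN, dS = est$dS,
               flags = paste(est$flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Spread of a strain triple over a set of gene alignments
#'
#' Computes the three pairwise dS values of the given triple for every gene,
#' projects each gene to its relative-dS ternary point and returns the
#' spread together with the per-gene points.
#'
#' @param alignments List of codon alignment matrices (rows named by
#'   genome).
#' @param triple Character vector of three genome names.
#' @param metric Distance space for the spread (see [spread()]).
#' @return List with `spread`, `points` (data frame gene, rel1..rel3, x, y,
#'   max_dS), and `n_excluded`.
#' @export
triple_spread <- function(alignments, triple, metric = "rel") {
  stopifnot(length(triple) == 3)
  prs <- combn(sort(triple), 2, simplify = FALSE)
  pts <- list()
  excluded <- 0L
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    ds <- vapply(prs, function(pr)
      estimate_dn_ds(aln[pr, , drop = FALSE])$dS, 0)
    if (any(is.na(ds)) || sum(ds) <= 0) {
      excluded <- excluded + 1L
      next
    }
    pt <- suppressWarnings(relative_ds(ds))
    if (is.null(pt)) {
      excluded <- excluded + 1L
      next
    }
    pts[[length(pts) + 1L]] <- data.frame(
      gene = i, rel1 = pt$rel[1], rel2 = pt$rel[2], rel3 = pt$rel[3],
      x = pt$xy[["x"]], y = pt$xy[["y"]], max_dS = pt$max_abs_dS)
  }
  if (!length(pts)) stop("no valid ternary points")
  tab <- do.call(rbind, pts)
  m <- if (metric == "rel") as.matrix(tab[, c("rel1", "rel2", "rel3")])
  else as.matrix(tab[, c("x", "y")])
  list(spread = spread(m, metric = metric), points = tab,
       n_excluded = excluded)
}
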