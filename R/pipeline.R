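# End-to-end orchestration over the bundled synthetic generator: simulate a
# gene set, run the tree census, the spread statistic, the recombination
# ensemble, the r/m post-processing and the group-specific gene calls, and
# collect everything into one report.

#' Pipeline configuration
#'
#' One declarative object holding every stage parameter and seed; reruns
#' with an identical configuration reproduce identical outputs.
#'
#' @param stree [species_tree] defining genomes and group labels.
#' @param n_genes Number of simulated genes (default 50).
#' @param params [sim_params] for the generator (its seed is the master
#'   seed of the run).
#' @param history `"clonal"` or `"randomized_within"` (see
#'   [simulate_gene_set()]).
#' @param recombination Overlay tract recombination events per gene.
#' @param n_recomb_genes How many genes get the four-detector ensemble
#'   (detectors are the slow stage; default all).
#' @param n_perm,n_perm_geneconv Permutation counts for the detectors.
#' @param gscales gscale settings for the GENECONV-style scan.
#' @param alpha Ensemble significance level.
#' @param support_floor Optional census support floor (needs
#'   `bootstrap_reps > 0`).
#' @param bootstrap_reps Bootstrap replicates per gene tree (0 = off).
#' @param inflation MCL inflation for the proteome stage.
#' @param proteome Arguments for [simulate_proteomes()] (list), or `NULL`
#'   to skip the gene-content stage.
#' @param track Arguments for [simulate_posterior_track()] (list), or
#'   `NULL` to skip the r/m stage.
#' @param out_dir Directory for stage artifacts (TSV), or `NULL`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(stree = wolbachia_tree(),
                            n_genes = 50,
                            params = sim_params(),
                            history = "clonal",
                            recombination = FALSE,
                            n_recomb_genes = n_genes,
                            n_perm = 1000,
                            n_perm_geneconv = 2000,
                            gscales = c(0, 1, 3),
                            alpha = 0.01,
                            support_floor = NULL,
                            bootstrap_reps = 0,
                            inflation = 1.5,
                            proteome = list(n_core = 10,
                                            n_specific_per_group = c(A = 5, B = 4)),
                            track = list(n_sites = 2000,
                                         events = list(c(100, 220, 0.99),
                                                       c(900, 1000, 0.97)),
                                         background_R = 0.02),
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full cohesion pipeline on synthetic data
#'
#' Stages in dependency order: gene simulation, exhaustive-ML topology
#' census, relative-dS spread per group triple, recombination ensemble with
#' fragment classification, r/m post-processing of a posterior track, and
#' group-specific gene calling on a simulated proteome set. All randomness
#' flows from `config$params$seed`.
#'
#' @param config A [pipeline_config].
#' @return Object of class `cohesion_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stree
  seed <- config$params$seed
  groups <- st$groups
  grp_names <- sort(unique(groups))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  note("simulate: n_genes=%d history=%s recombination=%s seed=%d",
       config$n_genes, config$history, config$recombination, seed)
  genes <- simulate_gene_set(st, config$params, config$n_genes,
                             history = config$history,
                             recombination = config$recombination)
  alns <- lapply(genes, `[[`, "alignment")

  # --- gene trees + census ---
  p_shared <- gtr_params(config$params$gtr_rates,
                         config$params$base_freqs,
                         config$params$gamma_shape)
  trees <- lapply(alns, function(a)
    exhaustive_ml_search(a, p0 = p_shared, optimize_model = FALSE)$tree)
  if (config$bootstrap_reps > 0) {
    trees <- lapply(seq_along(trees), function(i)
      bootstrap_support(alns[[i]], trees[[i]],
                        n_reps = config$bootstrap_reps,
                        seed = seed + 5000L + i, p0 = p_shared))
  }
  gA <- names(groups)[groups == grp_names[1]]
  gB <- names(groups)[groups == grp_names[2]]
  census <- topology_census(trees, gA, gB)
  census_filtered <- if (!is.null(config$support_floor) &&
                         config$bootstrap_reps > 0)
    topology_census(trees, gA, gB, support_floor = config$support_floor)
  else NULL
  note("census: %d/%d split-respecting", sum(census$counts), census$n)

  # --- spread per group triple ---
  spreads <- lapply(setNames(grp_names, grp_names), function(g) {
    triple <- names(groups)[groups == g]
    if (length(triple) != 3) return(NULL)
    ts <- triple_spread(alns, triple)
    note("spread[%s]: %.3f (%d genes excluded)", g, ts$spread, ts$n_excluded)
    ts
  })

  # --- recombination ensemble ---
  n_r <- min(config$n_recomb_genes, length(alns))
  tiers <- integer(0)
  frag_all <- list()
  if (n_r > 0) {
    reports <- lapply(seq_len(n_r), function(i)
      recombination_report(alns[[i]], gscale = config$gscales[1],
                           n_perm = config$n_perm,
                           n_perm_geneconv = config$n_perm_geneconv,
                           seed = seed + 9000L + 10L * i,
                           alpha = config$alpha))
    tiers <- vapply(reports, `[[`, 0L, "tier")
    for (gs in config$gscales) {
      frs <- lapply(seq_len(n_r), function(i) {
        gf <- geneconv_fragments(alns[[i]], gscale = gs,
                                 n_perm = config$n_perm_geneconv,
                                 seed = seed + 13000L + 10L * i)
        f <- gf$fragments
        f <- f[f$ka_p < 0.05, , drop = FALSE]
        if (nrow(f)) cbind(gene = i, gscale = gs, f) else NULL
      })
      frag_all[[as.character(gs)]] <- do.call(rbind,
                                              Filter(Negate(is.null), frs))
    }
    tier_tab <- tabulate(factor(tiers, levels = 0:4), nbins = 5)
    note("recomb: tier counts %s",
         paste(paste0(0:4, ":", tier_tab), collapse = " "))
  }
  frag_summaries <- lapply(frag_all, function(f) {
    if (is.null(f) || !nrow(f)) return(NULL)
    classify_fragments(f, groups)$summary
  })

  # --- r/m ---
  rm_res <- NULL
  if (!is.null(config$track)) {
    tr_args <- config$track
    tr_args$seed <- seed + 17L
    track <- do.call(simulate_posterior_track, tr_args)
    rm_res <- c(rm_counts(track), list(n_events = count_events(track)))
    note("rm: n_mut=%d n_rec=%d events=%d", rm_res$n_mut, rm_res$n_rec,
         rm_res$n_events)
  }

  # --- group-specific genes ---
  specific <- NULL
  if (!is.null(config$proteome)) {
    pr_args <- config$proteome
    pr_args$seed <- seed + 23L
    prot <- do.call(simulate_proteomes, pr_args)
    lens <- setNames(nchar(prot$proteins), names(prot$proteins))
    edges <- filter_edges(prot$hits_self, lens)
    clusters <- mcl_cluster(edges, inflation = config$inflation,
                            nodes = names(prot$proteins))
    presence <- presence_from_hits(clusters, prot$hits_cross, prot$genomes)
    specific <- call_group_specific(clusters, presence, prot$genomes)
    specific$truth <- prot$truth
    specific$n_core_recovered <-
      length(extract_single_copy_core(clusters, names(prot$genomes)))
    note("specific: %s",
         paste(names(specific$counts), specific$counts, sep = "=",
               collapse = " "))
  }

  report <- structure(list(census = census,
                           census_filtered = census_filtered,
                           spreads = spreads,
                           tiers = tiers,
                           fragment_summaries = frag_summaries,
                           rm = rm_res,
                           specific = specific,
                           seeds = c(master = seed),
                           log = log,
                           config = config),
                      class = "cohesion_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir, genes)
  report
}

write_report <- function(report, out_dir, genes = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  census_tab <- data.frame(class = c(names(report$census$counts),
                                     "incongruent"),
                           n = c(unname(report$census$counts),
                                 report$census$incongruent))
  write.table(census_tab, file.path(out_dir, "census.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(report$tiers))
    write.table(data.frame(gene = seq_along(report$tiers),
                           tier = report$tiers),
                file.path(out_dir, "tiers.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(genes)) write_truth_log(genes, file.path(out_dir, "truth.tsv"))
  writeLines(report$log, file.path(out_dir, "pipeline.log"))
  json <- jsonlite::toJSON(report_numbers(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, file.path(out_dir, "report.json"))
  invisible(out_dir)
}

# flat numeric summary of a report (JSON surface)
report_numbers <- function(report) {
  out <- list(n_genes = report$census$n,
              split_respecting = sum(report$census$counts),
              incongruent = report$census$incongruent)
  for (g in names(report$spreads)) {
    if (!is.null(report$spreads[[g]]))
      out[[paste0("spread_", g)]] <- report$spreads[[g]]$spread
  }
  if (length(report$tiers)) {
    out$tier4 <- sum(report$tiers == 4)
    out$tier3 <- sum(report$tiers == 3)
  }
  if (!is.null(report$rm)) {
    out$n_mut <- report$rm$n_mut
    out$n_rec <- report$rm$n_rec
    out$r_over_m <- report$rm$r_over_m
    out$n_events <- report$rm$n_events
  }
  if (!is.null(report$specific)) {
    for (g in names(report$specific$counts))
      out[[paste0("specific_", g)]] <- unname(report$specific$counts[[g]])
  }
  out
}

#' @export
print.cohesion_report <- function(x, ...) {
  cat("Cohesion pipeline report (", x$census$n, " genes)\n", sep = "")
  cat("Topology census:\n")
  print(x$census)
  for (g in names(x$spreads)) {
    if (!is.null(x$spreads[[g]]))
      cat(sprintf("Spread[%s] = %.3f\n", g, x$spreads[[g]]$spread))
  }
  if (length(x$tiers))
    cat("Ensemble tiers (0-4):",
        paste(tabulate(factor(x$tiers, levels = 0:4), nbins = 5),
              collapse = "/"), "\n")
  if (!is.null(x$rm))
    cat(sprintf("r/m: %d rec / %d mut = %s; %d events\n", x$rm$n_rec,
                x$rm$n_mut, format(x$rm$r_over_m), x$rm$n_events))
  if (!is.null(x$specific))
    cat("Group-specific clusters:",
        paste(names(x$specific$counts), x$specific$counts, sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}
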