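#' Match called DMRs against planted truth
#'
#' A planted DMR counts as recovered when some called DMR shares at least
#' `min_frac` of the member CpGs of each (reciprocal overlap) and agrees in
#' direction. Empirical FDR is the fraction of called DMRs overlapping no
#' planted region at all.
#'
#' @param called a `dmr_set` (or `dmr_result`).
#' @param truth_dmrs planted truth data.frame from [simulate_methylome()]
#'   (columns `chrom`, `pos` list column, `direction`).
#' @param min_frac reciprocal CpG-overlap fraction.
#' @return list `sensitivity`, `empirical_fdr`, `n_called`, `n_planted`,
#'   `n_recovered`, `n_false`.
#' @export
dmr_recovery <- function(called, truth_dmrs, min_frac = 0.5) {
  if (methods::is(called, "dmr_result")) called <- called$dmrs
  ckeys <- lapply(seq_len(nrow(called)), function(i)
    paste(called$chrom[i], called$members[[i]]$pos))
  tkeys <- lapply(seq_len(nrow(truth_dmrs)), function(i)
    paste(truth_dmrs$chrom[i], truth_dmrs$pos[[i]]))
  recovered <- logical(nrow(truth_dmrs))
  overlapped <- logical(nrow(called))
  for (t in seq_len(nrow(truth_dmrs))) {
    for (c in seq_len(nrow(called))) {
      sh <- length(intersect(tkeys[[t]], ckeys[[c]]))
      if (sh > 0L) overlapped[c] <- TRUE
      if (sh >= min_frac * length(tkeys[[t]]) &&
          sh >= min_frac * length(ckeys[[c]]) &&
          called$direction[c] == truth_dmrs$direction[t])
        recovered[t] <- TRUE
    }
  }
  list(sensitivity = if (nrow(truth_dmrs)) mean(recovered) else NA_real_,
       empirical_fdr = if (nrow(called)) mean(!overlapped) else NA_real_,
       n_called = nrow(called), n_planted = nrow(truth_dmrs),
       n_recovered = sum(recovered), n_false = sum(!overlapped))
}

#' Run the full simulation study
#'
#' Generates a genome, methylome and pooled two-group count tables, profiles
#' the methylomes, calls DMRs, annotates them against the simulated genes and
#' CGIs, scores recovery against the planted truth and summarizes the in
#' silico digestion of the simulated genome. With `out_dir`, the generated
#' data and results are also written to disk in the package's standard
#' formats.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed (stage seeds are derived from it).
#' @param per_individual draw per-individual tables and analyse their pooled
#'   sums (the pooled-library design; default) rather than single tables.
#' @param out_dir optional output directory.
#' @param ... DMR-caller parameters forwarded to [call_dmrs()].
#' @return list of class `study_bundle` with `metrics`, `dmr_result`,
#'   `annotated`, `profile`, `digestion`, `truth`, `genome_bundle`.
#' @export
run_simulation_study <- function(config = sim_config(), seed = 1L,
                                 per_individual = TRUE, out_dir = NULL,
                                 ...) {
  t0 <- proc.time()[["elapsed"]]
  bundle <- simulate_genome(config, seed)
  truth <- simulate_methylome(bundle, config, seed + 1L)
  counts <- simulate_counts(truth, config, seed + 2L,
                            per_individual = per_individual)
  g1 <- if (per_individual) counts$group1$pooled else counts$group1
  g2 <- if (per_individual) counts$group2$pooled else counts$group2
  t_sim <- proc.time()[["elapsed"]]

  lv1 <- site_levels(g1); lv2 <- site_levels(g2)
  prof <- list(
    context = list(group1 = context_breakdown(g1),
                   group2 = context_breakdown(g2)),
    quintiles = list(
      group1 = quintile_distribution(lv1$level[lv1$context == "CpG"]),
      group2 = quintile_distribution(lv2$level[lv2$context == "CpG"])),
    metagene = metagene_profile(lv1[lv1$context == "CpG", ], bundle$genes),
    region_diff = region_level_difference(g1, g2, bundle$genes))
  t_prof <- proc.time()[["elapsed"]]

  res <- call_dmrs(g1, g2, ...)
  check_dmr_invariants(res$dmrs, max_gap = res$params$max_gap,
                       min_sites = res$params$min_sites,
                       min_sig = res$params$min_sig)
  rec <- dmr_recovery(res, truth$dmrs)
  t_dmr <- proc.time()[["elapsed"]]

  ann <- assign_feature(res$dmrs, bundle$genes)
  ann <- overlap_cgi(ann, bundle$cgis)
  frag <- size_select(digest(bundle$genome))
  dig <- recovery_stats(frag, bundle$genome, cgis = bundle$cgis,
                        read_len = 50L)
  t_all <- proc.time()[["elapsed"]]

  metrics <- list(
    sensitivity = rec$sensitivity, empirical_fdr = rec$empirical_fdr,
    n_called = rec$n_called, n_planted = rec$n_planted,
    frac_hypo = if (nrow(res$dmrs)) mean(res$dmrs$direction == "hypo")
      else NA_real_,
    frac_cgi_overlap = if (nrow(ann)) mean(ann$cgi_overlap) else NA_real_,
    digestion_frac_all_cpgs = dig$frac_of_all_cpgs,
    digestion_frac_cgi_cpgs = dig$frac_of_cgi_cpgs,
    runtimes = c(simulate = t_sim - t0, profile = t_prof - t_sim,
                 dmr = t_dmr - t_prof, annotate_digest = t_all - t_dmr))
  out <- structure(list(metrics = metrics, dmr_result = res,
                        annotated = ann, profile = prof, digestion = dig,
                        truth = truth, genome_bundle = bundle,
                        seed = seed),
                   class = "study_bundle")
  if (!is.null(out_dir)) write_study(out, g1, g2, out_dir)
  out
}

write_study <- function(study, g1, g2, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  Biostrings::writeXStringSet(study$genome_bundle$genome, p("genome.fa"))
  write_bed12(study$genome_bundle$genes, p("genes.bed12"))
  write_bed(study$genome_bundle$cgis, p("cgis.bed"))
  td <- study$truth$dmrs
  write_bed(data.frame(chrom = td$chrom, start = td$start, end = td$end,
                       name = td$direction, score = 0, strand = "."),
            p("truth_dmrs.bed"))
  write_methylation_calls(g1, p("group1.tsv"))
  write_methylation_calls(g2, p("group2.tsv"))
  write_dmrs(study$dmr_result, tsv = p("dmrs.tsv"), bed = p("dmrs.bed"))
  jsonlite::write_json(study$metrics[setdiff(names(study$metrics),
                                             "runtimes")],
                       p("metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.study_bundle <- function(x, ...) {
  m <- x$metrics
  cat("<study_bundle>\n")
  cat(sprintf("  planted %d DMRs; called %d; sensitivity %.3f; empirical FDR %.3f\n",
              m$n_planted, m$n_called, m$sensitivity, m$empirical_fdr))
  cat(sprintf("  digestion recovers %.1f%% of CpGs (%.1f%% of CGI CpGs)\n",
              100 * m$digestion_frac_all_cpgs,
              100 * (m$digestion_frac_cgi_cpgs %||% NA)))
  invisible(x)
}

#' Run a two-group comparison on user count tables
#'
#' Calls DMRs between two methylation-call tables and summarizes them the
#' way the study's figures do: direction split, feature-category
#' distribution and the promoter-CGI gene list.
#'
#' @param calls_a,calls_b `cpg_counts` tables (or paths to call TSVs).
#' @param genes optional gene models; feature assignment is skipped with a
#'   warning when absent.
#' @param cgis optional CGI intervals.
#' @param ... DMR-caller parameters forwarded to [call_dmrs()].
#' @return list with `dmr_result`, `annotated`, `summary`.
#' @export
run_comparison <- function(calls_a, calls_b, genes = NULL, cgis = NULL,
                           ...) {
  if (is.character(calls_a)) calls_a <- read_methylation_calls(calls_a)
  if (is.character(calls_b)) calls_b <- read_methylation_calls(calls_b)
  res <- call_dmrs(calls_a, calls_b, ...)
  ann <- res$dmrs
  if (!is.null(genes)) ann <- assign_feature(ann, genes)
  else if (nrow(ann)) warning("no gene models; feature assignment skipped")
  if (!is.null(cgis)) ann <- overlap_cgi(ann, cgis)
  summ <- list(
    n_dmrs = nrow(ann),
    direction = if (nrow(ann)) as.list(table(ann$direction)) else list(),
    feature_distribution = if (!is.null(ann$category))
      as.list(table(ann$category) / nrow(ann)) else NULL,
    promoter_cgi_genes = attr(ann, "cgi_summary")$promoter_cgi_genes)
  list(dmr_result = res, annotated = ann, summary = summ)
}
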