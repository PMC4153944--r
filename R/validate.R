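#' Restrict a count table to amplicon CpGs
#'
#' Returns the CpG rows falling inside amplicons, plus a per-amplicon
#' coverage report: the fraction of the amplicon's genomic CpGs covered at
#' `min_depth` or more.
#'
#' @param table a `cpg_counts` table.
#' @param amplicons amplicon interval data.frame (0-based half-open,
#'   optional `name`).
#' @param genome the matching [Biostrings::DNAStringSet] (defines each
#'   amplicon's CpG complement).
#' @param min_depth minimum depth for a CpG to count as covered.
#' @return list with `sites` (covered rows with an `amplicon` column) and
#'   `coverage` (`amplicon, n_cpgs, n_covered, coverage`); amplicons without
#'   genomic CpGs are flagged with `NA` coverage and a warning.
#' @export
amplicon_levels <- function(table, amplicons, genome, min_depth = 1L) {
  stop_if_not_intervals(amplicons, "amplicons")
  if (is.null(amplicons$name))
    amplicons$name <- sprintf("amp%03d", seq_len(nrow(amplicons)))
  cpgs <- enumerate_cpgs(genome)
  lv <- site_levels(table, min_depth = min_depth)
  lv <- lv[lv$context == "CpG", , drop = FALSE]
  sites <- list(); cov <- list()
  for (i in seq_len(nrow(amplicons))) {
    a <- amplicons[i, ]
    univ <- cpgs$pos[cpgs$chrom == a$chrom & cpgs$pos >= a$start &
                       cpgs$pos + 2L <= a$end]     # 0-based C positions
    hit <- lv[lv$chrom == a$chrom & (lv$pos - 1L) %in% univ, , drop = FALSE]
    if (length(univ) == 0L) {
      warning("amplicon ", a$name, " contains no CpG")
      cov[[i]] <- data.frame(amplicon = a$name, n_cpgs = 0L, n_covered = 0L,
                             coverage = NA_real_)
      next
    }
    if (nrow(hit)) {
      hit$amplicon <- a$name
      sites[[length(sites) + 1L]] <- hit
    }
    cov[[i]] <- data.frame(amplicon = a$name, n_cpgs = length(univ),
                           n_covered = nrow(hit),
                           coverage = nrow(hit) / length(univ))
  }
  list(sites = if (length(sites)) do.call(rbind, sites) else
         cbind(lv[0, ], amplicon = character()),
       coverage = do.call(rbind, cov))
}

#' Per-CpG levels from a Sanger clone matrix
#'
#' @param clone_matrix 0/1/NA matrix, clones in rows, CpG columns named by
#'   position.
#' @return named numeric vector of per-CpG levels (methylated clones over
#'   non-missing clones).
#' @export
sanger_levels <- function(clone_matrix) {
  n_ok <- colSums(!is.na(clone_matrix))
  if (any(n_ok == 0L))
    stop("CpG column with no non-missing clone calls")
  colSums(clone_matrix, na.rm = TRUE) / n_ok
}

#' Concordance between two per-CpG level vectors
#'
#' Pearson correlation and ordinary least-squares slope/intercept over CpGs
#' present in both inputs (matched by name).
#'
#' @param levels_x,levels_y named numeric vectors of levels (names identify
#'   the CpG, e.g. `"chrom pos"` or the position).
#' @return list of class `concordance` with `n_paired_sites`, `pearson_r`,
#'   `slope`, `intercept`.
#' @export
concordance <- function(levels_x, levels_y) {
  shared <- intersect(names(levels_x), names(levels_y))
  if (length(shared) < 3L) stop("need at least 3 paired CpG sites")
  x <- as.numeric(levels_x[shared]); y <- as.numeric(levels_y[shared])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in paired levels")
  slope <- stats::cov(x, y) / stats::var(x)
  structure(list(n_paired_sites = length(shared),
                 pearson_r = stats::cor(x, y),
                 slope = slope,
                 intercept = mean(y) - slope * mean(x)),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance over %d CpGs: r = %.3f, y = %.3f x + %.3f\n",
              x$n_paired_sites, x$pearson_r, x$slope, x$intercept))
  invisible(x)
}

#' Per-CpG coefficient of variation across individuals
#'
#' For every (group, site): the sample standard deviation (n - 1) of the
#' individual levels and the coefficient of variation sd/mean. Sites whose
#' group mean is 0 get `NA` CV and are flagged.
#'
#' @param levels data.frame with columns `chrom, pos, individual, group,
#'   level` (one row per individual per site).
#' @param top_quantile fraction of sites flagged as `high_cv` (ranked by
#'   CV within the full record set).
#' @return data.frame `chrom, pos, group, n, mean, sd, cv, high_cv`.
#' @export
cpg_cv <- function(levels, top_quantile = 0.1) {
  req <- c("chrom", "pos", "group", "level")
  if (!all(req %in% names(levels)))
    stop("levels needs columns: ", paste(req, collapse = ", "))
  keys <- unique(levels[c("chrom", "pos", "group")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- levels$chrom == keys$chrom[i] & levels$pos == keys$pos[i] &
      levels$group == keys$group[i]
    v <- levels$level[sel]
    if (length(v) < 2L)
      stop("site ", keys$chrom[i], ":", keys$pos[i],
           " has fewer than 2 individuals")
    m <- mean(v); s <- stats::sd(v)
    data.frame(chrom = keys$chrom[i], pos = keys$pos[i],
               group = keys$group[i], n = length(v), mean = m, sd = s,
               cv = if (m > 0) s / m else NA_real_)
  })
  out <- do.call(rbind, rows)
  thr <- stats::quantile(out$cv, 1 - top_quantile, na.rm = TRUE)
  out$high_cv <- !is.na(out$cv) & out$cv >= thr & out$cv > 0
  rownames(out) <- NULL
  out
}

#' Re-call DMRs on amplicon panels and compare with RRBS DMRs
#'
#' Per-individual amplicon tables are pooled by summing counts within each
#' group, the DMR caller is run restricted to the amplicon CpGs with the
#' given parameters, and every RRBS DMR is classified: `validated` (an
#' amplicon DMR overlaps it with the same direction), `shifted` (an amplicon
#' DMR overlaps the amplicon but not the RRBS DMR, or disagrees in
#' direction), `absent` (its amplicon yielded no DMR) or `not_testable` (no
#' overlapping amplicon).
#'
#' @param tables_g1,tables_g2 lists of per-individual `cpg_counts` tables.
#' @param rrbs_dmrs a `dmr_set` from the genome-wide comparison.
#' @param amplicons amplicon interval data.frame.
#' @param ... parameters forwarded to [call_dmrs()].
#' @return list with `report` (one row per RRBS DMR), `amplicon_dmrs` (the
#'   re-called `dmr_result`).
#' @export
revalidate_amplicon_dmrs <- function(tables_g1, tables_g2, rrbs_dmrs,
                                     amplicons, ...) {
  stop_if_not_intervals(amplicons, "amplicons")
  if (length(tables_g1) == 0L || length(tables_g2) == 0L)
    stop("empty amplicon panel")
  pool <- function(tabs) {
    acc <- as.data.frame(tabs[[1L]])
    for (t in tabs[-1L]) {
      stopifnot(nrow(t) == nrow(acc))
      acc$count_meth <- acc$count_meth + t$count_meth
      acc$count_unmeth <- acc$count_unmeth + t$count_unmeth
    }
    new_cpg_counts(acc, check = FALSE)
  }
  restrict <- function(tab) {
    gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$pos, tab$pos))
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(gr, as_gr(amplicons))))
    new_cpg_counts(as.data.frame(tab)[hit, , drop = FALSE], check = FALSE)
  }
  res <- call_dmrs(restrict(pool(tables_g1)), restrict(pool(tables_g2)), ...)
  amp_gr <- as_gr(amplicons)
  called_gr <- as_gr(res$dmrs)
  rrbs_gr <- as_gr(rrbs_dmrs)
  status <- character(nrow(rrbs_dmrs))
  for (i in seq_len(nrow(rrbs_dmrs))) {
    amp_hit <- GenomicRanges::countOverlaps(rrbs_gr[i], amp_gr) > 0
    if (!amp_hit) { status[i] <- "not_testable"; next }
    ov <- S4Vectors::queryHits(
      GenomicRanges::findOverlaps(called_gr, rrbs_gr[i]))
    if (length(ov)) {
      status[i] <- if (any(res$dmrs$direction[ov] ==
                           rrbs_dmrs$direction[i])) "validated" else "shifted"
      next
    }
    # any amplicon DMR on the same amplicon(s) but off the RRBS region?
    amps <- S4Vectors::subjectHits(
      GenomicRanges::findOverlaps(rrbs_gr[i], amp_gr))
    near <- S4Vectors::queryHits(
      GenomicRanges::findOverlaps(called_gr, amp_gr[amps]))
    status[i] <- if (length(near)) "shifted" else "absent"
  }
  report <- data.frame(chrom = rrbs_dmrs$chrom, start = rrbs_dmrs$start,
                       end = rrbs_dmrs$end,
                       direction = rrbs_dmrs$direction, status = status)
  list(report = report, amplicon_dmrs = res)
}

#' Delta-delta-Ct relative expression analysis
#'
#' Per sample, dCt = Ct(gene) - Ct(reference); ddCt = mean dCt(group B) -
#' mean dCt(group A); fold change = 2^(-ddCt). Group dCt values are compared
#' with a two-sided Student's t-test; a gene is called significant when
#' p < `alpha` and the fold change is at least `fold_threshold` in either
#' direction.
#'
#' @param ct_table data.frame `sample, group, gene, ct`.
#' @param ref_gene reference gene (must be measured in every sample).
#' @param group_a,group_b the reference and test group labels.
#' @param fold_threshold minimum fold change (or its reciprocal).
#' @param alpha significance level on the t-test.
#' @return data.frame `gene, ddct, fold_change, p, significant`.
#' @export
ddct_analysis <- function(ct_table, ref_gene = "GAPDH", group_a, group_b,
                          fold_threshold = 2, alpha = 0.01) {
  req <- c("sample", "group", "gene", "ct")
  if (!all(req %in% names(ct_table)))
    stop("ct_table needs columns: ", paste(req, collapse = ", "))
  ct_table <- ct_table[ct_table$group %in% c(group_a, group_b), ]
  samples <- unique(ct_table$sample)
  ref <- ct_table[ct_table$gene == ref_gene, ]
  if (!all(samples %in% ref$sample))
    stop("reference gene ", ref_gene, " missing in some sample")
  for (g in c(group_a, group_b))
    if (length(unique(ct_table$sample[ct_table$group == g])) < 2L)
      stop("group ", g, " has fewer than 2 samples")
  ref_ct <- stats::setNames(ref$ct, ref$sample)
  genes <- setdiff(unique(ct_table$gene), ref_gene)
  rows <- lapply(genes, function(gn) {
    sub <- ct_table[ct_table$gene == gn, ]
    dct <- sub$ct - ref_ct[sub$sample]
    a <- dct[sub$group == group_a]; b <- dct[sub$group == group_b]
    ddct <- mean(b) - mean(a)
    p <- if (stats::sd(c(a - mean(a), b - mean(b))) == 0) NA_real_ else
      stats::t.test(b, a, var.equal = TRUE)$p.value
    fold <- 2^(-ddct)
    data.frame(gene = gn, ddct = ddct, fold_change = fold, p = p,
               significant = isTRUE(p < alpha) &&
                 (fold >= fold_threshold || fold <= 1 / fold_threshold))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
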