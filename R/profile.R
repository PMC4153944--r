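#' Per-site methylation levels
#'
#' @param table a `cpg_counts` table.
#' @param min_depth minimum depth for a site to be reported (>= 1).
#' @return data.frame `chrom, pos, strand, context, depth, level` with
#'   `level = count_meth / depth`.
#' @export
site_levels <- function(table, min_depth = 1L) {
  if (min_depth < 1L) stop("min_depth must be >= 1")
  df <- as.data.frame(table)
  df$depth <- df$count_meth + df$count_unmeth
  df <- df[df$depth >= min_depth, , drop = FALSE]
  df$level <- df$count_meth / df$depth
  rownames(df) <- NULL
  df[c("chrom", "pos", "strand", "context", "depth", "level")]
}

#' Global methylcytosine fraction per sequence context
#'
#' Read-weighted global levels: per context, the ratio of total methylated
#' counts to total depth (the ratio of total C reads to total reads).
#' Contexts with zero total depth are reported as `NA`.
#'
#' @param table a `cpg_counts` table (may contain CpG and non-CpG rows).
#' @return named numeric vector over `CpG`, `CHG`, `CHH`.
#' @export
context_breakdown <- function(table) {
  df <- as.data.frame(table)
  vapply(stats::setNames(CONTEXTS, CONTEXTS), function(ctx) {
    sel <- df$context == ctx
    tot <- sum(df$count_meth[sel]) + sum(df$count_unmeth[sel])
    if (tot == 0) NA_real_ else sum(df$count_meth[sel]) / tot
  }, numeric(1))
}

#' Quintile distribution of methylation levels
#'
#' Bins levels into `[0,0.2), [0.2,0.4), [0.4,0.6), [0.6,0.8), [0.8,1.0]`
#' (left-closed, last bin closed so a level of exactly 1 is counted once).
#'
#' @param levels numeric vector of levels in `[0, 1]`.
#' @return named vector of 5 proportions summing to 1.
#' @export
quintile_distribution <- function(levels) {
  if (length(levels) == 0L) stop("empty level vector")
  if (anyNA(levels) || any(levels < 0 | levels > 1))
    stop("levels must lie in [0, 1]")
  bin <- pmin(floor(levels / 0.2) + 1L, 5L)
  stats::setNames(tabulate(bin, 5L) / length(levels),
                  c("[0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)",
                    "[0.8,1]"))
}

#' Metagene methylation profile
#'
#' Pools site levels across genes into 120 orientation-normalized bins:
#' 50 upstream 100-bp bins (5 kb flank), 20 equal gene-body bins (5% each)
#' and 50 downstream 100-bp bins. Bin means are unweighted means of all site
#' levels falling in the bin, pooled over genes (`per_gene = TRUE` averages
#' per gene first). Genes with a body shorter than `body_bins` bp are skipped
#' with a warning; empty bins are `NA`.
#'
#' @param levels data.frame from [site_levels()] (1-based `pos`).
#' @param genes gene-model data.frame (see [load_annotation()]).
#' @param flank flank size in bp.
#' @param flank_bin flank bin width in bp.
#' @param body_bins number of gene-body bins.
#' @param per_gene average within genes before pooling.
#' @return numeric vector of length `2 * flank/flank_bin + body_bins`.
#' @export
metagene_profile <- function(levels, genes, flank = 5000L, flank_bin = 100L,
                             body_bins = 20L, per_gene = FALSE) {
  nf <- flank %/% flank_bin
  nbins <- 2L * nf + body_bins
  sums <- counts <- matrix(0, nrow = if (per_gene) nrow(genes) else 1L,
                           ncol = nbins)
  skipped <- 0L
  for (g in seq_len(nrow(genes))) {
    glen <- genes$end[g] - genes$start[g]
    if (glen < body_bins) { skipped <- skipped + 1L; next }
    sel <- levels$chrom == genes$chrom[g]
    if (!any(sel)) next
    p0 <- levels$pos[sel] - 1L
    lv <- levels$level[sel]
    tss <- if (genes$strand[g] == "+") genes$start[g] else genes$end[g] - 1L
    t <- if (genes$strand[g] == "+") p0 - tss else tss - p0
    keep <- t >= -flank & t < glen + flank
    t <- t[keep]; lv <- lv[keep]
    if (!length(t)) next
    bin <- integer(length(t))
    up <- t < 0
    bin[up] <- 1L + (t[up] + flank) %/% flank_bin
    body <- t >= 0 & t < glen
    bin[body] <- nf + 1L + pmin(floor(t[body] / glen * body_bins),
                                body_bins - 1L)
    down <- t >= glen
    bin[down] <- nf + body_bins + 1L + (t[down] - glen) %/% flank_bin
    row <- if (per_gene) g else 1L
    for (b in unique(bin)) {
      sums[row, b] <- sums[row, b] + sum(lv[bin == b])
      counts[row, b] <- counts[row, b] + sum(bin == b)
    }
  }
  if (skipped)
    warning(skipped, " gene(s) shorter than ", body_bins, " bp skipped")
  if (per_gene) {
    gm <- sums / counts                    # NaN where empty
    prof <- colMeans(gm, na.rm = TRUE)
    prof[colSums(!is.nan(gm)) == 0L] <- NA_real_
  } else {
    prof <- as.vector(sums[1L, ] / counts[1L, ])
    prof[counts[1L, ] == 0L] <- NA_real_
  }
  names(prof) <- c(sprintf("up%03d", seq_len(nf)),
                   sprintf("body%02d", seq_len(body_bins)),
                   sprintf("down%03d", seq_len(nf)))
  prof
}

#' Region-wide methylation difference between two tables
#'
#' Mean level difference (table2 - table1) over shared covered CpG sites in
#' gene bodies, upstream flanks and downstream flanks, used to compare global
#' regional methylation between two libraries.
#'
#' @param table1,table2 `cpg_counts` tables.
#' @param genes gene models.
#' @param flank flank size in bp.
#' @return named numeric vector `upstream, body, downstream`.
#' @export
region_level_difference <- function(table1, table2, genes, flank = 5000L) {
  l1 <- site_levels(table1); l2 <- site_levels(table2)
  sh <- merge(l1[c("chrom", "pos", "level")], l2[c("chrom", "pos", "level")],
              by = c("chrom", "pos"), suffixes = c("1", "2"))
  gr_of <- function(start, end, chrom) GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pmax(start, 0L) + 1L, pmax(end, 1L)))
  up <- ifelse(genes$strand == "+", genes$start - flank, genes$end)
  upe <- ifelse(genes$strand == "+", genes$start, genes$end + flank)
  dn <- ifelse(genes$strand == "+", genes$end, genes$start - flank)
  dne <- ifelse(genes$strand == "+", genes$end + flank, genes$start)
  site_gr <- GenomicRanges::GRanges(sh$chrom, IRanges::IRanges(sh$pos, sh$pos))
  mean_diff <- function(region_gr) {
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(site_gr, region_gr)))
    if (!length(hit)) return(NA_real_)
    mean(sh$level2[hit]) - mean(sh$level1[hit])
  }
  c(upstream = mean_diff(gr_of(up, upe, genes$chrom)),
    body = mean_diff(gr_of(genes$start, genes$end, genes$chrom)),
    downstream = mean_diff(gr_of(dn, dne, genes$chrom)))
}

#' Chromosome features versus mean methylation
#'
#' Per chromosome: length, GC content, CpG density, CpG observed/expected
#' ratio, gene density (genes per Mb), optional repeat density (fraction of
#' bases covered by a repeat BED) and the unweighted mean of site levels.
#' Pearson correlations of mean level against each feature are reported when
#' at least 3 chromosomes are present (features without variance give `NA`).
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param genes gene models (may be `NULL`).
#' @param levels data.frame from [site_levels()].
#' @param repeats optional repeat interval data.frame.
#' @return list with `features` (one row per chromosome) and `correlations`
#'   (named vector of Pearson r).
#' @export
chromosome_feature_correlation <- function(genome, genes, levels,
                                           repeats = NULL) {
  chroms <- names(genome)
  af <- Biostrings::alphabetFrequency(genome)[, c("A", "C", "G", "T"),
                                              drop = FALSE]
  cpgs <- enumerate_cpgs(genome)
  feat <- data.frame(
    chrom = chroms,
    length = BiocGenerics::width(genome),
    gc = (af[, "C"] + af[, "G"]) / rowSums(af),
    row.names = NULL)
  feat$cpg_density <- vapply(chroms, function(ch)
    sum(cpgs$chrom == ch), numeric(1)) / feat$length
  feat$cpg_oe <- ifelse(af[, "C"] > 0 & af[, "G"] > 0,
                        (feat$cpg_density * feat$length * feat$length) /
                          (af[, "C"] * af[, "G"]), NA_real_)
  feat$gene_density <- if (!is.null(genes)) vapply(chroms, function(ch)
    sum(genes$chrom == ch), numeric(1)) / feat$length * 1e6 else NA_real_
  feat$repeat_density <- if (!is.null(repeats)) vapply(chroms, function(ch) {
    r <- repeats[repeats$chrom == ch, , drop = FALSE]
    if (!nrow(r)) return(0)
    sum(BiocGenerics::width(GenomicRanges::reduce(as_gr(r))))
  }, numeric(1)) / feat$length else NA_real_
  feat$mean_level <- vapply(chroms, function(ch) {
    lv <- levels$level[levels$chrom == ch]
    if (length(lv)) mean(lv) else NA_real_
  }, numeric(1))
  feat_cols <- c("length", "gc", "cpg_density", "cpg_oe", "gene_density",
                 "repeat_density")
  cors <- vapply(feat_cols, function(f) {
    x <- feat[[f]]; y <- feat$mean_level
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, numeric(1))
  list(features = feat, correlations = cors)
}

#' Pairwise distance matrix over shared CpG levels
#'
#' Plain Euclidean/Manhattan distances between samples over CpG sites covered
#' in every table, for external hierarchical clustering.
#'
#' @param tables named list of `cpg_counts` tables.
#' @param method distance method passed to [stats::dist()].
#' @param min_depth per-site depth filter.
#' @return a `dist` object.
#' @export
methylome_distance <- function(tables, method = "euclidean", min_depth = 1L) {
  if (length(tables) < 2L) stop("need at least two tables")
  lv <- lapply(tables, function(t) {
    s <- site_levels(t, min_depth = min_depth)
    s <- s[s$context == "CpG", ]
    stats::setNames(s$level, paste(s$chrom, s$pos))
  })
  shared <- Reduce(intersect, lapply(lv, names))
  if (!length(shared)) stop("no shared CpG sites")
  m <- do.call(rbind, lapply(lv, `[`, shared))
  rownames(m) <- names(tables)
  stats::dist(m, method = method)
}
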