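#' Assign DMRs to genomic feature categories
#'
#' Each DMR receives exactly one category by >= 1 bp overlap with precedence
#' promoter > exon > intron > downstream > intergenic. Promoters are the
#' `promoter_up` bp upstream of the TSS in gene orientation; downstream
#' regions are `downstream_len` bp past the gene end. `gene_ids` lists all
#' genes contributing the winning category.
#'
#' @param dmrs a `dmr_set` (or any interval data.frame, 0-based half-open).
#' @param genes gene-model data.frame (see [load_annotation()]).
#' @param promoter_up promoter extent upstream of the TSS (bp).
#' @param downstream_len downstream extent past the gene end (bp).
#' @return `dmrs` with added columns `category` and `gene_ids`
#'   (comma-separated; `""` for intergenic).
#' @export
assign_feature <- function(dmrs, genes, promoter_up = 2000L,
                           downstream_len = 2000L) {
  stop_if_not_intervals(dmrs, "dmrs")
  plus <- genes$strand == "+"
  feat_gr <- function(start, end) {
    ok <- start < end & end > 0
    GenomicRanges::GRanges(genes$chrom[ok],
                           IRanges::IRanges(pmax(start[ok], 0L) + 1L,
                                            end[ok]),
                           gene_id = genes$gene_id[ok])
  }
  prom <- feat_gr(ifelse(plus, genes$start - promoter_up, genes$end),
                  ifelse(plus, genes$start, genes$end + promoter_up))
  down <- feat_gr(ifelse(plus, genes$end, genes$start - downstream_len),
                  ifelse(plus, genes$end + downstream_len, genes$start))
  ex_rows <- rep(seq_len(nrow(genes)), lengths(genes$exon_starts))
  exon <- GenomicRanges::GRanges(genes$chrom[ex_rows],
                                 IRanges::IRanges(
                                   unlist(genes$exon_starts) + 1L,
                                   unlist(genes$exon_ends)),
                                 gene_id = genes$gene_id[ex_rows])
  gene_gr <- feat_gr(genes$start, genes$end)
  intron <- GenomicRanges::setdiff(gene_gr, GenomicRanges::reduce(exon),
                                   ignore.strand = TRUE)
  # re-attach gene ids to intron pieces
  ih <- GenomicRanges::findOverlaps(intron, gene_gr)
  intron <- intron[S4Vectors::queryHits(ih)]
  intron$gene_id <- gene_gr$gene_id[S4Vectors::subjectHits(ih)]
  dmr_gr <- as_gr(dmrs)
  cats <- list(promoter = prom, exon = exon, intron = intron,
               downstream = down)
  category <- rep("intergenic", nrow(dmrs))
  gene_ids <- rep("", nrow(dmrs))
  undecided <- rep(TRUE, nrow(dmrs))
  for (nm in names(cats)) {
    h <- GenomicRanges::findOverlaps(dmr_gr, cats[[nm]])
    qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
    sel <- undecided[qh]
    if (!any(sel)) next
    hit_ids <- split(cats[[nm]]$gene_id[sh[sel]], qh[sel])
    rows <- as.integer(names(hit_ids))
    category[rows] <- nm
    gene_ids[rows] <- vapply(hit_ids, function(g)
      paste(unique(g), collapse = ","), character(1))
    undecided[rows] <- FALSE
  }
  dmrs$category <- category
  dmrs$gene_ids <- gene_ids
  dmrs
}

#' Flag CGI overlap of DMRs
#'
#' Any-bp overlap between each DMR and a CGI set, with a summary of
#' promoter DMRs overlapping CGIs and their genes (when the DMRs carry a
#' `category` column from [assign_feature()]).
#'
#' @param dmrs interval data.frame (ideally annotated).
#' @param cgis CGI interval data.frame.
#' @return `dmrs` with a logical `cgi_overlap` column; the summary is
#'   attached as attribute `cgi_summary` (list: `n_overlap`,
#'   `n_promoter_cgi`, `promoter_cgi_genes`).
#' @export
overlap_cgi <- function(dmrs, cgis) {
  stop_if_not_intervals(dmrs, "dmrs")
  stop_if_not_intervals(cgis, "cgis")
  flag <- rep(FALSE, nrow(dmrs))
  if (nrow(dmrs) && nrow(cgis)) {
    h <- GenomicRanges::findOverlaps(as_gr(dmrs), as_gr(cgis))
    flag[unique(S4Vectors::queryHits(h))] <- TRUE
  }
  dmrs$cgi_overlap <- flag
  genes <- character()
  n_prom <- NA_integer_
  if (!is.null(dmrs$category)) {
    pc <- dmrs$category == "promoter" & flag
    n_prom <- sum(pc)
    genes <- unique(unlist(strsplit(dmrs$gene_ids[pc], ",")))
    genes <- genes[nzchar(genes)]
  }
  attr(dmrs, "cgi_summary") <- list(n_overlap = sum(flag),
                                    n_promoter_cgi = n_prom,
                                    promoter_cgi_genes = genes)
  dmrs
}

#' Cross-match two DMR sets by shared CpG membership
#'
#' A pair (a, b) is matched when the CpGs shared by the two DMRs cover at
#' least `min_shared_frac` of the member sites of each. Over all shared CpGs
#' of all matched pairs, the Pearson correlation between the per-site
#' methylation differences observed in the two comparisons is reported.
#'
#' @param setA,setB `dmr_set` data.frames carrying `members` list columns.
#' @param min_shared_frac minimum shared fraction on both sides.
#' @return list with `pairs` (data.frame `idx_a, idx_b, n_shared`),
#'   `shared_diffs` (`diff_a`, `diff_b` per shared CpG) and `pearson_r`
#'   (`NA` with a warning when fewer than 3 shared CpGs exist).
#' @export
crossmatch_dmrs <- function(setA, setB, min_shared_frac = 0.5) {
  key <- function(ms, ch) paste(ch, ms$pos)
  pairs <- list(); da <- numeric(); db <- numeric()
  for (i in seq_len(nrow(setA))) {
    ka <- key(setA$members[[i]], setA$chrom[i])
    cand <- which(setB$chrom == setA$chrom[i] &
                    setB$start < setA$end[i] & setB$end > setA$start[i])
    for (j in cand) {
      kb <- key(setB$members[[j]], setB$chrom[j])
      sh <- intersect(ka, kb)
      if (length(sh) >= min_shared_frac * length(ka) &&
          length(sh) >= min_shared_frac * length(kb)) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(idx_a = i, idx_b = j, n_shared = length(sh))
        da <- c(da, setA$members[[i]]$diff[match(sh, ka)])
        db <- c(db, setB$members[[j]]$diff[match(sh, kb)])
      }
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(idx_a = integer(), idx_b = integer(), n_shared = integer())
  r <- NA_real_
  if (length(da) >= 3L && stats::sd(da) > 0 && stats::sd(db) > 0) {
    r <- stats::cor(da, db)
  } else if (length(da) < 3L) {
    warning("fewer than 3 shared CpGs; correlation undefined")
  }
  list(pairs = pairs,
       shared_diffs = data.frame(diff_a = da, diff_b = db),
       pearson_r = r)
}

#' Venn region counts for 2-3 gene sets
#'
#' @param gene_sets named list of 2 or 3 character vectors.
#' @return named integer vector of exclusive region sizes (names are
#'   membership patterns such as `"A"`, `"AB"`, `"ABC"`).
#' @export
venn_counts <- function(gene_sets) {
  k <- length(gene_sets)
  if (k < 2L || k > 3L) stop("venn_counts handles 2 or 3 sets")
  nm <- names(gene_sets) %||% LETTERS[seq_len(k)]
  if (is.null(names(gene_sets))) names(gene_sets) <- nm
  all_genes <- unique(unlist(gene_sets))
  member <- vapply(gene_sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L)
  pat <- apply(member, 1L, function(row) paste(nm[row], collapse = ""))
  pats <- unlist(lapply(seq_len(k), function(i)
    apply(utils::combn(nm, i), 2L, paste, collapse = "")))
  counts <- stats::setNames(integer(length(pats)), pats)
  tb <- table(pat)
  counts[names(tb)] <- as.integer(tb)
  counts
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric test of each gene set for over-representation in
#' the query versus the background, BH-adjusted across sets.
#'
#' @param query_genes character vector of genes of interest (must be a
#'   subset of the background).
#' @param background_genes character vector defining the universe.
#' @param gene_sets named list of character vectors (intersected with the
#'   background).
#' @param alpha FDR threshold for the `enriched` flag.
#' @return data.frame `set, n_set, n_overlap, p, q, enriched`.
#' @export
ora_enrichment <- function(query_genes, background_genes, gene_sets,
                           alpha = 0.05) {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  if (length(query_genes) == 0L || length(background_genes) == 0L)
    stop("empty query or background")
  if (!all(query_genes %in% background_genes))
    stop("query genes must be a subset of the background")
  N <- length(background_genes)
  k <- length(query_genes)
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background_genes)
    x <- length(intersect(set, query_genes))
    p <- stats::phyper(x - 1L, length(set), N - length(set), k,
                       lower.tail = FALSE)
    data.frame(set = nm, n_set = length(set), n_overlap = x, p = p)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$enriched <- out$q < alpha
  rownames(out) <- NULL
  out
}
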