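#' Load a genome from FASTA
#'
#' Reads a (multi-)FASTA file into a named [Biostrings::DNAStringSet].
#' Sequence names are truncated at the first whitespace, lowercase bases are
#' uppercased, and IUPAC ambiguity codes other than N are coerced to N with a
#' warning. Gap or other non-nucleotide symbols are rejected.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet], one element per chromosome, in file
#'   order.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(nm))) stop("empty FASTA header in ", path)
  if (anyDuplicated(nm))
    stop("duplicate FASTA header: ", nm[duplicated(nm)][1L])
  names(seqs) <- nm
  af <- colSums(Biostrings::alphabetFrequency(seqs))
  bad <- af[c("-", "+", ".")]
  if (any(bad > 0)) stop("non-nucleotide characters (gap symbols) in ", path)
  amb <- setdiff(names(af)[af > 0], c("A", "C", "G", "T", "N"))
  if (length(amb)) {
    warning("coercing IUPAC ambiguity codes to N: ",
            paste(amb, collapse = ", "))
    seqs <- Biostrings::DNAStringSet(
      chartr(paste(amb, collapse = ""),
             strrep("N", length(amb)),
             as.character(seqs)))
  }
  seqs
}

#' Enumerate forward-strand CpG dinucleotides
#'
#' @param genome a [Biostrings::DNAStringSet] as returned by [load_genome()].
#' @return data.frame with columns `chrom` and `pos` (0-based position of the
#'   forward-strand C), sorted by chromosome (genome order) then position.
#'   Dinucleotides containing N never match.
#' @export
enumerate_cpgs <- function(genome) {
  if (!methods::is(genome, "DNAStringSet")) stop("genome must be a DNAStringSet")
  hits <- Biostrings::vmatchPattern("CG", genome)
  res <- lapply(names(genome), function(ch) {
    st <- BiocGenerics::start(hits[[ch]])
    if (length(st) == 0L) return(NULL)
    data.frame(chrom = ch, pos = sort(st) - 1L)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) res <- data.frame(chrom = character(), pos = integer())
  rownames(res) <- NULL
  res
}

CONTEXTS <- c("CpG", "CHG", "CHH")

new_cpg_counts <- function(df, sample = NA_character_, check = TRUE) {
  req <- c("chrom", "pos", "strand", "context", "count_meth", "count_unmeth")
  if (!all(req %in% names(df)))
    stop("count table needs columns: ", paste(req, collapse = ", "))
  df <- df[req]
  if (check && nrow(df)) {
    if (any(df$count_meth < 0 | df$count_unmeth < 0))
      stop("negative counts in methylation table")
    if (!all(df$context %in% CONTEXTS))
      stop("unknown context token: ",
           paste(unique(setdiff(df$context, CONTEXTS)), collapse = ", "))
    if (!all(df$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
    key <- paste(df$chrom, df$pos, df$strand)
    if (anyDuplicated(key))
      stop("duplicate (chrom, pos, strand) key: ", key[duplicated(key)][1L])
  }
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, sample = sample, class = c("cpg_counts", "data.frame"))
}

#' Read a per-cytosine methylation call table
#'
#' The on-disk format is a tab-separated table with columns
#' `chrom, pos, strand, context, count_meth, count_unmeth` (1-based cytosine
#' positions; an optional header line starting with `#`). Methylation level at
#' a covered site is `count_meth / (count_meth + count_unmeth)`.
#'
#' @param path path to the TSV file.
#' @param sample_label label attached to the returned table.
#' @return a `cpg_counts` data.frame keyed by (chrom, pos, strand).
#' @export
read_methylation_calls <- function(path, sample_label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#",
                          col.names = c("chrom", "pos", "strand", "context",
                                        "count_meth", "count_unmeth"),
                          colClasses = c("character", "integer", "character",
                                        "character", "integer", "integer"))
  new_cpg_counts(df, sample = sample_label)
}

#' Write a methylation call table
#'
#' @param table a `cpg_counts` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylation_calls <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tpos\tstrand\tcontext\tcount_meth\tcount_unmeth", con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge CpG counts onto the forward strand
#'
#' Counts reported on the reverse-strand cytosine of a genomic CpG (position
#' p+1 of a CG at p, 0-based) are added to the forward-strand record so each
#' genomic CpG is represented once, at the position of its forward-strand C.
#' Non-CpG-context rows pass through untouched.
#'
#' @param table a `cpg_counts` table.
#' @param genome the matching [Biostrings::DNAStringSet]; used to verify that
#'   every reverse-strand record sits on a genomic CpG.
#' @return a `cpg_counts` table containing only `+`-strand CpG records (plus
#'   any non-CpG rows).
#' @export
merge_strands <- function(table, genome) {
  cg <- table$context == "CpG"
  cpg <- as.data.frame(table[cg, , drop = FALSE])
  rest <- as.data.frame(table[!cg, , drop = FALSE])
  if (nrow(cpg)) {
    if (!all(cpg$chrom %in% names(genome)))
      stop("count table chromosome absent from genome")
    neg <- cpg$strand == "-"
    if (any(neg)) {
      chk <- cpg[neg, , drop = FALSE]
      for (ch in unique(chk$chrom)) {
        s <- as.character(genome[[ch]])
        p <- chk$pos[chk$chrom == ch]         # 1-based G position
        if (any(p < 2L) || !all(substring(s, p - 1L, p) == "CG"))
          stop("reverse-strand CpG record without an opposing genomic CpG on ",
               ch)
      }
      cpg$pos[neg] <- cpg$pos[neg] - 1L       # fold onto the forward C
      cpg$strand[neg] <- "+"
      agg <- stats::aggregate(
        cbind(count_meth, count_unmeth) ~ chrom + pos,
        data = cpg, FUN = sum)
      agg$strand <- "+"
      agg$context <- "CpG"
      cpg <- agg[c("chrom", "pos", "strand", "context",
                   "count_meth", "count_unmeth")]
    }
  }
  new_cpg_counts(rbind(cpg, rest), sample = attr(table, "sample"))
}

#' Load interval, gene-model or gene-set annotation
#'
#' @param path file path.
#' @param kind one of `"intervals"` (BED3/6), `"genes"` (BED12) or
#'   `"genesets"` (GMT).
#' @return for `"intervals"`, a data.frame `chrom,start,end,name,strand`
#'   (0-based half-open); for `"genes"`, a data.frame
#'   `chrom,start,end,strand,gene_id` with list columns `exon_starts` /
#'   `exon_ends`; for `"genesets"`, a named list of character vectors.
#' @export
load_annotation <- function(path, kind = c("intervals", "genes", "genesets")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  if (kind == "genesets") {
    sets <- fgsea::gmtPathways(path)
    if (any(lengths(sets) == 0L)) stop("empty gene set in ", path)
    return(sets)
  }
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   name = if (!is.null(gr$name)) gr$name else NA_character_,
                   strand = as.character(BiocGenerics::strand(gr)))
  if (nrow(df) && any(df$start >= df$end)) stop("BED interval with start >= end")
  if (kind == "intervals") return(df)
  blocks <- gr$blocks
  if (is.null(blocks)) stop("BED12 block fields required for kind = 'genes'")
  if (any(!df$strand %in% c("+", "-")))
    stop("gene models require a '+' or '-' strand")
  df$gene_id <- if (!all(is.na(df$name))) df$name else
    sprintf("gene%04d", seq_len(nrow(df)))
  df$exon_starts <- lapply(seq_len(nrow(df)), function(i)
    df$start[i] + BiocGenerics::start(blocks[[i]]) - 1L)
  df$exon_ends <- lapply(seq_len(nrow(df)), function(i)
    df$start[i] + BiocGenerics::end(blocks[[i]]))
  validate_genes(df)
}

validate_genes <- function(genes) {
  req <- c("chrom", "start", "end", "strand", "gene_id",
           "exon_starts", "exon_ends")
  if (!all(req %in% names(genes)))
    stop("gene models need columns: ", paste(req, collapse = ", "))
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) == 0L || length(es) != length(ee))
      stop("gene ", genes$gene_id[i], ": malformed exon blocks")
    if (is.unsorted(es, strictly = TRUE) && length(es) > 1L)
      stop("gene ", genes$gene_id[i], ": exons must be sorted")
    if (any(es >= ee) || any(es < genes$start[i]) || any(ee > genes$end[i]))
      stop("gene ", genes$gene_id[i], ": exon outside gene span")
    if (length(es) > 1L && any(es[-1L] < ee[-length(ee)]))
      stop("gene ", genes$gene_id[i], ": overlapping exons")
  }
  genes[c("chrom", "start", "end", "strand", "gene_id",
          "exon_starts", "exon_ends")]
}

#' Write intervals as BED
#'
#' @param df interval data.frame (`chrom,start,end[,name][,strand][,score]`),
#'   0-based half-open.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  stop_if_not_intervals(df)
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end)
  if (!is.null(df$name) || !is.null(df$strand)) {
    out$name <- df$name %||% "."
    out$score <- df$score %||% 0
    out$strand <- df$strand %||% "."
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as BED12
#'
#' @param genes gene-model data.frame (see [load_annotation()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(genes, path) {
  genes <- validate_genes(genes)
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    paste(genes$chrom[i], genes$start[i], genes$end[i], genes$gene_id[i], 0,
          genes$strand[i], genes$start[i], genes$end[i], "0,0,0", length(es),
          paste0(paste(ee - es, collapse = ","), ","),
          paste0(paste(es - genes$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.cpg_counts <- function(x, ...) {
  cat(sprintf("<cpg_counts> %d sites (sample: %s)\n", nrow(x),
              attr(x, "sample") %||% NA))
  ctx <- table(x$context)
  cat("  contexts:", paste(sprintf("%s=%d", names(ctx), ctx), collapse = " "),
      "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}
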