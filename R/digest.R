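#' In silico restriction digest
#'
#' Cuts every chromosome at each occurrence of a recognition site, placing the
#' cut `cut_offset` bases into the site (MspI cuts C^CGG, i.e. offset 1).
#' Overlapping site occurrences each produce a cut. Fragments tile each
#' chromosome without gaps; chromosome-terminal fragment ends are flagged as
#' non-enzymatic.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param recognition recognition site (DNA string).
#' @param cut_offset cut position within the site, `0 <= cut_offset <=
#'   nchar(recognition)`.
#' @return data.frame `chrom, start, end, length, left_cut, right_cut`
#'   (0-based half-open).
#' @export
digest <- function(genome, recognition = "CCGG", cut_offset = 1L) {
  if (!methods::is(genome, "DNAStringSet")) stop("genome must be a DNAStringSet")
  if (length(genome) == 0L) stop("empty genome")
  if (!grepl("^[ACGT]+$", recognition)) stop("recognition must be a DNA string")
  if (cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset out of range")
  res <- lapply(names(genome), function(ch) {
    len <- length(genome[[ch]])
    st <- BiocGenerics::start(
      Biostrings::matchPattern(recognition, genome[[ch]]))
    cuts <- sort(unique(st - 1L + cut_offset))
    cuts <- cuts[cuts > 0L & cuts < len]
    bnd <- c(0L, cuts, len)
    n <- length(bnd) - 1L
    data.frame(chrom = ch, start = bnd[-length(bnd)], end = bnd[-1L],
               length = diff(bnd),
               left_cut = c(FALSE, rep(TRUE, n - 1L)),
               right_cut = c(rep(TRUE, n - 1L), FALSE))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Size-select digest fragments
#'
#' Keeps fragments whose length lies in `[min_len, max_len]`; with
#' `require_both_cuts` (the default, as both ends must carry enzyme overhangs
#' for adapter ligation) chromosome-terminal fragments are excluded.
#'
#' @param fragments output of [digest()].
#' @param min_len,max_len inclusive length bounds (the study's RRBS window is
#'   40-220 bp).
#' @param require_both_cuts drop fragments with a non-enzymatic end.
#' @return the retained fragment rows.
#' @export
size_select <- function(fragments, min_len = 40L, max_len = 220L,
                        require_both_cuts = TRUE) {
  if (min_len > max_len) stop("min_len > max_len")
  keep <- fragments$length >= min_len & fragments$length <= max_len
  if (require_both_cuts) keep <- keep & fragments$left_cut & fragments$right_cut
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CpG recovery of a fragment set
#'
#' Counts distinct genomic CpGs recovered by a set of (size-selected)
#' fragments, in two modes: whole-fragment (every CpG fully inside a fragment;
#' the theoretical maximum) and, when `read_len` is given, read-covered (CpGs
#' within the first/last `read_len` bases of each fragment, emulating
#' paired-end reads). Fractions are reported against all genomic CpGs and,
#' when a CGI set is supplied, against CpGs inside CGIs.
#'
#' @param fragments fragment data.frame (from [digest()]/[size_select()]).
#' @param genome the source [Biostrings::DNAStringSet].
#' @param cgis optional CGI interval data.frame (0-based half-open).
#' @param read_len optional read length for read-covered mode.
#' @return a list of class `recovery_stats`.
#' @export
recovery_stats <- function(fragments, genome, cgis = NULL, read_len = NULL) {
  cpgs <- enumerate_cpgs(genome)
  cpg_gr <- GenomicRanges::GRanges(cpgs$chrom,
                                   IRanges::IRanges(cpgs$pos + 1L, width = 2L))
  count_within <- function(regions_gr) {
    if (length(regions_gr) == 0L || length(cpg_gr) == 0L) return(0L)
    length(unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(cpg_gr, regions_gr, type = "within"))))
  }
  frag_gr <- as_gr(fragments)
  n_whole <- count_within(frag_gr)
  n_read <- NA_integer_
  if (!is.null(read_len)) {
    lead <- fragments
    lead$end <- pmin(lead$start + read_len, lead$end)
    tail_ <- fragments
    tail_$start <- pmax(tail_$end - read_len, tail_$start)
    n_read <- count_within(GenomicRanges::reduce(
      c(as_gr(lead), as_gr(tail_))))
  }
  n_all <- nrow(cpgs)
  res <- list(n_distinct_cpgs = n_whole,
              n_read_covered = n_read,
              n_all_cpgs = n_all,
              frac_of_all_cpgs = if (n_all) n_whole / n_all else 0,
              frac_read_covered = if (!is.na(n_read) && n_all)
                n_read / n_all else NA_real_)
  if (!is.null(cgis)) {
    stop_if_not_intervals(cgis, "cgis")
    if (nrow(cgis) && !all(cgis$chrom %in% names(genome)))
      stop("CGI set on a different chromosome namespace")
    cgi_gr <- as_gr(cgis)
    in_cgi <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(cpg_gr, cgi_gr, type = "within")))
    n_cgi <- length(in_cgi)
    hit_cgi <- if (length(frag_gr)) intersect(in_cgi, S4Vectors::queryHits(
      GenomicRanges::findOverlaps(cpg_gr, frag_gr, type = "within"))) else
        integer()
    res$n_cgi_cpgs <- n_cgi
    res$n_cgi_recovered <- length(hit_cgi)
    res$frac_of_cgi_cpgs <- if (n_cgi) length(hit_cgi) / n_cgi else NA_real_
  }
  structure(res, class = "recovery_stats")
}

#' @export
print.recovery_stats <- function(x, ...) {
  cat(sprintf("CpG recovery: %d / %d distinct CpGs (%.2f%%) whole-fragment\n",
              x$n_distinct_cpgs, x$n_all_cpgs, 100 * x$frac_of_all_cpgs))
  if (!is.na(x$n_read_covered))
    cat(sprintf("  read-covered: %d (%.2f%%)\n", x$n_read_covered,
                100 * x$frac_read_covered))
  if (!is.null(x$n_cgi_cpgs))
    cat(sprintf("  CGI CpGs: %d / %d (%.2f%%)\n", x$n_cgi_recovered,
                x$n_cgi_cpgs, 100 * x$frac_of_cgi_cpgs))
  invisible(x)
}

#' Scan a genome for CpG islands
#'
#' Classical sliding-window CGI definition: windows of `min_len` bp with GC
#' fraction >= `min_gc` and CpG observed/expected ratio
#' `(#CpG * L) / (#C * #G)` >= `min_oe` (Gardiner-Garden-Frommer). Qualifying
#' windows at 1-bp stride are merged and each merged region re-checked against
#' the same criteria.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param min_len window / minimum island length in bp.
#' @param min_gc minimum GC fraction.
#' @param min_oe minimum CpG observed/expected ratio.
#' @return interval data.frame `chrom,start,end,gc,oe` (0-based half-open).
#' @export
cgi_scan <- function(genome, min_len = 200L, min_gc = 0.5, min_oe = 0.6) {
  res <- lapply(names(genome), function(ch) {
    s <- strsplit(as.character(genome[[ch]]), "")[[1]]
    L <- length(s)
    if (L < min_len) return(NULL)
    isC <- cumsum(c(0L, s == "C"))
    isG <- cumsum(c(0L, s == "G"))
    cg <- cumsum(c(0L, s[-L] == "C" & s[-1L] == "G", 0L))
    win_stats <- function(a, b) {        # 0-based half-open [a, b)
      w <- b - a
      nC <- isC[b + 1L] - isC[a + 1L]
      nG <- isG[b + 1L] - isG[a + 1L]
      # CpG starts fully inside: positions a .. b-2  -> cumsum idx a+1 .. b-1
      ncpg <- cg[b] - cg[a + 1L]
      gc <- (nC + nG) / w
      oe <- if (nC > 0L && nG > 0L) (ncpg * w) / (nC * nG) else 0
      c(gc = gc, oe = oe)
    }
    starts <- 0:(L - min_len)
    ends <- starts + min_len
    nC <- isC[ends + 1L] - isC[starts + 1L]
    nG <- isG[ends + 1L] - isG[starts + 1L]
    ncpg <- cg[ends] - cg[starts + 1L]
    gc <- (nC + nG) / min_len
    oe <- ifelse(nC > 0L & nG > 0L, (ncpg * min_len) / (nC * nG), 0)
    ok <- which(gc >= min_gc & oe >= min_oe)
    if (length(ok) == 0L) return(NULL)
    # merge overlapping/adjacent qualifying windows
    runs <- split(ok, cumsum(c(1L, diff(ok) > min_len)))
    merged <- lapply(runs, function(idx)
      c(starts[idx[1L]], ends[idx[length(idx)]]))
    out <- lapply(merged, function(ab) {
      a <- ab[1L]; b <- ab[2L]
      # trim non-C/G termini (merging can pad a dense core with AT flank)
      while (b - a >= min_len && !(s[a + 1L] %in% c("C", "G"))) a <- a + 1L
      while (b - a >= min_len && !(s[b] %in% c("C", "G"))) b <- b - 1L
      st <- win_stats(a, b)
      if (b - a >= min_len && st["gc"] >= min_gc && st["oe"] >= min_oe)
        data.frame(chrom = ch, start = a, end = b,
                   gc = unname(st["gc"]), oe = unname(st["oe"]))
      else NULL
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), gc = numeric(), oe = numeric())
  rownames(out) <- NULL
  out
}
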