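#' Select candidate CpG sites for a two-group comparison
#'
#' Candidate sites are CpGs covered in both groups with depth at least
#' `min_depth` in each, outside the excluded (sex) chromosomes. When
#' `compute_tests` is set (the default) each site also carries the two-sided
#' Fisher exact p-value on its C/T counts and its BH-adjusted value across
#' all candidate sites of the comparison.
#'
#' @param table1,table2 strand-merged `cpg_counts` tables for the two groups.
#' @param min_depth minimum depth per group (study default 5).
#' @param exclude_chroms chromosome names dropped before testing (the study
#'   excluded the X chromosome).
#' @param compute_tests add `p_raw` / `p_adj` columns.
#' @return data.frame of class `candidate_sites`, sorted by (chrom, pos),
#'   with columns `chrom, pos, m1, u1, m2, u2, level1, level2, diff`
#'   (`diff = level2 - level1`) and, when tested, `p_raw, p_adj,
#'   is_significant`.
#' @export
select_candidates <- function(table1, table2, min_depth = 5L,
                              exclude_chroms = c("X", "chrX"),
                              compute_tests = TRUE) {
  if (min_depth < 1L) stop("min_depth must be >= 1")
  t1 <- as.data.frame(table1); t1 <- t1[t1$context == "CpG", ]
  t2 <- as.data.frame(table2); t2 <- t2[t2$context == "CpG", ]
  m <- merge(t1[c("chrom", "pos", "count_meth", "count_unmeth")],
             t2[c("chrom", "pos", "count_meth", "count_unmeth")],
             by = c("chrom", "pos"), suffixes = c("1", "2"))
  names(m) <- c("chrom", "pos", "m1", "u1", "m2", "u2")
  d1 <- m$m1 + m$u1; d2 <- m$m2 + m$u2
  m <- m[d1 >= min_depth & d2 >= min_depth &
           !(m$chrom %in% exclude_chroms), , drop = FALSE]
  if (nrow(m) == 0L) warning("no shared candidate sites between the groups")
  m <- m[order(m$chrom, m$pos), , drop = FALSE]
  rownames(m) <- NULL
  m$level1 <- ifelse(m$m1 + m$u1 > 0, m$m1 / (m$m1 + m$u1), NA_real_)
  m$level2 <- ifelse(m$m2 + m$u2 > 0, m$m2 / (m$m2 + m$u2), NA_real_)
  m$diff <- m$level2 - m$level1
  if (compute_tests && nrow(m)) {
    m$p_raw <- fisher_two_sided(m$m1, m$u1, m$m2, m$u2)
    m$p_adj <- bh_adjust(m$p_raw)
    m$is_significant <- m$p_adj < 0.05
  }
  class(m) <- c("candidate_sites", "data.frame")
  m
}

#' Sliding-window scan for candidate DMRs
#'
#' Scans candidate sites left to right per chromosome. The first site with
#' adjusted p below `seed_alpha` opens a window whose direction is the sign of
#' its methylation difference; following candidate sites are merged while the
#' inter-site distance stays within `max_gap` bp and their difference keeps
#' the window direction (zero differences never break a window). A window
#' closes on a gap violation, a direction flip or the chromosome end, and is
#' emitted as a candidate DMR when it holds at least `min_sites` candidate
#' CpGs of which at least `min_sig` are individually significant at raw
#' p < `site_alpha`. Scanning resumes after the closed window, so emitted
#' windows are disjoint.
#'
#' @param sites a `candidate_sites` data.frame carrying `p_raw` and `p_adj`.
#' @param max_gap maximum distance between neighboring member sites (bp).
#' @param min_sites minimum member CpGs per DMR.
#' @param min_sig minimum members with raw p < `site_alpha`.
#' @param seed_alpha threshold on the seeding p-value.
#' @param site_alpha per-site significance threshold for `min_sig`.
#' @param seed_on seed on the BH-adjusted (default) or raw per-site p-value.
#' @return data.frame of candidate DMRs with a `members` list column holding
#'   the member-site rows.
#' @export
scan_candidate_dmrs <- function(sites, max_gap = 300L, min_sites = 5L,
                                min_sig = 3L, seed_alpha = 0.05,
                                site_alpha = 0.05,
                                seed_on = c("adjusted", "raw")) {
  seed_on <- match.arg(seed_on)
  if (!all(c("p_raw", "p_adj") %in% names(sites)))
    stop("sites must carry p_raw and p_adj (see select_candidates)")
  if (nrow(sites) &&
      is.unsorted(order(sites$chrom, sites$pos)))  # defensive; see below
    sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  p_seed <- if (seed_on == "adjusted") sites$p_adj else sites$p_raw
  out <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    pos <- sites$pos[idx]
    if (is.unsorted(pos, strictly = TRUE)) stop("unsorted candidate sites")
    dif <- sites$diff[idx]
    ps <- p_seed[idx]
    pr <- sites$p_raw[idx]
    n <- length(idx)
    i <- 1L
    while (i <= n) {
      if (!(ps[i] < seed_alpha) || dif[i] == 0) { i <- i + 1L; next }
      dir <- sign(dif[i])
      j <- i
      while (j < n && pos[j + 1L] - pos[j] <= max_gap &&
             (dif[j + 1L] == 0 || sign(dif[j + 1L]) == dir))
        j <- j + 1L
      mem <- idx[i:j]
      n_sig <- sum(pr[i:j] < site_alpha & dif[i:j] != 0)
      if (length(mem) >= min_sites && n_sig >= min_sig) {
        ms <- as.data.frame(sites[mem, , drop = FALSE])
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch,
          start = ms$pos[1L] - 1L,                 # first C, 0-based
          end = ms$pos[nrow(ms)] + 1L,             # past the last G
          n_sites = nrow(ms),
          n_sig = n_sig,
          mean1 = mean(ms$level1),
          mean2 = mean(ms$level2),
          diff = mean(ms$level2) - mean(ms$level1),
          direction = if (dir > 0) "hyper" else "hypo",
          members = I(list(ms)))
      }
      i <- j + 1L
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_sites = integer(), n_sig = integer(), mean1 = numeric(),
               mean2 = numeric(), diff = numeric(), direction = character(),
               members = I(list()))
  rownames(res) <- NULL
  res
}

#' Aggregate test and filtering of candidate DMRs
#'
#' Each candidate window is tested once more with a two-sided Fisher exact
#' test on the per-group mean C and T counts over its member sites (means
#' rounded half-up to integers), the aggregate p-values are BH-adjusted
#' across all candidates of the comparison, and windows are retained when
#' `q_bh < fdr_alpha` and the absolute difference of mean member levels is at
#' least `min_abs_diff`.
#'
#' @param candidates output of [scan_candidate_dmrs()].
#' @param fdr_alpha FDR threshold (study default 0.05).
#' @param min_abs_diff minimum |mean2 - mean1| (study default 0.20).
#' @return data.frame of class `dmr_set` with `p_aggregate` and `q_bh`.
#' @export
test_and_filter_dmrs <- function(candidates, fdr_alpha = 0.05,
                                 min_abs_diff = 0.20) {
  if (nrow(candidates) == 0L) {
    candidates$p_aggregate <- numeric()
    candidates$q_bh <- numeric()
    class(candidates) <- c("dmr_set", "data.frame")
    return(candidates)
  }
  agg <- t(vapply(candidates$members, function(ms) {
    pmax(c(round_half_up(mean(ms$m1)), round_half_up(mean(ms$u1)),
           round_half_up(mean(ms$m2)), round_half_up(mean(ms$u2))), 0L)
  }, integer(4)))
  candidates$p_aggregate <-
    fisher_two_sided(agg[, 1], agg[, 2], agg[, 3], agg[, 4])
  candidates$q_bh <- bh_adjust(candidates$p_aggregate)
  keep <- candidates$q_bh < fdr_alpha & abs(candidates$diff) >= min_abs_diff
  out <- candidates[keep, , drop = FALSE]
  out$direction <- ifelse(out$diff > 0, "hyper", "hypo")
  rownames(out) <- NULL
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' Call DMRs between two groups
#'
#' One-stop wrapper running candidate selection, per-site Fisher testing with
#' BH adjustment, the sliding-window scan and the aggregate test/filter.
#'
#' @inheritParams select_candidates
#' @inheritParams scan_candidate_dmrs
#' @inheritParams test_and_filter_dmrs
#' @return object of class `dmr_result`: a list with `dmrs` (a `dmr_set`),
#'   `candidates` (tested candidate sites), `n_candidate_windows` and
#'   `params`.
#' @export
call_dmrs <- function(table1, table2, min_depth = 5L,
                      exclude_chroms = c("X", "chrX"), max_gap = 300L,
                      min_sites = 5L, min_sig = 3L, seed_alpha = 0.05,
                      site_alpha = 0.05, fdr_alpha = 0.05,
                      min_abs_diff = 0.20, seed_on = "adjusted") {
  sites <- select_candidates(table1, table2, min_depth = min_depth,
                             exclude_chroms = exclude_chroms)
  cand <- scan_candidate_dmrs(sites, max_gap = max_gap,
                              min_sites = min_sites, min_sig = min_sig,
                              seed_alpha = seed_alpha,
                              site_alpha = site_alpha, seed_on = seed_on)
  dmrs <- test_and_filter_dmrs(cand, fdr_alpha = fdr_alpha,
                               min_abs_diff = min_abs_diff)
  structure(list(dmrs = dmrs, candidates = sites,
                 n_candidate_windows = nrow(cand),
                 params = list(min_depth = min_depth,
                               exclude_chroms = exclude_chroms,
                               max_gap = max_gap, min_sites = min_sites,
                               min_sig = min_sig, seed_alpha = seed_alpha,
                               site_alpha = site_alpha,
                               fdr_alpha = fdr_alpha,
                               min_abs_diff = min_abs_diff,
                               seed_on = seed_on)),
            class = "dmr_result")
}

#' @export
print.dmr_result <- function(x, ...) {
  cat(sprintf("<dmr_result> %d DMRs from %d candidate windows (%d candidate sites)\n",
              nrow(x$dmrs), x$n_candidate_windows, nrow(x$candidates)))
  if (nrow(x$dmrs)) {
    tab <- table(x$dmrs$direction)
    cat("  direction:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = " "), "\n")
    cat(sprintf("  mean length %.0f bp, mean %.1f CpGs\n",
                mean(x$dmrs$end - x$dmrs$start), mean(x$dmrs$n_sites)))
  }
  invisible(x)
}

#' @export
summary.dmr_result <- function(object, ...) {
  d <- object$dmrs
  res <- list(
    n_dmrs = nrow(d),
    n_candidate_sites = nrow(object$candidates),
    n_candidate_windows = object$n_candidate_windows,
    n_hyper = sum(d$direction == "hyper"),
    n_hypo = sum(d$direction == "hypo"),
    mean_length_bp = if (nrow(d)) mean(d$end - d$start) else NA_real_,
    mean_n_cpgs = if (nrow(d)) mean(d$n_sites) else NA_real_,
    params = object$params)
  class(res) <- "summary.dmr_result"
  res
}

#' @export
print.summary.dmr_result <- function(x, ...) {
  cat(sprintf(
    "Two-group DMR call: %d DMRs (%d hyper / %d hypo) from %d windows over %d candidate sites\n",
    x$n_dmrs, x$n_hyper, x$n_hypo, x$n_candidate_windows,
    x$n_candidate_sites))
  if (!is.na(x$mean_length_bp))
    cat(sprintf("  mean length %.0f bp, mean %.1f CpGs per DMR\n",
                x$mean_length_bp, x$mean_n_cpgs))
  invisible(x)
}

#' Write a DMR set as TSV and BED6
#'
#' @param dmrs a `dmr_set` (or the `dmrs` element of a `dmr_result`).
#' @param tsv,bed output paths (either may be `NULL`).
#' @return invisibly, the written paths.
#' @export
write_dmrs <- function(dmrs, tsv = NULL, bed = NULL) {
  if (methods::is(dmrs, "dmr_result")) dmrs <- dmrs$dmrs
  if (!is.null(tsv)) {
    flat <- as.data.frame(dmrs[setdiff(names(dmrs), "members")])
    flat$member_pos <- vapply(dmrs$members, function(ms)
      paste(ms$pos, collapse = ","), character(1))
    utils::write.table(flat, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed)) {
    score <- pmin(round(-10 * log10(pmax(dmrs$q_bh, 1e-100))), 1000)
    write_bed(data.frame(chrom = dmrs$chrom, start = dmrs$start,
                         end = dmrs$end, name = dmrs$direction,
                         score = score, strand = "."), bed)
  }
  invisible(c(tsv = tsv, bed = bed))
}

#' Check the structural invariants of a DMR set
#'
#' Asserts, for every DMR: at least the minimum member count and significant
#' count, consistent member sign versus direction, bounded inter-member gaps
#' and p/q values in `[0, 1]`. Used as a post-hoc guard in tests and the
#' simulation study.
#'
#' @param dmrs a `dmr_set`.
#' @param max_gap,min_sites,min_sig the parameters the set was called with.
#' @return `TRUE` (invisibly); stops on violation.
#' @export
check_dmr_invariants <- function(dmrs, max_gap = 300L, min_sites = 5L,
                                 min_sig = 3L) {
  if (methods::is(dmrs, "dmr_result")) dmrs <- dmrs$dmrs
  for (i in seq_len(nrow(dmrs))) {
    ms <- dmrs$members[[i]]
    stopifnot(dmrs$n_sites[i] >= min_sites,
              dmrs$n_sig[i] >= min_sig,
              nrow(ms) == dmrs$n_sites[i],
              !is.unsorted(ms$pos, strictly = TRUE),
              all(diff(ms$pos) <= max_gap),
              dmrs$q_bh[i] >= 0, dmrs$q_bh[i] <= 1,
              dmrs$p_aggregate[i] >= 0, dmrs$p_aggregate[i] <= 1)
    dir_sign <- if (dmrs$direction[i] == "hyper") 1 else -1
    nz <- ms$diff[ms$diff != 0]
    stopifnot(all(sign(nz) == dir_sign))
  }
  if (nrow(dmrs) > 1L) {
    o <- order(dmrs$chrom, dmrs$start)
    d <- dmrs[o, ]
    same <- d$chrom[-1L] == d$chrom[-nrow(d)]
    stopifnot(all(d$start[-1L][same] >= d$end[-nrow(d)][same]))
  }
  invisible(TRUE)
}
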