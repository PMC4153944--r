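#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with validated
#' defaults. Defaults emulate a pooled two-group RRBS comparison:
#' CGI-hypomethylated / background-hypermethylated structure, 200 planted
#' DMRs of 10 CpGs with a +0.30 methylation shift in group 2, negative
#' binomial depth around 20x per individual library, mild beta-binomial
#' overdispersion (0.02) representing biological pooling variance, a 0.5%
#' bisulfite non-conversion rate at non-CpG cytosines, and 2-3 animals pooled
#' per library (3 here; validation panels use 6 individuals per group).
#'
#' @param n_chroms,chrom_length number and length (bp) of chromosomes.
#' @param cgi_count,cgi_length_mean,cgi_length_sd CGI placement parameters
#'   (counts are genome-wide).
#' @param gene_count,gene_length_mean number and mean length of genes.
#' @param cgi_mean,background_mean,beta_conc baseline Beta-distributed
#'   methylation means inside/outside CGIs and the Beta concentration.
#' @param dmr_count,dmr_width,dmr_delta planted DMRs: how many, how many
#'   consecutive CpGs each, and the signed level shift applied to group 2.
#' @param depth_mean,depth_dispersion negative-binomial depth model
#'   (dispersion 0 gives Poisson); depth is truncated at 1.
#' @param bb_dispersion beta-binomial overdispersion of methylated counts
#'   (0 gives the pure binomial model).
#' @param non_conversion_rate apparent methylation at non-CpG cytosines.
#' @param noncpg_sites number of non-CpG cytosine rows emitted per table.
#' @param n_individuals individuals per group.
#' @param clones_per_amplicon Sanger clones per amplicon.
#' @param bsp_depth mean HiSeq-BSP depth per CpG.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 4L, chrom_length = 1200000L,
                       cgi_count = 60L, cgi_length_mean = 1000L,
                       cgi_length_sd = 150L, gene_count = 120L,
                       gene_length_mean = 3000L, cgi_mean = 0.10,
                       background_mean = 0.75, beta_conc = 30,
                       dmr_count = 200L, dmr_width = 10L, dmr_delta = 0.3,
                       depth_mean = 20, depth_dispersion = 0.1,
                       bb_dispersion = 0.02, non_conversion_rate = 0.005,
                       noncpg_sites = 2000L, n_individuals = 3L,
                       clones_per_amplicon = 20L, bsp_depth = 1000) {
  cfg <- as.list(environment())
  rates <- c(cgi_mean, background_mean, bb_dispersion, non_conversion_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (abs(dmr_delta) > 1) stop("|dmr_delta| must be <= 1")
  if (depth_mean < 1) stop("depth_mean must be >= 1")
  if (depth_dispersion < 0 || beta_conc <= 0) stop("invalid dispersion")
  if (n_chroms < 1 || chrom_length < 1000) stop("invalid genome dimensions")
  structure(cfg, class = "sim_config")
}

# iid base sampler returning a character vector
rand_bases <- function(n, p) sample(c("A", "C", "G", "T"), n, TRUE, prob = p)

#' Simulate a genome with CGIs and gene models
#'
#' Background sequence is drawn at 40% GC with CpG dinucleotides thinned to
#' an observed/expected ratio near 0.25 (mimicking genome-wide CpG
#' depletion); CGI intervals are overwritten with 60% GC sequence at CpG
#' o/e near 1. Genes are placed without overlap, half of them (where
#' possible) with their TSS inside a CGI so promoter-CGI DMRs can arise;
#' each gene carries 1-3 exons.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; output is a pure function of (config, seed).
#' @return list of class `sim_genome` with `genome` (DNAStringSet), `genes`,
#'   `cgis`, `config`, `seed`.
#' @export
simulate_genome <- function(config = sim_config(), seed = 1L) {
  stopifnot(methods::is(config, "sim_config"))
  with_seed(seed, {
    L <- config$chrom_length
    chroms <- sprintf("chr%d", seq_len(config$n_chroms))
    per_chrom <- diff(round(seq(0, config$cgi_count,
                                length.out = config$n_chroms + 1L)))
    cgis <- list(); seqs <- character(config$n_chroms)
    for (ci in seq_len(config$n_chroms)) {
      s <- rand_bases(L, c(.3, .2, .2, .3))
      cg <- which(s[-L] == "C" & s[-1L] == "G")
      kill <- cg[stats::runif(length(cg)) > 0.25]
      s[kill + 1L] <- sample(c("A", "T"), length(kill), TRUE)
      n_cgi <- per_chrom[ci]
      if (n_cgi > 0L) {
        lens <- pmax(400L, round(stats::rnorm(n_cgi, config$cgi_length_mean,
                                              config$cgi_length_sd)))
        slots <- floor(L / n_cgi)
        if (any(lens + 2000L > slots))
          stop("requested CGIs do not fit in the genome")
        starts <- (seq_len(n_cgi) - 1L) * slots +
          floor(stats::runif(n_cgi, 1000, slots - lens - 1000))
        for (k in seq_len(n_cgi))
          s[(starts[k] + 1L):(starts[k] + lens[k])] <-
            rand_bases(lens[k], c(.2, .3, .3, .2))
        cgis[[ci]] <- data.frame(chrom = chroms[ci], start = starts,
                                 end = starts + lens,
                                 name = sprintf("cgi_%s_%d", chroms[ci],
                                                seq_len(n_cgi)))
      }
      seqs[ci] <- paste(s, collapse = "")
    }
    genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
    cgis <- do.call(rbind, cgis)
    rownames(cgis) <- NULL
    genes <- place_genes(config, chroms, L, cgis)
    structure(list(genome = genome, genes = genes, cgis = cgis,
                   config = config, seed = seed), class = "sim_genome")
  })
}

place_genes <- function(config, chroms, L, cgis) {
  n <- config$gene_count
  if (n == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_id = character(),
                      exon_starts = I(list()), exon_ends = I(list())))
  occupied <- lapply(chroms, function(ch) NULL)
  names(occupied) <- chroms
  free <- function(ch, a, b) {
    occ <- occupied[[ch]]
    a >= 0 && b <= L &&
      (is.null(occ) || !any(a < occ[, 2] & b > occ[, 1]))
  }
  rows <- vector("list", n)
  n_at_cgi <- min(n %/% 2L, if (is.null(cgis)) 0L else nrow(cgis))
  for (g in seq_len(n)) {
    glen <- max(600L, round(stats::rnorm(1, config$gene_length_mean,
                                         config$gene_length_mean * 0.3)))
    placed <- FALSE
    for (try in seq_len(400L)) {
      strand <- sample(c("+", "-"), 1L)
      if (g <= n_at_cgi && try <= 50L) {
        cgi <- cgis[g, ]
        ch <- cgi$chrom
        tss <- cgi$start + sample.int(max(cgi$end - cgi$start - 1L, 1L), 1L)
        a <- if (strand == "+") tss else tss - glen + 1L
      } else {
        ch <- sample(chroms, 1L)
        a <- sample.int(L - glen - 1L, 1L) - 1L
      }
      b <- a + glen
      if (free(ch, a, b)) {
        occupied[[ch]] <- rbind(occupied[[ch]], c(a, b))
        n_ex <- sample(1:3, 1L)
        cuts <- sort(sample.int(glen - 2L, 2L * n_ex - 1L))
        es <- a + c(0L, cuts[seq_len(n_ex - 1L) * 2L])
        ee <- c(a + cuts[seq_len(n_ex) * 2L - 1L], b)[seq_len(n_ex)]
        ee[n_ex] <- b
        rows[[g]] <- data.frame(chrom = ch, start = a, end = b,
                                strand = strand,
                                gene_id = sprintf("gene%04d", g),
                                exon_starts = I(list(es)),
                                exon_ends = I(list(ee)))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("requested genes do not fit in the genome")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_genes(out)
}

#' Simulate a two-group methylome with planted DMRs
#'
#' Baseline site levels are Beta-distributed around `cgi_mean` inside CGIs
#' and `background_mean` elsewhere and are identical between groups.
#' `dmr_count` disjoint runs of `dmr_width` consecutive CpGs (inter-CpG gaps
#' kept within 300 bp so each run is a compact region) are then shifted by
#' `dmr_delta` in group 2; runs are chosen among those whose baselines leave
#' room for the full shift, so the planted effect is exactly `dmr_delta`.
#'
#' @param bundle a `sim_genome`.
#' @param config a [sim_config()] (defaults to the bundle's).
#' @param seed integer seed.
#' @return list of class `methylome_truth` with `sites` (chrom, 1-based
#'   `pos` of the forward C, `in_cgi`, `level1`, `level2`), `dmrs` (planted
#'   truth intervals with member positions), `noncpg` (non-CpG cytosine
#'   rows with their context) and `config`.
#' @export
simulate_methylome <- function(bundle, config = bundle$config, seed = 1L) {
  stopifnot(methods::is(bundle, "sim_genome"))
  with_seed(seed, {
    cpgs <- enumerate_cpgs(bundle$genome)
    gr <- GenomicRanges::GRanges(cpgs$chrom,
                                 IRanges::IRanges(cpgs$pos + 1L, width = 2L))
    in_cgi <- rep(FALSE, nrow(cpgs))
    if (!is.null(bundle$cgis) && nrow(bundle$cgis))
      in_cgi[unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(
        gr, as_gr(bundle$cgis), type = "within")))] <- TRUE
    mu <- ifelse(in_cgi, config$cgi_mean, config$background_mean)
    base <- stats::rbeta(nrow(cpgs), mu * config$beta_conc,
                         (1 - mu) * config$beta_conc)
    sites <- data.frame(chrom = cpgs$chrom, pos = cpgs$pos + 1L,
                        in_cgi = in_cgi, level1 = base, level2 = base)
    dmrs <- plant_dmrs(sites, config)
    if (nrow(dmrs)) {
      idx <- unlist(dmrs$site_idx)
      sites$level2[idx] <- pmin(pmax(sites$level1[idx] + config$dmr_delta,
                                     0), 1)
    }
    noncpg <- sample_noncpg(bundle$genome, cpgs, config)
    structure(list(sites = sites, dmrs = dmrs, noncpg = noncpg,
                   config = config, seed = seed),
              class = "methylome_truth")
  })
}

# choose dmr_count disjoint runs of dmr_width consecutive CpGs whose
# baselines can absorb the full delta without clipping
plant_dmrs <- function(sites, config) {
  w <- config$dmr_width
  delta <- config$dmr_delta
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), delta = numeric(),
                      direction = character(), n_cpgs = integer(),
                      pos = I(list()), site_idx = I(list()))
  if (config$dmr_count == 0L) return(empty)
  win_sum <- function(x, w) {               # sum over sliding windows of w
    cs <- cumsum(c(0, x))
    cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]
  }
  starts <- integer()                       # global index of window starts
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    n <- length(idx)
    if (n < w) next
    pos <- sites$pos[idx]
    lev <- sites$level1[idx]
    ok_lev <- as.integer(lev + delta >= 0 & lev + delta <= 1)
    ok_gap <- as.integer(diff(pos) <= 300L)
    good <- win_sum(ok_lev, w) == w
    if (w > 1L) good <- good & (win_sum(ok_gap, w - 1L)[seq_along(good)] ==
                                  w - 1L)
    starts <- c(starts, idx[which(good)])
  }
  if (length(starts) < config$dmr_count)
    stop("not enough eligible CpG runs to plant ", config$dmr_count,
         " DMRs (", length(starts), " available)")
  ord <- sample(starts)
  used <- logical(nrow(sites))
  chosen <- integer()
  for (s in ord) {
    # keep runs separated by at least 2 CpG indices
    lo <- max(1L, s - 2L); hi <- min(nrow(sites), s + w + 1L)
    if (any(used[lo:hi])) next
    used[s:(s + w - 1L)] <- TRUE
    chosen <- c(chosen, s)
    if (length(chosen) == config$dmr_count) break
  }
  if (length(chosen) < config$dmr_count)
    stop("not enough disjoint CpG runs to plant ", config$dmr_count, " DMRs")
  rows <- lapply(chosen, function(s) {
    win <- s:(s + w - 1L)
    data.frame(chrom = sites$chrom[s],
               start = sites$pos[s] - 1L,
               end = sites$pos[win[w]] + 1L,
               delta = delta,
               direction = if (delta > 0) "hyper" else "hypo",
               n_cpgs = w,
               pos = I(list(sites$pos[win])),
               site_idx = I(list(win)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

sample_noncpg <- function(genome, cpgs, config) {
  if (config$noncpg_sites == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      context = character()))
  per <- diff(round(seq(0, config$noncpg_sites,
                        length.out = length(genome) + 1L)))
  rows <- lapply(seq_along(genome), function(ci) {
    ch <- names(genome)[ci]
    s <- as.character(genome[[ch]])
    cs <- gregexpr("C", s, fixed = TRUE)[[1]]       # 1-based C positions
    cg <- cpgs$pos[cpgs$chrom == ch] + 1L
    cs <- setdiff(cs, cg)
    cs <- cs[cs <= nchar(s) - 2L]
    if (!length(cs) || per[ci] == 0L) return(NULL)
    take <- sort(sample(cs, min(per[ci], length(cs))))
    plus2 <- substring(s, take + 2L, take + 2L)
    data.frame(chrom = ch, pos = take,
               context = ifelse(plus2 == "G", "CHG", "CHH"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(chrom = character(), pos = integer(),
                                      context = character())
  rownames(out) <- NULL
  out
}

# one count table draw for a vector of true levels
draw_counts <- function(levels, config) {
  n <- length(levels)
  depth <- if (config$depth_dispersion > 0)
    stats::rnbinom(n, size = 1 / config$depth_dispersion,
                   mu = config$depth_mean)
  else stats::rpois(n, config$depth_mean)
  depth <- pmax(depth, 1L)
  p <- levels
  if (config$bb_dispersion > 0) {
    rho <- config$bb_dispersion
    inner <- p > 0 & p < 1
    p[inner] <- stats::rbeta(sum(inner), p[inner] * (1 - rho) / rho,
                             (1 - p[inner]) * (1 - rho) / rho)
  }
  m <- stats::rbinom(n, depth, p)
  cbind(depth = depth, meth = m)
}

#' Simulate methylation count tables for both groups
#'
#' Depth per site is negative-binomial (truncated at 1); methylated counts
#' are beta-binomial around the true level (binomial when `bb_dispersion`
#' is 0). Non-CpG cytosine rows are emitted with apparent methylation at the
#' bisulfite non-conversion rate. With `per_individual`, `n_individuals`
#' tables are drawn per group and the pooled table is their exact sum
#' (mirroring the pooling of animals into one library).
#'
#' @param truth a `methylome_truth`.
#' @param config a [sim_config()] (defaults to the truth's).
#' @param seed integer seed.
#' @param per_individual also return per-individual tables.
#' @return list with elements `group1` and `group2`; each is a `cpg_counts`
#'   table (pooled) or, with `per_individual`, a list
#'   `list(individuals = <list of cpg_counts>, pooled = <cpg_counts>)`.
#' @export
simulate_counts <- function(truth, config = truth$config, seed = 1L,
                            per_individual = FALSE) {
  stopifnot(methods::is(truth, "methylome_truth"))
  with_seed(seed, {
    make_table <- function(group, label) {
      lev <- if (group == 1L) truth$sites$level1 else truth$sites$level2
      cg <- draw_counts(lev, config)
      df <- data.frame(chrom = truth$sites$chrom, pos = truth$sites$pos,
                       strand = "+", context = "CpG",
                       count_meth = cg[, "meth"],
                       count_unmeth = cg[, "depth"] - cg[, "meth"])
      if (nrow(truth$noncpg)) {
        nc <- draw_counts(rep(config$non_conversion_rate,
                              nrow(truth$noncpg)), config)
        df <- rbind(df, data.frame(chrom = truth$noncpg$chrom,
                                   pos = truth$noncpg$pos, strand = "+",
                                   context = truth$noncpg$context,
                                   count_meth = nc[, "meth"],
                                   count_unmeth = nc[, "depth"] - nc[, "meth"]))
      }
      new_cpg_counts(df, sample = label, check = FALSE)
    }
    pool <- function(tabs, label) {
      acc <- as.data.frame(tabs[[1L]])
      for (t in tabs[-1L]) {
        acc$count_meth <- acc$count_meth + t$count_meth
        acc$count_unmeth <- acc$count_unmeth + t$count_unmeth
      }
      new_cpg_counts(acc, sample = label, check = FALSE)
    }
    one_group <- function(group) {
      label <- paste0("group", group)
      if (!per_individual) return(make_table(group, label))
      ind <- lapply(seq_len(config$n_individuals), function(i)
        make_table(group, sprintf("%s_ind%d", label, i)))
      list(individuals = ind, pooled = pool(ind, label))
    }
    list(group1 = one_group(1L), group2 = one_group(2L))
  })
}

#' Simulate amplicon bisulfite validation data
#'
#' For each amplicon, group and individual, one methylation state per CpG is
#' realized from the group truth (beta-binomial biological variation applied
#' once), and both assays sample it: a deep HiSeq-BSP count table (Poisson
#' depth around `bsp_depth`) and a Sanger-BSP clone matrix
#' (`clones_per_amplicon` rows, one column per CpG, Bernoulli calls).
#'
#' @param truth a `methylome_truth`.
#' @param amplicons interval data.frame (0-based half-open) with a `name`
#'   column.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `hiseq` (`hiseq[[group]][[individual]]` =
#'   `cpg_counts`), `sanger` (`sanger[[group]][[individual]][[amplicon]]`
#'   = 0/1 matrix with CpG positions as column names) and `sample_levels`
#'   (the realized per-individual levels both assays sampled, named by
#'   position).
#' @export
simulate_bsp <- function(truth, amplicons, config = truth$config, seed = 1L) {
  stopifnot(methods::is(truth, "methylome_truth"))
  stop_if_not_intervals(amplicons, "amplicons")
  if (is.null(amplicons$name)) amplicons$name <-
      sprintf("amp%03d", seq_len(nrow(amplicons)))
  site_idx <- lapply(seq_len(nrow(amplicons)), function(i) {
    hit <- which(truth$sites$chrom == amplicons$chrom[i] &
                   truth$sites$pos - 1L >= amplicons$start[i] &
                   truth$sites$pos + 1L <= amplicons$end[i])
    if (!length(hit)) stop("amplicon ", amplicons$name[i],
                           " contains no CpG")
    hit
  })
  with_seed(seed, {
    groups <- lapply(1:2, function(g) {
      lev_all <- if (g == 1L) truth$sites$level1 else truth$sites$level2
      lapply(seq_len(config$n_individuals), function(ind) {
        rows <- list(); clone_mats <- list(); samp_lev <- list()
        for (i in seq_len(nrow(amplicons))) {
          idx <- site_idx[[i]]
          # one realized methylation state per (individual, site): both
          # assays sequence the same bisulfite-converted DNA sample
          q <- lev_all[idx]
          if (config$bb_dispersion > 0) {
            rho <- config$bb_dispersion
            inner <- q > 0 & q < 1
            q[inner] <- stats::rbeta(sum(inner),
                                     q[inner] * (1 - rho) / rho,
                                     (1 - q[inner]) * (1 - rho) / rho)
          }
          depth <- pmax(stats::rpois(length(idx), config$bsp_depth), 1L)
          m <- stats::rbinom(length(idx), depth, q)
          rows[[i]] <- data.frame(chrom = truth$sites$chrom[idx],
                                  pos = truth$sites$pos[idx],
                                  strand = "+", context = "CpG",
                                  count_meth = m,
                                  count_unmeth = depth - m)
          cm <- matrix(stats::rbinom(config$clones_per_amplicon *
                                       length(idx), 1L,
                                     rep(q,
                                         each = config$clones_per_amplicon)),
                       nrow = config$clones_per_amplicon)
          colnames(cm) <- truth$sites$pos[idx]
          clone_mats[[amplicons$name[i]]] <- cm
          samp_lev[[i]] <- stats::setNames(q, truth$sites$pos[idx])
        }
        list(hiseq = new_cpg_counts(do.call(rbind, rows),
                                    sample = sprintf("g%d_ind%d", g, ind),
                                    check = FALSE),
             sanger = clone_mats,
             sample_levels = unlist(samp_lev))
      })
    })
    list(hiseq = lapply(groups, function(g) lapply(g, `[[`, "hiseq")),
         sanger = lapply(groups, function(g) lapply(g, `[[`, "sanger")),
         sample_levels = lapply(groups, function(g)
           lapply(g, `[[`, "sample_levels")),
         amplicons = amplicons)
  })
}

#' Simulate a qPCR Ct table
#'
#' Per-gene baseline Ct values are shared between groups; group-B Ct values
#' are shifted by `-log2(fold_change)` so that the delta-delta-Ct fold
#' estimate recovers the planted fold. The reference gene must be included
#' with fold 1.
#'
#' @param fold_changes named numeric vector of planted fold changes
#'   (group B relative to group A), including the reference gene at 1.
#' @param n_per_group samples per group (>= 2).
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed integer seed.
#' @param ref_gene reference gene name.
#' @param baseline_ct mean baseline Ct.
#' @return data.frame `sample, group, gene, ct`.
#' @export
simulate_expression <- function(fold_changes, n_per_group = 6L,
                                noise_sd = 0.3, seed = 1L,
                                ref_gene = "GAPDH", baseline_ct = 24) {
  if (!(ref_gene %in% names(fold_changes)) ||
      fold_changes[[ref_gene]] != 1)
    stop("reference gene must be included with fold change 1")
  if (n_per_group < 2L) stop("need at least 2 samples per group")
  with_seed(seed, {
    genes <- names(fold_changes)
    base <- baseline_ct + stats::runif(length(genes), -2, 2)
    rows <- list()
    for (g in c("A", "B")) for (i in seq_len(n_per_group)) {
      ct <- base +
        (if (g == "B") -log2(unlist(fold_changes)) else 0) +
        stats::rnorm(length(genes), 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("%s%d", g, i), group = g, gene = genes, ct = ct)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
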