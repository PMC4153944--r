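# fixtures are built in code; oracles here are written independently of the
# package internals they check

toy_genome <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- paste0("chr", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}

# quick count-table constructor: one row per site
counts_tab <- function(chrom, pos, m, u, strand = "+", context = "CpG",
                       sample = "t") {
  perimeth:::new_cpg_counts(
    data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
               count_meth = m, count_unmeth = u),
    sample = sample)
}

# exhaustive two-sided Fisher oracle via binomial coefficients
oracle_fisher <- function(m1, u1, m2, u2, rel_tol = 1e-7) {
  n1 <- m1 + u1; n2 <- m2 + u2; M <- m1 + m2; N <- n1 + n2
  ks <- max(0, M - n2):min(M, n1)
  probs <- vapply(ks, function(k)
    choose(n1, k) * choose(n2, M - k) / choose(N, M), numeric(1))
  pobs <- probs[ks == m1]
  min(1, sum(probs[probs <= pobs * (1 + rel_tol)]))
}

# hand-coded BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  qs <- p[o] * m / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  q <- numeric(m)
  q[o] <- pmin(qs, 1)
  q
}

# brute-force window enumerator: for every chromosome, precompute via O(n^2)
# pair checks the maximal direction-consistent gap-bounded window starting at
# each site, then walk seeds left to right with the resume-after-window rule
oracle_scan <- function(sites, max_gap = 300, min_sites = 5, min_sig = 3,
                        seed_alpha = 0.05, site_alpha = 0.05) {
  out <- list()
  for (ch in unique(sites$chrom)) {
    d <- sites[sites$chrom == ch, , drop = FALSE]
    n <- nrow(d)
    # reach[i] = largest j such that window i..j is valid for seed i
    reach <- integer(n)
    for (i in seq_len(n)) {
      dir <- sign(d$diff[i])
      j_max <- i
      if (dir != 0) {
        for (j in seq_len(n)) {
          if (j <= i) next
          ok_gap <- all(diff(d$pos[i:j]) <= max_gap)
          dd <- d$diff[(i + 1):j]
          ok_dir <- all(dd == 0 | sign(dd) == dir)
          if (ok_gap && ok_dir) j_max <- j else break
        }
      }
      reach[i] <- j_max
    }
    cursor <- 1L
    repeat {
      seeds <- which(d$p_adj < seed_alpha & d$diff != 0)
      seeds <- seeds[seeds >= cursor]
      if (!length(seeds)) break
      s <- seeds[1L]
      j <- reach[s]
      mem <- s:j
      nsig <- sum(d$p_raw[mem] < site_alpha & d$diff[mem] != 0)
      if (length(mem) >= min_sites && nsig >= min_sig)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = d$pos[s] - 1L, end = d$pos[j] + 1L,
          n_sites = length(mem), n_sig = nsig)
      cursor <- j + 1L
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_sites = integer(), n_sig = integer())
}

# random candidate-site configuration for scan-oracle trials
random_sites <- function(n, seed) {
  set.seed(seed)
  gaps <- sample(c(5:60, 250:340), n - 1L, replace = TRUE)
  pos <- cumsum(c(sample(10:100, 1L), gaps))
  d1 <- sample(5:30, n, TRUE); d2 <- sample(5:30, n, TRUE)
  p1 <- runif(n)
  # a random subset gets a strong shared-direction shift to create seeds
  shift <- sample(c(-0.6, 0, 0.6), n, TRUE, prob = c(.3, .4, .3))
  p2 <- pmin(pmax(p1 + shift, 0), 1)
  m1 <- rbinom(n, d1, p1); m2 <- rbinom(n, d2, p2)
  s <- data.frame(chrom = "chr1", pos = pos, m1 = m1, u1 = d1 - m1,
                  m2 = m2, u2 = d2 - m2)
  s$level1 <- s$m1 / d1; s$level2 <- s$m2 / d2
  s$diff <- s$level2 - s$level1
  s$p_raw <- fisher_two_sided(s$m1, s$u1, s$m2, s$u2)
  s$p_adj <- bh_adjust(s$p_raw)
  s
}

# small simulation shared by several slow tests (cached per session)
small_cfg <- function(...) {
  base <- list(n_chroms = 2L, chrom_length = 200000L, cgi_count = 12L,
               gene_count = 20L, dmr_count = 10L, noncpg_sites = 500L)
  do.call(sim_config, utils::modifyList(base, list(...)))
}
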