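cfg <- small_cfg()

test_that("simulate_genome is deterministic and separates CGI from background composition", {
  a <- simulate_genome(cfg, 5)
  b <- simulate_genome(cfg, 5)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$genes, b$genes)
  expect_identical(a$cgis, b$cgis)

  s <- as.character(a$genome[["chr1"]])
  gc_of <- function(str) {
    v <- strsplit(str, "")[[1]]
    mean(v %in% c("C", "G"))
  }
  cg1 <- a$cgis[a$cgis$chrom == "chr1", ]
  gc_cgi <- mean(vapply(seq_len(nrow(cg1)), function(i)
    gc_of(substring(s, cg1$start[i] + 1L, cg1$end[i])), numeric(1)))
  gc_bg <- gc_of(substring(s, 1, cg1$start[1]))
  expect_gt(gc_cgi, gc_bg)
  expect_gt(gc_cgi, 0.55)

  empty <- simulate_genome(small_cfg(gene_count = 0L), 5)
  expect_equal(nrow(empty$genes), 0L)
})

test_that("simulated gene models are valid and genes do not overlap", {
  gb <- simulate_genome(cfg, 9)
  expect_silent(perimeth:::validate_genes(gb$genes))
  for (ch in unique(gb$genes$chrom)) {
    g <- gb$genes[gb$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1L) expect_true(all(g$start[-1L] >= g$end[-nrow(g)]))
  }
})

test_that("planted DMRs carry the configured effect and leave the rest untouched", {
  gb <- simulate_genome(cfg, 5)
  tr <- simulate_methylome(gb, cfg, 6)
  expect_identical(tr$sites,
                   simulate_methylome(gb, cfg, 6)$sites)
  planted <- unlist(tr$dmrs$site_idx)
  expect_equal(length(planted), sum(tr$dmrs$n_cpgs))
  expect_equal(mean(tr$sites$level2[planted] - tr$sites$level1[planted]),
               cfg$dmr_delta, tolerance = 0.02)
  outside <- setdiff(seq_len(nrow(tr$sites)), planted)
  expect_identical(tr$sites$level1[outside], tr$sites$level2[outside])
  # planted intervals disjoint
  d <- tr$dmrs[order(tr$dmrs$chrom, tr$dmrs$start), ]
  same <- d$chrom[-1L] == d$chrom[-nrow(d)]
  expect_true(all(d$start[-1L][same] >= d$end[-nrow(d)][same]))

  null_tr <- simulate_methylome(gb, small_cfg(dmr_delta = 0), 6)
  expect_identical(null_tr$sites$level1, null_tr$sites$level2)
})

test_that("count tables follow the binomial expectation at the extremes and in the mean", {
  gb <- simulate_genome(cfg, 5)
  cfg0 <- small_cfg(bb_dispersion = 0, non_conversion_rate = 0,
                    noncpg_sites = 0L)
  tr <- simulate_methylome(gb, cfg0, 6)
  tr$sites$level1[] <- 1; tr$sites$level2[] <- 0
  cnt <- simulate_counts(tr, cfg0, 7)
  expect_true(all(cnt$group1$count_unmeth == 0L))
  expect_true(all(cnt$group2$count_meth == 0L))

  tr$sites$level1[] <- 0.5
  cnt <- simulate_counts(tr, cfg0, 8)
  lv <- site_levels(cnt$group1)
  n <- nrow(lv)
  se <- sqrt(0.5 * 0.5 / sum(lv$depth))
  expect_lt(abs(sum(lv$level * lv$depth) / sum(lv$depth) - 0.5), 3 * se)
})

test_that("per-individual tables sum exactly to the pooled table", {
  gb <- simulate_genome(cfg, 5)
  tr <- simulate_methylome(gb, cfg, 6)
  cnt <- simulate_counts(tr, cfg, 9, per_individual = TRUE)
  for (g in cnt) {
    manual_m <- Reduce(`+`, lapply(g$individuals, `[[`, "count_meth"))
    manual_u <- Reduce(`+`, lapply(g$individuals, `[[`, "count_unmeth"))
    expect_identical(g$pooled$count_meth, manual_m)
    expect_identical(g$pooled$count_unmeth, manual_u)
  }
})

test_that("non-CpG rows show the bisulfite non-conversion rate", {
  gb <- simulate_genome(cfg, 5)
  tr <- simulate_methylome(gb, small_cfg(noncpg_sites = 10000L), 6)
  cnt <- simulate_counts(tr, small_cfg(noncpg_sites = 10000L), 10)
  tab <- as.data.frame(cnt$group1)
  nc <- tab[tab$context != "CpG", ]
  tot <- sum(nc$count_meth + nc$count_unmeth)
  rate <- sum(nc$count_meth) / tot
  se <- sqrt(0.005 * 0.995 / tot)
  expect_lt(abs(rate - 0.005), 3 * se)
})

test_that("BSP generator honors clone counts and Bernoulli expectations", {
  gb <- simulate_genome(cfg, 5)
  tr <- simulate_methylome(gb, cfg, 6)
  amp <- tr$dmrs[1:3, c("chrom", "start", "end")]
  amp$name <- paste0("amp", 1:3)
  bsp <- simulate_bsp(tr, amp, cfg, 11)
  for (cm in bsp$sanger[[1]][[1]])
    expect_equal(nrow(cm), cfg$clones_per_amplicon)

  zero <- tr; zero$sites$level1[] <- 0; zero$sites$level2[] <- 0
  bsp0 <- simulate_bsp(zero, amp, small_cfg(bb_dispersion = 0), 11)
  expect_true(all(unlist(bsp0$sanger[[1]][[1]]) == 0))

  # clone-mean converges to the sampled level (Bernoulli expectation)
  many <- small_cfg(clones_per_amplicon = 10000L, n_individuals = 1L)
  bspm <- simulate_bsp(tr, amp[1, ], many, 12)
  cm <- bspm$sanger[[1]][[1]][[1]]
  truth_lev <- bspm$sample_levels[[1]][[1]][colnames(cm)]
  se <- sqrt(pmax(truth_lev * (1 - truth_lev), 1e-6) / nrow(cm))
  expect_true(all(abs(colMeans(cm) - truth_lev) < 3 * se + 1e-9))

  noamp <- data.frame(chrom = "chr1", start = 0L, end = 4L, name = "bad")
  expect_error(simulate_bsp(tr, noamp, cfg, 11), "no CpG")
})

test_that("expression generator encodes fold changes in Ct space", {
  folds <- c(GAPDH = 1, up = 1, down = 0.25)
  ct <- simulate_expression(folds, n_per_group = 3L, noise_sd = 0, seed = 3)
  res <- ddct_analysis(ct, group_a = "A", group_b = "B")
  expect_equal(res$ddct[res$gene == "up"], 0)
  expect_equal(res$ddct[res$gene == "down"], 2)
  expect_equal(res$fold_change[res$gene == "down"], 0.25)
  expect_identical(ct, simulate_expression(folds, 3L, 0, 3))
  expect_error(simulate_expression(c(a = 2), seed = 1), "reference")
  expect_error(simulate_expression(folds, n_per_group = 1L, seed = 1),
               "2 samples")
})
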