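test_that("amplicon restriction reports half-open membership and coverage fractions", {
  # genome with 10 CpGs at known spots inside [0, 100)
  s <- paste(rep("ACGTATATAT", 10), collapse = "")      # CpG every 10 bp
  g <- toy_genome(chr1 = s)
  cp <- enumerate_cpgs(g)
  expect_equal(nrow(cp), 10L)
  amp <- data.frame(chrom = "chr1", start = 0L, end = 100L, name = "a1")
  covered <- cp$pos[1:8] + 1L
  tab <- counts_tab("chr1", covered, rep(5L, 8), rep(5L, 8))
  al <- amplicon_levels(tab, amp, g)
  expect_equal(al$coverage$coverage, 0.8)
  expect_equal(nrow(al$sites), 8L)

  none <- amplicon_levels(counts_tab("chr1", 1000L, 1L, 1L), amp, g)
  expect_equal(none$coverage$n_covered, 0L)
  expect_equal(none$coverage$coverage, 0)

  # CpG whose G is exactly at the amplicon end is included (half-open)
  amp_edge <- data.frame(chrom = "chr1", start = 0L, end = cp$pos[2] + 2L)
  tab2 <- counts_tab("chr1", cp$pos[1:2] + 1L, c(1L, 1L), c(1L, 1L))
  expect_equal(amplicon_levels(tab2, amp_edge, g)$coverage$n_covered, 2L)

  nocpg <- data.frame(chrom = "chr1", start = 3L, end = 5L, name = "bad")
  expect_warning(out <- amplicon_levels(tab, nocpg, g), "no CpG")
  expect_true(is.na(out$coverage$coverage))
})

test_that("Sanger clone levels handle missing calls", {
  cm <- matrix(c(rep(1, 10), rep(0, 10)), ncol = 1)
  expect_equal(unname(sanger_levels(cm)), 0.5)
  expect_equal(unname(sanger_levels(matrix(0, 20, 2))), c(0, 0))
  cm2 <- matrix(c(rep(NA, 5), rep(1, 5), rep(0, 10)), ncol = 1)
  expect_equal(unname(sanger_levels(cm2)), 1 / 3)
  expect_error(sanger_levels(matrix(NA_real_, 5, 1)), "non-missing")
})

test_that("concordance returns exact closed forms on constructed vectors", {
  x <- stats::setNames(seq(0.1, 1, by = 0.1), paste0("p", 1:10))
  cc <- concordance(x, x)
  expect_equal(cc$pearson_r, 1)
  expect_equal(cc$slope, 1)
  expect_equal(cc$intercept, 0)
  expect_equal(cc$n_paired_sites, 10L)
  expect_equal(concordance(x, 1 - x)$pearson_r, -1)
  expect_error(concordance(x[1:2], x[1:2]), "3 paired")
  expect_error(concordance(x, stats::setNames(rep(0.5, 10), names(x))),
               "variance")
})

test_that("per-CpG CV uses the sample sd and flags undefined means; scale-invariant", {
  lv <- data.frame(chrom = "chr1", pos = 10L,
                   individual = 1:3, group = "A",
                   level = c(0.5, 0.5, 0.5))
  expect_equal(cpg_cv(lv)$cv, 0)
  lv2 <- data.frame(chrom = "chr1", pos = 10L, individual = 1:2,
                    group = "A", level = c(0.2, 0.4))
  expect_equal(cpg_cv(lv2)$cv, sqrt(0.02) / 0.3, tolerance = 1e-9)
  lv3 <- lv; lv3$level <- 0
  expect_true(is.na(cpg_cv(lv3)$cv))
  expect_error(cpg_cv(lv[1, ]), "fewer than 2")
  # multiplying levels by c > 0 leaves cv unchanged
  lv4 <- data.frame(chrom = "chr1", pos = rep(c(5L, 9L), each = 3),
                    individual = rep(1:3, 2), group = "A",
                    level = c(0.1, 0.2, 0.15, 0.5, 0.6, 0.4))
  lv5 <- lv4; lv5$level <- lv5$level * 1.7
  expect_equal(cpg_cv(lv4)$cv, cpg_cv(lv5)$cv)
})

test_that("ddCt analysis recovers folds, tests dCt values and applies the dual call rule", {
  folds <- c(GAPDH = 1, flat = 1, down4 = 0.25, up8 = 8)
  ct <- simulate_expression(folds, n_per_group = 6L, noise_sd = 0.15,
                            seed = 13)
  res <- ddct_analysis(ct, group_a = "A", group_b = "B")
  expect_equal(res$fold_change[res$gene == "down4"], 0.25, tolerance = 0.25)
  expect_true(res$significant[res$gene == "down4"])
  expect_true(res$significant[res$gene == "up8"])
  expect_false(res$significant[res$gene == "flat"])

  ct0 <- simulate_expression(c(GAPDH = 1, g = 1), 3L, 0, 1)
  r0 <- ddct_analysis(ct0, group_a = "A", group_b = "B")
  expect_equal(r0$fold_change, 1)
  expect_false(r0$significant)

  bad <- ct[ct$gene != "GAPDH" | ct$sample != "A1", ]
  expect_error(ddct_analysis(bad, group_a = "A", group_b = "B"), "missing")
})

test_that("deep HiSeq-BSP beats 20-clone Sanger-BSP against the sampled truth", {
  cfg <- small_cfg(n_individuals = 1L)
  gb <- simulate_genome(cfg, 41)
  tr <- simulate_methylome(gb, cfg, 42)
  # 60 well-separated amplicons over CpG-bearing spots of one chromosome
  cp <- tr$sites[tr$sites$chrom == "chr1", ]
  idx <- round(seq(10, nrow(cp) - 10, length.out = 60))
  amp <- data.frame(chrom = cp$chrom[idx], start = cp$pos[idx] - 5L,
                    end = cp$pos[idx] + 120L,
                    name = sprintf("a%02d", 1:60))
  bsp <- simulate_bsp(tr, amp, cfg, 43)
  truth_lev <- bsp$sample_levels[[1]][[1]]
  hi <- site_levels(bsp$hiseq[[1]][[1]])
  hi_lev <- stats::setNames(hi$level, hi$pos)
  sg_lev <- do.call(c, unname(lapply(bsp$sanger[[1]][[1]], function(cm)
    stats::setNames(colMeans(cm), colnames(cm)))))
  shared <- intersect(names(truth_lev), intersect(names(hi_lev),
                                                  names(sg_lev)))
  mad_hi <- mean(abs(hi_lev[shared] - truth_lev[shared]))
  mad_sg <- mean(abs(sg_lev[shared] - truth_lev[shared]))
  expect_lt(mad_hi, mad_sg)
  expect_lt(mad_hi, 0.05)
})

test_that("amplicon re-calling validates planted DMRs and reports untestable ones", {
  cfg <- small_cfg(dmr_delta = 0.4, n_individuals = 6L)
  gb <- simulate_genome(cfg, 51)
  tr <- simulate_methylome(gb, cfg, 52)
  # amplicons: over the first two planted DMRs and one null region
  td <- tr$dmrs
  amp <- data.frame(chrom = c(td$chrom[1:2], td$chrom[1]),
                    start = c(td$start[1:2] - 10L, 50L),
                    end = c(td$end[1:2] + 10L, 800L),
                    name = c("d1", "d2", "null"))
  bsp <- simulate_bsp(tr, amp, cfg, 53)
  rrbs_dmrs <- data.frame(chrom = c(td$chrom[1:2], td$chrom[2]),
                          start = c(td$start[1:2], 1000000L),
                          end = c(td$end[1:2], 1000200L),
                          direction = td$direction[c(1, 2, 2)])
  out <- revalidate_amplicon_dmrs(bsp$hiseq[[1]], bsp$hiseq[[2]],
                                  rrbs_dmrs, amp)
  expect_equal(out$report$status[1:2], c("validated", "validated"))
  expect_equal(out$report$status[3], "not_testable")
  # the null amplicon must not contribute a DMR overlapping it
  null_gr <- out$amplicon_dmrs$dmrs
  expect_false(any(null_gr$start < 800L & null_gr$end > 50L &
                     null_gr$chrom == td$chrom[1]))
  expect_error(revalidate_amplicon_dmrs(list(), list(), rrbs_dmrs, amp),
               "empty")
})
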