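test_that("fisher_two_sided agrees with stats::fisher.test and handles edge tables", {
  expect_equal(fisher_two_sided(5, 5, 5, 5), 1.0)
  expect_equal(fisher_two_sided(0, 10, 0, 10), 1.0)
  set.seed(4)
  for (i in 1:50) {
    m1 <- sample(0:15, 1); u1 <- sample(0:15, 1)
    m2 <- sample(0:15, 1); u2 <- sample(0:15, 1)
    if (m1 + u1 == 0 || m2 + u2 == 0) next
    ref <- stats::fisher.test(matrix(c(m1, u1, m2, u2), 2,
                                     byrow = TRUE))$p.value
    expect_equal(fisher_two_sided(m1, u1, m2, u2), ref, tolerance = 1e-12)
  }
  expect_error(fisher_two_sided(0, 0, 1, 1), "depth")
  expect_error(fisher_two_sided(-1, 2, 1, 1), "non-negative")
})

test_that("bh_adjust reproduces the step-up rule and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.7), 0.7)
  set.seed(5)
  p <- runif(200)
  q <- bh_adjust(p)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("candidate selection enforces depth, chromosome exclusion and ordering", {
  t1 <- counts_tab(c("chr1", "chr1", "chr1", "chrX"), c(10L, 50L, 70L, 10L),
                   c(5L, 2L, 2L, 5L), c(0L, 3L, 2L, 0L))
  t2 <- counts_tab(c("chr1", "chr1", "chr1", "chrX"), c(10L, 50L, 70L, 10L),
                   c(5L, 2L, 5L, 5L), c(0L, 8L, 5L, 0L))
  cs <- select_candidates(t1, t2)
  expect_equal(cs$pos, c(10L, 50L))     # depth-4 site and chrX dropped
  expect_equal(cs$diff[1], 0)
  low <- counts_tab("chr1", 10L, 2L, 2L)
  expect_warning(cs2 <- select_candidates(low, t2), "no shared")
  expect_equal(nrow(cs2), 0L)
})

test_that("the window scan follows the seeding, gap, direction and support rules", {
  mk <- function(pos, m1, u1, m2, u2) {
    s <- data.frame(chrom = "chr1", pos = pos, m1 = m1, u1 = u1,
                    m2 = m2, u2 = u2)
    s$level1 <- m1 / (m1 + u1); s$level2 <- m2 / (m2 + u2)
    s$diff <- s$level2 - s$level1
    s$p_raw <- fisher_two_sided(m1, u1, m2, u2)
    s$p_adj <- bh_adjust(s$p_raw)
    s
  }
  pos6 <- seq(100L, by = 40L, length.out = 6L)
  strong <- mk(pos6, rep(2L, 6), rep(18L, 6), rep(18L, 6), rep(2L, 6))
  d <- scan_candidate_dmrs(strong)
  expect_equal(nrow(d), 1L)
  expect_equal(d$n_sites, 6L)
  expect_equal(d$n_sig, 6L)
  expect_equal(d$direction, "hyper")
  expect_equal(d$start, pos6[1] - 1L)
  expect_equal(d$end, pos6[6] + 1L)

  # opposite sign at site 4 closes the window too early on both sides
  flip <- mk(pos6, c(2L, 2L, 2L, 18L, 2L, 2L), c(18L, 18L, 18L, 2L, 18L, 18L),
             c(18L, 18L, 18L, 2L, 18L, 18L), c(2L, 2L, 2L, 18L, 2L, 2L))
  expect_equal(nrow(scan_candidate_dmrs(flip)), 0L)

  # a 301 bp gap splits the run; neither half reaches 5 sites
  gap <- mk(c(pos6[1:3], pos6[3] + 301L, pos6[3] + 341L, pos6[3] + 381L),
            rep(2L, 6), rep(18L, 6), rep(18L, 6), rep(2L, 6))
  expect_equal(nrow(scan_candidate_dmrs(gap)), 0L)
})

test_that("aggregate testing rounds mean counts half-up and applies both filters", {
  pos6 <- seq(100L, by = 40L, length.out = 6L)
  s <- data.frame(chrom = "chr1", pos = pos6, m1 = 2L, u1 = 18L,
                  m2 = 18L, u2 = 2L)
  s$level1 <- 0.1; s$level2 <- 0.9; s$diff <- 0.8
  s$p_raw <- fisher_two_sided(s$m1, s$u1, s$m2, s$u2)
  s$p_adj <- bh_adjust(s$p_raw)
  cand <- scan_candidate_dmrs(s)
  res <- test_and_filter_dmrs(cand)
  expect_equal(nrow(res), 1L)
  # aggregate table equals the common site table here
  expect_equal(res$p_aggregate, fisher_two_sided(2, 18, 18, 2))
  expect_equal(res$q_bh, res$p_aggregate)
  expect_equal(res$direction, "hyper")

  # small effect is dropped regardless of q
  weak <- cand
  weak$diff <- 0.15
  expect_equal(nrow(test_and_filter_dmrs(weak)), 0L)

  # identical groups yield nothing end to end
  t1 <- counts_tab("chr1", pos6, rep(10L, 6), rep(10L, 6))
  res0 <- call_dmrs(t1, t1)
  expect_equal(nrow(res0$dmrs), 0L)
})

test_that("emitted DMRs satisfy the structural invariants", {
  cfg <- small_cfg()
  gb <- simulate_genome(cfg, 21)
  tr <- simulate_methylome(gb, cfg, 22)
  cnt <- simulate_counts(tr, cfg, 23, per_individual = TRUE)
  res <- call_dmrs(cnt$group1$pooled, cnt$group2$pooled)
  expect_gt(nrow(res$dmrs), 0L)
  expect_true(check_dmr_invariants(res))
  expect_s3_class(summary(res), "summary.dmr_result")
})

test_that("the scan matches a brute-force window enumerator on random site configurations", {
  norm <- function(d) {
    d <- as.data.frame(d)[c("chrom", "start", "end", "n_sites", "n_sig")]
    rownames(d) <- NULL
    d
  }
  for (trial in 1:120) {
    s <- random_sites(sample(5:50, 1), seed = 9000 + trial)
    got <- norm(scan_candidate_dmrs(s))
    want <- norm(oracle_scan(s))
    expect_identical(got, want)
  }
})

test_that("DMR calling is invariant to input row order", {
  cfg <- small_cfg()
  gb <- simulate_genome(cfg, 31)
  tr <- simulate_methylome(gb, cfg, 32)
  cnt <- simulate_counts(tr, cfg, 33)
  g1 <- cnt$group1; g2 <- cnt$group2
  set.seed(1)
  shuf <- sample(nrow(g1))
  g1s <- perimeth:::new_cpg_counts(as.data.frame(g1)[shuf, ], check = FALSE)
  a <- call_dmrs(g1, g2)
  b <- call_dmrs(g1s, g2)
  expect_equal(as.data.frame(a$dmrs[setdiff(names(a$dmrs), "members")]),
               as.data.frame(b$dmrs[setdiff(names(b$dmrs), "members")]))
})
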