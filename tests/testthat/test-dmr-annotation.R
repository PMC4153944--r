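# one + strand gene [1000, 3000) with exons [1000,1500) and [2500,3000),
# and one - strand gene [6000, 8000)
genes_fx <- data.frame(
  chrom = "chr1", start = c(1000L, 6000L), end = c(3000L, 8000L),
  strand = c("+", "-"), gene_id = c("gp", "gm"),
  exon_starts = I(list(c(1000L, 2500L), 6000L)),
  exon_ends = I(list(c(1500L, 3000L), 8000L)))

dmr_at <- function(start, end) data.frame(chrom = "chr1", start = start,
                                          end = end)

test_that("feature assignment follows promoter > exon > intron > downstream precedence", {
  cases <- list(
    list(dmr_at(400L, 600L), "promoter", "gp"),       # TSS-600..TSS-400
    list(dmr_at(1600L, 1700L), "intron", "gp"),
    list(dmr_at(2600L, 2700L), "exon", "gp"),
    list(dmr_at(3100L, 3200L), "downstream", "gp"),
    list(dmr_at(11000L, 11100L), "intergenic", ""),
    list(dmr_at(950L, 1100L), "promoter", "gp"),      # spans promoter + exon
    list(dmr_at(8100L, 8200L), "promoter", "gm"),     # - strand promoter
    list(dmr_at(5500L, 5600L), "downstream", "gm"))   # - strand downstream
  for (cs in cases) {
    ann <- assign_feature(cs[[1]], genes_fx)
    expect_equal(ann$category, cs[[2]], info = paste(cs[[1]]$start))
    expect_equal(ann$gene_ids, cs[[3]], info = paste(cs[[1]]$start))
  }
})

test_that("feature categories partition any DMR set", {
  set.seed(6)
  dmrs <- dmr_at(sample(0:9000, 40), 0L)
  dmrs$end <- dmrs$start + sample(50:200, 40, TRUE)
  ann <- assign_feature(dmrs, genes_fx)
  expect_equal(sum(table(ann$category)), nrow(dmrs))
})

test_that("CGI overlap uses any-bp half-open logic and summarizes promoter-CGI genes", {
  cgis <- data.frame(chrom = "chr1", start = c(149L, 150L), end = c(300L, 300L))
  d <- dmr_at(100L, 150L)
  expect_true(overlap_cgi(d, cgis[1, ])$cgi_overlap)
  expect_false(overlap_cgi(d, cgis[2, ])$cgi_overlap)
  expect_false(overlap_cgi(d, cgis[0, ])$cgi_overlap)

  prom_dmr <- assign_feature(dmr_at(400L, 600L), genes_fx)
  out <- overlap_cgi(prom_dmr, data.frame(chrom = "chr1", start = 500L,
                                          end = 700L))
  expect_equal(attr(out, "cgi_summary")$promoter_cgi_genes, "gp")
  expect_equal(attr(out, "cgi_summary")$n_promoter_cgi, 1L)
})

test_that("cross-matching applies the reciprocal shared-CpG rule and pools diffs", {
  mk_set <- function(pos_list, diff_list) {
    rows <- lapply(seq_along(pos_list), function(i) {
      p <- pos_list[[i]]
      data.frame(chrom = "chr1", start = p[1] - 1L, end = p[length(p)] + 1L,
                 n_sites = length(p), direction = "hyper",
                 members = I(list(data.frame(pos = p,
                                             diff = diff_list[[i]]))))
    })
    do.call(rbind, rows)
  }
  a <- mk_set(list(c(100L, 110L, 120L, 130L, 140L)), list(rep(0.4, 5)))
  b <- mk_set(list(c(120L, 130L, 140L, 150L)), list(rep(0.4, 4)))
  cm <- crossmatch_dmrs(a, b)
  expect_equal(nrow(cm$pairs), 1L)
  expect_equal(cm$pairs$n_shared, 3L)

  disj <- mk_set(list(c(500L, 510L, 520L, 530L, 540L)), list(rep(0.4, 5)))
  expect_warning(cm_d <- crossmatch_dmrs(a, disj), "fewer than 3")
  expect_equal(nrow(cm_d$pairs), 0L)

  # identical diff vectors (with variation) give r = 1, and matching is symmetric
  a2 <- mk_set(list(c(100L, 110L, 120L, 130L)), list(c(.2, .3, .4, .5)))
  b2 <- mk_set(list(c(100L, 110L, 120L, 130L)), list(c(.2, .3, .4, .5)))
  cm2 <- crossmatch_dmrs(a2, b2)
  expect_equal(cm2$pearson_r, 1)
  cm2r <- crossmatch_dmrs(b2, a2)
  expect_equal(cm2r$pearson_r, cm2$pearson_r)
  expect_equal(cm2r$pairs$n_shared, cm2$pairs$n_shared)
})

test_that("venn counts cover 2- and 3-set exclusive regions", {
  v2 <- venn_counts(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(unname(v2[c("A", "B", "AB")]), c(1L, 1L, 2L))
  same <- venn_counts(list(A = c("a", "b"), B = c("a", "b")))
  expect_equal(unname(same[c("A", "B", "AB")]), c(0L, 0L, 2L))
  v3 <- venn_counts(list(A = "a", B = "b", C = "c"))
  expect_equal(unname(v3[c("A", "B", "C", "AB", "AC", "BC", "ABC")]),
               c(1L, 1L, 1L, 0L, 0L, 0L, 0L))
  expect_error(venn_counts(list(1, 2, 3, 4)), "2 or 3")
})

test_that("hypergeometric ORA matches closed forms and an enumeration oracle", {
  bg <- sprintf("g%04d", 1:1000)
  q <- bg[1:10]
  res <- ora_enrichment(q, bg, list(hit = q, miss = bg[900:950]))
  expect_equal(res$p[res$set == "hit"], 1 / choose(1000, 10))
  expect_equal(res$p[res$set == "miss"], 1)
  expect_true(res$enriched[res$set == "hit"])
  expect_error(ora_enrichment("zz", bg, list()), "subset")

  # exhaustive enumeration on a small background: P(overlap >= observed)
  bg2 <- letters[1:12]
  set2 <- c("a", "b", "c", "d")
  query <- c("a", "b", "e", "f")
  x_obs <- length(intersect(set2, query))
  combos <- combn(bg2, length(query))
  frac <- mean(apply(combos, 2, function(s)
    length(intersect(s, set2)) >= x_obs))
  res2 <- ora_enrichment(query, bg2, list(s = set2))
  expect_equal(res2$p, frac, tolerance = 1e-12)
})
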