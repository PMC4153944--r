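#' Two-sided Fisher exact test for 2x2 count tables
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of tables at most as probable as the
#' observed one (within relative tolerance `rel_tol`) — the same definition
#' [stats::fisher.test()] uses. Implemented as a direct hypergeometric
#' enumeration, vectorized over sites, because a genome-wide DMR scan tests
#' every candidate CpG.
#'
#' @param m1,u1 methylated / unmethylated counts in group 1 (vectors).
#' @param m2,u2 methylated / unmethylated counts in group 2.
#' @param rel_tol relative tolerance when comparing table probabilities.
#' @return vector of two-sided p-values in `[0, 1]`.
#' @export
fisher_two_sided <- function(m1, u1, m2, u2, rel_tol = 1e-7) {
  n <- max(length(m1), length(u1), length(m2), length(u2))
  m1 <- rep_len(as.numeric(m1), n); u1 <- rep_len(as.numeric(u1), n)
  m2 <- rep_len(as.numeric(m2), n); u2 <- rep_len(as.numeric(u2), n)
  if (anyNA(c(m1, u1, m2, u2)) || any(c(m1, u1, m2, u2) < 0))
    stop("counts must be non-negative")
  n1 <- m1 + u1; n2 <- m2 + u2; M <- m1 + m2
  if (any(n1 == 0 | n2 == 0))
    stop("each group needs total depth > 0")
  p <- numeric(n)
  for (i in seq_len(n)) {
    k <- max(0, M[i] - n2[i]):min(M[i], n1[i])
    d <- stats::dhyper(k, n1[i], n2[i], M[i])
    pobs <- d[k == m1[i]]
    p[i] <- min(1, sum(d[d <= pobs * (1 + rel_tol)]))
  }
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper around `stats::p.adjust(method = "BH")` with input validation,
#' exposed because both the per-site seeding step and the aggregate DMR test
#' of the caller use it.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return BH-adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
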