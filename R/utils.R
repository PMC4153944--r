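## internal helpers

# round-half-up to integer (round() rounds half to even, which would bias
# aggregate Fisher tables built from *.5 means)
round_half_up <- function(x) as.integer(floor(x + 0.5))

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators behave as pure functions of (config, seed)
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# intervals data.frame (chrom/start/end [, strand]) -> GRanges (1-based)
as_gr <- function(df, strand = NULL) {
  if (nrow(df) == 0L)
    return(GenomicRanges::GRanges())
  s <- strand %||% df$strand %||% "*"
  s[is.na(s) | !(s %in% c("+", "-"))] <- "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end),
                         strand = s)
}

stop_if_not_intervals <- function(df, what = "intervals") {
  req <- c("chrom", "start", "end")
  if (!is.data.frame(df) || !all(req %in% names(df)))
    stop(what, " must be a data.frame with columns chrom, start, end")
  if (nrow(df) && any(df$start < 0 | df$start >= df$end))
    stop(what, ": need 0 <= start < end for every row")
  invisible(df)
}
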