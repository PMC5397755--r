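# RNG plumbing.  Resampling uses one master seed from which a substream
# seed is derived for every (replicate, period, site) triple, so enlarging
# the replicate count or adding sites never reshuffles draws already made.

.with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Deterministic hash into [0, 2^31 - 2]; multipliers keep every product
# below 2^53 so double arithmetic stays exact.
.substream_seed <- function(seed, replicate, period_idx, site_idx) {
  s <- as.numeric(seed) %% 2147483647
  h <- (s * 48271 + replicate * 69621 + period_idx * 30307 +
        site_idx * 30323 + 17) %% 2147483647
  as.integer(h)
}
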