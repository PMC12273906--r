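## Independent oracles used by the tests; each is a deliberately naive
## implementation kept separate from the package code path it checks.

## Canonical circular form by brute-force enumeration of all rotations of
## both strands.
brute_canonical <- function(s) {
  n <- nchar(s)
  rc <- revcomp(s)
  min(vapply(0:(n - 1L), function(k) rotate_seq(s, k), ""),
      vapply(0:(n - 1L), function(k) rotate_seq(rc, k), ""))
}

## Rotation- and strand-aware identity of a called monomer against the true
## circle: locate the call's phase in the doubled truth via an exact anchor,
## then align globally. Returns matches / max(length) in [0, 1].
rotation_identity <- function(call, truth) {
  for (s in c(call, revcomp(call))) {
    Lc <- nchar(s); Lt <- nchar(truth)
    doubled <- paste0(truth, truth)
    for (astart in seq(1L, max(1L, Lc - 30L), by = 29L)) {
      anchor <- substr(s, astart, astart + 29L)
      hit <- regexpr(anchor, doubled, fixed = TRUE)
      if (hit > 0) {
        off <- (as.integer(hit) - 1L - (astart - 1L)) %% Lt
        rot <- rotate_seq(truth, off)
        pa <- Biostrings::pairwiseAlignment(s, rot, type = "global")
        return(Biostrings::nmatch(pa) / max(Lc, Lt))
      }
      if (astart > 20L * 29L) break
    }
  }
  0
}

## Two-sided exact binomial p-value by direct pmf summation: the sum of
## dbinom over all outcomes whose probability does not exceed the observed
## outcome's (with a tiny relative tolerance for floating-point ties).
brute_binom_p <- function(x, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

## Exhaustive substitution-only period scan: is there any period p in
## [min_p, L/2] whose segments agree with the first at >= floor identity?
brute_has_period <- function(read, min_p, floor = 0.9) {
  ch <- strsplit(read, "", fixed = TRUE)[[1]]
  L <- length(ch)
  for (p in min_p:(L %/% 2L)) {
    nseg <- L %/% p
    ids <- vapply(2:nseg, function(i) {
      mean(ch[1:p] == ch[((i - 1L) * p + 1L):(i * p)])
    }, 0)
    if (mean(ids) >= floor) return(TRUE)
  }
  FALSE
}
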