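## Shared desk-scale fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

fixture_genome <- function() {
  if (is.null(.fx$genome))
    .fx$genome <- generate_genome(n_chroms = 2L, chrom_length = 150000L,
                                  te_density = 0.3, centromere_fraction = 0.1,
                                  centromere_multiplier = 5, seed = 11L)
  .fx$genome
}

## Small circle length model keeping read sizes desk-scale.
small_length_model <- function(min = 500L, max = 5000L) {
  list(dist = "uniform", min = min, max = max)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Build a concatemer read by hand: rotate, repeat (fractional last round).
make_read <- function(mono, rounds, offset = 0L) {
  L <- nchar(mono)
  rot <- rotate_seq(mono, offset)
  full <- floor(rounds)
  frac <- round((rounds - full) * L)
  paste0(strrep(rot, full), substr(rot, 1L, frac))
}
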