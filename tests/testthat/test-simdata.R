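test_that("genome generation is deterministic and respects degenerate weights", {
  g1 <- generate_genome(n_chroms = 1L, chrom_length = 100000L,
                        te_density = 0.2, seed = 7L)
  g2 <- generate_genome(n_chroms = 1L, chrom_length = 100000L,
                        te_density = 0.2, seed = 7L)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$te, g2$te)
  expect_identical(g1$cds, g2$cds)

  g3 <- generate_genome(n_chroms = 1L, chrom_length = 100000L,
                        te_density = 0.2,
                        superfamily_weights = c("RC/Helitron" = 1.0),
                        seed = 3L)
  expect_true(all(g3$te$superfamily == "RC/Helitron"))

  expect_error(generate_genome(superfamily_weights = c("RC/Helitron" = 0.9),
                               seed = 1L), "sum to 1")
  expect_error(generate_genome(chrom_length = 49999L, seed = 1L))
})

test_that("genome invariants hold: feature bounds, alphabet, one centromere", {
  g <- fixture_genome()
  lens <- vapply(g$sequences, nchar, 1L)
  for (d in list(g$te, g$cds)) {
    expect_true(all(d$end > d$start))
    expect_true(all(d$start >= 0))
    expect_true(all(d$end <= lens[d$chrom]))
  }
  expect_equal(nrow(g$centromeres), length(g$sequences))
  expect_false(any(grepl("[^ACGT]", g$sequences)))
  ## family -> superfamily is a function
  expect_false(anyDuplicated(g$family_map$family) > 0)
})

test_that("centromeric TE placement bias is visible in the annotation", {
  g <- generate_genome(n_chroms = 2L, chrom_length = 200000L,
                       te_density = 0.3, centromere_fraction = 0.1,
                       centromere_multiplier = 5, seed = 1L)
  ## oracle: direct interval arithmetic on the emitted annotation
  cen_bp <- 0; tot_bp <- 0
  for (i in seq_len(nrow(g$te))) {
    cen <- g$centromeres[g$centromeres$chrom == g$te$chrom[i], ]
    cen_bp <- cen_bp + overlap_bp(cen$start, cen$end,
                                  g$te$start[i], g$te$end[i])
    tot_bp <- tot_bp + (g$te$end[i] - g$te$start[i])
  }
  expect_gt(cen_bp / tot_bp, 0.1)
})

test_that("circle simulation honours class mix, chimeric rate and sequence fidelity", {
  g <- fixture_genome()
  circ <- simulate_circles(g, n = 10L, class_mix = c(TE_full = 1),
                           length_model = small_length_model(),
                           chimeric_rate = 0, seed = 2L)
  expect_equal(nrow(circ$circles), 10L)
  expect_true(all(circ$circles$origin_class == "TE_full"))
  ## every TE_full circle fully contains its source TE feature
  for (i in seq_len(10L)) {
    iv <- circ$intervals[circ$intervals$circle_id ==
                           circ$circles$circle_id[i], ]
    te <- g$te[g$te$te_id == circ$circles$source_te_id[i], ]
    expect_equal(iv$chrom, te$chrom)
    expect_lte(iv$start, te$start)
    expect_gte(iv$end, te$end)
  }
  expect_true(all(circ$circles$n_intervals == 1L))

  ## class fidelity: sequences recoverable from genome + origin intervals
  for (i in seq_len(10L)) {
    iv <- circ$intervals[circ$intervals$circle_id ==
                           circ$circles$circle_id[i], ]
    refetched <- paste(vapply(seq_len(nrow(iv)), function(r)
      genome_fetch(g, iv$chrom[r], iv$start[r], iv$end[r], iv$strand[r]),
      ""), collapse = "")
    expect_identical(circ$sequences[[i]], refetched)
  }

  chim <- simulate_circles(g, n = 40L, chimeric_rate = 1,
                           length_model = small_length_model(), seed = 4L)
  expect_true(all(chim$circles$origin_class == "chimeric"))
  expect_true(all(chim$circles$n_intervals == 2L))

  partial <- simulate_circles(g, n = 15L, class_mix = c(TE_partial = 1),
                              length_model = small_length_model(),
                              chimeric_rate = 0, seed = 5L)
  te_len <- (g$te$end - g$te$start)[match(partial$circles$source_te_id,
                                          g$te$te_id)]
  expect_true(all(partial$circles$length < te_len))
})

test_that("default length model reproduces the target population scale", {
  set.seed(123)
  lens <- rollcirc:::.draw_length(default_length_model(), n = 10000L)
  expect_lt(abs(mean(lens) - 3681) / 3681, 0.05)
  expect_true(all(lens >= 500 & lens <= 22431))
})

test_that("concatemer reads have exact structure at error zero", {
  g <- fixture_genome()
  circ <- simulate_circles(g, n = 25L, length_model = small_length_model(),
                           chimeric_rate = 0, seed = 6L)
  reads <- simulate_rca_reads(circ,
                              rounds_model = list(dist = "constant",
                                                  value = 2.5),
                              error_rate = 0, min_read_length = 200L,
                              seed = 7L)
  tr <- reads$reads
  cl <- nchar(circ$sequences)[tr$circle_id]
  ## read length equals realized rounds x circle length exactly
  expect_equal(tr$length, as.integer(round(tr$true_rounds * cl)))
  expect_true(all(abs(tr$true_rounds - 2.5) <= 1 / cl))
  ## reads reconstructable from circle + rotation offset
  for (i in seq_len(5L)) {
    expected <- make_read(circ$sequences[[tr$circle_id[i]]],
                          tr$true_rounds[i], tr$rotation_offset[i])
    expect_identical(reads$sequences[[tr$read_id[i]]], expected)
  }
})

test_that("read simulation conserves counts, is seeded, and validates rates", {
  g <- fixture_genome()
  circ <- simulate_circles(g, n = 30L, length_model = small_length_model(),
                           seed = 8L)
  r1 <- simulate_rca_reads(circ, error_rate = 0.01,
                           linear_contaminant_rate = 0.2,
                           min_read_length = 1200L, genome = g, seed = 9L)
  r2 <- simulate_rca_reads(circ, error_rate = 0.01,
                           linear_contaminant_rate = 0.2,
                           min_read_length = 1200L, genome = g, seed = 9L)
  expect_identical(r1$sequences, r2$sequences)
  expect_identical(r1$reads, r2$reads)
  ## conservation: truth records = emitted + dropped
  expect_equal(nrow(r1$reads),
               length(r1$sequences) + sum(r1$reads$dropped))
  expect_error(simulate_rca_reads(circ, error_rate = -0.1), "error_rate")
  expect_error(simulate_rca_reads(circ, error_rate = 0.2), "error_rate")
  expect_error(simulate_rca_reads(circ, linear_contaminant_rate = 0.3),
               "genome")
})

test_that("realized per-base error rate matches the configured rate", {
  g <- fixture_genome()
  circ <- simulate_circles(g, n = 60L,
                           length_model = small_length_model(500L, 1500L),
                           chimeric_rate = 0, seed = 10L)
  reads <- simulate_rca_reads(circ,
                              rounds_model = list(dist = "constant", value = 2),
                              error_rate = 0.01, min_read_length = 200L,
                              seed = 11L)
  ## oracle: pairwise alignment of each read against its error-free truth
  nerr <- 0; nbase <- 0
  for (i in seq_len(nrow(reads$reads))) {
    tr <- reads$reads[i, ]
    truth <- make_read(circ$sequences[[tr$circle_id]], tr$true_rounds,
                       tr$rotation_offset)
    pa <- Biostrings::pairwiseAlignment(reads$sequences[[tr$read_id]], truth,
                                        type = "global")
    nerr <- nerr + Biostrings::nmismatch(pa) +
      Biostrings::nindel(pa)@insertion[2] + Biostrings::nindel(pa)@deletion[2]
    nbase <- nbase + nchar(truth)
  }
  expect_gte(nerr / nbase, 0.007)
  expect_lte(nerr / nbase, 0.013)
})

test_that("written genome and read files round-trip", {
  g <- fixture_genome()
  dir <- withr::local_tempdir()
  paths <- write_genome_files(g, dir)
  expect_identical(read_fasta(paths$fasta), g$sequences)
  feats <- read_annotation_gff3(paths$gff3)
  expect_equal(feats$te[, c("te_id", "family", "superfamily", "chrom",
                            "start", "end", "strand")],
               g$te[, c("te_id", "family", "superfamily", "chrom",
                        "start", "end", "strand")])
  cen <- read_bed(paths$centromeres)
  expect_equal(cen$start, g$centromeres$start)
  fam <- read_family_map(paths$family_map)
  expect_equal(fam, g$family_map)

  circ <- simulate_circles(g, n = 5L, length_model = small_length_model(),
                           seed = 12L)
  reads <- simulate_rca_reads(circ, error_rate = 0.005,
                              min_read_length = 200L, seed = 13L)
  fq <- file.path(dir, "reads.fastq")
  write_reads_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_identical(back$sequences, reads$sequences)
  expect_true(all(unlist(back$qualities) == reads$quality_phred))
})
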