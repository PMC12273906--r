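test_that("built-in aligner recovers exact substrings with correct strand convention", {
  g <- fixture_genome()
  q <- stats::setNames(substr(g$sequences[["chr1"]], 20001L, 21000L), "q1")
  hits <- map_sequences(q, g$sequences)
  best <- best_hit(hits[hits$query_id == "q1", ])
  expect_equal(best$subject_id, "chr1")
  expect_equal(best$percent_identity, 100)
  expect_equal(best$alignment_length, 1000L)
  expect_equal(best$s_start, 20001L)
  expect_equal(best$s_end, 21000L)

  ## reverse-complemented query: same locus, s_start > s_end
  qrc <- stats::setNames(revcomp(q[[1]]), "q1rc")
  hrc <- map_sequences(qrc, g$sequences)
  bestrc <- best_hit(hrc[hrc$query_id == "q1rc", ])
  expect_gt(bestrc$s_start, bestrc$s_end)
  expect_equal(bestrc$s_end, 20001L)
  expect_equal(bestrc$s_start, 21000L)

  expect_error(map_sequences(character(0), g$sequences), "non-empty")
})

test_that("tabular hit reader applies the e-value filter and max one HSP per subject", {
  dir <- withr::local_tempdir()
  lines <- c(
    "m1\tchr1\t98.5\t1200\t10\t2\t1\t1200\t5000\t6199\t1e-60\t900",
    "m1\tchr1\t95.0\t800\t30\t4\t1\t800\t9000\t9799\t1e-55\t700",
    "m1\tchr2\t97.0\t500\t10\t1\t1\t500\t100\t599\t1e-40\t450",
    "m2\tchr1\t99.0\t300\t2\t0\t1\t300\t700\t401\t1e-52\t280")
  path <- file.path(dir, "hits.tsv")
  writeLines(lines, path)
  hits <- read_alignment_hits(path)
  ## the 1e-40 hit is filtered; m1/chr1 keeps only the best HSP
  expect_equal(nrow(hits), 2L)
  expect_false(any(hits$e_value > 1e-50))
  expect_equal(hits$bit_score[hits$query_id == "m1"], 900)
  ## minus-strand encoding survives
  expect_gt(hits$s_start[hits$query_id == "m2"],
            hits$s_end[hits$query_id == "m2"])

  writeLines(c(lines[1], "m3\tchr1\t90\t100\t5\t1\t1\t100\t1\t100\t1e-60"),
             path)
  expect_error(read_alignment_hits(path), "line 2")
})

test_that("best hit ordering matches an exhaustive comparison oracle", {
  mk <- function(bit, ev, len, subj, s1) {
    data.frame(query_id = "q", subject_id = subj, percent_identity = 95,
               alignment_length = len, mismatches = 0L, gap_opens = 0L,
               q_start = 1L, q_end = len, s_start = s1, s_end = s1 + len,
               e_value = ev, bit_score = bit, stringsAsFactors = FALSE)
  }
  h <- rbind(mk(500, 1e-60, 400L, "chr1", 10L), mk(420, 1e-80, 900L, "chr1", 5L))
  expect_equal(best_hit(h)$bit_score, 500)
  ## full tie except subject id: lexicographically smallest wins
  h2 <- rbind(mk(500, 1e-60, 400L, "chr2", 10L), mk(500, 1e-60, 400L, "chr10", 10L))
  expect_equal(best_hit(h2)$subject_id, "chr10")

  ## randomized sets against a brute-force oracle of the documented order
  set.seed(81)
  for (i in 1:200) {
    n <- sample(2:8, 1L)
    h <- do.call(rbind, lapply(seq_len(n), function(j)
      mk(sample(100:110, 1L), 10^-sample(50:60, 1L), sample(100:105, 1L),
         sample(c("chr1", "chr2", "chr10"), 1L), sample(1:50, 1L))))
    ord <- order(-h$bit_score, h$e_value, -h$alignment_length,
                 h$subject_id, pmin(h$s_start, h$s_end))
    expect_identical(best_hit(h), h[ord[1], , drop = FALSE])
  }
})

test_that("TE completeness follows the length rule with a coverage guard", {
  expect_equal(classify_te_completeness(1200, 1500, 1100), "partial")
  expect_equal(classify_te_completeness(1500, 1500, 1500), "full")
  ## longer than the TE but covering only 92% of it: partial under the guard
  expect_equal(classify_te_completeness(5000, 1000, 920), "partial")
  expect_equal(classify_te_completeness(5000, 1000, 960), "full")
  expect_error(classify_te_completeness(1000, 500, 600))
})

test_that("origin classification applies the TE > CDS > intergenic priority", {
  g <- fixture_genome()
  dbs <- extract_feature_dbs(g)
  fake_hit <- function(subj) data.frame(
    query_id = "m", subject_id = subj, percent_identity = 99,
    alignment_length = 500L, mismatches = 1L, gap_opens = 0L,
    q_start = 1L, q_end = 500L, s_start = 1L, s_end = 500L,
    e_value = 0, bit_score = 990, stringsAsFactors = FALSE)
  both <- classify_origin(fake_hit(g$te$te_id[1]), fake_hit(g$cds$cds_id[1]),
                          g$family_map, dbs$te_families)
  expect_equal(both$origin_class, "TE")
  expect_equal(both$te_family, g$te$family[1])
  none <- classify_origin(rollcirc:::.empty_hits(), rollcirc:::.empty_hits(),
                          g$family_map, dbs$te_families)
  expect_equal(none$origin_class, "intergenic")
  cds_only <- classify_origin(rollcirc:::.empty_hits(),
                              fake_hit(g$cds$cds_id[1]),
                              g$family_map, dbs$te_families)
  expect_equal(cds_only$origin_class, "CDS")
  ## unknown TE id degrades to unclassified with a warning
  expect_warning(
    un <- classify_origin(fake_hit("TEX"), rollcirc:::.empty_hits(),
                          g$family_map, c(TEX = "no_such_family")),
    "missing")
  expect_equal(un$te_superfamily, "unclassified")
})

test_that("single-event classification distinguishes continuous from chimeric loci", {
  hit <- function(subj, qs, qe, ss, se) data.frame(
    query_id = "m", subject_id = subj, percent_identity = 99,
    alignment_length = qe - qs + 1L, mismatches = 0L, gap_opens = 0L,
    q_start = qs, q_end = qe, s_start = ss, s_end = se,
    e_value = 0, bit_score = 2L * (qe - qs), stringsAsFactors = FALSE)
  ## one hit covering the whole monomer
  expect_true(classify_single_event(hit("chr1", 1L, 1000L, 501L, 1500L), 1000L))
  ## two hits on different chromosomes, each half
  h2 <- rbind(hit("chr1", 1L, 500L, 100L, 599L),
              hit("chr2", 501L, 1000L, 5000L, 5499L))
  expect_false(classify_single_event(h2, 1000L))
  ## rotation-phase split: adjacent subject intervals merge into one locus
  h3 <- rbind(hit("chr1", 1L, 600L, 1401L, 2000L),
              hit("chr1", 601L, 1000L, 1001L, 1400L))
  expect_true(classify_single_event(h3, 1000L))
})

test_that("window assignment bins by best-hit midpoint with half-open windows", {
  w <- assign_window("chr1", 150000L, 151000L, 100000L)
  expect_equal(w$bin, 1L)
  ## midpoint exactly at a window boundary goes to the upper bin
  w2 <- assign_window("chr1", 199751L, 200250L, 100000L)
  expect_equal(w2$bin, 2L)
  w3 <- assign_window("chr1", 1L, 1000L, 150000L,
                      chrom_lengths = c(chr1 = 150000L))
  expect_equal(w3$bin, 0L)
  expect_error(assign_window("chr1", 140000L, 160001L, 100000L,
                             chrom_lengths = c(chr1 = 160000L)), "bounds")
  expect_error(assign_window("chrX", 1L, 10L, 100000L,
                             chrom_lengths = c(chr1 = 160000L)), "unknown")
})

test_that("annotation matches simulator truth on error-free circles", {
  g <- fixture_genome()
  dbs <- extract_feature_dbs(g)
  circ <- simulate_circles(g, n = 30L,
                           class_mix = c(TE_full = 0.3, TE_partial = 0.3,
                                         CDS = 0.2, intergenic = 0.2),
                           length_model = small_length_model(),
                           chimeric_rate = 0, seed = 14L)
  monomers <- circ$sequences
  names(monomers) <- circ$circles$circle_id
  ann <- annotate_monomers(monomers, g$sequences, dbs$te, dbs$cds,
                           dbs$te_families, g$family_map,
                           window_size = 20000L)
  expect_equal(length(ann$unmapped), 0L)
  a <- ann$annotations
  truth <- circ$circles
  m <- merge(a, truth, by.x = "monomer_id", by.y = "circle_id")
  expected_class <- c(TE_full = "TE", TE_partial = "TE", CDS = "CDS",
                      intergenic = "intergenic")
  expect_equal(m$origin_class.x, unname(expected_class[m$origin_class.y]))
  te_rows <- m$origin_class.x == "TE"
  expect_equal(m$te_id[te_rows], m$source_te_id[te_rows])
  expect_equal(m$te_completeness[te_rows],
               ifelse(m$origin_class.y[te_rows] == "TE_full",
                      "full", "partial"))
  expect_true(all(m$single_event))
  ## every monomer is annotated or unmapped, never both or neither
  expect_equal(nrow(a) + length(ann$unmapped), length(monomers))

  ## chimeric circles are flagged as multi-locus
  chim <- simulate_circles(g, n = 10L, chimeric_rate = 1,
                           length_model = small_length_model(), seed = 15L)
  cm <- chim$sequences
  names(cm) <- chim$circles$circle_id
  ann2 <- annotate_monomers(cm, g$sequences, dbs$te, dbs$cds,
                            dbs$te_families, g$family_map,
                            window_size = 20000L)
  expect_gte(mean(!ann2$annotations$single_event), 0.9)
})
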