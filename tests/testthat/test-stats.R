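test_that("genomic composition fractions sum to one and match direct summation", {
  g <- fixture_genome()
  comp <- genomic_composition(g$te)
  for (d in comp) {
    expect_equal(sum(d$fraction_by_count), 1, tolerance = 1e-9)
    expect_equal(sum(d$fraction_by_bp), 1, tolerance = 1e-9)
  }
  ## oracle: brute-force bp summation per superfamily
  for (sf in comp$superfamily$group) {
    sel <- g$te$superfamily == sf
    expect_equal(comp$superfamily$total_bp[comp$superfamily$group == sf],
                 sum(g$te$end[sel] - g$te$start[sel]))
  }
  one <- genomic_composition(data.frame(
    family = c("f1", "f2", "f3"), superfamily = "RC/Helitron",
    start = c(0L, 100L, 500L), end = c(50L, 400L, 900L)))
  expect_equal(one$superfamily$fraction_by_count, 1)
})

test_that("exact binomial p-values match brute-force pmf summation", {
  ## spec example: observed 30 of 100 at expected 0.2
  comp <- data.frame(group = "g", fraction_by_count = 0.2,
                     fraction_by_bp = 0.2)
  res <- enrichment_test(c(g = 30L), 100L, comp, correction = "none")
  expect_equal(res$p_value, brute_binom_p(30L, 100L, 0.2),
               tolerance = 1e-12)

  set.seed(141)
  for (i in 1:200) {
    n <- sample(10:500, 1L)
    p <- runif(1, 0.02, 0.95)
    x <- rbinom(1, n, runif(1, 0.02, 0.95))
    comp <- data.frame(group = "g", fraction_by_count = p,
                       fraction_by_bp = p)
    res <- enrichment_test(stats::setNames(x, "g"), n, comp,
                           correction = "none")
    expect_equal(res$p_value, brute_binom_p(x, n, p), tolerance = 1e-12)
  }
})

test_that("enrichment direction and adjustment behave as documented", {
  comp <- data.frame(group = c("a", "b"),
                     fraction_by_count = c(0.5, 0.5),
                     fraction_by_bp = c(0.5, 0.5))
  ## null-consistent observed counts: no direction
  res <- enrichment_test(c(a = 50L, b = 50L), 100L, comp)
  expect_true(all(res$direction == "none"))
  expect_true(all(res$p_value >= 0.05))
  ## strong overrepresentation is flagged
  comp2 <- data.frame(group = c("a", "b"),
                      fraction_by_count = c(0.1, 0.9),
                      fraction_by_bp = c(0.1, 0.9))
  res2 <- enrichment_test(c(a = 60L, b = 40L), 100L, comp2)
  expect_equal(res2$direction, c("over", "under"))
  expect_true(all(res2$adjusted_p >= res2$p_value))
  ## expected fraction zero with observed > 0: smallest representable p
  comp3 <- data.frame(group = "a", fraction_by_count = 0, fraction_by_bp = 0)
  expect_warning(res3 <- enrichment_test(c(a = 3L), 10L, comp3), "0")
  expect_lt(res3$p_value, 1e-300)
})

test_that("group comparisons pick the Welch t-test or ANOVA and hold their level", {
  ident <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("x", "y"), each = 3L))
  expect_equal(ident$method, "welch_t")
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_false(ident$significant)

  three <- compare_groups(c(1, 2, 1.5, 1, 2, 1.5, 7, 8, 7.5),
                          rep(c("a", "b", "c"), each = 3L))
  expect_equal(three$method, "anova")
  expect_true(three$significant)

  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")), "2 replicates")

  ## Monte-Carlo type-I error of the two-group path
  set.seed(151)
  rej <- mean(replicate(400, {
    compare_groups(rnorm(6), rep(c("a", "b"), each = 3L))$p_value < 0.05
  }))
  expect_gte(rej, 0.025)
  expect_lte(rej, 0.085)

  ## power: one group shifted by 3 SD at n = 3 is mostly detected
  set.seed(152)
  pow <- mean(replicate(200, {
    v <- c(rnorm(3), rnorm(3), rnorm(3, mean = 3))
    compare_groups(v, rep(c("a", "b", "c"), each = 3L))$p_value < 0.05
  }))
  expect_gte(pow, 0.8)
})

test_that("window correlation is exact on affine tracks and NA on zero variance", {
  prof <- data.frame(chrom = "chr1", bin = 0:9,
                     normalized = c(2, 5, 1, 7, 4, 0, 3, 8, 6, 2))
  track <- data.frame(chrom = "chr1", bin = 0:9,
                      value = 2 * prof$normalized + 1)
  res <- correlate_windows(prof, track)
  expect_equal(res$pearson_r, 1.0)
  expect_equal(res$r_squared, res$pearson_r^2, tolerance = 1e-12)
  expect_equal(res$n_windows, 10L)

  flat <- data.frame(chrom = "chr1", bin = 0:9, value = 5)
  expect_true(is.na(correlate_windows(prof, flat)$pearson_r))

  ## windows missing from either side are excluded and counted
  res2 <- correlate_windows(prof, track[1:6, ])
  expect_equal(res2$n_windows, 6L)
  expect_equal(res2$n_excluded, 4L)
  expect_error(correlate_windows(prof[1:2, ], track), "3 shared")

  ## independent tracks show no spurious correlation
  set.seed(161)
  big <- data.frame(chrom = "chr1", bin = 0:999, normalized = rnorm(1000))
  small_r <- vapply(1:40, function(i) {
    tr <- data.frame(chrom = "chr1", bin = 0:999, value = rnorm(1000))
    abs(correlate_windows(big, tr)$pearson_r)
  }, 0)
  expect_gte(mean(small_r < 0.1), 0.95)
})

test_that("LIR overlap counts use the one-bp rule and shares sum to 100", {
  ann <- data.frame(
    monomer_id = sprintf("m%d", 1:6), chrom = "chr1",
    start = c(100L, 300L, 1000L, 2000L, 100L, 5000L),
    end = c(200L, 400L, 1100L, 2100L, 200L, 5100L),
    sample = c("s1", "s1", "s1", "s2", "s2", "s2"),
    stringsAsFactors = FALSE)
  lir <- data.frame(chrom = "chr1", start = c(150L, 2050L),
                    end = c(160L, 2060L))
  res <- lir_overlap(ann, lir)
  expect_equal(res$lir_count[res$sample == "s1"], 1L)  # [100,200) vs [150,160)
  expect_equal(res$lir_count[res$sample == "s2"], 2L)
  expect_equal(sum(res$share_pct), 100)
  ## disjoint intervals are not counted
  none <- lir_overlap(ann, data.frame(chrom = "chr1", start = 9000L,
                                      end = 9100L))
  expect_true(all(none$lir_count == 0L))
})

test_that("centromeric partition matches brute-force overlap counts and tests", {
  g <- fixture_genome()
  ## all eccDNAs of one family inside centromeres, genomic fraction ~0.5
  cen <- g$centromeres
  ann <- data.frame(
    monomer_id = sprintf("m%02d", 1:20), chrom = cen$chrom[1],
    start = cen$start[1] + seq(0L, 1900L, by = 100L),
    end = cen$start[1] + seq(100L, 2000L, by = 100L),
    origin_class = "TE", te_family = "famX", stringsAsFactors = FALSE)
  te_feat <- data.frame(
    family = "famX", chrom = cen$chrom[1],
    start = c(cen$start[1] + 1:5 * 1000L, 1:5 * 1000L),
    end = c(cen$start[1] + 1:5 * 1000L + 500L, 1:5 * 1000L + 500L))
  res <- centromeric_partition(ann, te_feat, cen)
  expect_equal(res$partition$centromeric, 20L)
  expect_equal(res$partition$genomic_centromeric_fraction, 0.5)
  expect_lt(res$partition$p_value, 0.001)
  expect_equal(res$partition$p_value, brute_binom_p(20L, 20L, 0.5),
               tolerance = 1e-12)
  expect_equal(res$partition$direction, "over")

  ## share equal to the genomic fraction: no direction
  ann2 <- ann
  ann2$start[11:20] <- 1000L; ann2$end[11:20] <- 1100L
  res2 <- centromeric_partition(ann2, te_feat, cen)
  expect_equal(res2$partition$direction, "none")

  ## partition table equals brute-force interval arithmetic on a genome with
  ## centromere-biased placement
  circ <- simulate_circles(g, n = 40L, class_mix = c(TE_full = 1),
                           length_model = small_length_model(),
                           chimeric_rate = 0, seed = 17L)
  iv <- circ$intervals
  ann3 <- data.frame(
    monomer_id = iv$circle_id, chrom = iv$chrom, start = iv$start,
    end = iv$end, origin_class = "TE",
    te_family = g$te$family[match(circ$circles$source_te_id, g$te$te_id)],
    stringsAsFactors = FALSE)
  res3 <- centromeric_partition(ann3, g$te, g$centromeres)
  brute <- vapply(seq_len(nrow(ann3)), function(i) {
    cc <- g$centromeres[g$centromeres$chrom == ann3$chrom[i], ]
    overlap_bp(cc$start, cc$end, ann3$start[i], ann3$end[i]) > 0
  }, TRUE)
  for (fam in res3$partition$family) {
    sel <- ann3$te_family == fam
    expect_equal(res3$partition$centromeric[res3$partition$family == fam],
                 sum(brute[sel]))
  }
  expect_equal(sum(res3$by_chromosome$count), nrow(ann3))
})
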