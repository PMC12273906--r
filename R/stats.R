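## ---------------------------------------------------------------------------
## Inferential layer: TE-superfamily enrichment against genomic composition,
## group comparisons, track/fold-change correlations, inverted-repeat overlap
## counting, and centromeric partition tests.
## ---------------------------------------------------------------------------

#' Genomic TE composition
#'
#' Element counts, total bp, and both count- and bp-based fractions per
#' family and per superfamily; fractions sum to 1 over the vocabulary.
#'
#' @param te_features TE feature data frame (`family`, `superfamily`,
#'   `start`, `end`; 0-based half-open).
#' @return List with `family` and `superfamily` data frames
#'   (`group`, `element_count`, `total_bp`, `fraction_by_count`,
#'   `fraction_by_bp`).
#' @export
genomic_composition <- function(te_features) {
  stopifnot(nrow(te_features) >= 1L)
  one <- function(col) {
    cnt <- table(te_features[[col]])
    bp <- tapply(te_features$end - te_features$start, te_features[[col]], sum)
    g <- names(cnt)
    data.frame(group = g, element_count = as.integer(cnt[g]),
               total_bp = as.numeric(bp[g]),
               fraction_by_count = as.numeric(cnt[g]) / sum(cnt),
               fraction_by_bp = as.numeric(bp[g]) / sum(bp),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(family = one("family"), superfamily = one("superfamily"))
}

#' TE-group enrichment against genomic composition
#'
#' Per group, a two-sided exact binomial test of the observed eccDNA count
#' among `n_total` against the group's genomic fraction, with configurable
#' multiple-testing correction (Benjamini-Hochberg by default; `"none"`
#' mirrors reporting of bare p-values against the 0.05 rule).
#'
#' @param observed Named integer vector of eccDNA counts per group.
#' @param n_total Total number of trials (e.g. TE-derived eccDNA reads).
#' @param composition A composition data frame (`group`, fractions), e.g.
#'   one element of [genomic_composition()].
#' @param basis `"count"` or `"bp"` fractions as the expectation.
#' @param alpha Significance level (default 0.05).
#' @param correction Passed to [stats::p.adjust()]; default `"BH"`.
#' @return Data frame: `group`, `observed`, `n_total`, `expected_fraction`,
#'   `p_value`, `adjusted_p`, `direction` (`over`/`under`/`none`).
#' @export
enrichment_test <- function(observed, n_total, composition,
                            basis = c("count", "bp"), alpha = 0.05,
                            correction = "BH") {
  basis <- match.arg(basis)
  stopifnot(sum(observed) <= n_total)
  fcol <- if (basis == "count") "fraction_by_count" else "fraction_by_bp"
  groups <- names(observed)
  ef <- composition[[fcol]][match(groups, composition$group)]
  if (anyNA(ef)) stop("groups missing from composition: ",
                      paste(groups[is.na(ef)], collapse = ", "))
  p <- vapply(seq_along(groups), function(i) {
    if (ef[i] <= 0) {
      if (observed[i] > 0) {
        warning("expected fraction 0 with observed > 0 for ", groups[i])
        return(.Machine$double.xmin)
      }
      return(1)
    }
    stats::binom.test(observed[i], n_total, p = ef[i],
                      alternative = "two.sided")$p.value
  }, 0)
  adj <- stats::p.adjust(p, method = correction)
  dirn <- ifelse(adj >= alpha, "none",
                 ifelse(observed / n_total > ef, "over", "under"))
  data.frame(group = groups, observed = as.integer(observed),
             n_total = n_total, expected_fraction = ef,
             p_value = p, adjusted_p = adj, direction = dirn,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare normalized abundances across condition groups
#'
#' Two groups: Welch two-sample t-test; three or more: one-way ANOVA.
#' Significance is declared at p < alpha.
#'
#' @param values Numeric vector of per-replicate normalized abundances.
#' @param groups Factor or character vector of condition labels.
#' @param alpha Significance level (default 0.05).
#' @return List: `method`, `statistic`, `df`, `p_value`, `significant`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  ng <- nlevels(groups)
  stopifnot(ng >= 2L)
  tabn <- table(groups)
  if (any(tabn < 2L)) stop("every group needs at least 2 replicates")
  if (ng == 2L) {
    tt <- stats::t.test(values ~ groups)     # Welch by default
    list(method = "welch_t", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         significant = tt$p.value < alpha)
  } else {
    fit <- stats::aov(values ~ groups)
    s <- summary(fit)[[1]]
    list(method = "anova", statistic = s$`F value`[1],
         df = s$Df, p_value = s$`Pr(>F)`[1],
         significant = s$`Pr(>F)`[1] < alpha)
  }
}

#' Correlate a per-window eccDNA profile with a genomic track
#'
#' Pearson correlation over windows shared between the profile and the
#' track (inner join on chromosome and window index); missing windows are
#' excluded and counted. A zero-variance side yields an explicit NA result.
#'
#' @param profile Window profile data frame (`chrom`, `bin`, `normalized`),
#'   e.g. one sample of [window_profile()].
#' @param track Data frame `chrom`, `bin`, `value` (e.g. from
#'   [read_bedgraph_windows()]).
#' @return List: `n_windows`, `n_excluded`, `pearson_r`, `r_squared`,
#'   `p_value`.
#' @export
correlate_windows <- function(profile, track) {
  m <- merge(profile[, c("chrom", "bin", "normalized")],
             track[, c("chrom", "bin", "value")],
             by = c("chrom", "bin"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n_exc <- (nrow(profile) - nrow(m)) + (nrow(track) - nrow(m))
  if (nrow(m) < 3L) stop("fewer than 3 shared windows")
  if (stats::sd(m$normalized) == 0 || stats::sd(m$value) == 0)
    return(list(n_windows = nrow(m), n_excluded = n_exc,
                pearson_r = NA_real_, r_squared = NA_real_,
                p_value = NA_real_))
  ct <- stats::cor.test(m$normalized, m$value, method = "pearson")
  r <- unname(ct$estimate)
  list(n_windows = nrow(m), n_excluded = n_exc,
       pearson_r = r, r_squared = r^2, p_value = ct$p.value)
}

#' Count eccDNAs overlapping long-inverted-repeat intervals
#'
#' A monomer is LIR-derived iff its best genomic locus overlaps any LIR
#' interval by at least `min_overlap` bp. Returns per-sample counts and
#' each sample's share of the total LIR-derived count (shares sum to 100).
#'
#' @param annotations Annotation data frame with `sample`, `chrom`,
#'   `start`, `end` (0-based half-open best locus).
#' @param lir_intervals Data frame `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_bed()].
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Data frame: `sample`, `lir_count`, `total`, `share_pct`.
#' @export
lir_overlap <- function(annotations, lir_intervals, min_overlap = 1L) {
  gr_ann <- GenomicRanges::GRanges(
    annotations$chrom,
    IRanges::IRanges(start = annotations$start + 1L, end = annotations$end))
  gr_lir <- GenomicRanges::GRanges(
    lir_intervals$chrom,
    IRanges::IRanges(start = lir_intervals$start + 1L,
                     end = lir_intervals$end))
  ov <- GenomicRanges::countOverlaps(gr_ann, gr_lir,
                                     minoverlap = min_overlap) > 0
  samples <- sort(unique(annotations$sample))
  cnt <- vapply(samples, function(s) sum(ov[annotations$sample == s]), 0L)
  tot <- vapply(samples, function(s) sum(annotations$sample == s), 0L)
  share <- if (sum(cnt) > 0) 100 * cnt / sum(cnt) else rep(0, length(cnt))
  data.frame(sample = samples, lir_count = cnt, total = tot,
             share_pct = share, stringsAsFactors = FALSE, row.names = NULL)
}

#' Centromeric vs non-centromeric eccDNA partition per TE family
#'
#' Partitions eccDNA loci and genomic TE copies by centromere overlap and,
#' per family, runs an exact binomial test of the eccDNA centromeric share
#' against that family's genomic centromeric copy fraction. Also returns
#' the per-chromosome stacked counts.
#'
#' @param annotations Annotation data frame (TE rows used; `chrom`,
#'   `start`, `end`, `te_family`).
#' @param te_features Genomic TE feature table (`family`, `chrom`,
#'   `start`, `end`).
#' @param centromeres Data frame `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param alpha Significance level (default 0.05).
#' @return List with `partition` (per family: counts, genomic fraction,
#'   p-value, direction) and `by_chromosome` (family x chromosome counts).
#' @export
centromeric_partition <- function(annotations, te_features, centromeres,
                                  alpha = 0.05) {
  in_cen <- function(chrom, start, end) {
    vapply(seq_along(chrom), function(i) {
      cen <- centromeres[centromeres$chrom == chrom[i], , drop = FALSE]
      nrow(cen) > 0 &&
        any(overlap_bp(cen$start, cen$end, start[i], end[i]) > 0)
    }, TRUE)
  }
  te_ann <- annotations[annotations$origin_class == "TE" &
                          !is.na(annotations$te_family), , drop = FALSE]
  if (!nrow(te_ann)) stop("no TE-derived annotations")
  ecc_cen <- in_cen(te_ann$chrom, te_ann$start, te_ann$end)
  gen_cen <- in_cen(te_features$chrom, te_features$start, te_features$end)
  rows <- list()
  for (fam in sort(unique(te_ann$te_family))) {
    gsel <- te_features$family == fam
    if (!any(gsel)) {
      warning("family ", fam, " has no genomic copies; skipped")
      next
    }
    gfrac <- mean(gen_cen[gsel])
    esel <- te_ann$te_family == fam
    n <- sum(esel); x <- sum(ecc_cen[esel])
    p <- if (gfrac <= 0) { if (x > 0) .Machine$double.xmin else 1 }
    else if (gfrac >= 1) { if (x < n) .Machine$double.xmin else 1 }
    else stats::binom.test(x, n, p = gfrac)$p.value
    rows[[fam]] <- data.frame(
      family = fam, centromeric = x, non_centromeric = n - x,
      genomic_centromeric_fraction = gfrac, p_value = p,
      direction = if (p >= alpha) "none"
                  else if (x / n > gfrac) "over" else "under",
      stringsAsFactors = FALSE)
  }
  by_chrom <- as.data.frame(table(family = te_ann$te_family,
                                  chrom = te_ann$chrom),
                            stringsAsFactors = FALSE)
  names(by_chrom)[3] <- "count"
  list(partition = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       by_chromosome = by_chrom)
}
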