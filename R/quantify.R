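## ---------------------------------------------------------------------------
## Quantification: normalized window profiles and TE-group abundances. Two
## distinct denominators are kept explicit: window profiles are normalized by
## the sample's total eccDNA reads; TE abundances by the sample's total CCS
## reads. Outputs name the denominator to prevent silent mixing.
## ---------------------------------------------------------------------------

.check_manifest <- function(manifest) {
  need <- c("sample_id", "condition", "replicate",
            "total_ccs_reads", "total_eccdna_reads")
  stopifnot(all(need %in% names(manifest)))
  if (anyNA(manifest$total_ccs_reads))
    stop("manifest is missing total_ccs_reads values")
  if (anyNA(manifest$total_eccdna_reads))
    stop("manifest is missing total_eccdna_reads values")
  if (any(manifest$total_eccdna_reads > manifest$total_ccs_reads))
    stop("total_eccdna_reads exceeds total_ccs_reads in manifest")
  if (anyDuplicated(paste(manifest$condition, manifest$replicate)))
    stop("replicate indices must be unique within condition")
  manifest
}

#' Per-window normalized eccDNA profile
#'
#' For each sample, `normalized = window count / total eccDNA reads x 100`.
#' All windows of all chromosomes are present, zero-count windows included,
#' so per-sample normalized values sum to `100 x (mapped / total eccDNA
#' reads)`.
#'
#' @param annotations Annotation data frame with `monomer_id`, `chrom`,
#'   `window` and a `sample` column.
#' @param manifest Sample manifest: `sample_id`, `condition`, `replicate`,
#'   `total_ccs_reads`, `total_eccdna_reads`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param window_size Window size in bp (default 100,000).
#' @return Long-format data frame: `chrom`, `bin`, `sample`, `condition`,
#'   `replicate`, `raw`, `normalized`.
#' @export
window_profile <- function(annotations, manifest, chrom_lengths,
                           window_size = 100000L) {
  .check_manifest(manifest)
  if (any(manifest$total_eccdna_reads == 0))
    stop("total_eccdna_reads is zero for sample ",
         manifest$sample_id[manifest$total_eccdna_reads == 0][1])
  grid <- do.call(rbind, lapply(names(chrom_lengths), function(ch)
    data.frame(chrom = ch,
               bin = 0:((chrom_lengths[[ch]] - 1L) %/% window_size),
               stringsAsFactors = FALSE)))
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    s <- manifest$sample_id[i]
    a <- annotations[annotations$sample == s, , drop = FALSE]
    cnt <- stats::aggregate(list(raw = a$monomer_id),
                            by = list(chrom = a$chrom, bin = a$window),
                            FUN = length)
    g <- merge(grid, cnt, all.x = TRUE)
    g$raw[is.na(g$raw)] <- 0L
    g$sample <- s
    g$condition <- manifest$condition[i]
    g$replicate <- manifest$replicate[i]
    g$normalized <- g$raw / manifest$total_eccdna_reads[i] * 100
    out[[i]] <- g[order(g$chrom, g$bin),
                  c("chrom", "bin", "sample", "condition", "replicate",
                    "raw", "normalized")]
  }
  res <- do.call(rbind, out)
  attr(res, "denominator") <- "total_eccdna_reads"
  rownames(res) <- NULL
  res
}

#' Normalized TE-derived eccDNA abundance
#'
#' For each sample and TE group (element, family or superfamily),
#' `normalized = TE-derived eccDNA reads in group / total CCS reads x 100`.
#' Family-level values therefore sum exactly to their superfamily's value.
#'
#' @param annotations Annotation data frame with a `sample` column; only
#'   rows with `origin_class == "TE"` contribute.
#' @param manifest Sample manifest (requires `total_ccs_reads`).
#' @param axis One of `"te"`, `"family"`, `"superfamily"`.
#' @return Long-format data frame: `axis`, `group`, `sample`, `condition`,
#'   `replicate`, `raw`, `normalized`.
#' @export
te_abundance <- function(annotations, manifest,
                         axis = c("superfamily", "family", "te")) {
  axis <- match.arg(axis)
  .check_manifest(manifest)
  if (any(is.na(manifest$total_ccs_reads)))
    stop("manifest is missing total_ccs_reads")
  col <- switch(axis, te = "te_id", family = "te_family",
                superfamily = "te_superfamily")
  te_ann <- annotations[annotations$origin_class == "TE", , drop = FALSE]
  groups <- sort(unique(te_ann[[col]]))
  ## superfamily values are built by summing family-level values, so the
  ## additivity "families sum to their superfamily" holds bit-for-bit
  fam_groups <- sort(unique(te_ann$te_family))
  sf_of <- te_ann$te_superfamily[match(fam_groups, te_ann$te_family)]
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    s <- manifest$sample_id[i]
    a <- te_ann[te_ann$sample == s, , drop = FALSE]
    if (axis == "superfamily") {
      fam_raw <- vapply(fam_groups, function(g) sum(a$te_family == g), 0L)
      fam_norm <- fam_raw / manifest$total_ccs_reads[i] * 100
      raw <- vapply(groups, function(g) sum(fam_raw[sf_of == g]), 0)
      norm <- vapply(groups, function(g) sum(fam_norm[sf_of == g]), 0)
    } else {
      raw <- vapply(groups, function(g) sum(a[[col]] == g), 0L)
      norm <- raw / manifest$total_ccs_reads[i] * 100
    }
    out[[i]] <- data.frame(
      axis = axis, group = groups, sample = s,
      condition = manifest$condition[i], replicate = manifest$replicate[i],
      raw = raw, normalized = norm,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "denominator") <- "total_ccs_reads"
  rownames(res) <- NULL
  res
}

#' Fold change between two abundance tables
#'
#' Per-key ratio of normalized values, `(A + pseudo) / (B + pseudo)`, with
#' its log2. With the default `pseudo = 0`, a zero denominator yields `NA`
#' with a warning (a legitimate biological zero, not an error).
#'
#' @param table_a,table_b Abundance tables sharing the same axis, with
#'   columns `group` and `normalized` (already averaged over replicates or
#'   from single samples).
#' @param pseudo Pseudocount added to both sides (default 0).
#' @return Data frame `group`, `value_a`, `value_b`, `fold`, `log2_fold`.
#' @export
fold_change <- function(table_a, table_b, pseudo = 0) {
  if (!identical(unique(as.character(table_a$axis)),
                 unique(as.character(table_b$axis))))
    stop("abundance tables use different axes")
  m <- merge(stats::aggregate(normalized ~ group, table_a, mean),
             stats::aggregate(normalized ~ group, table_b, mean),
             by = "group", suffixes = c("_a", "_b"))
  denom <- m$normalized_b + pseudo
  fold <- ifelse(denom == 0, NA_real_, (m$normalized_a + pseudo) / denom)
  if (anyNA(fold))
    warning(sum(is.na(fold)), " group(s) with zero denominator -> NA fold change")
  data.frame(group = m$group, value_a = m$normalized_a,
             value_b = m$normalized_b, fold = fold,
             log2_fold = log2(fold), stringsAsFactors = FALSE)
}

#' Replicate means and standard deviations
#'
#' Summarizes an abundance table across replicates within condition, with
#' the sample (n - 1) standard deviation used for error bars.
#'
#' @param abundance A long-format abundance table with `group` (or `chrom` +
#'   `bin`), `condition` and `normalized`.
#' @return Data frame with per-group, per-condition `mean`, `sd`, `n`.
#' @export
replicate_summary <- function(abundance) {
  key <- if ("group" %in% names(abundance)) "group" else c("chrom", "bin")
  agg <- stats::aggregate(
    abundance$normalized,
    by = c(as.list(abundance[key]), list(condition = abundance$condition)),
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x)))
  out <- cbind(agg[setdiff(names(agg), "x")], as.data.frame(agg$x))
  names(out)[names(out) %in% c("mean", "sd", "n")] <- c("mean", "sd", "n")
  out
}
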