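## ---------------------------------------------------------------------------
## I/O layer: standard formats with the coordinate conversions centralized
## here. Internal coordinates are 0-based half-open; GFF3 is written 1-based
## inclusive; BED and bedGraph are written 0-based half-open; tabular
## alignment hits use the 12-column 1-based-inclusive dialect.
## ---------------------------------------------------------------------------

#' Write simulated genome files
#'
#' Writes the genome FASTA, a GFF3 with TE and CDS features (1-based
#' inclusive), a centromere BED (0-based half-open), and the two-column
#' family-to-superfamily TSV.
#'
#' @param genome A `sim_genome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "annotation.gff3"),
    centromeres = file.path(dir, "centromeres.bed"),
    family_map = file.path(dir, "te_families.tsv"))
  dna <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(dna, paths$fasta)
  te <- genome$te; cds <- genome$cds
  gff <- c("##gff-version 3",
    sprintf("%s\trollcirc_sim\ttransposable_element\t%d\t%d\t.\t%s\t.\tID=%s;family=%s;superfamily=%s",
            te$chrom, te$start + 1L, te$end, te$strand, te$te_id,
            te$family, te$superfamily),
    sprintf("%s\trollcirc_sim\tCDS\t%d\t%d\t.\t%s\t.\tID=%s",
            cds$chrom, cds$start + 1L, cds$end, cds$strand, cds$cds_id))
  writeLines(gff, paths$gff3)
  writeLines(sprintf("%s\t%d\t%d\tcentromere", genome$centromeres$chrom,
                     genome$centromeres$start, genome$centromeres$end),
             paths$centromeres)
  write.table(genome$family_map, paths$family_map, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write simulated reads as FASTQ plus truth TSV
#'
#' @param sim A `sim_reads` object.
#' @param fastq_path Output FASTQ path (Phred+33, flat qualities).
#' @param truth_path Optional truth-table TSV path.
#' @return Invisibly, `fastq_path`.
#' @export
write_reads_fastq <- function(sim, fastq_path, truth_path = NULL) {
  qchar <- rawToChar(as.raw(33L + sim$quality_phred))
  con <- file(fastq_path, "w")
  on.exit(close(con))
  for (id in names(sim$sequences)) {
    s <- sim$sequences[[id]]
    writeLines(c(paste0("@", id), s, "+",
                 strrep(qchar, nchar(s))), con)
  }
  if (!is.null(truth_path))
    write.table(sim$reads, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fastq_path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path.
#' @return A list with `sequences` (named character vector) and `qualities`
#'   (list of integer Phred vectors).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  quals <- as(Biostrings::PhredQuality(S4Vectors::mcols(x)$qualities),
              "IntegerList")
  ids <- sub("\\s.*$", "", names(x))
  list(sequences = stats::setNames(as.character(x), ids),
       qualities = stats::setNames(as.list(quals), ids))
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

.hit_columns <- c("query_id", "subject_id", "percent_identity",
                  "alignment_length", "mismatches", "gap_opens",
                  "q_start", "q_end", "s_start", "s_end",
                  "e_value", "bit_score")

#' Read 12-column tabular local-alignment hits
#'
#' Reads externally produced hits in the standard 12-column tabular dialect
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end 1-based inclusive with
#' `s_start > s_end` on the minus strand, e-value, bit score), applies the
#' e-value cutoff, and keeps at most one HSP (the best-scoring) per
#' query/subject pair.
#'
#' @param path Path to the tabular file.
#' @param max_evalue E-value cutoff (default `1e-50`).
#' @param max_hsps_per_subject Maximum HSPs kept per query/subject pair.
#' @return A data frame with the 12 dialect columns (`query_id` ...
#'   `bit_score`).
#' @export
read_alignment_hits <- function(path, max_evalue = 1e-50,
                                max_hsps_per_subject = 1L) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12)), .hit_columns))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("malformed tabular hit line (expected 12 fields) at line ",
         which(nf != 12L)[1])
  m <- do.call(rbind, parts)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    alignment_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    e_value = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  if (anyNA(hits$percent_identity) || anyNA(hits$q_start))
    stop("malformed tabular hit line: non-numeric field")
  hits <- hits[hits$e_value <= max_evalue, , drop = FALSE]
  if (nrow(hits) && is.finite(max_hsps_per_subject)) {
    o <- order(hits$query_id, hits$subject_id, -hits$bit_score, hits$e_value)
    hits <- hits[o, , drop = FALSE]
    key <- paste(hits$query_id, hits$subject_id, sep = "\r")
    keep <- stats::ave(seq_along(key), key, FUN = seq_along) <=
      max_hsps_per_subject
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Export a per-window profile as bedGraph
#'
#' @param profile A window-axis abundance table (see [window_profile()]).
#' @param sample_id Sample to export.
#' @param path Output path.
#' @param window_size Window size in bp.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(profile, sample_id, path, window_size = 100000L) {
  p <- profile[profile$sample == sample_id, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s", p$chrom,
                     p$bin * window_size, (p$bin + 1L) * window_size,
                     format(p$normalized, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}

#' Read per-window values from a bedGraph file
#'
#' Intervals are assigned to windows by midpoint; multiple intervals in one
#' window are averaged.
#'
#' @param path bedGraph path (0-based half-open).
#' @param window_size Window size in bp.
#' @return Data frame with `chrom`, `bin`, `value`.
#' @export
read_bedgraph_windows <- function(path, window_size = 100000L) {
  d <- read.delim(path, header = FALSE,
                  col.names = c("chrom", "start", "end", "value"))
  d$bin <- ((d$start + d$end) %/% 2) %/% window_size
  agg <- stats::aggregate(value ~ chrom + bin, data = d, FUN = mean)
  agg[order(agg$chrom, agg$bin), ]
}

#' Read a BED file of intervals
#' @param path BED path (0-based half-open).
#' @return Data frame with `chrom`, `start`, `end` (and `name` if present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  d <- data.frame(chrom = vapply(parts, `[`, "", 1),
                  start = as.integer(vapply(parts, `[`, "", 2)),
                  end = as.integer(vapply(parts, `[`, "", 3)),
                  stringsAsFactors = FALSE)
  if (all(lengths(parts) >= 4)) d$name <- vapply(parts, `[`, "", 4)
  d
}

#' Read a TE family-to-superfamily table
#' @param path TSV with columns `family`, `superfamily`.
#' @return Data frame.
#' @export
read_family_map <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("family", "superfamily") %in% names(d)))
  d
}

#' Parse a simulator GFF3 annotation back into feature tables
#'
#' Counterpart of [write_genome_files()]: returns TE and CDS data frames in
#' internal 0-based half-open coordinates.
#'
#' @param path GFF3 path.
#' @return List with `te` and `cds` data frames.
#' @export
read_annotation_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L)) stop("malformed GFF3 line")
  m <- do.call(rbind, parts)
  attr_get <- function(attrs, key) {
    ## anchor on a field boundary so e.g. "family" never matches inside
    ## "superfamily"
    pat <- sprintf("(?:^|;)%s=([^;]+)", key)
    m <- regmatches(attrs, regexec(pat, attrs))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  d <- data.frame(chrom = m[, 1], type = m[, 3],
                  start = as.integer(m[, 4]) - 1L, end = as.integer(m[, 5]),
                  strand = m[, 7], attrs = m[, 9], stringsAsFactors = FALSE)
  te <- d[d$type == "transposable_element", ]
  cds <- d[d$type == "CDS", ]
  list(
    te = data.frame(te_id = attr_get(te$attrs, "ID"),
                    family = attr_get(te$attrs, "family"),
                    superfamily = attr_get(te$attrs, "superfamily"),
                    chrom = te$chrom, start = te$start, end = te$end,
                    strand = te$strand, stringsAsFactors = FALSE),
    cds = data.frame(cds_id = attr_get(cds$attrs, "ID"), chrom = cds$chrom,
                     start = cds$start, end = cds$end, strand = cds$strand,
                     stringsAsFactors = FALSE))
}
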