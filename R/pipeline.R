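## ---------------------------------------------------------------------------
## Pipeline orchestration: declarative config, staged runner with
## machine-readable summaries, and format validation. The exported functions
## are the primary interface; inst/cli/rollcirc.R is a thin shell wrapper.
## ---------------------------------------------------------------------------

#' Default pipeline configuration
#'
#' Fully resolved configuration for the bundled desk-scale fixture: a
#' single-chromosome toy genome, a small circle population, and thresholds
#' scaled for it (reads from a toy genome use `min_read_length` 200 rather
#' than the 3000 of production data). Every run writes its resolved config
#' next to the outputs.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = "rollcirc_out",
    simulate = list(
      n_chroms = 1L, chrom_length = 120000L, te_density = 0.3,
      centromere_fraction = 0.1, centromere_multiplier = 5,
      n_circles = 40L,
      class_mix = c(TE_full = 0.35, TE_partial = 0.2, CDS = 0.2,
                    intergenic = 0.25),
      chimeric_rate = 0.05,
      length_model = list(dist = "lognormal", meanlog = log(1800),
                          sdlog = 0.35, min = 500L, max = 6000L),
      rounds_model = list(dist = "uniform", min = 2, max = 6),
      error_rate = 0.005, linear_contaminant_rate = 0.1,
      min_read_length = 200L),
    call = list(min_length = 200L, min_mean_quality = 0, min_monomer = 50L,
                identity_floor = 0.9, k = 13L, min_rounds = 1),
    annotate = list(window_size = 20000L, merge_gap = 100L,
                    cover_fraction = 0.9, full_cover_fraction = 0.95,
                    min_identity = 90, min_length = 100L),
    cluster = list(identity_threshold = 0.9),
    stats = list(alpha = 0.05, correction = "BH", basis = "count"))
}

.check_config_keys <- function(config, template = default_config(),
                               path = "") {
  extra <- setdiff(names(config), names(template))
  if (length(extra))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "))
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        nm %in% c("simulate", "call", "annotate", "cluster", "stats"))
      .check_config_keys(config[[nm]], template[[nm]], paste0(path, ".", nm))
  }
  invisible(TRUE)
}

## Merge user config over defaults (one level of stage nesting).
.resolve_config <- function(config) {
  base <- default_config(seed = if (!is.null(config$seed)) config$seed else 1L)
  .check_config_keys(config, base)
  for (nm in names(config)) {
    if (is.list(base[[nm]]) && nm %in%
        c("simulate", "call", "annotate", "cluster", "stats")) {
      for (k in names(config[[nm]])) base[[nm]][[k]] <- config[[nm]][[k]]
    } else base[[nm]] <- config[[nm]]
  }
  ## yaml round-trips named vectors as lists; restore where needed
  if (is.list(base$simulate$class_mix))
    base$simulate$class_mix <- unlist(base$simulate$class_mix)
  base
}

.stage_simulate <- function(cfg) {
  p <- cfg$simulate
  dir.create(file.path(cfg$outdir, "sim"), showWarnings = FALSE,
             recursive = TRUE)
  genome <- generate_genome(
    n_chroms = p$n_chroms, chrom_length = p$chrom_length,
    te_density = p$te_density, centromere_fraction = p$centromere_fraction,
    centromere_multiplier = p$centromere_multiplier,
    seed = derive_seed(cfg$seed, 101L))
  circ <- simulate_circles(
    genome, n = p$n_circles, class_mix = p$class_mix,
    length_model = p$length_model, chimeric_rate = p$chimeric_rate,
    seed = derive_seed(cfg$seed, 202L))
  reads <- simulate_rca_reads(
    circ, rounds_model = p$rounds_model, error_rate = p$error_rate,
    linear_contaminant_rate = p$linear_contaminant_rate,
    min_read_length = p$min_read_length, genome = genome,
    seed = derive_seed(cfg$seed, 303L))
  sim_dir <- file.path(cfg$outdir, "sim")
  write_genome_files(genome, sim_dir)
  write_reads_fastq(reads, file.path(sim_dir, "reads.fastq"),
                    truth_path = file.path(sim_dir, "truth_reads.tsv"))
  write.table(circ$circles, file.path(sim_dir, "truth_circles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(circ$intervals, file.path(sim_dir, "truth_intervals.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(reads_emitted = sum(!reads$reads$dropped),
       reads_dropped = sum(reads$reads$dropped),
       circles = nrow(circ$circles))
}

.stage_call <- function(cfg) {
  p <- cfg$call
  sim_dir <- file.path(cfg$outdir, "sim")
  res <- call_circular(file.path(sim_dir, "reads.fastq"),
                       min_length = p$min_length,
                       min_mean_quality = p$min_mean_quality,
                       min_monomer = p$min_monomer,
                       identity_floor = p$identity_floor,
                       k = p$k, min_rounds = p$min_rounds)
  call_dir <- file.path(cfg$outdir, "call")
  dir.create(call_dir, showWarnings = FALSE, recursive = TRUE)
  if (length(res$sequences))
    write_fasta(res$sequences, file.path(call_dir, "monomers.fasta"))
  write.table(res$calls, file.path(call_dir, "calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$rejection_log, file.path(call_dir, "rejection_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  res$summary
}

.stage_annotate <- function(cfg) {
  p <- cfg$annotate
  sim_dir <- file.path(cfg$outdir, "sim")
  call_dir <- file.path(cfg$outdir, "call")
  genome_seqs <- read_fasta(file.path(sim_dir, "genome.fa"))
  feats <- read_annotation_gff3(file.path(sim_dir, "annotation.gff3"))
  family_map <- read_family_map(file.path(sim_dir, "te_families.tsv"))
  genome <- structure(list(sequences = genome_seqs, te = feats$te,
                           cds = feats$cds), class = "sim_genome")
  dbs <- extract_feature_dbs(genome)
  monomers <- read_fasta(file.path(call_dir, "monomers.fasta"))
  ann <- annotate_monomers(monomers, genome_seqs, dbs$te, dbs$cds,
                           dbs$te_families, family_map,
                           window_size = p$window_size,
                           merge_gap = p$merge_gap,
                           cover_fraction = p$cover_fraction,
                           full_cover_fraction = p$full_cover_fraction,
                           min_identity = p$min_identity,
                           min_length = p$min_length)
  ann_dir <- file.path(cfg$outdir, "annotate")
  dir.create(ann_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(ann$annotations, file.path(ann_dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(ann$unmapped, file.path(ann_dir, "unmapped.txt"))
  as.list(ann$db_tally)
}

.stage_quantify <- function(cfg) {
  sim_dir <- file.path(cfg$outdir, "sim")
  ann <- read.delim(file.path(cfg$outdir, "annotate", "annotations.tsv"),
                    stringsAsFactors = FALSE)
  ann$sample <- "sim"
  truth <- read.delim(file.path(sim_dir, "truth_reads.tsv"),
                      stringsAsFactors = FALSE)
  calls <- read.delim(file.path(cfg$outdir, "call", "calls.tsv"),
                      stringsAsFactors = FALSE)
  manifest <- data.frame(sample_id = "sim", condition = "sim",
                         replicate = 1L,
                         total_ccs_reads = sum(!truth$dropped),
                         total_eccdna_reads = nrow(calls))
  chrom_lengths <- vapply(read_fasta(file.path(sim_dir, "genome.fa")),
                          nchar, 1L)
  wp <- window_profile(ann, manifest, chrom_lengths,
                       window_size = cfg$annotate$window_size)
  ta <- te_abundance(ann, manifest, axis = "superfamily")
  q_dir <- file.path(cfg$outdir, "quantify")
  dir.create(q_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(wp, file.path(q_dir, "window_profile.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ta, file.path(q_dir, "te_abundance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(manifest, file.path(q_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(windows = nrow(wp), te_groups = length(unique(ta$group)))
}

.stage_cluster <- function(cfg) {
  monomers <- read_fasta(file.path(cfg$outdir, "call", "monomers.fasta"))
  res <- cluster_monomers(monomers,
                          identity_threshold = cfg$cluster$identity_threshold)
  cl_dir <- file.path(cfg$outdir, "cluster")
  dir.create(cl_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(res$clusters, file.path(cl_dir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$members, file.path(cl_dir, "members.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(monomers[res$clusters$representative_id],
              file.path(cl_dir, "nonredundant.fasta"))
  ann <- read.delim(file.path(cfg$outdir, "annotate", "annotations.tsv"),
                    stringsAsFactors = FALSE)
  st <- cluster_stats(res, ann)
  st
}

.stage_stats <- function(cfg) {
  sim_dir <- file.path(cfg$outdir, "sim")
  feats <- read_annotation_gff3(file.path(sim_dir, "annotation.gff3"))
  ann <- read.delim(file.path(cfg$outdir, "annotate", "annotations.tsv"),
                    stringsAsFactors = FALSE)
  comp <- genomic_composition(feats$te)
  te_ann <- ann[ann$origin_class == "TE", , drop = FALSE]
  st_dir <- file.path(cfg$outdir, "stats")
  dir.create(st_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(te_eccdna = nrow(te_ann))
  if (nrow(te_ann)) {
    obs <- table(factor(te_ann$te_superfamily,
                        levels = comp$superfamily$group))
    enr <- enrichment_test(stats::setNames(as.integer(obs), names(obs)),
                           n_total = nrow(te_ann),
                           composition = comp$superfamily,
                           basis = cfg$stats$basis,
                           alpha = cfg$stats$alpha,
                           correction = cfg$stats$correction)
    write.table(enr, file.path(st_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cen <- read_bed(file.path(sim_dir, "centromeres.bed"))
    part <- centromeric_partition(te_ann, feats$te, cen,
                                  alpha = cfg$stats$alpha)
    write.table(part$partition,
                file.path(st_dir, "centromeric_partition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$enrichment_groups <- nrow(enr)
  }
  out
}

#' Run one pipeline stage (or all of them)
#'
#' Stages run in dependency order; each writes its artifacts under the
#' configured output directory plus an entry in `run_summary.json` (counts,
#' parameters, wall time). The fully resolved configuration is written next
#' to the outputs. All randomness derives from the single master seed.
#'
#' @param name One of `"simulate"`, `"call"`, `"annotate"`, `"quantify"`,
#'   `"cluster"`, `"stats"`, `"all"`.
#' @param config Partial configuration list (merged over
#'   [default_config()]) or a path to a YAML file.
#' @return Invisibly, the list of stage summaries.
#' @export
run_subcommand <- function(name = c("all", "simulate", "call", "annotate",
                                    "quantify", "cluster", "stats"),
                           config = list()) {
  name <- match.arg(name)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- .resolve_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(cfg$outdir, "resolved_config.yaml"))

  stages <- if (name == "all")
    c("simulate", "call", "annotate", "quantify", "cluster", "stats")
  else name
  summaries <- list()
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    res <- switch(st,
      simulate = .stage_simulate(cfg),
      call = .stage_call(cfg),
      annotate = .stage_annotate(cfg),
      quantify = .stage_quantify(cfg),
      cluster = .stage_cluster(cfg),
      stats = .stage_stats(cfg))
    summaries[[st]] <- list(counts = res,
                            wall_time_s = proc.time()[["elapsed"]] - t0)
  }
  if (name == "all") {
    cs <- summaries$call$counts
    stopifnot(cs$total == cs$filtered_out + cs$aperiodic +
                cs$consensus_rejected + cs$below_min_rounds + cs$circular)
  }
  jsonlite::write_json(summaries,
                       file.path(cfg$outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summaries)
}

#' Run the full pipeline
#'
#' Convenience wrapper for `run_subcommand("all", config)`.
#' @inheritParams run_subcommand
#' @return Invisibly, the list of stage summaries.
#' @export
run_pipeline <- function(config = list()) run_subcommand("all", config)

.validate_fasta <- function(path) {
  lines <- readLines(path)
  bad <- list()
  if (!length(lines) || !startsWith(lines[1], ">"))
    bad[[1]] <- c(1L, "FASTA must start with a header line")
  seqline <- !startsWith(lines, ">")
  viol <- which(seqline & grepl("[^ACGTNacgtn]", lines))
  for (v in viol) bad[[length(bad) + 1L]] <- c(v, "invalid sequence characters")
  bad
}

.validate_fastq <- function(path) {
  lines <- readLines(path)
  bad <- list()
  if (length(lines) %% 4L != 0L)
    bad[[1]] <- c(length(lines), "FASTQ line count not a multiple of 4")
  n <- length(lines) %/% 4L
  for (i in seq_len(n)) {
    h <- lines[4L * i - 3L]; s <- lines[4L * i - 2L]
    pl <- lines[4L * i - 1L]; q <- lines[4L * i]
    if (!startsWith(h, "@"))
      bad[[length(bad) + 1L]] <- c(4L * i - 3L, "header must start with @")
    if (!startsWith(pl, "+"))
      bad[[length(bad) + 1L]] <- c(4L * i - 1L, "separator must start with +")
    if (nchar(s) != nchar(q))
      bad[[length(bad) + 1L]] <- c(4L * i, "sequence/quality length mismatch")
  }
  bad
}

.validate_gff3 <- function(path) {
  lines <- readLines(path)
  bad <- list()
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], "#") || !nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      bad[[length(bad) + 1L]] <- c(i, "expected 9 tab-separated fields")
      next
    }
    st <- suppressWarnings(as.integer(f[4])); en <- suppressWarnings(as.integer(f[5]))
    if (is.na(st) || is.na(en) || st < 1L)
      bad[[length(bad) + 1L]] <- c(i, "start must be a 1-based integer")
    else if (en < st)
      bad[[length(bad) + 1L]] <- c(i, "end < start")
  }
  bad
}

.validate_bed <- function(path) {
  lines <- readLines(path)
  bad <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      bad[[length(bad) + 1L]] <- c(i, "expected >= 3 fields"); next
    }
    st <- suppressWarnings(as.integer(f[2])); en <- suppressWarnings(as.integer(f[3]))
    if (is.na(st) || is.na(en) || st < 0L || en <= st)
      bad[[length(bad) + 1L]] <- c(i, "invalid half-open interval")
  }
  bad
}

.validate_hits <- function(path) {
  lines <- readLines(path)
  bad <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i]) || startsWith(lines[i], "#")) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 12L) {
      bad[[length(bad) + 1L]] <- c(i, "expected 12 fields"); next
    }
    num <- suppressWarnings(as.numeric(f[3:12]))
    if (anyNA(num))
      bad[[length(bad) + 1L]] <- c(i, "non-numeric value in numeric field")
  }
  bad
}

#' Validate standard-format files
#'
#' Report-only well-formedness checks for FASTA, FASTQ, GFF3 (1-based
#' inclusive, end >= start), BED (0-based half-open) and 12-column tabular
#' alignment files. The format is taken from the names of `paths`
#' (`fasta`, `fastq`, `gff3`, `bed`, `hits`) or guessed from the extension.
#'
#' @param paths Character vector of paths, optionally named by format.
#' @return Data frame `path`, `line`, `message`; zero rows when everything
#'   is well-formed.
#' @export
validate_formats <- function(paths) {
  guess <- function(p) {
    switch(tolower(sub(".*\\.", "", p)),
           fa = , fasta = "fasta", fq = , fastq = "fastq",
           gff = , gff3 = "gff3", bed = "bed", "hits")
  }
  fmts <- if (!is.null(names(paths)) && all(nzchar(names(paths))))
    names(paths) else vapply(paths, guess, "")
  rows <- list()
  for (i in seq_along(paths)) {
    v <- switch(fmts[i],
                fasta = .validate_fasta(paths[i]),
                fastq = .validate_fastq(paths[i]),
                gff3 = .validate_gff3(paths[i]),
                bed = .validate_bed(paths[i]),
                hits = .validate_hits(paths[i]),
                stop("unknown format: ", fmts[i]))
    for (b in v)
      rows[[length(rows) + 1L]] <- data.frame(
        path = unname(paths[i]), line = as.integer(b[1]), message = b[2],
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(path = character(0), line = integer(0),
                      message = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
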