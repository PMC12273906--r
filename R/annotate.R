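## ---------------------------------------------------------------------------
## Annotation layer: map monomers to genome / TE / CDS databases, classify
## origin, TE completeness, single-event status and chromosome window.
## ---------------------------------------------------------------------------

.empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             percent_identity = numeric(0), alignment_length = integer(0),
             mismatches = integer(0), gap_opens = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             e_value = numeric(0), bit_score = numeric(0),
             stringsAsFactors = FALSE)
}

.gap_opens <- function(a_aln, b_aln) {
  n <- 0L
  for (s in c(a_aln, b_aln)) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]] == "-")
    n <- n + sum(r$values)
  }
  n
}

#' Map monomer sequences to a reference database
#'
#' Built-in exact-k-mer-seeded banded local aligner for desk-scale data.
#' Shared k-mers between query and database propose diagonal clusters; each
#' cluster is verified by a banded alignment and reported as one hit in the
#' 12-column tabular dialect (1-based inclusive coordinates,
#' `s_start > s_end` encoding the minus strand). Hits are filtered on
#' `percent_identity >= min_identity` and `alignment_length >= min_length`,
#' which act as the significance surrogate for this aligner; `e_value` is
#' reported as 0 and `bit_score` is the raw alignment score. Externally
#' produced tabular hits go through [read_alignment_hits()] instead, where
#' the e-value cutoff is applied verbatim; both backends return the same
#' contract.
#'
#' @param queries,database Named character vectors of DNA sequences, or
#'   FASTA paths.
#' @param k Seed k-mer size (default 13).
#' @param stride Query seed sampling stride (default 5).
#' @param min_identity Minimum percent identity (default 90).
#' @param min_length Minimum alignment length in bp (default 100).
#' @param diag_gap Seeds within this diagonal distance join one cluster.
#' @param max_kmer_hits Seed k-mers occurring more often than this in the
#'   database are skipped as repetitive.
#' @param circular Treat queries as circular monomers: each query is doubled
#'   before seeding so a locus split by the rotation phase is recovered as
#'   one contiguous alignment, and query coordinates are reported modulo the
#'   monomer length (a hit spanning the junction may have
#'   `q_end > query length`).
#' @return A data frame of alignment hits (12-column dialect).
#' @export
map_sequences <- function(queries, database, k = 13L, stride = 5L,
                          min_identity = 90, min_length = 100L,
                          diag_gap = 100L, max_kmer_hits = 100L,
                          circular = FALSE) {
  if (is.character(queries) && length(queries) == 1L && file.exists(queries))
    queries <- read_fasta(queries)
  if (is.character(database) && length(database) == 1L && file.exists(database))
    database <- read_fasta(database)
  if (!length(queries) || !length(database))
    stop("queries and database must be non-empty")

  sep <- strrep("N", k)
  db_concat <- paste(database, collapse = sep)
  db_len <- nchar(database)
  offsets <- cumsum(c(0L, head(db_len + k, -1L)))  # 0-based subject starts
  names(offsets) <- names(database)
  sub_of <- function(spos) findInterval(spos, offsets + 1L)

  nc <- nchar(db_concat)
  db_starts <- seq_len(nc - k + 1L)
  db_kmers <- substring(db_concat, db_starts, db_starts + k - 1L)
  ok <- !grepl("N", db_kmers, fixed = TRUE)
  idx <- list2env(split(db_starts[ok], db_kmers[ok]), hash = TRUE)

  hits <- list()
  for (qid in names(queries)) {
    nq0 <- nchar(queries[[qid]])
    for (strand in c("+", "-")) {
      q <- if (strand == "+") queries[[qid]] else revcomp(queries[[qid]])
      if (circular) q <- paste0(q, q)
      nq <- nchar(q)
      if (nq < k) next
      qstarts <- seq.int(1L, nq - k + 1L, by = stride)
      qk <- substring(q, qstarts, qstarts + k - 1L)
      pos <- mget(qk, envir = idx, ifnotfound = list(NULL))
      nhit <- lengths(pos)
      use <- nhit > 0L & nhit <= max_kmer_hits
      if (!any(use)) next
      qpos <- rep(qstarts[use], nhit[use])
      spos <- unlist(pos[use], use.names = FALSE)
      subj <- sub_of(spos)
      diag <- spos - qpos
      o <- order(subj, diag, qpos)
      subj <- subj[o]; diag <- diag[o]; qpos <- qpos[o]; spos <- spos[o]
      newgrp <- c(TRUE, diff(subj) != 0L | diff(diag) > diag_gap)
      grp <- cumsum(newgrp)
      for (g in unique(grp)) {
        sel <- grp == g
        if (sum(sel) < 2L) next
        sj <- subj[sel][1]
        sname <- names(database)[sj]
        off <- offsets[[sname]]
        qlo <- min(qpos[sel]); qhi <- max(qpos[sel]) + k - 1L
        slo <- min(spos[sel]) - off; shi <- max(spos[sel]) + k - 1L - off
        if (qhi - qlo + 1L < min_length * 0.5) next
        pad <- 50L
        qa <- max(1L, qlo - pad); qb <- min(nq, qhi + pad)
        sa <- max(1L, slo - pad); sb <- min(db_len[[sname]], shi + pad)
        spread <- diff(range(diag[sel]))
        res <- tryCatch(
          align_banded(substr(q, qa, qb), substr(database[[sname]], sa, sb),
                       band = spread + 80L, mode = "overlap"),
          error = function(e) NULL)
        if (is.null(res) || res$alen < min_length) next
        pid <- 100 * res$nmatch / res$alen
        if (pid < min_identity) next
        qs <- qa + res$p_start - 1L; qe <- qa + res$p_end - 1L
        ss <- sa + res$s_start - 1L; se <- sa + res$s_end - 1L
        if (strand == "-") {
          tmp_qs <- nq - qe + 1L; qe <- nq - qs + 1L; qs <- tmp_qs
          tmp <- ss; ss <- se; se <- tmp
        }
        if (circular && qs > nq0) { qs <- qs - nq0; qe <- qe - nq0 }
        hits[[length(hits) + 1L]] <- data.frame(
          query_id = qid, subject_id = sname,
          percent_identity = round(pid, 3),
          alignment_length = res$alen,
          mismatches = res$nmismatch,
          gap_opens = .gap_opens(res$a_aln, res$b_aln),
          q_start = qs, q_end = qe, s_start = ss, s_end = se,
          e_value = 0, bit_score = res$score, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(.empty_hits())
  out <- do.call(rbind, hits)
  if (circular) {
    ## doubling can report the same locus twice; keep the best-scoring copy
    o <- order(-out$bit_score)
    out <- out[o, , drop = FALSE]
    key <- paste(out$query_id, out$subject_id, out$q_start, out$q_end,
                 out$s_start, out$s_end)
    out <- out[!duplicated(key), , drop = FALSE]
    ## drop hits fully contained (on both query and subject) in a better one
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      j <- which(keep & seq_len(nrow(out)) > i &
                 out$query_id == out$query_id[i] &
                 out$subject_id == out$subject_id[i] &
                 out$q_start >= out$q_start[i] & out$q_end <= out$q_end[i] &
                 pmin(out$s_start, out$s_end) >=
                   min(out$s_start[i], out$s_end[i]) &
                 pmax(out$s_start, out$s_end) <=
                   max(out$s_start[i], out$s_end[i]))
      keep[j] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$query_id, out$subject_id, out$q_start), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

## Project query intervals of circular-mode hits back onto [1, L]; a hit
## spanning the rotation junction contributes two intervals.
.wrap_q_intervals <- function(q_start, q_end, L) {
  starts <- integer(0); ends <- integer(0)
  for (i in seq_along(q_start)) {
    if (q_end[i] <= L) {
      starts <- c(starts, q_start[i]); ends <- c(ends, q_end[i])
    } else {
      starts <- c(starts, q_start[i], 1L)
      ends <- c(ends, L, min(L, q_end[i] - L))
    }
  }
  IRanges::IRanges(start = starts, end = ends)
}

#' Best hit for one query
#'
#' Deterministic per-query hit selection: highest bit score, then lowest
#' e-value, then longest alignment, then lexicographically smallest
#' `(subject_id, min(s_start, s_end))`.
#'
#' @param hits Data frame of hits for a single query.
#' @return The selected single-row data frame.
#' @export
best_hit <- function(hits) {
  stopifnot(nrow(hits) >= 1L)
  smin <- pmin(hits$s_start, hits$s_end)
  o <- order(-hits$bit_score, hits$e_value, -hits$alignment_length,
             hits$subject_id, smin)
  hits[o[1], , drop = FALSE]
}

#' Classify TE completeness of an eccDNA monomer
#'
#' `partial` when the monomer is shorter than its source TE; `full` when
#' the monomer is at least as long as the TE *and* the alignments cover at
#' least `cover_fraction` of the TE, a guard ensuring that a long eccDNA
#' merely longer than an unrelated TE is not called full.
#'
#' @param monomer_length,te_length,te_coverage Lengths in bp;
#'   `te_coverage <= te_length`.
#' @param cover_fraction Coverage guard for a full call (default 0.95).
#' @return `"full"` or `"partial"`.
#' @export
classify_te_completeness <- function(monomer_length, te_length, te_coverage,
                                     cover_fraction = 0.95) {
  stopifnot(monomer_length > 0, te_length > 0, te_coverage >= 0,
            te_coverage <= te_length)
  if (monomer_length < te_length) return("partial")
  if (te_coverage >= cover_fraction * te_length) "full" else "partial"
}

#' Classify origin of one monomer from per-database hits
#'
#' Priority rule TE > CDS > intergenic: a monomer with any retained
#' TE-database hit is TE-derived; otherwise a CDS hit makes it CDS; a
#' genome-only monomer is intergenic. The TE label is taken from the best
#' TE hit and joined to the family/superfamily table.
#'
#' @param te_hits,cds_hits Hits of this monomer against the TE and CDS
#'   databases (possibly empty).
#' @param family_map Data frame `family`, `superfamily`.
#' @param te_families Named character vector mapping `te_id` to family.
#' @return List with `origin_class`, `te_id`, `te_family`, `te_superfamily`.
#' @export
classify_origin <- function(te_hits, cds_hits, family_map, te_families) {
  if (nrow(te_hits)) {
    bh <- best_hit(te_hits)
    te_id <- bh$subject_id
    fam <- if (te_id %in% names(te_families)) te_families[[te_id]]
           else NA_character_
    sf <- if (!is.na(fam) && fam %in% family_map$family)
      family_map$superfamily[match(fam, family_map$family)] else {
        if (!is.na(fam)) warning("family ", fam, " missing from family table")
        "unclassified"
      }
    list(origin_class = "TE", te_id = te_id,
         te_family = if (is.na(fam)) "unclassified" else fam,
         te_superfamily = sf)
  } else if (nrow(cds_hits)) {
    list(origin_class = "CDS", te_id = NA_character_,
         te_family = NA_character_, te_superfamily = NA_character_)
  } else {
    list(origin_class = "intergenic", te_id = NA_character_,
         te_family = NA_character_, te_superfamily = NA_character_)
  }
}

#' Single-event classification from genome hits
#'
#' Hits on the same chromosome and strand whose subject intervals lie
#' within `merge_gap` are merged into loci; the monomer is a single event
#' iff one merged locus covers at least `cover_fraction` of the monomer
#' length (rotation phase splits a continuous circle into two adjacent
#' hits, which the merge re-joins; a chimeric circle's loci stay separate).
#'
#' @param hits Genome hits of one monomer.
#' @param monomer_length Monomer length in bp.
#' @param merge_gap Maximum genomic gap merged (default 100).
#' @param cover_fraction Required monomer coverage (default 0.9).
#' @return Logical flag.
#' @export
classify_single_event <- function(hits, monomer_length, merge_gap = 100L,
                                  cover_fraction = 0.9) {
  stopifnot(nrow(hits) >= 1L)
  strand <- ifelse(hits$s_start <= hits$s_end, "+", "-")
  smin <- pmin(hits$s_start, hits$s_end)
  smax <- pmax(hits$s_start, hits$s_end)
  key <- paste(hits$subject_id, strand)
  for (kk in unique(key)) {
    sel <- key == kk
    ir <- IRanges::IRanges(start = smin[sel], end = smax[sel])
    red <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
    grp <- IRanges::findOverlaps(ir, red, select = "first")
    for (g in unique(grp)) {
      qir <- .wrap_q_intervals(hits$q_start[sel][grp == g],
                               hits$q_end[sel][grp == g], monomer_length)
      cov <- sum(IRanges::width(IRanges::reduce(qir)))
      if (cov >= cover_fraction * monomer_length) return(TRUE)
    }
  }
  FALSE
}

#' Assign a genome window to a locus
#'
#' Windows are half-open `[i * window_size, (i+1) * window_size)` bins; the
#' locus is assigned by the midpoint of its best hit.
#'
#' @param chrom Chromosome name.
#' @param s_start,s_end 1-based inclusive subject coordinates (either
#'   orientation).
#' @param window_size Window size in bp (default 100,000).
#' @param chrom_lengths Named vector of chromosome lengths (for bounds
#'   checking; optional).
#' @return List with `chrom` and `bin` (0-based window index).
#' @export
assign_window <- function(chrom, s_start, s_end, window_size = 100000L,
                          chrom_lengths = NULL) {
  stopifnot(window_size > 0)
  lo <- min(s_start, s_end); hi <- max(s_start, s_end)
  if (!is.null(chrom_lengths)) {
    if (!chrom %in% names(chrom_lengths)) stop("unknown chromosome: ", chrom)
    if (lo < 1L || hi > chrom_lengths[[chrom]])
      stop("locus outside chromosome bounds: ", chrom, ":", lo, "-", hi)
  }
  mid0 <- ((lo - 1L) + hi) %/% 2L      # 0-based midpoint
  list(chrom = chrom, bin = as.integer(mid0 %/% window_size))
}

#' Extract TE and CDS sequence databases from a simulated genome
#'
#' @param genome A `sim_genome`.
#' @return List with `te` and `cds` named character vectors (strand-aware
#'   feature sequences keyed by feature id) and `te_families` (te_id ->
#'   family).
#' @export
extract_feature_dbs <- function(genome) {
  te <- stats::setNames(vapply(seq_len(nrow(genome$te)), function(i)
    genome_fetch(genome, genome$te$chrom[i], genome$te$start[i],
                 genome$te$end[i], genome$te$strand[i]), ""),
    genome$te$te_id)
  cds <- stats::setNames(vapply(seq_len(nrow(genome$cds)), function(i)
    genome_fetch(genome, genome$cds$chrom[i], genome$cds$start[i],
                 genome$cds$end[i], genome$cds$strand[i]), ""),
    genome$cds$cds_id)
  list(te = te, cds = cds,
       te_families = stats::setNames(genome$te$family, genome$te$te_id))
}

#' Annotate monomers against genome, TE and CDS databases
#'
#' Maps every monomer to the three databases with the built-in aligner (or
#' consumes precomputed hits), then derives the per-monomer annotation:
#' best genomic locus, window assignment, exclusive origin class under the
#' TE > CDS > intergenic priority, TE identity/family/superfamily,
#' full/partial completeness, and the single-event flag. Monomers without
#' any genome hit are reported in the unmapped set. Per-database
#' (overlapping) tallies are returned alongside the exclusive classes.
#'
#' @param monomers Named character vector of monomer sequences.
#' @param genome_seqs Named character vector of chromosome sequences.
#' @param te_db,cds_db Named character vectors of TE / CDS sequences.
#' @param te_families Named character vector, te_id -> family.
#' @param family_map Data frame `family`, `superfamily`.
#' @param window_size Window size in bp.
#' @param merge_gap,cover_fraction Single-event parameters.
#' @param full_cover_fraction Coverage guard for full-TE calls.
#' @param min_identity,min_length Aligner retention thresholds.
#' @param hits Optional precomputed hits: list with elements `genome`,
#'   `te`, `cds` (12-column data frames), bypassing the built-in aligner.
#' @return List with `annotations` (one row per mapped monomer), `unmapped`
#'   (ids), and `db_tally` (per-database overlapping monomer counts).
#' @export
annotate_monomers <- function(monomers, genome_seqs, te_db, cds_db,
                              te_families, family_map,
                              window_size = 100000L,
                              merge_gap = 100L, cover_fraction = 0.9,
                              full_cover_fraction = 0.95,
                              min_identity = 90, min_length = 100L,
                              hits = NULL) {
  if (is.null(hits)) {
    hits <- list(
      genome = map_sequences(monomers, genome_seqs,
                             min_identity = min_identity,
                             min_length = min_length, circular = TRUE),
      te = if (length(te_db)) map_sequences(monomers, te_db,
                                            min_identity = min_identity,
                                            min_length = min_length,
                                            circular = TRUE)
           else .empty_hits(),
      cds = if (length(cds_db)) map_sequences(monomers, cds_db,
                                              min_identity = min_identity,
                                              min_length = min_length,
                                              circular = TRUE)
            else .empty_hits())
  }
  chrom_lengths <- vapply(genome_seqs, nchar, 1L)
  rows <- list(); unmapped <- character(0)
  for (mid in names(monomers)) {
    gh <- hits$genome[hits$genome$query_id == mid, , drop = FALSE]
    if (!nrow(gh)) { unmapped <- c(unmapped, mid); next }
    th <- hits$te[hits$te$query_id == mid, , drop = FALSE]
    ch <- hits$cds[hits$cds$query_id == mid, , drop = FALSE]
    bg <- best_hit(gh)
    orig <- classify_origin(th, ch, family_map, te_families)
    mlen <- nchar(monomers[[mid]])
    completeness <- "none"
    if (orig$origin_class == "TE") {
      th_best <- th[th$subject_id == orig$te_id, , drop = FALSE]
      te_len <- max(pmax(th_best$s_start, th_best$s_end))
      te_len <- nchar_or(te_db, orig$te_id, te_len)
      cov <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(
        start = pmin(th_best$s_start, th_best$s_end),
        end = pmax(th_best$s_start, th_best$s_end)))))
      cov <- min(cov, te_len)
      completeness <- classify_te_completeness(
        mlen, te_len, cov, cover_fraction = full_cover_fraction)
    }
    win <- assign_window(bg$subject_id, bg$s_start, bg$s_end,
                         window_size, chrom_lengths)
    rows[[length(rows) + 1L]] <- data.frame(
      monomer_id = mid, chrom = bg$subject_id,
      start = min(bg$s_start, bg$s_end) - 1L,
      end = max(bg$s_start, bg$s_end),
      strand = if (bg$s_start <= bg$s_end) "+" else "-",
      window = win$bin,
      origin_class = orig$origin_class, te_id = orig$te_id,
      te_family = orig$te_family, te_superfamily = orig$te_superfamily,
      te_completeness = completeness,
      single_event = classify_single_event(gh, mlen, merge_gap,
                                           cover_fraction),
      stringsAsFactors = FALSE)
  }
  ann <- if (length(rows)) do.call(rbind, rows) else NULL
  db_tally <- c(
    genome = length(unique(hits$genome$query_id)),
    te = length(unique(hits$te$query_id)),
    cds = length(unique(hits$cds$query_id)),
    unmapped = length(unmapped))
  list(annotations = ann, unmapped = unmapped, db_tally = db_tally,
       hits = hits)
}

## Safe length lookup in a sequence db.
nchar_or <- function(db, id, fallback) {
  if (!is.null(db) && id %in% names(db)) nchar(db[[id]]) else fallback
}
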