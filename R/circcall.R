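## ---------------------------------------------------------------------------
## Circularity caller: tandem-period detection in concatemer reads, rounds
## estimation, majority-vote monomer consensus, canonical circular form.
## ---------------------------------------------------------------------------

#' Filter reads by length and mean base quality
#'
#' Length/quality gate applied before period detection, standing in for the
#' accuracy and insert-length filters applied upstream of circular consensus
#' read extraction. A read passes iff its length is at least `min_length`
#' and its mean Phred quality is at least `min_mean_quality` (reads with no
#' quality information pass the quality gate).
#'
#' @param reads A list with `sequences` (named character vector) and
#'   optionally `qualities` (list of integer Phred vectors), as returned by
#'   [read_fastq()], or a path to a FASTQ file.
#' @param min_length Minimum read length in bases (default 3000).
#' @param min_mean_quality Minimum mean Phred quality (default 30).
#' @return A list with `passed` (same shape as `reads`) and `log`
#'   (data frame `read_id`, `reason` for each rejected read).
#' @export
filter_reads <- function(reads, min_length = 3000L, min_mean_quality = 30) {
  stopifnot(min_length >= 0, min_mean_quality >= 0)
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  seqs <- reads$sequences
  quals <- reads$qualities
  lens <- nchar(seqs)
  meanq <- if (!is.null(quals))
    vapply(names(seqs), function(id) {
      q <- quals[[id]]
      if (is.null(q) || !length(q)) Inf else mean(q)
    }, 0) else rep(Inf, length(seqs))
  reason <- ifelse(lens < min_length, "below_min_length",
                   ifelse(meanq < min_mean_quality, "below_min_quality", ""))
  keep <- reason == ""
  list(passed = list(sequences = seqs[keep],
                     qualities = if (!is.null(quals)) quals[names(seqs)[keep]]),
       log = data.frame(read_id = names(seqs)[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE))
}

.aperiodic <- function(reason) {
  structure(list(periodic = FALSE, reason = reason,
                 period = NA_integer_, rounds = NA_real_,
                 identity = NA_real_, support = 0L),
            class = "period_estimate")
}

#' @export
print.period_estimate <- function(x, ...) {
  if (x$periodic)
    cat(sprintf("period %d bp, %.3f rounds, identity %.3f (support %d)\n",
                x$period, x$rounds, x$identity, x$support))
  else cat("aperiodic:", x$reason, "\n")
  invisible(x)
}

## Refine a candidate period by pinning the second occurrence of the read
## prefix with a pattern-global alignment; returns NULL when the prefix does
## not recur near the candidate spacing.
.refine_once <- function(read, p, min_monomer, identity_floor) {
  L <- nchar(read)
  A <- min(400L, p)
  delta <- min(80L, max(20L, p %/% 10L))
  ws <- max(min_monomer + 1L, p - delta + 1L)
  we <- min(L, p + A + delta)
  if (we - ws + 1L < A) return(NULL)
  res <- tryCatch(
    align_banded(substr(read, 1L, A), substr(read, ws, we),
                 band = delta + 40L, mode = "glocal"),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  if (res$identity < identity_floor) return(NULL)
  spacing <- ws + res$s_start - 2L
  if (spacing < min_monomer || spacing > L %/% 2L) return(NULL)
  spacing
}

## Iterated to a fixed point: when the candidate is off, the first window can
## clip the repeated prefix and bias the detected spacing by a few bases;
## re-centering the window on the detected spacing converges in one or two
## steps.
.refine_period <- function(read, p, min_monomer, identity_floor) {
  sp <- .refine_once(read, p, min_monomer, identity_floor)
  for (i in 1:3) {
    if (is.null(sp) || identical(sp, p)) break
    p <- sp
    sp <- .refine_once(read, p, min_monomer, identity_floor)
  }
  sp
}

## Band half-width for segment-vs-template alignments: indel drift over a
## read is a random walk, so the band grows with the square root of read
## length (sized for ~1% error with a 20% indel share, with generous slack).
.drift_band <- function(L) max(60L, as.integer(8 * sqrt(0.01 * L)) + 20L)

## Mean identity between the first period-length segment and up to
## `max_support` later full segments.
.verify_segments <- function(read, p, identity_floor, max_support = 3L) {
  L <- nchar(read)
  nseg <- L %/% p
  if (nseg < 2L) return(NULL)
  idx <- unique(c(2L, if (nseg >= 4L) (nseg + 2L) %/% 2L, nseg))
  idx <- head(idx[idx >= 2L & idx <= nseg], max_support)
  template <- substr(read, 1L, p)
  band <- .drift_band(L)
  ids <- vapply(idx, function(i) {
    seg <- substr(read, (i - 1L) * p + 1L, i * p)
    res <- align_banded(seg, template, band = band, mode = "overlap")
    if (res$alen < 0.5 * p) return(0)
    res$nmatch / res$alen
  }, 0)
  list(identity = mean(ids), support = length(ids),
       ok = mean(ids) >= identity_floor)
}

#' Estimate the tandem period of a concatemer read
#'
#' Proposes candidate periods from the distance spectrum of repeated k-mer
#' anchors (for short reads, by exhaustive scan), refines each candidate by
#' pinning the recurrence of the read prefix with a banded alignment, and
#' verifies it by aligning later period-length segments to the first. The
#' smallest verifying period is returned: when a candidate `p` verifies, its
#' integer fractions `p/2, p/3, ...` down to `min_monomer` are tested first
#' so that a doubled monomer is never reported. Homopolymer and
#' microsatellite pseudo-periods fall below `min_monomer` and are never
#' proposed, so such reads come back aperiodic.
#'
#' @param read A DNA string.
#' @param min_monomer Smallest admissible monomer length (default 50).
#' @param identity_floor Minimum mean identity between period-length
#'   segments (default 0.9).
#' @param k Anchor k-mer size for candidate proposal (default 13).
#' @return A `period_estimate`: `periodic`, `period` (bp), `rounds`
#'   (read length / period), `identity`, `support`; or an aperiodic result
#'   with a reason.
#' @export
estimate_period <- function(read, min_monomer = 50L, identity_floor = 0.9,
                            k = 13L) {
  L <- nchar(read)
  if (L < 2L * min_monomer) return(.aperiodic("read shorter than two monomers"))
  pmax_ <- L %/% 2L

  try_candidate <- function(p) {
    sp <- .refine_period(read, p, min_monomer, identity_floor)
    if (is.null(sp)) return(NULL)
    v <- .verify_segments(read, sp, identity_floor)
    if (is.null(v) || !v$ok) return(NULL)
    structure(list(periodic = TRUE, reason = "",
                   period = as.integer(sp), rounds = L / sp,
                   identity = v$identity, support = v$support),
              class = "period_estimate")
  }

  if (L <= 600L) {
    seen <- integer(0)
    for (p in seq.int(min_monomer, pmax_)) {
      sp <- .refine_period(read, p, min_monomer, identity_floor)
      if (is.null(sp) || sp %in% seen) next
      seen <- c(seen, sp)
      v <- .verify_segments(read, sp, identity_floor)
      if (!is.null(v) && v$ok)
        return(structure(list(periodic = TRUE, reason = "",
                              period = as.integer(sp), rounds = L / sp,
                              identity = v$identity, support = v$support),
                         class = "period_estimate"))
    }
    return(.aperiodic("no verifying period"))
  }

  kp <- kmer_positions(read, k)
  if (!length(kp)) return(.aperiodic("no repeated k-mer anchors"))
  diffs <- unlist(lapply(kp, diff), use.names = FALSE)
  diffs <- diffs[diffs >= min_monomer & diffs <= pmax_]
  if (!length(diffs)) return(.aperiodic("no candidate period in range"))
  tab <- sort(table(diffs), decreasing = TRUE)
  cand <- as.integer(names(tab))[seq_len(min(8L, length(tab)))]

  tried <- integer(0)
  for (d in cand) {
    subs <- unique(as.integer(round(d / seq_len(max(1L, d %/% min_monomer)))))
    subs <- sort(subs[subs >= min_monomer & subs <= pmax_])
    for (p in subs) {
      if (any(abs(tried - p) <= 2L)) next
      tried <- c(tried, p)
      est <- try_candidate(p)
      if (!is.null(est)) return(est)
    }
  }
  .aperiodic("no verifying period")
}

## Encoding used by the consensus voter.
.base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L, "-" = 6L)
.code_base <- names(.base_code)

#' Deconcatenate a read into its monomer consensus
#'
#' Slices the read into successive period-length segments, aligns each later
#' segment (and the fractional trailing segment) to the first, and emits a
#' per-column majority-vote consensus. A column's tie is broken by the
#' highest base quality supporting a candidate base, then by the first
#' segment's base. Insertions relative to the first segment are included
#' when a plurality of covering segments agree on the same inserted string,
#' which restores bases deleted from the template copy by sequencing error.
#'
#' @param read A DNA string.
#' @param est A periodic `period_estimate` for this read.
#' @param qualities Optional integer Phred vector, one per read base.
#' @param identity_floor A full segment failing this identity against the
#'   first segment rejects the whole call.
#' @return A list (`monomer_call`) with `sequence`, `length`, `rounds`,
#'   `canonical_sequence`, `identity`, `n_segments`; or `NULL` with a
#'   warning when a segment fails the identity floor.
#' @export
deconcatenate <- function(read, est, qualities = NULL, identity_floor = 0.9) {
  stopifnot(inherits(est, "period_estimate"), est$periodic, est$rounds > 1)
  p <- est$period
  L <- nchar(read)
  nseg <- L %/% p
  frac_len <- L - nseg * p
  template <- substr(read, 1L, p)
  if (is.null(qualities)) qualities <- rep(30L, L)
  band <- .drift_band(L)

  segs <- list()
  for (i in seq_len(nseg - 1L) + 1L)
    segs[[length(segs) + 1L]] <-
      list(seq = substr(read, (i - 1L) * p + 1L, i * p),
           offset = (i - 1L) * p, fractional = FALSE)
  if (frac_len >= max(30L, as.integer(0.02 * p)))
    segs[[length(segs) + 1L]] <-
      list(seq = substr(read, nseg * p + 1L, L),
           offset = nseg * p, fractional = TRUE)

  nvote <- length(segs) + 1L
  M <- matrix(NA_integer_, nrow = p, ncol = nvote)
  Q <- matrix(NA_integer_, nrow = p, ncol = nvote)
  tch <- strsplit(template, "", fixed = TRUE)[[1]]
  M[, 1] <- .base_code[tch]
  Q[, 1] <- qualities[seq_len(p)]
  inserts <- list()
  idents <- numeric(0)

  for (si in seq_along(segs)) {
    sg <- segs[[si]]
    subj <- if (sg$fractional)
      substr(template, 1L, min(p, nchar(sg$seq) + band)) else template
    res <- align_banded(sg$seq, subj, band = band, mode = "overlap")
    idn <- if (res$alen > 0) res$nmatch / res$alen else 0
    if (!sg$fractional) {
      if (idn < identity_floor || res$alen < 0.5 * p) {
        warning("segment ", si + 1L, " failed the identity floor; call rejected")
        return(NULL)
      }
      idents <- c(idents, idn)
    } else if (idn < identity_floor) next
    a <- strsplit(res$a_aln, "", fixed = TRUE)[[1]]
    b <- strsplit(res$b_aln, "", fixed = TRUE)[[1]]
    bng <- b != "-"
    tpos <- res$s_start - 1L + cumsum(bng)
    ang <- a != "-"
    ppos <- res$p_start - 1L + cumsum(ang)
    rpos <- sg$offset + ppos
    ## column votes where the template consumed a base
    sel <- which(bng)
    M[tpos[sel], si + 1L] <- .base_code[a[sel]]
    Q[tpos[sel], si + 1L] <- ifelse(ang[sel], qualities[rpos[sel]], 0L)
    ## insertion votes at junctions (template gap columns)
    gsel <- which(!bng)
    if (length(gsel)) {
      r <- rle(diff(c(-10L, gsel)) == 1L)
      grp <- cumsum(c(TRUE, diff(gsel) != 1L))
      for (g in unique(grp)) {
        cols <- gsel[grp == g]
        j <- tpos[cols[1]]            # insert goes after template position j
        ins <- paste(a[cols], collapse = "")
        inserts[[length(inserts) + 1L]] <-
          data.frame(seg = si + 1L, junction = j, insert = ins,
                     stringsAsFactors = FALSE)
      }
    }
  }

  ## majority vote per template column
  counts <- sapply(1:6, function(kk) rowSums(M == kk, na.rm = TRUE))
  maxn <- apply(counts, 1L, max)
  winner <- max.col(counts, ties.method = "first")
  nties <- rowSums(counts == maxn)
  for (i in which(nties > 1L)) {
    tied <- which(counts[i, ] == maxn[i])
    qbest <- vapply(tied, function(cc) {
      sel <- which(M[i, ] == cc)
      if (!length(sel)) -1L else max(Q[i, sel], na.rm = TRUE)
    }, 0L)
    top <- tied[qbest == max(qbest)]
    winner[i] <- if (M[i, 1] %in% top) M[i, 1] else min(top)
  }

  ## insertion plurality at junctions
  ins_after <- character(p + 1L)       # index j+1 = insert after position j
  if (length(inserts)) {
    idf <- do.call(rbind, inserts)
    for (j in unique(idf$junction)) {
      if (j < 1L || j >= p) next
      covering <- which(!is.na(M[j, ]) & !is.na(M[min(j + 1L, p), ]))
      props <- idf$insert[idf$junction == j]
      voted <- idf$seg[idf$junction == j]
      blanks <- setdiff(covering, voted)
      tab <- table(c(props, rep("", length(blanks))))
      best <- max(tab)
      cands <- names(tab)[tab == best]
      pick <- if ("" %in% cands) "" else sort(cands)[1]
      if (nzchar(pick) && best > length(c(props, blanks)) / 2)
        ins_after[j + 1L] <- pick
    }
  }

  pieces <- ifelse(winner == 6L, "", .code_base[winner])
  pieces <- paste0(pieces, ins_after[-1L])
  consensus <- paste0(ins_after[1L], paste(pieces, collapse = ""))
  list(sequence = consensus, length = nchar(consensus),
       rounds = est$rounds,
       canonical_sequence = canonicalize(consensus),
       identity = if (length(idents)) mean(idents) else est$identity,
       n_segments = nseg)
}

#' Canonical form of a circular sequence
#'
#' Returns the lexicographically least string among all rotations of the
#' sequence and all rotations of its reverse complement, computed with a
#' linear-time least-rotation algorithm. Two reads of the same circle, at
#' any rotation phase and on either strand, share one canonical form; the
#' function is idempotent.
#'
#' @param seq A non-empty DNA string over \{A,C,G,T,N\}.
#' @return The canonical string.
#' @export
#' @examples
#' canonicalize("GAT")  # "ATC"
canonicalize <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  if (grepl("[^ACGTN]", seq)) stop("sequence must use alphabet {A,C,G,T,N}")
  rc <- revcomp(seq)
  fwd <- rotate_seq(seq, .cpp_least_rotation(seq))
  rev <- rotate_seq(rc, .cpp_least_rotation(rc))
  if (fwd <= rev) fwd else rev
}

#' Call circular monomers from a set of reads
#'
#' Full caller: read filtering, period estimation, deconcatenation, and
#' retention of calls evidencing circularity (`rounds > min_rounds`,
#' strictly). Reads that show no verified tandem structure are reported as
#' aperiodic; counts are conserved across all categories.
#'
#' @param reads As for [filter_reads()].
#' @param min_length,min_mean_quality Read filter thresholds.
#' @param min_monomer,identity_floor,k Period-detection parameters, see
#'   [estimate_period()].
#' @param min_rounds Calls are retained iff estimated rounds exceed this
#'   value strictly (default 1).
#' @return A list with `calls` (data frame: `monomer_id`, `source_read_id`,
#'   `length`, `rounds`, `period`, `identity`), `sequences` and `canonical`
#'   (named character vectors keyed by monomer id), `rejection_log`, and a
#'   `summary` list (`total`, `filtered_out`, `aperiodic`,
#'   `consensus_rejected`, `below_min_rounds`, `circular`).
#' @export
call_circular <- function(reads, min_length = 3000L, min_mean_quality = 30,
                          min_monomer = 50L, identity_floor = 0.9,
                          k = 13L, min_rounds = 1) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  total <- length(reads$sequences)
  flt <- filter_reads(reads, min_length, min_mean_quality)
  seqs <- flt$passed$sequences
  quals <- flt$passed$qualities

  calls <- list(); cseqs <- character(0); ccanon <- character(0)
  n_aper <- 0L; n_rejcons <- 0L; n_lowrounds <- 0L
  logs <- list(list(read_id = flt$log$read_id, reason = flt$log$reason))
  for (id in names(seqs)) {
    est <- estimate_period(seqs[[id]], min_monomer = min_monomer,
                           identity_floor = identity_floor, k = k)
    if (!est$periodic) {
      n_aper <- n_aper + 1L
      logs[[length(logs) + 1L]] <- list(read_id = id,
                                        reason = paste0("aperiodic:", est$reason))
      next
    }
    if (est$rounds <= min_rounds) {
      n_lowrounds <- n_lowrounds + 1L
      logs[[length(logs) + 1L]] <- list(read_id = id, reason = "rounds_not_above_min")
      next
    }
    call <- withCallingHandlers(
      deconcatenate(seqs[[id]], est, qualities = quals[[id]],
                    identity_floor = identity_floor),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(call)) {
      n_rejcons <- n_rejcons + 1L
      logs[[length(logs) + 1L]] <- list(read_id = id, reason = "consensus_rejected")
      next
    }
    mid <- sprintf("monomer_%s", id)
    calls[[length(calls) + 1L]] <- data.frame(
      monomer_id = mid, source_read_id = id, length = call$length,
      rounds = call$rounds, period = est$period, identity = call$identity,
      stringsAsFactors = FALSE)
    cseqs[mid] <- call$sequence
    ccanon[mid] <- call$canonical_sequence
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(monomer_id = character(0), source_read_id = character(0),
               length = integer(0), rounds = numeric(0), period = integer(0),
               identity = numeric(0), stringsAsFactors = FALSE)
  log_df <- data.frame(
    read_id = unlist(lapply(logs, `[[`, "read_id")),
    reason = unlist(lapply(logs, `[[`, "reason")), stringsAsFactors = FALSE)
  list(calls = calls, sequences = cseqs, canonical = ccanon,
       rejection_log = log_df,
       summary = list(total = total, filtered_out = nrow(flt$log),
                      aperiodic = n_aper, consensus_rejected = n_rejcons,
                      below_min_rounds = n_lowrounds,
                      circular = nrow(calls)))
}
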