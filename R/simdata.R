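## ---------------------------------------------------------------------------
## Synthetic-data module: toy genome with planted TE/CDS annotation, circle
## populations, and rolling-circle concatemer reads with truth tables.
## Internal coordinates are 0-based half-open throughout.
## ---------------------------------------------------------------------------

.default_superfamilies <- c("RC/Helitron", "LTR/Copia", "LTR/Gypsy",
                            "DNA/MuDR", "DNA/En-Spm", "LINE/L1")

.default_superfamily_weights <- c(
  "RC/Helitron" = 0.35, "LTR/Gypsy" = 0.20, "LTR/Copia" = 0.12,
  "DNA/MuDR" = 0.12, "DNA/En-Spm" = 0.11, "LINE/L1" = 0.10)

## Consensus length range (bp) per superfamily; full-length copies are planted.
.superfamily_length_ranges <- list(
  "RC/Helitron" = c(500, 2500),  "LTR/Copia" = c(3000, 5500),
  "LTR/Gypsy"  = c(3500, 6000),  "DNA/MuDR" = c(1500, 4000),
  "DNA/En-Spm" = c(2500, 4500),  "LINE/L1"  = c(1500, 3500))

.mutate_subs <- function(seq, rate) {
  n <- nchar(seq)
  pos <- which(runif(n) < rate)
  if (!length(pos)) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
  paste(ch, collapse = "")
}

#' Generate a toy genome with planted TE and CDS annotation
#'
#' Builds one or more random chromosomes, marks a single centromere interval
#' per chromosome, and plants full-length transposable-element copies as
#' mutated descendants of per-family consensus sequences, with a configurable
#' placement bias toward the centromere. CDS intervals are placed in the
#' remaining space. The genome stands in for a real assembly plus its TE/CDS
#' annotation so the downstream stages can be exercised at desk scale.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp (>= 50,000).
#' @param te_density Target fraction of each chromosome covered by TEs,
#'   in (0, 0.9).
#' @param superfamily_weights Named numeric vector of sampling weights over
#'   the TE superfamily vocabulary; must sum to 1 (tolerance 1e-9).
#' @param centromere_fraction Fraction of each chromosome assigned to the
#'   (single, central) centromere interval.
#' @param centromere_multiplier TE placement probability inside the
#'   centromere is this multiple of the outside rate.
#' @param families_per_superfamily Number of distinct families per
#'   superfamily.
#' @param divergence Per-base substitution rate applied to each planted copy
#'   relative to its family consensus.
#' @param cds_density Target CDS fraction per chromosome.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return An object of class `sim_genome`: a list with `sequences` (named
#'   character vector), `te` / `cds` / `centromeres` data frames (0-based
#'   half-open coordinates), and `family_map` (family, superfamily).
#' @export
generate_genome <- function(n_chroms = 2L, chrom_length = 200000L,
                            te_density = 0.3,
                            superfamily_weights = .default_superfamily_weights,
                            centromere_fraction = 0.1,
                            centromere_multiplier = 5,
                            families_per_superfamily = 2L,
                            divergence = 0.08,
                            cds_density = 0.15,
                            seed = 1L) {
  stopifnot(chrom_length >= 50000, te_density > 0, te_density < 0.9,
            centromere_fraction > 0, centromere_fraction < 0.5)
  if (abs(sum(superfamily_weights) - 1) > 1e-9)
    stop("superfamily_weights must sum to 1")
  sfs <- names(superfamily_weights)
  bad <- setdiff(sfs, .default_superfamilies)
  if (length(bad)) stop("unknown superfamilies: ", paste(bad, collapse = ", "))
  set.seed(seed)

  ## family consensus sequences
  fam_rows <- list(); consensus <- list()
  for (sf in sfs) {
    rng <- .superfamily_length_ranges[[sf]]
    short <- gsub("[^A-Za-z0-9]", "", sf)
    for (i in seq_len(families_per_superfamily)) {
      fam <- sprintf("%s_fam%d", short, i)
      len <- as.integer(round(runif(1, rng[1], rng[2])))
      consensus[[fam]] <- random_dna(len)
      fam_rows[[fam]] <- data.frame(family = fam, superfamily = sf,
                                    stringsAsFactors = FALSE)
    }
  }
  family_map <- do.call(rbind, fam_rows)
  rownames(family_map) <- NULL

  chroms <- sprintf("chr%d", seq_len(n_chroms))
  cen_len <- as.integer(round(centromere_fraction * chrom_length))
  cen_start <- as.integer((chrom_length - cen_len) %/% 2)
  longest_te <- max(vapply(consensus, nchar, 1L))
  if (chrom_length < cen_len + longest_te + 1000)
    stop("chromosome too short to host the centromere plus one TE copy")
  cf <- centromere_fraction
  p_cen <- (centromere_multiplier * cf) /
    (centromere_multiplier * cf + (1 - cf))

  seqs <- character(0); te_list <- list(); cds_list <- list(); cen_list <- list()
  te_counter <- 0L; cds_counter <- 0L
  for (ch in chroms) {
    cen <- c(cen_start, cen_start + cen_len)
    occupied <- matrix(numeric(0), ncol = 2)
    target_bp <- te_density * chrom_length
    placed_bp <- 0; tries <- 0L
    while (placed_bp < target_bp && tries < 20000L) {
      tries <- tries + 1L
      fam_sf <- sample(sfs, 1L, prob = superfamily_weights)
      fams <- family_map$family[family_map$superfamily == fam_sf]
      fam <- if (length(fams) == 1L) fams else sample(fams, 1L)
      len <- nchar(consensus[[fam]])
      inside <- runif(1) < p_cen
      if (inside && cen_len > len) {
        start <- as.integer(floor(runif(1, cen[1], cen[2] - len)))
      } else {
        repeat {
          start <- as.integer(floor(runif(1, 0, chrom_length - len)))
          mid <- start + len / 2
          if (mid < cen[1] || mid >= cen[2]) break
        }
      }
      end <- start + len
      if (nrow(occupied) &&
          any(overlap_bp(occupied[, 1], occupied[, 2], start, end) > 0))
        next
      occupied <- rbind(occupied, c(start, end))
      te_counter <- te_counter + 1L
      te_list[[te_counter]] <- data.frame(
        te_id = sprintf("TE%05d", te_counter), family = fam,
        superfamily = fam_sf, chrom = ch, start = start, end = end,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      placed_bp <- placed_bp + len
    }
    ## CDS intervals in remaining space
    cds_bp <- 0; tries <- 0L
    while (cds_bp < cds_density * chrom_length && tries < 20000L) {
      tries <- tries + 1L
      len <- as.integer(round(runif(1, 300, 3000)))
      start <- as.integer(floor(runif(1, 0, chrom_length - len)))
      end <- start + len
      if (any(overlap_bp(occupied[, 1], occupied[, 2], start, end) > 0)) next
      occupied <- rbind(occupied, c(start, end))
      cds_counter <- cds_counter + 1L
      cds_list[[cds_counter]] <- data.frame(
        cds_id = sprintf("CDS%05d", cds_counter), chrom = ch,
        start = start, end = end, strand = sample(c("+", "-"), 1L),
        stringsAsFactors = FALSE)
      cds_bp <- cds_bp + len
    }
    cen_list[[ch]] <- data.frame(chrom = ch, start = cen[1], end = cen[2],
                                 stringsAsFactors = FALSE)
    ## assemble sequence: background + planted (mutated) copies
    ch_seq <- random_dna(chrom_length)
    te_here <- do.call(rbind, te_list)
    te_here <- te_here[te_here$chrom == ch, , drop = FALSE]
    if (nrow(te_here)) {
      for (r in seq_len(nrow(te_here))) {
        copy <- .mutate_subs(consensus[[te_here$family[r]]], divergence)
        if (te_here$strand[r] == "-") copy <- revcomp(copy)
        substr(ch_seq, te_here$start[r] + 1L, te_here$end[r]) <- copy
      }
    }
    seqs[[ch]] <- ch_seq
  }

  te <- do.call(rbind, te_list); rownames(te) <- NULL
  cds <- do.call(rbind, cds_list); rownames(cds) <- NULL
  structure(list(sequences = seqs, te = te, cds = cds,
                 centromeres = do.call(rbind, cen_list),
                 family_map = family_map,
                 params = list(seed = seed, te_density = te_density,
                               centromere_fraction = centromere_fraction,
                               centromere_multiplier = centromere_multiplier,
                               divergence = divergence)),
            class = "sim_genome")
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d chromosome(s), %d TE copies, %d CDS features\n",
              length(x$sequences), nrow(x$te), nrow(x$cds)))
  invisible(x)
}

## Fetch a genomic substring (0-based half-open), optionally minus strand.
genome_fetch <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome$sequences[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s) else s
}

.draw_length <- function(model, n = 1L) {
  if (is.numeric(model)) return(rep(as.integer(model), n))
  out <- integer(0)
  while (length(out) < n) {
    x <- switch(model$dist,
      lognormal = rlnorm(n, meanlog = model$meanlog, sdlog = model$sdlog),
      uniform = runif(n, model$min, model$max),
      constant = rep(model$value, n),
      stop("unknown length model: ", model$dist))
    x <- as.integer(round(x))
    x <- x[x >= model$min & x <= model$max]
    out <- c(out, x)
  }
  out[seq_len(n)]
}

#' Default circle length model
#'
#' Truncated lognormal chosen so that the simulated population matches the
#' scale reported for plant leaf eccDNA: median about 3,350 nt, mean about
#' 3,680 nt, range 0.5--22.4 kb. `meanlog = log(3347)` sets the median;
#' `sdlog = 0.436` then sets the mean, since for a lognormal
#' mean = median * exp(sdlog^2 / 2).
#'
#' @return A length-model list understood by [simulate_circles()].
#' @export
default_length_model <- function() {
  list(dist = "lognormal", meanlog = log(3347), sdlog = 0.436,
       min = 500L, max = 22431L)
}

#' Simulate an eccDNA circle population from a toy genome
#'
#' Draws circles of the requested origin classes: `TE_full` (circle fully
#' contains a planted TE copy, plus flanks), `TE_partial` (circle is a
#' sub-interval of a TE, hence shorter than the element), `CDS` (overlaps a
#' CDS feature), `intergenic` (avoids TE and CDS), plus a configurable
#' minority of chimeric circles joining two distant loci. Each circle's
#' sequence is the concatenation of its origin intervals' genomic sequence
#' (reverse-complemented for minus strand).
#'
#' @param genome A `sim_genome`.
#' @param n Number of circles.
#' @param class_mix Named weights over `TE_full`, `TE_partial`, `CDS`,
#'   `intergenic`.
#' @param length_model See [default_length_model()].
#' @param chimeric_rate Fraction of circles built from two distant loci.
#' @param min_length Minimum circle length (bp).
#' @param seed Integer seed.
#' @return A `sim_circles` object: list with `circles` (truth data frame),
#'   `intervals` (origin intervals, 0-based half-open) and `sequences`
#'   (named character vector).
#' @export
simulate_circles <- function(genome, n,
                             class_mix = c(TE_full = 0.30, TE_partial = 0.25,
                                           CDS = 0.20, intergenic = 0.25),
                             length_model = default_length_model(),
                             chimeric_rate = 0.05,
                             min_length = 500L,
                             seed = 1L) {
  stopifnot(inherits(genome, "sim_genome"), n >= 1)
  bad <- setdiff(names(class_mix), c("TE_full", "TE_partial", "CDS", "intergenic"))
  if (length(bad)) stop("unknown classes in class_mix: ", paste(bad, collapse = ", "))
  for (cls in names(class_mix)[class_mix > 0]) {
    if (cls %in% c("TE_full", "TE_partial") && nrow(genome$te) == 0)
      stop("genome has no TE features but class_mix requests ", cls)
    if (cls == "CDS" && nrow(genome$cds) == 0)
      stop("genome has no CDS features but class_mix requests CDS")
  }
  set.seed(seed)
  chroms <- names(genome$sequences)
  chrom_len <- vapply(genome$sequences, nchar, 1L)
  occ <- rbind(genome$te[, c("chrom", "start", "end")],
               stats::setNames(genome$cds[, c("chrom", "start", "end")],
                               c("chrom", "start", "end")))

  circles <- vector("list", n); ivals <- vector("list", n); seqs <- character(n)
  for (i in seq_len(n)) {
    cls <- sample(names(class_mix), 1L, prob = class_mix)
    chim <- runif(1) < chimeric_rate
    L <- max(min_length, .draw_length(length_model))
    if (chim) {
      ## two distant loci, concatenated
      parts <- list()
      l1 <- max(250L, as.integer(L %/% 2)); l2 <- max(250L, L - l1)
      for (l in c(l1, l2)) {
        ch <- sample(chroms, 1L)
        st <- as.integer(floor(runif(1, 0, chrom_len[[ch]] - l)))
        parts[[length(parts) + 1L]] <-
          data.frame(chrom = ch, start = st, end = st + l,
                     strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      }
      ## enforce non-adjacency: same chrom and gap < 10 kb -> push apart
      if (parts[[1]]$chrom == parts[[2]]$chrom &&
          abs(parts[[1]]$start - parts[[2]]$start) < 10000) {
        parts[[2]]$chrom <- sample(chroms, 1L)
        parts[[2]]$start <- as.integer(
          floor(runif(1, 0, chrom_len[[parts[[2]]$chrom]] - l2)))
        parts[[2]]$end <- parts[[2]]$start + l2
      }
      seq <- paste0(
        genome_fetch(genome, parts[[1]]$chrom, parts[[1]]$start,
                     parts[[1]]$end, parts[[1]]$strand),
        genome_fetch(genome, parts[[2]]$chrom, parts[[2]]$start,
                     parts[[2]]$end, parts[[2]]$strand))
      iv <- rbind(parts[[1]], parts[[2]]); iv$ord <- 1:2
      cls_out <- "chimeric"; src_te <- NA_character_
    } else if (cls == "TE_full") {
      ## flanks must not run into other TE or CDS features, so the truth
      ## label (this TE, and only this TE) stays exclusive
      st <- NA; Lc <- NA; te <- NULL
      for (attempt in seq_len(300L)) {
        te <- genome$te[sample(nrow(genome$te), 1L), ]
        te_len <- te$end - te$start
        Lc_try <- if (attempt <= 150L) max(L, te_len + 40L) else te_len + 40L
        flank <- Lc_try - te_len
        fl <- as.integer(floor(runif(1, 0, flank + 1)))
        st_try <- max(0L, te$start - fl)
        en_try <- min(chrom_len[[te$chrom]], st_try + Lc_try)
        st_try <- max(0L, en_try - Lc_try)
        occ_ch <- occ[occ$chrom == te$chrom, , drop = FALSE]
        other <- !(occ_ch$start == te$start & occ_ch$end == te$end)
        if (!any(overlap_bp(occ_ch$start[other], occ_ch$end[other],
                            st_try, en_try) > 0)) {
          st <- st_try; Lc <- en_try - st_try; break
        }
      }
      if (is.na(st)) stop("could not place a TE_full circle without ",
                          "running into neighbouring features")
      strand <- sample(c("+", "-"), 1L)
      seq <- genome_fetch(genome, te$chrom, st, st + Lc, strand)
      iv <- data.frame(chrom = te$chrom, start = st, end = st + Lc,
                       strand = strand, ord = 1L, stringsAsFactors = FALSE)
      cls_out <- "TE_full"; src_te <- te$te_id
    } else if (cls == "TE_partial") {
      cand <- genome$te[genome$te$end - genome$te$start > min_length + 1L, ]
      if (!nrow(cand)) stop("no TE long enough for a TE_partial circle")
      te <- cand[sample(nrow(cand), 1L), ]
      te_len <- te$end - te$start
      Lp <- max(min_length, min(L, te_len - 1L))
      st <- te$start + as.integer(floor(runif(1, 0, te_len - Lp)))
      strand <- sample(c("+", "-"), 1L)
      seq <- genome_fetch(genome, te$chrom, st, st + Lp, strand)
      iv <- data.frame(chrom = te$chrom, start = st, end = st + Lp,
                       strand = strand, ord = 1L, stringsAsFactors = FALSE)
      cls_out <- "TE_partial"; src_te <- te$te_id
    } else if (cls == "CDS") {
      ## the circle must overlap a CDS but stay clear of TE copies, so the
      ## CDS truth label cannot be pre-empted by the TE priority rule
      st <- NA; Lg <- L; cd <- NULL
      for (attempt in seq_len(300L)) {
        cd <- genome$cds[sample(nrow(genome$cds), 1L), ]
        mid <- (cd$start + cd$end) %/% 2
        st_try <- max(0L, as.integer(mid - Lg %/% 2))
        en_try <- min(chrom_len[[cd$chrom]], st_try + Lg)
        st_try <- max(0L, en_try - Lg)
        te_ch <- genome$te[genome$te$chrom == cd$chrom, , drop = FALSE]
        if (!nrow(te_ch) ||
            all(overlap_bp(te_ch$start, te_ch$end, st_try, en_try) == 0)) {
          st <- st_try; break
        }
        if (attempt %% 75L == 0L) Lg <- max(min_length, as.integer(Lg %/% 2L))
      }
      if (is.na(st)) stop("could not place a CDS circle clear of TE copies")
      en <- min(chrom_len[[cd$chrom]], st + Lg)
      strand <- sample(c("+", "-"), 1L)
      seq <- genome_fetch(genome, cd$chrom, st, en, strand)
      iv <- data.frame(chrom = cd$chrom, start = st, end = en,
                       strand = strand, ord = 1L, stringsAsFactors = FALSE)
      cls_out <- "CDS"; src_te <- NA_character_
    } else {
      ## intergenic: avoid any TE/CDS overlap; shrink on repeated failure
      Lg <- L; st <- NA
      for (attempt in seq_len(400L)) {
        ch <- sample(chroms, 1L)
        cand_st <- as.integer(floor(runif(1, 0, chrom_len[[ch]] - Lg)))
        occ_ch <- occ[occ$chrom == ch, , drop = FALSE]
        if (!nrow(occ_ch) ||
            all(overlap_bp(occ_ch$start, occ_ch$end, cand_st, cand_st + Lg) == 0)) {
          st <- cand_st; break
        }
        if (attempt %% 100 == 0) Lg <- max(min_length, as.integer(Lg %/% 2))
      }
      if (is.na(st)) stop("could not place an intergenic circle; genome too dense")
      strand <- sample(c("+", "-"), 1L)
      seq <- genome_fetch(genome, ch, st, st + Lg, strand)
      iv <- data.frame(chrom = ch, start = st, end = st + Lg,
                       strand = strand, ord = 1L, stringsAsFactors = FALSE)
      cls_out <- "intergenic"; src_te <- NA_character_
    }
    id <- sprintf("circle%05d", i)
    iv$circle_id <- id
    circles[[i]] <- data.frame(
      circle_id = id, origin_class = cls_out, length = nchar(seq),
      source_te_id = src_te, n_intervals = nrow(iv), stringsAsFactors = FALSE)
    ivals[[i]] <- iv
    seqs[i] <- seq; names(seqs)[i] <- id
  }
  structure(list(circles = do.call(rbind, circles),
                 intervals = do.call(rbind, ivals),
                 sequences = seqs),
            class = "sim_circles")
}

#' @export
print.sim_circles <- function(x, ...) {
  cat(sprintf("sim_circles: %d circles, classes: %s\n", nrow(x$circles),
              paste(names(table(x$circles$origin_class)), collapse = ", ")))
  invisible(x)
}

.apply_errors <- function(seq, error_rate, err_mix) {
  if (error_rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  hit <- which(runif(n) < error_rate)
  if (!length(hit)) return(seq)
  bases <- c("A", "C", "G", "T")
  types <- sample(names(err_mix), length(hit), replace = TRUE, prob = err_mix)
  out <- ch
  for (k in seq_along(hit)) {
    p <- hit[k]
    out[p] <- switch(types[k],
      sub = sample(setdiff(bases, ch[p]), 1L),
      ins = paste0(ch[p], sample(bases, 1L)),
      del = "")
  }
  paste(out, collapse = "")
}

#' Simulate rolling-circle concatemer reads
#'
#' Each circular read is the circle sequence rotated by a uniform random
#' offset and tandemly repeated `rounds` times (fractional last repeat), then
#' corrupted by i.i.d. substitutions/insertions/deletions. Linear contaminant
#' reads are genomic fragments carrying no repeat structure
#' (`true_rounds = 1`). Reads shorter than `min_read_length` are dropped and
#' logged, mirroring the read-length filter applied to circular consensus
#' sequencing data.
#'
#' @param circles A `sim_circles` object.
#' @param rounds_model List, e.g. `list(dist = "uniform", min = 2, max = 8)`
#'   or `list(dist = "constant", value = 3)`; support must include values
#'   >= 2.
#' @param error_rate Per-base error rate in `[0, 0.05]`.
#' @param err_mix Relative weights of substitution / insertion / deletion
#'   errors (default 8:1:1, substitution-dominated as in high-accuracy
#'   consensus reads).
#' @param linear_contaminant_rate Fraction of emitted reads that are linear
#'   genome fragments.
#' @param min_read_length Reads shorter than this are dropped (default 3000,
#'   the standard insert-length filter; small fixtures use 200).
#' @param genome `sim_genome`, required when `linear_contaminant_rate > 0`.
#' @param seed Integer seed.
#' @return A `sim_reads` object: list with `reads` (truth table including
#'   dropped reads), `sequences` (kept reads) and `quality_phred` (flat
#'   per-base quality implied by `error_rate`).
#' @export
simulate_rca_reads <- function(circles,
                               rounds_model = list(dist = "uniform",
                                                   min = 2, max = 8),
                               error_rate = 0.01,
                               err_mix = c(sub = 0.8, ins = 0.1, del = 0.1),
                               linear_contaminant_rate = 0,
                               min_read_length = 3000L,
                               genome = NULL,
                               seed = 1L) {
  stopifnot(inherits(circles, "sim_circles"))
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]")
  if (linear_contaminant_rate < 0 || linear_contaminant_rate >= 1)
    stop("linear_contaminant_rate must lie in [0, 1)")
  if (linear_contaminant_rate > 0 && is.null(genome))
    stop("genome is required to draw linear contaminant reads")
  draw_rounds <- function() {
    switch(rounds_model$dist,
      uniform = runif(1, rounds_model$min, rounds_model$max),
      constant = rounds_model$value,
      stop("unknown rounds model: ", rounds_model$dist))
  }
  set.seed(seed)
  n_circ <- nrow(circles$circles)
  n_lin <- if (linear_contaminant_rate > 0)
    as.integer(round(linear_contaminant_rate * n_circ /
                       (1 - linear_contaminant_rate))) else 0L

  recs <- vector("list", n_circ + n_lin); seqs <- character(n_circ + n_lin)
  for (i in seq_len(n_circ)) {
    cid <- circles$circles$circle_id[i]
    cl <- nchar(circles$sequences[[cid]])
    r <- draw_rounds()
    off <- as.integer(floor(runif(1, 0, cl)))
    rot <- rotate_seq(circles$sequences[[cid]], off)
    full <- as.integer(floor(r))
    frac_len <- as.integer(round((r - full) * cl))
    read <- paste0(strrep(rot, full), substr(rot, 1L, frac_len))
    true_rounds <- (full * cl + frac_len) / cl
    read <- .apply_errors(read, error_rate, err_mix)
    recs[[i]] <- data.frame(
      read_id = sprintf("read%05d", i), circle_id = cid,
      true_rounds = true_rounds, rotation_offset = off,
      is_linear = FALSE, length = nchar(read), stringsAsFactors = FALSE)
    seqs[i] <- read
  }
  if (n_lin > 0) {
    chrom_len <- vapply(genome$sequences, nchar, 1L)
    for (j in seq_len(n_lin)) {
      i <- n_circ + j
      tmpl <- sample(nchar(circles$sequences), 1L)
      fl <- min(as.integer(round(tmpl * draw_rounds())),
                max(chrom_len) - 1L)
      ch <- names(chrom_len)[sample.int(length(chrom_len), 1L,
                                        prob = chrom_len)]
      fl <- min(fl, chrom_len[[ch]] - 1L)
      st <- as.integer(floor(runif(1, 0, chrom_len[[ch]] - fl)))
      read <- genome_fetch(genome, ch, st, st + fl,
                           sample(c("+", "-"), 1L))
      read <- .apply_errors(read, error_rate, err_mix)
      recs[[i]] <- data.frame(
        read_id = sprintf("read%05d", i), circle_id = NA_character_,
        true_rounds = 1.0, rotation_offset = 0L,
        is_linear = TRUE, length = nchar(read), stringsAsFactors = FALSE)
      seqs[i] <- read
    }
  }
  reads <- do.call(rbind, recs)
  names(seqs) <- reads$read_id
  reads$dropped <- reads$length < min_read_length
  reads$drop_reason <- ifelse(reads$dropped, "below_min_read_length", "")
  if (mean(reads$dropped) > 0.5)
    warning("min_read_length excludes more than half of the simulated reads")
  q <- if (error_rate > 0)
    min(60L, max(2L, as.integer(round(-10 * log10(error_rate))))) else 60L
  structure(list(reads = reads,
                 sequences = seqs[!reads$dropped],
                 quality_phred = q),
            class = "sim_reads")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("sim_reads: %d emitted, %d dropped (Q%d)\n",
              sum(!x$reads$dropped), sum(x$reads$dropped), x$quality_phred))
  invisible(x)
}
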