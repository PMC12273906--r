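## ---------------------------------------------------------------------------
## Non-redundant eccDNA set: greedy identity clustering of canonical monomer
## sequences, and cluster-level statistics.
## ---------------------------------------------------------------------------

## Unique k-mer set of a sequence; shared k-mers between two sequences act
## as a prefilter (unrelated sequences share essentially no 13-mers, while
## >= 90% identity over >= 100 bp implies many).
.kmer_set <- function(s, k = 13L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Greedy identity clustering of monomer sequences
#'
#' Builds a non-redundant eccDNA set the way greedy incremental clustering
#' tools do: sequences are visited in order of decreasing length (ties
#' broken by id, so repeat runs are byte-identical); each sequence joins the
#' first cluster whose representative reaches `identity_threshold` identity
#' over the shorter sequence's length, else founds a new cluster. Identity
#' is computed on canonical circular forms (see [canonicalize()]) so that
#' rotation phase and strand never split a cluster; exact canonical
#' equality short-circuits the alignment.
#'
#' @param sequences Named character vector of monomer sequences (canonical
#'   or raw; canonicalization is applied internally).
#' @param identity_threshold Identity threshold in (0.5, 1]; default 0.9,
#'   the wrapped-tool default.
#' @param prefilter_kmers Minimum shared 13-mers before an alignment is
#'   attempted (default 4).
#' @return A list with `clusters` (data frame `cluster_id`,
#'   `representative_id`, `size`, `representative_length`) and `members`
#'   (data frame `cluster_id`, `monomer_id`).
#' @export
cluster_monomers <- function(sequences, identity_threshold = 0.9,
                             prefilter_kmers = 4L) {
  stopifnot(identity_threshold > 0.5, identity_threshold <= 1)
  canon <- vapply(sequences, canonicalize, "")
  ord <- order(-nchar(canon), names(canon))
  ids <- names(canon)[ord]

  rep_id <- character(0); rep_seq <- character(0); rep_kmers <- list()
  assign <- integer(length(ids)); names(assign) <- ids
  for (id in ids) {
    s <- canon[[id]]
    ks <- unique(c(.kmer_set(s), .kmer_set(revcomp(s))))
    placed <- FALSE
    for (ci in seq_along(rep_id)) {
      r <- rep_seq[[ci]]
      if (identical(s, r)) { assign[id] <- ci; placed <- TRUE; break }
      if (nchar(s) < identity_threshold * nchar(r)) next
      if (sum(ks %in% rep_kmers[[ci]]) < prefilter_kmers) next
      idn <- max(seq_identity_short(s, r),
                 seq_identity_short(revcomp(s), r))
      if (idn >= identity_threshold) { assign[id] <- ci; placed <- TRUE; break }
    }
    if (!placed) {
      rep_id <- c(rep_id, id)
      rep_seq <- c(rep_seq, s)
      rep_kmers[[length(rep_id)]] <- ks
      assign[id] <- length(rep_id)
    }
  }
  members <- data.frame(cluster_id = sprintf("cluster%05d", assign),
                        monomer_id = ids, stringsAsFactors = FALSE)
  sizes <- table(members$cluster_id)
  clusters <- data.frame(
    cluster_id = sprintf("cluster%05d", seq_along(rep_id)),
    representative_id = rep_id,
    size = as.integer(sizes[sprintf("cluster%05d", seq_along(rep_id))]),
    representative_length = nchar(rep_seq),
    stringsAsFactors = FALSE)
  list(clusters = clusters, members = members)
}

#' Cluster-level statistics
#'
#' Reports the total cluster count, the singleton fraction (clusters with a
#' single member), and -- when annotations are supplied -- the single-event
#' cluster fraction, i.e. clusters whose representative maps to one
#' continuous genomic locus. The two fractions answer different questions
#' (redundancy vs genomic continuity) and are reported separately.
#'
#' @param clustering Result of [cluster_monomers()].
#' @param annotations Optional annotation data frame with `monomer_id` and
#'   `single_event`.
#' @return A list of counts and fractions.
#' @export
cluster_stats <- function(clustering, annotations = NULL) {
  cl <- clustering$clusters
  n <- nrow(cl)
  singleton <- sum(cl$size == 1L)
  out <- list(n_clusters = n, n_members = sum(cl$size),
              singleton_count = singleton, singleton_fraction = singleton / n)
  if (!is.null(annotations)) {
    se <- annotations$single_event[match(cl$representative_id,
                                         annotations$monomer_id)]
    out$single_event_count <- sum(se, na.rm = TRUE)
    out$single_event_fraction <- sum(se, na.rm = TRUE) / sum(!is.na(se))
  }
  out
}
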