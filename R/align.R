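#' Banded pairwise alignment
#'
#' Aligns two DNA strings with a linear gap cost inside a diagonal band.
#' Three modes are supported: `"global"` (both sequences end to end),
#' `"overlap"` (terminal gaps free on both sequences; used for concatemer
#' segments whose phases drift by a few bases), and `"glocal"` (the pattern
#' is aligned end to end, the subject's flanks are free; used to pin the
#' position of a repeated prefix). The band is centred on the stretched main
#' diagonal (`"global"`/`"glocal"`) or the identity diagonal (`"overlap"`)
#' and must contain the true path; callers pick a band wide enough for the
#' expected indel drift.
#'
#' @param pattern,subject Character strings (DNA).
#' @param band Half-width of the diagonal band in bases.
#' @param mode One of `"global"`, `"overlap"`, `"glocal"`.
#' @param match,mismatch,gap Integer scores (linear gap cost).
#' @return A list with `score`, 1-based coordinates `p_start`, `p_end`,
#'   `s_start`, `s_end` of the aligned cores, gapped strings `a_aln` /
#'   `b_aln`, and counts `nmatch`, `nmismatch`, `ngap`. `identity` is
#'   `nmatch / alignment length`.
#' @export
align_banded <- function(pattern, subject, band = 50L,
                         mode = c("global", "overlap", "glocal"),
                         match = 2L, mismatch = -3L, gap = -4L) {
  mode <- match.arg(mode)
  mode_i <- c(global = 0L, overlap = 1L, glocal = 2L)[[mode]]
  res <- .cpp_banded_align(pattern, subject, as.integer(band),
                           as.integer(match), as.integer(mismatch),
                           as.integer(gap), mode_i)
  res$alen <- nchar(res$a_aln)
  res$identity <- if (res$alen > 0) res$nmatch / res$alen else 0
  res
}

## Identity of two near-collinear strings over the shorter length, via a
## banded overlap alignment; fast path for equal strings.
seq_identity_short <- function(a, b, band = NULL) {
  if (identical(a, b)) return(1)
  if (is.null(band)) band <- max(60L, abs(nchar(a) - nchar(b)) + 40L)
  res <- align_banded(a, b, band = band, mode = "overlap")
  res$nmatch / min(nchar(a), nchar(b))
}
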