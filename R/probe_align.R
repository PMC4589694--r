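#' Local alignment of two sequences
#'
#' Smith-Waterman local alignment with affine gaps (a gap run of length k
#' costs `gap_open + k * gap_extend`). IUPAC ambiguity codes in the first
#' sequence (`a`, the pattern) match by the subset rule of [iupac_match()].
#' Among equal-score alignments the one with fewer gap columns, then fewer
#' mismatches, is chosen; remaining ties resolve to the smallest pattern
#' then subject end coordinate.
#'
#' @param a Pattern sequence (probe or cluster member).
#' @param b Subject sequence.
#' @param scoring [probe_scoring()].
#' @return A one-row data frame with `score`, `identities`, `mismatches`,
#'   `gaps` (gap columns), `a_start`, `a_end`, `b_start`, `b_end` and
#'   `columns` (alignment length), or `NULL` when no positive-scoring local
#'   alignment exists.
#' @export
local_align <- function(a, b, scoring = probe_scoring()) {
  a <- toupper(a); b <- toupper(b)
  res <- .sw_local(a, b, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend)
  if (length(res) == 1) return(NULL)
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Align a TaqMan probe inside an amplicon
#'
#' Searches both strands of the amplicon for the best local alignment of the
#' probe (probes may be designed on either strand). The alignment is
#' reported only when it covers at least `scoring$min_coverage` of the probe
#' (default 50%). Strand ties break toward fewer gaps, then the plus strand.
#'
#' @param probe Probe sequence (IUPAC letters, length >= 10).
#' @param amplicon_seq Amplicon sequence.
#' @param scoring [probe_scoring()].
#' @return A one-row data frame with `probe_start`, `probe_end` (positions on
#'   the probe), `amp_start`, `amp_end` (positions on the amplicon sequence),
#'   `strand`, `identities`, `mismatches`, `gaps` and `covered_fraction`, or
#'   `NULL` when no qualifying alignment exists.
#' @export
align_probe <- function(probe, amplicon_seq, scoring = probe_scoring()) {
  probe <- toupper(probe)
  if (nchar(probe) < 10) stop("probe shorter than 10 nt")
  L <- nchar(probe)
  plus <- local_align(probe, amplicon_seq, scoring)
  minus <- local_align(revcomp(probe), amplicon_seq, scoring)
  pick <- NULL; strand <- "+"
  if (!is.null(plus)) { pick <- plus; strand <- "+" }
  if (!is.null(minus)) {
    if (is.null(pick) || minus$score > pick$score ||
        (minus$score == pick$score && minus$gaps < pick$gaps)) {
      pick <- minus; strand <- "-"
    }
  }
  if (is.null(pick)) return(NULL)
  if (strand == "-") {
    # map coordinates on the reverse-complemented probe back to the probe
    ps <- L - pick$a_end + 1L; pe <- L - pick$a_start + 1L
  } else {
    ps <- pick$a_start; pe <- pick$a_end
  }
  covered <- (pick$a_end - pick$a_start + 1L) / L
  if (covered < scoring$min_coverage) return(NULL)
  data.frame(probe_start = as.integer(ps), probe_end = as.integer(pe),
             amp_start = as.integer(pick$b_start),
             amp_end = as.integer(pick$b_end),
             strand = strand,
             identities = as.integer(pick$identities),
             mismatches = as.integer(pick$mismatches),
             gaps = as.integer(pick$gaps),
             covered_fraction = covered,
             stringsAsFactors = FALSE)
}

#' Annotate probe annealing on amplicons
#'
#' Fills the probe fields of amplicons produced by [simulate_pcr()] for one
#' method: `no_probe` when the method has no probe, `perfect` when the probe
#' aligns over its full length with zero mismatches and zero gaps,
#' `mismatched` when an alignment is found but carries edits or partial
#' coverage, and `not_found` when no alignment reaches the coverage floor.
#' Probe verification never removes an amplicon; strict filtering happens
#' downstream in [build_matrix()].
#'
#' @param amplicons Amplicon data frame (rows of one method).
#' @param method Single-row method data frame.
#' @param scoring [probe_scoring()].
#' @return The amplicon data frame with probe fields filled.
#' @export
annotate_probe <- function(amplicons, method, scoring = probe_scoring()) {
  method <- as.data.frame(method, stringsAsFactors = FALSE)
  if (nrow(amplicons) == 0) return(amplicons)
  probe <- method$probe
  if (is.null(probe) || is.na(probe) || !nzchar(probe)) {
    amplicons$probe_status <- "no_probe"
    amplicons$probe_mismatches <- 0L
    amplicons$probe_gaps <- 0L
    return(amplicons)
  }
  L <- nchar(probe)
  for (i in seq_len(nrow(amplicons))) {
    aln <- align_probe(probe, amplicons$amplicon_sequence[i], scoring)
    if (is.null(aln)) {
      amplicons$probe_status[i] <- "not_found"
      amplicons$probe_mismatches[i] <- 0L
      amplicons$probe_gaps[i] <- 0L
    } else {
      perfect <- aln$covered_fraction == 1 && aln$mismatches == 0 &&
        aln$gaps == 0
      amplicons$probe_status[i] <- if (perfect) "perfect" else "mismatched"
      amplicons$probe_mismatches[i] <- aln$mismatches
      amplicons$probe_gaps[i] <- aln$gaps
    }
  }
  amplicons
}
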