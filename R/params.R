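#' In silico PCR parameters
#'
#' Bundle the search tolerances of the in silico PCR engine. Defaults mirror
#' the e-PCR settings commonly used for GMO method screening: product size
#' window 50-500 bp, at most 2 mismatches and 2 indels per primer, and a
#' combined cap of 2 edits summed over both primers.
#'
#' @param d_min,d_max Product size window in bp (outer primer end to outer
#'   primer end, primers included).
#' @param n_max Maximum mismatches allowed per primer.
#' @param g_max Maximum indels (gap columns) allowed per primer.
#' @param total_edit_max Maximum mismatches plus indels summed over the two
#'   primers; the probe is not part of this cap.
#' @return A list of class `pcr_params`.
#' @examples
#' pcr_params()
#' pcr_params(d_min = 60, d_max = 200, n_max = 1)
#' @export
pcr_params <- function(d_min = 50, d_max = 500, n_max = 2, g_max = 2,
                       total_edit_max = 2) {
  stopifnot(length(d_min) == 1, length(d_max) == 1,
            d_min > 0, d_min <= d_max,
            n_max >= 0, g_max >= 0, total_edit_max >= 0)
  structure(list(d_min = as.integer(d_min), d_max = as.integer(d_max),
                 n_max = as.integer(n_max), g_max = as.integer(g_max),
                 total_edit_max = as.integer(total_edit_max)),
            class = "pcr_params")
}

#' Clustering parameters
#'
#' Thresholds for greedy incremental clustering of amplicon sequences:
#' minimum pairwise identity and bidirectional alignment coverage, following
#' the cd-hit convention (`-aL`: coverage of the longer sequence, `-aS`:
#' coverage of the shorter).
#'
#' @param identity_min Minimum identity (matches / alignment columns).
#' @param aL Minimum aligned fraction of the longer sequence.
#' @param aS Minimum aligned fraction of the shorter sequence.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(identity_min = 0.9, aL = 0.9, aS = 0.9) {
  stopifnot(identity_min > 0, identity_min <= 1,
            aL > 0, aL <= 1, aS > 0, aS <= 1)
  structure(list(identity_min = identity_min, aL = aL, aS = aS),
            class = "cluster_params")
}

#' Probe alignment scoring
#'
#' Scoring scheme for local alignment of a TaqMan probe inside an amplicon:
#' match +1, mismatch -2, and a gap run of length k costs
#' `gap_open + k * gap_extend`. An alignment is only reported when it covers
#' at least `min_coverage` of the probe.
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Gap penalties (negative).
#' @param min_coverage Minimum fraction of probe bases that must be aligned.
#' @return A list of class `probe_scoring`.
#' @export
probe_scoring <- function(match = 1, mismatch = -2, gap_open = -2,
                          gap_extend = -1, min_coverage = 0.5) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0,
            min_coverage > 0, min_coverage <= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_coverage = min_coverage),
            class = "probe_scoring")
}
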