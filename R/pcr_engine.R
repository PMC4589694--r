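#' Reverse complement of IUPAC nucleotide sequences
#'
#' Vectorised reverse complement with IUPAC-aware complementation
#' (R<->Y, S<->S, N<->N, ...).
#'
#' @param seq Character vector of DNA sequences (IUPAC letters only).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGT")   # palindromic
#' revcomp("AAN")    # "NTT"
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  .revcomp_cpp(toupper(seq))
}

IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

#' Does a target base satisfy a (possibly degenerate) primer base?
#'
#' True when the target base's ambiguity set is a subset of the primer
#' base's set. A target `N` never matches (so N-runs in draft records do not
#' produce spurious binding sites), while a primer `N` matches any
#' unambiguous target base.
#'
#' @param primer_base,target_base Single IUPAC letters (vectorised).
#' @return Logical vector.
#' @examples
#' iupac_match("R", c("A", "G", "C"))  # TRUE TRUE FALSE
#' iupac_match("A", "N")               # FALSE
#' @export
iupac_match <- function(primer_base, target_base) {
  p <- IUPAC_BITS[toupper(primer_base)]
  t <- IUPAC_BITS[toupper(target_base)]
  if (any(is.na(p)) || any(is.na(t))) stop("non-IUPAC base")
  unname(t != 15L & bitwAnd(t, bitwNot(p)) == 0L)
}

as_record <- function(target) {
  if (is.character(target) && length(target) == 1) {
    return(data.frame(record_id = "target", description = "",
                      sequence = toupper(target), dataset_label = "",
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(target), nrow(target) == 1,
            all(c("record_id", "sequence") %in% names(target)))
  if (is.null(target$dataset_label)) target$dataset_label <- ""
  target
}

# Reduce raw qualifying windows to reported hits: greedy selection in order
# (fewer total edits, fewer gaps, length closest to the primer, leftmost),
# accepting a window only if it does not overlap an already accepted one.
# This collapses the alternative gapped alignments that surround a single
# physical binding site into one hit while keeping all distinct loci.
reduce_hits <- function(raw, primer_len) {
  if (nrow(raw) == 0) return(raw)
  total <- raw$mismatches + raw$gaps
  dev <- abs((raw$end - raw$start + 1L) - primer_len)
  ord <- order(total, raw$gaps, dev, raw$start, raw$end)
  raw <- raw[ord, , drop = FALSE]
  keep <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    sel <- which(keep)
    if (!length(sel) ||
        all(raw$start[i] > raw$end[sel] | raw$end[i] < raw$start[sel]))
      keep[i] <- TRUE
  }
  out <- raw[keep, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

#' Find primer binding sites in a target sequence
#'
#' Locates every target window to which the primer can be aligned end-to-end
#' (full primer coverage) with at most `n_max` mismatches and `g_max` indels,
#' reporting the minimal-edit alignment counts. For `strand = "-"` the primer
#' is matched against the reverse complement of the target; coordinates are
#' always 1-based inclusive on the forward strand.
#'
#' Overlapping alternative windows around one physical site are collapsed to
#' the best-scoring one (fewest total edits, then fewest gaps, then length
#' closest to the primer length, then leftmost); reported hits are mutually
#' non-overlapping per primer and strand.
#'
#' @param target A single-row record data frame (see [read_fasta()]) or a
#'   plain sequence string.
#' @param primer Primer sequence (IUPAC letters, length >= 10).
#' @param params [pcr_params()].
#' @param strand `"+"` to match against the forward sequence, `"-"` against
#'   its reverse complement.
#' @param role Label stored in the `primer_role` column (`"forward"` or
#'   `"reverse"`).
#' @return Data frame with columns `record_id`, `primer_role`, `strand`,
#'   `start`, `end`, `mismatches`, `gaps`.
#' @export
find_primer_sites <- function(target, primer, params = pcr_params(),
                              strand = c("+", "-"),
                              role = c("forward", "reverse")) {
  strand <- match.arg(strand)
  role <- match.arg(role)
  target <- as_record(target)
  primer <- toupper(primer)
  if (!grepl(valid_seq_regex(), primer)) stop("non-IUPAC character in primer")
  if (nchar(primer) < 10) stop("primer shorter than 10 nt")
  oriented <- if (strand == "+") primer else revcomp(primer)
  raw <- .primer_window_hits(target$sequence, oriented,
                             params$n_max, params$g_max)
  hits <- reduce_hits(raw, nchar(primer))
  n <- nrow(hits)
  data.frame(record_id = rep(target$record_id, n),
             primer_role = rep(role, n),
             strand = rep(strand, n),
             start = as.integer(hits$start), end = as.integer(hits$end),
             mismatches = as.integer(hits$mismatches),
             gaps = as.integer(hits$gaps),
             stringsAsFactors = FALSE)
}

#' Pair primer hits into candidate products
#'
#' Combines forward- and reverse-primer binding sites in convergent
#' orientation (3' ends facing inward, footprints non-overlapping, forward
#' match strictly upstream of the reverse match in amplicon orientation)
#' whose outer-to-outer span lies within the product-size window.
#'
#' @param fw_hits Hits of the forward primer, all on one strand.
#' @param rv_hits Hits of the reverse primer, all on the opposite strand.
#' @param params [pcr_params()].
#' @return Data frame of candidate products, one row per pair, with the
#'   amplicon strand (the forward primer's strand), outer coordinates, span
#'   and the per-primer edit counts.
#' @export
pair_hits <- function(fw_hits, rv_hits, params = pcr_params()) {
  empty <- data.frame(strand = character(0), start = integer(0),
                      end = integer(0), span = integer(0),
                      fw_mismatches = integer(0), fw_gaps = integer(0),
                      rv_mismatches = integer(0), rv_gaps = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(fw_hits) == 0 || nrow(rv_hits) == 0) return(empty)
  fs <- unique(fw_hits$strand); rs <- unique(rv_hits$strand)
  if (length(fs) != 1 || length(rs) != 1 || fs == rs)
    stop("fw_hits and rv_hits must lie on single, opposite strands")
  if (fs == "+") { left <- fw_hits; right <- rv_hits } else {
    left <- rv_hits; right <- fw_hits
  }
  idx <- expand.grid(l = seq_len(nrow(left)), r = seq_len(nrow(right)))
  span <- right$end[idx$r] - left$start[idx$l] + 1L
  ok <- left$end[idx$l] < right$start[idx$r] &
    span >= params$d_min & span <= params$d_max
  idx <- idx[ok, , drop = FALSE]
  if (!nrow(idx)) return(empty)
  fw <- if (fs == "+") idx$l else idx$r
  rv <- if (fs == "+") idx$r else idx$l
  out <- data.frame(
    strand = fs,
    start = left$start[idx$l], end = right$end[idx$r],
    span = span[ok],
    fw_mismatches = fw_hits$mismatches[fw], fw_gaps = fw_hits$gaps[fw],
    rv_mismatches = rv_hits$mismatches[rv], rv_gaps = rv_hits$gaps[rv],
    stringsAsFactors = FALSE)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Simulate PCR of one detection method on one target record
#'
#' Runs the in silico PCR search for a primer pair: finds binding sites of
#' both primers on both strands, pairs them convergently within the product
#' size window, applies the combined-edit filter
#' (`fw + rv mismatches + gaps <= total_edit_max`), and extracts the product
#' sequences. Extracted sequences always read forward-primer to
#' reverse-primer (reverse-complemented when the forward primer matched the
#' minus strand). Probe fields are initialised to `no_probe`; use
#' [annotate_probe()] to verify probe annealing.
#'
#' @param target Single-row record data frame or sequence string.
#' @param method Single-row method data frame (see [read_methods_table()]).
#' @param params [pcr_params()].
#' @return Amplicon data frame in the fixed 18-column layout.
#' @export
simulate_pcr <- function(target, method, params = pcr_params()) {
  target <- as_record(target)
  method <- as.data.frame(method, stringsAsFactors = FALSE)
  stopifnot(nrow(method) == 1,
            all(c("method_id", "specificity", "fw_primer", "rv_primer")
                %in% names(method)))
  fw <- toupper(method$fw_primer); rv <- toupper(method$rv_primer)
  fwp <- find_primer_sites(target, fw, params, "+", "forward")
  fwm <- find_primer_sites(target, fw, params, "-", "forward")
  rvp <- find_primer_sites(target, rv, params, "+", "reverse")
  rvm <- find_primer_sites(target, rv, params, "-", "reverse")
  pairs <- rbind(pair_hits(fwp, rvm, params), pair_hits(fwm, rvp, params))
  if (nrow(pairs)) {
    total <- pairs$fw_mismatches + pairs$fw_gaps +
      pairs$rv_mismatches + pairs$rv_gaps
    pairs <- pairs[total <= params$total_edit_max, , drop = FALSE]
  }
  if (!nrow(pairs)) return(empty_amplicons())
  pairs <- pairs[!duplicated(pairs[, c("strand", "start", "end")]), ,
                 drop = FALSE]
  seqs <- substring(target$sequence, pairs$start, pairs$end)
  minus <- pairs$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  n <- nrow(pairs)
  out <- data.frame(
    record_id = rep(target$record_id, n),
    dataset_label = rep(target$dataset_label, n),
    method_id = rep(method$method_id, n),
    specificity = rep(method$specificity, n),
    strand = pairs$strand,
    start = as.integer(pairs$start), end = as.integer(pairs$end),
    product_length = as.integer(pairs$span),
    fw_mismatches = as.integer(pairs$fw_mismatches),
    fw_gaps = as.integer(pairs$fw_gaps),
    rv_mismatches = as.integer(pairs$rv_mismatches),
    rv_gaps = as.integer(pairs$rv_gaps),
    total_edits = as.integer(pairs$fw_mismatches + pairs$fw_gaps +
                               pairs$rv_mismatches + pairs$rv_gaps),
    probe_status = rep("no_probe", n),
    probe_mismatches = rep(0L, n), probe_gaps = rep(0L, n),
    species = rep("unknown", n),
    amplicon_sequence = seqs,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

#' Scan datasets with a method panel
#'
#' Runs the full per-record pipeline over a set of records and a panel of
#' detection methods: in silico PCR, probe verification and species
#' assignment. This is the library-level equivalent of the `scan`
#' subcommand.
#'
#' @param records Record data frame from [read_fasta()] (possibly several
#'   datasets row-bound together).
#' @param methods Methods data frame from [read_methods_table()].
#' @param params [pcr_params()].
#' @param scoring [probe_scoring()] used for probe verification.
#' @param species_map Optional data frame from [read_species_map()]; when
#'   `NULL`, species are parsed from `[...]` tokens in record descriptions.
#' @param verbose Emit per-dataset progress messages.
#' @return Amplicon data frame (18 columns), annotated.
#' @export
scan_amplicons <- function(records, methods, params = pcr_params(),
                           scoring = probe_scoring(), species_map = NULL,
                           verbose = FALSE) {
  out <- vector("list", nrow(records) * max(1L, nrow(methods)))
  k <- 0L
  for (i in seq_len(nrow(records))) {
    rec <- records[i, , drop = FALSE]
    for (j in seq_len(nrow(methods))) {
      amp <- simulate_pcr(rec, methods[j, , drop = FALSE], params)
      if (nrow(amp)) {
        amp <- annotate_probe(amp, methods[j, , drop = FALSE], scoring)
        k <- k + 1L
        out[[k]] <- amp
      }
    }
  }
  res <- if (k) do.call(rbind, out[seq_len(k)]) else empty_amplicons()
  res <- assign_species(res, species_map, records)
  rownames(res) <- NULL
  if (verbose) {
    for (lab in unique(records$dataset_label)) {
      message(sprintf("dataset %s: %d records, %d amplicons", lab,
                      sum(records$dataset_label == lab),
                      sum(res$dataset_label == lab)))
    }
  }
  res
}
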