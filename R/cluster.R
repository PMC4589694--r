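new_cluster_set <- function(amplicons, clusters, mode) {
  structure(list(amplicons = amplicons, clusters = clusters, mode = mode),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("cluster_set (%s): %d amplicons in %d clusters\n",
              x$mode, nrow(x$amplicons), length(x$clusters)))
  if (length(sizes))
    cat(sprintf("  sizes: min %d / median %g / max %d\n",
                min(sizes), stats::median(sizes), max(sizes)))
  invisible(x)
}

#' Cluster sizes
#' @param cs A `cluster_set`.
#' @return Integer vector of member counts, one per cluster.
#' @export
cluster_sizes <- function(cs) lengths(cs$clusters)

#' Group amplicons with 100% identical sequences
#'
#' Exact partition of an amplicon set by sequence string. Each group's
#' representative is its first member in input order; the group count equals
#' the number of distinct sequences.
#'
#' @param amplicons Amplicon data frame.
#' @return A `cluster_set` (mode `"exact"`) whose `clusters` element lists
#'   member row indices per group, representative first.
#' @export
dedup_identical <- function(amplicons) {
  if (nrow(amplicons) == 0)
    return(new_cluster_set(amplicons, list(), "exact"))
  key <- amplicons$amplicon_sequence
  groups <- split(seq_along(key), factor(key, levels = unique(key)))
  new_cluster_set(amplicons, unname(groups), "exact")
}

# join test of the greedy clustering: local alignment of member vs
# representative must reach the identity threshold with sufficient aligned
# coverage of both the longer and the shorter sequence
cluster_join_ok <- function(member_seq, rep_seq, params, scoring) {
  aln <- local_align(member_seq, rep_seq, scoring)
  if (is.null(aln)) return(FALSE)
  identity <- aln$identities / aln$columns
  cov_a <- (aln$a_end - aln$a_start + 1) / nchar(member_seq)
  cov_b <- (aln$b_end - aln$b_start + 1) / nchar(rep_seq)
  if (nchar(member_seq) >= nchar(rep_seq)) {
    cov_long <- cov_a; cov_short <- cov_b
  } else {
    cov_long <- cov_b; cov_short <- cov_a
  }
  identity >= params$identity_min && cov_long >= params$aL &&
    cov_short >= params$aS
}

#' Greedy incremental clustering of amplicons
#'
#' cd-hit-style non-redundant set construction: sequences are taken longest
#' first (ties in input order); each joins the first existing cluster whose
#' representative it matches with identity >= `identity_min`
#' (matches / alignment columns) and aligned coverage >= `aL` of the longer
#' and >= `aS` of the shorter sequence, otherwise it founds a new cluster.
#' Pairwise comparison is by local alignment with the [probe_scoring()]
#' scheme (match +1, mismatch -2).
#'
#' @param amplicons Amplicon data frame.
#' @param params [cluster_params()].
#' @param scoring Alignment scoring, [probe_scoring()].
#' @return A `cluster_set` (mode `"approximate"`); in each cluster the
#'   founding representative is the first member index.
#' @export
greedy_cluster <- function(amplicons, params = cluster_params(),
                           scoring = probe_scoring()) {
  n <- nrow(amplicons)
  if (n == 0) return(new_cluster_set(amplicons, list(), "approximate"))
  seqs <- amplicons$amplicon_sequence
  ord <- order(-nchar(seqs), seq_len(n))
  reps <- integer(0)
  clusters <- list()
  for (i in ord) {
    joined <- FALSE
    for (k in seq_along(reps)) {
      if (seqs[i] == seqs[reps[k]] ||
          cluster_join_ok(seqs[i], seqs[reps[k]], params, scoring)) {
        clusters[[k]] <- c(clusters[[k]], i)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      clusters[[length(clusters) + 1L]] <- i
    }
  }
  new_cluster_set(amplicons, clusters, "approximate")
}

#' Export cluster representatives as a non-redundant sequence set
#'
#' One record per cluster representative; the header carries the
#' representative's record and method ids plus the cluster size, so the
#' export can be fed to similarity-search tools (e.g. `makeblastdb`).
#'
#' @param clusters A `cluster_set`.
#' @return Record data frame suitable for [write_fasta()].
#' @export
export_nonredundant <- function(clusters) {
  cs <- clusters
  stopifnot(inherits(cs, "cluster_set"))
  if (!length(cs$clusters))
    return(data.frame(record_id = character(0), description = character(0),
                      sequence = character(0), dataset_label = character(0),
                      stringsAsFactors = FALSE))
  rep_idx <- vapply(cs$clusters, `[`, integer(1), 1L)
  sizes <- lengths(cs$clusters)
  amp <- cs$amplicons[rep_idx, , drop = FALSE]
  data.frame(
    record_id = paste(amp$record_id, amp$method_id, sep = "|"),
    description = sprintf("cluster_size=%d", sizes),
    sequence = amp$amplicon_sequence,
    dataset_label = amp$dataset_label,
    stringsAsFactors = FALSE)
}
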