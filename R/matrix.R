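#' Build the record-by-method screening matrix
#'
#' Counts amplicons per (record, dataset, method). In strict mode only
#' perfect products are counted: zero mismatches and gaps in both primers
#' and, when the method carries a probe, perfect probe annealing
#' (`probe_status` of `perfect` or `no_probe`).
#'
#' @param amplicons Annotated amplicon data frame.
#' @param strict Apply the perfect-match filter.
#' @return A `screening_matrix`: list with `counts` (data frame `record_id`,
#'   `dataset_label`, `method_id`, `specificity`, `n`) and `strict`.
#' @export
build_matrix <- function(amplicons, strict = FALSE) {
  keep <- if (strict) {
    amplicons$total_edits == 0 &
      amplicons$probe_status %in% c("perfect", "no_probe")
  } else rep(TRUE, nrow(amplicons))
  amp <- amplicons[keep, , drop = FALSE]
  if (nrow(amp)) {
    counts <- aggregate(list(n = rep(1L, nrow(amp))),
                        amp[, c("record_id", "dataset_label", "method_id",
                                "specificity")],
                        FUN = sum)
  } else {
    counts <- data.frame(record_id = character(0), dataset_label = character(0),
                         method_id = character(0), specificity = character(0),
                         n = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(counts = counts, strict = strict), class = "screening_matrix")
}

#' @export
print.screening_matrix <- function(x, ...) {
  cat(sprintf("screening_matrix (%s): %d record x method cells, %d amplicons\n",
              if (x$strict) "strict" else "non-strict",
              nrow(x$counts), sum(x$counts$n)))
  invisible(x)
}

#' Consistency summaries per dataset and method specificity
#'
#' For every dataset label and specificity class, computes the fraction of
#' methods of that class that detect at least one record in the dataset, the
#' fraction of the dataset's records detected by at least one method of the
#' class, the total amplicon count, the number of detected (target) records,
#' and the amplicon-to-record ratio (`NA` when no record is detected). The
#' full record and method tables are required so that undetected records and
#' silent methods enter the denominators.
#'
#' @param matrix A `screening_matrix` from [build_matrix()].
#' @param records Record data frame covering all scanned records.
#' @param methods Methods data frame covering the full panel.
#' @return Data frame with one row per (dataset_label, specificity):
#'   `methods_detecting_fraction`, `records_detected_fraction`,
#'   `amplicon_count`, `record_count`, `amplicons_per_record`.
#' @export
summarize_detection <- function(matrix, records, methods) {
  stopifnot(inherits(matrix, "screening_matrix"))
  counts <- matrix$counts
  datasets <- unique(records$dataset_label)
  classes <- intersect(SPECIFICITY_LEVELS, unique(methods$specificity))
  out <- list()
  for (ds in datasets) {
    ds_records <- records$record_id[records$dataset_label == ds]
    for (cl in classes) {
      cl_methods <- methods$method_id[methods$specificity == cl]
      sub <- counts[counts$dataset_label == ds &
                      counts$method_id %in% cl_methods, , drop = FALSE]
      detected_records <- unique(sub$record_id)
      out[[length(out) + 1L]] <- data.frame(
        dataset_label = ds, specificity = cl,
        methods_detecting_fraction =
          length(unique(sub$method_id)) / length(cl_methods),
        records_detected_fraction =
          length(detected_records) / length(ds_records),
        amplicon_count = sum(sub$n),
        record_count = length(detected_records),
        amplicons_per_record = if (length(detected_records))
          sum(sub$n) / length(detected_records) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Shortlist candidate records from screening calls
#'
#' Given observed positive/negative calls for a subset of methods, returns
#' the records whose strict-mode detection pattern is consistent with every
#' observed positive, ranked by the number of observed negatives they also
#' satisfy (i.e. methods called negative that indeed do not detect the
#' record). This formalises the triage workflow used to shortlist candidate
#' (possibly unauthorized) GM events from a screening result.
#'
#' @param matrix A strict-mode `screening_matrix`.
#' @param observed Named logical vector: `TRUE` for methods with a positive
#'   screening call, `FALSE` for negative.
#' @return Data frame `record_id`, `dataset_label`,
#'   `consistent_negatives`, `n_positive_methods`, best candidates first.
#' @export
candidate_events <- function(matrix, observed) {
  stopifnot(inherits(matrix, "screening_matrix"),
            is.logical(observed), !is.null(names(observed)))
  counts <- matrix$counts
  pos <- names(observed)[observed]
  neg <- names(observed)[!observed]
  recs <- unique(counts[, c("record_id", "dataset_label")])
  if (!nrow(recs) || !length(pos))
    return(data.frame(record_id = character(0), dataset_label = character(0),
                      consistent_negatives = integer(0),
                      n_positive_methods = integer(0),
                      stringsAsFactors = FALSE))
  detected <- function(rec, m)
    any(counts$record_id == rec & counts$method_id == m & counts$n > 0)
  keep <- vapply(seq_len(nrow(recs)), function(i)
    all(vapply(pos, function(m) detected(recs$record_id[i], m), logical(1))),
    logical(1))
  recs <- recs[keep, , drop = FALSE]
  if (!nrow(recs))
    return(data.frame(record_id = character(0), dataset_label = character(0),
                      consistent_negatives = integer(0),
                      n_positive_methods = integer(0),
                      stringsAsFactors = FALSE))
  recs$consistent_negatives <- vapply(seq_len(nrow(recs)), function(i)
    sum(!vapply(neg, function(m) detected(recs$record_id[i], m), logical(1))),
    integer(1))
  recs$n_positive_methods <- length(pos)
  recs <- recs[order(-recs$consistent_negatives, recs$record_id), ,
               drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Write consistency summaries as TSV
#'
#' @param summary Data frame from [summarize_detection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summary, path) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
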