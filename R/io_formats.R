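#' Read a FASTA dataset
#'
#' Reads a (plain or line-wrapped) FASTA file into a data frame of sequence
#' records, tagging every record with a dataset label so downstream summaries
#' can be grouped by dataset of origin. The record id is the first
#' whitespace-delimited token of the header; the rest is kept as description.
#' Sequences are uppercased and validated against the IUPAC nucleotide
#' alphabet.
#'
#' @param path Path to a FASTA file.
#' @param dataset_label Label attached to every record (e.g. the name of the
#'   source collection).
#' @return A data.frame with columns `record_id`, `description`, `sequence`,
#'   `dataset_label`, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, dataset_label) {
  stopifnot(is.character(path), length(path) == 1,
            is.character(dataset_label), length(dataset_label) == 1)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  head_lines <- readLines(path, n = 1000L, warn = FALSE)
  first <- which(nzchar(trimws(head_lines)))[1]
  if (!is.na(first) && !startsWith(trimws(head_lines[first]), ">"))
    stop("malformed FASTA in ", path, ": sequence data before first header at line ",
         first)
  if (is.na(first)) {
    return(data.frame(record_id = character(0), description = character(0),
                      sequence = character(0), dataset_label = character(0),
                      stringsAsFactors = FALSE))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  record_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  dup <- record_id[duplicated(record_id)]
  if (length(dup))
    stop("duplicate record_id in ", path, ": ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- !grepl(valid_seq_regex(), seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("record '", record_id[i], "' contains non-IUPAC characters")
  }
  if (any(!nzchar(seqs))) {
    i <- which(!nzchar(seqs))[1]
    stop("record '", record_id[i], "' has an empty sequence")
  }
  if (any(!nzchar(record_id)))
    stop("empty record_id in ", path)
  data.frame(record_id = record_id, description = unname(description),
             sequence = unname(seqs), dataset_label = dataset_label,
             stringsAsFactors = FALSE)
}

valid_seq_regex <- function() {
  sprintf("^[%s]+$", paste(IUPAC_LETTERS, collapse = ""))
}

#' Write sequence records as FASTA
#'
#' Writes records in standard FASTA with 60-column line wrapping. Headers are
#' `record_id` followed, when non-empty, by a space and the description.
#'
#' @param records Data frame with at least `record_id`, `description` and
#'   `sequence` columns (as produced by [read_fasta()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(set) <- ifelse(nzchar(desc),
                       paste(records$record_id, desc), records$record_id)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a detection-methods table
#'
#' Reads a TSV panel of PCR detection methods. Required columns:
#' `method_id`, `specificity` (one of event/construct/element/taxon),
#' `target_name`, `fw_primer`, `rv_primer`, `probe` (may be empty for
#' qualitative, probe-free assays). Primers and probes may contain IUPAC
#' ambiguity codes and are uppercased; primers must be at least 10 nt.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of validated methods; absent probes are `NA`.
#' @export
read_methods_table <- function(path) {
  if (!file.exists(path)) stop("methods table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
  need <- c("method_id", "specificity", "target_name",
            "fw_primer", "rv_primer", "probe")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("methods table is missing column(s): ", paste(miss, collapse = ", "))
  tab <- tab[, need]
  if (nrow(tab) == 0) return(tab)
  tab$specificity <- tolower(trimws(tab$specificity))
  bad_spec <- !(tab$specificity %in% SPECIFICITY_LEVELS)
  if (any(bad_spec)) {
    i <- which(bad_spec)[1]
    stop("row ", i, " (", tab$method_id[i], "): unknown specificity '",
         tab$specificity[i], "'; expected one of ",
         paste(SPECIFICITY_LEVELS, collapse = "/"))
  }
  for (cl in c("fw_primer", "rv_primer", "probe"))
    tab[[cl]] <- toupper(trimws(tab[[cl]]))
  for (cl in c("fw_primer", "rv_primer")) {
    bad <- !grepl(valid_seq_regex(), tab[[cl]])
    if (any(bad)) {
      i <- which(bad)[1]
      ch <- setdiff(strsplit(tab[[cl]][i], "")[[1]], IUPAC_LETTERS)
      stop("row ", i, " (", tab$method_id[i], "): non-IUPAC character '",
           paste(ch, collapse = "','"), "' in ", cl)
    }
    short <- nchar(tab[[cl]]) < 10
    if (any(short)) {
      i <- which(short)[1]
      stop("row ", i, " (", tab$method_id[i], "): ", cl,
           " shorter than 10 nt")
    }
  }
  tab$probe[!nzchar(tab$probe)] <- NA_character_
  has_probe <- !is.na(tab$probe)
  bad <- has_probe & !grepl(valid_seq_regex(), tab$probe)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- setdiff(strsplit(tab$probe[i], "")[[1]], IUPAC_LETTERS)
    stop("row ", i, " (", tab$method_id[i], "): non-IUPAC character '",
         paste(ch, collapse = "','"), "' in probe")
  }
  dup <- tab$method_id[duplicated(tab$method_id)]
  if (length(dup))
    stop("duplicate method_id: ", paste(unique(dup), collapse = ", "))
  tab
}

#' Read a record-to-species mapping
#'
#' @param path TSV with columns `record_id` and `species`.
#' @return A data.frame mapping record ids to species names.
#' @export
read_species_map <- function(path) {
  if (!file.exists(path)) stop("species map not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("record_id", "species")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("species map is missing column(s): ", paste(miss, collapse = ", "))
  dup <- tab$record_id[duplicated(tab$record_id)]
  if (length(dup))
    stop("duplicate record_id in species map: ",
         paste(unique(dup), collapse = ", "))
  tab[, need]
}

#' Write the tab-delimited amplicon table
#'
#' Writes the pipeline's 18-column TAB output (see [amplicon_columns()] for
#' the layout). Coordinates are 1-based inclusive on the forward strand of
#' the input record regardless of amplicon strand.
#'
#' @param amplicons Amplicon data frame as produced by the scan pipeline.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_amplicon_table()]
#' @export
write_amplicon_table <- function(amplicons, path) {
  if (nrow(amplicons) == 0) amplicons <- empty_amplicons()
  miss <- setdiff(AMPLICON_COLUMNS, names(amplicons))
  if (length(miss))
    stop("amplicon table is missing column(s): ", paste(miss, collapse = ", "))
  write.table(amplicons[, AMPLICON_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tab-delimited amplicon table
#'
#' Round-trip reader for files produced by [write_amplicon_table()].
#'
#' @param path Path to the TAB file.
#' @return Amplicon data frame with the fixed 18-column layout.
#' @export
read_amplicon_table <- function(path) {
  if (!file.exists(path)) stop("amplicon table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(AMPLICON_COLUMNS, names(tab))
  if (length(miss))
    stop("amplicon table is missing column(s): ", paste(miss, collapse = ", "))
  tab <- tab[, AMPLICON_COLUMNS]
  for (cl in AMPLICON_INT_COLUMNS) tab[[cl]] <- as.integer(tab[[cl]])
  tab
}
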