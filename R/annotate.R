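#' Assign species to amplicons
#'
#' Sets the `species` column of an amplicon table from an offline
#' record-to-species mapping. Records absent from the map get `"unknown"`.
#' When no map is supplied, a fallback parses `[Genus species]`-style
#' organism tokens from the record descriptions (when `records` is given).
#' Assignment is total and idempotent and changes only the species field.
#'
#' @param amplicons Amplicon data frame.
#' @param species_map Data frame from [read_species_map()], or `NULL`.
#' @param records Optional record data frame used for the description
#'   fallback.
#' @return The amplicon data frame with `species` filled.
#' @export
assign_species <- function(amplicons, species_map = NULL, records = NULL) {
  if (nrow(amplicons) == 0) return(amplicons)
  species <- rep("unknown", nrow(amplicons))
  if (!is.null(species_map) && nrow(species_map)) {
    m <- match(amplicons$record_id, species_map$record_id)
    hit <- !is.na(m)
    species[hit] <- species_map$species[m[hit]]
  } else if (!is.null(records) && "description" %in% names(records)) {
    tok <- species_from_description(records$description)
    m <- match(amplicons$record_id, records$record_id)
    hit <- !is.na(m) & !is.na(tok[pmax(m, 1L)])
    species[hit] <- tok[m[hit]]
  }
  amplicons$species <- species
  amplicons
}

# extract "[Zea mays]"-style organism tokens; NA when absent
species_from_description <- function(description) {
  hit <- regmatches(description, regexpr("\\[[^]]+\\]", description))
  out <- rep(NA_character_, length(description))
  has <- grepl("\\[[^]]+\\]", description)
  out[has] <- sub("^\\[", "", sub("\\]$", "", hit))
  out
}
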