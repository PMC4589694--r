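## Synthetic datasets with planted primer/probe sites.  Every planted site is
## accompanied by a ground-truth amplicon row, and backgrounds are
## rejection-sampled so the record carries no binding sites other than the
## planted ones under the current PCR parameters.

random_dna <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

IUPAC_SET <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# concrete 0-mismatch instance of a possibly degenerate oligo
concretize <- function(oligo) {
  ch <- strsplit(toupper(oligo), "")[[1]]
  paste(vapply(ch, function(b) {
    s <- IUPAC_SET[[b]]
    if (is.null(s)) stop("non-IUPAC base '", b, "' in oligo")
    if (length(s) == 1) s else sample(s, 1)
  }, character(1)), collapse = "")
}

# pick k positions from `candidates`, each at distance >= min_space from the
# positions in `taken` and from each other
pick_spaced <- function(k, candidates, taken = integer(0), min_space = 4L) {
  pos <- integer(0)
  for (p in candidates[sample.int(length(candidates))]) {
    if (all(abs(p - c(taken, pos)) >= min_space)) pos <- c(pos, p)
    if (length(pos) == k) break
  }
  if (length(pos) < k) stop("cannot place ", k, " spaced edits in oligo")
  pos
}

# Concrete instance of a (possibly degenerate) oligo carrying exactly n_sub
# substitution edits and n_del deletion edits.  Edits sit in the oligo
# interior, mutually spaced by >= min_space, so the minimal end-to-end
# alignment of the oligo against the instance has exactly (n_sub, n_del)
# (mismatches, gaps) and a local aligner has no incentive to trim them away.
plant_oligo_instance <- function(oligo, n_sub, n_del = 0L, edge = 3L,
                                 min_space = 4L) {
  ch <- strsplit(concretize(oligo), "")[[1]]
  och <- strsplit(toupper(oligo), "")[[1]]
  L <- length(ch)
  if (n_sub + n_del >= L) stop("more edits requested than oligo length")
  interior <- which(seq_len(L) > edge & seq_len(L) <= L - edge)
  del <- if (n_del > 0) pick_spaced(n_del, interior, min_space = min_space)
    else integer(0)
  if (n_sub > 0) {
    subable <- interior[lengths(IUPAC_SET[och[interior]]) < 4]
    sub <- pick_spaced(n_sub, subable, taken = del, min_space = min_space)
    for (p in sub) {
      choices <- setdiff(c("A", "C", "G", "T"), IUPAC_SET[[och[p]]])
      ch[p] <- choices[sample.int(length(choices), 1)]
    }
  }
  if (length(del)) ch <- ch[-del]
  paste(ch, collapse = "")
}

normalize_site_specs <- function(site_specs, methods) {
  stopifnot(is.data.frame(site_specs),
            all(c("method_id", "fw_edits", "rv_edits", "probe_edits",
                  "spacer_length") %in% names(site_specs)))
  if (is.null(site_specs$fw_indels)) site_specs$fw_indels <- 0L
  if (is.null(site_specs$rv_indels)) site_specs$rv_indels <- 0L
  if (is.null(site_specs$strand)) site_specs$strand <- "+"
  unknown <- setdiff(site_specs$method_id, methods$method_id)
  if (length(unknown))
    stop("site specs reference unknown method(s): ",
         paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(site_specs))) {
    m <- methods[methods$method_id == site_specs$method_id[i], ]
    if (site_specs$fw_edits[i] + site_specs$fw_indels[i] >= nchar(m$fw_primer) ||
        site_specs$rv_edits[i] + site_specs$rv_indels[i] >= nchar(m$rv_primer))
      stop("site spec ", i, ": requested edits exceed primer length")
  }
  site_specs
}

# build the planted block (fw instance + spacer incl. probe + revcomp(rv
# instance)) for one site spec; returns the block string and its bookkeeping
build_site_block <- function(method, spec, background_gc) {
  fw <- plant_oligo_instance(method$fw_primer, spec$fw_edits, spec$fw_indels)
  rv <- plant_oligo_instance(method$rv_primer, spec$rv_edits, spec$rv_indels)
  spacer_len <- spec$spacer_length
  has_probe <- !is.na(method$probe) && nzchar(method$probe)
  if (has_probe) {
    pl <- nchar(method$probe)
    if (pl > spacer_len)
      stop("spacer (", spacer_len, " nt) too short for probe (", pl, " nt) of ",
           method$method_id)
    probe_inst <- plant_oligo_instance(method$probe, spec$probe_edits)
    lpad <- (spacer_len - pl) %/% 2
    spacer <- paste0(random_dna(lpad, background_gc), probe_inst,
                     random_dna(spacer_len - pl - lpad, background_gc))
  } else {
    spacer <- random_dna(spacer_len, background_gc)
  }
  block <- paste0(fw, spacer, revcomp(rv))
  list(block = block, fw_len = nchar(fw), rv_len = nchar(rv),
       has_probe = has_probe)
}

site_truth_row <- function(method, spec, block, offset, record_id,
                           dataset_label, params) {
  plen <- nchar(block$block)
  start <- offset + 1L
  end <- offset + plen
  fw_mm <- spec$fw_edits; fw_g <- spec$fw_indels
  rv_mm <- spec$rv_edits; rv_g <- spec$rv_indels
  total <- fw_mm + fw_g + rv_mm + rv_g
  in_bounds <- fw_mm <= params$n_max && rv_mm <= params$n_max &&
    fw_g <= params$g_max && rv_g <= params$g_max &&
    total <= params$total_edit_max &&
    plen >= params$d_min && plen <= params$d_max
  probe_status <- if (!block$has_probe) "no_probe"
    else if (spec$probe_edits == 0) "perfect" else "mismatched"
  data.frame(
    record_id = record_id, dataset_label = dataset_label,
    method_id = method$method_id, specificity = method$specificity,
    strand = spec$strand, start = start, end = end,
    product_length = plen,
    fw_mismatches = as.integer(fw_mm), fw_gaps = as.integer(fw_g),
    rv_mismatches = as.integer(rv_mm), rv_gaps = as.integer(rv_g),
    total_edits = as.integer(total),
    probe_status = probe_status,
    probe_mismatches = as.integer(if (block$has_probe) spec$probe_edits else 0L),
    probe_gaps = 0L,
    species = "unknown",
    amplicon_sequence = block$block,
    in_bounds = in_bounds,
    stringsAsFactors = FALSE)
}

#' Generate one synthetic construct record with planted PCR sites
#'
#' Builds a DNA record that embeds, for each site spec, a forward-primer
#' instance (with the requested number of substitution and indel edits), a
#' spacer containing the method's probe (with its own substitution edits)
#' when one exists, and the reverse complement of a reverse-primer instance.
#' Sites are separated by more than `d_max` of background so they cannot
#' cross-pair. The background is sampled i.i.d. at `background_gc` and
#' rejection-checked: the full method panel is scanned in silico and the
#' background is redrawn until the observed amplicons equal the ground
#' truth exactly, so the record carries no unintended binding sites.
#'
#' @param methods Methods data frame (the full panel is used for the
#'   cleanliness check).
#' @param site_specs Data frame with columns `method_id`, `fw_edits`,
#'   `rv_edits`, `probe_edits`, `spacer_length` and optionally `fw_indels`,
#'   `rv_indels` (indel-type edits, default 0) and `strand` (`"+"` or
#'   `"-"`, default `"+"`; minus-strand sites are planted reverse
#'   complemented).
#' @param seed Integer seed; the record is deterministic given the seed.
#' @param params [pcr_params()] defining what counts as in-bounds.
#' @param background_gc GC fraction of the background sequence.
#' @param flank Background length added at both ends.
#' @param record_id,dataset_label Provenance fields of the record.
#' @param site_seed Separate seed for the planted blocks; two records built
#'   with the same `site_seed` but different `seed` carry byte-identical
#'   planted amplicons in different backgrounds (patent-style redundancy).
#' @param max_attempts Background redraw limit before giving up.
#' @return List with `record` (one-row record data frame) and `truth`
#'   (ground-truth amplicon table with an extra `in_bounds` column; sites
#'   whose edit budgets or product size violate `params` are marked
#'   `in_bounds = FALSE` and must not be recovered).
#' @export
generate_construct <- function(methods, site_specs, seed,
                               params = pcr_params(), background_gc = 0.4,
                               flank = 80L, record_id = "construct_1",
                               dataset_label = "synthetic",
                               site_seed = seed, max_attempts = 60L) {
  site_specs <- normalize_site_specs(site_specs, methods)
  blocks <- run_seeded(site_seed, {
    lapply(seq_len(nrow(site_specs)), function(i) {
      m <- methods[methods$method_id == site_specs$method_id[i], , drop = FALSE]
      build_site_block(m, site_specs[i, ], background_gc)
    })
  })
  gap <- params$d_max + 50L
  for (attempt in seq_len(max_attempts)) {
    built <- run_seeded(seed + 7919L * attempt, {
      pieces <- character(0)
      truth <- list()
      offset <- 0L
      add <- function(piece) {
        pieces[[length(pieces) + 1L]] <<- piece
        offset <<- offset + nchar(piece)
      }
      add(random_dna(flank, background_gc))
      for (i in seq_len(nrow(site_specs))) {
        if (i > 1) add(random_dna(gap, background_gc))
        m <- methods[methods$method_id == site_specs$method_id[i], ,
                     drop = FALSE]
        tr <- site_truth_row(m, site_specs[i, ], blocks[[i]], offset,
                             record_id, dataset_label, params)
        planted <- if (site_specs$strand[i] == "-")
          revcomp(blocks[[i]]$block) else blocks[[i]]$block
        add(planted)
        truth[[i]] <- tr
      }
      add(random_dna(flank, background_gc))
      list(sequence = paste(pieces, collapse = ""), truth = do.call(rbind, truth))
    })
    record <- data.frame(record_id = record_id, description = "",
                         sequence = built$sequence,
                         dataset_label = dataset_label,
                         stringsAsFactors = FALSE)
    expected <- built$truth[built$truth$in_bounds, , drop = FALSE]
    observed <- scan_amplicons(record, methods, params)
    if (truth_matches(observed, expected)) {
      rownames(built$truth) <- NULL
      return(list(record = record, truth = built$truth))
    }
  }
  stop("could not generate a clean construct for record ", record_id,
       " within ", max_attempts, " attempts")
}

# field-for-field comparison of a scan result against expected ground truth
truth_matches <- function(observed, expected) {
  cols <- c("record_id", "method_id", "strand", "start", "end",
            "product_length", "fw_mismatches", "fw_gaps", "rv_mismatches",
            "rv_gaps", "total_edits", "probe_status", "probe_mismatches",
            "probe_gaps", "amplicon_sequence")
  if (nrow(observed) != nrow(expected)) return(FALSE)
  if (nrow(observed) == 0) return(TRUE)
  o <- observed[order(observed$method_id, observed$start), cols]
  e <- expected[order(expected$method_id, expected$start), cols]
  rownames(o) <- rownames(e) <- NULL
  isTRUE(all.equal(o, e, check.attributes = FALSE))
}

#' Specification of a synthetic fixture corpus
#'
#' Describes a mixed corpus emulating the classes of public sequence
#' collections: transgenic-like records (GM-specific sites only), plant-like
#' genomic records (taxon-specific sites only), and patent-like records
#' (each construct emitted in several near-identical copies to exercise
#' deduplication and clustering).
#'
#' @param seed Master seed; the whole corpus is deterministic given it.
#' @param n_transgenic,n_plant,n_patent Records per class (for the patent
#'   class, the number of distinct constructs).
#' @param redundancy Copies per patent-like construct.
#' @param background_gc Background GC fraction.
#' @param labels Dataset labels for the three classes.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_transgenic = 12L, n_plant = 12L,
                         n_patent = 4L, redundancy = 5L, background_gc = 0.4,
                         labels = c(transgenic_like = "transgenic_like",
                                    plant_like = "plant_like",
                                    patent_like = "patent_like")) {
  stopifnot(n_transgenic >= 0, n_plant >= 0, n_patent >= 0, redundancy >= 1,
            all(c("transgenic_like", "plant_like", "patent_like")
                %in% names(labels)))
  structure(list(seed = as.integer(seed), n_transgenic = as.integer(n_transgenic),
                 n_plant = as.integer(n_plant), n_patent = as.integer(n_patent),
                 redundancy = as.integer(redundancy),
                 background_gc = background_gc, labels = labels),
            class = "fixture_spec")
}

#' Synthetic detection-method panel
#'
#' Generates a deterministic panel of synthetic PCR methods across the four
#' specificity classes. Quantitative (`QT-`) methods carry a TaqMan probe;
#' qualitative (`QL-`) methods do not. Taxon-specific methods are named
#' after plant species, mirroring ingredient-identification assays. One
#' element-specific forward primer carries a degenerate base so IUPAC
#' handling is exercised end to end.
#'
#' @param n_event,n_construct,n_element,n_taxon Methods per class.
#' @param seed Seed making the panel reproducible.
#' @return Methods data frame as from [read_methods_table()].
#' @export
synthetic_methods_panel <- function(n_event = 6L, n_construct = 3L,
                                    n_element = 4L, n_taxon = 4L,
                                    seed = 101L) {
  species <- c("Zea mays", "Glycine max", "Oryza sativa", "Brassica napus",
               "Solanum lycopersicum", "Gossypium hirsutum")
  run_seeded(seed, {
    rows <- list()
    mk <- function(class, tag, i, target, with_probe) {
      id <- sprintf("%s-%s-SY-%03d", if (with_probe) "QT" else "QL", tag, i)
      fw <- random_dna(sample(18:24, 1), 0.5)
      rv <- random_dna(sample(18:24, 1), 0.5)
      probe <- if (with_probe) random_dna(sample(20:26, 1), 0.5) else ""
      data.frame(method_id = id, specificity = class, target_name = target,
                 fw_primer = fw, rv_primer = rv, probe = probe,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_event))
      rows[[length(rows) + 1L]] <-
        mk("event", "EVE", i, sprintf("synthetic event %d", i), i %% 2 == 1)
    for (i in seq_len(n_construct))
      rows[[length(rows) + 1L]] <-
        mk("construct", "CON", i, sprintf("synthetic junction %d", i),
           i %% 2 == 0)
    for (i in seq_len(n_element))
      rows[[length(rows) + 1L]] <-
        mk("element", "ELE", i, sprintf("synthetic element %d", i),
           i %% 2 == 1)
    for (i in seq_len(n_taxon))
      rows[[length(rows) + 1L]] <-
        mk("taxon", "TAX", i, species[(i - 1) %% length(species) + 1],
           i %% 2 == 0)
    tab <- do.call(rbind, rows)
    # plant one degenerate base in an element-specific primer
    ele <- which(tab$specificity == "element")[1]
    if (!is.na(ele)) {
      fw <- strsplit(tab$fw_primer[ele], "")[[1]]
      p <- length(fw) %/% 2
      fw[p] <- switch(fw[p], A = "R", G = "R", C = "Y", T = "Y")
      tab$fw_primer[ele] <- paste(fw, collapse = "")
    }
    tab$probe[!nzchar(tab$probe)] <- NA_character_
    tab
  })
}

#' Generate a mixed synthetic corpus
#'
#' Materialises a [fixture_spec()]: transgenic-like records each carry one
#' event-specific site (every second record also an element site, every
#' third a construct site); plant-like records carry one taxon-specific site
#' each; patent-like constructs carry one event site and are emitted in
#' `redundancy` copies whose planted amplicon regions are byte-identical
#' while the background differs. All planted sites are edit-free, so strict
#' and relaxed screening agree on this corpus by construction.
#'
#' @param spec A [fixture_spec()].
#' @param methods Methods panel; defaults to [synthetic_methods_panel()].
#' @param params [pcr_params()].
#' @param dir Optional directory: when given, one FASTA per class,
#'   `species_map.tsv` and `ground_truth.tsv` are written there.
#' @return List with `records`, `species_map`, `truth`, `methods` (and
#'   `files` when `dir` is given).
#' @export
generate_dataset <- function(spec = fixture_spec(),
                             methods = synthetic_methods_panel(),
                             params = pcr_params(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  ev <- methods$method_id[methods$specificity == "event"]
  co <- methods$method_id[methods$specificity == "construct"]
  el <- methods$method_id[methods$specificity == "element"]
  tx <- methods[methods$specificity == "taxon", , drop = FALSE]
  crops <- c("Zea mays", "Glycine max", "Oryza sativa", "Brassica napus")
  cyc <- function(v, i) v[(i - 1) %% length(v) + 1]
  site <- function(id, spacer = 64L)
    data.frame(method_id = id, fw_edits = 0L, rv_edits = 0L, probe_edits = 0L,
               spacer_length = spacer, stringsAsFactors = FALSE)
  records <- list(); truth <- list(); map <- list()
  push <- function(res, species) {
    records[[length(records) + 1L]] <<- res$record
    tr <- res$truth
    tr$species <- species
    truth[[length(truth) + 1L]] <<- tr
    map[[length(map) + 1L]] <<- data.frame(record_id = res$record$record_id,
                                           species = species,
                                           stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_transgenic)) {
    sp <- site(cyc(ev, i), 60L + 4L * i)
    if (length(el) && i %% 2 == 0) sp <- rbind(sp, site(cyc(el, i), 80L))
    if (length(co) && i %% 3 == 0) sp <- rbind(sp, site(cyc(co, i), 100L))
    res <- generate_construct(methods, sp, seed = spec$seed + 1000L + i,
                              params = params,
                              background_gc = spec$background_gc,
                              record_id = sprintf("TGN%03d", i),
                              dataset_label = spec$labels[["transgenic_like"]])
    push(res, cyc(crops, i))
  }
  for (i in seq_len(spec$n_plant)) {
    m <- tx[(i - 1) %% nrow(tx) + 1, , drop = FALSE]
    res <- generate_construct(methods, site(m$method_id, 70L + 3L * i),
                              seed = spec$seed + 2000L + i, params = params,
                              background_gc = spec$background_gc,
                              record_id = sprintf("PLN%03d", i),
                              dataset_label = spec$labels[["plant_like"]])
    push(res, m$target_name)
  }
  for (j in seq_len(spec$n_patent)) {
    sp <- site(cyc(ev, j), 90L + 6L * j)
    for (k in seq_len(spec$redundancy)) {
      res <- generate_construct(methods, sp,
                                seed = spec$seed + 3000L + 100L * j + k,
                                params = params,
                                background_gc = spec$background_gc,
                                record_id = sprintf("PAT%03d_%02d", j, k),
                                dataset_label = spec$labels[["patent_like"]],
                                site_seed = spec$seed + 5000L + j)
      push(res, "synthetic construct")
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(record_id = character(0), description = character(0),
               sequence = character(0), dataset_label = character(0),
               stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  map <- if (length(map)) do.call(rbind, map) else
    data.frame(record_id = character(0), species = character(0),
               stringsAsFactors = FALSE)
  rownames(records) <- NULL
  if (!is.null(truth)) rownames(truth) <- NULL
  out <- list(records = records, species_map = map, truth = truth,
              methods = methods)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (lab in unique(records$dataset_label)) {
      f <- file.path(dir, paste0(lab, ".fasta"))
      write_fasta(records[records$dataset_label == lab, , drop = FALSE], f)
      files <- c(files, f)
    }
    f <- file.path(dir, "species_map.tsv")
    write.table(map, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "ground_truth.tsv")
    write.table(truth, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    out$files <- files
  }
  out
}
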