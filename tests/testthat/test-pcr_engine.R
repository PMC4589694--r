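test_that("revcomp is IUPAC-aware and involutive", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAN"), "NTT")
  expect_error(revcomp("ACXT"), "non-IUPAC")
  set.seed(11)
  seqs <- replicate(20, random_seq(sample(1:80, 1), setdiff(names(ORACLE_COMP), "U")))
  expect_equal(revcomp(revcomp(seqs)), seqs)
  # independent implementation agreement
  expect_equal(revcomp(seqs),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAStringSet(seqs))))
})

test_that("iupac_match follows the subset rule with target-N exclusion", {
  expect_true(iupac_match("R", "A"))
  expect_false(iupac_match("R", "C"))
  expect_true(iupac_match("A", "A"))
  expect_false(iupac_match("A", "N"))
  expect_true(iupac_match("N", "A"))
  expect_false(iupac_match("N", "N"))
  expect_true(iupac_match("D", "K"))   # {G,T} within {A,G,T}
  expect_error(iupac_match("A", "Z"), "non-IUPAC")
})

test_that("a planted exact primer copy yields exactly one clean hit", {
  set.seed(21)
  primer <- "ACGGATTCACGGTTAGACCA"
  for (rep in 1:10) {
    rec <- planted_record(random_seq(40), primer, random_seq(40))
    hits <- find_primer_sites(rec, primer, pcr_params(), "+", "forward")
    oracle <- oracle_sites(rec$sequence, primer, pcr_params(), "+")
    expect_equal(hits[, c("start", "end", "mismatches", "gaps")], oracle,
                 ignore_attr = TRUE)
    if (nrow(oracle) == 1 && oracle$start == 41) {
      expect_equal(hits$start, 41)
      expect_equal(hits$end, 60)
      expect_equal(hits$mismatches, 0)
      expect_equal(hits$gaps, 0)
    }
  }
})

test_that("a site with three substitutions is over budget at n_max = 2", {
  set.seed(22)
  primer <- "ACGGATTCACGGTTAGACCA"
  mutated <- {
    ch <- strsplit(primer, "")[[1]]
    for (p in c(5, 10, 15)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  rec <- planted_record(random_seq(40), mutated, random_seq(40))
  hits <- find_primer_sites(rec, primer, pcr_params(g_max = 0), "+", "forward")
  # no hit overlapping the planted locus (flanks may not match either)
  expect_false(any(hits$start <= 60 & hits$end >= 41))
})

test_that("find_primer_sites equals the window-DP oracle on random targets", {
  set.seed(23)
  for (rep in 1:12) {
    n <- sample(c(0:2), 1); g <- sample(c(0:2), 1)
    params <- pcr_params(n_max = n, g_max = g)
    primer <- random_seq(sample(15:25, 1))
    target <- random_seq(500)
    # plant a corrupted copy to make non-trivial hits likely
    inst <- strsplit(primer, "")[[1]]
    k <- sample(0:3, 1)
    if (k > 0) {
      pos <- sample(seq_along(inst), k)
      for (p in pos) inst[p] <- sample(c("A", "C", "G", "T"), 1)
    }
    target <- paste0(substr(target, 1, 200), paste(inst, collapse = ""),
                     substr(target, 201, 500))
    for (strand in c("+", "-")) {
      hits <- find_primer_sites(target, primer, params, strand)
      oracle <- oracle_sites(toupper(target), primer, params, strand)
      expect_equal(hits[, c("start", "end", "mismatches", "gaps")], oracle,
                   ignore_attr = TRUE)
    }
  }
})

test_that("pair_hits enforces convergent geometry and the size window", {
  fw <- data.frame(record_id = "r", primer_role = "forward", strand = "+",
                   start = 101L, end = 120L, mismatches = 0L, gaps = 0L,
                   stringsAsFactors = FALSE)
  rv <- data.frame(record_id = "r", primer_role = "reverse", strand = "-",
                   start = 181L, end = 200L, mismatches = 0L, gaps = 0L,
                   stringsAsFactors = FALSE)
  p <- pair_hits(fw, rv, pcr_params())
  expect_equal(nrow(p), 1)
  expect_equal(p$span, 100L)
  expect_equal(p$strand, "+")
  expect_equal(nrow(pair_hits(fw, rv, pcr_params(d_min = 150))), 0)
  # overlapping footprints never pair
  rv2 <- rv; rv2$start <- 110L; rv2$end <- 129L
  expect_equal(nrow(pair_hits(fw, rv2, pcr_params())), 0)
})

test_that("simulate_pcr recovers a constructed product on both strands", {
  set.seed(24)
  fw <- random_seq(20); rv <- random_seq(20)
  m <- one_method(fw, rv)
  core <- paste0(fw, random_seq(64), revcomp(rv))
  rec <- planted_record(random_seq(30), core, random_seq(30))
  amp <- simulate_pcr(rec, m, pcr_params())
  expect_equal(nrow(amp), 1)
  expect_equal(amp$product_length, 104L)
  expect_equal(amp$strand, "+")
  expect_equal(amp$total_edits, 0L)
  expect_equal(amp$amplicon_sequence, core)
  expect_equal(amp$start, 31L)

  rec2 <- rec; rec2$sequence <- revcomp(rec$sequence)
  amp2 <- simulate_pcr(rec2, m, pcr_params())
  expect_equal(nrow(amp2), 1)
  expect_equal(amp2$strand, "-")
  expect_equal(amp2$amplicon_sequence, amp$amplicon_sequence)
  L <- nchar(rec$sequence)
  expect_equal(amp2$start, L - amp$end + 1L)
  expect_equal(amp2$end, L - amp$start + 1L)
})

test_that("per-primer edits within bounds but summing to 3 are filtered", {
  panel <- tiny_panel()
  m <- panel[1, , drop = FALSE]
  ss <- data.frame(method_id = m$method_id, fw_edits = 2L, rv_edits = 1L,
                   probe_edits = 0L, spacer_length = 64L)
  res <- generate_construct(panel, ss, seed = 31,
                            params = pcr_params(total_edit_max = 4))
  expect_equal(res$truth$total_edits, 3L)
  amp_default <- simulate_pcr(res$record, m, pcr_params())
  expect_equal(nrow(amp_default), 0)
  amp_wide <- simulate_pcr(res$record, m, pcr_params(total_edit_max = 4))
  expect_equal(nrow(amp_wide), 1)
  expect_equal(amp_wide$fw_mismatches, 2L)
  expect_equal(amp_wide$rv_mismatches, 1L)
})

test_that("enlarging tolerances never removes reported amplicons", {
  panel <- tiny_panel()
  m <- panel[2, , drop = FALSE]
  ss <- data.frame(method_id = m$method_id, fw_edits = 1L, rv_edits = 1L,
                   probe_edits = 0L, spacer_length = 80L)
  res <- generate_construct(panel, ss, seed = 33)
  key <- function(a) paste(a$strand, a$start, a$end)
  base <- simulate_pcr(res$record, m, pcr_params())
  wider <- list(pcr_params(n_max = 2, g_max = 2, total_edit_max = 4),
                pcr_params(d_min = 40, d_max = 600),
                pcr_params(total_edit_max = 6))
  for (p in wider) {
    amp <- simulate_pcr(res$record, m, p)
    expect_true(all(key(base) %in% key(amp)))
  }
})
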