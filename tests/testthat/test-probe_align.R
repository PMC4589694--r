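test_that("probe contained verbatim in the amplicon aligns perfectly", {
  set.seed(41)
  amp <- random_seq(120)
  probe <- substr(amp, 40, 61)
  aln <- align_probe(probe, amp)
  expect_equal(aln$mismatches, 0L)
  expect_equal(aln$gaps, 0L)
  expect_equal(aln$covered_fraction, 1)
  expect_equal(aln$strand, "+")
  expect_equal(aln$amp_start, 40L)
  expect_equal(aln$amp_end, 61L)
})

test_that("a single interior substitution gives one probe mismatch", {
  set.seed(42)
  amp <- random_seq(120)
  probe <- substr(amp, 40, 61)
  ch <- strsplit(probe, "")[[1]]
  ch[11] <- setdiff(c("A", "C", "G", "T"), ch[11])[1]
  probe_mut <- paste(ch, collapse = "")
  aln <- align_probe(probe_mut, amp)
  expect_equal(aln$mismatches, 1L)
  expect_equal(aln$gaps, 0L)
  expect_equal(aln$covered_fraction, 1)
})

test_that("probes anneal on either amplicon strand", {
  set.seed(43)
  amp <- random_seq(100)
  probe <- revcomp(substr(amp, 30, 52))
  aln <- align_probe(probe, amp)
  expect_equal(aln$strand, "-")
  expect_equal(aln$mismatches, 0L)
  expect_equal(aln$covered_fraction, 1)
})

test_that("unrelated probes fall below the coverage floor", {
  set.seed(44)
  aln <- align_probe(random_seq(24), random_seq(60))
  if (!is.null(aln)) expect_lt(aln$covered_fraction, 1)
  # a probe absent from a short amplicon of disjoint alphabet
  expect_null(align_probe(strrep("AC", 12), strrep("G", 40)))
})

test_that("alignment counts match the exhaustive local-alignment oracle", {
  set.seed(45)
  for (rep in 1:40) {
    probe_len <- sample(12:25, 1)
    amp <- random_seq(sample(60:150, 1))
    if (rep %% 2 == 0) {
      # plant a corrupted copy so non-trivial alignments occur
      ins <- strsplit(random_seq(probe_len), "")[[1]]
      pos <- substr(amp, 10, 10 + probe_len - 1)
      probe <- pos
      ch <- strsplit(probe, "")[[1]]
      for (p in sample(seq_along(ch), sample(0:3, 1)))
        ch[p] <- sample(c("A", "C", "G", "T"), 1)
      probe <- paste(ch, collapse = "")
    } else {
      probe <- random_seq(probe_len)
    }
    mine <- local_align(probe, amp)
    oracle <- oracle_local_align(probe, amp)
    if (is.null(oracle)) {
      expect_null(mine)
    } else {
      expect_equal(mine$score, oracle$score)
      expect_equal(mine$identities, oracle$identities)
      expect_equal(mine$mismatches, oracle$mismatches)
      expect_equal(mine$gaps, oracle$gaps)
    }
  }
})

test_that("local alignment scores agree with Biostrings on plain sequences", {
  set.seed(46)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  for (rep in 1:10) {
    a <- random_seq(30); b <- random_seq(80)
    mine <- local_align(a, b)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 2, gapExtension = 1)
    expect_equal(if (is.null(mine)) 0 else mine$score,
                 max(0, Biostrings::score(ref)))
  }
})

test_that("annotate_probe classifies perfect, mismatched and no_probe", {
  set.seed(47)
  fw <- random_seq(20); rv <- random_seq(20)
  probe <- random_seq(22)
  spacer <- paste0(random_seq(20), probe, random_seq(20))
  core <- paste0(fw, spacer, revcomp(rv))
  rec <- planted_record(random_seq(30), core, random_seq(30))

  m_probe <- one_method(fw, rv, probe)
  amp <- simulate_pcr(rec, m_probe, pcr_params())
  amp <- annotate_probe(amp, m_probe)
  expect_equal(amp$probe_status, "perfect")
  expect_equal(amp$probe_mismatches, 0L)

  m_none <- one_method(fw, rv)
  amp0 <- annotate_probe(simulate_pcr(rec, m_none, pcr_params()), m_none)
  expect_equal(amp0$probe_status, "no_probe")

  # one substituted base inside the probe site: found, with one mismatch
  ch <- strsplit(probe, "")[[1]]
  ch[10] <- setdiff(c("A", "C", "G", "T"), ch[10])[1]
  m_mut <- one_method(fw, rv, paste(ch, collapse = ""))
  amp1 <- annotate_probe(simulate_pcr(rec, m_mut, pcr_params()), m_mut)
  expect_equal(amp1$probe_status, "mismatched")
  expect_equal(amp1$probe_mismatches, 1L)
  expect_equal(amp1$probe_gaps, 0L)

  # probe annotation never drops rows
  expect_equal(nrow(amp1), 1)
})
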