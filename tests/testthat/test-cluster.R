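# minimal amplicon table carrying only what clustering reads
amp_stub <- function(seqs) {
  n <- length(seqs)
  data.frame(record_id = sprintf("r%03d", seq_len(n)),
             dataset_label = "ds", method_id = "M1",
             amplicon_sequence = seqs, stringsAsFactors = FALSE)
}

test_that("exact deduplication partitions by sequence string", {
  seqs <- c("AAAA", "CCCC", "AAAA", "GGGG", "AAAA")
  cs <- dedup_identical(amp_stub(seqs))
  expect_equal(cs$mode, "exact")
  expect_equal(length(cs$clusters), 3)
  expect_equal(sum(cluster_sizes(cs)), 5)
  # representative is the first member in input order
  expect_equal(vapply(cs$clusters, `[`, integer(1), 1L), c(1L, 2L, 4L))
  # partition property
  expect_setequal(unlist(cs$clusters), 1:5)
})

test_that("exact group count equals the distinct-string count", {
  set.seed(61)
  pool <- replicate(120, random_seq(sample(60:140, 1)))
  seqs <- sample(pool, 1000, replace = TRUE)
  cs <- dedup_identical(amp_stub(seqs))
  expect_equal(length(cs$clusters), length(unique(seqs)))
  expect_setequal(unlist(cs$clusters), seq_along(seqs))
})

test_that("greedy clustering honours identity and coverage thresholds", {
  set.seed(62)
  base <- random_seq(100)
  # identical pair -> one cluster
  cs <- greedy_cluster(amp_stub(c(base, base)))
  expect_equal(length(cs$clusters), 1)
  expect_equal(cluster_sizes(cs), 2L)

  # 15 substitutions (85% identity) -> two clusters at identity_min = 0.9
  ch <- strsplit(base, "")[[1]]
  pos <- seq(5, by = 6, length.out = 15)
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  mut <- paste(ch, collapse = "")
  cs2 <- greedy_cluster(amp_stub(c(base, mut)))
  expect_equal(length(cs2$clusters), 2)

  # exact 80-mer substring -> two clusters (coverage of the longer is 0.8)
  sub80 <- substr(base, 11, 90)
  cs3 <- greedy_cluster(amp_stub(c(base, sub80)))
  expect_equal(length(cs3$clusters), 2)

  # 95-mer substring passes both coverage thresholds -> one cluster
  sub95 <- substr(base, 1, 95)
  cs4 <- greedy_cluster(amp_stub(c(base, sub95)))
  expect_equal(length(cs4$clusters), 1)
  # longest-first: the 100-mer founds the cluster
  expect_equal(cs4$clusters[[1]][1], 1L)
})

test_that("clusters partition the input and representatives are separated", {
  set.seed(63)
  fams <- replicate(6, random_seq(sample(80:120, 1)))
  seqs <- unlist(lapply(fams, function(f) {
    c(f, replicate(3, {
      ch <- strsplit(f, "")[[1]]
      for (p in sample(seq_along(ch), sample(0:4, 1)))
        ch[p] <- sample(c("A", "C", "G", "T"), 1)
      paste(ch, collapse = "")
    }))
  }))
  params <- cluster_params()
  cs <- greedy_cluster(amp_stub(seqs), params)
  expect_setequal(unlist(cs$clusters), seq_along(seqs))
  expect_equal(sum(cluster_sizes(cs)), length(seqs))
  # each representative fails the join test against every earlier-founded
  # representative (representative-separation property)
  reps <- vapply(cs$clusters, `[`, integer(1), 1L)  # founding order
  if (length(reps) > 1) {
    for (k in 2:length(reps)) {
      for (j in 1:(k - 1)) {
        expect_false(seqs[reps[k]] == seqs[reps[j]] ||
                       amplimine:::cluster_join_ok(seqs[reps[k]],
                                                   seqs[reps[j]], params,
                                                   probe_scoring()))
      }
    }
  }
  # exact dedup never has fewer groups than greedy clustering
  expect_gte(length(dedup_identical(amp_stub(seqs))$clusters),
             length(cs$clusters))
})

test_that("equal-length input order does not change exact group count", {
  set.seed(64)
  seqs <- sample(c(replicate(5, random_seq(90)),
                   replicate(5, random_seq(90))), 20, replace = TRUE)
  n1 <- length(dedup_identical(amp_stub(seqs))$clusters)
  n2 <- length(dedup_identical(amp_stub(rev(seqs)))$clusters)
  expect_equal(n1, n2)
})

test_that("non-redundant export carries one record per representative", {
  seqs <- c("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",
            "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",
            "TTTTTTTTTTGGGGGGGGGGCCCCCCCCCCAAAAAAAAAATTTTTTTTTTGG")
  cs <- dedup_identical(amp_stub(seqs))
  nr <- export_nonredundant(cs)
  expect_equal(nrow(nr), 2)
  expect_equal(nr$sequence, unique(seqs))
  expect_equal(nr$description, c("cluster_size=2", "cluster_size=1"))
  # sizes encoded in headers match the cluster sizes
  expect_equal(as.integer(sub("cluster_size=", "", nr$description)),
               unname(cluster_sizes(cs)))
  # singleton input round-trips the sequence
  one <- export_nonredundant(dedup_identical(amp_stub(seqs[3])))
  expect_equal(one$sequence, seqs[3])
})
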