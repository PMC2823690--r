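test_that("perfectly overlapping reads merge; dissimilar reads do not", {
  set.seed(23)
  core <- paste(sample(c("A", "C", "G", "T"), 160, replace = TRUE),
                collapse = "")
  r1 <- substr(core, 1, 100)          # 1..100
  r2 <- substr(core, 41, 160)         # 60 nt overlap with r1
  ests <- Biostrings::DNAStringSet(c(a = r1, b = r2))
  ctg <- greedyAssemble(ests)
  expect_equal(length(ctg), 1L)
  expect_equal(as.character(consensusSeqs(ctg)[[1]]), core)
  other <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                 collapse = "")
  ctg2 <- greedyAssemble(Biostrings::DNAStringSet(c(a = r1, c = other)))
  expect_equal(length(ctg2), 2L)
  # reverse-complement overlap is found too
  r2rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r2)))
  ctg3 <- greedyAssemble(Biostrings::DNAStringSet(c(a = r1, b = r2rc)))
  expect_equal(length(ctg3), 1L)
  expect_setequal(contigMembers(ctg3)$strand, c("+", "-"))
})

test_that("assembly partitions the input and spans stay in bounds", {
  tx <- makeTranscriptome(transcriptomeSpec(n_transcripts = 12,
                                            length_min = 300,
                                            length_max = 600,
                                            abundance_skew = 0.5,
                                            seed = 13))
  sim <- makeReads(tx, cloneSimSpec(n_reads = 120, error_rate = 0.005,
                                    empty_vector_fraction = 0,
                                    short_insert_fraction = 0,
                                    low_quality_fraction = 0,
                                    insert_len_mean = 550,
                                    insert_len_sd = 80, seed = 13))
  pre <- runPreprocess(sim$reads)
  ctg <- greedyAssemble(pre$ests)
  m <- contigMembers(ctg)
  expect_setequal(m$est_id, names(pre$ests))
  expect_false(anyDuplicated(m$est_id) > 0)
  lens <- Biostrings::width(consensusSeqs(ctg))[
    match(m$contig_id, names(consensusSeqs(ctg)))]
  expect_true(all(m$offset >= 1 & m$offset + m$width - 1 <= lens))
  # consensus at least as long as its longest member span
  for (cid in names(consensusSeqs(ctg))) {
    mm <- m[m$contig_id == cid, ]
    expect_gte(Biostrings::width(consensusSeqs(ctg)[cid]),
               max(mm$width))
  }
})

test_that("raising min_identity never decreases the contig count", {
  tx <- makeTranscriptome(transcriptomeSpec(n_transcripts = 8,
                                            length_min = 300,
                                            length_max = 500,
                                            abundance_skew = 0.5,
                                            seed = 19))
  sim <- makeReads(tx, cloneSimSpec(n_reads = 60, error_rate = 0.02,
                                    empty_vector_fraction = 0,
                                    short_insert_fraction = 0,
                                    low_quality_fraction = 0, seed = 19))
  pre <- runPreprocess(sim$reads)
  ns <- vapply(c(0.9, 0.95, 0.99), function(idn)
    length(greedyAssemble(pre$ests,
                          assemblyParams(min_identity = idn))),
    integer(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("assembly recovers planted transcripts from 5x coverage", {
  tx <- makeTranscriptome(transcriptomeSpec(n_transcripts = 50,
                                            length_min = 300,
                                            length_max = 600,
                                            abundance_skew = 0.2,
                                            seed = 77))
  sim <- makeReads(tx, cloneSimSpec(n_reads = 330, error_rate = 0.005,
                                    empty_vector_fraction = 0,
                                    short_insert_fraction = 0,
                                    low_quality_fraction = 0,
                                    insert_len_mean = 650,
                                    insert_len_sd = 60, seed = 77))
  pre <- runPreprocess(sim$reads)
  ctg <- greedyAssemble(pre$ests)
  m <- contigMembers(ctg)
  truth <- sim$truth
  read_tx <- stats::setNames(truth$transcript_id, truth$read_id)
  covered <- tapply(read_tx[m$est_id], m$contig_id, function(v)
    names(sort(table(v), decreasing = TRUE))[[1]])
  clen <- stats::setNames(Biostrings::width(consensusSeqs(ctg)),
                          names(consensusSeqs(ctg)))
  tx_reads <- table(read_tx[names(pre$ests)])
  eligible <- names(tx_reads)[tx_reads >= 5]
  expect_gte(length(eligible), 25)
  recovered <- vapply(eligible, function(t) {
    cids <- names(covered)[covered == t]
    if (!length(cids)) return(FALSE)
    max(clen[cids]) >= 0.9 * nchar(as.character(tx$sequences[[t]]))
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
})

test_that("contig statistics reproduce hand counts and enforce totals", {
  # 2894 contigs, 2000 singletons: the published redundancy profile
  counts <- c(rep(1L, 2000), rep(2L, 387),
              rep(10L, 377), rep(30L, 130))
  st <- contigStats(counts)
  expect_equal(st$n_contigs, 2894)
  expect_equal(round(st$singleton_fraction, 3), 0.691)
  expect_equal(round(st$two_member_fraction, 3), 0.134)
  expect_equal(st$n_contigs_gt20, 130)
  # conservation: mean x count = total
  set.seed(5)
  rand <- as.integer(table(sample(200, 1000, replace = TRUE)))
  st2 <- contigStats(rand, 1000)
  expect_equal(st2$mean_ests_per_contig * st2$n_contigs, 1000)
  # degenerate single-contig cases
  expect_equal(contigStats(5L)$singleton_fraction, 0)
  expect_equal(contigStats(1L)$singleton_fraction, 1)
  # total mismatch is an integrity error
  expect_error(contigStats(c(2L, 3L), 6), "integrity")
})

test_that("empty input assembles to an empty ContigSet", {
  ctg <- greedyAssemble(Biostrings::DNAStringSet(character(0)))
  expect_equal(length(ctg), 0L)
  expect_equal(nrow(contigMembers(ctg)), 0L)
})
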