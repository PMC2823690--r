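test_that("quality filter partitions reads by mean Phred score", {
  mk <- function(q, n) {
    s <- Biostrings::DNAStringSet(rep("ACGTACGTACGT", n))
    names(s) <- paste0("q", q, "_", seq_len(n))
    Biostrings::QualityScaledDNAStringSet(
      s, Biostrings::PhredQuality(rep(strrep(rawToChar(as.raw(q + 33L)), 12),
                                      n)))
  }
  hi <- mk(40, 5); lo <- mk(10, 4)
  expect_length(qualityFilter(hi, 20)$removed, 0)
  expect_length(qualityFilter(lo, 20)$kept, 0)
  both <- c(hi, lo)
  qf <- qualityFilter(both, 20)
  expect_setequal(c(names(qf$kept), names(qf$removed)), names(both))
  # plain DNAStringSet: everything kept
  plain <- Biostrings::DNAStringSet(c(a = "ACGT"))
  expect_length(qualityFilter(plain)$removed, 0)
})

test_that("low-quality removal rate matches the simulated fraction", {
  tx <- makeTranscriptome(transcriptomeSpec(n_transcripts = 10, seed = 21))
  sim <- makeReads(tx, cloneSimSpec(n_reads = 5000,
                                    low_quality_fraction = 0.10,
                                    empty_vector_fraction = 0,
                                    short_insert_fraction = 0, seed = 21))
  qf <- qualityFilter(sim$reads, 20)
  frac <- length(qf$removed) / 5000
  expect_gt(frac, 0.09)
  expect_lt(frac, 0.11)
})

test_that("vector clipping recovers exact insert intervals", {
  cfg <- preprocessConfig()
  f5 <- cfg$five_prime_flank; f3 <- cfg$three_prime_flank
  set.seed(17)
  insert <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
  read <- paste0(f5, insert, f3)
  cl <- clipVector(read, cfg)
  expect_true(cl$found_5 && cl$found_3)
  expect_equal(cl$start, nchar(f5) + 1L)
  expect_equal(cl$end, nchar(f5) + nchar(insert))
  # no flank similarity: whole read
  cl2 <- clipVector(insert, cfg)
  expect_false(cl2$found_5 || cl2$found_3)
  expect_equal(c(cl2$start, cl2$end), c(1L, nchar(insert)))
  # empty insert: zero-length interval, both flanks flagged
  cl3 <- clipVector(paste0(f5, f3), cfg)
  expect_true(cl3$found_5 && cl3$found_3)
  expect_equal(cl3$end, cl3$start - 1L)
})

test_that("polyA trimming follows the shared tail rule", {
  expect_equal(trimPolya(paste0("ACGT", strrep("A", 20))),
               list(sequence = "ACGT", had_polya = TRUE))
  expect_equal(trimPolya("ACGT"),
               list(sequence = "ACGT", had_polya = FALSE))
  # tail with one sequencing error is still found (windowed fallback)
  noisy <- paste0(strrep("CGTT", 30), "AAAAAAAAAAGAAAAAAAAAA")
  expect_true(trimPolya(noisy)$had_polya)
})

test_that("error-free reads are clipped exactly back to the truth", {
  tx <- makeTranscriptome(transcriptomeSpec(n_transcripts = 20, seed = 7))
  sim <- makeReads(tx, cloneSimSpec(n_reads = 200, error_rate = 0,
                                    seed = 11))
  pre <- runPreprocess(sim$reads)
  mc <- S4Vectors::mcols(pre$ests)
  idx <- match(names(pre$ests), sim$truth$read_id)
  expect_equal(mc$clip_5, sim$truth$insert_start[idx])
  expect_equal(mc$clip_3, sim$truth$insert_end[idx])
  expect_true(all(mc$had_polya))
})

test_that("flowchart accounting conserves reads and respects min_len", {
  tx <- makeTranscriptome(transcriptomeSpec(n_transcripts = 15, seed = 31))
  sim <- makeReads(tx, cloneSimSpec(n_reads = 2000, error_rate = 0.01,
                                    low_quality_fraction = 0.05,
                                    empty_vector_fraction = 0.10,
                                    short_insert_fraction = 0.02,
                                    seed = 31))
  pre <- runPreprocess(sim$reads)
  cnt <- stats::setNames(pre$counts$count, pre$counts$category)
  expect_equal(cnt[["input"]],
               sum(cnt[c("low_quality", "empty", "short", "kept")]))
  # categories within 3 sd of the binomial expectation
  for (cat in c("low_quality", "empty", "short")) {
    p <- c(low_quality = 0.05, empty = 0.10, short = 0.02)[[cat]]
    expect_lt(abs(cnt[[cat]] - 2000 * p), 3 * sqrt(2000 * p * (1 - p)) + 1)
  }
  expect_true(all(Biostrings::width(pre$ests) >= 100))
  # empty input
  empty <- runPreprocess(Biostrings::DNAStringSet(character(0)))
  expect_true(all(empty$counts$count == 0))
})

test_that("insert length boundary: 99 nt is short, 100 nt is kept", {
  cfg <- preprocessConfig()
  mk <- function(n) paste0(cfg$five_prime_flank,
                           substr(strrep("CGT", 70), 1, n),
                           strrep("A", 20), cfg$three_prime_flank)
  reads <- Biostrings::DNAStringSet(c(r99 = mk(99), r100 = mk(100)))
  pre <- runPreprocess(reads, cfg)
  expect_identical(names(pre$ests), "r100")
  expect_equal(pre$counts$count[pre$counts$category == "short"], 1)
})

test_that("preprocessing is idempotent on its own output", {
  tx <- makeTranscriptome(transcriptomeSpec(n_transcripts = 10, seed = 41))
  sim <- makeReads(tx, cloneSimSpec(n_reads = 150, error_rate = 0.01,
                                    seed = 41))
  pre <- runPreprocess(sim$reads)
  again <- runPreprocess(pre$ests)
  expect_identical(as.character(again$ests), as.character(pre$ests))
  expect_equal(again$counts$count[again$counts$category == "kept"],
               length(pre$ests))
})
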