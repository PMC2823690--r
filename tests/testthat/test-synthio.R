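test_that("transcriptome generation is deterministic and well-formed", {
  spec <- transcriptomeSpec(n_transcripts = 25, seed = 5)
  a <- makeTranscriptome(spec)
  b <- makeTranscriptome(spec)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$weights, b$weights)
  w <- Biostrings::width(a$sequences)
  expect_true(all(w >= 300 & w <= 1500))
  expect_equal(sum(a$weights), 1)
  one <- makeTranscriptome(transcriptomeSpec(n_transcripts = 1, seed = 1))
  expect_length(one$sequences, 1)
  expect_equal(unname(one$weights), 1)
})

test_that("extreme abundance skew concentrates reads on the top transcript", {
  tx <- makeTranscriptome(transcriptomeSpec(n_transcripts = 30,
                                            abundance_skew = 12, seed = 9))
  sim <- makeReads(tx, cloneSimSpec(n_reads = 10000, error_rate = 0,
                                    empty_vector_fraction = 0,
                                    short_insert_fraction = 0,
                                    low_quality_fraction = 0, seed = 9))
  share <- mean(sim$truth$transcript_id == "T0001")
  expect_gte(share, 0.95)
})

test_that("invalid generator specifications are configuration errors", {
  expect_error(transcriptomeSpec(length_min = 150), "200")
  expect_error(transcriptomeSpec(n_transcripts = 0), "count")
  expect_error(cloneSimSpec(error_rate = 0.5), "error_rate")
  expect_error(cloneSimSpec(empty_vector_fraction = 0.7,
                            short_insert_fraction = 0.4), "sum")
  expect_error(makeDensitometry("g1", timepoints = c(4, 7)), "day 0")
})

test_that("read simulation honours category structure and truth table", {
  tx <- makeTranscriptome(transcriptomeSpec(n_transcripts = 15, seed = 3))
  spec <- cloneSimSpec(n_reads = 400, error_rate = 0, seed = 3)
  sim <- makeReads(tx, spec)
  expect_equal(nrow(sim$truth), 400)
  expect_identical(names(sim$reads), sim$truth$read_id)
  # conservation: categories partition the reads
  expect_equal(sum(table(sim$truth$category)), 400)
  # error-free: every truth insert is an exact substring of its source
  good <- sim$truth[sim$truth$category %in% c("good", "short"), ]
  reads <- as.character(sim$reads)
  for (i in sample(nrow(good), 50)) {
    r <- good[i, ]
    insert <- substr(reads[[r$read_id]], r$insert_start, r$insert_end)
    expect_identical(insert,
                     substr(as.character(tx$sequences[[r$transcript_id]]),
                            r$t_start, r$t_end))
  }
  # determinism
  sim2 <- makeReads(tx, spec)
  expect_identical(as.character(sim$reads), as.character(sim2$reads))
  expect_identical(sim$truth, sim2$truth)
  # n_reads = 0 is an empty result, not an error
  none <- makeReads(tx, cloneSimSpec(n_reads = 0, seed = 1))
  expect_length(none$reads, 0)
  expect_equal(nrow(none$truth), 0)
})

test_that("all-empty-vector libraries are fully discarded by preprocessing", {
  tx <- makeTranscriptome(transcriptomeSpec(n_transcripts = 5, seed = 2))
  sim <- makeReads(tx, cloneSimSpec(n_reads = 40,
                                    empty_vector_fraction = 1,
                                    short_insert_fraction = 0,
                                    low_quality_fraction = 0, seed = 2))
  pre <- runPreprocess(sim$reads)
  expect_equal(pre$counts$count[pre$counts$category == "kept"], 0)
  expect_equal(pre$counts$count[pre$counts$category == "empty"], 40)
})

test_that("reads round-trip through FASTQ", {
  tx <- makeTranscriptome(transcriptomeSpec(n_transcripts = 5, seed = 8))
  sim <- makeReads(tx, cloneSimSpec(n_reads = 20, seed = 8))
  f <- tempfile(fileext = ".fastq")
  writeReadsFastq(sim$reads, f)
  back <- readReads(f, "fastq")
  expect_identical(as.character(back), as.character(sim$reads))
  expect_identical(as.character(Biostrings::quality(back)),
                   as.character(Biostrings::quality(sim$reads)))
})

test_that("synthetic GO worlds are valid, deterministic and nested", {
  world <- testWorld()
  dag <- world$dag
  expect_s4_class(dag, "GODag")
  expect_length(goRoots(dag), 3)
  # determinism of the emitted OBO text
  w2 <- makeGoWorld(n_terms_per_ns = 40L, depth = 4L, n_proteins = 400L,
                    seed = 202L)
  f1 <- tempfile(); f2 <- tempfile()
  writeObo(world$dag, f1); writeObo(w2$dag, f2)
  expect_identical(readLines(f1), readLines(f2))
  # every protein maps to at least one term; nesting: a term never has
  # more proteins than any of its ancestors
  expect_true(all(table(world$mapping$protein_id) >= 1))
  prop <- world$baseline
  for (id in goTerms(dag)$id) {
    for (p in goParents(dag)[[id]]) {
      expect_lte(length(propagatedProteins(prop, id)),
                 length(propagatedProteins(prop, p)))
    }
  }
  # star world: depth 1 propagates straight to the roots
  star <- makeGoWorld(n_terms_per_ns = 6L, depth = 1L, n_proteins = 30L,
                      seed = 4L)
  for (id in goTerms(star$dag)$id) {
    ps <- goParents(star$dag)[[id]]
    expect_true(length(ps) == 0L || all(ps %in% goRoots(star$dag)))
  }
})

test_that("planted enrichment scenarios deliver the requested fold", {
  world <- testWorld()
  term <- plantableTerm(world)
  # fold 1 everywhere: measured fold stays near 1 on average
  folds <- vapply(1:60, function(i) {
    sc <- makeEnrichmentScenario(world, stats::setNames(1, term),
                                 n_dataset_proteins = 400, seed = 300 + i)
    foldAccumulation(sc$annotation_set, world$baseline, term)$fold
  }, numeric(1))
  expect_gt(mean(folds), 0.8)
  expect_lt(mean(folds), 1.2)
  # an impossible fold is a configuration error
  expect_error(makeEnrichmentScenario(world, stats::setNames(1000, term)),
               "exceed")
  expect_error(makeEnrichmentScenario(world, c(BOGUS = 2)), "exist")
})

test_that("densitometry tables have planted structure and full truth", {
  d <- makeDensitometry(c("g1", "g2"), n_pools = 3,
                        effects = list(g1 = c(1, 0.5, 1, 1, 1)),
                        noise_sd = 0, seed = 6)
  # genes (incl. control) x 5 timepoints x 3 pools
  expect_equal(nrow(d$table), 3 * 5 * 3)
  prof <- foldChangeProfile(d$table, d$control_gene)
  expect_equal(prof$fold[prof$gene == "g1" & prof$timepoint == 4], 0.5)
  expect_true(all(prof$fold[prof$gene == "g2"] == 1))
})
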