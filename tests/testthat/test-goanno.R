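test_that("OBO parsing handles chains, round trips, and rejects cycles", {
  f <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: mid",
    "namespace: biological_process",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf",
    "namespace: biological_process",
    "is_a: GO:0000002", "",
    "[Term]", "id: GO:0000009", "name: gone",
    "namespace: biological_process",
    "is_a: GO:0000001", "is_obsolete: true", ""), f)
  dag <- readObo(f)
  expect_equal(nrow(goTerms(dag)), 3)   # obsolete dropped
  expect_equal(sum(lengths(goParents(dag))), 2)
  expect_equal(goAncestors(dag, "GO:0000003")[[1]],
               c("GO:0000002", "GO:0000001"))
  # synthetic world round-trips exactly
  world <- testWorld()
  f2 <- tempfile(fileext = ".obo")
  writeObo(world$dag, f2)
  back <- readObo(f2)
  expect_equal(goTerms(back), goTerms(world$dag))
  expect_equal(goParents(back), goParents(world$dag))
  # a cycle is a format error naming the terms
  writeLines(c(
    "[Term]", "id: GO:1", "name: a", "namespace: biological_process",
    "is_a: GO:2", "",
    "[Term]", "id: GO:2", "name: b", "namespace: biological_process",
    "is_a: GO:1", ""), f)
  expect_error(readObo(f), "cycle")
})

test_that("protein identifier assignment applies both gates in rank order", {
  mk_hit <- function(q, s, e, bits, len = 120L) {
    data.frame(qseqid = q, sseqid = s, pident = 90, length = len,
               mismatch = 2L, gapopen = 0L, qstart = 1L, qend = len,
               sstart = 1L, send = ceiling(len / 3),
               evalue = e, bitscore = bits, algorithm = "blastx",
               subject_description = s, taxon_class = "mammalian",
               stringsAsFactors = FALSE)
  }
  # e-value gate passes regardless of score
  h1 <- mk_hit("Q1", "P1", 1e-25, 40)
  expect_equal(assignProteinIds(h1)[["Q1"]], "P1")
  # both gates fail
  h2 <- mk_hit("Q1", "P2", 1e-10, 40)
  expect_length(assignProteinIds(h2), 0)
  # sigma gate rescues a weak e-value with a strong normalized score
  h3 <- mk_hit("Q1", "P3", 1e-10, 500)
  expect_equal(assignProteinIds(h3)[["Q1"]], "P3")
  # top_k truncation in rank order
  hits <- do.call(rbind, lapply(1:60, function(i)
    mk_hit("Q2", sprintf("P%03d", i), 10^(-30 - i), 100)))
  ids <- assignProteinIds(hits, goAssignConfig(top_k = 50))[["Q2"]]
  expect_length(ids, 50)
  expect_equal(ids[1], "P060")   # smallest e-value first
  # loosening e_cutoff never removes an identifier (monotonicity)
  strict <- assignProteinIds(hits, goAssignConfig(e_cutoff = 1e-40))
  loose <- assignProteinIds(hits, goAssignConfig(e_cutoff = 1e-20))
  expect_true(all(strict[["Q2"]] %in% loose[["Q2"]]))
})

test_that("true-path propagation equals the brute-force union oracle", {
  # hand toy DAG: protein at two sibling leaves counted once above
  parents <- list("GO:r" = character(0), "GO:a" = "GO:r",
                  "GO:b" = "GO:r", "GO:a1" = "GO:a",
                  "GO:a2" = "GO:a", "GO:ab" = c("GO:a", "GO:b"))
  terms <- data.frame(id = names(parents),
                      name = names(parents),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  dag <- new("GODag", terms = terms, parents = parents)
  direct <- list("GO:a1" = "p1", "GO:a2" = c("p1", "p2"),
                 "GO:ab" = "p3")
  ann <- propagateAnnotations(dag, direct)
  want <- oraclePropagate(parents, direct)
  for (t in names(parents))
    expect_setequal(propagatedProteins(ann, t), want[[t]])
  expect_setequal(propagatedProteins(ann, "GO:a"), c("p1", "p2", "p3"))
  expect_setequal(propagatedProteins(ann, "GO:r"), c("p1", "p2", "p3"))
  # single protein at a leaf reaches every ancestor and the root
  ann1 <- propagateAnnotations(dag, list("GO:a1" = "x"))
  for (t in c("GO:a1", "GO:a", "GO:r"))
    expect_equal(propagatedProteins(ann1, t), "x")
  expect_length(propagatedProteins(ann1, "GO:b"), 0)
  # empty direct map: everything empty
  ann0 <- propagateAnnotations(dag, list())
  expect_true(all(lengths(ann0@propagated) == 0))
  # unknown term id errors, listing the id
  expect_error(propagateAnnotations(dag, list("GO:nope" = "p")), "GO:nope")
})

test_that("propagation matches the oracle on a generated world", {
  world <- makeGoWorld(n_terms_per_ns = 25L, depth = 3L,
                       n_proteins = 60L, seed = 55L)
  dag <- world$dag
  ann <- world$baseline
  direct <- lapply(split(world$mapping$protein_id, world$mapping$go_id),
                   unique)
  direct_full <- stats::setNames(vector("list", nrow(goTerms(dag))),
                                 goTerms(dag)$id)
  direct_full[names(direct)] <- direct
  want <- oraclePropagate(goParents(dag), direct_full)
  for (t in goTerms(dag)$id)
    expect_setequal(propagatedProteins(ann, t), want[[t]])
  # true-path count monotonicity along every edge
  for (id in goTerms(dag)$id)
    for (p in goParents(dag)[[id]])
      expect_lte(length(propagatedProteins(ann, id)),
                 length(propagatedProteins(ann, p)))
})

test_that("summary counts tally namespaces and taxa like a hand count", {
  world <- testWorld()
  taxon_of <- tapply(world$mapping$taxon_class, world$mapping$protein_id,
                     `[[`, 1L)
  sm <- summaryCounts(world$baseline, world$dag, taxon_of)
  expect_equal(nrow(sm$domains), 3)
  for (ns in sm$domains$namespace) {
    ids <- goTerms(world$dag)$id[goTerms(world$dag)$namespace == ns]
    want <- sum(vapply(ids, function(t)
      length(directProteins(world$baseline, t)) > 0, logical(1)))
    expect_equal(sm$domains$n_terms[sm$domains$namespace == ns], want)
  }
  expect_equal(sum(sm$taxa$count[sm$taxa$taxon_class != "All Organisms"]),
               sm$taxa$count[sm$taxa$taxon_class == "All Organisms"])
  expect_equal(sum(sm$taxa$percentage[
    sm$taxa$taxon_class != "All Organisms"]), 100, tolerance = 1e-9)
})
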