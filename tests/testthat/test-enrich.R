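test_that("fold accumulation is the ratio of dataset and baseline ratios", {
  # direct arithmetic through the AnnotationSet interface
  mkAnn <- function(k, N, term, root) {
    direct <- list()
    direct[[term]] <- sprintf("p%03d", seq_len(k))
    direct[[root]] <- sprintf("p%03d", seq_len(N))
    parents <- stats::setNames(list(character(0), root), c(root, term))
    terms <- data.frame(id = c(root, term), name = c(root, term),
                        namespace = "biological_process",
                        stringsAsFactors = FALSE)
    dag <- new("GODag", terms = terms, parents = parents)
    list(dag = dag, ann = propagateAnnotations(dag, direct))
  }
  a <- mkAnn(10, 100, "GO:t", "GO:bp")
  b <- mkAnn(10, 1000, "GO:t", "GO:bp")
  fa <- foldAccumulation(a$ann, b$ann, "GO:t")
  expect_equal(fa$fold, 10)
  expect_equal(fa[, c("k_ds", "N_ds", "k_base", "N_base")],
               data.frame(k_ds = 10L, N_ds = 100L, k_base = 10L,
                          N_base = 1000L))
  # equal ratios give fold 1
  fa1 <- foldAccumulation(a$ann, a$ann, "GO:t")
  expect_equal(fa1$fold, 1)
  # k_base = 0: infinite fold, flagged undefined
  c0 <- mkAnn(0, 50, "GO:t", "GO:bp")
  fa0 <- foldAccumulation(a$ann, c0$ann, "GO:t")
  expect_true(is.infinite(fa0$fold))
  expect_false(fa0$defined)
  # fold invariant under scaling both datasets by a common factor
  a3 <- mkAnn(30, 300, "GO:t", "GO:bp")
  b3 <- mkAnn(30, 3000, "GO:t", "GO:bp")
  expect_equal(foldAccumulation(a3$ann, b3$ann, "GO:t")$fold, fa$fold)
})

test_that("chi-square equals the closed-form oracle on an exhaustive grid", {
  grid <- expand.grid(N1 = 1:10, N2 = 1:10, f1 = seq(0, 1, 0.1),
                      f2 = seq(0, 1, 0.1))
  grid$k1 <- floor(grid$N1 * grid$f1)
  grid$k2 <- floor(grid$N2 * grid$f2)
  grid <- unique(grid[, c("k1", "N1", "k2", "N2")])
  got <- chiSquare2x2(grid$k1, grid$N1, grid$k2, grid$N2)
  want <- mapply(function(k1, N1, k2, N2) {
    a <- k1; b <- N1 - k1; c <- k2; d <- N2 - k2
    if ((a + c) == 0 || (b + d) == 0) NA_real_
    else oracleChi2(a, b, c, d)
  }, grid$k1, grid$N1, grid$k2, grid$N2)
  expect_equal(got$computable, !is.na(want))
  expect_equal(got$chi2[got$computable], want[!is.na(want)],
               tolerance = 1e-12)
  # identical proportions: chi2 = 0, p = 1
  z <- chiSquare2x2(10, 100, 100, 1000)
  expect_equal(z$chi2, 0)
  expect_equal(z$p_value, 1)
  # spot check against the standard library implementation
  got <- chiSquare2x2(10, 100, 10, 1000)
  ref <- suppressWarnings(stats::chisq.test(
    matrix(c(10, 90, 10, 990), nrow = 2, byrow = TRUE), correct = FALSE))
  expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_error(chiSquare2x2(5, 3, 1, 10), "0 <= k <= N")
})

test_that("null chi-square rejection rate is calibrated at alpha", {
  world <- testWorld()
  term <- plantableTerm(world)
  root <- goRoots(world$dag)[["biological_process"]]
  pool <- propagatedProteins(world$baseline, root)
  p <- length(propagatedProteins(world$baseline, term)) / length(pool)
  # null: both annotation samples share the term probability p
  set.seed(881)
  n_rep <- 1000; n_ds <- 600; n_base <- 2000
  k_ds <- stats::rbinom(n_rep, n_ds, p)
  k_base <- stats::rbinom(n_rep, n_base, p)
  res <- chiSquare2x2(k_ds, rep(n_ds, n_rep), k_base,
                      rep(n_base, n_rep))
  rate <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("planted 10-fold terms are recovered with high power", {
  world <- testWorld()
  term <- plantableTerm(world)
  hits <- 0; folds <- numeric(0)
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    sc <- makeEnrichmentScenario(world, stats::setNames(10, term),
                                 n_dataset_proteins = 600,
                                 seed = 4000 + i)
    en <- goEnrichment(sc$annotation_set, world$baseline, world$dag,
                       terms = term,
                       filter = enrichFilter(min_counts = c(8L, 3L),
                                             fold_threshold = 10))
    folds <- c(folds, en$fold)
    # recovery = the planted term passes the count screen and is
    # chi-square significant (the fold >= 10 flag alone is a coin flip
    # when the true fold sits exactly on the threshold)
    if (en$passes_counts && !is.na(en$p_value) && en$p_value < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 95)
  expect_gte(mean(folds), 8)
  expect_lte(mean(folds), 12)
})

test_that("without planted enrichment no term passes the 10-fold screen", {
  world <- testWorld()
  clean <- 0
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    sc <- makeEnrichmentScenario(world, numeric(0),
                                 n_dataset_proteins = 600,
                                 seed = 7000 + i)
    en <- goEnrichment(sc$annotation_set, world$baseline, world$dag,
                       filter = enrichFilter(min_counts = c(8L, 3L),
                                             fold_threshold = 10))
    if (!any(en$enriched)) clean <- clean + 1
  }
  expect_gte(clean, 95)
})

test_that("the enrichment screen combines fold and minimum counts", {
  res <- data.frame(term = c("a", "b", "c"),
                    k_ds = c(54L, 2L, 20L), k_ds2 = c(18L, 5L, 2L),
                    fold = c(10.4, 25, 12))
  out <- selectEnriched(res, enrichFilter(min_counts = c(8L, 3L),
                                          fold_threshold = 10))
  expect_equal(out$enriched, c(TRUE, FALSE, FALSE))
  # without the second dataset column only the first minimum applies
  out2 <- selectEnriched(res[, c("term", "k_ds", "fold")],
                         enrichFilter(min_counts = c(8L, 3L)))
  expect_equal(out2$enriched, c(TRUE, FALSE, TRUE))
})
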