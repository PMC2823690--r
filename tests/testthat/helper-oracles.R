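# Independent oracles used against the package implementations. These
# deliberately use naive algorithms (recursive walks, explicit O/E sums)
# so they share no code path with the functions under test.

# recursive ancestor closure from a raw parent list (excluding self)
oracleAncestors <- function(parents, id) {
  seen <- character(0)
  walk <- function(x) {
    for (p in parents[[x]]) {
      if (!p %in% seen) {
        seen <<- c(seen, p)
        walk(p)
      }
    }
  }
  walk(id)
  sort(unique(seen))
}

# brute-force true-path propagation: propagated[t] = union of direct
# proteins over every descendant d of t (including t itself)
oraclePropagate <- function(parents, direct) {
  ids <- names(parents)
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (t in ids) {
    prot <- character(0)
    for (d in ids) {
      if (d == t || t %in% oracleAncestors(parents, d))
        prot <- c(prot, direct[[d]])
    }
    out[[t]] <- sort(unique(prot))
  }
  out
}

# textbook Pearson chi-square: sum over cells of (O - E)^2 / E with
# expectations from the margins
oracleChi2 <- function(a, b, c, d) {
  O <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  sum((O - E)^2 / E)
}

# a small fixed GO world shared by annotation/enrichment tests (cached:
# building it is not free and its content is deterministic)
.world_cache <- new.env(parent = emptyenv())
testWorld <- function(seed = 202L) {
  key <- paste0("w", seed)
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- makeGoWorld(n_terms_per_ns = 40L, depth = 4L,
                                       n_proteins = 400L, seed = seed)
  .world_cache[[key]]
}

# a biological_process term of the test world with baseline ratio small
# enough to plant a 10-fold enrichment
plantableTerm <- function(world, max_ratio = 0.08, min_ratio = 0.01) {
  root <- goRoots(world$dag)[["biological_process"]]
  pool <- propagatedProteins(world$baseline, root)
  bp <- goTerms(world$dag)
  bp <- bp$id[bp$namespace == "biological_process"]
  ratios <- vapply(bp, function(t)
    length(propagatedProteins(world$baseline, t)) / length(pool),
    numeric(1))
  ok <- ratios >= min_ratio & ratios <= max_ratio
  stopifnot(any(ok))
  names(sort(ratios[ok], decreasing = TRUE))[[1L]]
}
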