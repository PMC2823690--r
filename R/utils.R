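## Internal helpers shared across modules: local RNG scoping, child-seed
## fan-out, random DNA, and the polyA window rule (shared by preprocessing
## and full-length calling so both apply the identical definition).

#' Evaluate an expression with a locally scoped RNG seed
#'
#' The global \code{.Random.seed} is saved and restored so generators are
#' pure functions of their \code{seed} argument and never perturb the
#' caller's random stream.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

## One global integer seed fans out to per-generator child seeds by fixed
## offsets; kept below 2^31 - 1.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483646) + 1L
}

DNA_BASES4 <- c("A", "C", "G", "T")

## Random DNA of length n at a given GC fraction; returns a single string.
randomDna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

## Substitution-only sequencing error model: each base mutates to one of
## the three other bases with probability `rate`.
mutateDna <- function(x, rate) {
  if (rate <= 0 || nchar(x) == 0L) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(DNA_BASES4, ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## polyA tail rule, shared by trimPolya() and detectPolya(). Two stages:
## (1) a maximal terminal run of pure A of length >= min_run defines the
## tail exactly (this is the error-free case and never eats into the
## insert); (2) otherwise, within the last `window` nt, the leftmost
## position s whose suffix s..end is >= min_run long and >= min_frac
## adenine (error-tolerant fallback). Returns the 1-based start of the
## tail, or NA if neither stage fires.
polyaStart <- function(sequence, window = 50L, min_run = 10L, min_frac = 0.9) {
  n <- nchar(sequence)
  if (n < min_run) return(NA_integer_)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  run <- 0L
  while (run < n && ch[n - run] == "A") run <- run + 1L
  if (run >= min_run) return(n - run + 1L)
  lo <- max(1L, n - window + 1L)
  isA <- as.integer(ch == "A")
  sufA <- rev(cumsum(rev(isA)))
  for (s in lo:(n - min_run + 1L)) {
    len <- n - s + 1L
    if (sufA[s] / len >= min_frac) return(s)
  }
  NA_integer_
}

## k-mer starts of a character sequence, as a named integer vector
## (kmer -> first position) or full list of positions.
kmerPositions <- function(x, k = 16L) {
  n <- nchar(x)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  kms <- substring(x, starts, starts + k - 1L)
  split(starts, kms)
}

## Ungapped identity between two character vectors over aligned region.
## a[i] vs b[i + d]; returns list(overlap, identity) or NULL if overlap
## shorter than `min_overlap`.
offsetOverlap <- function(a, b, d, min_overlap) {
  la <- length(a); lb <- length(b)
  i1 <- max(1L, 1L - d); i2 <- min(la, lb - d)
  ov <- i2 - i1 + 1L
  if (ov < min_overlap) return(NULL)
  idx <- i1:i2
  idn <- sum(a[idx] == b[idx + d]) / ov
  list(overlap = ov, identity = idn, from = i1, to = i2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnotScalarCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop(sprintf("'%s' must be a single count >= %d", name, min), call. = FALSE)
}
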