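# Shared fixtures and independent oracles for the test suite.

# Build a PeakSet directly from summit positions (one chromosome unless
# chrom is a vector).
ps_from_summits <- function(summits, factor = "A", cell_line = "K562",
                            chrom = "chr1", ...) {
  summits <- as.integer(summits)
  peak_set(data.frame(chrom = rep_len(chrom, length(summits)),
                      start = pmax(summits - 75L, 0L),
                      end = summits + 75L,
                      name = if (length(summits)) {
                        sprintf("%s_%d", factor, seq_along(summits))
                      } else character(0),
                      signal = rep(1, length(summits)), summit = summits,
                      stringsAsFactors = FALSE),
           factor = factor, cell_line = cell_line, ...)
}

# O(n^2) brute-force oracle for count_overlap: number of a-summits with some
# b-summit within half_window on the same chromosome.
brute_count <- function(a, b, half_window = 150L) {
  pa <- a$peaks; pb <- b$peaks
  sum(vapply(seq_len(nrow(pa)), function(i) {
    any(pb$chrom == pa$chrom[i] &
          abs(pb$summit - pa$summit[i]) <= half_window)
  }, TRUE))
}

# Direct-summation oracle for the Poisson upper/lower tail.
poisson_tail_oracle <- function(k, lambda, upper = TRUE) {
  if (upper) {
    kmax <- max(k + 50L, ceiling(lambda + 40 * sqrt(lambda) + 50))
    sum(stats::dpois(k:kmax, lambda))
  } else {
    sum(stats::dpois(0:k, lambda))
  }
}

# Enumeration oracle for the one-sided hypergeometric upper tail:
# P(X >= q) with m pathway genes, N universe, k targets.
hyper_tail_oracle <- function(q, m, N, k) {
  support <- max(0L, k - (N - m)):min(k, m)
  sum(stats::dhyper(support[support >= q], m, N - m, k))
}

# Enumeration oracle for the two-sided Fisher exact test by the
# point-probability method on a 2x2 table.
fisher_twosided_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0L, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

# A tiny but complete JASPAR text fixture written on the fly.
write_jaspar_fixture <- function(path) {
  writeLines(c(
    ">MA0060.1 NFYA",
    "A [ 3 2 94 91 2 42 25 20 40 30 20 55 25 30 25 26 ]",
    "C [ 92 94 2 3 4 23 30 40 20 20 40 15 25 20 30 24 ]",
    "G [ 2 3 2 2 2 20 25 20 20 35 20 15 30 25 20 25 ]",
    "T [ 3 1 2 4 92 15 20 20 20 15 20 15 20 25 25 25 ]",
    ">MA0099.1 FOS::JUN",
    "A [ 10 2 80 2 60 2 10 ]",
    "C [ 10 6 4 2 10 90 20 ]",
    "G [ 70 2 12 90 20 4 30 ]",
    "T [ 10 90 4 6 10 4 40 ]"), path)
  path
}
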