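# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (all-pairs loops, substring search, explicit summation)
# so the package's index-based fast paths are checked against a different
# route.

PROBE_LEN <- 25L

# random pool of distinct probes, independent of the package's generators
rand_probe_pool <- function(n, len = PROBE_LEN) {
  pool <- character(0)
  while (length(pool) < n) {
    cand <- replicate(n - length(pool) + 4L,
                      paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                             collapse = ""))
    pool <- unique(c(pool, cand))
  }
  pool[seq_len(n)]
}

# random catalog drawn from a small probe pool so sharing/containment happens
# by chance; returns a probe_catalog
random_shared_catalog <- function(n_sets, pool_size = 30L, max_probes = 8L) {
  pool <- rand_probe_pool(pool_size)
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(pool, sample.int(min(max_probes, length(pool)), 1L))
  })
  names(sets) <- sprintf("S%02d", seq_len(n_sets))
  probe_catalog(sets, min_set_size = 1L)
}

# all-pairs subset test
oracle_subset_sets <- function(catalog) {
  ps <- catalog$probe_sets
  ids <- names(ps)
  out <- list()
  for (a in ids) {
    sup <- ids[vapply(ids, function(b) {
      b != a && all(ps[[a]] %in% ps[[b]])
    }, logical(1))]
    if (length(sup) > 0L) out[[a]] <- sort(sup)
  }
  out
}

# per-set unique-probe counts by pairwise comparison against all other sets
oracle_unique_counts <- function(catalog) {
  ps <- catalog$probe_sets
  ids <- names(ps)
  vapply(ids, function(a) {
    others <- unique(unlist(ps[setdiff(ids, a)], use.names = FALSE))
    sum(!(ps[[a]] %in% others))
  }, integer(1))
}

# naive hybridization: substring-search every probe in every sample sequence
oracle_hybridize_counts <- function(catalog, sample) {
  vapply(catalog$probe_sets, function(probes) {
    sum(vapply(probes, function(p) {
      any(vapply(sample, function(s) grepl(p, s, fixed = TRUE), logical(1)))
    }, logical(1)))
  }, integer(1))
}

# upper-tail hypergeometric by explicit summation of the mass function
oracle_hyper_upper <- function(N, K, n, k) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# hand-sized three-set catalog used across I/O and uniqueness tests:
# A and B share probe p1; C is disjoint
tiny_catalog <- function() {
  p <- rand_probe_pool(5L)
  probe_catalog(list(A = c(p[1], p[2]), B = c(p[1], p[3]), C = c(p[4], p[5])),
                min_set_size = 1L)
}

expect_same_catalog <- function(a, b) {
  expect_identical(a$probe_sets, b$probe_sets)
  expect_identical(a$source_sequences, b$source_sequences)
}
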