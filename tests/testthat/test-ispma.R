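# In-silico hybridization: k-mer decomposition, presence calls, tracing.

test_that("kmerize enumerates windows at step 1 and skips ambiguous ones", {
  k4 <- kmerize("ACGTACGT", k = 4)
  expect_identical(as.character(k4), c("ACGT", "CGTA", "GTAC", "TACG", "ACGT"))
  expect_identical(attr(k4, "n_skipped"), 0L)

  # windows overlapping the N are skipped and counted
  kn <- kmerize("ACGNACGT", k = 4)
  expect_identical(as.character(kn), "ACGT")
  expect_identical(attr(kn, "n_skipped"), 4L)

  expect_length(kmerize(strrep("A", 25), k = 25), 1L)
  expect_length(kmerize("ACG", k = 25), 0L)
  expect_identical(as.character(kmerize("acgt", k = 4)), "ACGT")
})

test_that("hybridize matches naive substring search on shared synthetic catalogs", {
  for (seed in 401:404) {
    set.seed(seed)
    g <- generate_catalog(generator_config(
      n_sets = 15L, set_size_min = 4L, set_size_max = 10L,
      n_subset_pairs = 2L, n_zero_unique = 1L, sharing_intensity = 0.3,
      shared_pool_size = 40L, seed = seed))
    refs <- generate_references(g$catalog, seed = seed + 1000L)
    sample_ids <- sort(sample(names(refs), 6L))
    rep1 <- hybridize(g$catalog, refs[sample_ids])
    want <- oracle_hybridize_counts(g$catalog, refs[sample_ids])
    expect_identical(setNames(rep1$n_matched, rep1$otu_id), want)
    # presence calls follow the strict comparator
    expect_identical(rep1$present_0.95, rep1$match_fraction > 0.95)
  }
})

test_that("self-hybridization of a disjoint catalog detects exactly the sample", {
  set.seed(405)
  g <- generate_catalog(generator_config(
    n_sets = 12L, set_size_min = 5L, set_size_max = 9L, n_subset_pairs = 0L,
    n_zero_unique = 0L, sharing_intensity = 0, shared_pool_size = 0L,
    seed = 405))
  refs <- generate_references(g$catalog, seed = 406)
  comm <- sort(sample(names(refs), 5L))
  rep1 <- hybridize(g$catalog, refs[comm])
  for (t in attr(rep1, "thresholds")) {
    expect_identical(detected_otus(rep1, t), comm)
  }
  expect_true(all(rep1$match_fraction[rep1$otu_id %in% comm] == 1))
  expect_true(all(rep1$match_fraction[!rep1$otu_id %in% comm] == 0))
})

test_that("match fractions are monotone in the sample and presence in the threshold", {
  set.seed(407)
  g <- generate_catalog(generator_config(
    n_sets = 10L, set_size_min = 4L, set_size_max = 8L, n_subset_pairs = 1L,
    n_zero_unique = 1L, sharing_intensity = 0.4, shared_pool_size = 30L,
    seed = 407))
  refs <- generate_references(g$catalog, seed = 408)
  small <- hybridize(g$catalog, refs[1:3], thresholds = c(0.5, 0.9, 0.95))
  big <- hybridize(g$catalog, refs[1:5], thresholds = c(0.5, 0.9, 0.95))
  expect_true(all(big$match_fraction >= small$match_fraction))
  expect_true(all(detected_otus(big, 0.95) %in% detected_otus(big, 0.9)))
  expect_true(all(detected_otus(big, 0.9) %in% detected_otus(big, 0.5)))
})

test_that("comparator and strand options behave as documented", {
  set.seed(409)
  p <- rand_probe_pool(4L)
  cat1 <- probe_catalog(list(A = p[1:2], B = p[3:4]), min_set_size = 1L)
  smp <- c(s1 = paste0(p[1], "AC", p[2]))
  gt <- hybridize(cat1, smp, thresholds = 1)
  geq <- hybridize(cat1, smp, thresholds = 1, comparator = "geq")
  expect_false(gt$present_1[gt$otu_id == "A"])    # 2/2 not > 1
  expect_true(geq$present_1[geq$otu_id == "A"])   # 2/2 >= 1

  # reverse-complement lookup finds probes on the opposite strand
  smp_rc <- c(s1 = revcomp_dna(paste0(p[3], "GG", p[4])))
  fwd <- hybridize(cat1, smp_rc)
  rc <- hybridize(cat1, smp_rc, revcomp = TRUE)
  expect_identical(fwd$n_matched[fwd$otu_id == "B"], 0L)
  expect_identical(rc$n_matched[rc$otu_id == "B"], 2L)

  expect_warning(empty <- hybridize(cat1, setNames(character(0), character(0))),
                 "empty sample")
  expect_true(all(empty$n_matched == 0L))
})

test_that("community comparison tallies missed and spurious groups per threshold", {
  # planted: input families F1,F2; detected families F2,F3
  tax <- data.frame(otu_id = c("o1", "o2", "o3", "o4"),
                    domain = "Bacteria", phylum = "P", class = "C",
                    order = "O",
                    family = c("F1", "F2", "F2", "F3"),
                    genus = "G", stringsAsFactors = FALSE)
  set.seed(410)
  p <- rand_probe_pool(8L)
  cat1 <- probe_catalog(list(o1 = p[1:2], o2 = p[3:4], o3 = p[5:6],
                             o4 = p[7:8]), min_set_size = 1L)
  smp <- c(x = paste0(p[3], p[4], p[7], p[8]))   # matches o2 and o4 fully
  rep1 <- hybridize(cat1, smp, thresholds = 0.95)
  cc <- compare_communities(c("o1", "o2", "o3"), rep1, tax)
  b <- cc$by_threshold[["0.95"]]
  expect_identical(b$detected_otus, c("o2", "o4"))
  expect_identical(b$missed_groups, "F1")
  expect_identical(b$spurious_groups, "F3")
  expect_identical(b$group_counts$group, c("F1", "F2", "F3"))
  expect_identical(b$group_counts$n_input, c(1L, 2L, 0L))
  expect_identical(b$group_counts$n_detected, c(0L, 1L, 1L))

  # identity: input == detected leaves nothing missed or spurious
  cc2 <- compare_communities(c("o2", "o4"), rep1, tax)
  expect_length(cc2$by_threshold[["0.95"]]$missed_groups, 0L)
  expect_length(cc2$by_threshold[["0.95"]]$spurious_groups, 0L)

  # OTUs absent from the taxonomy bucket as unclassified
  cc3 <- compare_communities("o9", rep1, tax)
  expect_true("unclassified" %in% cc3$by_threshold[["0.95"]]$missed_groups)
})

test_that("trace_target attributes every matched probe to sequences and sharers", {
  set.seed(411)
  p <- rand_probe_pool(6L)
  cat1 <- probe_catalog(list(T = p[1:3], D1 = c(p[1], p[4]),
                             D2 = c(p[2], p[5])), min_set_size = 1L)
  # target absent; donors supply two of its three probes
  smp <- c(d1 = paste0(p[1], "AAGG", p[4]), d2 = paste0(p[2], p[5]))
  tr <- trace_target(cat1, smp, "T")
  expect_identical(sort(tr$probe), sort(p[1:2]))
  expect_identical(tr$sample_ids[[which(tr$probe == p[1])]], "d1")
  expect_identical(tr$other_otus[[which(tr$probe == p[1])]], "D1")
  # trace explains n_matched exactly
  rep1 <- hybridize(cat1, smp)
  expect_identical(nrow(tr), rep1$n_matched[rep1$otu_id == "T"])

  expect_identical(nrow(trace_target(cat1, setNames(character(0), character(0)),
                                     "T")), 0L)
  expect_error(trace_target(cat1, smp, "zz"), "unknown target")

  # self-hybridization traces every probe to the target's own sequence
  self_seq <- c(T = paste0(p[1], "AC", p[2], "GT", p[3]))
  tr2 <- trace_target(cat1, self_seq, "T")
  expect_identical(sort(tr2$probe), sort(p[1:3]))
  expect_true(all(vapply(tr2$sample_ids, identical, logical(1), "T")))
})
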