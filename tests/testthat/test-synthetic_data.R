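# Generators: determinism, feasibility guards, planted structure, and the
# statistical behaviour of the simulated abundances and detections.

small_cfg <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_sets = 14L, set_size_min = 4L, set_size_max = 10L,
         n_subset_pairs = 2L, n_zero_unique = 2L, sharing_intensity = 0.2,
         shared_pool_size = 30L, seed = seed),
    list(...))
  do.call(generator_config, args)
}

test_that("generation is seed-deterministic and truth accompanies the data", {
  g1 <- generate_catalog(small_cfg(801))
  g2 <- generate_catalog(small_cfg(801))
  expect_identical(g1$catalog, g2$catalog)
  expect_identical(g1$truth$unique_counts, g2$truth$unique_counts)
  expect_identical(generate_references(g1$catalog, seed = 9),
                   generate_references(g2$catalog, seed = 9))
  g3 <- generate_catalog(small_cfg(802))
  expect_false(identical(g1$catalog, g3$catalog))
  expect_s3_class(g1$truth, "synthetic_truth")
})

test_that("zero sharing intensity yields a fully unique, containment-free background", {
  g <- generate_catalog(small_cfg(803, n_subset_pairs = 0L, n_zero_unique = 0L,
                                  sharing_intensity = 0, shared_pool_size = 0L))
  idx <- build_index(g$catalog)
  expect_true(all(idx$multiplicity == 1L))
  expect_identical(nrow(find_subset_sets(g$catalog, idx)), 0L)
  expect_identical(g$truth$zero_unique_otus, character(0))
})

test_that("infeasible configurations are rejected with an explanation", {
  expect_error(generator_config(n_sets = 5L, n_subset_pairs = 3L, seed = 1),
               "infeasible")
  expect_error(generator_config(n_sets = 4L, n_subset_pairs = 1L,
                                n_zero_unique = 1L, seed = 1),
               "infeasible")
  expect_error(generator_config(seed = 1, set_size_min = 20L,
                                set_size_max = 20L, n_subset_pairs = 1L),
               "infeasible")
  expect_error(generator_config(n_sets = 10L), "seed is mandatory")
  g <- generate_catalog(small_cfg(804))
  expect_error(generate_references(g$catalog, backbone_length = 30L,
                                   seed = 1), "infeasible")
  expect_error(generate_detected_list(g$truth, 100L, seed = 1), "infeasible")
  expect_error(generate_detected_list(g$truth, 100L, enrichment = Inf,
                                      seed = 1), "infeasible")
})

test_that("planted structure is recovered exactly by the audit pipeline", {
  for (seed in 805:809) {
    g <- generate_catalog(small_cfg(seed))
    idx <- build_index(g$catalog)
    ut <- uniqueness_table(g$catalog, idx)
    expect_identical(setNames(ut$n_unique, ut$otu_id),
                     g$truth$unique_counts[ut$otu_id])
    expect_identical(sort(ut$otu_id[ut$n_unique == 0L]),
                     g$truth$zero_unique_otus)
    ss <- find_subset_sets(g$catalog, idx)
    expect_identical(ss$subset_otu, sort(g$truth$subset_pairs$subset_otu))
    expect_identical(
      unname(unlist(ss$superset_otus)),
      g$truth$subset_pairs$superset_otu[order(g$truth$subset_pairs$subset_otu)])
    # planted zero-unique sets are 100% union-assemblable from their donors
    for (z in g$truth$planted_zero_unique) {
      uc <- union_cover(g$catalog, idx, z)
      expect_equal(uc$covered_fraction_excl_self, 1.0)
      expect_identical(sort(uc$donor_decomposition$otu_id),
                       g$truth$donors[[z]])
    }
  }
})

test_that("references embed every probe and a planted mutation is detected", {
  g <- generate_catalog(small_cfg(810))
  refs <- generate_references(g$catalog, backbone_length = 600L, seed = 811)
  expect_true(all(nchar(refs) == 600L))
  v <- validate_probe_sets(g$catalog, refs)
  expect_true(all(v$functional))

  otu <- v$otu_id[3]
  probe <- g$catalog$probe_sets[[otu]][2]
  pos <- as.integer(regexpr(probe, refs[[otu]], fixed = TRUE)) + 12L
  substring(refs[[otu]], pos, pos) <-
    setdiff(c("A", "C", "G", "T"), substring(refs[[otu]], pos, pos))[1]
  rep1 <- hybridize(g$catalog, refs[otu], thresholds = 0.999,
                    comparator = "geq")
  expect_lt(rep1$match_fraction[rep1$otu_id == otu], 1)
})

test_that("zero-unique sets become false positives when their donors are sampled", {
  g <- generate_catalog(small_cfg(812))
  refs <- generate_references(g$catalog, seed = 813)
  z <- g$truth$planted_zero_unique[1]
  donors <- g$truth$donors[[z]]
  rep1 <- hybridize(g$catalog, refs[donors])
  expect_true(z %in% detected_otus(rep1, 0.95))   # present without its target
  expect_equal(rep1$match_fraction[rep1$otu_id == z], 1)
})

test_that("identical probe sets correlate perfectly in noiseless abundances", {
  set.seed(814)
  p <- rand_probe_pool(6L)
  cat1 <- probe_catalog(list(A = p[1:5], B = p[1:5], C = p[6]),
                        min_set_size = 1L)
  truth <- structure(list(seed = 1L,
                          unique_counts = c(A = 0L, B = 0L, C = 1L),
                          zero_unique_otus = c("A", "B"),
                          probe_origin = setNames(c(rep("A", 5), "C"), p[1:6])),
                     class = "synthetic_truth")
  am <- generate_abundance(cat1, truth, n_arrays = 10L, noise_sd = 0,
                           seed = 815)
  expect_equal(cor(am$intensities["A", ], am$intensities["B", ]), 1,
               tolerance = 1e-12)
})

test_that("independent blocks reproduce the null tail; shared blocks exceed it", {
  # disjoint catalog: pairwise r should follow the independence null
  g <- generate_catalog(small_cfg(816, n_sets = 40L, n_subset_pairs = 0L,
                                  n_zero_unique = 0L, sharing_intensity = 0,
                                  shared_pool_size = 0L))
  tax <- generate_taxonomy(names(g$catalog$probe_sets), n_classes = 1L,
                           n_families = 2L, seed = 817)
  am <- generate_abundance(g$catalog, g$truth, n_arrays = 18L,
                           noise_sd = 0.25, seed = 818, taxonomy = tax)
  rs <- pairwise_correlations(am, "Class01")
  h <- histogram_with_null(rs, null_density(18L))
  p <- h$frac_gt_0.5_expected
  se <- sqrt(p * (1 - p) / length(rs))
  expect_lt(abs(h$frac_gt_0.5_observed - p), 3 * se)

  # heavy sharing: observed right tail exceeds the null expectation
  g2 <- generate_catalog(small_cfg(819, n_sets = 40L, n_subset_pairs = 8L,
                                   n_zero_unique = 4L,
                                   sharing_intensity = 0.8,
                                   shared_pool_size = 15L))
  tax2 <- generate_taxonomy(names(g2$catalog$probe_sets), n_classes = 1L,
                            n_families = 2L, seed = 820)
  am2 <- generate_abundance(g2$catalog, g2$truth, n_arrays = 18L,
                            noise_sd = 0.1, seed = 821, taxonomy = tax2)
  rs2 <- pairwise_correlations(am2, "Class01")
  h2 <- histogram_with_null(rs2, null_density(18L))
  expect_gt(h2$frac_gt_0.5_observed, h2$frac_gt_0.5_expected)
})

test_that("detected lists honour the enrichment weighting", {
  g <- generate_catalog(small_cfg(822, n_sets = 30L, n_zero_unique = 6L,
                                  n_subset_pairs = 4L))
  zu <- g$truth$zero_unique_otus
  # infinite enrichment draws only zero-unique sets
  d_inf <- generate_detected_list(g$truth, length(zu), enrichment = Inf,
                                  seed = 823)
  expect_identical(d_inf, zu)
  # bookkeeping reconstructs the enrichment-test inputs
  d <- generate_detected_list(g$truth, 12L, enrichment = 4, seed = 824)
  k <- length(intersect(d, zu))
  e <- enrichment_test(N = length(g$truth$unique_counts), K = length(zu),
                       n = length(d), k = k)
  expect_identical(e$k, k)
  expect_true(e$p_value >= 0 && e$p_value <= 1)
})

test_that("uniform detection sampling is calibrated against the hypergeometric null", {
  g <- generate_catalog(small_cfg(825, n_sets = 30L, n_zero_unique = 6L,
                                  n_subset_pairs = 4L))
  zu <- g$truth$zero_unique_otus
  N <- length(g$truth$unique_counts); K <- length(zu); n <- 10L
  ks <- vapply(1:200, function(i) {
    d <- generate_detected_list(g$truth, n, enrichment = 1, seed = 9000L + i)
    length(intersect(d, zu))
  }, integer(1))
  # exact goodness of fit of the overlap counts against dhyper
  xs <- 0:min(K, n)
  expected <- dhyper(xs, K, N - K, n)
  obs <- tabulate(ks + 1L, nbins = length(xs))
  keep <- expected > 1e-6
  chi <- suppressWarnings(chisq.test(obs[keep], p = expected[keep],
                                     rescale.p = TRUE))
  expect_gt(chi$p.value, 0.01)
})
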