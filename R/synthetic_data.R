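# Seed-deterministic generators for every input the audit pipeline consumes,
# with planted, machine-readable ground truth.
#
# The generative model builds each probe set from fresh (globally distinct)
# random 25-mers plus, for ordinary sets, draws from a common shared pool with
# a probability that can grow with set size — reproducing the qualitative
# pattern of real catalogs, where probe-set uniqueness declines as set size
# increases. On top of that background, three structures are planted exactly:
#   * subset pairs: one set's probes are a strict subset of one other set;
#   * zero-unique sets: a set whose probes are split between >= 2 donor sets,
#     so it is union-assemblable but contained in no single other set;
#   * everything else keeps at least one fresh probe, so no accidental
#     containment or zero-uniqueness can arise.
# The model makes no attempt to mimic the phylogenetic covariance of real 16S
# sequences; backbones are uniform random DNA.

#' Configuration for the synthetic catalog generator
#'
#' Defaults describe a scaled-down catalog with the audited array's structural
#' rules: 25-mer probes, presence-callable sets of at least 11 probes, and
#' background probe sharing that intensifies with set size.
#'
#' @param n_sets Number of probe sets (default 60).
#' @param set_size_min,set_size_max Per-set size range (defaults 11 and 80).
#' @param n_subset_pairs Planted subset/superset pairs (default 3).
#' @param n_zero_unique Planted zero-unique, union-assemblable sets
#'   (default 3); each is split across 2 donor sets.
#' @param sharing_intensity Probability scale in `[0, 1]` that an ordinary
#'   set's probe is drawn from the shared pool instead of being fresh
#'   (default 0.15); 0 gives a fully disjoint background.
#' @param shared_pool_size Number of distinct probes in the shared pool
#'   (default 150).
#' @param size_dependent_sharing If `TRUE` (default) the sharing probability
#'   of a set is `sharing_intensity * set_size / set_size_max`, so larger sets
#'   share more.
#' @param probe_length Probe length in nt (default 25).
#' @param backbone_length Reference-sequence length for
#'   [generate_references()]; default `NULL` lets that generator choose.
#' @param seed Mandatory RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_sets = 60L, set_size_min = 11L,
                             set_size_max = 80L, n_subset_pairs = 3L,
                             n_zero_unique = 3L, sharing_intensity = 0.15,
                             shared_pool_size = 150L,
                             size_dependent_sharing = TRUE,
                             probe_length = 25L, backbone_length = NULL,
                             seed) {
  if (missing(seed)) stop("generator seed is mandatory")
  n_special <- 2L * n_subset_pairs + n_zero_unique
  n_regular <- n_sets - n_special
  if (n_subset_pairs > n_sets / 2) stop("infeasible: n_subset_pairs > n_sets/2")
  if (n_regular < 0L || (n_zero_unique > 0L && n_regular < 2L)) {
    stop("infeasible: planted structure needs at least 2 ordinary donor sets")
  }
  if (set_size_max <= set_size_min && n_subset_pairs > 0L) {
    stop("infeasible: subset pairs need set_size_max > set_size_min")
  }
  stopifnot(set_size_min >= 1L, sharing_intensity >= 0, sharing_intensity <= 1,
            shared_pool_size >= 0L, probe_length >= 1L)
  structure(list(n_sets = as.integer(n_sets),
                 set_size_min = as.integer(set_size_min),
                 set_size_max = as.integer(set_size_max),
                 n_subset_pairs = as.integer(n_subset_pairs),
                 n_zero_unique = as.integer(n_zero_unique),
                 sharing_intensity = sharing_intensity,
                 shared_pool_size = as.integer(shared_pool_size),
                 size_dependent_sharing = isTRUE(size_dependent_sharing),
                 probe_length = as.integer(probe_length),
                 backbone_length = backbone_length,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic probe catalog with planted structure
#'
#' See the module notes above for the generative model. The returned truth
#' records everything the generator planted, via its own construction-time
#' bookkeeping (not by re-indexing the catalog): per-set unique-probe counts,
#' the subset pairs, the zero-unique sets and their donors, and each probe's
#' originating set (the set whose "organism" carries the probe — used by
#' [generate_abundance()]).
#'
#' @param config A [generator_config()].
#' @return A list with elements `catalog` (a `probe_catalog`) and `truth`
#'   (class `synthetic_truth`: fields `seed`, `config`, `subset_pairs`
#'   (data.frame `subset_otu`, `superset_otu`), `planted_zero_unique`,
#'   `donors` (list), `unique_counts` (named int), `zero_unique_otus`,
#'   `probe_origin` (named chr)).
#' @export
generate_catalog <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  cf <- config
  ids <- sprintf("OTU%04d", seq_len(cf$n_sets))
  shuffled <- sample(ids)
  np <- cf$n_subset_pairs; nz <- cf$n_zero_unique
  supersets <- sort(shuffled[seq_len(np)])
  subsets <- sort(shuffled[np + seq_len(np)])
  zsets <- sort(shuffled[2L * np + seq_len(nz)])
  regular <- sort(setdiff(ids, c(supersets, subsets, zsets)))

  rand_size <- function(n, lo = cf$set_size_min, hi = cf$set_size_max) {
    sample(seq(lo, hi), n, replace = TRUE)
  }
  sets <- list(); origin <- character(0)
  unique_counts <- stats::setNames(integer(cf$n_sets), ids)

  # the shared pool, then a lazily grown supply of fresh probes guaranteed
  # distinct from the pool and from each other
  pool <- if (cf$shared_pool_size > 0L) {
    random_distinct_dna(cf$shared_pool_size, cf$probe_length)
  } else character(0)
  fresh_pool <- character(0); fresh_ptr <- 0L
  need_fresh <- function(n) {
    if (n == 0L) return(character(0))
    if (fresh_ptr + n > length(fresh_pool)) {
      fresh_pool <<- c(fresh_pool,
                       random_distinct_dna(max(n, 256L), cf$probe_length,
                                           avoid = c(pool, fresh_pool)))
    }
    out <- fresh_pool[fresh_ptr + seq_len(n)]
    fresh_ptr <<- fresh_ptr + n
    out
  }
  pool_users <- list()
  for (otu in regular) {
    sz <- rand_size(1L)
    p_share <- cf$sharing_intensity *
      if (cf$size_dependent_sharing) sz / cf$set_size_max else 1
    n_shared <- if (length(pool) == 0L) 0L else
      min(stats::rbinom(1L, sz, p_share), sz - 1L, length(pool))
    shared <- if (n_shared > 0L) sample(pool, n_shared) else character(0)
    fresh <- need_fresh(sz - n_shared)
    sets[[otu]] <- c(fresh, shared)
    origin[fresh] <- otu
    pool_users[[otu]] <- shared
    unique_counts[otu] <- length(fresh)   # pool corrections below
  }
  # pool probe origin: lexicographically first user; single-user pool probes
  # are still unique
  if (length(pool_users) > 0L) {
    usage <- table(unlist(pool_users, use.names = FALSE))
    for (otu in names(pool_users)) {
      pp <- pool_users[[otu]]
      unique_counts[otu] <- unique_counts[otu] + sum(usage[pp] == 1L)
    }
    all_used <- sort(unique(unlist(pool_users, use.names = FALSE)))
    first_user <- vapply(all_used, function(p) {
      min(names(pool_users)[vapply(pool_users, function(x) p %in% x,
                                   logical(1))])
    }, character(1))
    origin[all_used] <- first_user
  }

  # planted subset pairs: subset probes are a strict subset of the superset's
  pairs <- data.frame(subset_otu = subsets, superset_otu = supersets,
                      stringsAsFactors = FALSE)
  for (i in seq_len(np)) {
    a_sz <- rand_size(1L, cf$set_size_min + 1L, cf$set_size_max)
    b_sz <- rand_size(1L, cf$set_size_min, a_sz - 1L)
    a_probes <- need_fresh(a_sz)
    b_probes <- sample(a_probes, b_sz)
    sets[[supersets[i]]] <- a_probes
    sets[[subsets[i]]] <- b_probes
    origin[a_probes] <- supersets[i]
    unique_counts[supersets[i]] <- a_sz - b_sz
    unique_counts[subsets[i]] <- 0L
  }

  # planted zero-unique sets: probes split between two ordinary donors, so the
  # set is union-assemblable but not a subset of any single OTU
  donors <- list()
  for (z in zsets) {
    sz <- rand_size(1L)
    zp <- need_fresh(sz)
    d <- sample(regular, 2L)
    half <- sample(seq_len(sz), ceiling(sz / 2))
    chunks <- list(zp[half], zp[-half])
    for (j in 1:2) {
      sets[[d[j]]] <- c(sets[[d[j]]], chunks[[j]])
      origin[chunks[[j]]] <- d[j]   # the donor organism carries the probe
    }
    sets[[z]] <- zp
    donors[[z]] <- sort(d)
    unique_counts[z] <- 0L
  }

  catalog <- probe_catalog(sets[ids], min_set_size = cf$set_size_min,
                           provenance = sprintf("synthetic catalog, seed %d",
                                                cf$seed),
                           probe_length = cf$probe_length)
  truth <- structure(
    list(seed = cf$seed, config = cf,
         subset_pairs = pairs,
         planted_zero_unique = zsets,
         donors = donors,
         unique_counts = unique_counts,
         zero_unique_otus = sort(names(unique_counts)[unique_counts == 0L]),
         probe_origin = origin),
    class = "synthetic_truth")
  list(catalog = catalog, truth = truth)
}

#' Generate reference sequences embedding each probe set
#'
#' Builds, for every OTU, a random-DNA backbone that contains every probe of
#' its set verbatim on the forward strand at non-overlapping positions, with
#' random filler distributed between probes so the sequence has exactly
#' `backbone_length` bases. By construction [validate_probe_sets()] on the
#' result is 100% functional (random filler creating a spurious 25-mer
#' collision with another set has probability ~4^-25 per window and is
#' neglected).
#'
#' @param catalog A `probe_catalog`.
#' @param backbone_length Total reference length; must be at least
#'   `probe_length * max(set size)`. Default: that minimum plus 200.
#' @param seed RNG seed.
#' @return Named character vector of sequences (one per OTU).
#' @export
generate_references <- function(catalog, backbone_length = NULL, seed) {
  stopifnot(inherits(catalog, "probe_catalog"))
  set.seed(seed)
  k <- catalog$probe_length
  min_len <- k * max(set_sizes(catalog))
  backbone_length <- backbone_length %||% (min_len + 200L)
  if (backbone_length < min_len) {
    stop(sprintf("infeasible backbone_length %d < %d needed to embed the largest set",
                 backbone_length, min_len))
  }
  out <- vapply(catalog$probe_sets, function(probes) {
    probes <- sample(probes)
    total_filler <- backbone_length - k * length(probes)
    cuts <- sort(sample.int(total_filler + 1L, length(probes), replace = TRUE) - 1L)
    fill_len <- diff(c(0L, cuts, total_filler))
    pieces <- character(2L * length(probes) + 1L)
    pieces[seq(1L, by = 2L, length.out = length(probes) + 1L)] <-
      vapply(fill_len, function(l) if (l > 0L)
        random_dna(1L, l) else "", character(1))
    pieces[seq(2L, by = 2L, length.out = length(probes))] <- probes
    paste0(pieces, collapse = "")
  }, character(1))
  out
}

#' Generate a synthetic taxonomy table
#'
#' Assigns OTUs uniformly at random to `n_families` families nested inside
#' `n_classes` classes (families are distributed round-robin over classes);
#' the remaining ranks are filled with matching placeholder labels.
#'
#' @param otu_ids Character vector of OTU ids.
#' @param n_classes,n_families Numbers of distinct classes and families.
#' @param seed RNG seed.
#' @return A taxonomy data.frame as from [parse_taxonomy()].
#' @export
generate_taxonomy <- function(otu_ids, n_classes = 3L, n_families = 8L, seed) {
  set.seed(seed)
  stopifnot(n_families >= n_classes)
  fam_class <- rep(seq_len(n_classes), length.out = n_families)
  fam <- sample.int(n_families, length(otu_ids), replace = TRUE)
  data.frame(
    otu_id = otu_ids,
    domain = "Bacteria",
    phylum = sprintf("Phylum%02d", fam_class[fam]),
    class = sprintf("Class%02d", fam_class[fam]),
    order = sprintf("Order%02d", fam),
    family = sprintf("Family%02d", fam),
    genus = sprintf("Genus%03d", fam),
    stringsAsFactors = FALSE
  )
}

#' Generate an abundance matrix with sharing-driven correlation
#'
#' Emulates intensity data across arrays: each originating organism (the sets
#' recorded in `truth$probe_origin`) gets an independent standard-normal
#' latent signal per array; every probe carries the signal of its originating
#' organism; an OTU's intensity on an array is the mean of its probes' signals
#' plus Gaussian noise. OTUs built from disjoint, self-originating probe sets
#' are therefore independent (their pairwise r follows the [null_density()]
#' distribution), while OTUs sharing probes — planted subsets, zero-unique
#' sets and their donors, co-users of pool probes — are positively correlated
#' in expectation.
#'
#' @param catalog A `probe_catalog` from [generate_catalog()].
#' @param truth The matching `synthetic_truth`.
#' @param n_arrays Number of arrays (default 18).
#' @param noise_sd Standard deviation of the per-OTU measurement noise
#'   (default 0.25).
#' @param seed RNG seed.
#' @param taxonomy Optional taxonomy data.frame supplying class labels.
#' @return An `abundance_matrix`.
#' @export
generate_abundance <- function(catalog, truth, n_arrays = 18L,
                               noise_sd = 0.25, seed, taxonomy = NULL) {
  stopifnot(inherits(catalog, "probe_catalog"),
            inherits(truth, "synthetic_truth"), n_arrays >= 4L, noise_sd >= 0)
  set.seed(seed)
  orgs <- sort(unique(truth$probe_origin))
  latent <- matrix(stats::rnorm(length(orgs) * n_arrays), nrow = length(orgs),
                   dimnames = list(orgs, sprintf("array%02d", seq_len(n_arrays))))
  ids <- names(catalog$probe_sets)
  m <- t(vapply(ids, function(otu) {
    org_of_probe <- truth$probe_origin[catalog$probe_sets[[otu]]]
    colMeans(latent[org_of_probe, , drop = FALSE]) +
      stats::rnorm(n_arrays, sd = noise_sd)
  }, numeric(n_arrays)))
  rownames(m) <- ids
  cls <- if (!is.null(taxonomy)) stats::setNames(taxonomy$class,
                                                 taxonomy$otu_id) else NULL
  abundance_matrix(m, class_of = cls)
}

#' Generate a detected-OTU list enriched in zero-unique sets
#'
#' Samples `n_detected` OTU ids without replacement, with zero-unique sets
#' over-weighted by `enrichment` (1 = no enrichment, i.e. uniform sampling so
#' the overlap with the zero-unique subpopulation is hypergeometric;
#' `Inf` = only zero-unique sets are drawn).
#'
#' @param truth A `synthetic_truth`.
#' @param n_detected Number of OTUs to draw.
#' @param enrichment Relative sampling weight of zero-unique OTUs (>= 0).
#' @param seed RNG seed.
#' @return Sorted character vector of OTU ids.
#' @export
generate_detected_list <- function(truth, n_detected, enrichment = 1, seed) {
  stopifnot(inherits(truth, "synthetic_truth"), enrichment >= 0)
  set.seed(seed)
  ids <- names(truth$unique_counts)
  zu <- truth$zero_unique_otus
  if (is.infinite(enrichment)) {
    if (n_detected > length(zu)) {
      stop("infeasible: n_detected exceeds the zero-unique subpopulation")
    }
    return(sort(sample(zu, n_detected)))
  }
  if (n_detected > length(ids)) stop("infeasible: n_detected exceeds catalog size")
  w <- ifelse(ids %in% zu, enrichment, 1)
  sort(sample(ids, n_detected, prob = w))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth (seed %d): %d sets, %d subset pairs, %d planted zero-unique (of %d total zero-unique)\n",
              x$seed, length(x$unique_counts), nrow(x$subset_pairs),
              length(x$planted_zero_unique), length(x$zero_unique_otus)))
  invisible(x)
}
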