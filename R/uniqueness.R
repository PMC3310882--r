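# Inverted probe index and probe / probe-set uniqueness statistics.
#
# 16S targets are highly conserved, so many 25-mer probes recur across probe
# sets. A probe's multiplicity is the number of distinct OTU sets that carry
# it; a probe with multiplicity 1 is unique, and a probe set whose probes all
# have multiplicity >= 2 ("zero-unique") can be fully lit up by other taxa.

#' Build the inverted probe index
#'
#' Maps each distinct probe sequence to the sorted set of OTU ids whose probe
#' sets contain it, together with its multiplicity (the number of such OTUs).
#' The index is canonical: independent of the order in which the catalog was
#' assembled.
#'
#' @param catalog A non-empty `probe_catalog`.
#' @return An object of class `probe_index` with fields `probes` (sorted
#'   character vector of distinct probes), `otus` (parallel list of sorted OTU
#'   id vectors), `multiplicity` (parallel integer vector), `n_instances`
#'   (total probe instances) and `otu_ids`.
#' @export
build_index <- function(catalog) {
  stopifnot(inherits(catalog, "probe_catalog"))
  if (n_probe_sets(catalog) == 0L) stop("cannot index an empty catalog")
  inst_probe <- unlist(catalog$probe_sets, use.names = FALSE)
  inst_otu <- rep(names(catalog$probe_sets), lengths(catalog$probe_sets))
  by_probe <- split(inst_otu, inst_probe)          # keys sorted by factor levels
  by_probe <- lapply(by_probe, sort)
  structure(
    list(probes = names(by_probe),
         otus = unname(by_probe),
         multiplicity = unname(lengths(by_probe)),
         n_instances = length(inst_probe),
         otu_ids = names(catalog$probe_sets)),
    class = "probe_index"
  )
}

#' @export
print.probe_index <- function(x, ...) {
  cat(sprintf("probe_index: %d distinct probes over %d probe instances in %d sets\n",
              length(x$probes), x$n_instances, length(x$otu_ids)))
  cat(sprintf("  unique probes (multiplicity 1): %d; max multiplicity: %d\n",
              sum(x$multiplicity == 1L), max(x$multiplicity)))
  invisible(x)
}

# Internal: positions of a set's probes in the index (error if any missing).
index_positions <- function(index, probes) {
  pos <- match(probes, index$probes)
  if (anyNA(pos)) stop("catalog/index mismatch: probe absent from index")
  pos
}

#' Probe multiplicity histogram
#'
#' Counts, for each multiplicity k, how many distinct probe sequences occur in
#' exactly k probe sets.
#'
#' @param index A `probe_index`.
#' @return A data.frame with integer columns `multiplicity` (observed values,
#'   ascending) and `n_probes`; `sum(n_probes)` equals the number of distinct
#'   probes and `sum(multiplicity * n_probes)` the number of probe instances.
#' @export
multiplicity_histogram <- function(index) {
  stopifnot(inherits(index, "probe_index"))
  tab <- table(index$multiplicity)
  data.frame(multiplicity = as.integer(names(tab)),
             n_probes = as.integer(tab))
}

#' Per-probe-set uniqueness table
#'
#' For every probe set, counts its probes that are unique across the whole
#' catalog (multiplicity exactly 1 in `index`).
#'
#' @param catalog A `probe_catalog`.
#' @param index The `probe_index` built from `catalog` (a consistency check
#'   rejects a mismatched pair).
#' @return A data.frame with one row per probe set: `otu_id`, `set_size`,
#'   `n_unique`, `fraction_unique`, sorted by `otu_id`.
#' @export
uniqueness_table <- function(catalog, index) {
  stopifnot(inherits(catalog, "probe_catalog"), inherits(index, "probe_index"))
  if (index$n_instances != total_probe_instances(catalog) ||
      !identical(index$otu_ids, names(catalog$probe_sets))) {
    stop("index was not built from this catalog")
  }
  inst_probe <- unlist(catalog$probe_sets, use.names = FALSE)
  inst_otu <- rep(names(catalog$probe_sets), lengths(catalog$probe_sets))
  uniq <- index$multiplicity[index_positions(index, inst_probe)] == 1L
  n_unique <- vapply(split(uniq, inst_otu), sum, integer(1))
  n_unique <- n_unique[names(catalog$probe_sets)]  # split() sorts; keep canonical order
  sz <- set_sizes(catalog)
  data.frame(otu_id = names(sz),
             set_size = unname(sz),
             n_unique = unname(n_unique),
             fraction_unique = unname(n_unique / sz),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select OTUs with low probe-set uniqueness
#'
#' @param table A uniqueness table from [uniqueness_table()].
#' @param max_fraction Upper bound: OTUs with `fraction_unique` strictly below
#'   this are returned (so `max_fraction = 0` selects nothing and the selection
#'   grows monotonically with `max_fraction`).
#' @return Sorted character vector of OTU ids.
#' @export
low_uniqueness_otus <- function(table, max_fraction) {
  stopifnot(max_fraction >= 0, max_fraction <= 1)
  sort(table$otu_id[table$fraction_unique < max_fraction])
}

#' Catalog-level uniqueness summary
#'
#' Convenience roll-up of the headline audit statistics: set counts and sizes,
#' distinct/unique/shared probe counts, maximum multiplicity, and the number
#' of zero-unique sets.
#'
#' @param catalog A `probe_catalog`.
#' @param index Optional pre-built `probe_index`.
#' @return A one-row data.frame.
#' @export
uniqueness_summary <- function(catalog, index = build_index(catalog)) {
  ut <- uniqueness_table(catalog, index)
  data.frame(
    n_sets = n_probe_sets(catalog),
    n_probe_instances = total_probe_instances(catalog),
    n_distinct_probes = length(index$probes),
    n_unique_probes = sum(index$multiplicity == 1L),
    n_shared_probes = sum(index$multiplicity >= 2L),
    max_multiplicity = max(index$multiplicity),
    mean_set_size = mean(ut$set_size),
    max_set_size = max(ut$set_size),
    n_zero_unique_sets = sum(ut$n_unique == 0L)
  )
}
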