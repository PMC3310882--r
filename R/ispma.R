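# In Silico Phylogenetic MicroArray (ISPMA): exact-match hybridization of a
# FASTA "sample" against the probe catalog.
#
# Each sample sequence is decomposed into its complete set of 25-mers; a probe
# is matched when any 25-mer from any sample sequence equals it exactly, and a
# probe set is called present when its matched fraction exceeds a threshold
# (typically 90/92/95%). This is the best-case, perfect-match scenario: no
# mismatch tolerance and no cross-hybridization model.

#' Decompose a sequence into k-mers
#'
#' All length-`k` windows at step 1 (1-based positions `1..L-k+1`). Windows
#' containing characters outside ACGT are skipped and counted in the
#' `n_skipped` attribute. A sequence shorter than `k` yields no windows.
#'
#' @param sequence A single DNA string (uppercased internally).
#' @param k Window length (default 25).
#' @return Character vector of k-mers in sequence order, with integer
#'   attribute `n_skipped`.
#' @export
#' @examples
#' kmerize("ACGTACGT", k = 4)
kmerize <- function(sequence, k = 25L) {
  stopifnot(length(sequence) == 1L, k >= 1L)
  s <- toupper(sequence)
  L <- nchar(s)
  if (L < k) return(structure(character(0), n_skipped = 0L))
  win <- substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
  ok <- grepl("^[ACGT]+$", win)
  structure(win[ok], n_skipped = sum(!ok))
}

#' Hybridize a sequence sample to a probe catalog
#'
#' Runs the in-silico microarray: every sample sequence is turned into its
#' complete set of 25-mers (or `catalog$probe_length`-mers) and each probe set
#' is scored by the fraction of its probes matched by at least one k-mer from
#' any sequence. A probe counts at most once per OTU no matter how many k-mers
#' or sequences hit it. Presence is called per threshold with a strict `>`
#' comparator by default (configurable to `>=`).
#'
#' @param catalog A `probe_catalog` (normally already filtered with
#'   [filter_small_sets()]).
#' @param sample Named character vector of sample sequences, as returned by
#'   [parse_fasta()] (names must be unique).
#' @param thresholds Numeric vector of presence thresholds in `(0, 1]`
#'   (default `c(0.90, 0.92, 0.95)`).
#' @param revcomp If `TRUE`, the reverse complement of each k-mer is also
#'   looked up. Default `FALSE`: probes are matched against the given strand.
#' @param comparator `"gt"` (present when `match_fraction > t`, default) or
#'   `"geq"`.
#' @return An object of class `hybridization_report`: a data.frame with one
#'   row per probe set — `otu_id`, `set_size`, `n_matched`, `match_fraction`
#'   and one logical `present_<t>` column per threshold — plus attributes
#'   `thresholds`, `comparator`, `n_sequences`, `n_kmers` (distinct),
#'   `n_kmers_skipped`.
#' @export
hybridize <- function(catalog, sample, thresholds = c(0.90, 0.92, 0.95),
                      revcomp = FALSE, comparator = c("gt", "geq")) {
  stopifnot(inherits(catalog, "probe_catalog"),
            all(thresholds > 0), all(thresholds <= 1))
  comparator <- match.arg(comparator)
  if (length(sample) > 0L &&
      (is.null(names(sample)) || anyDuplicated(names(sample)))) {
    stop("sample sequences must have unique names")
  }
  if (length(sample) == 0L) warning("empty sample: all match fractions are 0")

  kms <- lapply(sample, kmerize, k = catalog$probe_length)
  n_skipped <- sum(vapply(kms, function(x) attr(x, "n_skipped"), integer(1)))
  all_kmers <- unique(unlist(kms, use.names = FALSE))
  if (isTRUE(revcomp)) all_kmers <- unique(c(all_kmers, revcomp_dna(all_kmers)))

  inst_probe <- unlist(catalog$probe_sets, use.names = FALSE)
  inst_otu <- rep(names(catalog$probe_sets), lengths(catalog$probe_sets))
  hit <- inst_probe %in% all_kmers
  n_matched <- vapply(split(hit, inst_otu), sum, integer(1))
  n_matched <- n_matched[names(catalog$probe_sets)]
  sz <- set_sizes(catalog)
  rep_df <- data.frame(otu_id = names(sz),
                       set_size = unname(sz),
                       n_matched = unname(n_matched),
                       match_fraction = unname(n_matched / sz),
                       row.names = NULL, stringsAsFactors = FALSE)
  for (t in thresholds) {
    rep_df[[sprintf("present_%g", t)]] <-
      if (comparator == "gt") rep_df$match_fraction > t
      else rep_df$match_fraction >= t
  }
  structure(rep_df,
            thresholds = thresholds, comparator = comparator,
            n_sequences = length(sample),
            n_kmers = length(all_kmers), n_kmers_skipped = n_skipped,
            class = c("hybridization_report", "data.frame"))
}

#' OTUs called present at a threshold
#'
#' @param report A `hybridization_report`.
#' @param threshold One of the thresholds the report was computed at.
#' @return Sorted character vector of OTU ids called present.
#' @export
detected_otus <- function(report, threshold) {
  col <- sprintf("present_%g", threshold)
  if (!col %in% names(report)) {
    stop("report has no presence call at threshold ", threshold)
  }
  sort(report$otu_id[report[[col]]])
}

#' Compare input and detected communities at a taxonomic rank
#'
#' Tallies, for each presence threshold of a hybridization report, the
#' taxonomic groups gained and lost relative to the input community: groups in
#' the input but absent from the detections ("missed") and groups detected but
#' absent from the input ("spurious"), plus per-group OTU counts before and
#' after. OTUs missing from the taxonomy table (or with an empty rank value)
#' are bucketed as `"unclassified"`.
#'
#' @param input_otus Character vector of OTU ids actually present in the
#'   simulated sample.
#' @param report A `hybridization_report`.
#' @param taxonomy A taxonomy data.frame as from [parse_taxonomy()].
#' @param rank Rank column to compare at (default `"family"`).
#' @return An object of class `community_comparison`: a list with `rank`,
#'   `input_otus`, and per-threshold elements `detected_otus`,
#'   `missed_groups`, `spurious_groups`, `group_counts` (data.frame `group`,
#'   `n_input`, `n_detected`, alphabetical).
#' @export
compare_communities <- function(input_otus, report, taxonomy,
                                rank = "family") {
  stopifnot(rank %in% names(taxonomy))
  group_of <- function(otus) {
    g <- taxonomy[[rank]][match(otus, taxonomy$otu_id)]
    g[is.na(g) | !nzchar(g)] <- "unclassified"
    g
  }
  in_groups <- group_of(input_otus)
  thresholds <- attr(report, "thresholds")
  per_t <- lapply(thresholds, function(t) {
    det <- detected_otus(report, t)
    det_groups <- group_of(det)
    groups <- sort(unique(c(in_groups, det_groups)))
    gc <- data.frame(group = groups,
                     n_input = as.integer(table(factor(in_groups, groups))),
                     n_detected = as.integer(table(factor(det_groups, groups))),
                     stringsAsFactors = FALSE)
    list(threshold = t,
         detected_otus = det,
         missed_groups = sort(setdiff(in_groups, det_groups)),
         spurious_groups = sort(setdiff(det_groups, in_groups)),
         group_counts = gc)
  })
  names(per_t) <- sprintf("%g", thresholds)
  structure(list(rank = rank, input_otus = sort(input_otus),
                 thresholds = thresholds, by_threshold = per_t),
            class = "community_comparison")
}

#' @export
print.community_comparison <- function(x, ...) {
  cat(sprintf("community comparison at rank '%s' (%d input OTUs)\n",
              x$rank, length(x$input_otus)))
  for (b in x$by_threshold) {
    cat(sprintf("  threshold %g: %d detected OTUs; groups at rank %s: %d missed, %d spurious\n",
                b$threshold, length(b$detected_otus), x$rank,
                length(b$missed_groups), length(b$spurious_groups)))
  }
  invisible(x)
}

#' Trace all sample matches to one OTU's probe set
#'
#' Explains a target OTU's matched-probe count: for every probe of the target
#' matched by the sample, which sample sequences carry a matching k-mer and
#' which other OTUs share that probe.
#'
#' @param catalog A `probe_catalog`.
#' @param sample Named character vector of sample sequences.
#' @param target OTU id present in the catalog.
#' @return A data.frame with one row per matched probe of the target:
#'   `probe`, list-columns `sample_ids` and `other_otus`.
#' @export
trace_target <- function(catalog, sample, target) {
  if (!target %in% names(catalog$probe_sets)) stop("unknown target OTU: ", target)
  probes <- catalog$probe_sets[[target]]
  kms <- lapply(sample, function(s)
    unique(as.character(kmerize(s, k = catalog$probe_length))))
  holders <- lapply(probes, function(p) {
    names(catalog$probe_sets)[vapply(catalog$probe_sets, function(ps)
      p %in% ps, logical(1))]
  })
  rows <- lapply(seq_along(probes), function(i) {
    p <- probes[i]
    in_seq <- names(kms)[vapply(kms, function(k) p %in% k, logical(1))]
    if (length(in_seq) == 0L) return(NULL)
    list(probe = p, sample_ids = sort(in_seq),
         other_otus = sort(setdiff(holders[[i]], target)))
  })
  rows <- Filter(Negate(is.null), rows)
  data.frame(
    probe = vapply(rows, `[[`, character(1), "probe"),
    sample_ids = I(lapply(rows, `[[`, "sample_ids")),
    other_otus = I(lapply(rows, `[[`, "other_otus")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
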