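# Structural confounding between probe sets: exact subsets and union cover.
#
# A probe set that is an exact subset of another OTU's set is necessarily
# co-detected with it ("subsetting"); a set whose every probe occurs in at
# least one other set ("union-assemblable", equivalently zero-unique) can be
# matched to 100% without its target organism being present.

#' Find probe sets contained in other probe sets
#'
#' An OTU is reported when every probe of its set also occurs in the probe set
#' of at least one single other OTU. Containment is non-strict set inclusion
#' with distinct OTU ids, so two identical probe sets contain each other and
#' both are reported. Candidates are enumerated through the inverted index
#' (only OTUs sharing at least one probe with the target are examined), so the
#' cost is near-linear in probe instances rather than quadratic in sets.
#'
#' @param catalog A `probe_catalog`.
#' @param index The `probe_index` built from `catalog`.
#' @return A data.frame with one row per contained OTU: `subset_otu`,
#'   `n_supersets`, and list-column `superset_otus` (sorted OTU ids), sorted by
#'   `subset_otu`. Zero rows when no set is contained.
#' @export
find_subset_sets <- function(catalog, index) {
  stopifnot(inherits(catalog, "probe_catalog"), inherits(index, "probe_index"))
  ids <- names(catalog$probe_sets)
  res_sub <- character(0); res_sup <- list()
  for (otu in ids) {
    probes <- catalog$probe_sets[[otu]]
    holders <- index$otus[index_positions(index, probes)]
    # fast reject: any catalog-unique probe means no container
    if (any(lengths(holders) == 1L)) next
    tab <- table(unlist(holders, use.names = FALSE))
    sup <- names(tab)[tab == length(probes)]
    sup <- setdiff(sup, otu)
    if (length(sup) > 0L) {
      res_sub <- c(res_sub, otu)
      res_sup <- c(res_sup, list(sort(sup)))
    }
  }
  data.frame(subset_otu = res_sub,
             n_supersets = lengths(res_sup),
             superset_otus = I(res_sup),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Internal: per-probe external multiplicity (holders other than `otu` itself).
external_multiplicity <- function(catalog, index, otu) {
  probes <- catalog$probe_sets[[otu]]
  index$multiplicity[index_positions(index, probes)] - 1L
}

#' Union cover of one probe set by the rest of the catalog
#'
#' Measures how much of a target OTU's probe set can be assembled from the
#' probe sets of other OTUs: the covered fraction (probes present in at least
#' one other set), a greedy donor decomposition (at each step the OTU covering
#' the most still-uncovered target probes, ties broken toward the smaller OTU
#' id), and the critical donors — probes for which exactly one other OTU is
#' the sole external holder, so removing that donor loses the probe.
#'
#' @param catalog A `probe_catalog`.
#' @param index The `probe_index` built from `catalog`.
#' @param target OTU id present in the catalog.
#' @return An object of class `union_cover_record`: a list with `target_otu`,
#'   `set_size`, `covered_fraction_excl_self`, `uncovered_probes`,
#'   `donor_decomposition` (data.frame `otu_id`, `n_newly_covered`) and
#'   `critical_donors` (data.frame `otu_id`, `probe`).
#' @export
union_cover <- function(catalog, index, target) {
  stopifnot(inherits(catalog, "probe_catalog"), inherits(index, "probe_index"))
  if (!target %in% names(catalog$probe_sets)) stop("unknown target OTU: ", target)
  probes <- catalog$probe_sets[[target]]
  ext <- external_multiplicity(catalog, index, target)
  coverable <- probes[ext >= 1L]
  covered_fraction <- length(coverable) / length(probes)

  crit_idx <- which(ext == 1L)
  critical <- data.frame(otu_id = character(0), probe = character(0),
                         stringsAsFactors = FALSE)
  if (length(crit_idx) > 0L) {
    donor <- vapply(crit_idx, function(i) {
      setdiff(index$otus[[index_positions(index, probes[i])]], target)[1L]
    }, character(1))
    critical <- data.frame(otu_id = donor, probe = probes[crit_idx],
                           stringsAsFactors = FALSE)
    critical <- critical[order(critical$otu_id, critical$probe), ,
                         drop = FALSE]
    rownames(critical) <- NULL
  }

  # greedy cover over external donors of the coverable probes
  uncovered <- coverable
  donors <- character(0); gains <- integer(0)
  if (length(uncovered) > 0L) {
    holders <- index$otus[index_positions(index, coverable)]
    donor_probes <- split(rep(coverable, lengths(holders)),
                          unlist(holders, use.names = FALSE))
    donor_probes[[target]] <- NULL
    repeat {
      gain <- vapply(donor_probes, function(p) sum(p %in% uncovered), integer(1))
      if (length(gain) == 0L || max(gain) == 0L) break
      best <- sort(names(gain)[gain == max(gain)])[1L]
      donors <- c(donors, best)
      gains <- c(gains, max(gain))
      uncovered <- setdiff(uncovered, donor_probes[[best]])
      donor_probes[[best]] <- NULL
      if (length(uncovered) == 0L) break
    }
  }
  structure(
    list(target_otu = target,
         set_size = length(probes),
         covered_fraction_excl_self = covered_fraction,
         uncovered_probes = probes[ext == 0L],
         donor_decomposition = data.frame(otu_id = donors,
                                          n_newly_covered = gains,
                                          stringsAsFactors = FALSE),
         critical_donors = critical),
    class = "union_cover_record"
  )
}

#' @export
print.union_cover_record <- function(x, ...) {
  cat(sprintf("union cover of %s: %d/%d probes (%.1f%%) coverable by other sets\n",
              x$target_otu, x$set_size - length(x$uncovered_probes), x$set_size,
              100 * x$covered_fraction_excl_self))
  if (nrow(x$donor_decomposition) > 0L) {
    cat("greedy donors:", paste(sprintf("%s(+%d)", x$donor_decomposition$otu_id,
                                        x$donor_decomposition$n_newly_covered),
                                collapse = ", "), "\n")
  }
  cat(sprintf("critical donors (sole external holders): %d probe(s)\n",
              nrow(x$critical_donors)))
  invisible(x)
}

#' Coverage of a target after removing one donor OTU
#'
#' Fraction of the target's probes still held by at least one OTU other than
#' the target and the removed donor.
#'
#' @param catalog,index As in [union_cover()].
#' @param target Target OTU id.
#' @param removed_donor OTU id excluded (with the target) from the holders.
#' @return Numeric scalar in `[0, 1]`.
#' @export
coverage_without_donor <- function(catalog, index, target, removed_donor) {
  if (!target %in% names(catalog$probe_sets)) stop("unknown target OTU: ", target)
  probes <- catalog$probe_sets[[target]]
  holders <- index$otus[index_positions(index, probes)]
  covered <- vapply(holders, function(h) {
    length(setdiff(h, c(target, removed_donor))) > 0L
  }, logical(1))
  mean(covered)
}

#' Flag OTUs callable present without their target organism
#'
#' For every OTU, compares the externally coverable fraction of its probe set
#' with a presence threshold: an OTU whose covered fraction (excluding itself)
#' reaches the threshold can be called present by donor taxa alone. At
#' threshold 1 this flags exactly the zero-unique probe sets.
#'
#' @param catalog A `probe_catalog`.
#' @param index The `probe_index` built from `catalog`.
#' @param threshold Presence threshold in `(0, 1]`; the flag uses `>=`.
#' @return A data.frame: `otu_id`, `covered_fraction_excl_self`,
#'   `can_be_called_present_when_absent`.
#' @export
presence_hazard_report <- function(catalog, index, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  inst_probe <- unlist(catalog$probe_sets, use.names = FALSE)
  inst_otu <- rep(names(catalog$probe_sets), lengths(catalog$probe_sets))
  shared <- index$multiplicity[index_positions(index, inst_probe)] >= 2L
  n_cov <- vapply(split(shared, inst_otu), sum, integer(1))
  n_cov <- n_cov[names(catalog$probe_sets)]
  frac <- unname(n_cov) / unname(set_sizes(catalog))
  data.frame(otu_id = names(catalog$probe_sets),
             covered_fraction_excl_self = frac,
             can_be_called_present_when_absent = frac >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
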