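# Probe-set self-validation: does each probe set detect its own reference
# 16S sequence under perfect matching?
#
# A functional probe set has every probe matched by at least one 25-mer of its
# reference. Non-functional sets in real catalogs typically arise from
# reference sequences whose undefined bases (Ns) were deleted and the flanks
# rejoined before probe design, or from probes designed against consensus
# sequences that differ from the deposited reference by a few substitutions.

#' Validate probe sets against their reference sequences
#'
#' For every OTU with a reference, decomposes the reference into k-mers
#' ([kmerize()]) and checks that each probe of the set is matched. OTUs
#' without a reference are reported with status `"unvalidatable"` rather than
#' failed.
#'
#' @param catalog A `probe_catalog`.
#' @param references Named character vector of reference 16S sequences. Names
#'   are reference ids; by default they are taken to be OTU ids.
#' @param id_map Optional named character vector mapping `otu_id` to reference
#'   id (e.g. a prokMSA id from a taxonomy file). Default: identity.
#' @return A data.frame with one row per OTU: `otu_id`, `reference_id`,
#'   `status` (`"validated"`/`"unvalidatable"`), `n_probes`, `n_hit`,
#'   `functional`, and list-column `missing_probes`. For unvalidatable OTUs
#'   `n_hit` and `functional` are `NA`.
#' @export
validate_probe_sets <- function(catalog, references, id_map = NULL) {
  stopifnot(inherits(catalog, "probe_catalog"))
  if (length(references) == 0L) stop("empty reference map")
  if (is.null(names(references))) stop("references must be named")
  ids <- names(catalog$probe_sets)
  ref_ids <- if (is.null(id_map)) ids else unname(id_map[ids])
  rows <- lapply(seq_along(ids), function(i) {
    otu <- ids[i]
    rid <- ref_ids[i]
    if (is.na(rid) || !rid %in% names(references)) {
      return(list(otu_id = otu, reference_id = NA_character_,
                  status = "unvalidatable", n_probes =
                    length(catalog$probe_sets[[otu]]),
                  n_hit = NA_integer_, functional = NA,
                  missing_probes = character(0)))
    }
    probes <- catalog$probe_sets[[otu]]
    kms <- unique(as.character(kmerize(references[[rid]],
                                       k = catalog$probe_length)))
    hit <- probes %in% kms
    list(otu_id = otu, reference_id = unname(rid), status = "validated",
         n_probes = length(probes), n_hit = sum(hit),
         functional = all(hit), missing_probes = probes[!hit])
  })
  data.frame(
    otu_id = vapply(rows, `[[`, character(1), "otu_id"),
    reference_id = vapply(rows, `[[`, character(1), "reference_id"),
    status = vapply(rows, `[[`, character(1), "status"),
    n_probes = vapply(rows, `[[`, integer(1), "n_probes"),
    n_hit = vapply(rows, `[[`, integer(1), "n_hit"),
    functional = vapply(rows, `[[`, logical(1), "functional"),
    missing_probes = I(lapply(rows, `[[`, "missing_probes")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Heuristically classify why a probe set failed validation
#'
#' Two failure signatures are recognised:
#' * `"join_artifact"`: some missing probe matches the reference once its runs
#'   of undefined bases (Ns) are deleted and the flanking bases rejoined —
#'   the probe was designed on the N-collapsed sequence.
#' * `"possible_consensus"`: some missing probe aligns to the reference with
#'   exactly 1–2 substitutions, as expected if it was designed against a
#'   consensus rather than the deposited sequence. The 1–2 substitution cutoff
#'   is this package's operationalisation of a qualitative judgment and is
#'   heuristic.
#'
#' Anything else is `"unknown"`. `join_artifact` takes precedence.
#'
#' @param record One row of the output of [validate_probe_sets()] (a
#'   data.frame row or a list with fields `functional` and `missing_probes`).
#' @param reference The reference sequence the record was validated against.
#' @return One of `"join_artifact"`, `"possible_consensus"`, `"unknown"`.
#' @export
classify_failure <- function(record, reference) {
  functional <- if (is.data.frame(record)) record$functional else record$functional
  missing <- if (is.data.frame(record)) record$missing_probes[[1]] else
    record$missing_probes
  if (is.na(functional) || isTRUE(functional)) {
    stop("classify_failure expects a non-functional validation record")
  }
  ref <- toupper(reference)
  joined <- gsub("N+", "", ref)
  if (any(vapply(missing, function(p) grepl(p, joined, fixed = TRUE),
                 logical(1)))) {
    return("join_artifact")
  }
  near <- vapply(missing, function(p) {
    hits <- Biostrings::matchPattern(p, Biostrings::DNAString(ref),
                                     max.mismatch = 2L, fixed = TRUE)
    length(hits) > 0L
  }, logical(1))
  if (any(near)) "possible_consensus" else "unknown"
}
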