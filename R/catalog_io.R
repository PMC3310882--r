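# Probe-catalog model and I/O.
#
# The canonical on-disk format is a TSV with one row per (otu_id, probe) pair,
# header `otu_id<TAB>probe` and an optional third `source_sequence` column
# (repeated on every row of the OTU). A best-effort adapter for the Greengenes
# "probes to OTU alignments" web dump is provided as a second dialect.

#' Construct a probe catalog
#'
#' A probe catalog maps OTU identifiers to their probe sets: the collection of
#' 25-mer DNA probes that represent each OTU on a phylogenetic microarray.
#' Within a set, probes are deduplicated (presence calling is per distinct
#' probe) and the model is canonicalised — probes sorted within sets, sets
#' sorted by OTU id — so that two catalogs built from the same records in any
#' order compare `identical()`.
#'
#' @param probe_sets Named list of character vectors; names are OTU ids,
#'   values are probe sequences (uppercase ACGT, all of `probe_length`).
#' @param source_sequences Optional named character vector of source 16S
#'   sequences (names must be a subset of the OTU ids).
#' @param min_set_size Nominal minimum probe-set size used for presence
#'   calling on the physical array (default 11); stored as metadata and
#'   applied by [filter_small_sets()].
#' @param provenance Free-text description of where the catalog came from.
#' @param probe_length Required probe length in nucleotides (default 25).
#' @return An object of class `probe_catalog`.
#' @seealso [parse_catalog()], [filter_small_sets()], [build_index()]
#' @export
#' @examples
#' probe_catalog(list(
#'   A = c(strrep("A", 25), strrep("C", 25)),
#'   B = strrep("A", 25)
#' ))
probe_catalog <- function(probe_sets, source_sequences = NULL,
                          min_set_size = 11L, provenance = "",
                          probe_length = 25L) {
  stopifnot(is.list(probe_sets), length(probe_sets) >= 0L)
  ids <- names(probe_sets)
  if (length(probe_sets) > 0L && (is.null(ids) || anyDuplicated(ids) ||
                                  any(!nzchar(ids)))) {
    stop("probe_sets must be a named list with unique, non-empty OTU ids")
  }
  probe_sets <- lapply(probe_sets, function(p) {
    p <- toupper(as.character(p))
    bad <- !is_valid_probe(p, probe_length)
    if (any(bad)) {
      stop("invalid probe(s): ", paste(utils::head(p[bad], 3L), collapse = ", "))
    }
    sort(unique(p))
  })
  if (any(lengths(probe_sets) == 0L)) stop("every probe set must have >= 1 probe")
  probe_sets <- probe_sets[order(names(probe_sets))]
  if (!is.null(source_sequences)) {
    if (is.null(names(source_sequences)) ||
        !all(names(source_sequences) %in% names(probe_sets))) {
      stop("source_sequences names must be a subset of the OTU ids")
    }
    source_sequences <- toupper(source_sequences[order(names(source_sequences))])
  }
  structure(
    list(probe_sets = probe_sets,
         source_sequences = source_sequences,
         min_set_size = as.integer(min_set_size),
         provenance = provenance,
         probe_length = as.integer(probe_length)),
    class = "probe_catalog"
  )
}

#' @export
print.probe_catalog <- function(x, ...) {
  cat(sprintf("probe_catalog: %d probe sets, %d probe instances (probe length %d)\n",
              n_probe_sets(x), total_probe_instances(x), x$probe_length))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Catalog summary accessors
#'
#' `n_probe_sets()` counts the probe sets, `total_probe_instances()` counts
#' probe instances (the sum of per-set sizes, counting a shared probe once per
#' set that carries it), and `set_sizes()` returns the named vector of per-set
#' sizes.
#'
#' @param catalog A `probe_catalog`.
#' @return An integer scalar, or for `set_sizes()` a named integer vector.
#' @export
n_probe_sets <- function(catalog) length(catalog$probe_sets)

#' @rdname n_probe_sets
#' @export
total_probe_instances <- function(catalog) sum(lengths(catalog$probe_sets))

#' @rdname n_probe_sets
#' @export
set_sizes <- function(catalog) lengths(catalog$probe_sets)

#' Parse a probe catalog from disk
#'
#' Reads an OTU-to-probe catalog. Two dialects are supported:
#' * `canonical_tsv`: the package's own format, one row per (otu_id, probe)
#'   pair with header `otu_id`, `probe` and optional `source_sequence`.
#' * `greengenes_probe_alignment`: a best-effort adapter for the text dump of
#'   the Greengenes "probes to OTU alignments" web tool. Records start with a
#'   `>` header whose first token is taken as the OTU id; within a record,
#'   whitespace/comma-separated tokens of exactly `probe_length` ACGT
#'   characters are taken as probes, and longer DNA-like lines (gaps `-`/`.`
#'   allowed, stripped) are concatenated into the source sequence. The format
#'   of that dump is not formally documented, hence best effort.
#'
#' Probes are uppercased; records whose probe has the wrong length or
#' characters outside ACGT are rejected (counted, with a warning). Duplicate
#' probes within a set are collapsed and counted. The parse log (records read,
#' rejected, duplicates collapsed) is attached as attribute `parse_log`.
#'
#' @param path Path to the input file.
#' @param dialect `"canonical_tsv"` (default) or `"greengenes_probe_alignment"`.
#' @param min_set_size,probe_length Passed to [probe_catalog()].
#' @return A `probe_catalog` with attribute `parse_log`.
#' @export
parse_catalog <- function(path,
                          dialect = c("canonical_tsv",
                                      "greengenes_probe_alignment"),
                          min_set_size = 11L, probe_length = 25L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read catalog file: ", path)
  rec <- switch(dialect,
    canonical_tsv = parse_canonical_tsv(path),
    greengenes_probe_alignment = parse_greengenes_dump(path, probe_length)
  )
  probes <- toupper(rec$probe)
  ok <- is_valid_probe(probes, probe_length)
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) {
    warning(sprintf("rejected %d probe record(s) (wrong length or non-ACGT)",
                    n_rejected))
  }
  otu <- rec$otu_id[ok]
  probes <- probes[ok]
  if (length(probes) == 0L) stop("no valid probe records parsed from ", path)
  sets <- split(probes, otu)
  n_dups <- sum(lengths(sets)) - sum(vapply(sets, function(p)
    length(unique(p)), integer(1)))
  src <- NULL
  if (!is.null(rec$source_sequence)) {
    s <- rec$source_sequence[ok]
    keep <- !is.na(s) & nzchar(s)
    if (any(keep)) {
      src <- tapply(s[keep], rec$otu_id[ok][keep], function(v) v[[1]])
      src <- stats::setNames(as.character(src), names(src))
    }
  }
  cat_obj <- probe_catalog(as.list(sets), source_sequences = src,
                           min_set_size = min_set_size,
                           provenance = sprintf("parsed from %s (%s)",
                                                path, dialect),
                           probe_length = probe_length)
  log <- list(records_read = length(rec$probe), probes_rejected = n_rejected,
              duplicates_collapsed = n_dups)
  message(sprintf(
    "parse_catalog: %d records read, %d rejected, %d within-set duplicates collapsed, %d probe sets",
    log$records_read, log$probes_rejected, log$duplicates_collapsed,
    n_probe_sets(cat_obj)))
  attr(cat_obj, "parse_log") <- log
  cat_obj
}

parse_canonical_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "")
  if (nrow(df) == 0L) stop("no probe records parsed from ", path)
  if (!all(c("otu_id", "probe") %in% names(df))) {
    stop("canonical TSV must have columns otu_id and probe")
  }
  list(otu_id = df$otu_id, probe = df$probe,
       source_sequence = if ("source_sequence" %in% names(df))
         df$source_sequence else NULL)
}

parse_greengenes_dump <- function(path, probe_length) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no '>' record headers found; not a Greengenes-style dump")
  rec_id <- cumsum(hdr)
  otu_of_rec <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  out_otu <- character(0); out_probe <- character(0); out_src <- character(0)
  for (r in seq_along(otu_of_rec)) {
    body <- lines[rec_id == r & !hdr]
    toks <- unlist(strsplit(body, "[\\s,;|]+", perl = TRUE))
    toks <- toks[nzchar(toks)]
    up <- toupper(toks)
    is_probe <- nchar(up) == probe_length & grepl("^[ACGT]+$", up)
    seqish <- !is_probe & nchar(up) > probe_length &
      grepl("^[ACGTUMRWSYKVHDBN.-]+$", up)
    src <- paste0(gsub("[.-]", "", up[seqish]), collapse = "")
    n <- sum(is_probe)
    if (n > 0L) {
      out_otu <- c(out_otu, rep(otu_of_rec[r], n))
      out_probe <- c(out_probe, up[is_probe])
      out_src <- c(out_src, rep(src, n))
    }
  }
  list(otu_id = out_otu, probe = out_probe,
       source_sequence = if (any(nzchar(out_src))) out_src else NULL)
}

#' Remove small probe sets
#'
#' Probe sets below the minimum size are usually excluded from presence
#' calling. The kept condition is size >= `min_size` (sets with
#' `min_size - 1` or fewer probes are removed).
#'
#' @param catalog A `probe_catalog`.
#' @param min_size Minimum probe-set size to keep (default: the catalog's
#'   `min_set_size`, nominally 11).
#' @return A list with elements `catalog` (the filtered `probe_catalog`) and
#'   `removed` (OTU ids of removed sets, sorted).
#' @export
filter_small_sets <- function(catalog, min_size = catalog$min_set_size) {
  stopifnot(inherits(catalog, "probe_catalog"), min_size >= 1L)
  sz <- set_sizes(catalog)
  removed <- sort(names(sz)[sz < min_size])
  kept <- catalog$probe_sets[sz >= min_size]
  src <- catalog$source_sequences
  if (!is.null(src)) src <- src[names(src) %in% names(kept)]
  if (!is.null(src) && length(src) == 0L) src <- NULL
  out <- probe_catalog(kept, source_sequences = src,
                       min_set_size = min_size,
                       provenance = catalog$provenance,
                       probe_length = catalog$probe_length)
  list(catalog = out, removed = removed)
}

#' Write a probe catalog as canonical TSV
#'
#' Writes one row per (otu_id, probe) pair; if the catalog carries source
#' sequences a third `source_sequence` column is repeated on each row of the
#' OTU. `parse_catalog(write_catalog(x))` reproduces `x` field for field.
#'
#' @param catalog A non-empty `probe_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "probe_catalog"))
  if (n_probe_sets(catalog) == 0L) stop("refusing to write an empty catalog")
  otu <- rep(names(catalog$probe_sets), lengths(catalog$probe_sets))
  df <- data.frame(otu_id = otu, probe = unlist(catalog$probe_sets,
                                                use.names = FALSE),
                   stringsAsFactors = FALSE)
  if (!is.null(catalog$source_sequences)) {
    df$source_sequence <- catalog$source_sequences[df$otu_id]
    df$source_sequence[is.na(df$source_sequence)] <- ""
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read FASTA sequences
#'
#' Reads a (possibly aligned) FASTA file, strips alignment gaps (`-` and `.`),
#' uppercases, and returns a named character vector. Duplicate record ids are
#' made unique with a deterministic `_dup<k>` suffix (warning). The id is the
#' first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (possibly empty, with warning).
#' @export
parse_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(ss) == 0L) {
    warning("FASTA file contains no records: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  seqs <- toupper(gsub("[.-]", "", as.character(ss)))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids suffixed deterministically")
    ids <- make.unique(ids, sep = "_dup")
  }
  stats::setNames(unname(seqs), ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read an OTU taxonomy table
#'
#' A TSV with header `otu_id`, then the ranks `domain`, `phylum`, `class`,
#' `order`, `family`, `genus` (missing ranks allowed as empty strings).
#'
#' @param path Path to the TSV.
#' @return A data.frame with character columns `otu_id` + the six ranks.
#' @export
parse_taxonomy <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  if (!"otu_id" %in% names(df)) stop("taxonomy table must have an otu_id column")
  for (r in setdiff(ranks, names(df))) df[[r]] <- ""
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in taxonomy table")
  df[, c("otu_id", ranks)]
}
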