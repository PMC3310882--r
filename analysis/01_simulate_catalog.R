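#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# Builds a synthetic probe catalog with planted confounding structure (subset
# pairs, zero-unique union-assemblable sets, a shared probe pool whose use
# grows with set size), reference 16S-like sequences embedding every probe
# set, a taxonomy, and the planted-truth record that later stages are checked
# against. Everything is seed-deterministic.

suppressPackageStartupMessages({
  library(probeaudit)
  library(jsonlite)
})

out_dir <- file.path("results", "synthetic")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
SEED <- 20120322L

cfg <- generator_config(seed = SEED)   # package defaults: 60 sets, sizes 11-80
g <- generate_catalog(cfg)
refs <- generate_references(g$catalog, seed = SEED + 1L)
tax <- generate_taxonomy(names(g$catalog$probe_sets), n_classes = 3L,
                         n_families = 8L, seed = SEED + 2L)

write_catalog(g$catalog, file.path(out_dir, "catalog.tsv"))
write_fasta(refs, file.path(out_dir, "references.fasta"))
write.table(tax, file.path(out_dir, "taxonomy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_json(list(seed = g$truth$seed,
                subset_pairs = g$truth$subset_pairs,
                planted_zero_unique = g$truth$planted_zero_unique,
                donors = g$truth$donors,
                unique_counts = as.list(g$truth$unique_counts),
                zero_unique_otus = g$truth$zero_unique_otus),
           file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
saveRDS(g$truth, file.path("scratch", "truth.rds"))  # full truth for reuse

cat(sprintf("simulated catalog: %d probe sets, %d probe instances\n",
            n_probe_sets(g$catalog), total_probe_instances(g$catalog)))
cat(sprintf("planted: %d subset pairs, %d zero-unique sets (donor-split), shared pool of %d probes\n",
            nrow(g$truth$subset_pairs), length(g$truth$planted_zero_unique),
            cfg$shared_pool_size))
cat(sprintf("total zero-unique sets incl. planted subsets: %d\n",
            length(g$truth$zero_unique_otus)))
cat("outputs in", out_dir, "\n")
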