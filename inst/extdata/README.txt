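Place real-array inputs here (none are shipped with the package):

  greengenes_catalog.tsv   the G2 PhyloChip OTU->probe catalog, either as the
                           package's canonical TSV (otu_id<TAB>probe) or the
                           raw Greengenes probes-to-OTU-alignments dump (any
                           non-.tsv extension; parsed with the
                           greengenes_probe_alignment dialect)
  ispma_sample.fasta       the 64-OTU anaerobic community sample (one 16S
                           reference sequence per input OTU)

With these present, the acceptance tests in tests/testthat/test-acceptance.R
additionally verify the published catalog statistics and the 96-taxon
in-silico detection result. Alternatively set
options(probeaudit.catalog = "<path>") to point at a catalog elsewhere.
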