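---
title: "Auditing phylogenetic microarray probe catalogs: methods and design"
author: "probeaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing phylogenetic microarray probe catalogs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probeaudit)
```

## The problem

Phylogenetic microarrays such as the G2 PhyloChip detect bacterial and
archaeal taxa by hybridizing labelled 16S rDNA to sets of 25-mer probes, one
probe set per operational taxonomic unit (OTU). An OTU is called *present*
when a specified fraction of its probe set — typically 90 to 95% — lights up.
Because 16S is highly conserved, the same 25-mer is often a perfect match to
many taxa and therefore appears in many probe sets. That sharing undermines
the independence assumption behind per-OTU presence calls in three
structurally distinct ways, all of which this package detects directly from
the catalog, before any chip is ever run:

1. **Subset sets.** If probe set $B$ is an exact subset of probe set $A$,
   any sample containing organism $A$ necessarily lights 100% of $B$'s
   probes: $B$ is reported present whether or not it is there.
2. **Union-assemblable (zero-unique) sets.** If every probe of $B$ occurs in
   *some* other set, a combination of donor organisms can light all of $B$'s
   probes with $B$ absent. Zero-unique sets are exactly the sets whose
   externally coverable fraction is 1.
3. **Non-functional sets.** A probe set that fails to match its *own*
   reference 16S sequence cannot report its target even when the organism is
   present.

On top of the structural audit, the package quantifies two downstream
consequences: inflation and distortion of a known community under in-silico
hybridization, and excess positive correlation of OTU intensities across
arrays relative to the exact independence null of Pearson's $r$.

## The catalog model and the inverted index

A catalog maps OTU ids to probe sets. Probes are concrete oligos: uppercase,
exactly 25 nt, alphabet `ACGT`; anything else is rejected at parse time
rather than masked, since ambiguity codes in what should be a synthesized
25-mer indicate upstream corruption. Within a set, duplicate probes are
collapsed (presence calling is per *distinct* probe), and the in-memory model
is canonicalised — probes sorted within sets, sets sorted by OTU id — so
parsing is order-insensitive and the canonical TSV round-trips exactly.

The audit's workhorse is the inverted index: probe sequence $\to$ sorted set
of OTU ids carrying it. A probe's *multiplicity* is the size of that set;
*unique* means multiplicity exactly 1 across the whole catalog being indexed.
Per-set uniqueness is then a single pass over probe instances, and subset
detection enumerates candidate containers through the index (only OTUs
sharing at least one probe with the target are counted), which keeps the cost
near-linear in probe instances instead of quadratic in sets. Both paths are
verified in the test suite against deliberately naive oracles: an all-pairs
subset test and a pairwise uniqueness count.

Two conventions matter and are configurable at the call site:

* Uniqueness is computed over whatever catalog is indexed. The workflow
  filters out sets below the minimum presence-callable size (default 11
  probes, kept condition $\ge 11$) *before* indexing, so "zero-unique"
  refers to the effective catalog; indexing the unfiltered catalog is a
  one-line change.
* Containment is non-strict set inclusion with distinct OTU ids, so two
  identical probe sets are reported as containing each other — both are
  hazards, and the symmetric report makes that visible.

## Union cover and the presence hazard

For a target set of size $m$ with $u$ probes held by no other OTU, the
externally coverable fraction is $(m-u)/m$; it equals 1 exactly when the set
is zero-unique, an equivalence asserted on every synthetic catalog the tests
generate. The donor decomposition uses greedy set cover — at each step the
OTU covering the most still-uncovered probes, ties broken toward the smaller
OTU id — because minimum-cardinality cover is NP-hard and the decomposition
is diagnostic, not claimed minimal. *Critical donors* are reported where a
probe's external multiplicity is exactly 1: removing that single donor
organism is the only way the probe goes dark, and
`coverage_without_donor()` quantifies how little that helps (a 22-probe set
with one critical donor still shows 21/22 = 95.4% coverage, above a 95%
presence cutoff).

The presence-hazard report flags, at a given threshold $t$, every OTU whose
coverable fraction is $\ge t$. The flag uses $\ge$ deliberately: it answers
"could donors alone reach the cutoff", the conservative reading for a
screening report, and is monotone in $t$. At $t = 1$ it flags exactly the
zero-unique sets.

## In-silico hybridization (ISPMA)

A sample is a FASTA file of reference sequences. Each sequence is decomposed
into its complete set of 25-mers at step 1; windows containing non-ACGT
characters are skipped and counted. A probe is matched when any window from
any sequence equals it exactly, and counts at most once per OTU. Presence is
called per threshold on the matched fraction.

Assumptions and switches:

* **Perfect match only.** This is the best-case scenario; mismatch tolerance
  and cross-hybridization free energies are out of scope, so real chips can
  only do worse than the distortions shown here.
* **Strand.** Probes are matched against the given strand by default, since
  the catalog's probes are written in the sense of the reference sequences
  they were designed from; `revcomp = TRUE` also looks up each window's
  reverse complement for protocols that label the complementary strand.
* **Comparator.** Presence uses strict `>` by default ("more than 90%"),
  with `comparator = "geq"` available; at the usual thresholds the two differ
  only for sets whose matched fraction lands exactly on the cutoff.
* **Intensities.** None are simulated: the perfect-match/mismatch 1.3×
  intensity rule is chip physics below the presence-level abstraction this
  audit works at.

`trace_target()` explains any OTU's matched count probe by probe — which
sample sequences contributed each match and which other OTUs share the probe
— which is how a false positive is attributed to its donors.

## Probe-set self-validation

`validate_probe_sets()` asks whether each set would detect its own reference:
every probe must be matched by at least one 25-mer of the reference. OTUs
with no reference supplied are reported as *unvalidatable*, not failed. For
failures, `classify_failure()` applies two heuristics in order:

* *join artifact*: a missing probe matches the reference after deleting runs
  of Ns and rejoining the flanks — the signature of probes designed on an
  N-collapsed sequence;
* *possible consensus*: a missing probe aligns to the reference with exactly
  1–2 substitutions, as expected for probes designed against a consensus.

The 1–2 substitution cutoff operationalises a qualitative judgment and is
labelled heuristic; everything else is *unknown*. Indels are deliberately not
searched — with 25-mers, a 1–2 substitution window test already separates the
two documented failure modes on constructed fixtures.

## Correlation independence null

If two OTUs' intensities across $n$ arrays were independent bivariate-normal
draws, Pearson's $r$ would have the exact density

$$ f(r) = \frac{(1 - r^2)^{(n-4)/2}}{B(\tfrac12, \tfrac{n-2}{2})},
   \qquad r \in [-1, 1], \; n \ge 4 , $$

implemented in closed form rather than via a numerical p-value table; the
tests check it integrates to 1 within $10^{-6}$, equals the independent
re-derivation $r = 2\,\mathrm{Beta}(\tfrac{n-2}{2}, \tfrac{n-2}{2}) - 1$, and
matches Monte-Carlo $r$ from simulated independent data (Kolmogorov–Smirnov,
$n \in \{5, 18, 30\}$, 20&nbsp;000 replicates). Observed within-class $r$
values are binned at width 0.02 over $[-1, 1]$ (100 bins) and both curves are
reported on the density scale, i.e. scaled to equal area, so shape is
comparable regardless of pair count. The single-number skew diagnostic is the
fraction of pairs with $r > 0.5$, observed versus expected under the null
(about 0.017 at $n = 18$); probe sharing drags it upward several-fold in the
confounded simulations. Rows with zero variance have undefined $r$; pairs
involving them are skipped and counted, and at least 4 arrays are required
(the null density is otherwise improper).

The enrichment question — are detected OTUs disproportionately drawn from
the zero-unique subpopulation? — is the upper-tail hypergeometric probability
$P(X \ge k)$ for $k$ of $n$ detections falling in a special class of $K$ out
of $N$ sets, computed by exact summation (`phyper`, checked against explicit
enumeration for $N \le 20$). The population size $N$ is a parameter: the
workflow defaults to the size-filtered catalog, which is the population the
detections were called against, but nothing in the test fixes that choice.

## The synthetic-data generator

Every pipeline input can be generated with planted, machine-readable truth,
so the whole audit is testable without any external download. The model:

* **Catalog.** Each ordinary set mixes globally distinct fresh 25-mers with
  draws from a common shared pool; the per-set sharing probability is
  `sharing_intensity * set_size / set_size_max` by default, so uniqueness
  declines as set size grows, the qualitative pattern of real catalogs.
  Planted exactly on top of that background: subset pairs (one set a strict
  subset of one other), and zero-unique sets whose probes are split between
  two donor sets — union-assemblable but contained in no single OTU. Every
  non-planted set keeps at least one fresh probe, so no accidental
  containment or zero-uniqueness can occur and recovery checks can demand
  exactness. Truth (per-set unique counts, pairs, donors, each probe's
  originating set) is recorded from construction-time bookkeeping, not by
  re-indexing the catalog.
* **References.** Each OTU gets a uniform-random DNA backbone with its probes
  embedded verbatim, non-overlapping, on the forward strand, filler
  distributed so the sequence has exactly the requested length. A filler
  junction colliding with another set's 25-mer has probability about
  $4^{-25}$ per window and is neglected. Default backbone length is the
  embedding minimum plus 200 nt; real 16S genes are ~1.5 kb, and nothing
  downstream depends on the length beyond feasibility.
* **Abundances.** Each originating organism gets an independent standard
  normal latent signal per array; a probe carries its originator's signal;
  an OTU's intensity is the mean over its probes plus $N(0,
  \sigma_\text{noise}^2)$ noise. Disjoint sets are then exactly independent
  (their $r$ follows the null), identical sets correlate perfectly at zero
  noise, and shared-probe blocks are positively correlated — the three
  regimes the tests pin down. The default of 18 arrays matches the
  multi-array reanalysis setting the correlation machinery targets.
* **Detected lists.** OTUs are sampled without replacement with zero-unique
  sets over-weighted by a factor; weight 1 makes the overlap exactly
  hypergeometric (verified by a goodness-of-fit test over 200 replicates),
  and infinite weight draws only zero-unique sets.

What the generator does *not* emulate: phylogenetic covariance among
sequences (backbones are random DNA, so there is no "sharing is concentrated
within classes" structure unless planted), realistic intensity distributions,
or the empirical joint distribution of set size and uniqueness in any real
catalog — the real G2 catalog has an order of magnitude more zero-unique sets
than a background-sharing model of this kind produces. Passing tests
therefore demonstrate the *machinery* is correct on data whose ground truth
is known, not that any particular physical chip is faulty; conclusions about
a real array require running the same functions on its downloaded catalog.

## Defaults, sizes and numerical choices

* Probe length 25 nt; minimum presence-callable set size 11 (kept condition
  $\ge 11$); thresholds 0.90/0.92/0.95 with strict `>`.
* Generator defaults: 60 sets, sizes 11–80, 3 subset pairs, 3 zero-unique
  sets, sharing intensity 0.15 against a 150-probe pool — a catalog small
  enough to audit in milliseconds while exercising every structure; the
  property suites run 100 seeded configurations of 12 sets each, and the
  oracle-equivalence checks use random catalogs of up to 40 sets × 30
  probes, where brute force is still instant.
* Ties anywhere (greedy donor choice, orderings) break toward the
  lexicographically smaller OTU id; all outputs are sorted, so every
  function is deterministic given its inputs and seed.
* `low_uniqueness_otus()` uses a strict `<` bound (so 0 selects nothing);
  the hazard flag uses `>=` (could donors reach the cutoff).
* Quadrature for the null's tail uses `integrate` at `rel.tol = 1e-10`; the
  density-integral acceptance tolerance is $10^{-6}$.
* Degenerate inputs: empty catalogs refuse to index; an empty hybridization
  sample yields an all-zero report with a warning; zero-variance abundance
  rows are skipped with a count; infeasible generator configurations fail
  with an explanation rather than silently clamping.

## Known limitations

* The Greengenes probe-dump adapter is best-effort: that export format is
  not formally documented, so the package defines a canonical TSV and treats
  the dump parser as a tolerant front end — check the parse log's rejected
  and collapsed counts when ingesting real dumps.
* Exact matching only; a probe one mismatch away from a sample 25-mer
  contributes nothing, so the simulated distortions are a lower bound on
  what a physical chip with imperfect hybridization could report.
* The independence null assumes bivariate normality of intensities; on real
  intensity data the equal-area histogram comparison is diagnostic, not a
  calibrated test.
* `classify_failure()` recognises the two documented failure signatures
  only; failures arising from other catalog-curation errors land in
  `unknown`.
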