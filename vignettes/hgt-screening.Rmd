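---
title: "Detecting and curating horizontal gene transfer with HGTscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and curating horizontal gene transfer with HGTscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HGTscan)
```

## The problem and the model

Phagotrophic protists ingest bacteria and microscopic algae, and some of
their food's genes end up integrated into the nuclear genome. Detecting such
horizontally transferred (HGT) genes from a sequenced genome is an inference
problem with two complementary signals:

1. **Similarity structure.** A vertically inherited gene of, say, a
   choanoflagellate finds its strongest homologs among metazoans and fungi
   (its "kin"); a transferred gene finds them in the donor lineage. The
   *alien index* condenses this into one number per query: the ratio of the
   best bit score among candidate-donor taxa (prokaryotes and algae) to the
   best among kin. Bit scores rather than E-values are compared because they
   are database-size independent.
2. **Tree topology.** A transferred gene should branch *inside* the donor
   diversity. On an unrooted maximum-likelihood or distance gene tree this
   is a bipartition question: some supported internal edge must separate the
   query (plus any focal-lineage homologs) together with donor leaves from
   everything else, with no kin leaf on the query side.

Neither signal alone is reliable — top-hit ranks are noisy, single gene
trees are noisy — so curated surveys combine candidate screening, a
bootstrap-support requirement, phyletic-distribution rules, and manual
checks. HGTscan encodes that protocol so the decisions are explicit,
parameterized, and testable.

### Taxon grouping

Every subject taxon maps to one of five groups — `SELF`, `KIN`,
`PROKARYOTE`, `ALGA`, `OTHER_EUK` — by longest-prefix match on its
semicolon-delimited lineage. Longest-prefix matching tolerates ranks missing
from some records and lets specific rules (oomycetes, ciliates) override
broader ones. Design points worth stating:

* "Algae" is deliberately loose: all lineages with primary, secondary or
  tertiary plastids, **plus oomycetes and ciliates**, which are widely
  interpreted as secondarily non-photosynthetic. The point of the group is
  "plausible algal donor", not photosynthesis today.
* Archaea and bacteria share the `PROKARYOTE` group for screening, but each
  taxon's domain is retained in the scheme so reports can distinguish them.
* A second species of the focal lineage maps to `SELF`: shared presence in a
  sister species indicates acquisition before their split, never evidence
  against transfer.
* A eukaryotic lineage matching no specific group falls back to
  `OTHER_EUK`; a lineage whose domain cannot be resolved at all is dropped
  as an error.

### Hit filtering

Three exclusions are applied before screening, mirroring standard practice:
self-group hits (the query's own lineage), hits covering less than 10% of
the query length, and subjects annotated as artificial sequences, synthetic
constructs or plasmids (case-insensitive substring match, because annotation
strings in the wild vary). Coverage is defined relative to the *query*
length: the companion rule used for tree building (at least 60% of the
query) shows query-relative coverage is what such protocols intend. The two
E-value ceilings in common use — 1e-5 for similarity screening, 1e-10 for
tree-screening input — are parameters, not constants. The three rules
commute and are applied in one stable pass.

### The alien index

For a filtered table, `alienIndex()` computes the ratio of group-wise
bit-score maxima. Conventions:

* The candidate rule is **inclusive**: AI ≥ 1.2 flags a candidate. The
  threshold 1.2 is the established default of similarity-ratio screeners;
  genes below it are exactly the ones such screens are known to miss.
* "Close" defaults to `KIN` only. `OTHER_EUK` counts toward neither side by
  default — the screen targets specifically prokaryotic/algal affiliation —
  but both group sets are arguments.
* Donor homologs with no kin homolog give AI = ∞ (a candidate). No homologs
  on either side is `NO_HOMOLOGY`: never a candidate, reported separately,
  because every transfer call ultimately rests on donor-group homology.

Lineage-probability detectors (DarkHorse-style) and automated tree pipelines
are *not* reimplemented; `importCandidates()` ingests their candidate lists
so consensus accounting across detectors still works.

### The clade test

`cladeTest()` evaluates unrooted bipartitions, since published gene trees
are unrooted: a "clade with donors" means a support-annotated split
isolating query + donors (+ `SELF`, optionally + `OTHER_EUK`). Numerical
and policy choices:

* **Missing supports fail closed** (treated as 0): the criterion demands
  explicit bootstrap support.
* **Dual supports** ("85/70" from ML and distance analyses) combine by the
  minimum by default — if two analyses disagree, the weaker number is the
  honest one — with `combine = "first"` available for ML-only reading.
  Labels that are all ≤ 1 are read as fractions and rescaled; `*` and empty
  labels mean unknown.
* **`OTHER_EUK` leaves inside the clade are tolerated by default**
  (lenient): real gene trees routinely show stray eukaryotic sequences
  branching with prokaryotic homologs, and such genes were retained in
  curated surveys. Strict mode is one argument away.
* Among passing splits the **smallest query side** is reported (ties to the
  higher support): it is the most specific statement about the donor.
* A binary-rooted input shows one split twice (both root children); the
  duplicate is collapsed keeping the better-annotated support, which makes
  the test invariant under rerooting.
* Screening uses support ≥ 50, curation ≥ 70. Both are arguments; the
  50/70 pairing follows the convention of batch tree screens followed by
  per-gene curation.

### Curation rules

A gene is `ACCEPTED` on either of two recorded evidence routes: a passing
70% clade test, or a phyletic distribution restricted to the focal lineage
plus donor groups (`PROK_ONLY`, `ALGA_ONLY`, `PROK_ALGA_ONLY`). The second
route covers genes whose trees are uninformative but whose distribution
alone is inconsistent with vertical descent. Genes with no non-self
homology are `NO_CALL`; the rest are `REJECTED`.

* **Donor class**: pure algal clade → `ALGA`, pure prokaryotic →
  `BACTERIA`, mixed → `EITHER`; pattern-route genes map analogously. An
  optional margin rule demotes a pure call to `EITHER` when the best algal
  and prokaryotic bit scores are within a configurable ratio; it is **off by
  default** because no published numeric rule exists for the ambiguous
  class, and the mixed-clade route already produces it.
* **Direction**: restricted patterns and donor-affiliated broad patterns are
  called `INTO_FOCAL`; the asymmetry rests on phagotrophy (the focal
  organism eats the donors) and on donor lineages predating it.
* **Events**: accepted paralogs that form one focal clade in their family
  tree collapse to a single acquisition event. All focal-genome leaves
  participate in the clustering — a non-accepted paralog inside an accepted
  clade should not split the event — but only clusters containing accepted
  genes become events. Clustering is implemented by rooting the family tree
  at a non-focal leaf and taking maximal all-focal subtrees, which is
  exactly the unrooted-split notion and hence invariant to rerooting and
  child order. Cross-family merging is deliberately not attempted; event
  totals are estimates.
* **Sharing**: a gene whose best hit in the sister proteome reaches
  E ≤ 1e-40 is marked acquired before the two species diverged.
* **Manual evidence** (shared indels, conserved residues, gene structure,
  alignment quality, contamination) is a checklist an operator fills, not an
  algorithmic decision. One helper exists: `flagContamination()` marks
  accepted genes whose scaffold neighbors all lack kin affiliation, i.e.
  genes whose genomic context cannot rule out assembly contamination.

## The simulator

`simulateGenome()` emulates the *data shapes* the pipeline consumes, not
sequences: no residues are evolved. On a fixed 23-taxon scaffold spanning
all five groups it emits, per gene, a hit table, a support-annotated family
tree, a sister-proteome hit, and truth labels.

* **Scores**: bitscore = base − decay × (taxonomic distance from the gene's
  origin) + Gaussian noise, floored at 0. E-values are a fixed strictly
  decreasing transform of the bit score — only the ordering is contractual.
  With the defaults (base 300, decay 40) a vertical gene has kin scores
  around 260 against donor scores around 180 (AI ≈ 0.7), and a transferred
  gene the reverse margin (AI ≈ 1.6), so the 1.2 threshold sits between the
  two populations.
* **Trees**: vertical genes attach next to the kin clade; transfers are
  regrafted inside their donor clade (a mixed bacterial+algal clade for
  `EITHER` donors), with the sister species joining the query block when the
  event predates the split. The attachment edge draws its support from
  `supportStrong` (85–100) or, for a configurable fraction, `supportWeak`
  (30–65) to exercise the 50/70 thresholds. Background edges draw from
  20–45, below both thresholds, so the planted attachment edge alone decides
  the test — that is what makes threshold experiments interpretable.
* **Noise coupling**: the bitscore noise level also degrades attachment
  supports (subtracting half-noise-scaled folded-normal draws), modelling
  that noisier data weakens bootstrap support. This single knob makes
  full-pipeline sensitivity genuinely non-increasing in noise.
* **Families**: each planted transfer either starts a new family (one event)
  or, with the duplication probability, joins the previous transfer's family
  as a post-transfer paralog. Planted event counts are therefore known
  exactly and `collapseEvents()` can be validated against them.
* **Determinism**: all randomness flows from one seed; two runs with the
  same configuration are identical, and the global RNG state is restored.
  Emitted files carry the configuration (and a small digest of it) in header
  comments.

Defaults are the package's validation conditions: 500 genes, 20% planted
transfers, donors mixed 240:139:26, pre-split fraction 213/405, noise sd 10.
What the simulator does **not** model — database composition bias,
long-branch attraction, alignment quality, differential loss, contamination
— is precisely what the manual checklist exists for in real data, so passing
synthetic tests demonstrates the correctness of the decision rules, not the
biological error rate of the protocol.

## Validation and sizes

The test suite checks each operation against an independent oracle where one
exists: the clade test against exhaustive bipartition enumeration (through a
different tree library) on hundreds of random ≤ 12-leaf trees; the alien
index against a single-pass maximum scan on ~1,000 random hit tables;
threshold monotonicity of both screens; invariance of clade calls and event
partitions under rerooting and child permutation; and exact recovery
(sensitivity, specificity, event counts, pre-split flags all 1.0/exact) on
noise-free simulations of a few hundred genes — sizes chosen to exercise
every code path while keeping the default suite fast. The packaged 405-gene
reference ledger reproduces its survey's printed summary statistics
arithmetically; only its *marginal* totals are meaningful, the per-row flag
assignment being an arbitrary consistent construction.

## Known limitations

* The pipeline consumes precomputed hits and trees; search, alignment and
  tree inference quality are upstream of it.
* Monophyly is the only topological signal used; reconciliation-based or
  likelihood transfer models are out of scope.
* The ambiguous donor class has no principled numeric boundary; the margin
  rule is provided but off by default.
* Event collapsing never merges across families, so event totals are upper
  estimates under fragmented family assignments.
* Taxon mapping is by exact name with no synonym handling or taxonomy
  database access.
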