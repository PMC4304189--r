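---
title: "Methods: annotating and cross-mapping bidirectional promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and cross-mapping bidirectional promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method: the model and
its assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic benchmark does and does not demonstrate, and
the numerical and design choices made where the procedure was genuinely
underdetermined.

## The model

A bidirectional promoter is defined purely positionally: a minus-strand
gene locus and a plus-strand gene locus on the same chromosome,
transcribed away from each other, whose transcription start sites are
separated by at most 1,000 bp. The promoter is the inter-TSS interval
`[tss_left, tss_right)`. Three assumptions carry the whole analysis:

* **Annotation-driven discovery.** Loci come from transcript evidence
  (curated gene models, or spliced ESTs with at least one intron), not
  from epigenomic signal, so the method is tissue-independent but
  inherits any incompleteness of the annotations.
* **Coding-anchored orthology.** Orthology of the flanking genes — not
  sequence conservation of the promoter — identifies the orthologous
  promoter. Alignments are consumed as UCSC chains (gapless aligned
  blocks separated by target/query gaps) and nets; only level-1 net
  fills are treated as orthologous, because deeper levels capture
  rearrangements and paralogous copies.
* **Divergent-pair synteny for anonymous transcripts.** Spliced ESTs
  carry no protein identity, so their orthology criterion is purely
  positional: a divergent pair present at the mapped location under the
  same distance rule.

### The five-category decision procedure

Each gene of each pair is assessed independently, in a fixed order that
makes the categories mutually exclusive:

(a) its TSS must be covered by a level-1 net fill — otherwise **C5**;
(b) the union of its exon blocks must have at least half of its bases
    inside gapless chain blocks (configurable), and its span must map to
    at least one base — otherwise **C5**;
(c) the best-overlapping gene locus at the mapped location is looked up:
    none → **C5**; present but failing the identity check (ortholog
    table for known genes, position for ESTs) → **C4**;
(d) the nearest divergent partner of that target ortholog is sought
    within the distance limit, measured between *target-side* TSSs:
    none → **C3**;
(e) the partner is checked for orthology to the source partner:
    yes → **C1**, no → **C2**.

A promoter is confirmed orthologous when both genes are C1. Counts always
partition the assessed genes, and relaxing the distance limit can only
move genes out of C3 (into C1 or C2), never create C4/C5 — both
properties are asserted in the test suite.

Where the mapped gene is non-orthologous *and* a divergent partner
exists, the order above records C4: the identity failure at the assessed
location is treated as more informative than the partner's existence.
When several level-1 fills cover one TSS (possible at fill boundaries),
the higher-scoring chain wins. Whether the 1,000 bp rule on the target
side should be measured between target TSSs or between lifted source
coordinates was an open choice; we use target TSSs, since that is the
same definition a discovery run in the target genome would apply.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `max_tss_distance` | 1,000 | bp | the field's standard definition of a bidirectional pair |
| CAGE coincidence tolerance | 100 | bp | resolves a CAGE summit to one promoter while absorbing 5'-end jitter of capped tags |
| profile `window` / `bin` | 500 / 50 | bp | wide enough to show the TSS peak against background; bins are *centred* on offsets −500…500 so a single central bin contains offset 0 |
| CpG promoter width floor | 200 | bp | a zero-width promoter (shared TSS) still represents a real region; 200 bp is a conservative island-overlap window |
| single-gene promoter flank | ±500 | bp | symmetric window around the TSS of unpaired genes |
| `align_threshold` | 0.5 | fraction | exons must fall mostly into alignable positions; 0.5 tolerates partial 3' gaps without accepting spurious overlaps |
| confidence cutoffs | 2 / 5 | transcripts | levels 2 and 3 require both loci to reach the cutoff; monotone by construction |

All of these are exposed in `pipeline_config()`; none is hard-coded in
the classifiers.

The correlation analysis uses Pearson on `log2(value + 1)` profiles
(Spearman available). "Median expression ratio" is implemented as the
per-tissue median over replicate arrays taken *before* the log transform;
correlations are then invariant to per-gene affine rescaling on the log
scale, which the suite verifies.

## The synthetic benchmark

`generate_dataset()` lays out 20 kb cassettes along each chromosome, one
divergent pair per cassette, and plants one orthology category per
cassette: conserved pairs (C1), a non-orthologous partner (C2), a deleted
or over-limit partner (C3), an unrelated gene at the mapped location
(C4), and cassettes inside alignment gaps, optionally under a level-2
paralog fill (C5). Chains are built block-by-block with planted
insertions (unequal target/query gaps) so coordinates drift between
genomes; the span invariants of the chain format are checked on write and
re-checked on read. The generator emits both alignment directions, and
every file goes through the package's own writers so the round-trip
property is exercised on realistic content.

Emulated statistical structure: TSS distances uniform on 100–1,000 bp
(plus an over-limit fraction for no-limit tests), CAGE summits
Normal(0, 30 bp) around true TSSs with a 66% coordinated-activation
rate, CpG islands at 90.6% of bidirectional and 55.3% of single-gene
promoters, 79 tissues (21 shared across species) with two replicate
arrays each, a latent-factor pair co-expression loading of 0.6, and a
cross-species ortholog correlation of 0.5. Expression values are
generated as `2^z − 1` of Gaussian log-profiles, so the analysis-side
`log2(value + 1)` transform recovers the planted correlation scale
exactly up to replicate noise.

What passing the benchmark does **not** show: real annotations have
fragmented and overlapping transcript models, chains carry
translocations and inversions (the generator's alignments are co-linear
and plus-strand; minus-strand mapping is exercised separately against a
per-base oracle and an independent liftOver implementation), true CAGE
background is far denser, and real ortholog tables contain one-to-many
relations. Recovery rates on this benchmark are therefore upper bounds,
not estimates of genome-wide performance.

Problem sizes: the category-recovery benchmark uses 40 cassettes per
category over 8 chromosomes; monotonicity is checked over 50 independent
7-pair datasets; expression recovery uses 500 genes over 21 tissues.
These sizes put all planted rates well inside detectable range for
binomial confidence checks while keeping the full suite quick to run.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally (the native
  convention of BED, genePred and chain files); the only 1-based shift
  happens at the IRanges boundary, in one helper.
* Reverse-strand chain query coordinates are stored exactly as the file
  states them (reversed-strand convention) and flipped only inside
  `map_interval()`, keeping parsing lossless.
* A zero-width promoter (TSS distance 0) is treated as a 1 bp point for
  overlap purposes and padded for CpG statistics.
* Greedy pairing ranks candidate pairs by TSS distance with ties broken
  by smaller start coordinate, so each locus joins at most one pair
  deterministically. The underlying annotations never address a locus
  with two equally eligible partners, so this tie-break is a package
  decision.
* `collapse_promoters()` resolves overlapping candidates toward the
  candidate with the most supporting transcripts (ties: smaller TSS
  distance, then leftmost), aggregates the absorbed supporters, and is
  idempotent.
* Constant expression profiles make a correlation undefined; such
  records are flagged, reported, and excluded from histograms rather
  than coerced to 0.
* In the spliced-EST BED12 dialect the score column carries the
  canonical-intron flag (1/0), since BED12 has no natural slot for it;
  with a genome sequence supplied, GT..AG (CT..AC on the minus strand)
  is verified directly instead of trusting the flag.
* An empty pair list makes the coordinated-activation fraction
  undefined; it is reported as `NA`, not 0.

## Known limitations

* One-to-one greedy pairing cannot represent a locus participating in
  two promoters (tandem arrangements with shared genes).
* EST orthology by position alone cannot distinguish a conserved ncRNA
  pair from an unrelated transcript that happens to occupy the syntenic
  interval.
* The five-category scheme assesses genes independently; a pair whose
  two genes map through different chains to different chromosomes is
  reported gene-by-gene, with the promoter verdict simply requiring both
  to be C1.
* Genome-wide counts from specific public assemblies depend on those
  releases' annotation sets and are out of scope here; the package
  reproduces the arithmetic and the statistical behaviour of the
  procedure, not release-specific totals.
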