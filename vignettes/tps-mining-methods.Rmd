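---
title: "Mining terpene synthase gene families: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining terpene synthase gene families: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpsminer)
```

## Overview

`tpsminer` reconstructs, as tested reusable code, the standard procedure for
cataloguing a plant terpene synthase (TPS) gene family from a genome
assembly: profile-based domain screening, splice-and-translate curation into
functional / partial / probable-pseudogene categories, degenerate-motif
profiling, intron-exon structural classing, and neighbor-joining subfamily
assignment against a labeled reference panel. Because genome surveys of this
kind are usually run against in-house assemblies that never become public,
the package treats a synthetic-genome generator as a first-class module: it
plants genes with known subfamily, category, motif complement and intron
count, so that every downstream stage can be validated against ground truth.

This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and the places where the design was genuinely open.

## The synthetic-genome generator

`make_subfamily_template()` builds one protein template per subfamily with
the motif complement the family shows in real surveys:

| subfamily | length (aa) | planted motifs | structural class |
|---|---|---|---|
| a, b | 560 | RR(X)8W, RXR, DDXXD, NSE/DTE | III (6 introns) |
| g | 560 | RXR, DDXXD, NSE/DTE | III |
| e, f | 820 | DDXXD, NSE/DTE | I (12-14 introns) |
| c | 820 | DXDD only (class II: no DDXXD) | I |

Lengths follow the catalogue ranges of real full-length TPS proteins
(roughly 560 aa for mono-/sesquiterpene synthases, 820 aa for diterpene
synthases). Where both RXR and DDXXD are planted, the DDXXD start sits
exactly 35 residues downstream of the RXR start, the canonical arrangement.
All templates additionally share two fixed 80-residue domain cores — one
N-terminal, one C-terminal — that emulate the cross-subfamily conservation
of the two TPS Pfam domains that real screens key on. The cores are
synthetic constants (hard-coded in the source, verified to contain no
canonical motif match under any flanking context); they are not taken from
any real protein.

Filler positions are uniform-random residues. Any chance match to a motif
that was *not* planted is re-drawn ("scrubbed"), so a template's motif scan
returns exactly the planted set — this is what makes 100%-recall and
exact-class assertions meaningful. Gene copies within a subfamily are derived
by `mutate_template()`: per-site substitution at `core_divergence` outside
the planted motif spans, followed by the same scrub. Templates of different
subfamilies are drawn independently, giving ~95% divergence at filler sites.

`simulate_gene()` reverse-translates a template with a fixed
most-frequent-codon table (deterministic output; realistic codon-usage bias
is a non-goal), appends a terminal stop, and splits the CDS into exons
separated by GT..AG introns with lengths uniform on [60, 200] nt (intron
counts are what the literature specifies; lengths are not, so a compact
band was chosen to keep synthetic scaffolds small). Category effects:

* **pseudogene** — one in-frame premature stop codon or a single 1-nt
  deletion (frameshift), placed in the 45-75% span of the CDS. That window
  sits downstream of the N-terminal domain core, so pseudogenes remain
  discoverable by the screen, as they are in real surveys, while the lesion
  itself stays outside planted motif spans.
* **partial** — the protein is truncated to 150-280 residues, which always
  removes the catalytic C-terminal region (and at least one planted motif)
  while retaining the N-terminal domain core.
* **functional** — splicing and translating the emitted gene model
  reproduces the template exactly (a tested round-trip).

`simulation_spec()` partitions each subfamily's gene count deterministically:
`n_pseudo = round(f_pseudo * n)`, `n_partial = round(f_partial * n)`, the
remainder functional. The derived per-subfamily category counts are exposed
via `spec_category_counts()` and are what end-to-end checks compare
recovered summaries against. Defaults emulate the published holy-basil
catalogue: 18/16/5/2/1/5 genes across subfamilies a/b/c/e/f/g. The
divergence defaults — `core_divergence = 0.10` within a subfamily,
`between_subfamily_divergence = 0.45` (floor) between subfamilies — are
calibration choices, not published values: no within-family divergence
levels are printed for this genome, and 10%/45%+ gives the comfortable
within-clade cohesion and between-clade separation a curated single-species
TPS family shows.

Background decoy genes are uniform-random proteins of 300-700 aa with 0-3
introns and no planted motifs; they exercise screen specificity. Genes are
placed ~50 per scaffold with 200-500 nt spacers, on random strands. All
outputs (FASTA wrapped at 60 columns, GFF3 with gene/mRNA/exon/CDS features,
labeled panel FASTA, truth TSV) are byte-identical under a fixed seed.

What the generator does **not** emulate: insertions/deletions (templates are
indel-free, so query+reference sets can be stacked without an external
aligner), codon-usage bias, sequencing or assembly artifacts, UTRs and
alternative splicing, intergenic repeats, and realistic phylogenetic rate
variation. Passing tests on synthetic data therefore validate the pipeline's
logic and numerics, not its robustness to alignment error or fragmented
assemblies.

## Domain screening

`build_profile()` turns a seed alignment into per-column log-odds scores (in
bits) with a pseudocount: `log2(((count + k*b) / (n_eff + k)) / b)`.
Majority-gap columns are dropped; gaps are excluded from column counts. The
two screening profiles ship as `reference_domain_profiles()`, built from the
80-residue domain-core slices of the labeled reference panel (the positions
are part of the generator's contract; with real data, externally computed
HMMER3 results enter through `parse_domtblout()` instead).

`scan_protein()` scores every ungapped window placement and takes the
maximum — full profile-HMM dynamics (insert/delete states, glocal alignment,
analytic E-value calibration) are out of scope, since the procedure being
reproduced only thresholds hmmsearch output and real HMMER output can be
imported. Significance is empirical: the protein is residue-shuffled
`decoy_count` times and the Laplace-smoothed p-value is
`(1 + #exceedances) / (decoy_count + 1)`. This is assumption-free but has a
resolution floor of `1/(decoy_count+1)`; with the default 9999 decoys the
best attainable e-value is 1e-4, below the 1e-3 cutoff. Because of that
floor, multiplying p by a whole-batch size would push every e-value over the
cutoff for realistic batches, so the batch multiplier defaults to 1
(per-protein e-values, matching the scale at which the cutoff is used) and
is exposed as `batch_size` for callers who want the conservative correction.
The cutoff itself is a strict `<` at 1e-3. Decoy evaluation stops early once
enough exceedances have accumulated to put the final e-value over the
cutoff; this changes no decision, only the cost of scoring obvious
non-candidates. `run_tps_pipeline()` trims the decoy count to 4999 (floor
2e-4, still five-fold under the cutoff) as its default run size.

Whether a candidate needs one domain or both is not settled in the
literature this reproduces; `require_domains` defaults to `"any"` (union of
the two domain screens), with `"both"` available.

## Triage

Rules run in a fixed order, and every triggered rule is recorded as a
machine-readable reason:

1. internal stop codons >= 1 or a frameshifted CDS (joined length not
   divisible by 3) -> **pseudogene**;
2. protein < 100 aa (`min_report_length`) -> **excluded**;
3. protein < 250 aa (`min_functional_length`) or, by default, fewer than two
   distinct domain profiles hit -> **partial**;
4. otherwise **functional** (reasons empty).

The published survey never states its numeric "short sequence" cutoff; 250
is the largest round value that admits every full-length entry of the
packaged catalogue (minimum printed length 274 aa), and it is exposed in
`triage_config()`. A single frameshift suffices for a pseudogene call
(stricter than the "multiple frameshifts" phrasing, and documented as such).
The rule order resolves an ambiguity the source leaves open: a gene that is
both truncated and stop-disrupted is reported as a probable pseudogene.
Codons containing N translate to `X` and never count as stops.

## Motif profiling

`compile_pattern()` encodes the five canonical degenerate motifs as explicit
allowed-residue sets (see the README for the consensi). Scanning tests every
start offset, reports all matches, and is position-equivariant. The
"modified" RR(X)8W form ((R/K)R...W) is scanned alongside the exact form and
labelled separately. `spacing_ok` accepts a DDXXD start 25-45 residues
downstream of an RXR start: the literature gives the point value 35 without
a tolerance, so a +/-10 window was chosen and is configurable. Catalytic
class is presence-based: DDXXD without DXDD is class I, DXDD without DDXXD
is class II, both is reported `ambiguous` (bifunctional-like), neither
`unclassified`.

## Structural classing

Two band conventions circulate and they disagree; both are kept as explicit
modes rather than silently reconciled. `canonical` (the default): class I =
12-14 introns, class II = 9, class III = 6. `extended` (matching how
surveyed families are grouped in practice): class III = 5-7, class I = 9-14,
class II unused. Counts outside all bands are `atypical` with a note
(typically an incomplete gene model); 7 introns in a TPS-a/b/g gene earns an
intron-gain note. Structural class is reported independently of the
motif-based catalytic class — the two "class" systems are different things
and the catalogue shows both.

## Phylogeny and subfamily assignment

Distances are p-distances with pairwise deletion: differing sites over sites
where both rows carry a defined residue; a pair with no comparable sites is
an error, not a silent zero. Neighbor joining is the standard Saitou-Nei
agglomeration on the Q criterion. Numerical choices: ties in Q (within a
1e-12 relative tolerance) are broken by the lexicographically smallest
taxon pair, with a merged node represented by the smallest leaf label under
it, so results are independent of input order; negative branch-length
estimates are clamped to zero on output (the raw values are kept in an
attribute); on additive matrices the tree reproduces the input distances
exactly, which the tests verify against an exhaustive least-squares oracle
over all topologies for up to six taxa.

Bootstrap supports resample alignment columns with replacement, keyed to
column positions (not taxon labels), so supports are invariant to input
order under a fixed seed; support is the percentage of replicates containing
the same bipartition, reported as integers. `assign_subfamily()` gives each
query the majority reference label in the smallest bipartition side that
contains the query, at least one reference, and support at or above the
threshold (default 80%, the usual display convention). Label ties yield
`unclassified` with reason `TIE`; if no supported clade qualifies, the
nearest reference by patristic distance is used and flagged
`FALLBACK_NEAREST`. Trees are unrooted throughout; outgroup rooting is a
display concern and out of scope. Alignments are an input: the synthetic
panels are indel-free and stack directly (`stack_alignment()` right-pads
with gaps, and pairwise deletion makes mixed 560/820-aa sets comparable);
for real data use any external aligner.

`phylo_config()` defaults to 1000 bootstrap replicates, the conventional
publication setting. The packaged study runs use smaller sizes chosen as
this package's own test-scale conditions: 100 replicates inside
`run_tps_pipeline()` and 200 in the dedicated bootstrap checks — on the
synthetic panels, supports for planted clades are effectively saturated well
below 1000 replicates.

## Catalogue

`integrate_catalogue()` joins the per-gene calls into one row per screened
candidate; missing upstream calls become explicit `"unclassified"`/`NA`
values, and pseudogene/partial rows are retained rather than dropped.
`summarize_catalogue()` produces the cross-species-table layout (a, b, c, e,
f, merged e/f, g, h, unclassified, total); the merged e/f column is derived
from the separate e and f counts, which the fixture stores separately.
`predict_product_class()` maps subfamily to coarse product chemistry only
(TPS-a -> sesquiterpene/diterpene, b -> monoterpene/isoprene, g -> acyclic
monoterpene, c -> copalyl-diphosphate-related diterpene, e -> kaurene-type
diterpene, f -> other class I diterpene); per-gene enzyme assignment needs
database annotation and is out of scope.

The packaged fixtures (`inst/extdata/`) transcribe the published holy-basil
catalogue: 47 functional genes (gene code, subfamily, protein length, plus
the reported best-hit identifiers carried for reference) and the
per-subfamily distribution of 19 partial and 15 pseudogene calls. The
fixture's gi/organism columns are not reproduced by the pipeline — external
database annotation is a non-goal.

## Problem sizes in the packaged checks

The test suite and `scripts/acceptance.R` run, as this package's chosen
study conditions: 100 random additive matrices (4-6 taxa) against the
least-squares oracle; 1000 diverged templates for motif recall and 10,000
uniform 500-aa proteins for the analytic false-positive calibration (each
pattern's match count must sit within 3 standard deviations of `n*p` with
`p` the product of allowed-set sizes over 20); five synthetic genomes of 47
TPS genes + 200 decoys (20% pseudogene, 20% partial) for end-to-end
screen/triage/subfamily recovery; and ten seeds at 200 bootstrap replicates
for clade-support and reproducibility checks.

## Known limitations

* The ungapped window scorer is not a profile HMM; real screens should
  import hmmsearch domtblout output.
* Empirical e-values cannot go below `1/(decoy_count+1)`; genuinely
  marginal domains near the cutoff are better judged by HMMER's analytic
  E-values.
* `stack_alignment()` is not an aligner; with indels, use MAFFT/MUSCLE
  upstream and feed the alignment in.
* Subfamily assignment is only as good as the reference panel; a query from
  a subfamily with no references can only be mis-assigned or flagged
  `FALLBACK_NEAREST`.
* The synthetic generator validates logic, not robustness to assembly
  fragmentation, gene-model error, or alignment noise.
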