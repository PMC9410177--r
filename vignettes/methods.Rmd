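---
title: "Methods: pan-genome oxidase census and pinoresinol-synthase candidate screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome oxidase census and pinoresinol-synthase candidate screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lignanscreen)
```

## The problem and the model

(+)-Pinoresinol is the entry metabolite of the sesame lignan pathway: two
coniferyl alcohol radicals, generated by an oxidase (a class III peroxidase,
POD, or a laccase, LAC) and stereoselectively coupled by a dirigent protein,
yield the precursor of sesamin, sesamolin and sesaminol, which accumulate in
the maturing seed (~30 days after anthesis, DAA). The oxidase itself is
unidentified. `lignanscreen` encodes a screening logic for nominating it:
the responsible gene should (i) exist in every variety of the pan-genome
(its function is not dispensable), (ii) be preferentially expressed in seed,
(iii) be expressed already at the earliest sampled stages of seed
development (an upstream enzyme must act before its products accumulate),
and (iv) follow the rise-fall kinetic of pinoresinol content rather than
being constitutively expressed.

The pipeline is deliberately modular: census, duplication/synteny, screen,
promoter regulation and qPCR validation each have a plain-function surface
and standard text-format I/O, so each claim about a gene is traceable to one
stage output.

## Stage models and numerical choices

### Family census

Membership calls start from HMMER3 `--domtblout` hits against the class III
peroxidase profile (PF00141) and the laccase profile (TIGR03390). A hit is
accepted when full-sequence E-value <= 1e-5 **and** per-domain independent
E-value <= 1e-5; comparisons are inclusive because `hmmsearch -E` reports
hits at-or-below the threshold, and the boundary must be fixed for tests.
Genes whose independent PfamScan-style domain list lacks the family's named
domain are demoted to `rejected_spurious` — this is the spurious-gene
filter. Duplicate domain rows are merged into one assignment per
(gene, family), keeping all rows as evidence; a gene with accepted evidence
for both families would be reported under both with a warning (none is
expected).

Orthogrouping is single-linkage: connected components of the similarity
graph thresholded at `min_score` (default 50 on a 0-100 similarity scale).
This is a deliberate simplification of OrthoFinder's MCL clustering: the
downstream census consumes only each group's presence/absence pattern
across varieties, for which connected components are sufficient, exactly
testable against a transitive-closure oracle, and pluggable if a finer
method is needed. "Core" means at least one member in every variety (not
single-copy), "specific" means exactly one variety; counts are summarized
as arithmetic mean and sample (n-1) standard deviation, rounded half-up to
integers only in the reporting layer (hence summaries like "44 +/- 7").

### Duplication and synteny

Genes are ranked along each chromosome by start coordinate (ties by end,
then id); ranks are the only coordinates the chaining uses, following the
MCScanX convention. Collinear blocks are chains of anchor pairs whose ranks
increase strictly on side A and increase (orientation `same`) or decrease
(`inverted`) strictly on side B, with consecutive-anchor gaps of at most
`max_gap = 25` ranks on both sides. Chains are scored by anchor count (unit
weights — the simplest deterministic criterion); the maximum-length chain is
extracted first, ties preferring orientation `same` and then the
lexicographically smallest anchor sequence; extraction repeats until no
chain reaches `min_anchors = 5`. The greedy longest-first extraction is
deterministic and is verified against exhaustive chain enumeration on small
instances. One consequence, verified by counterexample, is that widening
`max_gap` can *reduce* the total number of chained anchors (a longer first
chain may strand remaining anchors below `min_anchors`), although it never
shortens the first chain; the test suite asserts the properties that
actually hold.

A paralog pair is `tandem` when both genes are on one chromosome within
`tandem_max_rank_gap = 1` of each other (MCScanX's "consecutive homologs"
notion; the threshold is configurable because no published value exists),
`segmental` when the pair is an anchor inside any intragenomic block, else
`dispersed`. Proximal/WGD subclasses are intentionally not called — the
three-way classification is what the downstream summaries consume. The
interspecies synteny fraction counts family genes occurring as a side-A
anchor of at least one cross-species block, reported as a percentage
rounded half-up (31 of 83 -> 37%; 26 of 48 -> 54%).

### The candidate screen

The criteria published for this screen are qualitative ("preferentially
expressed in seed", "expressed early"); all quantitative thresholds here
are package choices, live in `screen_config()`, and are echoed in every
report header:

| parameter | default | units | rationale |
|---|---|---|---|
| `min_expr` | 1.0 | FPKM | conventional floor for "expressed" in bulk RNA-seq |
| `seed_fold` | 2.0 | fold | minimal fold usually read as "preferential" on a log2 heatmap |
| `early_stages` | earliest sampled stage | DAA | 10 DAA in the oil panel; "early" as the dataset defines it |
| `color_early_max` | 8 | DAA | the white/black panel's early stages are 5 and 8 DAA |
| `decline_stage` | 23 | DAA | the stage at which candidate expression is expected to decline, about one week before seed maturity |
| `decline_ratio` | 0.7 | fraction of peak | late mean must fall below this to count as declining |
| `flat_cv` | 0.3 | CV across stages | excludes constitutively expressed genes (the flat-confounder rule) |
| `pseudocount` | 1.0 | FPKM | log2(FPKM + 1) display/concordance transform |

Filters run sequentially (organ -> oil panel -> color panel -> kinetic ->
core membership) on the survivors of each previous stage, replicates
averaged first, all comparisons inclusive; the report keeps every gene with
its per-stage booleans (`NA` where not evaluated) so the funnel is
auditable. Stage 3 requires *presence* in the white-seeded variety's early
stages, not dominance over the black variety: a gene can be higher in black
seed early on and still pass, which is exactly why the kinetic criterion
exists — a constitutively expressed gene survives stage 3 and is removed
only by its flat trajectory (CV below `flat_cv`) or missing late decline.
The Pearson correlation between each surviving gene's white-seed trajectory
and the pinoresinol profile is reported but not thresholded: the published
argument from the metabolite kinetic is qualitative, and a hard correlation
cutoff would manufacture precision the data do not support. Tightening any
threshold can only shrink the final set (tested over randomized
configurations).

### Promoters and regulation

Promoters are the 2000 bp upstream of the annotated gene start (start and
end are 1-based closed GFF3 coordinates; the annotation does not
distinguish transcription from translation start), truncated at the
chromosome edge, reverse-complemented for minus-strand genes so output is
always 5'->3' relative to the gene. Scanning is exact IUPAC-degenerate
matching on both strands, with a minus-strand occurrence reported at the
start of the reverse-complemented consensus's match on the given string. An
`N` in the promoter matches nothing — degenerate pattern letters express
uncertainty about the motif, but an `N` base is missing data, and counting
it as a match would fabricate occurrences. Web services for element lookup
and TF enrichment are replaced by local tables (a bundled toy element set
and a user-supplied binding map) so runs are reproducible offline; the
enrichment itself is the standard upper-tail hypergeometric test per TF
family with Benjamini-Hochberg adjustment at the conventional 0.05 level.

### qPCR validation

`ddct()` implements textbook 2^-ddCt: arithmetic mean of replicate Ct
values, dCt against the reference gene per sample, ddCt against the
calibrator sample per gene, amplification efficiency fixed at 2 (no
efficiency correction). The method is exact on rational inputs and
invariant to any global Ct shift. Concordance with RNA-seq is the squared
Pearson correlation of log2(relative expression) against log2(FPKM + 1)
over shared (gene, sample) points; zero variance on either axis is reported
as undefined rather than 0 or 1.

## What the generator emulates, and what it does not

`simulate_pangenome()` + `simulate_expression()` produce every pipeline
input with planted truth. The defaults are the study conditions the
package's acceptance checks run under: 6 varieties; 60 POD + 40 LAC
orthogroups with `core_fraction = 0.65` (the published censuses place most
clusters in the core with a handful of variety-specific ones); 4 planted
candidates drawn from core orthogroups of the reference variety plus one
flat seed-preferential confounder; 18 segmental pairs planted inside
generated collinear blocks (one inverted), 1 tandem pair, 2 dispersed
pairs; per-variety decoy genes above the E-value threshold and
spurious-domain decoys; promoter motifs planted at known positions and
strands; a TF-binding map in which MYB binds every candidate, emulating the
published predominance of MYB. Expression panels mirror the published
sampling design: a five-organ atlas, an oil panel at 10/20/25/30 DAA over
one high-oil and two low-oil varieties, and a white/black panel at
5-30 DAA (9 stages).

No FPKM magnitudes for the candidates are published, so effect sizes are
free generator parameters chosen once: candidate peak 30 FPKM at 20 DAA,
seed/other-organ fold 8, early level ~0.3 of peak (rise from 5 DAA), then
exponential decay with a 3-day constant, giving a late/peak ratio of ~0.18
versus the 0.7 threshold and early FPKM of ~9-16 versus the 1-FPKM floor —
margins of roughly 4x the thresholds, so that recovery tests exercise the
logic rather than the noise. The trajectory CV (~0.66 versus the 0.3 floor)
has a smaller, ~2x margin, the most a realistic nonnegative unimodal
trajectory admits. Noise is multiplicative lognormal with sigma
`noise_sd = 0.15` (log-FPKM Gaussian around the log of the planted mean;
the zero-noise limit is exact); Ct values are back-computed as
`intercept - log2(FPKM + 1)` plus Gaussian noise, in triplicate. The
metabolite profile is a parametric Gaussian-shaped rise-fall curve peaking
at 20 DAA standing in for the figure-derived published values, which are
not printed anywhere.

The generator does **not** emulate: sequencing reads or alignment (FPKM
matrices are consumed directly), sequence evolution (similarity scores are
drawn, not computed from sequences), real HMM emission (decoys are
threshold-side draws, not homologs), genome rearrangement beyond the
planted blocks, or between-replicate structure beyond i.i.d. noise.
Passing recovery tests therefore demonstrates that the *decision logic* is
correct under the declared noise model — not that the thresholds are optimal
for real tissue panels, where library-size effects, isoform switching and
correlated replicates all exist.

A note on pooled concordance: qPCR values are relative to a calibrator
sample, so each gene's log2 values are offset by its calibrator level while
FPKM values are absolute. Pooling genes with very different calibrator
levels (e.g. a flat housekeeping-like gene with rise-fall candidates) can
attenuate pooled R² even when every per-gene correlation is high; the
package's concordance checks therefore pool the assayed candidate panel,
matching the published design of five primer pairs (four candidates plus
the actin reference).

## Degenerate inputs and tie-breaks

Empty expression matrices yield empty (but well-formed) reports; a screen
whose floor exceeds all FPKM leaves the full audit trail of stage-1
failures. Genes missing from every orthogroup are non-core by definition
(with a warning). Orthogroup ids are assigned by lexicographic smallest
member; blocks are emitted per sorted chromosome pair in extraction order;
rank ties break by end coordinate then gene id. All outputs are pure
functions of inputs plus the configured seed: fixed seed, bit-identical
files.

## Problem sizes used by the test suite

Unit tests run on reduced pan-genomes (30 orthogroups, 1 planted block) to
keep feedback immediate; the acceptance checks run the full default
conditions — 100 orthogroups, ~100 reference genes, 20 independent seeds —
plus 200 randomized chaining instances, 100 hypergeometric instances and a
5-kb scanning oracle comparison. These sizes were chosen as the smallest
that exercise every code path a full-genome run would.

## Known limitations

- Single-linkage orthogrouping can chain distinct families through one
  spurious high-scoring edge; the similarity threshold is the only guard.
- Chaining weights anchors equally; a bit-score-weighted chain criterion
  (closer to MCScanX's scoring) is pluggable but not implemented.
- The kinetic criterion anchors "decline" at a fixed stage (23 DAA by
  default) rather than estimating the inflection from the metabolite curve.
- Promoter scanning is presence/absence; no PWM scoring, no de-novo motif
  discovery.
- The 2^-ddCt model assumes perfect doubling per cycle; no efficiency
  correction from dilution series.
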