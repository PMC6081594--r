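---
title: "Short inverted repeats in organellar genomes: detection model and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Short inverted repeats in organellar genomes: detection model and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirscan)
```

## The biological object and the detection model

A short inverted repeat (S-IR) is a DNA segment of the form

```
left arm (a bp)  --  spacer (s bp)  --  right arm (a bp)
```

where the right arm is the reverse complement of the left arm, up to a
small number of mismatched pairings. Under torsional stress the two arms
can pair intramolecularly, extruding a four-way cruciform whose loop is
the spacer. Cruciforms are bound by dedicated resolvases and regulatory
proteins, and S-IRs cluster non-randomly in organellar genomes —
plastid genomes in particular are AT-rich, compact, and carry many of
them. `sirscan` detects these elements and quantifies their abundance
and genomic context.

Throughout this package **"S-IR length" means arm length `a`**, not the
total span `2a + s`. The scan window is the cruciform-competent regime:

| parameter      | default | meaning                               |
|----------------|---------|---------------------------------------|
| `min_arm`      | 6 bp    | shortest arm considered               |
| `max_arm`      | 60 bp   | longest arm considered                |
| `max_spacer`   | 10 bp   | longest loop between the arms         |
| `max_mismatch` | 1       | internal non-Watson-Crick arm pairings|
| `flank_bp`     | 100 bp  | feature neighborhood width            |

### Maximality and the terminal-match rule

Two conventions make per-length counting well defined:

1. **Terminal pairs are exact.** The outermost pair of the arms and the
   pair adjacent to the spacer must be Watson–Crick matches; the allowed
   mismatch is internal. Without this rule, any perfect arm-`a` repeat
   would "extend" to `a + 1` by spending the mismatch budget on a
   non-pairing terminal, and the reported length distribution would be
   an artifact of the budget.
2. **One hit per center, one hit per span.** Candidates are generated
   per center (gap position × spacer length) and extended outward as far
   as the budget and the terminal rule allow. Among candidates with an
   identical outer span, only the largest-arm (hence smallest-spacer)
   representation is kept. Hits with distinct outer spans are all
   reported, even when nested or overlapping — they are different
   physical structures. Each structure is reported once, not once per
   strand, because an inverted repeat is strand-symmetric.

`N` never pairs: ambiguous residues (all IUPAC codes are collapsed to
`N` on input) always count as mismatches, and can therefore never be
arm terminals. Mismatch budget applies to arm pairings only; spacer
content is unconstrained.

`find_irs()` implements this scan in C++ in `O(n · spacers · max_arm)`;
`brute_force_irs()` is an independent exhaustive enumeration over all
`(start, arm, spacer)` triples, reduced by the same two rules. The test
suite holds the two equal on hundreds of random sequences across GC
contents — the enumeration is the oracle, the scanning code the
implementation under test.

## Frequency statistics

Per genome, hits are binned by arm length (6–60 bp) with per-kbp rates
`1000 · count / genome bp`, plus cumulative classes **all / 8+ / 10+ /
12+** (arm ≥ 8, ≥ 10, ≥ 12 bp). Group statistics pool member counts and
bp, and additionally report:

* **mean frequency** — the unweighted mean of per-genome S-IR/kbp
  values. Pooling counts over pooled bp answers a different question
  (it weights big genomes more), so both are emitted under separate
  names (`mean_freq`, `pooled_freq`).
* **longest S-IR for 50% of genomes** — the largest arm length `L` such
  that at least half of the group's genomes contain a hit with arm
  ≥ `L`. Genomes without hits participate with maximum 0. With an even
  group size the "at least half" reading is the one consistent with the
  definition's own arithmetic (e.g. maxima {32,32,32,32,20,20,20,20}
  give 32: exactly half the genomes reach 32).

The dataset-level table (`table1_report()`) shows arms 6–30 individually
and pools everything above 30 bp into one `>30` row; frequencies are
computed from its own counts and bp, never copied from elsewhere.

## Feature context and enrichment

For each annotated feature `[start, end)` and flank `f = 100` bp the
regions are `before = [start−f, start)`, `inside = [start, end)`,
`after = [end, end+f)`, clipped at genome ends (clipped widths enter the
bp denominator). A hit is counted in **every** region its outer span
overlaps by ≥ 1 bp. This multi-membership convention is the only one
that needs no tie-break for boundary-spanning hits; it slightly inflates
all regions equally and so cancels in ratios. Regions are
genome-coordinate based, not strand-aware, and overlapping features of
the same type each contribute their own regions (per-feature counting —
the denominators double-count shared bp deliberately, which keeps
"counts per annotated feature neighborhood" the quantity measured).

Enrichment divides each `(type, region, class)` frequency by the
`(gene, inside, class)` baseline — `gene` being the most abundant
annotation in organellar feature tables. A zero or absent baseline makes
the ratio undefined; it is reported as `NA` with a warning, never as a
number.

## Arm similarity

Abundance ranking (`rank_arms()`) counts identical left-arm sequences
within one arm-length class, pooled over genomes: the tally is
**occurrence events**, not genomes-containing. The left arm read 5'→3'
represents the hit; for a one-mismatch repeat family this reproduces the
pairs of near-identical abundant arms seen in real data. Neighborhood
grouping (`near_group()`) collects all arms of the class within
Levenshtein distance ≤ 2 (insertions and deletions allowed inside the
metric even though the compared strings have equal length). Distances
are computed with `utils::adist`; the tests verify it against a full
dynamic-programming matrix written independently.

## Multivariate structure

`profile_matrix()` turns profiles into a fixed-order matrix of per-kbp
frequencies (arms 6–30, `>30`, and the 8+/10+/12+ aggregates — the
granularity of the length table). `ward_cluster()` runs agglomerative
clustering with Euclidean distances under the Ward.D2 criterion (squared
distances inside the Lance–Williams update, heights on the distance
scale); the tests recompute the merge heights with a hand-written
Lance–Williams loop. `pca()` centers and unit-scales columns by default
— frequency columns for different arm lengths differ by orders of
magnitude, and unscaled PCA would simply rank bins by their absolute
rate. Scaling is a choice, not a necessity, and is exposed as
`pca_scale`. Zero-variance columns are excluded from scaling with a
warning. Loadings follow a deterministic sign convention (the
largest-magnitude loading of each component is positive), so outputs
are reproducible across platforms. Dendrograms export to Newick via the
standard hclust-to-phylo conversion (merge heights split evenly over
child branches).

## The synthetic-data generator

Real plastid data cannot ship with the package, so every pipeline stage
is validated against generated genomes with known ground truth. The
generator emulates:

* **AT-rich background** — i.i.d. residues at GC 0.37 (the typical
  plastid composition), configurable. Random AT-rich sequence alone
  already yields on the order of 45 S-IR hits per kbp at these scan
  parameters, which matches the magnitude reported for real plastid
  genomes — most short S-IRs in such genomes are statistically expected.
* **annotated features** — non-overlapping intervals of the common
  plastid annotation types (gene, CDS, tRNA, rRNA, exon, intron,
  stem_loop, repeat_region, regulatory, misc_feature), placed uniformly
  at random, longest first.
* **planted repeats** — `arm + spacer + reverse complement(arm)` written
  over the background, with optional internal right-arm mismatches.
  Planting forces the two flanking pairs just outside the arms to
  mismatch, so the planted arm length is maximal by construction, and
  verifies each plant with the exhaustive oracle (retrying elsewhere on
  failure). Plants never overlap; a 2 bp guard separates them.
* **location bias** — per-(type, region) Poisson planting rates
  `base_rate × multiplier × region kbp`. Defaults: ×10 inside
  stem_loop, ×5 before repeat_region, ×0.2 inside rRNA, mirroring the
  qualitative enrichment pattern of real plastid data (stem-loops are
  themselves inverted repeats; rRNA is depleted).

What the generator does **not** emulate: phylogenetic correlation
between genomes, the quadripartite LSC/IRa/SSC/IRb architecture (the
large repeat appears only as a labeled `repeat_region` feature),
compositional heterogeneity along the genome, and annotation errors.
Passing recovery tests therefore demonstrates correctness of the
machinery, not biological conclusions about real genomes.

### Problem sizes and study conditions

Recovery tests plant ≥ 50 repeats spanning the whole parameter range
(arms 6–60, spacers 0–10, 0–1 internal mismatches) into screened,
repeat-free loci of a 30 kbp background and require exact arm/spacer
recovery of all of them. Enrichment recovery uses ten 30 kbp genomes
with 120 genes and 100 stem-loops, planted arms of 12–20 bp, and a
generative stem_loop:gene inside-density ratio of 10; the
context/enrichment machinery applied to the ground-truth hit list must
estimate that ratio within [7, 13] (the width follows from Poisson
counting error at these feature numbers). The estimate deliberately uses
the ground-truth hits: running the detector first would add the ~45/kbp
chance background of AT-rich sequence to both numerator and denominator
and measure dilution, not the context logic — the detector-based variant
is asserted as an ordering check (stem-loop interior frequency above
gene interior frequency for arms ≥ 12). Oracle-equivalence sweeps use
200 random sequences of 0.5–2 kbp at GC 0.2/0.37/0.5. Genome sizes
default to desk scale (20–30 kbp, against 11 kbp–1 Mbp in real plastid
collections) so that the exhaustive oracle stays exact and fast.

## Numerical and degenerate-input choices

* Sequences are treated as **linear**; no wrap-around detection across
  the circular origin. Deposited organellar records are linearized
  arbitrarily, and a wrap-aware scan would change at most a handful of
  hits near the origin.
* Coordinates are 0-based half-open internally; 1-based inclusive at
  the NCBI feature-table and GFF3 boundaries. Conversion is involutive
  and tested.
* Empty sequence → empty hit list; empty group → error; genome of
  length 0 → error; all-constant PCA input → error; fewer than two
  rows → clustering error.
* Ranking ties break lexicographically; span-deduplication ties break
  by fewer mismatches, then smaller spacer. All outputs are
  deterministic given a seed.
* `longest_for_half` returns 0 when more than half the group is
  hit-free.

## Known limitations

* The per-center/per-span maximality convention is one of several
  defensible deduplication rules; published per-length counts from
  other tools may differ slightly in how nested representations are
  collapsed.
* Enrichment denominators double-count bp shared by overlapping
  same-type features.
* The Levenshtein neighborhood search is exhaustive over distinct arm
  sequences of one length class; it is quadratic in their number and
  intended for the short lists that arm-abundance ranking produces, not
  for all-against-all sweeps of millions of arms.
* The generator's Poisson placement with overlap rejection slightly
  deflates realized densities in very crowded regions; configurations
  shipped with the package keep occupancy low enough that the effect is
  far below counting noise.
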