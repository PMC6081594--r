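# sirscan

Short inverted repeats (S-IRs) — two DNA arms in head-to-head
orientation separated by a short spacer — can extrude into cruciform
structures and are non-randomly distributed in organellar genomes.
`sirscan` is an R package for people studying these elements in
plastid-like (AT-rich, compact, densely annotated) genomes. It finds
every maximal S-IR in a set of genomes, quantifies abundance by arm
length, measures enrichment in and around annotated features, groups
abundant arm sequences by edit distance, and compares genomes and
taxonomic groups by clustering and ordination of their length-frequency
profiles. A built-in synthetic-genome generator with planted repeats
provides exact ground truth, so the whole pipeline is testable without
any downloads.

## The model

A hit is a triple (arm `a`, spacer `s`, position) with

```
5'-- [left arm, a bp] [spacer, s bp] [right arm = revcomp(left), a bp] --3'
```

scanned over arms 6–60 bp, spacers 0–10 bp, and at most **one internal
mismatch**: the outermost arm pair and the pair flanking the spacer must
be exact Watson–Crick matches, which makes per-length counts
well-defined ("S-IR length" always means **arm** length). Candidates are
maximal per center and deduplicated per outer span. Frequencies are
reported per kbp, by individual arm length and in cumulative 8+/10+/12+
classes; feature context counts hits whose span overlaps the 100 bp
windows before/after or the interior of each annotated feature, with
enrichment expressed relative to the gene-interior baseline; arm
similarity uses Levenshtein distance (identity and distance ≤ 2);
group profiles feed Ward.D2 clustering and PCA.

## Worked example

Detect a single inverted repeat — a 6 bp arm with a 3 bp spacer:

```r
library(sirscan)
find_irs(paste0("AAATTC", "GCA", "GAATTT"))
#>   genome_id left_start arm_len spacer_len mismatches left_arm_seq
#> 1       seq          0       6          3          0       AAATTC
```

`left_start` is 0-based; the hit spans `2*6 + 3 = 15` bp. Now a
synthetic two-genome dataset with annotated features and planted
repeats (density ×10 inside stem-loops), run end to end:

```r
ds  <- gen_dataset(synth_config(seed = 42, n_genomes = 2L),
                   out_dir = "demo")
res <- run_all(run_config(fasta    = "demo/genomes.fasta",
                          features = "demo/features.tbl",
                          manifest = "demo/manifest.tsv",
                          out_dir  = "demo_out"))
#> scan: 2 genome(s), 40000 bp, 1683 S-IR hit(s)
#> run_all: reports written to demo_out

head(res$table1, 4)
#>   ir_size amount freq_per_kbp
#> 1       6   1080       27.000
#> 2       7    351        8.775
#> 3       8    135        3.375
#> 4       9     41        1.025

res$profiles[[1]]
#> <length_profile> synth01: 876 S-IRs over 20000 bp (43.80 /kbp)
```

About 44 hits/kbp, dominated by 6–7 bp arms and falling steeply with
length — AT-rich sequence produces most short S-IRs by chance, which is
exactly the magnitude seen in real plastid genomes. The feature-context
report shows the planted stem-loop signal against that background:

```r
ctx <- res$context
ctx[ctx$ftype == "stem_loop" & ctx$region == "inside", ]
#>         ftype region length_class ir_count region_bp freq_per_kbp enrichment
#> 101 stem_loop inside          all      133      2400     55.41667   1.320099
#> 102 stem_loop inside           8+       45      2400     18.75000   3.272727
#> 103 stem_loop inside          10+       33      2400     13.75000   7.764706
#> 104 stem_loop inside          12+       33      2400     13.75000  11.000000
```

Planted arms are 12–20 bp, so the enrichment over gene interiors grows
with the length class and reaches 11× for arms ≥ 12 bp — the short
classes are diluted by the chance background. `demo_out/` additionally
contains per-genome hit TSV/BED files, group summaries, the group
Ward.D2 dendrogram in Newick format, the similarity report and a JSON
run manifest with parameters and input checksums.

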