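# regulonkit

Regulon inference for prokaryotic transcription factors by integrating
ChIP-seq binding with RNA-seq induction — modelled on the analysis of the
copper-responsive regulator CopR in the archaeon *Pyrococcus furiosus*.

The package is aimed at anyone analysing a condition-responsive
transcription factor on a small (typically circular) genome, where a
peak-caller-free treatment of ChIP-seq is both sufficient and more
transparent. It provides, as tested building blocks:

- **Occupancy tracks** — fragment extension, depth scaling, per-replicate
  IP/input ratios, linear replicate averaging with log2 display tracks,
  and per-gene window occupancy:
  occupancy(g) = mean over the 300 bp window at the gene start of the
  replicate-averaged linear IP/input ratio.
- **Differential expression** — median-of-ratios size factors, moderated
  method-of-moments NB dispersion, a Wald test on
  log2(mean₂/mean₁) with Var = μ + αμ², and Benjamini–Hochberg FDR,
  plus 2^−ΔΔCt qPCR arithmetic.
- **The regulon rule** — a gene is a regulon member iff
  (FC > 2) ∧ (padj < 0.05) ∧ (occupancy ≥ 2 in *both* conditions),
  with exact boundary semantics (FC 2.0 fails, occupancy 2.0 passes),
  and length-bias-corrected category enrichment by weighted resampling.
- **Motif machinery** — ZOOPS EM discovery over widths 8–18 with
  BIC-style width selection, IUPAC consensus and palindromicity scoring,
  and PWM scanning with *exact* p-values (dynamic programming over
  integer-discretised log-odds scores) and q-value control.
- **TSS-anchored profiles** — strand-aware promoter windows, positional
  nucleotide enrichment (target vs background), and trinucleotide DNA
  bendability profiles with bootstrap confidence bands.
- **A synthetic-data generator** — seeded circular genomes with planted
  regulons, planted `TTNNCAWWWTGNNAA` sites, ChIP read mixtures and NB
  count matrices, with a truth record for recovery scoring.

File formats go through the standard Bioconductor stack: FASTA
(Biostrings), GFF3/BED/bedGraph (rtracklayer), counts/results as TSV,
motifs as minimal MEME text.

## Worked example

Simulate the default study (200 genes, 10-gene planted regulon, ChIP
enrichment 20×, triplicates in two conditions, NB counts), run the whole
pipeline, and score it against the planted truth:

```r
library(regulonkit)

ex    <- simulate_regulon_experiment(seed = 42)
occ   <- experiment_occupancy(ex)           # per-gene occupancy, both conditions
res   <- dge(ex$counts)                     # NB Wald test, BH-adjusted
calls <- select_regulon(res, occ)           # the two-criterion rule
regulon_recovery(calls, ex$truth$regulon_gene_ids)
#>  precision     recall n_selected
#>          1          1         10
```

All ten planted genes are recovered with no false positives. The selected
table shows the estimated induction tracking the planted effect sizes and
promoter occupancies far above the threshold of 2:

```
   gene_id log2FC      padj occupancy_control occupancy_shock planted_lfc
 gene_0154   8.67 4.50e-230              8.60            8.60        8.20
 gene_0094   8.40 9.40e-205              9.50           10.43        8.20
 gene_0027   6.19 1.59e-137              8.21            9.23        6.14
 gene_0118   2.52  3.20e-23              8.78            9.36        2.50
 ...
```

Discover the planted motif in the ten regulon promoters and scan with
exact p-values:

```r
reg   <- ex$genome$genes[ex$genome$genes$gene_id %in% ex$truth$regulon_gene_ids, ]
up    <- extract_anchored(ex$genome, reg, from_pos = -60, to_pos = 0)
bg    <- estimate_background(intergenic_sequences(ex$genome))
motif <- choose_width(up$sequences, bg, widths = 8:18, seed = 1)
motif
#> <motif_model> width 11, gamma 1.000, logLik -759.43
#> consensus: CAWTTTGNNAA
nrow_hits <- scan_pwm(motif, up$sequences, q_threshold = 0.05)
length(unique(nrow_hits$seq_id))
#> 10          # a significant site in all 10 promoters
```

With only ten promoters the BIC penalty truncates the width-15 palindrome
to its 11-column core; at 30 planted promoters the full
`TTNNCAWWWTGNNAA`-compatible consensus and width 15–17 are recovered
(this is what the acceptance suite measures across 20 seeds).

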