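# regupeaks

Genome-wide analysis of transcription-factor binding sites called from
ChIP-seq, aimed at dimeric factors of the p53/p63 family. Given peak
intervals, a genome, gene models, a per-base conservation track, CTCF sites
and a disease-by-feature-term matrix, the package answers the questions a
regulatory-genomics study asks of a binding-site catalogue:

* **Which sites carry the factor's motif?** Dimeric position weight matrices
  (two half-sites, configurable spacer) are scored as summed log-odds in bits,
  `S = Σ_j log2(p_j(b_j) / q(b_j))`, over both strands and every placement.
  The calling threshold is chosen by maximum f-measure
  `F = 2PR/(P + R)` against a background sequence set, and the false
  discovery rate of calls is estimated as the ratio of background to
  positive call rates.
* **Is a candidate motif significant?** A de novo pipeline splits peaks into
  training and evaluation sets, generates candidates by over-represented-word
  seeding with iterative PWM refinement, and tests each candidate with the
  hypergeometric upper tail against **two** backgrounds — length- and
  chromosome-matched random genomic sequence, and a first-order Markov model
  matching the peaks' dinucleotide composition — keeping motifs with
  Benjamini–Hochberg-adjusted `p < 0.001` and more than 1.5-fold enrichment
  against both, and selecting the winner by ROC AUC. A binomial test with
  Bonferroni correction screens library motifs between two peak subsets.
* **Where do sites fall relative to genes?** Summits are classified as
  TSS-flanking (5 kb upstream of the TSS, first exon, first intron),
  intragenic, near (5–25 kb upstream or ≤25 kb downstream), or intergenic,
  with enrichment assessed by a within-chromosome relocation permutation
  test. Genes with a peak within 25 kb become potential target genes (PTGs).
* **Are sites conserved?** Per-region mean conservation (PCCS) with
  missing-data accounting, cumulative cut-off curves, Mann–Whitney set
  comparisons, and peak-height quartile summaries.
* **Which sites could be enhancers of a disease gene?** Peak–gene pairs
  within 300 kb are retained as candidate regulatory elements unless a CTCF
  insulator site lies strictly between them.
* **Do the target genes share disease phenotypes?** Mean pairwise cosine
  similarity of disease term vectors, tested against a
  without-replacement resampling null, plus hypergeometric ranking of
  over-represented terms and top-10% query-term enrichment.

Every stage is also covered by a synthetic-data generator
(`simulate_scenario()`) that emits a genome, gene models, peaks with planted
motif instances, an elevated conservation track, CTCF sites and a clustered
disease matrix together with ground-truth tables, so the whole pipeline is
testable without downloading any external data.

## Worked example

```r
library(regupeaks)

# A dimeric PWM from aligned binding-site sequences: two 8-bp half-sites
pwm <- build_pwm(c("AACATGTTAACATGTT", "AACATGTCGACATGTT", "AGCATGTTAACATGCT",
                   "AACATGTTTACATGTT", "CACATGTTAACATGTG", "AACGTGTTAACATGTT"),
                 split_at = 8, name = "p53_family_dimer")
pwm
#> dimeric_pwm 'p53_family_dimer': half-sites 8 + 8 bp, spacer 0-0,
#>   consensus AACATGTTAACATGTT

scan_sequence(pwm, "TTGCAACATGTTAACATGTTGGA")$best
#>   position strand spacer    score
#> 1        4      -      0 27.31839

# Calibrate a genome-wide calling threshold on synthetic peaks
g   <- make_genome(c(chr1 = 200000), seed = 1)
pl  <- plant_peaks(g, 100, pwm, planting_rate = 0.94, peak_length = 200,
                   category_mix = c(intergenic = 1), seed = 1)
seqs <- fetch_sequence(pl$genome, summit_window(pl$peaks, 100))
bg   <- markov_background(seqs, 1, n = 100, length = 100, seed = 2)
cal  <- calibrate_threshold(best_scores(pwm, seqs), best_scores(pwm, bg))
cal
#> scan calibration: threshold 7.229 bits (F = 0.954, est. FDR = 0.032)

mean(best_scores(pwm, seqs) >= cal$threshold)   # 0.94: fraction with a motif
roc_auc(best_scores(pwm, seqs), best_scores(pwm, bg))  # 0.977
```

The best hit sits at position 4 on the minus strand because the planted site
reads as its own near-reverse-complement; 27.3 bits is close to the maximum
for this matrix. At the calibrated 7.2-bit threshold, 94% of the synthetic
sites carry a call — matching the 0.94 planting rate — with an estimated FDR
of 3%.

The full pipeline (`run_pipeline()`, or `inst/cli/regupeaks run` from a
shell) chains scanning, dual-background enrichment, genomic-category
annotation, PTG mapping, conservation analysis, CTCF-bounded domain search
and phenotype similarity, writing per-stage TSVs and a JSON manifest whose
artifacts are byte-identical across reruns with the same config and seed.

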