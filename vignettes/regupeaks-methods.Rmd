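---
title: "Methods: binding-site scanning, annotation, conservation and phenotype similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding-site scanning, annotation, conservation and phenotype similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regupeaks)
```

# Scope and data model

`regupeaks` analyses a catalogue of transcription-factor binding sites called
from ChIP-seq. Peak calling itself is out of scope: peaks arrive as BED
intervals with an optional summit column (offset relative to the interval
start, the MACS convention) and a read-count height. Internally every
coordinate is 0-based half-open; 1-based inclusive browser/GTF coordinates
are converted only at I/O boundaries (`browser_interval()`), so a printed
range like 96,030,294–96,030,493 measures 200 bp. Peaks without an explicit
summit fall back to the interval midpoint (floor) — the only summit-free
proxy available.

# The dimeric motif model

p53-family factors bind sites composed of two half-sites. A `dimeric_pwm`
stores the two half-site probability matrices, an allowed spacer range
(in bp, between the half-sites), and the background nucleotide frequencies.
A placement's score is the summed base-2 log-odds of both half-sites:

$$S = \sum_j \log_2 \frac{p_j(b_j)}{q(b_j)}$$

summed over all informative columns, maximised over start positions, both
strands and every allowed spacer.

Numerical choices:

* **Score floor.** Zero-probability cells would give $-\infty$; they are
  floored at −10 bits per position, deeper than any realistic column, so
  scores stay finite and comparable.
* **Ambiguity.** `N` (and any non-ACGT base) contributes exactly 0 bits,
  neither reward nor penalty, so peaks spanning assembly gaps are scored
  rather than discarded.
* **Spacer default.** The default spacer range is `{0}` — a contiguous
  site read as two adjacent half-sites — configurable up to several bp.
  p53-family sites are predominantly spacer-less, and leaving the range
  open-ended would multiply the search space without evidence.
* **Pseudocounts.** Column frequencies are
  $(c_b + \alpha)/(n + 4\alpha)$ with $\alpha = 0.25$ by default, the
  conventional light smoothing for small instance sets.

One best hit per sequence is the unit of calibration, FDR estimation and ROC
analysis ("a site contains the motif"); all placements remain available from
`scan_sequence()` for motif-level conservation work.

# Threshold calibration and FDR

`calibrate_threshold()` sweeps candidate thresholds over the union of
observed best scores from a positive and a background set and returns the
threshold maximising the f-measure (harmonic mean of precision and recall).
Ties are resolved to the smallest maximising threshold: at equal F this
maximises recall, which suits a scanner whose selling point is sensitivity.
The FDR at a threshold is estimated as (background call rate)/(positive call
rate), clipped to [0, 1], with the convention FDR = 1 when nothing is
called. This estimator is a documented choice — published FDR-at-threshold
figures rarely state their exact definition — and it is validated on
synthetic data: at planting rate 0.9 with n = 500 sites the estimate tracks
the realised (truth-table) FDR within 0.05.

# De novo motif significance

The discovery pipeline mirrors the shape of published multi-tool pipelines
while replacing the external finders with a deliberately simple built-in
stand-in (external PWMs in MEME format are first-class inputs):

1. **Split.** `split_train_eval()` assigns `floor(f·n)` peaks to training
   (default f = 0.2; 11,369 peaks give exactly 2,273), each contributing a
   200-bp summit-centred window.
2. **Seed.** For each width, every exact word on both strands is counted and
   ranked by observed/expected count under a first-order Markov model of the
   training set (add-one smoothing); the top words seed candidates.
3. **Refine.** Each seed is realigned iteratively: scan, keep the best hit
   per sequence with positive log-odds (or the top 10 when fewer), rebuild
   the PWM, until the mean per-column information content changes by
   < 10⁻³ bits or 50 iterations.
4. **Test.** Each candidate is scored on the evaluation set against two
   backgrounds — genomic (length- and chromosome-matched random regions,
   allocated by largest remainder so proportions are matched exactly) and
   first-order Markov — with the hypergeometric upper tail on the count of
   motif-containing sequences. The conservative maximum of the two p-values
   is BH-adjusted across candidates; significance requires adjusted
   p < 0.001 **and** >1.5-fold enrichment against both backgrounds. Whether
   the published 0.001 cut applies to raw or adjusted values is ambiguous;
   adjusted is the default and `adjust = FALSE` restores raw filtering.
5. **Select.** Among significant candidates the highest ROC AUC wins; ties
   go to the narrower motif, then the lexicographically smaller consensus.

The per-candidate counting threshold is that candidate's own max-f-measure
threshold calibrated against the Markov background, the same rule used for
the main scanner.

# Genomic-category annotation

Summits (not whole intervals) are classified — the summit is the
binding-point estimate that sequence windows are centred on. Categories,
strand-aware:

| category | definition |
|---|---|
| TSS_flanking | ≤5 kb upstream of a TSS, or in a first exon or first intron |
| intragenic | elsewhere in a gene body |
| near | 5–25 kb upstream, or ≤25 kb downstream of the gene end |
| intergenic | everything else |

When several genes apply, the priority is TSS_flanking > intragenic > near,
so classification is a partition. "Downstream" is measured from the gene
end; for the gene models used here this coincides with the last exon end.
Enrichment is tested by a permutation null that relocates each peak
uniformly on its own chromosome (length preserved), keeping chromosome
composition fixed — the same philosophy as the genomic background for motif
testing. The empirical p is `(1 + #null ≥ obs)/(1 + n_perm)`, bounded away
from zero.

PTG mapping is deliberately many-to-many: a gene is a potential target gene
when any peak lies within 25 kb (overlap counts), and one peak may support
several genes. The CTCF-bounded search retains peak–gene pairs within
300 kb unless a CTCF site lies **strictly** inside the gap between their
nearest edges; a site overlapping the peak or the gene does not block — an
insulator must separate, not touch — and overlapping pairs are always
retained.

# Conservation

`region_mean_score()` averages per-base conservation over all bases of a
region. Bases without track data count as 0 (uncovered treated as
unconserved) and the covered fraction is reported alongside, so the
alternative present-bases-only reading stays auditable. Summit windows use
floor-based centring for odd sizes. The two-set comparison is Mann–Whitney —
distribution-free and standard for conservation scores — exact for small
tie-free sets, normal approximation with tie correction otherwise, with the
two-sided p defined as 1 when the rank variance vanishes. Peak-height
quartiles rank by height with ties broken by input order.

# Phenotype similarity

Disease profiles are rows of a non-negative disease×term matrix (binary by
default, arbitrary weights accepted — the weighting of the source matrix is
not dictated here, so both modes exist). Pairwise similarity is the cosine
of the weight vectors, anchored at 0 = no term overlap and 1 = identical
profiles; a set's score is the mean over all unordered pairs. Significance
uses a Monte-Carlo null of uniform without-replacement sets of equal size
rather than a chi-square on the score — a mean of dependent pairwise
cosines has no convenient reference distribution, while the resampling null
makes the score/null-mean contrast directly reproducible. Both the null mean
and the empirical p are reported. Term over-representation within a set is
hypergeometric per term, and top-fraction enrichment of a query term list is
hypergeometric on membership in the top ⌈k·m⌉ ranked terms.

Two properties worth noting: the empirical p can never be 0 (floor
`1/(n+1)`), and mean pairwise similarity is **not** monotone under
duplicating a set member once the set has ≥4 diseases (a duplicated outlier
drags the mean down); it is monotone for pairs and triples, which the tests
assert.

# Synthetic data: what it emulates and what it does not

The generators produce the study conditions every stage is tested under:

* `make_genome()` — i.i.d. bases at 41% GC (the human genome-wide value).
* `make_gene_models()` — non-overlapping stranded genes, 2–5 exons of
  100–300 bp, introns 0.5–3 kb, spaced ≥55 kb so neighbouring annotation
  windows stay disjoint.
* `plant_peaks()` — peaks realising a category mix (defaults: 13%
  TSS-flanking and 17% near, matching the printed counts 1,460 and 1,908 of
  11,369; the remainder split 30/40 between intragenic and intergenic as a
  genome-plausible allocation), with a PWM-*sampled* instance embedded at the
  summit with probability 0.94 (the fraction of motif-positive sites the
  study reports) on a uniform random strand, and log-normal heights.
  Sampling instances from the PWM rather than planting consensus copies
  gives calibrated thresholds a realistic score spread.
* `make_conservation_track()` — per-base beta noise with stated means
  (baseline 0.10, elevated 0.60 under peaks), exact means at zero noise.
* `make_disease_matrix()` — Bernoulli background (density 0.08) plus one
  disease cluster sharing a dense term block.

One global seed fans out to per-generator child seeds by stable name
hashing, so adding a generator never perturbs another's draws — this is what
makes the end-to-end pipeline byte-reproducible.

The synthetic data deliberately omits several features of real data:
repeat structure and compositional heterogeneity (i.i.d. background),
co-occurring partner motifs, peak-calling artefacts, conservation
autocorrelation beyond planted segments, and correlated disease annotations.
Passing recovery tests therefore demonstrates the *machinery* — calibration,
counting, testing — not performance on real genomes.

# Problem sizes and runtime choices

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path in seconds-to-minutes: synthetic genomes of 0.3–2 Mb, 50–500
peaks, discovery at widths {8, 10, 12, 16} with 4 seeds per width on 120
training sequences, 999-draw permutation/resampling nulls, and 10–20 seeds
for recovery-rate statements. The headline genome-wide counts of the
motivating study (tens of thousands of peaks against a 3-Gb genome) are
inputs, not constants, and the same functions run unchanged at that scale —
scanning is vectorised across equal-length sequence sets, and annotation
classifies summits against a flattened region table rather than per-gene
loops.

# Known limitations

* The built-in discoverer is a stand-in: word seeding plus refinement finds
  strong planted or over-represented motifs but is no substitute for
  dedicated finders on subtle real signals; external MEME-format PWMs are
  the intended route for published matrices.
* Scanning is linear per sequence; there is no genome-wide index.
* bigWig tracks are not read natively — convert to bedGraph/wiggle first.
* The FDR-at-threshold estimator assumes the background set represents
  unbound sequence; compositional mismatch biases it, which is why the
  significance pipeline insists on two backgrounds.
* Liftover between assemblies and SAM/BAM handling are out of scope.
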