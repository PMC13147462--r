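---
title: "Breakpoint-centric INDEL mutation-rate modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint-centric INDEL mutation-rate modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(indelrate)
```

## The model

`indelrate` estimates germline short insertion/deletion (INDEL) mutation
rates at single-junction resolution from sequence context alone. The unit
of prediction is a *junction* — the gap between two adjacent reference
bases, indexed so that junction $j_0$ lies between 1-based bases $j_0$ and
$j_0 + 1$. An insertion occupies one junction; a deletion is bounded by two
(its *start* and *end*), and the three breakpoint kinds are modeled by
separate networks because their sequence determinants differ.

INDELs are stratified by length: events of 1–6 bp each get their own class,
events of 7–20 bp are pooled into a seventh class, and longer events are
excluded (`length_binning()`). A model maps the one-hot encoded context
window around a junction (L/2 bases on each side; no central base — the
focus is a gap, not a base) to an $(n+1)$-vector: the probability of no
INDEL plus one probability per length class.

### Rare variants as mutation proxies

De novo INDELs are too scarce to train on, so the framework uses rare
population variants as proxies. Saturation and recurrent mutation at
hypermutable sites distort allele counts in very large cohorts; to mitigate
this the cohort is thinned to a fixed total allele number $AN_{down}$ by
hypergeometric sampling of each variant's alternate count
(`downsample_ac()`), and only the resulting singletons are kept
(`extract_rare()`). Repeats make INDEL placement ambiguous, so every
retained variant is realigned by enumerating all placements that produce
the same alternate haplotype (`enumerate_placements()`) and assigning one
at random with a per-variant seeded stream, making the result independent
of record order. Positions outside a closed coverage band
$[\lfloor \bar c (1-f) \rfloor, \lfloor \bar c (1+f) \rfloor]$ are masked
(with $\bar c = 30.5$, $f = 0.5$ this is the 15–45x band; with
$\bar c = 113$ it is 56–169x), and training data exclude exonic junctions,
where selection — not mutation — shapes the variant distribution.

A useful identity for planning: under the neutral-like spectrum
$P(AC = a) \propto 1/a$ truncated at $AN$, the expected singleton fraction
after thinning to *any* $AN_{down}$ is $1 / H(AN)$ (with $H$ the harmonic
number) — the choice of $AN_{down}$ moves which variants become singletons,
not how many.

### Network

The network is a 1-D U-Net. The encoder is a stride-1 stem followed by five
dimensionality-expansion stages; each stage is a strided convolution, batch
normalization, ReLU and a ResNet-style residual block (two convolutions
with an identity shortcut). Channels grow linearly: $c_0, 2c_0, \dots,
5c_0$. The stride list has six entries whose first is fixed at 1; their
product must divide L (for L = 8000 the default is (1,4,5,5,5,4), giving a
bottleneck of 4 positions). The decoder mirrors the stride list with
transposed convolutions (kernel = stride, so upsampling is exact) and
concatenates the spatially matched encoder map at each level before a
fusing convolution. The head is a 1x1 convolution that collapses channels,
followed by a flatten of the **central `head_crop` columns** and two fully
connected layers producing $n+1$ logits and a softmax.

The head crop deserves a note, because the design was genuinely open. The
prediction is focal: what matters is whether a feature sits *at* the
junction, to 1-bp precision. With the head reading the full-length map, the
fully connected layer can fit flank fingerprints of individual training
windows faster than the convolutional path learns positional precision —
at desk scale this memorization wins and validation performance stays at
chance. Restricting the head to the central columns removes that failure
mode without losing long-range context, which still reaches the head
through the encoder–decoder path. For the same reason the compact test
configuration uses $c_0 = 8$: the base-agnostic "homopolymer run at the
junction" feature needs at least four stem channels (one equality detector
per base) plus slack, and with exactly four channels the feature does not
emerge within a 10-epoch budget.

Training minimizes cross-entropy with Adam (weight decay on convolution and
dense weights), a stepwise learning-rate decay (factor 0.5; every 2 epochs
at the human scale, every 4 at test scale where epochs are fewer and
noisier), and the strict early-stopping rule: stop when three consecutive
epochs fail to beat the running minimum validation loss. The returned
checkpoint is the epoch with minimum validation loss; `grid_trials()` runs
a seeded hyperparameter grid and keeps the globally best checkpoint.
Transfer learning (`init_from_checkpoint()`) copies all weights from a
pretrained model of identical architecture and leaves every layer
trainable.

At desk scale the validation set is small (~2000 examples), so the
validation loss carries sampling noise of the same order as per-epoch
improvements; the strict patience rule then occasionally stops a run
before context features have emerged. We keep the rule as stated and note
the sensitivity as a limitation.

### Calibration and scaling

Raw softmax outputs are refined in a fixed order:

1. **Dirichlet calibration** (`fit_dirichlet()`): the map
   $\mathrm{softmax}(W \log(p + \epsilon) + b)$, fitted on held-out
   validation data by multinomial likelihood with a light L2 penalty on the
   off-diagonal of $W$ ($\epsilon = 10^{-10}$). Effectiveness is measured
   by the top-label expected calibration error over 10 equal-width bins.
2. **Poisson correction** (`poisson_correct()`): class-balanced training
   inflates absolute probabilities, and recurrent mutation makes "at least
   one event" differ from "expected events"; the total mutation
   probability $s = \sum_i p_i$ is mapped to a rate
   $\lambda = -\ln(1 - s)$, redistributed over classes proportionally.
   The correction is monotone, never decreases a probability, and vanishes
   as $s \to 0$.
3. **Genome-rate scaling** (`scale_rates()`): a single factor
   $f^{mut} = \mu^{genome} |S| / \sum_{i \in S} p_i$ over a site set $S$
   makes the mean scaled rate equal the genome-wide per-bp per-generation
   rate exactly (human de novo INDEL value $1.5 \times 10^{-9}$);
   `scale_to_spectrum()` applies per-class factors against a target
   spectrum before aggregating across models. Pearson correlations are
   affine-invariant, so scaling does not change the evaluation metrics
   below.

### Uncertainty

A deep ensemble of $M$ independently initialized models (default 3,
configurable 2–10) yields the mean prediction $\bar p$ and the mutual
information $\mathrm{MI} = H[\bar p] - \frac{1}{M}\sum_m H[p^{(m)}]$
(natural log). MI is zero iff members agree, bounded by $H[\bar p]$, and
invariant to member order; it quantifies epistemic uncertainty and
correlates with the Brier score on heteroscedastic tasks.

### Evaluation

Per-junction accuracy is unmeasurable directly, so agreement is evaluated
at two aggregations: **k-mer correlation** — junctions grouped by the k/2
flanking bases on each side; per subtype the observed rate $m_i/N_i$
against the mean predicted probability; Pearson over subtypes — and
**regional correlation** over non-overlapping bins anchored at coordinate
0, with bins failing $N > 20\% \cdot N_{median}$ (median per contig)
excluded. The coefficient-of-variation gap between observed and predicted
regional rates measures dispersion fidelity.

### Constraint and interpretation

`dr_scores()` ranks 500-bp windows (50-bp step) by $(O - E)/\sqrt{E}$,
where $E$ is the summed scaled rate times a correction factor anchored on
a user-supplied neutral site set; the $i$-th lowest window receives
$DR = 100 (i - 0.5)/n$, so depleted (constrained) regions have low DR.
`kmer_density()` computes the average rare-variant density of a k-mer over
its $k-1$ internal junctions; `metagene_profile()` averages rates around
genes with bodies rescaled to a fixed length; strand-stratified densities
compare motif instances on the transcribed and non-transcribed strands
across predicted-rate deciles.

Attribution uses integrated gradients (midpoint Riemann sum along the path
from an all-zero "absent sequence" baseline; 64 steps by default, with the
completeness identity checked at 128) and gradient x input. Seqlet
extraction is a deliberately simplified stand-in for full motif-discovery
clustering: contiguous runs of smoothed positive attribution above a
quantile threshold, recentred on the attribution peak at fixed width,
clustered by greedy star alignment. Motifs carry a PWM (column base
frequencies), per-column information content against a uniform background
(columns below 0.1 bit are trimmed from the flanks), and a CWM (mean of
one-hot x attribution). Retention requires all three filters: elevated
observed rare-variant density at motif-containing high-rate sites, more
than 100 occurrences, and a contribution score above the median (both
strict).

## The synthetic data generator

Every stage is testable without downloads against `fixture_bundle()`:

* **Genome** — iid background at a chosen GC fraction with planted
  homopolymer runs (~2/kb, lengths 4–12), dinucleotide repeats (~1/kb, 3–8
  units) and a CTTACG hot motif (~0.5/kb, both strands). Annotations are
  re-derived from the final sequence, so chance occurrences count like
  planted ones.
* **True rates** — class-c rate at a junction is a base rate times
  multiplicative context effects: $2^{\ell - 3}$ for class-1 events inside
  a homopolymer run of length $\ell \ge 4$ (the per-extra-base fold change
  reported for 1-bp INDELs in mononucleotide runs), $1.6^{u-2}$ for
  class-2 events in a dinucleotide run of $u \ge 3$ units, and 50x for
  class-1 insertions at the motif's five internal junctions. Base class-1
  rates are $3 \times 10^{-5}$ (insertion) and $3.5 \times 10^{-5}$
  (deletion) per junction with geometric decay 0.55 per class, saturating
  at a cap of $10^{-3}$ where effects compound. These values were sized so
  that the rare-variant pipeline yields enough singletons (~12k insertion
  breakpoints from the 2 x 1 Mb standard fixture) for aggregate recovery
  analyses to be statistically identifiable — with an order of magnitude
  fewer events, even the empirical per-4-mer rates of the extracted
  singletons no longer track the generative map.
* **Cohort** — per junction and class an event occurs with probability
  `rate * event_scale` (default 700); allele counts follow the truncated
  $1/a$ spectrum, so singleton logic has realistic prey and recurrence is
  possible; representation conflicts at one anchor drop the later event.
  The emitted VCF, coverage bedGraph (Poisson around 30x in 100-bp blocks
  with dropout and collapsed-repeat blocks) and exon/gene BEDs are
  cross-consistent.

What the generator does **not** emulate: linkage, demography, selection,
sequencing error, alignment artifacts, GC-biased composition, and the
full heterogeneity of real repeat families. Passing recovery tests shows
the pipeline can identify planted context effects from cohort data at desk
scale — not that real-genome accuracy matches the full-scale system.

## Problem sizes used in the packaged analyses

The test-scale experiments train on the standard fixture with up to 10k
insertion positives and an equal number of non-mutated junctions (the full
framework uses 1:10 for insertions; at desk scale the balanced ratio gives
the strongest per-example gradient signal), 256-bp windows, batches of 64,
at most 10 epochs, and evaluate on ~50k junctions aggregated into 4-mers.
The attribution analyses use the central 200 bp, 100-site batches and
32–128 integration steps.

## Numerical choices

* One-hot rows are fixed to A,C,G,T; N and out-of-contig positions encode
  as all-zero columns and receive exactly zero attribution.
* Cross-entropy is computed from logits via log-softmax; softmax columns
  are max-shifted.
* Batch normalization uses batch statistics in training and running
  statistics (momentum 0.1) at inference; $\epsilon = 10^{-5}$.
* "Smaller than the current minimum" in early stopping is strict;
  ties in DR ranking are broken by (contig, start); windows with zero
  expected count are dropped with a warning.
* Dirichlet fitting uses BFGS with an analytic gradient; the identity map
  is the starting point, so fitted calibration can never be worse than
  raw on the fitting set beyond optimizer tolerance.
* The hypergeometric sampler is R's `rhyper`; placement assignment derives
  a per-variant seed from (global seed, contig, left-aligned position).

## Known limitations

* The exact stride lists, kernel sizes and head widths of the full-scale
  system are not public; defaults satisfy the stated constraints but are
  not guaranteed identical.
* Validation-loss noise at desk scale interacts with the strict patience
  rule (see above); runs with unlucky early stops under-train.
* The seqlet clusterer is a stand-in: ungapped, greedy, and unsuited to
  soft or composite motifs.
* Deletion-end generative truth is implied by deletion-start events rather
  than modeled independently.
* The coverage-band floor rule reproduces the 15–45x and 56–169x printed
  bands; a 10–30x band from a mean of 21x is inconsistent with flooring
  (which gives 31) and is left as an open question.
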