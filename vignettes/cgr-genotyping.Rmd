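---
title: "Genotype chaos-game images for species and cultivar typing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype chaos-game images for species and cultivar typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrtyper)
```

## The problem

Whole-genome sequencing of a crop collection yields, after joint variant
calling against a reference, a genotype call for every sample at every
shared variant locus — millions of loci per sample.  True-to-type testing
asks whether a sample genetically matches its declared species or cultivar.
`cgrtyper` implements a compact route from such genotype tables to
classifiers: encode each sample's genotypes as a *pseudo-DNA sequence*,
render the sequence as a greyscale *chaos game representation* (CGR) image,
and classify the images under class imbalance, with balanced accuracy as
the metric and sequence-similarity methods as baselines.

## Pseudo-DNA encoding

The joint call must keep the same locus list for every sample (in
`bcftools call` terms, per-sample variant filtering disabled), so the i-th
symbol of every sample's sequence refers to the same genomic position.
Each diploid genotype becomes one symbol:

* homozygous calls map to the allele base;
* heterozygous SNPs map to the IUPAC two-base code (`A/G` → `R`, `C/T` →
  `Y`, `C/G` → `S`, `A/T` → `W`, `G/T` → `K`, `A/C` → `M`);
* indel alleles and missing calls map to `N`.

One symbol per locus keeps all samples the same length; the encoding is
locus-local, so editing one genotype changes exactly one base.  How a
production pipeline encodes heterozygous or missing calls is a genuine
design choice; IUPAC codes were chosen here because the CGR stage treats
every non-`ACGT` symbol as a step toward the centre of the square, which
keeps heterozygous and missing information distinguishable in the FASTA
while mapping both away from the four base corners.  Per-chromosome
sequences and a concatenated genome sequence (chromosomes in natural sort
order) are both supported, mirroring the two granularities the classifiers
consume.

## Chaos game representation

The CGR places `A`, `C`, `G`, `T` at the corners `(0,0)`, `(0,1)`,
`(1,1)`, `(1,0)` of the unit square.  Starting from the centre
`(0.5, 0.5)` (not itself counted), each symbol moves the current point
halfway toward its corner; non-`ACGT` symbols move halfway toward the
centre.  Binning the trajectory on an `R × R` grid gives a count matrix
whose total equals the sequence length; at dyadic resolutions `R = 2^k`
the cell of a point is determined by the last `k` standard bases, which is
exactly the frequency-CGR / k-mer-table equivalence and is what the test
suite verifies against a brute-force suffix oracle.

```{r cgr-example}
traj <- cgr_trajectory("ACGT")
round(traj, 5)
m <- cgr_matrix("ACGTACGTTTGA", resolution = 4)
sum(m) == 12
```

Two conventions are deliberate and documented rather than prescribed by
the method: the walk starts at the centre, and the image puts `y = 1` at
the top row, so the `C` and `G` corners render at the top.  Coordinates
exactly 1.0 clamp into the last pixel.

Count images are normalized to `[0, 1]` before classification.  `"none"`
divides by the maximum, `"linear"` is min-max, `"log"` applies `log1p`
first (compressing the heavy-tailed counts of long sequences), and
`"robust"` centres by the median and scales by the IQR of all pixels
before a final min-max rescale.  Because an affine transform followed by
min-max is itself min-max, robust scaling without clipping coincides
numerically with linear scaling; it is kept as a distinct, named method
because the scaling statistics are reported and because a clipping variant
is a natural extension.  On sparse images (short sequences at high
resolution) the pixel IQR is frequently zero; the implementation then
falls back to linear scaling and says so once per image batch.

## Class imbalance, loss, and the classifier contract

Species collections are extremely imbalanced, so training weights each
class inversely to its frequency: with `n_c` training samples in class
`c`, `C` classes and `N = Σ n_c`,

$$ w_c = \frac{N}{C\,n_c}, \qquad \sum_c w_c n_c = N . $$

The weighted cross-entropy for a minibatch of `M` samples averages
per-sample losses over `M`:

$$ \ell = \frac{1}{M}\sum_{m=1}^{M} l_m, \qquad
   l_m = -w_{y_m}\,\log\mathrm{softmax}(x_m)_{y_m} . $$

Dividing by `M` rather than by `Σ w_{y_m}` is intentional — the two differ
whenever weights are non-uniform — and keeps the loss insensitive to batch
size.  The implementation is stabilized by row-max subtraction and is
tested against an unstabilized independent softmax implementation.

Classifiers are pluggable: any constructor registered with
`register_classifier()` that fits on (images, labels, class weights,
hyperparameters, seed) and returns per-class score vectors over a fixed
class list satisfies the contract.  The built-in `"reference"` model is a
nearest-centroid classifier on flattened normalized images (score =
negative Euclidean distance): closed-form, deterministic, and invariant to
training-order permutations.  It deliberately stands at the opposite end
of the complexity scale from fine-tuned deep backbones; those slot into
the same contract (the `hyperparams()` defaults — batch 16, 200 epochs,
learning rate 0.01 — are forwarded to such plugins and ignored by the
closed-form fit).

## Integration strategies

Four ways to combine per-chromosome information:

* **Chromosome-wise** — one model per chromosome, each evaluated on its
  own test images; the summary is the unweighted mean of per-chromosome
  balanced accuracies.
* **Early integration** — all chromosome images pooled into one training
  set for a single model; evaluation is per image by default, with an
  optional per-sample majority aggregation (per-image is the default
  because the pooled model is explicitly meant to see each chromosome as a
  separate view).
* **Late integration** — one model per chromosome; for a test sample each
  model votes its argmax class and the modal class wins.  Vote ties are
  broken deterministically: first by the largest summed score mass for the
  tied classes across all models, then by the lexicographically smallest
  label; the vote record logs tallies and whether a tie-break fired.  The
  voting rule uses predicted classes only (plain votes, not score-weighted
  voting, which is left as future work).
* **Whole genome** — one CGR per concatenated genome sequence, one model.

A genome-level CGR is almost the sum of its chromosome CGRs: at
`R = 2^k` only the first `k` points after each concatenation boundary can
fall in different cells, a bound the tests assert exactly.

## Evaluation

Per-class recall is `R_c = TP_c / (TP_c + FN_c)` and balanced accuracy is
the unweighted mean of recalls, so no majority class can dominate the
metric.  Classes absent from the truth of a given test set are excluded
from the mean (and reported), rather than scored zero — the "average of
recalls on each class present" reading; the behaviour is visible in the
returned `excluded` field.  Repeated-run aggregation reports mean and
sample standard deviation (n−1) over a contiguous block of seeds, 20 runs
by default.

## Baselines

Three similarity methods provide reference points on the concatenated
genome sequences:

* **identity k-NN** (`k = 1`): pairwise proportion of identical symbols
  over the aligned positions; since pseudo-sequences are fixed-length and
  position-aligned, no alignment gaps arise and `N` participates as an
  ordinary symbol (it matches another `N`, mismatches any base), which
  preserves "similarity 1 iff identical".
* **k-mer nearest neighbour** (`k = 21`): Jaccard similarity of distinct
  k-mer sets; windows containing a non-`ACGT` symbol are skipped, and no
  reverse-complement canonicalization is applied because the sequences
  have a fixed reference orientation.
* **kernel SVM** (`C = 2`): a class-weighted soft-margin SVM trained on
  the train-by-train k-mer Jaccard kernel and applied to the test-by-train
  kernel (via `kernlab::ksvm` with a precomputed kernel).

Similarity ties in the nearest-neighbour vote resolve by training-set
order, label-count ties by the lexicographically smallest label — all
deterministic.

## The simulator and what it does (not) show

Real collections cannot ship with a package, so the simulator generates
the same *structure*: a root sequence drawn uniformly over `{A,C,G,T}`,
species founders at `round(species_divergence · L)` substituted loci
(positions sampled without replacement, substitutions uniform over the
three other bases — a deterministic count with random placement keeps the
truth bookkeeping exact), cultivars nested within species, samples nested
within cultivars, and an optional per-sample `N` rate.  Every mutated
locus is recorded, so tests can compare observed mismatch fractions
against exact truth counts instead of asymptotic formulas.

The default configuration is the package's study condition: 5 species ×
3 cultivars × 3 samples over 19 chromosomes of 2,000 loci, divergence
0.05 / 0.005 / 0.001.  No public estimate exists for the real divergence
levels between grapevine species and cultivars at joint-call loci; these
defaults were chosen once to make the task feasible but non-trivial
(between-species distance ≈ 7%, within-cultivar ≈ 0.2%) and are not
revisited.  Images are rendered at resolution 64 for these studies —
2,000-locus chromosomes carry roughly 2,000 CGR points, which a 64 × 64
grid resolves without being dominated by empty pixels — while 224, 512 and
1024 remain the natural choices for megabase-scale real data.

What passing these studies shows: the full pipeline — encoding, imaging,
weighting, integration, voting, evaluation — is internally consistent and
recovers hierarchical population structure when it exists, and loses it as
divergence goes to zero.  What it does not show: performance on real WGS
genotype data, where linkage, shared ancestry between classes,
heterozygosity, coverage-dependent missingness and variant-calling noise
all violate the simulator's independence assumptions.  One such effect is
visible even in simulation: zeroing *species* divergence alone does not
drive species-level accuracy to chance, because shared cultivar ancestry
between training and test samples still identifies the species — class
signal can live below the nominal class level.

## Numerical and degenerate-input choices

* Trajectory computation uses the linear recursion
  `p_i = p_{i-1}/2 + t_i/2` via a recursive filter; all quantities are
  dyadic rationals, exact in double precision for any realistic length.
* Empty sequences, resolutions below 1, non-finite logits, zero-count
  classes, unsorted variant positions, asymmetric kernels and
  out-of-range allele indices raise immediate, specific errors.
* Constant images min-max to all zeros; two empty k-mer profiles have
  similarity 0 (with a warning).
* Splits are stratified per class at whole-sample granularity with
  validation/test sizes `floor(fraction · n)` (bumped to at least 1) and
  the remainder in training, so a 3-sample class splits 1/1/1 and a
  10-sample class 6/2/2; no sample's images can appear in two splits.

## Known limitations

The reference classifier is linear in pixel space and is not a statement
about attainable accuracy — it is the contract's deterministic floor.  The
simulator has no linkage, recombination or indel model.  Printed
"random guess" levels in empirical benchmark tables are often empirical
rather than the analytic `1/C`; the package reports the uniform chance
level only.
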