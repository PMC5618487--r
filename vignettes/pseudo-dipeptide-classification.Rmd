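---
title: "Pseudo-dipeptide composition and hierarchical ion channel classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-dipeptide composition and hierarchical ion channel classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdcpred)
```

## The problem

Ion channels are pore-forming membrane proteins that conduct inorganic
ions across lipid bilayers. They divide into voltage-gated (VGIC) and
ligand-gated (LGIC) channels, and the voltage-gated family further splits
into potassium, calcium, sodium and anion channel types. Given only an
amino acid sequence, we want to decide (1) whether the protein is an ion
channel at all, (2) if so, whether it is voltage- or ligand-gated, and
(3) for voltage-gated channels, which of the four types it is. `pdcpred`
implements this as a cascade of binary/multiclass RBF-SVM classifiers
over a sequence-order-aware composition descriptor, with ANOVA-based
feature selection — a design in wide use for membrane-protein function
prediction from primary sequence alone.

## The descriptor

A sequence $P = R_1 R_2 \dots R_L$ over the 20 canonical residues is
mapped to a vector of dimension $400 + n\lambda$:

$$
P_u = \begin{cases}
\dfrac{f_u}{\sum_{i=1}^{400} f_i + \omega \sum_{j=1}^{n\lambda} \tau_j}
  & 1 \le u \le 400\\[2ex]
\dfrac{\omega\,\tau_{u-400}}{\sum_{i=1}^{400} f_i + \omega \sum_{j=1}^{n\lambda} \tau_j}
  & 400 < u \le 400 + n\lambda
\end{cases}
$$

where $f_u$ is the normalized occurrence frequency of the $u$-th
dipeptide among the $L-1$ adjacent pairs, and the sequence-order
correlation factors are, tier-major for lags $j = 1,\dots,\lambda$ and
properties $k = 1,\dots,n$,

$$
\tau_{(j-1)n+k} = \frac{1}{L-j} \sum_{i=1}^{L-j} h_k(R_i)\, h_k(R_{i+j}).
$$

$h_k$ is the $k$-th physicochemical scale after the standard conversion
(below). Because $\sum f_i = 1$ by construction, the components always
sum to 1 and the dipeptide and correlation blocks carry mass
$1/(1+\omega T)$ and $\omega T/(1+\omega T)$ with $T = \sum_j \tau_j$.

Two parameters matter:

* $\lambda$ (lag depth, dimensionless, default search range 1–30, step
  1) — how far apart two residues may be and still contribute
  correlation information. Larger $\lambda$ captures longer-range
  sequence order but adds $n$ features per tier and requires $L >
  \lambda$.
* $\omega$ (correlation weight, dimensionless, default search range
  0.05–0.70, step 0.05) — how much the correlation block counts
  relative to the dipeptide block. At $\omega = 0$ the descriptor
  degenerates to plain dipeptide composition. The crossed default grid
  has $30 \times 14 = 420$ combinations (`encoder_param_grid()`).

Settings used throughout the examples: $(\lambda, \omega)$ = (21, 0.20)
for channel vs non-channel, (7, 0.30) for VGIC vs LGIC and (9, 0.15) for
the four-type problem give dimensions 589, 463 and 481 with the default
nine properties.

### Physicochemical scales and their standardization

Each scale is converted so that its 20 values have zero mean and unit
*population* standard deviation (denominator 20):

$$
h_k(R_i) = \frac{h^0_k(R_i) - \overline{h^0_k}}
  {\sqrt{\tfrac{1}{20}\sum_{u=1}^{20}\big(h^0_k(R_u)-\overline{h^0_k}\big)^2}}.
$$

This form is the unique affine standardization that is both zero-mean
and idempotent — applying it twice changes nothing — which makes
correlation factors comparable across scales of wildly different units
(pK units, daltons, mutability percentages). A constant scale has no
spread and is rejected with an error naming the property.

The shipped `"default9"` registry covers hydrophobicity (consensus
scale), hydrophilicity (Hopp–Woods), side-chain mass, pK of the
α-carboxyl and α-amino groups, isoelectric point, Zimmerman bulkiness
(used here as a steric-rigidity proxy), Bhaskaran–Ponnuswamy average
flexibility, and Dayhoff relative mutability (the inverse sense of
residue irreplaceability). The classical nine-property formulation of
this descriptor names rigidity, flexibility and irreplaceability scales
whose numeric tables are not published alongside it; we substitute the
three documented scales above, which measure the same physical axes.
Every operation takes the property table as an argument, so any
$n$-property table — loaded from a plain TSV via
`load_property_table()` — can replace the default, and all dimension
arithmetic follows $400 + n\lambda$.

### Numerical edge cases

Standardized scales take negative values, so individual $\tau_j$ — and
in principle the normalizer $D = 1 + \omega \sum_j \tau_j$ — can be
negative. On realistic sequences with $\omega \le 0.70$, $D$ stays
comfortably positive (the $\tau_j$ average near 0 for natural and
uniform-random sequences); should an adversarial input drive
$|D| \le 10^{-9}$, `encode()` raises a "degenerate normalization" error
rather than emitting unbounded features. Sequences with $L \le \lambda$
are rejected, not padded: the tier-$\lambda$ factor is undefined there.
Negative $\tau$ values are kept as-is — the descriptor is not clipped or
shifted, so correlation components can be negative while the vector
still sums to 1.

## Feature selection

Each feature gets a one-way ANOVA F-value, the ratio of between-class
to within-class mean squares:

$$
F = \frac{\sum_i n_i(\bar{x}_i - \bar{x})^2/(K-1)}
         {\sum_i \sum_j (x_{ij}-\bar{x}_i)^2/(N-K)}.
$$

A feature with zero within-class variance but distinct class means is a
perfect separator on the training data and is scored $+\infty$ (ranked
first, ties by column index); a feature constant everywhere scores 0
with a warning. F is invariant to shifting or rescaling a feature, so
no per-feature normalization is needed before ranking.

Incremental feature selection (IFS) then walks prefixes of the ranked
list: the classifier is evaluated on the top-$k$ features for growing
$k$, and the smallest $k$ attaining the maximal accuracy wins — the
parsimony tie-break. The evaluator is injected; the standard choice is
jackknife overall accuracy with fixed SVM hyperparameters
(`svm_jackknife_evaluator()`), and tests use a cheap nearest-centroid
evaluator where SVM cost would be wasted. `k_grid` lets callers thin
the curve (e.g. every feature up to 15, then strided): the default is
step 1 over all features, which is exact but quadratic-ish in cost.

## Classification and evaluation

The classifier is an RBF-kernel SVM, $K(x,y) = \exp(-\gamma\|x-y\|^2)$,
trained by libsvm through `e1071`, with one-vs-one decomposition for
multiclass problems. The default hyperparameter grid crosses
$C \in \{2^{-5}, 2^{-3}, \dots, 2^{15}\}$ (11 values) with
$\gamma \in \{2^5, 2^4, \dots, 2^{-15}\}$ (21 values), 231 pairs,
searched exhaustively with ties resolved toward smaller $C$ then
smaller $\gamma$ — a deterministic rule independent of enumeration
order. No additional feature scaling is applied before the SVM: the
descriptor already normalizes each vector to unit sum, and rescaling
would distort the deliberate $\omega$-controlled mass split.

Evaluation is the jackknife (leave-one-out) test: each sample is
predicted by a model trained on the other $N-1$. From the resulting
confusion matrix we report per-class sensitivity
$Sn(i) = TP_i/(TP_i+FN_i)$, overall accuracy $OA = \sum_i TP_i/N$ and
average accuracy $AA = \sum_i Sn(i)/n$. OA equals AA exactly when all
classes have equal size. The protocol tunes $(C,\gamma)$ once on the
full dataset and then jackknifes with them fixed; this is mildly
optimistic (the tuning has seen every sample), which is why
`grid_search()` and `jackknife_evaluate()` are separate building
blocks — nesting the grid search inside each fold is a one-line loop
for callers who need the unbiased estimate, at $231\times$ the cost.
Class imbalance (e.g. 81/29/12/26 in the four-type problem) is reported
through per-class $Sn$ and $AA$ but not corrected by class weights.

The hierarchical predictor (`predict_hierarchy()`) chains three
bundles: channel vs non-channel, then VGIC vs LGIC, then the four-type
model. Stages may use different $(\lambda, \omega)$; a query shorter
than a stage's $\lambda$ gets an explicit `unencodable` verdict at that
stage rather than an error, and records rejected at stage 1 never touch
the later models.

## The synthetic-data generator

No curated channel benchmark ships with the package, so
`generate_dataset()` builds labeled datasets in which the
class-separating structure is *planted* and therefore known. Sequences
are drawn residue-by-residue from a background distribution (default:
uniform over the 20 residues — the simplest null); for a signalled
class, each chosen dipeptide is written over non-overlapping random
positions so that its expected count is an `enrichment` multiple of its
background expectation, with Poisson-distributed per-sequence counts. A
secondary `periodic` mode overwrites every $p$-th position with a
residue from a pool (e.g. hydrophobic residues), creating lag-$p$
physicochemical autocorrelation that exercises the $\tau$ block rather
than the dipeptide block. The default class sizes mirror a curated
channel benchmark (300 non-channels, 150 ligand-gated, 148
voltage-gated split 81/29/12/26); lengths default to 60–600 residues,
within the range of real channel domains and comfortably above the
largest default $\lambda$.

What passing tests on such data do show: the encoder, ranking, IFS,
grid search and jackknife machinery recover planted signal of realistic
effect size, end to end. What they do not show: performance on real
proteins, where class signal is distributed across many weakly
informative features, sequence composition is non-uniform, and homology
structures the classes — planted dipeptide enrichment is a much cleaner
signal than evolution provides. Benchmarks built from real databases
should additionally be redundancy-filtered (the usual contract is a 40%
identity ceiling via CD-HIT, plus removal of fragments,
homology-only annotations and sequences with ambiguous residues —
`validate_records()` enforces only the last of these, the only one
visible in plain FASTA).

## Sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the full pipeline on a
two-class planted dataset of 60 + 60 sequences of length 200 with five
enriched dipeptides, with IFS on a thinned prefix grid (every prefix up
to 15, then every 50th) and a reduced 3 × 3 hyperparameter grid; the
property-based suites use 100–1000 random sequences or datasets per
invariant. These sizes give stable results while keeping a full run in
the order of a minute on a single core.

## Known limitations

* The default protocol (tune once, then jackknife) overestimates
  generalization slightly; use nested tuning for unbiased numbers.
* ANOVA scores features marginally; complementary or redundant feature
  sets are invisible to it, and IFS inherits that myopia.
* The descriptor discards residue position entirely beyond lag
  correlations; motif-position information is out of reach.
* `Inf`-scored features are perfect separators *on the training data*
  only; with few samples per class they arise by chance.
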