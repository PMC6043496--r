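---
title: "Disorder-aware PPI prediction: models, design choices and limits"
author: "disoPPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disorder-aware PPI prediction: models, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disoPPI)
```

## The problem and the model

Intrinsically disordered proteins (IDPs) bind structurally diverse partners
through interfaces that are shaped more by residue composition — charge,
hydrophilicity, a deficit of bulky hydrophobics — than by a folded
geometry. disoPPI treats partner prediction as binary classification of
ordered (IDP, partner) sequence pairs, with two composition-derived
encodings per protein:

**Dipeptide composition.** Every ordered pair of consecutive residues is a
unit; the 400 dipeptide frequencies (counts divided by $L-1$) capture local
sequence patterning and sum to one. Ordering of the 400 names is
lexicographic and fixed by the schema, so exported feature tables are
stable across runs.

**Pseudo amino acid composition (PAAC, Type I).** Each of the five
propensity scales $S_k$ (TOP-IDP, B-values, FoldUnfold, DisProt, net
charge) is standardized to zero mean and unit *population* standard
deviation over the 20 residues — the population convention (divide by
$n=20$) is deliberate, so $\theta$ values are bit-reproducible. The pair
correlation of residues $a,b$ is the mean squared difference of their
standardized scale values,
$\Theta(a,b)=\frac{1}{\Gamma}\sum_k\left[S_k(b)-S_k(a)\right]^2$, tier $j$
averages $\Theta$ over all residue pairs $j$ positions apart, and the
final vector normalizes the raw residue counts $f_u$ and the weighted
tiers jointly:

$$x_u = \frac{f_u}{\sum f + w\sum\theta},\qquad
  x_{20+j} = \frac{w\,\theta_j}{\sum f + w\sum\theta}.$$

A single correlation function averaged over the $\Gamma=5$ scales (Type I)
is the only convention consistent with a $20+\lambda$-dimensional vector:
per-scale tiers would give $20+5\lambda$ components instead.

A protein is the 470-vector `[PAAC | dipeptide]`; a pair is the
940-vector with the IDP always in the first slot. The orientation is a
package convention (it is not derivable from the data) and is recorded in
the pair attributes so that models are reproducible.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `lambda` | 50 tiers | deepest sequence-order correlation; fixes the minimum encodable length at 51 residues and the PAAC dimension at 70 |
| `weight` (w) | 0.05 | balance of correlation tiers against residue counts in the shared normalization; the standard PAAC convention. The published analyses this package follows do not report their value, so exact numeric reproduction of their tables is not expected for any choice; the simplex structure is insensitive to it |
| `nonstandard` | `"delete"` | nonstandard letters (B, J, O, U, X, Z, ...) are removed with a warning that counts them; deleting more than 5% of a sequence, or any nonstandard letter under `"error"`, refuses the sequence. Silent coercion would bias composition |
| `minLength` | 50 aa | sequences shorter than 50 residues are fragments or peptides and are filtered before pairing |
| `identityThreshold` | 0.40 | pairwise identity above which two sequences are redundant; identity is matches / alignment length from a global alignment (BLOSUM62, gap open 10, gap extend 0.5). Desk-scale clustering is internal and greedy (longest first, ties by id — deterministic); full-scale datasets should use CD-HIT and the `.clstr` import hook |
| `testFraction` | 0.30 | fraction of partner proteins assigned to the test side of each C2 repeat; a conventional holdout share |
| `nRepeats` | 5 | holdout repetitions; reports are mean ± sd across repeats |
| decision threshold | 0.5 | a score exactly at the boundary counts as a positive prediction (documented tie-break) |

Classifier defaults (all overridable, all searchable by inner
cross-validated AUC): random forest 500 trees, $\sqrt{p}$ features per
split, minimum node size 1; gradient boosting 150 rounds, learning rate
0.1, depth 3, row subsample 0.8; ridge logistic regression $\lambda=0.01$
solved along a warm-start path; RBF-SVM cost 1, $\gamma = 1/p$.

## Why degree balance changes what is learnable

Degree-balanced negative sampling makes each protein appear exactly as
often among negatives as among positives. This has a sharp and, in our
experience, underappreciated consequence: every pair feature is a function
of one protein's identity, so under exact parity **every feature column has
identical class means**, and

* the intercept is a stationary point of any generalized linear model —
  a GLM trained on balanced negatives can only ever exploit signal that
  parity does not cancel (there is none at first order);
* any threshold split on a per-protein feature partitions complete
  per-protein row groups and therefore has exactly zero gain, so
  deterministic gradient boosting on the full sample never grows its first
  tree. Row subsampling (the 0.8 default) breaks the exact parity per
  boosting iteration and restores learning;
* random forests learn regardless, because bootstrap resampling breaks
  parity per tree — one reason tree ensembles are the natural model family
  for this protocol.

The same argument dictated the synthetic generator's planted rule. A rule
of the form "positively charged IDP × negatively charged partner" produces
a *product set* of edges, which degree-balanced re-pairing of the same
protein multisets reproduces exactly — the training signal vanishes by
construction. The shipped rule is therefore symmetric *charge
complementarity*: an edge prefers a partner whose net charge per residue
mirrors the IDP's ($q_\text{partner} \approx -q_\text{IDP}$, quadratic
mismatch penalty, log-linear strength 20). Matching is a joint property of
the pair; re-pairing breaks it, so the signal survives balanced training
while remaining invisible to any purely marginal statistic.

## What the generator emulates, and what it does not

`syntheticConfig()` describes the benchmark conditions used across the
test suite: 30 IDP-like sequences (150–400 aa) against 300 ordered-like
partners (200–500 aa), disorder bias 0.5 (IDP residue distributions tilted
toward disorder-promoting residues, with the packaged TOP-IDP scale as the
single source of truth), heavy-tailed IDP hub weights (power-law exponent
2.5) with a mean of 6 interactions per IDP, and per-sequence charge tilts
drawn from six stratified levels at amplitude 2.5 so that complementarity
classes are distinct and evenly populated. Degree caps (10 per IDP, 3 per
partner) keep IDPs as the hubs — mean IDP degree is 20× the mean partner
degree — while guaranteeing that exact degree-balanced negatives remain
combinatorially feasible; the rule strength was calibrated once against
the brute-force rule itself used as a scoring oracle, then frozen. With
the rule disabled, the same pipeline yields chance-level AUC (95% CI over
ten seeds contains 0.5), which is the package's standing audit against
leakage anywhere in the encoding/split/training chain.

The generator emulates compositional bias, charge heterogeneity and hub
structure. It does **not** emulate real proteomes' domain architecture,
repeat content, nonstandard residues, sequence homology (and hence the
need for redundancy reduction), isoforms, post-translational
modifications, or experimentally derived confidence scores. Passing the
synthetic benchmark therefore demonstrates that the machinery is correct
and leak-free — not that the classifier reaches any particular accuracy on
real interactomes.

## Numerical and degenerate-input conventions

* Metric denominators of zero (no predicted positives, single-class folds
  after thresholding, ...) yield 0 with the metric name in a `flagged`
  attribute rather than NaN, so small folds aggregate.
* AUC is the rank statistic with ties counted one half; AUPRC is
  step-wise average precision over unique thresholds, with no linear
  interpolation. Both match brute-force reference implementations to
  1e-12 in the tests.
* Aggregates are exactly the arithmetic mean/sd of the per-repeat rows and
  this identity is enforced by the report class's validity method.
* Imbalance sweeps score nested negative draws (the 1N and 10N sets are
  subsets of the 100N draw), so ratio effects are not confounded with
  sampling noise.
* Balanced sampling re-pairs the positive degree multisets by random
  permutation with rejection of known positives, duplicates and IDP–IDP
  pairs, and repairs stuck leftovers by swapping with an accepted pair;
  after a bounded number of attempts (100 per requested pair) an
  infeasibility error reports how many pairs were placed.
* Empty test or train sides of a split, single-class training sets, folds
  without both classes, schema mismatches at prediction time and leaked
  splits are all hard errors, never warnings.

## Problem sizes

The test suite runs the full pipeline at the 30 × 300 benchmark (about 180
positive pairs, five C2 repeats with a 1N/10N/100N sweep, and ten
null-rule fits), oracle-checks encoders and metrics on 110 random
fixtures, and keeps individual unit fixtures at 8–12 IDPs against 40–80
partners; the whole suite completes in about a minute on one CPU, which we
consider the right budget for a continuously run check of a method of this
size.

## Known limitations

* Published-scale performance tables for predictors of this family are
  computed on curated interactome snapshots with tuned models; without
  those exact pair lists and tunings, absolute values are not reproducible
  at desk scale. The package ships the mechanism for a full-scale rerun
  (supplementary-style labelled pair lists with confidence cutoffs, CD-HIT
  cluster import, the same split/evaluation engine) and verifies the
  mechanism, not the historical numbers.
* Two of the five packaged propensity scales (FoldUnfold, DisProt) are
  synthetic reconstructions that preserve the published residue rankings;
  their files are labelled accordingly. After standardization only
  relative spacing enters PAAC, but users wanting publication-grade runs
  should transcribe the primary tables.
* The exact PAAC weight w used in the published analyses is unreported;
  0.05 is the field convention and is exposed as configuration.
* The reduced-alphabet triad baseline defaults to the 343-feature conjoint
  triad; a raw 8000-feature tripeptide variant is provided because
  one-line descriptions of "tri-peptide composition" are ambiguous between
  the two.
* SVM probability estimates are Platt-calibrated by the backing library
  and are reproducible only to solver tolerance; their orientation is
  checked against the model's own class predictions because the library
  ties its sign convention to training row order.
* Isoforms and post-translational modifications are out of scope: a
  protein is its reference amino-acid string.
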