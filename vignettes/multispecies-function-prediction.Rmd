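---
title: "Multispecies protein function prediction from homology-informed network similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispecies protein function prediction from homology-informed network similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protein function prediction from a protein–protein interaction (PPI)
network is a node-classification problem: given a graph whose nodes are one
organism's proteins and a partial assignment of Gene Ontology (GO) terms,
score every (protein, term) pair. Methods tied to a single organism's
network cannot use the much larger body of annotations available in other
species, and cannot say anything about organisms with no interaction data
at all — a common situation for non-model species.

`isofun` addresses both limitations by building one shared feature space
over the proteins of several species. Sequence homology (BLAST e-values)
supplies the cross-species links; network diffusion turns those links plus
each species' PPI topology into a dense similarity profile for every
protein; and a single multi-label classifier is trained on all species'
annotated proteins at once.

## The similarity model

For species $i$ and $j$ with row-normalized adjacency matrices
$\hat{A}_i, \hat{A}_j$ and a homology matrix $R_{ij}$, the cross-species
similarity $S_{ij}$ is the fixed point of the IsoRank-style diffusion
recurrence

$$ S_{ij} \leftarrow \alpha\, \hat{A}_i^\top S_{ij} \hat{A}_j
   + (1-\alpha)\, R_{ij}, $$

iterated from the rectangular identity until the Frobenius norm of the
change drops below a tolerance. The entry $R_{ij}[k,l]$ is the
$-\log$-transformed BLAST e-value between proteins $k$ and $l$, zeroed
above an e-value cutoff of $10^{-3}$ and scaled into $[0,1]$. The mixing
weight $\alpha \in [0,1)$ sets how much similarity flows through network
neighborhoods rather than direct homology. The same computation with
$i = j$ yields the intra-species block $S_{ii}$, a homology-regularized
diffusion of the species' own network.

All blocks are assembled into one symmetric $N \times N$ matrix $S$ over
the concatenated proteomes ($S_{ji} = S_{ij}^\top$ by construction). Row
$k$ of $S$ is the feature vector of protein $k$: its similarity to every
protein of every species.

Because $\alpha < 1$ makes the update an affine contraction, the fixed
point exists, is unique, and does not depend on the starting matrix; the
iteration residual decays like $\alpha^t$. The test suite verifies the
iterate against an independent Kronecker-product linear solve
$\mathrm{vec}(S) = (1-\alpha)\,(I - \alpha\, \hat{A}_j^\top \otimes
\hat{A}_i^\top)^{-1} \mathrm{vec}(R)$ on small fixtures.

### Numerical choices

* **Convergence**: Frobenius norm, tolerance $10^{-6}$, at most 50
  iterations (non-convergence is flagged on the result object).
* **Homology scaling**: natural log (any base cancels after scaling);
  e-values of exactly 0 are floored at $\varepsilon = 10^{-180}$, and one
  global constant $-\ln \varepsilon$ scales every species pair, so
  homology strength is comparable across blocks of $S$. Per-pair max
  scaling would make blocks incommensurable.
* **BLAST asymmetry**: per unordered protein pair the stronger (smaller)
  e-value of the two search directions is used, which makes
  $R_{ji} = R_{ij}^\top$ exact; multiple HSPs collapse to the minimum
  e-value and maximum percent identity.
* **Zero-degree proteins**: all-zero adjacency rows stay zero under row
  normalization (no teleportation). Such proteins receive similarity only
  through the $(1-\alpha)R$ term, which is the intended semantics for
  network-isolated proteins.
* **Symmetrization order**: STRING edge scores are max-symmetrized before
  normalization.

## The classifier

A maxout network maps each row of $S$ to $c$ per-term scores. A maxout
layer computes $h_i(x) = \max_{j \in 1..k} (x^\top W_{:,i,j} + b_{ij})$ —
the element-wise maximum over $k$ learned affine maps — so the activation
function itself is learned; $k = 1$ recovers a plain affine layer and the
unit never "dies" the way a ReLU can. Each maxout layer is followed by
batch normalization and (optionally) dropout; a final affine layer with a
logistic output gives scores in $(0,1)$.

Training minimizes mean binary cross-entropy over all (protein, term)
entries with AdaGrad. After every epoch the micro-averaged AUPR on a
held-out 20% of the training proteins is computed; training stops when it
has not improved for `patience` consecutive epochs, and the best epoch's
parameters are restored. The loss and the output activation are this
package's choices (they are the standard multi-label pairing and match
the score-in-$(0,1)$ contract); the early-stopping metric is micro AUPR
because it is stable on small validation splits. All randomness —
initialization (uniform fan-in), the validation split, shuffling, dropout
masks — derives from one seed, making training bit-reproducible on a
single machine.

Three presets are provided. `preset_bacteria()` and `preset_eukaryote()`
are the published STRING-scale architectures (hidden dims
[500, 800, 800], 3 or 4 maxout pieces, dropout 0.2, batch normalization,
AdaGrad at 0.01, batch 16/32, at most 100/300 epochs, patience 30).
`preset_compact()` (one hidden layer of 128 units, $k = 3$, no dropout,
learning rate 0.1, batch 16, at most 300 epochs, patience 30) is sized
for the few-hundred-protein fixtures of the synthetic generator: with
only one or two positives per term in ~100 training rows, smaller
networks under-fit the rarest terms, and dropout mainly slows their
convergence at this scale, where early stopping already supplies the
regularization. The preset was selected by the worst-case left-one-out
macro AUPR across six independent generator seeds, not any single
fixture.

## Leave-one-species-out imputation

When the target organism has no PPI network, its similarity profile is
built in four steps:

1. For every species $i$ with a network, run the diffusion with the
   identity matrix standing in for the missing network:
   $S_{i,\text{test}} \leftarrow \alpha \hat{A}_i^\top S_{i,\text{test}}
   + (1-\alpha) R_{i,\text{test}}$.
2. Project each cross block onto the test side:
   $S_{i,\text{test}}^\top S_{i,\text{test}}$ connects test proteins
   through shared neighbors in species $i$ (a one-mode projection).
3. Average the projections element-wise over contributing species to get
   the proxy network $\hat{A}_\text{test}$, and zero its diagonal
   (self-similarity is not an interaction; a flag retains it for
   sensitivity checks).
4. Run the intra-species diffusion of $\hat{A}_\text{test}$ with itself,
   combined with the organism's own self-BLAST homology, to obtain
   $S_{\text{test},\text{test}}$.

The training species' mutual blocks are unchanged, and the test blocks
occupy the left-out species' rows and columns of the global layout, so
training and test rows live in the same column space. Because the proxy
network is a mean of Gram matrices, its scale is quadratic in the cross
blocks; the diffusion row-normalizes its inputs, so this scale only
affects the zero/nonzero row pattern. `run_loso()` additionally
max-normalizes every feature row by default — the imputed blocks'
magnitudes differ systematically from measured ones, and per-row scaling
removes that nuisance before training.

## Evaluation

Five measures are computed by `metric_report()`:

* **macro / micro AUPR** — per-term AUPR averaged over terms with at
  least one positive (terms without positives are excluded and counted),
  and AUPR of the flattened matrices. AUPR uses the non-interpolated
  step-curve estimator with tied scores treated as one threshold.
* **top-3 F1** — each protein's three highest-scoring terms are called
  positive (ties broken toward the lower term index for reproducibility)
  and the geometric mean $\sqrt{P \cdot R}$ of micro precision and recall
  is reported. The geometric form is kept as published even though the
  name suggests the harmonic mean.
* **subset accuracy** — the fraction of proteins whose terms thresholded
  at 0.5 match the true set exactly.
* **F-max** — the CAFA protein-centric measure: over a threshold grid of
  0.01, precision averaged over proteins with at least one prediction
  (a flag switches to all-protein averaging), recall averaged over
  proteins with at least one true term, maximizing
  $2 \cdot pr \cdot rc / (pr + rc)$. A score of exactly 0 never counts
  as a prediction — zero encodes "no prediction", which keeps the
  $\tau = 0$ grid point from trivially calling the whole ontology.

Every metric is checked against an independently written brute-force
implementation on random fixtures at $10^{-10}$ tolerance.

Training labels use annotations of **any** evidence code (including the
electronic IEA), while evaluation labels are restricted to the
experimental-style codes EXP, IDA, IPI, IMP, IGI, IEP, TAS and IC, as in
CAFA; evaluation positives are therefore a subset of training positives.
Cross-validation holds out 20% of the target species' retained proteins,
five times; the paper-style ablations (`subsampled`,
`single_annotations`, `single_species`) reduce the
training rows and/or feature columns to disentangle sample-size effects
from feature effects.

### Term filtering

A GO term is kept when, in at least one species, between 0.5% and 5%
(inclusive at both ends; the bounds are configurable) of that species'
indexed proteins carry it — counting every evidence code. The denominator
is the species' protein count in the PPI-file namespace. Terms kept for
one species are kept globally: columns are shared across species, and a
union is the only reading consistent with a single multi-species label
matrix. Filtering is done once, globally, not per cross-validation fold
(per-organism term counts are fixed quantities of a dataset). Proteins
left with no kept-term annotation are masked out of training and
evaluation. Rare terms below the window are statistically untrainable;
frequent terms above it are shallow ontology ancestors whose inclusion
would mostly measure the GO hierarchy, which this package deliberately
does not propagate (no OBO parsing — the window stands in for hierarchy
control).

## The synthetic generator

`simulate_multispecies()` produces complete input sets — STRING-style
edge lists, 12-column BLAST tables, annotation tables — from a known
ground truth, so every stage is testable offline:

* An **ancestral planted-partition graph** over functional modules
  (within-module edge probability 0.3, between 0.03 by default): the
  premise being tested is precisely that function tracks network modules
  conserved across species, so a generator without module structure could
  not exercise the method's value-add.
* Each species is a noisy copy: a configurable fraction of nodes is
  inherited (the rest are lineage-specific, randomly attached), and a
  configurable fraction of inherited edges is rewired.
* **BLAST tables** concentrate strong hits on ortholog pairs (e-value
  exponents uniform in 50–180 decades), include self-hits at e-value 0,
  and add spurious pairs above the $10^{-3}$ cutoff; percent identity is
  anti-correlated with the e-value exponent so the homology matrices and
  the identity-based BLAST baseline share one fixture.
* **Annotations** attach terms to modules; each term's positives are a
  small fixed set of ancestral nodes sized into the 0.5–5% frequency
  window, inherited by orthologs with probability `annotation_density`
  and tagged IEA with probability `iea_fraction`. Positives are tiled
  across each module so that, at the defaults, most of each proteome
  carries at least one kept term — mirroring real post-filter coverage.

What the generator does **not** emulate: realistic sequence evolution (no
FASTA sequences are produced), degree heterogeneity and hub structure of
real PPI networks, the GO hierarchy's term–term dependence, and
annotation biases that correlate with node degree. Passing tests
therefore demonstrate correctness of the machinery and the expected
qualitative behavior of the method — not performance on real proteomes.

`degrade()` removes information along one axis (cross-species homology,
network edges, annotation records) to support directional experiments:
removing all cross-species homology must collapse left-out-species
predictions to the chance floor, and increasing degradation must
monotonically hurt the BLAST-transfer baseline.

## Problem sizes and defaults

The packaged experiments use 3 species of 50 proteins with 5 modules and
35 terms per branch — large enough that chance-level macro AUPR is close
to term prevalence, small enough that a full pipeline run takes seconds.
$\alpha$ defaults to 0.6 (the share of similarity drawn through network
structure; the published experiments selected $\alpha$ per dataset by
grid search, and the value is exposed per run). The e-value cutoff
($10^{-3}$), floor ($10^{-180}$), frequency window and all seeds are
configurable through the function arguments and the CLI.

## Known limitations

* Dense matrix algebra throughout: fine for $N$ in the low tens of
  thousands, not for the millions of proteins of a full STRING download.
* The hierarchical store is a plain directory of TSVs plus a JSON
  manifest with stable dataset names (`isorank/<i>_<j>`, `block_S`,
  `labels/<branch>`), not an HDF5 container.
* One model per GO branch; no cross-branch parameter sharing.
* No GO-hierarchy propagation; the frequency window is the only
  hierarchy mitigation.
* The BLAST baseline consumes tabular BLAST output; the package never
  runs BLAST itself.
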