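---
title: "Functional representations from PPI networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional representations from PPI networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Interacting proteins tend to share biological roles — the
guilt-by-association premise behind every network-based function
predictor. `string2go` turns a weighted protein–protein interaction
(PPI) network plus a set of experimentally supported Gene Ontology (GO)
biological-process annotations into calibrated per-term predictions, in
three stages:

1. **Network embedding.** Each protein becomes a dense vector that
   summarizes its position in the network.
2. **Supervised representation learning.** A deep maxout neural network
   is trained to map embeddings to the full multi-label vector of GO
   term annotations; the activations of its third hidden layer are kept
   as a *functional representation* that encodes both the interaction
   geometry and the co-annotation structure of the terms.
3. **Per-term classification.** One RBF-kernel SVM per vocabulary term,
   with Platt-scaled posteriors, scores every protein; alternatively the
   network's own sigmoid outputs serve as the prediction head.

# Stage 1 — network embeddings

## Diffusion states and truncated SVD (Mashup-style)

For node $i$, the diffusion state $s_i$ is the stationary distribution
of a random walk with restart:

$$ s_i = r\,e_i + (1 - r)\,P^{\top} s_i, $$

with $P$ the row-normalized weighted adjacency matrix and restart
probability $r$ (default $0.5$). Networks of up to 2000 nodes are
solved exactly as the linear system $s_i = r (I - (1-r)P^\top)^{-1}
e_i$; larger ones by power iteration to an $L_1$ tolerance of $10^{-8}$
(the two agree to $10^{-6}$ on random graphs, and the tolerance-based
stopping rule is this package's choice). Isolated nodes keep all restart
mass at home ($s_i = e_i$), the limit of the defining equation.
Disconnected graphs are embedded jointly with no per-component
renormalization — the restart term makes each component's rows proper
distributions on its own.

The embedding is $U_d\sqrt{\Sigma_d}$ from the truncated SVD of the
diffusion-state matrix, so inner products approximate the diffusion
Gram matrix (Eckart–Young). The genome-scale recommendation is $d =
800$; on desk-scale fixtures $d$ is clamped to the node count. An
optional $\log(s + 1/n)$ transform of the diffusion states is provided
but off by default: the diffusion-state description is taken at face
value rather than inheriting the multinomial-logistic formulation of
the original Mashup.

## Second-order walks and skip-gram (node2vec-style)

Truncated random walks of length 10 sample each node's neighborhood.
Steps are second-order: from node $v$, having arrived from $t$, the
unnormalized probability of moving to neighbor $x$ is the edge weight
$w(v,x)$ times $1/p$ if $x = t$, $1$ if $x$ is adjacent to $t$, and
$1/q$ otherwise. The in-out parameter defaults to $q = 2$, biasing
walks toward the previous node's neighborhood (close neighbors); the
return parameter is unspecified in the protocol this package follows
and defaults to $p = 1$. Walks use the STRING confidence weights as-is
rather than binarized edges. Walks per node (10), window (5), negative
samples (5) and epochs (5) are standard skip-gram defaults, all
configurable and recorded.

The skip-gram trainer (negative sampling, unigram$^{3/4}$ proposal,
linearly decaying learning rate) is single-threaded and driven by R's
RNG, so a seed fully determines the result.

# Stage 2 — the deep maxout network

The architecture is fixed: three hidden blocks, each computing
batch-normalization of its inputs, $k = 3$ parallel affine maps
combined by an elementwise maximum (maxout), then dropout (rate 0.5
during training); a sigmoid output layer one neuron per vocabulary
term. Training minimizes binary cross-entropy summed over terms and
averaged over proteins — the loss is this package's choice, the
standard pairing with a sigmoid multi-label output — with AdaGrad
(learning rate 0.05), minibatches of 100, 150 epochs, Glorot-uniform
initialization.

The functional representation is the post-maxout activation of hidden
block 3 in inference mode: dropout off, batch-norm using running
statistics (momentum 0.9). Inference mode makes extraction
deterministic — identical inputs always yield identical rows — and the
extraction never consults the labels.

All three hidden layers share one width. The reference protocol tunes
it over $\{300, 500, 700, 1000\}$ (an input-matched width is also
admissible) by $k$-fold cross-validation: per candidate, the pooled
out-of-fold sigmoid predictions are thresholded at 0.5 — the threshold
is unstated in the protocol and 0.5 is this package's documented
choice — scored by per-term F1, and summarized by the median over
terms rounded to two decimals; the smallest width attaining the
maximum rounded median wins (the curse-of-dimensionality tie-break).

# Stage 3 — per-term SVMs

For term $t$, positives are the training proteins annotated with $t$
*or any is_a descendant of $t$*; negatives are all remaining training
proteins. Features are standardized (centered, unit variance) over the
training set — RBF kernels need comparable feature scales, and the
scaling is stored with each classifier. The $(C, \gamma)$ grid
(defaults $C \in 2^{-5..9}$, $\gamma \in 2^{-11..3}$, log-spaced) is
searched by stratified $k$-fold cross-validated mean F1; ties break
toward smaller $C$, then smaller $\gamma$ (the simpler model). Platt
scaling is fitted on the *out-of-fold* decision values — calibrating on
resubstitution values would be optimistic — using Platt's
prior-smoothed targets, and the final machine is refitted on all
training data. Terms with fewer positives than folds reduce the fold
count (minimum 2, with a warning); terms with no positives are skipped
and score zero.

## Baselines

*Naive*: every protein receives each term's training-set frequency —
the database prior, constant across proteins. *PPI-homolog*: the
homolog set $H(p)$ collects annotated training proteins homologous (at
an E-value threshold) to any PPI partner of $p$; the score for $t$ is
the fraction of $H(p)$ annotated with $t$. The original PPI-homolog
method's exact vote weighting is not documented in the protocol this
package follows; the plain fraction-of-homologs score is used, and the
homology relation comes from a precomputed hit table (BLAST tabular
format) behind a small oracle interface — running the alignment is out
of scope.

# Evaluation

Term-centric: per-term F1 and MCC at decision threshold 0.5 on the
posteriors (the conversion threshold is unstated in the protocol;
0.5 is the documented choice here), plus step-interpolated AUPRC.
Zero denominators yield 0 for precision/recall/F1/MCC, so a degenerate
always-negative classifier scores 0; AUPRC without positives is NA and
such terms are excluded from medians with a warning. Reported medians
are *lower* medians (an element of the vector), matching the
two-decimal rounding granularity of the selection protocol.

Protein-centric: for threshold $\tau$,

$$ \overline{Pr}_\tau = \frac{1}{m_\tau}\sum_{s:\,|\hat T_s(\tau)|>0}
   \frac{|\hat T_s(\tau) \cap T_s|}{|\hat T_s(\tau)|}, \qquad
   \overline{Rc}_\tau = \frac{1}{n}\sum_{s}
   \frac{|\hat T_s(\tau) \cap T_s|}{|T_s|}, $$

precision averaged over the $m_\tau$ proteins with a nonempty
predicted set, recall over all $n$ proteins. $F_{max}$ maximizes the
harmonic mean over the grid $\tau = 0.01, \dots, 1.00$ (step 0.01, the
CAFA convention); $\tau^*$ is the *largest* maximizing threshold (the
most conservative prediction set). $F_\tau$ evaluates the same formula
at a fixed carried-over threshold, e.g. the hold-out $\tau^*$ applied
to a temporal validation set, and equals $F_{max}$ when evaluated at
$\tau^*$ on the same data.

Method comparisons use per-term paired tests: Wilcoxon signed-rank for
two methods (zero differences dropped; the exact two-sided distribution
is computed for up to 25 nonzero differences by enumerating sign
assignments over midranks, which stays exact under ties; the normal
approximation beyond), and the Friedman test with Holm-corrected
pairwise comparisons for more. The centroid-distance analysis min-max
standardizes each representation dimension to $[0,1]$, measures the
Euclidean distance between a term's positive and negative centroids,
and correlates distances with per-term F1 — a lens on *why* a
representation predicts well.

# Splits

Hold-out: a seeded uniform sample of the well-annotated proteins (at
least a configurable number of annotated terms); the rest are the
training pool. Temporal validation: proteins with no vocabulary
annotation at the training snapshot that gained one in a later
snapshot. Homolog-removal: evaluation proteins with any training
homolog at E-value $\le$ threshold are dropped; sweeping the threshold
upward ($10^{-5} \to 10^{-2}$) widens the homology definition, so the
filtered set shrinks monotonically.

# The synthetic testbed

`synthetic_spec()` defines the study conditions: 300 proteins in 3
equal communities, planted-partition edges ($p_{in} = 0.3$,
$p_{out} = 0.02$), edge weights jittered (sd 0.05) around 0.8 within
and 0.3 between communities, a toy ontology with one root and
3 leaf terms per community at depth 2, and annotations sampled with
true-positive rate 0.9 for a community's own leaves and background rate
0.05 for foreign leaves. The jitter centers, term counts and DAG depth
are this package's one-time choices of a realistic desk-scale regime:
confident within-module STRING edges, noisier cross-module ones, and a
vocabulary small enough to train in seconds. A planted-partition graph
rather than a degree-corrected block model is the simplest structure
expressing guilt-by-association. Homology is simulated directly as a
hit table (E-values log-uniform in $[10^{-10}, 10^{-1}]$) because only
the oracle interface is consumed downstream — no sequences exist.

What the testbed does *not* emulate: heavy-tailed PPI degree
distributions, hub proteins, the real GO DAG's breadth and depth,
annotation incompleteness correlated with study bias, or
inter-ontology structure. Passing tests on it demonstrate that the
machinery recovers planted guilt-by-association signal, not that
genome-scale accuracy figures transfer.

## Desk-scale protocol and problem sizes

The packaged study (tests and `scripts/acceptance.R`) uses the default
generator, a hold-out of 60 proteins, node2vec embeddings at $d = 32$,
a maxout width of 64, and a reduced SVM grid ($C \in 2^{-1..7}$,
$\gamma \in 2^{-7..1}$, steps of $2^2$) with 5-fold selection — sizes
chosen so the whole study trains in about a minute while every stage
still runs at full fidelity (150 epochs, full calibration).

Two methodological notes on the headline property — that SVMs on the
learned functional representation match or beat SVMs on the raw
embedding, and both beat the Naive prior:

* The representation-vs-raw comparison is made on the *training-stage*
  cross-validated median F1, the same quantity the grid search
  maximizes and the quantity the reference protocol reports when
  comparing representations at the classifier-training stage. On the
  desk-scale fixture the hold-out medians of both heads saturate at
  the ceiling imposed by the annotation noise (tpr 0.9 / fpr 0.05) —
  at that ceiling the hold-out difference is a single misranked
  protein and carries no information about the representations.
* The baseline comparison (both heads beat Naive) is made on hold-out
  median F1 and $F_{max}$, where the Naive prior's constant scores
  leave it far behind.

# Numerical choices and degenerate inputs

* Sigmoid outputs are clipped to $[10^{-12}, 1-10^{-12}]$ inside the
  loss; non-finite loss aborts training with the epoch named.
* Batch-norm uses $\epsilon = 10^{-5}$; a one-piece maxout block with
  dropout 0 and identity batch-norm statistics is exactly affine,
  which the tests exploit.
* SVD sign ambiguity is fixed by making each component's
  largest-magnitude loading positive, so embeddings reproduce across
  platforms.
* Duplicate network edges collapse to the maximum weight (symmetric
  and idempotent); self-loops are dropped and counted. Scores are
  divided by 1000 (configurable) because STRING confidences are
  integers on that scale and the walk only needs relative weights.
* Vocabulary selection interprets "deepest terms" as the candidate-set
  antichain: a candidate survives iff no other candidate is its strict
  is_a descendant. Note that raising the frequency threshold can
  *add* a vocabulary term (removing a deep candidate un-shadows its
  ancestor); the suite tests the faithful weaker property.
* Unknown or retired term identifiers in annotation input are dropped
  with a warning, not fatal — release skew between ontology and
  annotation files is normal.
* The STRING confidence cutoff before embedding defaults to "no
  cutoff" (an optional `min_score` is available): the diffusion and
  walk machinery already weight edges by confidence.
* Term counts for the vocabulary are taken over the full propagated
  annotation set, before any training-set restriction.

# Known limitations

* The DMNN trains on CPU in plain R; genome-scale corpora (5000+
  proteins, 200+ terms, 800-dim inputs) are out of reach at tolerable
  runtimes — the package targets method development and desk-scale
  validation.
* Hierarchical consistency of predicted scores across the DAG is not
  enforced (no true-path post-processing of posteriors).
* Only is_a edges propagate; part_of/regulates semantics are ignored
  by design.
* The PPI-homolog baseline is a plain homolog-vote fraction; E-value
  weighting variants are not reproduced.
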