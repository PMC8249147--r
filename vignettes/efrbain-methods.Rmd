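---
title: "Fuzzy radial basis adaptive inference networks for multichannel signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy radial basis adaptive inference networks for multichannel signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frbain)
```

## The problem

Clinical time-series classification problems — the motivating case is
distinguishing cardiac arrhythmias from multi-lead ECG heartbeats — often
come with three compounding difficulties: the records are multichannel and
unevenly stretched in time, the labeled sample sets are small, and the class
frequencies are strongly imbalanced. End-to-end deep models have too many
free parameters for such data. The model implemented here takes the opposite
route: it embeds *prior feature knowledge* — actual prototype records,
chosen by clustering — into a small fuzzy inference network whose structure
is completely determined by the data, and learns only a handful of
parameters on top.

## The model

A record is a matrix $X \in \mathbb{R}^{T \times n}$ (timepoints by
channels); records may differ in $T$ but share $n$. The pipeline has two
stages.

**Stage 1 — prototype selection.** Similarity between records is measured by
multivariate dynamic time warping (DTW): the minimum cumulative Euclidean
frame distance over monotone alignment paths with steps
$\{(1,0),(0,1),(1,1)\}$, which makes the metric insensitive to local
stretching of the time axis. Within each of the $K$ pattern classes, the
class's records are clustered on their DTW distance matrix with relational
*fuzzy c-medoids*: memberships follow the standard inverse-distance update
$u_{ij} \propto d(i,j)^{-2/(m-1)}$, medoids minimize the fuzzily weighted
distance sum, and (because alternating optimization alone stalls in
swap-improvable optima on small matrices) the converged solution is refined
by single-medoid swaps while the objective improves. The number of
subclasses $m_k$ per class is chosen by scanning a range of cluster counts
and minimizing the validity index

$$GD(c) = \alpha\, C_d(c) + (1-\alpha)\, \frac{1}{S_d(c)},$$

where the coupling degree $C_d$ is the fuzzily weighted mean distance to the
medoids (compactness) and the separation degree $S_d$ is the minimum
inter-medoid distance. The winning medoids — real records, never synthetic
averages — become the *kernel bank* $Z_{kl}$, ordered class-major.

**Stage 2 — the network.** For an input $X$ the layers are:

1. *FRBN fuzzification*: node $j$ outputs
   $\mu_j = \mathrm{clamp}\!\left(\frac{1}{1+\exp(d_j^2/\sigma_j^2 - a_j)} - c_j,\ 0,\ 1\right)$,
   a decreasing sigmoid of the squared DTW distance $d_j$ from $X$ to kernel
   center $j$; $\sigma_j$ is a smoothing scale in distance units, $a_j$ sets
   the membership at $d=0$, and the offset $c_j \in [0,1)$ suppresses weak
   matches.
2. *Regularization I*: the $m$ memberships are normalized jointly onto the
   simplex. An all-zero membership vector means the record matches no kernel
   and is reported as unclassifiable rather than silently assigned.
3. *Pattern layer*: per-class pooling $q_k = \sum_{j \in \Omega_k} h_j$
   (sum mode conserves total mass; max pooling is available).
4. *Rule layer*: all $L = K^K$ ordered $K$-tuples over the $K$ pattern
   memberships, combined with the product t-norm (min t-norm available).
   Under sum pooling $\sum_t z_t = (\sum_k q_k)^K = 1$, so mass is conserved
   end to end.
5. *Regularization II* and the *T-S classifier head*: the normalized rule
   activations pass through an affine map to $K$ class scores and a softmax.
   The paper-level formulation emits a single scalar; a multiclass decision
   needs $K$ calibrated outputs, so the head here is softmax with
   cross-entropy — recorded as an interpretation.

Only $\{\sigma, a, c, W, r\}$ are trained; the kernel centers are frozen, so
all sample-to-center DTW distances are computed once before training and
each epoch runs on the closed-form layer chain.

## Training

The default regime: initial learning rate 0.5 multiplied by 0.1 every 50
epochs (0.5 / 0.05 / 0.005 at epochs 0 / 50 / 100), at most 500 epochs,
early stop when the epoch mean cross-entropy falls below 0.005, stochastic
batches of roughly 54 records (`batch_count = NULL` derives the count from
the dataset size).

Two numerical choices deserve explanation:

* **Membership-mass barrier.** The classification loss only ever sees
  *normalized* memberships, so it is exactly flat along a joint shrinkage of
  all memberships: gradient descent happily raises every offset $c_j$ until
  entire node groups clamp to zero, after which their gradient is zero
  forever and the layer is dead. The training objective therefore adds a
  log-barrier $-\lambda\, \overline{\log \sum_j \mu_j}$ with
  $\lambda = 0.01$ (`barrier` in `train_control()`), which pins the flat
  direction and pushes back exactly when the layer approaches collapse.
  Early stopping monitors the cross-entropy alone.
* **Optimizer.** Plain stochastic gradient descent is the default. Adam is
  available (`optimizer = "adam"`), but with a learning rate of 0.5 its
  sign-normalized steps are as large as the entire admissible range of the
  bounded offsets $c_j \in [0,1)$; in experiments on the synthetic
  generator it repeatedly threw whole node groups across the clamp boundary
  into the dead region, collapsing the network to a one-class predictor.
  Magnitude-proportional gradient steps are stable under the same printed
  schedule and reach perfect held-out accuracy on every seed tried.

During training, a sample whose memberships are all zero at the current
parameters carries no usable gradient; it is dropped from the batch update
and charged the uniform loss $\ln K$ so early stopping cannot trigger while
records are unclassifiable. At prediction time such records are flagged
(`NA` label, `degenerate` column in the CLI output).

Gradients of the full objective with respect to all five parameter groups
are computed analytically (vectorized backpropagation through the layer
chain) and are verified against central finite differences in the test
suite. No gradient flows through DTW itself.

## Parameter defaults and their rationale

| Parameter | Default | Meaning |
|---|---|---|
| `fuzzifier` | 2 | standard fuzzy-clustering exponent |
| `alpha` | 0.5 | equal weight of compactness and separation in $GD(c)$ |
| `c_range` | (2, 5) | scanned subclass counts per class |
| `restarts` | 5 | seeded clustering restarts per count |
| `sigma` init | half the median center-to-center DTW distance | see below |
| `a` init / `c` init | 1 / 0 | membership $\approx 0.73$ at the kernel center |
| `barrier` | 0.01 | membership-mass log-barrier weight |

Two interpretation points. First, the validity index mixes a distance
($C_d$) with a reciprocal distance ($1/S_d$), so its balance depends on the
measurement units; `select_cluster_count()` computes the score table on the
distance matrix divided by its mean off-diagonal entry, making the two terms
commensurate for any input scale (the partitions themselves are
scale-invariant). Second, the kernel width: initializing $\sigma_j$ at the
full median distance to the other centers makes every membership nearly
equal (the sigmoid sees $d^2/\sigma^2 \approx 1$ for all inputs) and the
network starts uninformative; half that median places same-subclass records
on the responsive part of the sigmoid while keeping other-class records in
the tail, and trained accuracy confirms the choice.

## The synthetic generator

`generator_spec()` / `generate_dataset()` emulate the structure of a small,
imbalanced multichannel dataset: $K$ classes, $m_k$ subclass templates per
class (smooth random-phase sinusoid mixtures with class-specific envelopes,
baselines and per-template fundamentals), per-record random monotone time
warping applied identically across channels (physiological channels share a
time base), additive Gaussian noise, and exact largest-remainder class
counts from the requested proportions. Template draws are accepted only if
every inter-template DTW distance is at least `template_separation` times
the largest template-to-perturbed-record distance at the spec's own
warp/noise level; retries widen the frequency and baseline spacing, and the
generator fails loudly if separation cannot be met.

Defaults (`K = 3`, two subclasses per class, 3 channels, 60 timepoints,
`warp_strength = 0.15`, `noise_sd = 0.1` on unit-scale templates, uniform
proportions, 300 records) describe a modest, clearly structured recovery
problem: the bank should find the planted subclass counts and a trained
model should classify held-out records nearly perfectly. What passing these
tests shows is that the pipeline is *internally correct* — it recovers
structure its own generative assumptions plant. It does not show clinical
performance: real ECG morphology, baseline wander, inter-patient
variability and label noise are all outside the generator's scope.

## Numerical and degenerate-input choices

* DTW backtracking prefers the diagonal step on ties, so returned paths are
  deterministic; the distance itself is tie-independent. A Sakoe–Chiba band
  and path-length normalization are available but off by default.
* Zero DTW distance to a medoid triggers the standard crisp-assignment rule
  in the membership update.
* Duplicate medoids (possible on degenerate distance matrices) make the
  separation degree zero; such counts score $GD = \infty$ and are skipped
  with a warning.
* Cluster-count ties break toward the smaller count; argmax ties at
  prediction break toward the earlier class in the class order.
* Classes too small to cluster contribute a single medoid (or their lone
  record) with a warning.
* $K^K$ rules are capped (default $10^6$, i.e. $K \le 7$) with an
  instructive error beyond the cap.

## Problem sizes in the test suite

The suite and the acceptance script run entirely on generated data: the DTW
oracle sweep covers all 66,066 unordered pairs of ternary sequences up to
length 5; clustering is checked against exhaustive medoid search for up to 8
samples; recovery runs use 60–300 records of length ~60. These sizes were
chosen so the full pipeline exercises every code path in well under a
minute per component on one CPU.

## Known limitations

* Pairwise DTW is $O(N^2 T^2)$; the design targets small-sample problems
  (hundreds, not tens of thousands, of records).
* The $K^K$ rule layer restricts the architecture to single-digit class
  counts.
* The validity index can prefer merging over splitting when clusters lie on
  a near-collinear chain in DTW space (the minimum-separation term drops
  when an intermediate cluster is recognized); well-spread subclasses are
  recovered reliably.
* Records far from every kernel center are unclassifiable by construction;
  this is surfaced, not hidden, and is the intended behavior of a
  prototype-based model.
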