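# frbain

Classification of multichannel time-varying signals with **fuzzy radial
basis adaptive inference networks**. The intended setting is small,
imbalanced labeled collections of physiological records — e.g. multi-lead
ECG heartbeats spanning a handful of arrhythmia classes — where end-to-end
deep models overfit and where stretch and drift along the time axis defeat
lockstep distance measures.

## The method

For records $X \in \mathbb{R}^{T\times n}$ (timepoints × channels, lengths
may differ), the pipeline is:

1. **DTW similarity.** Multivariate dynamic time warping
   $D(X,Y)=\min_{\phi}\sum_t d\big(X(t),\,Y(\phi(t))\big)$ with Euclidean
   frame distance and steps $\{(1,0),(0,1),(1,1)\}$ — insensitive to local
   contraction/expansion of the time axis.
2. **Prototype selection.** Per class, relational fuzzy c-medoids over the
   DTW distance matrix splits the class into subclasses; the number of
   subclasses is picked by minimizing the validity index
   $GD(c)=\alpha C_d(c) + (1-\alpha)/S_d(c)$ (coupling = fuzzily weighted
   mean distance to medoids, separation = minimum inter-medoid distance).
   The medoids — actual records — become the model's kernel bank
   $Z_{kl}$, the mechanism of prior-knowledge embedding.
3. **The network.** Each fuzzy radial basis neuron outputs
   $\mu_j=\mathrm{clamp}\big(1/(1+e^{d_j^2/\sigma_j^2-a_j})-c_j,\,0,\,1\big)$
   for the DTW distance $d_j$ to its kernel center; memberships are
   normalized, pooled per class (sum rule), combined over all $K^K$ ordered
   tuples with a product t-norm, normalized again and fed to a
   Takagi–Sugeno head (affine map + softmax over the $K$ classes).
4. **Training.** Only $\{\sigma, a, c, W, r\}$ are learned (stochastic
   gradient descent on cross-entropy plus a small membership-mass barrier;
   learning rate 0.5 decayed ×0.1 every 50 epochs, early stop at loss
   0.005). Kernel centers are frozen, so all DTW distances are precomputed
   once.

A seeded synthetic generator (`generator_spec()` / `generate_dataset()`)
produces class/subclass-structured multichannel datasets with random time
warping, additive noise and exact class imbalance, and is the test substrate
for the whole pipeline. See the methods vignette
(`vignettes/efrbain-methods.Rmd`) for the model's assumptions, parameter
rationale and limitations.

## Worked example

```r
library(frbain)
set.seed(42)

# 300 records, 3 classes x 2 subclass templates, warped and noisy
gen <- generate_dataset(generator_spec(K = 3, n_total = 300, seed = 42))
test_idx <- sample.int(300, 90)
train_ds <- dataset_subset(gen$dataset, setdiff(1:300, test_idx))
test_ds  <- dataset_subset(gen$dataset, test_idx)

fit <- efrbain(train_ds, seed = 42)   # cluster -> assemble -> train
print(fit)
#> Extended fuzzy radial basis adaptive inference network
#>
#> Call: efrbain(x = train_ds, seed = 42)
#>
#> Structure: 6 kernel centers (subclasses 2+2+2), 3 classes, 27 rules
#> Training: 500 epochs, final loss 0.01927 (max_epochs)
#> Training accuracy: 1.0000

evaluate_model(fit$model, test_ds)
#> Confusion matrix (truth in rows):
#>      predicted
#> truth C1 C2 C3
#>    C1 28  0  0
#>    C2  0 28  0
#>    C3  0  0 34
#>  class support precision recall f1
#>     C1      28         1      1  1
#>     C2      28         1      1  1
#>     C3      34         1      1  1
#> macro P/R/F1: 1.0000 / 1.0000 / 1.0000   accuracy: 1.0000
```

The printed structure is the model's defining property: the clustering
found the two planted subclasses in each class (6 kernel centers), the
pattern layer has one node per class, and the rule layer enumerates
$3^3 = 27$ product rules. `predict(fit, newdata)` returns labels,
`type = "prob"` class probabilities, and `type = "full"` every intermediate
layer (memberships, pattern pooling, rule activations) per record.

A command-line interface covering the same pipeline
(`simulate | dtw | cluster | train | predict | evaluate`) is installed at
`inst/scripts/frbain`; every subcommand takes explicit seeds and writes a
config echo beside its outputs.

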