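---
title: "Denoised graph-convolutional prediction of SM–miRNA associations: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoised graph-convolutional prediction of SM–miRNA associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smmagcn)
```

## The model

The package scores unobserved small molecule (SM)–miRNA pairs from a
binary association matrix $A \in \{0,1\}^{n_s \times n_m}$ (SMs on
rows) and two integrated similarity matrices: $SSM$ ($n_s \times n_s$)
for SMs and $SMR$ ($n_m \times n_m$) for miRNAs. Its premise is the
usual one in chemogenomic link prediction: similar molecules perturb
overlapping sets of miRNAs, and similar miRNAs respond to overlapping
sets of molecules, so a similarity-weighted graph lets the few known
associations propagate to their neighborhoods.

### Similarity integration

When several similarity sources per entity type are available, they
are combined as a weighted elementwise mean
$\sum_i w_i S_i / \sum_i w_i$ (`integrate_similarities()`), with equal
weights by default — absent a reason to prefer one source, each
contributes equally. `normalize_similarity()` then rescales entry
$(i,j)$ by $\sqrt{r_i c_j}$, the geometric mean of its row and column
sums. The elementwise form with the radical is chosen because it is
symmetric for symmetric input, invariant to a global rescaling of the
source similarities, and consistent with the $D^{-1/2} S D^{-1/2}$
degree normalization used on the graph blocks below; dividing by the
raw product $r_i c_j$ is available as `norm_style = "product"`.
Entries that are exactly zero stay zero, which makes all-zero
rows/columns safe.

### Low-rank denoising

Curated association sets contain both missing links and spurious ones.
The first stage separates structure from noise by low-rank
representation (LRR):

$$\min_{X,E} \; \lVert X\rVert_* + \alpha\,\lVert E\rVert_{2,1}
\quad\text{s.t.}\quad A = A X + E,$$

with the nuclear norm promoting a low-rank coefficient matrix $X$
($n_m \times n_m$ by default; `lrr_side = "sm"` transposes the
problem) and the column-wise L2,1 norm promoting column-sparse noise
$E$. The balance parameter defaults to $\alpha = 0.1$. The denoised
matrix is $A^* = A X^*$, kept real-valued so that downstream graph
edges carry graded weights.

`ialm_solve()` implements the inexact augmented Lagrange multiplier
(IALM) iteration with two multipliers and a growing penalty $\mu$:

1. $J \leftarrow \mathrm{SVT}_{1/\mu}(X + Y_2/\mu)$ — singular-value
   soft-thresholding, the proximal operator of the nuclear norm;
2. $X \leftarrow (I + A^\top A)^{-1}\big(A^\top A - A^\top E + J +
   (A^\top Y_1 - Y_2)/\mu\big)$ — the exact minimizer of the
   quadratic $X$-subproblem; $(I + A^\top A)$ is symmetric positive
   definite and its Cholesky factor is computed once and cached across
   iterations;
3. $E \leftarrow \mathrm{shrink}^{2,1}_{\alpha/\mu}(A - AX + Y_1/\mu)$
   — column-wise shrinkage, the proximal operator of the L2,1 norm;
4. multiplier updates $Y_1 \mathrel{+}= \mu(A - AX - E)$,
   $Y_2 \mathrel{+}= \mu(X - J)$; then
   $\mu \leftarrow \min(\rho\mu, \mu_{\max})$.

Defaults: $\mu_0 = 10^{-4}$, $\mu_{\max} = 10^{10}$, $\rho = 1.1$.
Iteration stops when both infinity-norm residuals
$\lVert A - AX - E\rVert_\infty$ and $\lVert X - J\rVert_\infty$ fall
below `tol = 1e-7`; a `max_iter = 500` cap guards against
non-convergence, which is reported as a flag plus warning rather than
an error, since a near-feasible iterate is still usable. IALM is not
monotone in the Lagrangian, so the package asserts final-iterate
feasibility, never per-iteration descent. Both proximal operators are
validated in the test suite against brute-force one-dimensional
numerical minimization oracles (per singular value for SVT, per
column for the L2,1 shrinkage), which are independent of the
closed-form expressions.

One behavior of LRR worth knowing: the all-noise point $X = 0$,
$E = A$ is always feasible at cost $\alpha \sum_j \lVert A_j\rVert_2$,
while explaining a rank-$r$ structure through $X$ costs at least $r$
nuclear-norm units. On very small or very sparse matrices the
all-noise branch can genuinely be the optimum, making $A^* = 0$. This
is correct optimization, not failure — but it means tiny toy inputs
need strong planted structure (or a larger $\alpha$) before the
denoiser preserves anything. The test fixtures are sized accordingly.

### Heterogeneous graph

`build_hetero_graph()` assembles, with the miRNA block leading,

$$G = \begin{bmatrix}\mu\,\widetilde{SMR} & A^{*\top}\\
A^* & \mu\,\widetilde{SSM}\end{bmatrix},\qquad
H^{(0)} = \begin{bmatrix}0 & A^{*\top}\\ A^* & 0\end{bmatrix},$$

where $\widetilde{S} = D^{-1/2} S D^{-1/2}$ is the symmetric degree
normalization of each similarity block and $\mu = 6$ (the
`graph_penalty`) tilts message passing toward within-type similarity
edges. The penalty multiplies the similarity blocks of the propagation
graph $G$ only; the unpenalized block adjacency is kept alongside as
`AH`. Zero-degree nodes receive all-zero normalized rows/columns (with
a warning) instead of NaNs. The initial embeddings carry only the
cross-type association blocks, so node representations start from the
(denoised) association profile.

### Layer-attention GCN

The encoder applies $L = 3$ layers of

$$H^{(l+1)} = \mathrm{ELU}\!\big(D^{-1/2} G D^{-1/2} H^{(l)} W^{(l)}\big),$$

with $W^{(0)} \in \mathbb{R}^{(n_m+n_s)\times k}$,
$W^{(l\ge1)} \in \mathbb{R}^{k\times k}$, $k = 64$. Because different
depths capture different neighborhood radii, the final embedding is a
learned combination of all layers,
$[H_m; H_s] = \sum_{l=1}^{L} a_l H^{(l)}$, with free scalar attention
coefficients initialized to $1/(l+1)$ — deeper layers start with less
weight — and no softmax constraint, so training can discover any
mixture. Layer 0 is excluded from the sum: it is the raw input, not an
encoded representation. The decoder is bilinear,
$A' = \mathrm{sigmoid}(H_m W' H_s^\top)$, whose output the package
clamps to $[10^{-12}, 1-10^{-12}]$ so scores are strictly inside
$(0,1)$ and cross-entropy terms stay finite.

### Training objective and optimization

The model family this package belongs to typically leaves the training
objective implicit; here it is stated explicitly as a design choice:
full-matrix binary cross-entropy between $A'$ and the *original*
binary $A$ (not $A^*$ — the denoised matrix shapes the graph, but the
ground truth supervises), with known associations up-weighted by the
negative/positive count ratio to counter class imbalance that in
curated data reaches several hundred to one. Plain unweighted BCE is
available (`loss = "bce"`). Optimization is Adam at the published
initial rate 0.00725 for 600 epochs; gradients are computed by exact
reverse-mode differentiation through the decoder, attention sum, and
convolution layers (verified against central finite differences during
development). Regularization uses two dropout rates, applied only
during training: `dropout_edge = 0.6` masks entries of the normalized
adjacency (one mask per forward pass), `dropout_feature = 0.4` masks
each layer's input features; both use inverted scaling so evaluation
needs no rescaling. The final score matrix always comes from a
dropout-free forward pass.

All stochastic elements — weight initialization (symmetric-uniform
fan-based), edge and feature dropout — derive from `seed` in
`run_config()`, so a rerun with the same configuration reproduces
$A'$ bit for bit. Cross-validation partitions use the separate
`cv_seed` and are drawn up-front, so scorer-internal randomness cannot
desynchronize fold assignments.

## Evaluation protocol

`rank_auc()` computes the area under the rank-threshold ROC: sweeping
a threshold over the pooled scores, the true positive rate is the
fraction of held-out (test) samples above it and the false positive
rate the fraction of candidate samples above it. This equals the
Mann–Whitney statistic with midranks, so ties contribute one half —
a scorer assigning a constant gets exactly 0.5, the behavior a
calibrated harness must show.

Three leave-one-out modes hold out each known association in turn:
candidates are all unknown pairs (global), unknown pairs sharing the
held-out miRNA (miRNA-fixed) or SM (SM-fixed). The held-out entry is
zeroed *before* denoising and training, so no stage ever sees the test
label. One pooled AUC is reported per mode: all held-out scores
against the union of all candidate scores across retrainings. Pooling
raw scores assumes score scales are comparable across retrainings;
with per-sample rank averaging as the alternative, pooling was chosen
because it reduces to one Mann–Whitney computation and reproduces the
two calibration anchors exactly (oracle scorer $\to$ 1, random scorer
$\to$ 0.5, both verified in the acceptance tests). `kfold_cv()`
partitions the known associations into $k$ near-equal folds
(sizes differ by at most one), scores each fold against all unknown
pairs, and reports mean ± sd over folds × repeats; the published
protocol repeats the partition 100 times, and the package default is
one repeat with `repeats` exposed.

Case studies rank candidate miRNAs for one SM either from the full
training data (mode 1) or after deleting all of that SM's known
associations (mode 2, the cold-start setting); `random_control()`
scores a random sample of unknown pairs as a negative control. Ties
in reported rankings are broken lexicographically by miRNA identifier
so reports are reproducible.

## The synthetic generator, and what passing tests mean

`generate_synthetic()` plants block structure: entities are assigned
round-robin to `n_blocks` blocks; associations are Bernoulli —
`p_in = 0.06` within blocks, `p_out = 0.001` across at the default
40 SMs × 120 miRNAs, giving ≈146 associations at a realistic ~3%
density; similarities are `sim_in = 0.8` within blocks and
`sim_out = 0.2` across, with symmetric Gaussian jitter
(`sim_noise = 0.05`), clipped to $[0,1]$ with unit diagonal. The
similarities are generated consistently with the association blocks,
mirroring the premise that similar entities share associations. The
end-to-end tests use 30 SMs × 100 miRNAs with `p_in = 0.3`,
`p_out = 0.01` so that the low-rank stage retains signal at desk
scale, and 200 training epochs with 5-fold CV over three seeds — sizes
chosen to exercise every stage at meaningful density while keeping the
default test run short.

This design has a quantifiable ceiling worth understanding before
reading any AUC from it. Conditional on the blocks, within-block cells
are i.i.d. Bernoulli, so a held-out association is *exchangeable* with
every within-block negative: no scorer can do better than tie them.
With $N_w$ within-block and $N_c$ cross-block unknown candidates, the
expected AUC of an ideal (block-aware) scorer for a within-block test
pair is $(0.5\,N_w + N_c)/(N_w + N_c)$ — about 0.80 at the test
dimensions, lower still after the few cross-block test pairs. The
pipeline's observed 5-fold AUC sits essentially at this ceiling, which
is the strongest possible result on such data. The flip side: passing
these tests shows correct mechanics and full signal extraction on
block-structured data, but says nothing about the fine-grained,
non-block similarity structure of real chemical and miRNA data, nor
about curation biases (popular drugs are better annotated), nor about
the realistic regime where similarity matrices are noisy estimates
rather than generated consistently with the truth.

## Numerical and degenerate-input choices

- The $X$-update factorization is computed once per solve; cost is one
  $n_m^3/3$ Cholesky plus an SVD per iteration.
- Stopping uses infinity norms on both residuals, threshold `1e-7`;
  the acceptance checks verify `1e-6` feasibility is reached on random
  binary matrices within the 500-iteration cap.
- An empty pair file yields an all-zero association matrix (valid when
  universes are supplied); duplicate pairs collapse to one with a
  warning; identifiers outside a declared universe are an error naming
  the offender.
- `degree_filter()` errors rather than returning an empty dataset.
- Zero-degree graph nodes are normalized to zero rows, not NaN.
- Config files round-trip numerics at full double precision
  (17 significant digits).

## Known limitations

- Training is full-batch dense linear algebra: fine to a few thousand
  nodes, not engineered for much larger graphs (no mini-batching, no
  sparse message passing).
- LOOCV retrains per held-out association; with the full model this is
  honest but expensive, which is why the harnesses accept pluggable
  scorers and the calibration targets use cheap ones.
- The pooled-AUC convention can differ from per-sample averaging when
  score scales drift across retrainings of the full model.
- Early stopping is deliberately absent (fixed epoch budget); on very
  small inputs the weighted loss can plateau quickly.
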