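---
title: "Interaction mapping from combinatorial knockdown screens"
author: "epifuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction mapping from combinatorial knockdown screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the tunables that matter, and the
numerical choices made where a published description leaves the design
open.

## 1. Epistasis under the multiplicative null

### Model

For a gene pair $(a, b)$ with control-normalized single-knockdown
viabilities $W_a$, $W_b$ and double-knockdown viability $W_{ab}$, the
neutrality model is multiplicative:

$$E(W_{ab}) = W_a \, W_b, \qquad
  \varepsilon = \bar W_{ab} - E(W_{ab}).$$

Negative $\varepsilon$ is aggravating (synergistic), positive is
alleviating. The multiplicative form is the standard choice for viability
phenotypes: if two knockdowns act independently, their fractional effects
compound. The package deliberately supports no additive or log-additive
alternative.

### The Z-test and its variance

`callInteractions(method = "ztest")` tests $\varepsilon$ against zero with

$$z = \frac{\varepsilon}{\mathrm{SE}}, \qquad
  \mathrm{SE}^2 = \frac{s^2}{n_{ab}}
  + \bar W_b^2 \frac{s^2}{n_a} + \bar W_a^2 \frac{s^2}{n_b},$$

the second and third terms being the delta-method variance of the product
of two sample means. Treating $E(W_{ab})$ as a constant would ignore that
the product of sample means is itself a random quantity and would inflate
the type-I error.

Two design choices deserve explanation:

* **Pooled replicate variance (default).** Screens of this kind run
  technical triplicates. A per-measurement sample SD on 3 replicates has
  2 degrees of freedom; plugging it into a normal-reference Z-statistic
  produces far more than $\alpha$ false calls (the statistic is really a
  t with few df). The default therefore pools the replicate variance
  across all measurements of the panel (sum of squares over summed df,
  the same homoscedasticity assumption the noise model makes), which
  gives the Z reference hundreds of df and restores the nominal level —
  the same motivation as variance moderation in expression analysis.
  `seMethod = "replicate"` switches to per-measurement variances, and
  `refDist = "t"` substitutes a t reference, for users who want them.
* **Degenerate measurements.** Zero variance with nonzero $\varepsilon$
  admits no finite z; such pairs are flagged `degenerate` and called by
  the sign of $\varepsilon$ rather than silently assigned an infinite
  statistic. An $|\varepsilon| \le 10^{-10}$ guard keeps exact-null
  zero-noise panels from tripping this path through floating-point dust.

### The interaction-density region

`callInteractions(method = "density")` calls a pair significant when its
$\varepsilon$ falls strictly outside the central empirical-probability
region of all pairwise scores in the same panel (cell line). The region
is the symmetric-percentile interval at the configured coverage — 0.90
for the looser (dotted-line) tier, 0.95 for the strict tier — with
midpoint interpolation (type-2 quantiles); the tail probabilities are
snapped to 10 significant digits so that $(1-0.9)/2$ selects exactly the
5th-percentile order statistics. This is the simplest estimator
consistent with "central share of the interaction density", and it is the
rule the tests' brute-force sorting oracle re-implements.

### Cell-cycle phases

The same null applies per phase on control-relative ratios: with control
fractions $F_{0,k}$,

$$\hat r_{ab,k} = \frac{F_{a,k}}{F_{0,k}} \frac{F_{b,k}}{F_{0,k}}, \qquad
  E(F_{ab,k}) \propto \hat r_{ab,k} F_{0,k},$$

renormalized across phases so the expectation stays on the simplex (the
published description leaves compositional closure open; renormalization
is the choice here, and phases with $F_{0,k} = 0$ are excluded with a
warning rather than dividing by zero). The per-phase score is observed
minus expected fraction; positive scores are reported as "increase"
(rendered cyan/blue in phase networks), negative as "decrease" (brown).
Significance mirrors the viability caller: a pooled-variance Z-test when
replicate fraction matrices exist, the density region otherwise.

### Summaries

`binScores()` uses equal-width bins over the observed $\varepsilon$ range
(five by default; the published figures do not state edges), with
interior right edges belonging to the lower bin and the maximum closing
the last bin. `compareBins()` reports median and quartiles by linear
interpolation — declared explicitly so the test oracles agree.
`pairwiseSpearman()` and `overlapCounts()` intersect pair sets before
comparing, warning on mismatch.

## 2. Latent-factor network inference

### Model

Inputs are the symmetric averaged double-knockdown matrix $G$, the single
vector $S$, and $H = S S^\top$. Stage one fits

$$\hat G = \mathrm{logistic}(U V^\top), \qquad
  \mathrm{logistic}(x) = \frac{c}{1 + e^{-k (x - x_0)}},$$

by minimizing squared error on the observed off-diagonal entries. The
logistic map gives a nonlinear, bounded transfer from latent space to
viability, absorbing differences in single-knockdown background; its
ceiling is initialized just above $\max G$ and constrained to stay there
so the map can represent every observed value.

Numerical choices:

* **Optimizer.** Monotone alternating gradient descent over the blocks
  $U$, $V$ and the map parameters, each with its own backtracking step
  size; iteration cap 5,000, relative-objective tolerance $10^{-8}$.
  Every accepted step decreases the objective, so the per-iteration trace
  is nonincreasing by construction.
* **Initialization.** Two deterministic-given-the-seed candidates per
  rank: (i) a spectral start — invert the logistic map entrywise on the
  observed entries (gaps and diagonal imputed with row means) and take
  the leading eigenpairs of the logit-scale matrix — which lands very
  close to the optimum for ranks near $n$; and (ii) a warm start from the
  previous rank's solution with the new $U$ column at zero, whose initial
  objective equals the previous optimum exactly. The better final
  objective wins. The warm-start candidate is what makes the NRMSE-by-
  rank curve provably nonincreasing.
* **Rank selection.** NRMSE (RMSE over observed entries divided by the
  observed range); the smallest rank within 1% of the grid minimum is
  selected — parsimony when the curve plateaus.

### Four-way relationship scoring

Stage two compares the denoised $\hat g_{uv}$ against four predictions:
$S_u$ (a linear pathway in which $u$'s knockdown phenotype masks $v$'s),
$S_v$ (the mirror orientation), $S_u S_v$ (parallel, independent action),
and $\lambda s_{\text{near}} + (1 - \lambda) S_u S_v$ with
$\lambda \in [0.05, 0.95]$ chosen optimally (partial interdependence;
$s_{\text{near}}$ is the single nearer to $\hat g_{uv}$). Residuals enter
a Gaussian likelihood with scale $\sigma$ estimated from replicate
scatter (the pooled standard error of a double-knockdown mean), floored
at 0.02 when replicates are absent or noiseless; the interpolation
hypothesis pays a one-parameter penalty of 1 on the log scale (AIC-like),
without which it would nest the two linear hypotheses at the $\lambda$
boundaries and never lose. The four likelihoods are normalized to
probabilities; swapping the pair order swaps exactly the two linear
components. Class labels in all outputs are explicit strings
(`u_masks_v`, `v_masks_u`, `parallel`, `partial`) — never indices — to
make orientation bugs impossible to silently propagate.

`inferNetwork()` draws a directed edge from the masking to the masked
gene when a linear class exceeds the threshold (default 0.5, exposed), an
undirected edge for dominant partial interdependence, and nothing for
parallel pairs.

### Stability

`stabilityAnalysis()` adds independent symmetric Gaussian noise to $G$ at
each level of a grid spanning $[10^{-6}, \mathrm{sd}(G)/3]$ (three levels
by default), refits at the selected rank $M = 100$ times per level,
re-infers the network, and classifies each candidate edge by its
appearance fraction: solid at $\ge 40\%$, dashed in $[20\%, 40\%)$,
absent below. Because pooling across noise levels is ambiguous in the
published description, the report carries both per-level fractions and a
pooled summary. Perturbation refits default to a 300–500 iteration cap:
the refit starts from the same spectral/warm initialization and only
needs to track a small perturbation, and the full run (M = 100, 20
genes, 3 levels) completes in about a minute at that setting.

## 3. Data fusion by collective tri-factorization

Every relation matrix is first normalized in two steps — each nonzero row
divided by its Euclidean norm, then each nonzero column of the result —
with zero rows/columns left untouched to preserve object indexing. The
system

$$R_{ij} \approx G_i S_{ij} G_j^\top, \qquad G_i \ge 0$$

is fitted by multiplicative updates with one shared factor matrix per
object type, so information flows between relations through the shared
$G_i$. Two safeguards shape the solver:

* each individual factor/core update is accepted only if it does not
  increase the total squared reconstruction error (reverted otherwise),
  which turns the usual heuristic monotonicity of multiplicative updates
  into a guarantee the tests assert;
* the fit restarts from `nStarts = 5` random initializations and keeps
  the lowest final objective — multiplicative updates only find local
  optima, and a single unlucky start can land far from the planted
  structure.

Rank selection, where needed, is a grid search minimizing held-out
reconstruction error on a 10% entry mask, keeping the smallest rank
within 1% of the optimum. On noise-free or strongly structured data the
held-out error is flat for every rank at or above the true one, so the
procedure's real guarantee is rejecting underfitting ranks, and that is
what the tests pin down.

Profiles are rows of the reconstructed (dense, smooth) relations oriented
so the target type indexes rows; distances are cosine ($1 -$ cosine
similarity, range $[0, 1]$ for nonnegative reconstructions), averaged
unweighted across relations (a weight vector is accepted), with
zero-vector profiles assigned distance 1 under a warning. Hierarchical
clustering uses average linkage by default and sorts objects by label
before clustering, which makes tie-breaking deterministic and the output
invariant to input order.

## 4. The synthetic screens

The generators produce every input the pipeline consumes, with planted
ground truth (`TruthSet`) sufficient to score precision/recall of any
caller and ARI of any clustering. Defaults encode the study conditions
the pipeline is meant for:

| parameter | default | rationale |
|---|---|---|
| `nGenes` | 24 | a 24-target panel gives the canonical 276 pairwise combinations |
| `nReplicates` | 3 | technical triplicates |
| `noiseSd` | 0.05 | plate-reader-scale viability noise; the level at which planted effects of 0.3 are comfortably recoverable |
| `singleRange` | [0.4, 1.0] | keeps products well above 0, so floor effects (a separate phenomenon) never mix with epistasis |
| `effectSize` | 0.3 | a strong, unambiguous interaction on the viability scale |
| `phaseControl` | (0.05, 0.40, 0.20, 0.30, 0.05) | a typical cycling population over sub-G0/G1, G1, S, G2/M, >4N |
| `blockMargin` / `fusionNoiseSd` | 0.5 / 0.1 | a 5x signal-to-noise planted block structure; recovery degrades gracefully as the margin shrinks |

Choices worth noting:

* **Noise model.** I.i.d. Gaussian per technical replicate, truncated at
  0 by resampling — matching additive plate-reader noise and keeping the
  Z-test's assumptions inspectable. No published noise magnitudes exist
  for screens of this design; these defaults are calibration choices of
  this package, not estimates of any particular study.
* **Planted-pair placement.** An aggravating effect cannot push a double
  mean below zero; the generator therefore plants aggravating pairs only
  on pairs whose product of single means supports the full effect and
  raises a configuration error when none exists. Planting on an
  infeasible pair would silently truncate the very effect the recovery
  tests measure.
* **Phase fractions.** Noise is applied as log-ratio perturbations
  followed by renormalization, keeping every vector on the simplex; the
  planted per-phase deviation (default +0.1) is added to sub-G0/G1 for
  aggravating pairs (emulating increased cell death) and to G1 for
  alleviating pairs (emulating arrest), before renormalization.
* **Seeds.** One master seed; every generator draws from a deterministic
  substream, so components are independently reproducible and equal
  seeds give byte-identical output.

What the generators do **not** emulate: raw resazurin chemistry and plate
layouts, image-derived counting error, batch/edge effects,
heteroscedastic or correlated replicate noise, off-target silencing, and
real screens' incomplete pair coverage. Passing recovery tests on these
synthetics therefore demonstrates correctness of the computations under
the stated noise model, not robustness to every artifact of a wet screen.

## 5. Problem sizes in the shipped checks

The test suite and acceptance script run at desk scale by choice: null
calibration on 1,000 simulated pairs (binomial error ±0.014 at the 0.05
level), the density region on 5,000 scores, four-way hypothesis recovery
on 12-gene noise-free landscapes, the stability analysis at M = 100 on
20 genes and 3 noise levels, and fusion recovery on 12 genes x 8
substrates over 3 relations with medians over 20 seeds. These sizes make
every Monte-Carlo tolerance explicit and keep the whole suite
reproducible in minutes on one CPU.

## 6. Known limitations

* The Z reference is normal by fidelity to the method's description even
  though a t reference is arguably more honest for per-measurement
  variances; both are exposed, and the default pooled variance makes the
  distinction nearly moot.
* The four-way scoring is a concrete instantiation of a probabilistic
  scheme whose published description is a summary; the Gaussian
  likelihood, the penalty of 1, and the lambda clamp are this package's
  contract, chosen so that exact-hypothesis pairs are classified
  correctly and the partial class cannot trivially dominate.
* Latent-model and fusion fits are nonconvex; determinism is guaranteed
  given a seed, global optimality is not. Restarts and spectral
  initialization make failures rare at the shipped sizes, not
  impossible.
* `fitLatentModel()` consumes averaged doubles; replicate-level scatter
  enters only through the scoring scale sigma.
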