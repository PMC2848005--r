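---
title: "Permutation importance under predictor correlation: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation importance under predictor correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrvim)
library(dplyr)
```

## The question

Tree ensembles rank predictors by permutation importance: how much the
out-of-bag (OOB) prediction error grows when one predictor's values are
shuffled. When predictors are correlated — markers in linkage
disequilibrium, co-expressed genes, collinear exposures — this ranking can
diverge sharply from the coefficients of the model that actually generated
the data. A correlated proxy with *no* effect of its own can look more
important than a genuinely influential but uncorrelated predictor, because
at any single split a tree only ever sees a predictor's *marginal*
association with the outcome.

corrvim packages a controlled simulation environment in which this
behaviour can be measured rather than argued about: a linear generating
model with a known correlation structure, closed-form truths for what
marginal (single-predictor) analyses should see, a fully instrumented
regression forest, and three permutation importance measures.

## The generating model

Twelve predictors are standard normal. The first four form an
equi-correlated block with pairwise correlation $\rho = 0.9$; the other
eight are independent. The response is linear with no intercept,

$$ y = 5x_1 + 5x_2 + 2x_3 + 0x_4 - 5x_5 - 5x_6 - 2x_7 + 0\,(x_8..x_{12})
   + \varepsilon, \qquad \varepsilon \sim N(0, \sigma_\varepsilon^2). $$

So within the correlated block, $x_1, x_2$ carry strong signal, $x_3$ weak
signal, and $x_4$ none at all — $x_4$ is a pure proxy. The uncorrelated
$x_5, x_6$ mirror the strong block coefficients (with opposite sign), $x_7$
mirrors the weak one, and $x_8..x_{12}$ are noise. The null scenario
(`"H0"`) keeps the correlation structure and zeroes every coefficient.

```{r model}
ha <- generating_model("HA")
tidy(ha)
```

**On $\sigma_\varepsilon$.** The noise is specified as "$N(0, 0.5)$", which
is ambiguous between an SD and a variance. We take `sigma_eps = 0.5` as a
*standard deviation* — the argument convention of the R generator this
class of study is run with — and expose it as a model parameter. The choice
barely matters for any correlation (both readings agree to two decimals
except for $r(x_4,y)$, 0.785 vs 0.784), but it scales the absolute size of
null-hypothesis importance values, so it is fixed once here and never
tuned.

## Closed-form truths

For unit-variance predictors with correlation matrix $V$ and coefficient
vector $b$, the population slope of $y$ on $x_i$ alone is $(Vb)_i$, and the
marginal correlation is $(Vb)_i / \sigma_y$ with
$\sigma_y^2 = b^\top V b + \sigma_\varepsilon^2$. For this design
$b^\top V b = 189$:

```{r truth}
truth_table(ha)
```

The proxy $x_4$ has bivariate slope $10.8$ and marginal correlation
$\approx 0.785$ despite its zero coefficient. This single table explains
most of what the forest experiments show: the first split of a tree is a
bivariate analysis.

## OLS bias and coverage

`bias_coverage()` and `bias_coverage_table()` quantify the same point with
linear regression: across replicates, the full 12-predictor OLS model is
unbiased for $b$ with calibrated 95% intervals, while single-predictor
models are biased for the correlated block by exactly
$(Vb)_i - b_i$ (6.3 for $x_1, x_2$; 9.0 for $x_3$; 10.8 for $x_4$) and
their intervals essentially never contain the generating coefficient.
*Bias is always measured against the generating-model coefficient*, not
the population bivariate slope — that definition is what makes the
single-model bias "large by construction" and is the point of the
comparison. Intervals are t-based; an intercept-free variant is produced
alongside the intercept model because the generating model has no
intercept (the two agree closely).

## The instrumented forest

`grow_forest()` fits CART-style regression trees:

* **Subsampling without replacement**, 63.2% of rows per tree, so each
  tree's OOB set is exactly 36.8% — the subsample/OOB split is recorded
  per tree.
* **mtry** candidate predictors drawn uniformly without replacement,
  fresh at every node.
* **Split criterion**: maximal reduction in pooled sum of squared
  deviations from child means, over all midpoints between consecutive
  distinct in-bag values of the candidates.
* **Minimum node size 20**: a node with fewer than 20 in-bag rows is
  terminal; children may be smaller (this matches the `nodesize`
  semantics of the reference regression-forest implementation; the child
  sizes are not separately constrained).
* **Determinism**: criterion ties break towards the lowest feature index,
  then the smallest threshold; one seed fixes the whole forest. VIM
  permutations draw from a separate seed, so forest structure is
  invariant to importance settings.

Every internal node's (feature, threshold, depth) triple is kept
(`split_records()`), which is what selection-frequency tallies and the
conditional importance read.

## The three importance measures

For tree $t$ and predictor $j$ the raw quantity is
$d_{tj} = \mathrm{MSE}^{OOB}_{t,\pi(j)} - \mathrm{MSE}^{OOB}_t$: the OOB
mean squared error after permuting $x_j$ among the tree's OOB rows, minus
the unpermuted OOB MSE (positive = important; one fresh permutation per
tree–predictor pair by default, `nperm` averages more).

* **Unconditional**: $\bar d_j$, the mean over trees.
* **Scaled**: $\bar d_j / (s_{d_j} / \sqrt{\text{ntree}})$ — the mean over
  its Monte-Carlo standard error. Because the denominator shrinks as the
  forest grows, this measure *grows with forest size* and over-ranks
  predictors whose $d_{tj}$ are consistently positive — which is exactly
  what happens to frequently-selected uncorrelated predictors. It is
  reported for study, not recommended.
* **Conditional**: the same average, but $x_j$ is permuted only within
  strata defined by the predictors correlated with it (its *conditioning
  set*: all $k \ne j$ with $|\mathrm{cor}(x_j, x_k)| \ge$ a threshold,
  default 0.2). Strata are the cells of the partition the tree's own
  recorded split points induce on the conditioning predictors
  (`strata_source = "tree_splits"`); a cross-classification of global
  quantile bins is available as an alternative. A conditioning predictor
  the tree never split on contributes no refinement; a predictor with an
  empty conditioning set reduces *exactly* to the unconditional
  computation, consuming the identical permutation stream (this equality
  is asserted by test). Singleton strata are left fixed — an identity
  permutation, not an error.

With this design's correlations at 0.9 versus 0, any conditioning
threshold strictly between those values selects the same conditioning
sets, so the 0.2 default is uncritical here.

```{r vim-demo}
d <- simulate_dataset(ha, n = 2000, seed = 1)
f <- grow_forest(d, ntree = 250, mtry = 8, seed = 2)
vim_unconditional(f, perm_seed = 3)
```

## Study orchestration and scales

`run_replicates()` runs one (scenario, mtry) arm — simulate, grow, measure
— reusing each replicate's forest for both importance and
selection-frequency tallies. `run_study()` sweeps the full grid and writes
the CSV bundle plus a manifest holding every derived seed, so any single
replicate is individually re-runnable.

Two preset scales are built in. The `"paper"` scale is the full-scale study
design: $n = 2000$ observations, 500 replicates, 5000 trees, with the
conditional measure computed on 500-observation subsets and 500-tree
forests (the within-strata permutation is by far the most expensive
measure; running it on reduced data is part of the full-scale procedure,
and the `conditional_n_obs` / `conditional_ntree` knobs expose it). The
`"desk"` scale keeps $n = 2000$ — the per-dataset sample size changes the
phenomenon and is not reduced — and drops to 50 replicates and 250 trees,
chosen so that each arm finishes in minutes on one core while the
Monte-Carlo error still cleanly decides every ordinal claim (importance
and selection rankings). Package tests and the bundled acceptance script
run at desk scale.

## What the generator does and does not emulate

The synthetic design isolates one mechanism: *linear* signal with one
tight equi-correlated block among independent Gaussian predictors.
Passing tests demonstrate the importance measures' behaviour under that
mechanism — they say nothing about non-Gaussian or categorical predictors,
several overlapping correlation blocks, interactions or non-linear signal,
or correlation induced by confounding. Findings about VIM *rankings*
transfer qualitatively to settings like dense marker panels; absolute
importance values do not transfer at all (they scale with
$\sigma_\varepsilon^2$ and the coefficient sizes).

## Numerical and design notes

* Split-criterion comparisons use an absolute guard of `1e-12` so exact
  ties and zero-variance nodes terminate cleanly; a constant response
  yields a single-leaf tree.
* Subsample size is `round(0.632 * n)`; with $n = 2000$ each tree trains
  on 1264 rows and holds 736 out of bag.
* `bias_coverage*()` draws each replicate's seed up front from the caller
  seed, so full-model and single-predictor summaries can be computed on
  identical datasets.
* Scaled importance is undefined for a single tree (no between-tree
  spread); it is returned as `NA` with a warning rather than an error.
* Predictors a tree never splits on are skipped in the permutation loop:
  their predictions cannot change, so their per-tree difference is an
  exact 0, and skipping keeps the permutation streams of conditional and
  unconditional runs aligned.
* A forest-level OOB prediction exists for a row only if at least one
  tree holds it out of bag; rows OOB in no tree (possible only for tiny
  forests) are dropped from the aggregate with their absence visible in
  `predict_oob()`'s `n_trees` column.

## Known limitations

* The conditional measure inherits the instability reported for deep
  trees: with many split points on the conditioning predictors the strata
  become fine, and its replicate-to-replicate variability for strongly
  associated uncorrelated predictors is visibly larger than the
  unconditional measure's.
* The null-hypothesis inflation of correlated predictors' unconditional
  importance is small in absolute terms but real; its size depends on
  forest geometry (node size, subsample fraction) and on
  $\sigma_\varepsilon$, so comparisons against any externally reported magnitude are
  only meaningful under the matching configuration.
* Classification forests, impurity-based importances and p-value-based
  split selection are out of scope; the study is regression-only.
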