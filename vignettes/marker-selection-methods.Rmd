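---
title: "Selecting non-redundant gene markers with a multiobjective binary PSO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting non-redundant gene markers with a multiobjective binary PSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two-class expression studies (tumor vs. normal tissue, before vs. after
therapy) measure thousands of genes on a few dozen samples. Univariate
rankings — t statistics, rank sums, signal-to-noise ratios — find *relevant*
genes, but the top of any such ranking is typically saturated with mutually
correlated probes that carry the same information. A useful marker panel
needs genes that are individually discriminative **and** mutually
non-redundant.

`mobpso` casts this joint requirement as a graph problem. Every gene is a
node of a complete weighted graph:

* **node weight** — the magnitude of the gene's signal-to-noise ratio (SNR)
  between the two classes,

  $$\mathrm{SNR}(f) = \frac{\mu_{c1}(f) - \mu_{c2}(f)}{\sigma_{c1}(f) + \sigma_{c2}(f)},$$

  with sample ($n-1$) standard deviations;
* **edge weight** — the correlation dissimilarity
  $1 - \rho(f_i, f_j)$ between the two gene profiles, ranging from 0
  (perfectly correlated, fully redundant) to 2 (perfectly anti-correlated).

A good marker panel is then a node subset whose **average node weight**
(relevance) and **average pairwise edge weight** (non-redundancy) are both
large — a biobjective "densest subgraph" in the average-weight sense, not the
classical single-ratio densest-subgraph problem. The two averages genuinely
conflict: packing more top-SNR genes into a panel drags correlated ranking
neighbours in and depresses the average dissimilarity. The package therefore
treats them as two objectives and approximates the Pareto front.

## The optimizer

`run_mobpso()` implements a binary particle swarm with Pareto bookkeeping.

* **Encoding.** A particle is a 0/1 vector over genes; bit $j$ means gene $j$
  is in the candidate panel.
* **Initialization.** Every bit is a fair coin; all velocities start at 0;
  each particle's personal best (`pbest`) is its initial position.
* **Fitness.** For a mask selecting $m \ge 2$ genes,
  $f_1 = -\mathrm{avg\ edge\ weight}$ and $f_2 = -\mathrm{avg\ node\ weight}$
  (both objectives are maximized; the optimizer minimizes). Negation rather
  than a reciprocal is used deliberately: it is total (average SNR magnitudes
  can be arbitrarily small), strictly decreasing, and any strictly decreasing
  transform produces the identical Pareto set — a property the test suite
  checks by exhaustive enumeration on 8-gene instances. Masks with fewer than
  two genes are infeasible and scored $(+\infty, +\infty)$, so they are
  dominated by every feasible solution and self-extinguish without a repair
  step.
* **Velocity update.** Per cell,
  $v' = w\,v + c_1 r_1 (\mathrm{pbest}_j - x_j) + c_2 r_2 (\mathrm{gbest}_j - x_j)$
  with fresh $r_1, r_2 \sim U(0,1)$ per cell, clamped to $[-v_\max, v_\max]$.
* **Discretization.** The default is the standard stochastic sigmoid rule of
  binary PSO: bit $= 1$ with probability $S(v) = 1/(1+e^{-v})$. A fixed
  threshold $\delta$ (bit $= 1$ iff $S(v) > \delta$, no randomness) is
  available via `pso_params(delta = ...)` and the CLI's `--delta` for users
  who prefer a deterministic discretization; it intensifies the search at
  the cost of late-run diversity.
* **Inertia.** $w$ decreases linearly from `w_max` = 0.9 to `w_min` = 0.4
  over the run — the canonical schedule for a time-dependent inertia weight.
* **Guides.** `pbest` is replaced when the new fitness Pareto-dominates it,
  kept when dominated, and decided by a fair coin when the two are mutually
  non-dominated. The global guide `gbest` is drawn uniformly from the
  archive, independently for every particle at every iteration, which spreads
  the swarm across the current front approximation.
* **Archive.** A bounded store (default cap 100) of all mutually
  non-dominated solutions seen so far. After every generation the updated
  positions are merged in, duplicate masks are collapsed, only the first
  non-dominated front of the union is kept, and overflow is resolved by
  keeping the entries with the largest crowding distance (boundary solutions
  are infinitely crowded and therefore never truncated). Merging makes the
  archive elitist: its best $f_1$ and best $f_2$ never regress, which the
  per-iteration log exposes.

Defaults follow the reference configuration: swarm 25, 100 iterations,
$c_1 = c_2 = 2$, $v_\max = 6$ (keeps $S(v)$ away from full saturation).
All randomness flows from a single integer seed through a fixed draw order
(gbest, then the $r_1$ vector, then $r_2$, then the discretization uniforms,
then the optional pbest coin), so runs are reproducible bit-for-bit.

## From archive to markers

The archive approximates a Pareto front; a single panel still has to be
picked. `pick_best()` scores every entry with a **tStat score** and keeps the
maximum (ties: fewer genes, then earlier archive order). Per gene,

$$\eta = \frac{|\mu_{ctr} - \mu|}{\mu} \cdot \frac{CV}{CV_{ctr}}, \qquad
  \mathrm{score} = \eta \cdot t,$$

where $\mu_{ctr}, CV_{ctr}$ are the control-group mean and coefficient of
variation, $\mu, CV$ the both-group values, and $t$ is the product of the two
per-group true-positive rates of a univariate logistic regression of group
membership on the gene. The $\eta$ factor rewards a strong relative mean
shift and penalizes control-group noise; the logistic factor demands actual
discrimination. A solution's score is the **mean** over its genes — a sum
would systematically favor large panels, and archive entries differ in size.
The logistic fit is a ridge-stabilized IRLS (at most 50 iterations, ridge
$10^{-6}$ on the normal equations) so that perfectly separating genes — the
interesting ones — converge to saturated predictions instead of failing.

Because a single optimizer run is stochastic, the marker protocol runs the
pipeline 10 times (seeds `seed + 0 ... seed + 9`) and keeps **consensus
markers**: genes selected in at least 5 of the 10 runs (`consensus_markers()`,
threshold inclusive). Each consensus gene is called up- or down-regulated by
the sign of its class1 − class2 mean difference.

## Preprocessing

`select_markers()` fixes the stage order: SNR relevance is computed on the
raw matrix, the top `k` genes by $|\mathrm{SNR}|$ are kept (default 100, ties
broken by original column order), and only then is each gene min–max
normalized to $[0, 1]$. Node weights for the graph are recomputed on the
normalized matrix — the optimizer takes a single data matrix, and SNR is
invariant under the positive affine map that min–max normalization applies,
so the ranking is unchanged.

Two sign decisions deserve emphasis, because the SNR's sign only encodes
*which* class is up-regulated:

* genes are ranked by $|\mathrm{SNR}|$, not signed SNR — a signed ranking
  would discard every down-regulated marker;
* the graph's node weights are likewise $|\mathrm{SNR}|$ — maximizing the
  signed average would steer the swarm away from down-regulated genes
  entirely, leaving half of the relevant biology undiscoverable. The exported
  `relevance()` itself stays signed so the direction information is never
  lost.

## Synthetic data: what it emulates and what it does not

`generate_expression()` plants a known truth so every downstream stage is
testable without external downloads:

* `n_relevant` independent class-separating genes (`REL_i`): unit Gaussians
  with a `+effect` mean shift in class 2 (defaults: effect 2, i.e. a 2-sd
  shift);
* `n_blocks` redundant blocks (`BLK_b_j`): each member is
  $\rho \cdot \mathrm{REL}_b + \sqrt{1 - \rho^2}\,\varepsilon$ with fresh
  noise $\varepsilon$, giving an analytically controlled expected correlation
  with the prototype (default target 0.8); block members inherit a
  $\rho$-scaled class shift, making them relevant *and* redundant — exactly
  the trap a good selector must avoid;
* `n_noise` class-independent unit Gaussians (`NSE_k`).

The default configuration (50 samples per class, 5 relevant genes, two
5-gene blocks, 40 noise genes) is the package's reference study condition,
sized like a small two-class microarray cohort after aggressive
prefiltering. What the generator deliberately does **not** model: microarray
platform noise (probe effects, background, saturation), heavy-tailed or
heteroscedastic expression, batch effects, and multi-class designs. Passing
tests therefore demonstrate that the method recovers planted
relevant-but-non-redundant structure under clean Gaussian assumptions — not
that it is robust to real-world artifacts.

## Evaluation protocols

* `repeated_holdout()`: stratified 2/3–1/3 splits (the split ratio is a
  convention choice; stratification keeps both classes in every part), the
  **whole** selection pipeline re-run on each training part, a linear
  soft-margin SVM trained on the selected genes, and sensitivity,
  specificity, accuracy, F-score, AUC and average correlation collected on
  the test part; means and standard deviations over 10 repeats.
* `kfold_cv()`: a fixed gene set validated by stratified 10-fold
  cross-validation with the SVM; held-out predictions are pooled
  (micro-averaged) into one report per run.
* AUC uses the Mann–Whitney rank formulation with midrank ties. Average
  correlation is the mean **absolute** pairwise correlation of the selected
  genes on the full matrix — redundancy is symmetric in sign.
* A dependency-free nearest-centroid classifier is bundled for tests; any
  object providing `fit(x, y)` and a continuous `score(model, x)` plugs in.

## Numerical choices and degenerate inputs

* Zero pooled standard deviation in the SNR: denominator replaced by
  $10^{-12}$, keeping the score finite and enormous — a constant-but-shifted
  gene is maximally informative and should win the ranking.
* Zero-variance gene in a correlation: $\rho$ defined as 0 (dissimilarity 1),
  avoiding NaN propagation through the graph.
* Constant gene under min–max normalization: mapped to all zeros.
* tStat on normalized data: when a group mean is $\le 10^{-12}$ all values
  are shifted by +1 before means and CVs are taken (scores are only ranked,
  and the shift is uniform); $CV_{ctr}$ is floored at $10^{-12}$.
* Correlations are clamped to $[-1, 1]$ against floating-point rounding, so
  edge weights stay in $[0, 2]$.

## Problem sizes in the shipped tests

The test suite exercises exhaustive oracles where enumeration is feasible:
all $2^{12}$ masks for objective arithmetic and Pareto-front recovery,
peel-off sorting oracles up to 50 solutions, and 20-seed replications of the
planted-marker study at the reference conditions (100 samples, 55 genes).
The optimizer's front-recovery property is pinned at a 100-iteration,
10-particle budget on 12-gene instances, where the archive reliably attains
the majority of the exhaustively enumerated front; at much smaller budgets
the attainment fraction drops — the per-iteration log's monotone extremes
and the weak-domination consistency check still hold there.

## Known limitations

* Two classes only; multi-class SNR generalizations are out of scope.
* Only $1-\rho$ dissimilarity is implemented (no Euclidean or
  information-based alternatives).
* The tStat score is a documented reconstruction from its constituent
  quantities (group means, CVs, logistic true-positive rates); alternative
  per-solution aggregations (sum, max) are deliberately not exposed beyond
  the mean.
* The optimizer is the single-swarm variant; constriction factors, mutation
  operators and parallel subswarms are not implemented.
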