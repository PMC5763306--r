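---
title: "Coupling regulator influence to flux balance analysis"
author: "regflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling regulator influence to flux balance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regflux)
```

## The modeling problem

Genome-scale metabolic models predict growth and exchange fluxes by linear
programming (flux balance analysis, FBA), but a stoichiometric model alone
knows nothing about the transcriptional state of the cell: it will happily
respire glucose in a condition where the cell is actually fermenting. This
package couples a signed gene regulatory network (GRN) to an FBA model so
that condition-specific transcriptomes reshape the flux space. The chain has
five stages, each usable on its own:

1. **GRN inference** (`infer_network`): a simplified co-regulator mining
   stage that assigns each target gene a best set of co-activators and
   co-repressors.
2. **Influence scoring** (`compute_influence`): per sample, each regulator's
   activity is summarized as a Welch two-sample statistic contrasting its
   activated and repressed targets.
3. **Expression prediction** (`fit_influence_model`, `predict`): a per-gene
   linear model expresses metabolic-gene expression as a weighted sum of
   regulator influences, trained on a broad background compendium and
   applied to new contexts.
4. **Constraint building** (`condition_model`, `simulate_fluxes`): boolean
   gene-protein-reaction (GPR) rules are evaluated continuously on the
   predicted expression (OR = max over isoenzymes, AND = min over complex
   subunits, missing genes discarded) and passed through a softplus to
   become flux upper bounds.
5. **Phenotype simulation**: static FBA (`solve_fba`), growth-matched
   calibration (`calibrate_theta`), and dynamic FBA with phase switching
   (`run_scenario`) for diauxic growth.

## The influence statistic

For regulator $j$ in sample $k$, with activated target values $X_A$ and
repressed target values $X_R$ inside that sample,

$$ I_{jk} = \frac{\bar X_A - \bar X_R}
  {\sqrt{s_A^2/n_A + s_R^2/n_R}} , $$

the Welch unpooled-variance form. It is location- and scale-invariant within
a sample, which already removes most array-level normalization effects. Two
numerical decisions matter:

* a regulator needs at least `min_targets = 2` expressed targets per class —
  a variance needs two observations — otherwise the entry is undefined
  (`NA`) and every downstream stage treats it as missing;
* if both classes have zero variance the statistic is $0$ for equal means
  and otherwise clamped to `±1e6` with a warning. Propagating infinities
  into the downstream regression would poison it silently; a large finite
  value keeps the sign information.

Whether to center genes before scoring is left as a flag
(`center_genes = FALSE` by default): the statistic is computed on values as
given, and centering only matters when activated and repressed regulons have
systematically different baselines.

## The linear influence model

Expression of gene $i$ is modeled as
$x_{ik} = \sum_{j \in Pa(i)} \beta_j I_{jk}$ over its network regulators
$Pa(i)$, fitted per gene by ordinary least squares. The model form has no
intercept, and the package keeps that default; an `intercept = TRUE` flag
exists because real log-scale expression has gene-specific baselines, and
the synthetic diauxic benchmark uses it for exactly that reason. Rank
deficiency (collinear influences) falls back to the minimum-norm solution
with a warning rather than failing; optional ridge regularization is exposed
for ill-posed regulator sets but defaults to off, so the default behavior
remains plain least squares.

Genes without regulators, or with fewer usable samples than covariates plus
one, are skipped and recorded in the model's skip report. A missing
influence in a context sample makes the affected predictions `NA`; the GPR
discard rule then treats those genes as unavailable, so missingness flows
through the pipeline without special cases.

## From expression to bounds: the softplus

A reaction with GPR evaluation $g_r$ receives the upper bound

$$ v_r \le \ln\!\left(1 + e^{\,g_r + \theta}\right) , $$

which maps any real evaluation to a positive bound and saturates linearly.
The offset $\theta$ is condition-specific: it absorbs the unknown scaling
between (log) expression and enzyme capacity. Bounds combine with the
model's own bounds by min/max, never replacement, so thermodynamic
irreversibility is never relaxed; for reversible reactions the bound is
mirrored to $-b_r$ on the lower side, since enzyme limitation caps the
magnitude of catalysis regardless of direction. As $\theta \to +\infty$
every softplus bound exceeds the model's own bounds and the solution
converges to plain FBA; as $\theta \to -\infty$ all GPR-bearing reactions
close. Both limits, and the monotonicity of growth in $\theta$, are asserted
in the test suite.

## Calibrating theta

Observed growth $v^B_{obs}$ is matched by maximizing
$-\ln(|v^B_{obs} - v^B_{sim}(\theta)| / v^B_{obs})$, with the relative error
floored at $10^{-9}$ so an exact match stays finite. Because growth is
nondecreasing in $\theta$ and saturates at the plain-FBA optimum, the
objective is unimodal, and the calibrator needs nothing fancier than a
10-point uniform grid on $[-10, 10]$ followed by deterministic
golden-section refinement around the best grid point. A stochastic surrogate
optimizer would add a seed dependence without improving a one-dimensional
unimodal search, so the deterministic method is the default; the refinement
method is recorded in the result. When observed growth exceeds what the
unconstrained model can reach (beyond a $10^{-3}$ relative tolerance), no
$\theta$ can close the gap — the result then carries status
`fba_underestimates` and the best grid value, mirroring the situation where
an FBA model structurally under-predicts a measured growth yield.

The budget is 50 simulate calls; the grid takes 10 and golden section
converges to $10^{-7}$ interval width in roughly 35 more, stopping early
when the relative error reaches $10^{-6}$.

## Dynamic FBA and phase switching

`run_scenario` integrates batch growth with forward Euler at `dt = 0.01` h
by default: per step, each tracked metabolite's uptake is capped at
$\min(V_{max}, C/(X\,\Delta t))$ — the availability cap makes negative
concentrations impossible by construction — then the FBA problem is solved
and biomass and concentrations are updated. Switch conditions (substrate
below a threshold, or a fixed time) are checked at step boundaries only, a
bias of order $\Delta t$; the recorded phase of a row is the phase whose
model produced that state. Step-halving convergence, the closed-form
exponential, and the analytic batch depletion time are all asserted in the
tests at 1–2%.

A diauxic shift is represented as an ordered list of phase models — the
same metabolic model constrained under different contexts and $\theta$
values — with state carried across switches. On the bundled toy, the
glucose-phase model ferments (ethanol accumulates) and the ethanol-phase
model respires the accumulated ethanol, producing the two growth phases;
the unconstrained FBA scenario respires glucose directly, grows faster
pre-switch, makes no ethanol, and never starts a second phase.

## The synthetic study

No external data ships with the package; `make_planted_network`,
`make_expression` and `make_diauxic_benchmark` generate everything, as pure
functions of their parameters and a seed, with ground truth attached.

* Regulator profiles are standard normal per sample; a target combines its
  regulators as $m = \min(\text{activators}, -\text{repressors})$ and adds
  Gaussian noise (`noise_sd = 0.2`, effect size `w = 1` — large enough to
  be recoverable, small enough that recovery is not trivial). The
  `discrete_logic` regime thresholds regulator profiles at one SD first,
  producing the AND/OR-style patterns that the co-regulator miner assumes.
* The diauxic benchmark's regulons carry eight filler targets per class on
  top of the metabolic genes. Influence is a regulon average; with two or
  three targets the statistic has no averaging to work with, which is not
  the regime the method is meant for.
* Genes receive fixed per-gene baseline offsets (SD 2 log-units, shared
  between training and context data). Log expression spans several log
  units between genes, and this heterogeneity is what makes raw expression
  fragile under cross-gene permutation while influence degrades gracefully.
  Without baselines the toy context is essentially two-valued and feeding
  raw expression into GPRs is artificially robust.

What the toys do *not* emulate: genome-scale GPR complexity (three GPR
reactions versus thousands), probe-level noise models, correlated regulator
programs, and compartmentalized metabolism. Passing tests demonstrate that
the statistics, the constraint machinery and the simulators implement their
definitions correctly and behave as the method's rationale predicts at
small scale — not that the pipeline's biological conclusions transfer to
any particular organism.

## The robustness protocol

`perturb_expression` draws a fraction `level` of genes (seeded) and, within
each sample, shuffles the values of the selected genes among those rows —
value multisets per sample are preserved exactly. `exchange_flux_error`
scores simulated against reference exchange fluxes as a normalized mean
square, with the normalization constant $s = \max |v_{obs}|$, making the
statistic unit-free. `robustness_run` chains perturbation, influence,
prediction and FBA at a fixed calibrated $\theta$, with replicate seeds
derived independently from the master seed.

On the bundled benchmark the median error is nondecreasing in the noise
level and the influence route beats feeding perturbed raw expression into
the GPRs replicate-by-replicate (paired Wilcoxon), with a smaller mean and
variance: raw GPR input occasionally gets lucky but carries a heavy error
tail. One honest caveat: with only three GPR reactions the *median* of the
two routes is a near-tie that can flip with the replicate seed, so the
suite asserts the paired comparison and the dispersion, not the median gap.
At genome scale the averaging argument strengthens with regulon size and
GPR count; at toy scale it is visible but not overwhelming.

## Numerical choices

* **LP solver.** The package implements a two-phase primal simplex with
  Bland's anti-cycling rule behind `solve_lp()`. FBA bases are highly
  degenerate (steady-state rows with zero right-hand side), which is
  exactly where naive pivoting cycles or fails, and Bland's rule makes
  termination unconditional. All model bounds are required finite, so the
  LP is always bounded; fixed variables are eliminated before solving.
  Solutions are verified against $|S v| \le 10^{-6}$ and the bounds, and
  cross-checked in the tests against a brute-force vertex-enumeration
  oracle on the small models.
* **Softplus overflow.** For arguments above 30 the bound is computed as
  $z + \log(1 + e^{-z})$; below, as `log1p(exp(z))`. Negative GPR
  evaluations are passed through unchanged — the softplus already maps
  them to small positive bounds, so flooring expression at zero would only
  discard information.
* **Determinism.** Inference tie-breaks (equal merged scores) resolve by
  smallest regulator-set size, then lexicographic order under C collation;
  all iteration orders that feed seeded draws use locale-independent radix
  sorting, so generated benchmarks are identical across locales.
* **Mining enumeration.** Candidate signed regulator sets are enumerated
  level-wise up to `max_set_size` without support-based pruning between
  levels: match support under the min-combination is not anti-monotone (an
  AND pair can match where neither singleton does), so classic Apriori
  pruning would silently lose exactly the co-regulation the miner exists to
  find. At the intended scale (tens of regulators, set size 2) exhaustive
  level-wise enumeration is cheap.

## Scale of the shipped experiments

The bundled studies are sized for a laptop: 100 training samples, 31-gene
benchmark, 20 replicates per noise level, 1,200-step dFBA runs. These sizes
were chosen so every recovery property is comfortably inside its tolerance
while a full run of the test suite and the analysis script stays in the
minutes range; all of them are parameters, and scaling them up only
sharpens the same comparisons.

## Known limitations

* The GRN stage is a deliberate simplification of full local-model
  inference: no bootstrapping, no merging across runs, no cooperativity
  network; the min-combination and the support definition (matches among
  target-active samples) are this package's fixed semantics.
* Eq.-style linearity between influence and expression is an approximation;
  with min-combined multi-regulator targets it holds only locally, which is
  visible as imperfect (though well-conditioned) predictor fits on the
  linear-regime generator.
* The calibration assumes growth is the only observable being matched;
  matching exchange fluxes jointly would need a different objective.
* Switch detection at step boundaries biases switch times by up to one
  Euler step.
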