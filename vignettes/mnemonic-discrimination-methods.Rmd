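---
title: "Curve-based mnemonic discrimination indices: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curve-based mnemonic discrimination indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdindex)
```

## The measurement problem

Mnemonic discrimination (MD) is the ability to tell a novel stimulus apart
from a highly similar stored memory, and is the behavioral signature usually
attributed to hippocampal pattern separation. The gold-standard behavioral
assay, the mnemonic similarity task (MST), measures it with a categorical
design: test items are either exact repeats ("old"), similar-but-not-identical
"lures", or unrelated "new" foils, and MD is scored with the lure
discrimination index

$$\mathrm{LDI} = P(\text{"similar"} \mid \text{lure}) - P(\text{"similar"} \mid \text{foil}),$$

alongside the overall recognition score

$$\mathrm{REC} = P(\text{"old"} \mid \text{old}) - P(\text{"old"} \mid \text{foil}).$$

Many recognition tests used in clinical batteries do not have this
categorical lure/foil structure: stimulus interference varies continuously.
`mdindex` implements a pair of indices that only require a per-trial
*dissimilarity* value in $[0,1]$ between each test item and the study list,
making MD measurable from such tests.

## The performance curve and the two indices

For each participant we model the probability of judging a test item as
novel (responding "similar" or "new" rather than "old") as a function of its
dissimilarity $x$ with a five-parameter logistic (5PL):

$$P_{NEW}(x) = d + \frac{a - d}{\left(1 + (x/c)^{b}\right)^{e}}.$$

Parameter $a$ sets the lower asymptote ($P_{NEW}(0) = a$ exactly: the rate of
calling old items new), $d$ the upper asymptote (calling the most distinct
items new), $b$ the steepness, $c$ the horizontal position and $e$ the
asymmetry. Two indices are read off the fitted curve:

* **Recognition:** $\Delta = P_{NEW}(1) - P_{NEW}(0)$, the curve-based
  analogue of REC.
* **Mnemonic discrimination:** $\lambda = 1 - A/\Delta$ with
  $A = P_{NEW}(1) - \int_0^1 P_{NEW}(x)\,dx$, the area between the curve and
  its value at maximal dissimilarity. A participant who already responds
  "new-ish" to barely-dissimilar lures has $A \approx 0$ and
  $\lambda \approx 1$; a linear ramp between the asymptotes gives exactly
  $\lambda = 0.5$ (a useful analytic anchor that the test suite checks).
  Dividing by $\Delta$ decorrelates the discrimination index from overall
  recognition.

Ordinal MST lure bins are converted to dissimilarities by dividing by the
maximum bin of 6, with old items assigned bin 0 and foils bin 6; three-way
responses are collapsed to the binary novelty outcome (old $\to$ 0,
similar/new $\to$ 1).

## Fitting: choices and rationale

The published description of the method fixes the estimator — nonlinear
least squares on the trial-level binary outcomes — but not the optimizer
details, so the following are this package's own choices:

* **Trial-level target.** The curve is fit to the raw 0/1 outcomes, not to
  binned proportions (binned fitting exists as a diagnostic via
  `fit_pnew_curve(..., binned = TRUE)`). With few trials per level, binned
  least squares would weight sparsely-observed levels equally with
  well-observed ones.
* **Optimizer.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`). The LM
  damping handles the singular Jacobians that arise when a participant's
  responses are nearly flat (then $b$, $c$, $e$ are unidentified); a
  Gauss–Newton `nls` fit fails on exactly those participants.
* **Bounds.** $a, d \in [-0.2, 1.2]$, $b \in (0.01, 100]$,
  $c \in (0.01, 10]$, $e \in (0.01, 10]$. Asymptotes may overshoot $[0,1]$
  slightly because least squares on binary data is not constrained to the
  probability scale; clamping at the boundary would bias $\Delta$ downward
  for near-ceiling participants.
* **Starts and restarts.** $a_0$ and $d_0$ start at the observed novelty
  rates at dissimilarity 0 and 1; $b_0 = 5$, $c_0 = 0.5$, $e_0 = 1$. On
  failure, a $3 \times 3$ restart grid over $b_0 \in \{1, 5, 20\}$,
  $c_0 \in \{0.2, 0.5, 0.8\}$ is tried and the best converged solution kept.
  Participants with no converged fit are flagged and excluded from the
  validation regressions (in the synthetic study below, failed fits plus
  undefined-$\lambda$ flat responders exclude roughly 1–3% of agents,
  comparable to the 1488/1500 retention reported for this design).
* **Quadrature.** $A$ uses composite Simpson's rule with 8193 equally spaced
  nodes on $[0,1]$: the integrand is smooth and the rule deterministic. The
  node count is set by the steepest admissible curve ($b = 100$,
  $c = 0.01$), for which a coarser 1001-node rule misses a $10^5$-node
  trapezoid oracle by a few parts in $10^6$; at 8193 nodes the agreement is
  below $10^{-7}$ everywhere, checked in the property tests.
* **Division guard.** $\lambda$ is undefined when $|\Delta| \le 0.01$
  (`delta_floor`, configurable): for a flat curve the ratio $A/\Delta$ is
  numerically meaningless. Neither $\Delta$ nor $\lambda$ is clamped to
  $[0,1]$; the validation models are linear and clamping would distort them.

## The synthetic-agent generator

`simulate_experiment()` generates MST data from a multinomial processing
tree. An agent recognizes old items with probability $\rho$ and rejects new
items with probability $\psi$. On a lure trial, recognition of the studied
counterpart (probability $\rho$) is followed by discrimination: with
probability $\delta(\ell) = 1/(1+e^{-\beta(\ell - \tau)})$ the agent answers
"similar", otherwise "old". Whenever initial recognition fails the agent
guesses old/similar/new with probabilities $(\gamma_O, \gamma_S, \gamma_N)$.
The latent MD ability of an agent is the area under its discriminability
curve, $\int_0^1 \delta(\ell)\,d\ell$, available in closed form
(`ground_truth_lambda`).

The population defaults *are* the synthetic study conditions: 1500 agents,
$\rho, \psi, \tau \sim U(0,1)$, $\beta \sim U(0,50)$, and each agent
responding to a 48-item test list of 16 old, 16 new and 16 lure stimuli with
lure dissimilarities on the discrete grid $\{1/6, \dots, 5/6\}$. Two points
were genuinely open and decided here:

* **Guessing simplex.** "Random $\gamma$" is sampled uniformly on the
  2-simplex (normalized exponentials) — the least-informative distribution
  consistent with $\gamma_O + \gamma_S + \gamma_N = 1$.
* **Lure allocation.** 16 lures cannot split evenly over 5 levels; counts
  are $(4,3,3,3,3)$ with the extra lure rotated across levels from agent to
  agent so no level is favoured in the population.
* **Failed-discrimination branch.** An agent that recognizes a lure's
  studied counterpart but fails to discriminate answers "old" (not a guess);
  guessing only follows failed recognition. This follows the established
  processing-tree structure for this task.

What the generator deliberately does **not** emulate: encoding-phase
variability (study items are never modelled), response times, sequential
effects (trials are exchangeable), and lapses/missing responses. Passing
validation on these data therefore shows that the indices recover a known
discrimination signal from categorical responses of the stated design size —
not that they are robust to the attentional and strategic noise of real
participants.

## Validation models

`fit_validation_models()` z-standardizes $\lambda$, $\Delta$, LDI and REC
over the pooled analysis sample (listwise-excluding participants with failed
fits or undefined $\lambda$) and fits

1. `ldi ~ lambda + delta` — convergent validity of $\lambda$,
2. `rec ~ lambda + delta` — convergent validity of $\Delta$,
3. `lambda ~ delta` — collinearity check.

With a grouping label (several studies) these become random-intercept mixed
models (`lme4`, REML) with Wald 95% intervals, ICC
$= \tau_{00}/(\tau_{00}+\sigma^2)$ and Nakagawa–Schielzeth marginal and
conditional $R^2$; singular random-effect fits fall back to OLS with a
warning. Single-sample data (e.g. the synthetic study) use plain OLS, for
which marginal and conditional $R^2$ coincide with the ordinary $R^2$.
Standardization uses the $n-1$ SD; on standardized variables a
single-predictor slope equals the Pearson correlation, which the tests
exploit as an exact cross-check.

`delta_threshold_sweep()` restricts the sample to $\Delta \ge t$ for a grid
of thresholds and reports $R^2$ of $\lambda$ against LDI and against the
ground-truth index: discrimination is measurable only in agents whose
overall recognition is intact, and both curves rise with the threshold.
`sensitivity_exclude_similar_lures()` drops the most similar lure bins and
refits, emulating tests that lack high-interference items.

## Problem sizes and reproducibility

The synthetic study (`run_synthetic_study()`) uses the full stated design —
1500 agents $\times$ 48 trials with per-agent 5PL fits — and completes in
about a minute and a half on one core; the test suite re-runs it once at a
fixed seed plus five single-threshold sweeps for the trend check, and uses
smaller populations (3–200 agents) and closed-form oracles everywhere else.
All randomness flows through R's global RNG: `simulate_experiment(seed =)`
calls `set.seed()`, so any fixed seed reproduces the entire trial log,
fits and model summaries bit-for-bit. File outputs print doubles with 9
significant digits, making repeated runs byte-identical.

## Known limitations

* Least squares on binary outcomes is not maximum likelihood; it matches the
  published estimator but gives no standard errors on the curve parameters,
  and fitted asymptotes can fall slightly outside $[0,1]$.
* Five parameters against 48 binary trials is heavily over-parameterized;
  individual parameter values are not interpretable (only the functionals
  $\Delta$, $\lambda$, $A$ are used downstream).
* $\lambda$ is undefined for flat responders and unstable for
  $|\Delta|$ just above the floor; the threshold sweep quantifies this.
* The mixed-model machinery assumes a random intercept only; random slopes
  by study are out of scope.
* With 16 lures per agent, LDI itself is noisy; synthetic-study $R^2$ values
  are bounded well below 1 even for a perfect index.
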