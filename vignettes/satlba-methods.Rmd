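---
title: "Methods: a neurally constrained LBA account of the speed-accuracy tradeoff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a neurally constrained LBA account of the speed-accuracy tradeoff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`satlba` models two-choice decisions under speed, neutral and accuracy
emphasis with the linear ballistic accumulator (LBA). Each trial is a race
between a target and a distractor accumulator. An accumulator starts at a
point drawn uniformly on $[0, A]$ and accrues evidence exactly linearly at
a drift rate drawn once per trial from $\mathcal{N}(v, s^2)$; the first
accumulator to reach its threshold $b$ triggers the response, and the
observed response time is the crossing time plus a non-decision time
$t_0$ covering perceptual encoding and motor execution.

With $A = 0$ (the package default, see below) the crossing time of one
accumulator is simply $b/d$ with $d \sim \mathcal{N}(v, s^2)$, giving the
analytic first-passage density and distribution

$$f(t) = \frac{b}{s\,t^2}\,\phi\!\left(\frac{b/t - v}{s}\right), \qquad
  F(t) = \Phi\!\left(\frac{v - b/t}{s}\right),$$

defective in the sense that $F(\infty) = \Phi(v/s)$: only trials with a
positive drift draw ever cross. For $A > 0$ the standard LBA closed form
(differences of scaled Gaussian cdf/pdf terms) is used instead. The joint
density of (response, RT) is the usual race expression
$f_{\mathrm{win}}(t - t_0)\,\{1 - F_{\mathrm{lose}}(t - t_0)\}$,
renormalized by the race's finish probability
$Z = 1 - \Phi(-v_t/s_t)\,\Phi(-v_d/s_d)$ so that the model is a proper
distribution over terminating trials; the simulator correspondingly
redraws the (rare) trials in which neither accumulator finishes.

### The emphasis-condition structure

Two parameter settings exist, tied together by constraints taken from
frontal-eye-field recordings rather than estimated freely:

* **Threshold:** $b_{\mathrm{speed}} = 1.2\, b_{\mathrm{acc}}$, exactly —
  the 20% firing-rate threshold increase observed under speed emphasis.
* **Scale:** $s_{\mathrm{speed}} = 1$, exactly. The LBA likelihood is
  invariant to a common rescaling of all evidence-dimension parameters
  ($b$, $A$, $v$, $s$), so one parameter must be fixed to pin the scale;
  the test suite demonstrates the invariance directly.
* **Yoking:** the neutral condition shares the speed setting unchanged,
  reflecting how similar those two conditions' data are.
* **Cue neglect:** an accuracy-emphasis trial is, with probability $p$, a
  full speed-setting trial (threshold, drifts and drift SD all switched);
  otherwise an accuracy-setting trial. The density for the accuracy
  condition is the corresponding two-component mixture. Neglected trials
  are modelled as *identical* to speed-emphasis trials; intermediate
  settings are deliberately out of scope.

This leaves 7 core free parameters
($t_0, b_{\mathrm{acc}}, v_{t,\mathrm{acc}}, v_{d,\mathrm{acc}},
v_{t,\mathrm{spd}}, v_{d,\mathrm{spd}}, s_{\mathrm{acc}}$) plus the
mixture proportion $p$, flagged separately by
`sat_free_parameter_names()`. One shared $t_0$ is used across conditions
(per-condition $t_0$, which would absorb the ~19 ms condition differences
in neural onset latency, is a documented possible extension, not a
package feature).

### Start-point variability

The source analyses fixed the start-point range to an unquantified
"small" value. The package default is $A = 0$ with the exact analytic
limit formulas: it is numerically stable, reproducible, and removes an
arbitrary constant; $A$ remains configurable (`sat_parameters(A = ...)`)
and the $A > 0$ closed form is implemented and tested against simulation.

### Numerical choices

* **Density floor.** Per-trial densities are floored at $10^{-29}$ before
  logging, so pathological proposals (e.g. $t_0$ above an observed RT)
  yield very poor but finite log-likelihoods instead of `-Inf` plateaus
  with undefined gradients. The floor only binds where the model is
  already essentially ruled out.
* **Choice probabilities** integrate the defective density by adaptive
  quadrature over $(t_0, \infty)$ using `stats::integrate`'s interval
  transformation. The $A = 0$ crossing-time density has a $1/t^2$ tail
  (drift draws near zero cross arbitrarily late), which the
  transformation handles without an explicit truncation point; the
  target and distractor probabilities sum to 1 within $10^{-6}$ in
  practice (tested at $10^{-4}$ tolerance).
* **Ties** between the two crossing times have probability zero; the
  simulator breaks the measure-zero numerical case toward the target.

## Estimation

Posterior sampling uses Markov chain Monte Carlo with differential-
evolution proposals: chain $i$ proposes
$x^* = x_i + \gamma\,(x_j - x_k) + \epsilon$ with $j \ne k \ne i$ drawn
from the other chains, $\gamma = 2.38/\sqrt{2d}$ (10% of proposals use
$\gamma = 1$ for mode jumping), and $\epsilon$ uniform on
$(-0.001, 0.001)$ per coordinate. Defaults are 3 chains per free
parameter (24 for the main model) and 5000 iterations with half burn-in;
chains initialize from the priors, which are overdispersed relative to
the posterior so that the Gelman–Rubin diagnostic (`rhat()`) can detect
non-convergence.

**Priors** (weakly informative on the scale set by
$s_{\mathrm{speed}} = 1$; all overridable): $t_0 \sim U(0, 0.5)$ s;
$b_{\mathrm{acc}}, s_{\mathrm{acc}} \sim \mathcal{N}(0.5, 0.5^2)$
truncated to $(0, \infty)$; drift means $\sim \mathcal{N}(1, 2^2)$
truncated to $(-3, 8)$; $p \sim U(0, 1)$. These are design choices — the
original sampling supplement's hyperparameters are not public.

**Outlier-chain correction.** Pure DE-MC has a known failure mode: once
most chains converge, the difference vectors $x_j - x_k$ become small, so
a chain stranded on a distant low-density ridge can no longer take large
steps and stays stranded for the entire run. At this model's mandated
budget that reliably left a handful of 24 chains unconverged. The sampler
therefore applies a DREAM-style remedy **during burn-in only**: every
100 iterations, chains whose mean log posterior over the recent half of
their history falls far below the population median — more than four
upper half-spreads $(Q_3 - \mathrm{median})$, floored at $5\sqrt{d}$ —
are reset to the best chain's current state. (The classic
$Q_1 - 2\,\mathrm{IQR}$ cutoff references the lower quartile, which the
stranded chains themselves contaminate whenever more than a quarter of
the population is stranded; the upper half-spread is immune to that.) Retained
(post-burn-in) iterations use the unmodified DE kernel, so the kept
sample is a valid DE-MCMC draw; the Gaussian-target tests verify the
stationary distribution. The correction can be disabled
(`outlier_correct = FALSE`).

## Synthetic data: what it emulates and what it does not

The monkey behavioral data are not publicly deposited, so
`generate_dataset()` stands in for them. It emulates the statistical
structure the analysis assumes: three emphasis conditions with the
neutral condition much smaller (defaults 2000/400/2000 — the published
figures note many fewer neutral trials but print no counts, so the counts
are a package decision), sub-second RTs, speed/neutral yoked to one
setting, and per-trial cue neglect at rate $p$ in the accuracy condition
(realized labels are kept in a sidecar attribute, never visible to the
likelihood). Generated at the published Monkey Q estimates it reproduces
the signature motivating the mixture: a broadened fast left tail of the
accuracy-condition RT distribution overlapping the speed distribution.

It does **not** emulate session/block structure, reward and timeout
scheduling, neural covariates, the eight-alternative nature of the real
search array, or any drift between sessions. A green recovery test
therefore establishes that *the estimation machinery recovers the
generating parameters of the assumed model at realistic sample sizes* —
not that the model is the true account of any particular monkey.

## The over-constrained negative control

An alternative way to satisfy the scaling property fixes the sum of the
two mean drift rates instead of $s$. Applying *both* constraints at once
(`over_constrained_variant()`, fitted via
`fit_sat(variant = "over_constrained")`) removes real degrees of freedom
rather than just pinning the scale and is expected to fit strictly worse;
the acceptance suite reproduces this qualitative failure on synthetic
data, mirroring the poor fit reported for the doubly constrained model.

## Known limitations

* Two accumulators only; the original task was an eight-item search.
* No within-trial accumulation noise (ballistic paths), no leakage.
* Shared $t_0$ across conditions; no per-condition perceptual latency.
* Neutral condition fully yoked to speed; any genuine neutral-specific
  parameters are invisible to this model.
* The recovery studies use the published posterior means as generating
  truths; they validate the pipeline, not the original data analysis,
  which cannot be reproduced without the undeposited recordings.
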