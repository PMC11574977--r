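---
title: "Learning a color attentional template: model, fitting, and neural analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning a color attentional template: model, fitting, and neural analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In visual search, behavior is guided by an *attentional template*: an
internally held description of the currently relevant stimulus feature.
templateRL models a task in which that template is a **color on a
continuous wheel** and must be learned purely from reward feedback. On
each trial three colored disks appear in three of four screen locations;
choosing one delivers a number of liquid-reward drops that falls off as a
von Mises function of the circular distance between the chosen color and
a hidden template color. The template is constant within a block and
switches, without any cue, once performance reaches a criterion. The
package simulates this task, fits a family of reinforcement-learning
models to the choices, validates the fits by generate-and-refit recovery,
and runs the downstream neural analyses (encoding models, population
decoding, value-geometry) on synthetic populations with known ground
truth.

# The behavioral model

The expected value of each color is represented with *circular function
approximation*: N von Mises radial basis functions \(x_i(\theta)\) with
equally spaced centers (\(\mu_1 = 0\)) and shared concentration
\(\kappa\),

\[ v(\theta) = \sum_{i=1}^{N} w_i\, x_i(\theta), \qquad
   x_i(\theta) = \frac{e^{\kappa \cos(\theta - \mu_i)}}{2\pi I_0(\kappa)}. \]

Because the basis is smooth, reward feedback about one color generalizes
to nearby colors; smaller \(\kappa\) generalizes more. After choosing
\(\theta_c\) and receiving \(R\) drops, the reward prediction error is
\(\delta = R - v(\theta_c)\) and all weights move along the basis:

\[ w_i \leftarrow (1 - k)\,\bigl(w_i + \alpha\,\delta\,x_i(\theta_c)\bigr)
   + k\, R\, x_i(\theta_c). \]

The *reset fraction* \(k\) implements a discrete re-initialization of the
template after a surprising outcome: \(k = \sigma\!\left(\beta_r
(|\delta| - \tau(n))\right)\) with \(\beta_r = 10^4\) (so \(k\) is
effectively 0 or 1), and a dynamic threshold
\(\tau(n) = \tau_0 / \tanh(\text{volatility} \cdot n)\) where \(n\)
counts trials since the last reset. Right after a reset the threshold is
high and it decays to \(\tau_0\), so consecutive resets are penalized;
smaller volatility penalizes them longer. The *No Reset* variant forces
\(k = 0\); a *dual learning rate* variant uses a separate \(\alpha\) for
negative prediction errors.

Choices are made by softmax (temperature \(\beta = 0.3\), never fitted)
over the option values plus small biases: a per-location bias (one of the
four pinned at 0, because the softmax ignores a common shift), a bias for
a visually smaller or bigger stimulus, and proximity biases
\(b\,(\pi - |d(\theta, \theta_{\text{pref}})|)\) toward a preferred color
and toward the previously chosen color. The *estimated template* on each
trial is the argmax of \(v\) on the 100-color wheel grid (ties broken by
the lowest grid index), and the uncertainty about it is the entropy of
the min-shifted, normalized value function (a flat \(v\) gives
\(\log 2\pi\) nats).

Two non-incremental baselines are included for model comparison:
*win-stay-lose-forget* (the template is simply the previously rewarded
color, forgotten after a below-threshold reward) and
*win-stay-lose-shift* (shifted to the opposite color instead). Their
option value is the proximity to the remembered color with unit gain —
the softmax temperature already sets its scale — giving the printed count
of 8 free parameters (threshold, 3 location biases, 2 size biases,
preferred-color gain and angle).

## Conventions and resolved ambiguities

* All angles are radians in \([-\pi, \pi)\); the wheel's zero is the
  arbitrary "red" anchor. Signed distance is
  \(d(\theta,\theta_0) = \mathrm{mod}(\theta - \theta_0 + \pi, 2\pi) - \pi\).
* Reward drops are rounded half-away-from-zero (the lay reading of
  "nearest unit"; the convention at exact .5 is otherwise unspecified).
* The reset sigmoid is oriented so that \(k \to 1\) when \(|\delta|\)
  *exceeds* the threshold, matching the mechanism's description.
* The reset clock starts at 1 at the session start: freshly zeroed
  weights are literally a reset state, so early-session resets are
  suppressed. Simulation and likelihood use the same convention, which
  is what matters for fitting.
* \((b, \theta_{\text{pref}})\) and \((-b, \theta_{\text{pref}} + \pi)\)
  produce identical choice probabilities (the proximity regressors differ
  by an additive constant). Fits are canonicalized to \(b \ge 0\).

# The task simulator

`run_session()` reproduces the study conditions: 100 evenly spaced
isoluminant colors, three stimuli at least \(\pi/6\) apart (rejection
sampling), three of four locations, reward
\(R(\theta) = \mathrm{round}(R_{\max} \cdot \text{vM}(\theta;
\text{template}, \kappa = 2.5))\) with \(R_{\max} = 6\) drops (an
escalating per-block scheme is available), an uncued template switch when
the best target was chosen on \(\ge 85\%\) of the last 30 trials (0.80 is
the other animal's setting) with a 35-trial minimum block length, and new
templates sampled with down-weighting near recent templates (window
\(\pi/4\), weight 0.2) so sessions cover the wheel. "Best" means closest
to the true template, ties to the lowest stimulus index. A size
perturbation (bigger/smaller) hits one stimulus on 5% of trials by
default (20% matches the other animal).

What the simulator does **not** emulate: broken fixations and aborted
trials (they carry no model information), within-trial timing and eye
kinematics, and session-to-session parameter drift. Passing tests on
synthetic sessions therefore demonstrates the correctness and
recoverability of the machinery under the model's own assumptions, not
the behavior of real animals.

## Generative defaults

The study's fitted per-animal parameter values are not available, so the
package fixes one "monkey-like" generative set and uses it everywhere:
\(\alpha = 0.3\), \(\kappa = 2\), \(\tau_0 = 0.3\) or \(0.5\),
volatility 0.02, location biases \((0, 0.1, -0.1, 0.05)\), size biases
\((0.1, -0.05)\), preferred- and previous-color gains 0.05. The bias
gains are deliberately small — the biases are described as having only a
marginal effect on choices, and 0.05 caps their contribution at roughly
5% of the value range. Volatility 0.02 was chosen because integer-drop
rewards give the prediction error an irreducible \(\pm 0.5\)-drop
rounding component: a faster-decaying threshold floods the model with
resets, while 0.02 keeps resets rare events clustered at template
switches, the regime the reset mechanism is meant to capture.

# Fitting

`fit_session()` maximizes the choice likelihood with the softmax
temperature fixed. The likelihood surface is extremely sharp in the
dynamics parameters (\(\alpha\), \(\kappa\), \(\tau_0\), volatility) —
small changes compound across the whole latent trajectory — and piecewise
constant in the reset threshold. A generic multi-start local optimizer
fails here, so the fit proceeds in three stages:

1. a coarse grid over the dynamics parameters with all biases at 0
   (the forward pass is ~1 ms for 3,000 trials, so the screen is cheap);
2. bounded quasi-Newton, a Nelder–Mead pass on a sinusoidal bound
   transform, and a final quasi-Newton polish from each of the best
   `n_starts` candidates (top grid cells, Latin-hypercube draws, and any
   warm starts — model comparison seeds each model with its nested
   neighbor's solution, e.g. Reset started from the fitted No Reset
   parameters with a high threshold);
3. a circular scan of \((b, \theta_{\text{pref}})\), whose shallow
   contribution otherwise strands gradient descent in a local optimum of
   the preferred angle.

Bounds follow the fitted ranges: biases in \([-10, 10]\),
\(\kappa = 10^\rho\) with \(\rho \in [-2.5, 2.5]\),
\(\alpha \in [0, 1]\), thresholds \(\ge 0\). Models are compared with
\(\mathrm{BIC} = k \ln n + 2\,\mathrm{NLL}\). The learning rate and basis
concentration trade off (a taller basis needs a smaller step), so their
individual recovery is poor while the estimated-template trajectory — the
quantity all neural analyses consume — is recovered with circular
correlation above 0.93–0.96 in the validation suite.

`recovery_experiment()` packages the generate-and-refit loop:
simulate choice sequences from known parameters, refit candidate
variants, and report BIC identification margins, template circular
correlations, and parameter errors.

# Synthetic neural populations

`generate_population()` draws trial × neuron × time-bin firing rates in
which each neuron follows one ground-truth encoding model mirroring the
single-neuron analyses: von Mises tuning to the estimated template or to
the chosen color, the tuned integral of the value function, its mean, a
per-location stimulus value or choice indicator, or nothing. The time
base is six 200-ms bins covering −600 to +600 ms around target onset
(the first bin serves as the pre-target baseline); a neuron's modulation
occupies a configurable latency/width window of bins. Noise is Gaussian
(σ = 1 on the z-scored scale) or Poisson.
`generate_hemifield_value_population()` is the fixture for the
local-to-global value transformation: before a configurable lag the
chosen-value code is a within-hemifield contrast (+w at the neuron's
receptive-field location, −w at the paired location, which cancels in a
location-agnostic regression); at the lag the loadings rotate onto a
shared global axis.

# Neural analyses

* **Encoding** (`fit_tuning_model()`, `encode_population()`): four
  competing single-neuron models fitted by cross-validated constrained
  least squares (10 random, seeded folds shared across models; 8 angular
  starts via a grid + polish; \(\beta\)s clipped to \([-10,10]\),
  \(\rho \in [-2.5, 2.5]\)). A neuron is sensitive if its mean validation
  \(R^2\) is positive; winners are mutually exclusive by highest mean
  \(R^2\). Whether the original folds were contiguous or random is not
  stated; random seeded folds are used.
* **Decoding** (`build_pseudopopulation()`, `decode_template_accuracy()`,
  `cross_generalization()`): balanced bootstrap pseudo-populations;
  one-vs-rest linear max-margin classifiers per color third (anchored at
  red = 0) with the regularization strength chosen by seeded inner grid
  CV — a reproducible stand-in for a Bayesian hyperparameter search —
  and sigmoid-calibrated posteriors; a small softmax network readout
  over the three posteriors, always reported next to the deterministic
  argmax accuracy; chance is 1/3 (multi-class) or 1/2 (binary).
* **Trial-wise template decoding** (`decode_trialwise_template()`): the
  first 35 trials of every block are withheld; a feedforward readout with
  one hidden layer of 10 rectified-linear units and 2 linear outputs
  maps the three posteriors to \((\cos, \sin)\) and the decoded angle is
  their atan2. The readout is hand-written (trained by BFGS with an
  analytic gradient) because no installed package provides a ReLU hidden
  layer with linear outputs. Accuracy is z-scored against a
  template-label permutation null; the signed update statistic
  \( \mathrm{sign}(\delta)\,\mathrm{sign}(d(ET, CC))\,d(ET_{n-1}, ET_n)\)
  is positive when the template moves toward the chosen color after a
  positive prediction error.
* **Value geometry** (`value_glm()`, `split_half_reliability()`,
  `disattenuated_alignment()`, `pca_geometry()`, `mds_embedding()`):
  per-neuron GLM weights on baseline-subtracted, per-bin z-scored rates;
  split-half reliability over 10 random disjoint splits with neuron
  bootstraps (5,000 by default) and one-sided z-tests, Bonferroni
  corrected over the configured number of time bins; disattenuated
  alignment \(\gamma = r_{XY} / \sqrt{r_{XX} r_{YY}}\) (the printed form
  of the disattenuation is garbled; the standard Spearman form is used),
  always across different halves, with bins of non-positive reliability
  masked rather than clipped. When a concatenated multi-location local
  vector (2N) is aligned with a global vector (N), the global weights are
  tiled per location. Effective dimensionality is the participation ratio
  \((\sum \gamma_i)^2 / \sum \gamma_i^2\); the embedding uses classical
  metric MDS with metric stress reported.

# Problem sizes

The validation suite runs at desk scale, chosen so the whole test suite
completes in tens of minutes on one CPU: 3 sequences of 3,000 trials per
generative condition for template/model recovery, 2 sequences of 29,874
trials for the win-stay-lose-forget rejection (each long fit is
warm-started from a fit to its first 5,000 trials and polished on the
full sequence — the rejection margin is hundreds of BIC nats, so the
economical search cannot change the conclusion), 20+ sequences for the
preferred-color recovery ensemble, and populations of tens of neurons
with a few hundred to ~1,000 trials for the neural-analysis property
tests. Bootstrap and permutation counts in tests are reduced
correspondingly (the defaults in the functions match the full-scale
analyses: 100 pseudo-populations, 5,000 bootstraps, 500–1,000
permutations).

A caveat on the preferred-color parameter: its likelihood contribution is
deliberately marginal, so the absolute circular error of the recovered
\(\theta_{\text{pref}}\) is information-limited and scales roughly as
\(1/\sqrt{n}\) in the sequence length. At the desk-scale 3,000-trial
sequences the per-fit error is several times larger than what
full-length (~30,000-trial) sequences support, and the ensemble median
of that error is noticeably seed-dependent; the recovery suite reports
it as computed rather than at full scale.

# Known limitations

* \(\alpha\) and \(\kappa\) are not individually identified (only their
  combination); parameter-level recovery claims are limited to the
  biases, the preferred color, and the template trajectory.
* The reset threshold enters the likelihood as a step function; its
  estimate is only as fine as the spacing of observed |RPE| values.
* Posterior uncertainty over parameters is out of scope: fitting is
  point maximum likelihood + BIC, not variational inference.
* The WSLF/WSLS option-value form (unit-gain proximity) is a
  reconstruction; the original form is not printed. Conclusions about
  those baselines are robust to this choice only insofar as they lose by
  enormous BIC margins, which is what the validation shows.
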