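---
title: "Estimating feed palatability with a threshold multiverse and the Bradley-Terry model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating feed palatability with a threshold multiverse and the Bradley-Terry model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaterry)
```

## The problem

Short-term paired-preference trials measure palatability behaviorally: an
animal is offered two feeds side by side and the dry-matter intake (DMI)
from each bin is recorded after a fixed interval. The prototypical layout
has 4 feeds, so 6 unordered pairs, each offered once to each of 12 subjects
over 6 occasions — 72 offerings in all, with left/right position
randomized. The analytic question is the direction *and degree* of
preference among the feeds, and whether any pairwise difference is
statistically credible at that sample size.

Two arbitrary processing choices sit between raw intakes and a conclusion:
how decisively one feed must dominate an offering before it is called
"preferred", and what to do with offerings that are not decisive. This
package treats the first choice as a *multiverse*: the identical analysis
is run at a grid of preference thresholds and the ensemble of results is
read jointly, instead of betting the conclusion on any single threshold.

## The two-step procedure

**Step 1 — win/loss/tie coding.** At threshold $t \in [0.5, 1)$, feed A
wins an offering when its share of the total intake, $s_A =
y_A/(y_A+y_B)$, satisfies $s_A \ge t$ and $s_A > \tfrac12$; feed B wins
symmetrically; every other offering — including one where nothing was
eaten — is a tie. Ties are *retained*, not dropped, so the number of
comparisons is identical in every branch. The default grid is
$t \in \{0.50, 0.60, 0.70, 0.80\}$. The tie fraction is non-decreasing in
$t$ by construction; reading it alongside the estimates shows how much
information each branch throws away.

**Step 2 — Bradley-Terry estimation.** Each feed $i$ carries a latent
palatability $\lambda_i$ on a log-odds scale, and the probability that $i$
is selected over $j$ in one comparison is

$$\Pr(i \succ j) = \frac{1}{1 + e^{-(\lambda_i - \lambda_j)}}.$$

A unit palatability advantage therefore means the better feed is selected
with probability $1/(1+e^{-1}) \approx 0.731$. One feed is designated the
reference and pinned at $\lambda = 0$; all other palatabilities are
log-odds relative to it, so negative values mean "less palatable than the
reference", not unpalatable in absolute terms. The model is fitted by
maximum likelihood; a tie enters the likelihood as half a win for each
order, i.e. a factor $p^{1/2}(1-p)^{1/2}$. This half-win device is the
standard way to keep non-decisive comparisons in a plain Bradley-Terry
likelihood; an explicit tie parameter (Davidson or Rao-Kupper model) is a
different model and out of scope here.

**Inference.** The covariance of the free parameters is the inverse
observed information. From the implied contrast variances
$v_{ij} = c_{ii} + c_{jj} - 2c_{ij}$ we compute *quasi-variances*: one
number $q_i$ per feed (the reference included) minimizing
$\sum_{i<j} \left[\log(q_i + q_j) - \log v_{ij}\right]^2$, so that
$\sqrt{q_i + q_j}$ is a pooled SE for any pairwise contrast. Pairwise
tests are Wald $z$-tests, $z = (\lambda_i - \lambda_j)/\sqrt{q_i+q_j}$,
against the normal distribution (the covariance is asymptotic, so no
$t$ degrees of freedom are claimed); confidence intervals are
$\lambda_i \pm z_{(1+\gamma)/2}\sqrt{q_i}$, drawn for every feed including
the reference, whose point estimate is pinned but whose uncertainty
relative to the others is not zero. A compact letter display
(insert-and-absorb) translates the $p$-matrix into letters such that two
feeds share a letter if and only if their test is non-significant at
$\alpha$.

For $K = 3$ the quasi-variance equations can be satisfied exactly; for
$K \ge 4$ they are an approximation, and `quasi_variances()` reports the
worst relative error of $q_i + q_j$ against $v_{ij}$ rather than hiding
it (on the balanced designs here it is typically well under 1%).
Quasi-variances can legitimately be negative; they are then flagged and
the corresponding quasi-SE is `NA`. No multiplicity correction is applied
across the 6 pairwise tests by default, matching the raw per-pair
$p \le 0.05$ letter criterion; `pairwise_tests(p_adjust = "holm")` is
available for users who want one.

**The ensemble.** `run_multiverse()` runs both steps at every threshold
with otherwise identical settings and `summarize_concordance()` counts,
per pair, the branches in which the test is significant and whether the
sign of the difference agrees across branches. No pooled cross-threshold
statistic is computed, deliberately: the ensemble is not a single formal
test, and collapsing it into one would misrepresent the method. A branch
whose fit fails — typically separation, when a high threshold leaves a
feed with no decisive losses or wins — is reported as failed with its
reason, never dropped silently.

## Numerical choices

- The optimizer is Newton's method on the $K-1$ free parameters, started
  at all-zero palatabilities (the symmetric point), with a minorization
  (MM) step as fallback whenever a Newton step fails to improve the
  log-likelihood. Convergence is declared at gradient max-norm
  $\le$ `tol` (default `1e-8`, `max_iter = 200`) — conventional for a
  smooth concave likelihood in at most a handful of parameters.
- Separation is flagged when any palatability exceeds 15 in magnitude or
  the information matrix is numerically singular; estimates are reported
  with the flag set rather than clamped.
- The quasi-variance objective is minimized over unconstrained $q$ (BFGS
  with analytic gradient), initialized at the linear least-squares
  solution on the $v$ scale; negative $q$ is permitted and flagged, as
  the quasi-variance methodology prescribes.
- Threshold boundary: a share exactly equal to the threshold counts as a
  win (`boundary = "ge"`). With continuous intakes the choice almost
  never matters; `boundary = "gt"` is provided so either convention is
  reproducible.
- An offering with zero total intake codes as a tie (behavioral
  indifference). Excluding such rows would silently change the
  comparison count across branches; `zero_total = "drop"` exists for
  sensitivity analysis.
- At $t = 0.5$ an exactly even split is a tie, not a double win: a win
  requires a strict majority in addition to attaining the threshold.

## Power analysis

`estimate_power()` is a Monte-Carlo wrapper around the same inferential
machinery. Each replicate draws every scheduled comparison as an
independent Bernoulli win with the Bradley-Terry probability of the true
palatabilities, fits the model, computes quasi-variances, and applies the
pooled quasi-SE $z$-test to the chosen contrast at $\alpha$. Simulated
outcomes contain no ties: the power statement is framed directly in terms
of the Bradley-Terry selection probability, which has no tie component.
Defaults are $\alpha = 0.05$ and 2000 replicates (Monte-Carlo SE about
0.011 near a power of 0.64). Replicates whose fit separates are excluded
from the denominator and counted; `failed = "nonreject"` treats them as
non-rejections instead, and a result with more than 20% failures is
flagged unreliable. Two reference configurations are exercised by the
test suite and the acceptance script:

- 4 feeds with palatabilities $(0, 0, 0, -1)$, 6 pairs $\times$ 12
  subjects (72 comparisons), testing the unit-difference pair: power
  around 64%.
- 3 feeds with palatabilities $(0, 0, -1)$ and the same 72 comparisons
  split evenly (24 per pair), again testing the unit-difference pair:
  power around 82%. The even split is the natural allocation when the
  total number of offerings is held fixed.

Under all-equal palatabilities the same machinery estimates the type-I
error, which the test suite checks against the nominal 0.05.

## The synthetic-trial generator

No public accession of the motivating trial's data is available, so the
generator emulates its statistical structure, and all pipeline-level
claims are validated against it:

- **Schedule**: every unordered pair once per subject, pairs assigned to
  occasions in random order, left/right position randomized. Defaults: 4
  items, 12 subjects, 72 offerings.
- **Offered amounts**: truncated normal, mean 2.64, SD 0.22, bounds
  [2.09, 2.99] kg DM per bin (the truncation bounds are the observed
  extremes, so the realized SD is slightly below 0.22).
- **30-min consumption**: the total eaten at an offering is gamma
  (right-skewed, effectively allowing near-zero intakes), capped at the
  total offered; its moments are derived internally so that *per-bin*
  intake has mean 0.48 and SD 0.40 kg DM at equal palatabilities.
- **Preference**: the split of the total between the two bins is a beta
  draw with concentration `share_precision` (default 3). The beta mean
  is calibrated, per pair, so that the probability of a feed taking the
  *majority* of the intake equals its Bradley-Terry selection
  probability. This is the design choice that makes the intake layer
  consistent with the model layer: majority-threshold coding of
  generated intakes recovers the true palatabilities (matching the mean
  share to the selection probability instead would bias the implied win
  probability — e.g. to 0.17 instead of 0.27 for a unit deficit at the
  default concentration — and the two calibrations coincide at equal
  palatabilities). The default concentration leaves roughly 40–50% of
  equal-palatability offerings non-decisive at the 70% threshold, a
  realistic middle ground for this kind of trial.
- **3-h intakes** (optional): the 30-min intake plus an independent
  gamma increment sized to give a correlation of about 0.89 with the
  30-min values. They exist to exercise I/O and that correlation
  property only; all analysis uses the 30-min intakes, which is the
  point the high correlation licenses.

What the generator does **not** emulate: subject-level preference
heterogeneity (that would need a mixed-effects Bradley-Terry model,
deliberately out of scope), acclimation or time trends in palatability,
and any dependence between offerings of the same subject. Passing tests
on synthetic data therefore demonstrate correctness of the machinery and
calibration of the procedure under independence, not robustness to those
real-data features.

## Problem sizes used in validation

The test suite fits the model on trials of 72 offerings (the default
design), checks tie-growth and letter-display invariants exhaustively for
4 items, verifies the estimator against a closed form (2 items), a dense
grid search with step $10^{-3}$ (3 items) and the exact linear solve of
the quasi-variance equations (3 items), and runs the three power/type-I
configurations at 2000 Monte-Carlo replicates each. End-to-end parameter
recovery uses a 600-subject (3600-offering) synthetic trial — 50 times
the default size — and requires the unit deficit to be recovered within
±0.15. Marginal intake statistics are checked within 15% at 72 offerings
and within 3% at 10,000.

## Known limitations

- Inference is asymptotic ($z$ tests) on 72 comparisons; the type-I
  simulation shows it is close to nominal for the balanced default
  design, but heavily unbalanced or sparse designs can separate, and the
  package flags rather than repairs that.
- The half-win tie device is a convention, not a tie model; at high
  thresholds, where over half the offerings tie, branches lean heavily
  on it (which is exactly the kind of fragility the multiverse display
  is meant to surface).
- Only the threshold choice is multiversed. Exclusion rules or the
  30-min vs 3-h choice could be handled the same way but are not built.
- Main effects and interactions of feed attributes, mixed-effects
  structure, and Plackett-Luce-style ranking models are out of scope.
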