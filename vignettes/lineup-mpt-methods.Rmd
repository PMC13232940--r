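---
title: "Measuring eyewitness lineup decisions with the 2-HT multinomial processing tree model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring eyewitness lineup decisions with the 2-HT multinomial processing tree model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineup2ht)
```

## The measurement problem

An eyewitness shown a lineup — one suspect among five appearance-matched
fillers — produces one of three observable responses: a suspect selection, a
filler selection, or a rejection of the whole lineup. Raw response rates
confound the latent processes behind them: a correct culprit identification
may reflect genuine detection of the culprit's presence, or a lucky guess, or
an unfair lineup that draws selections toward the suspect. Any claim about
*memory* therefore needs a measurement model that separates these processes.

The two-high-threshold (2-HT) eyewitness identification model is a
multinomial processing tree (MPT) model doing exactly that. It has four
parameters, each a probability of a latent process:

* `dP` — detection of the culprit's *presence* (culprit-present lineups only),
  which produces a culprit identification;
* `dA` — detection of the culprit's *absence* (culprit-absent lineups only),
  which produces a lineup rejection;
* `b` — biased suspect selection in the absence of detection: an unfair
  lineup makes the suspect stand out, drawing selections toward the suspect
  whether or not the witness remembers anything;
* `g` — guessing-based selection in the absence of detection and bias, which
  lands on the suspect with the random-sampling probability
  `c = 1 / lineup size` and on some filler with probability `1 - c`.

The category probabilities are sums of branch products. For a culprit-present
lineup,

$$
\begin{aligned}
P(\text{suspect}) &= d_P + (1-d_P)\,b + (1-d_P)(1-b)\,g\,c\\
P(\text{filler}) &= (1-d_P)(1-b)\,g\,(1-c)\\
P(\text{reject}) &= (1-d_P)(1-b)(1-g)
\end{aligned}
$$

and for a culprit-absent lineup the detection state flips to `dA`, which
produces a rejection rather than a selection:

$$
\begin{aligned}
P(\text{suspect}) &= (1-d_A)\,b + (1-d_A)(1-b)\,g\,c\\
P(\text{filler}) &= (1-d_A)(1-b)\,g\,(1-c)\\
P(\text{reject}) &= d_A + (1-d_A)(1-b)(1-g).
\end{aligned}
$$

`category_probs()` implements these equations; `mpt_model()` replicates the
two trees over experimental conditions with equality constraints (shared
parameters) and fixed constants.

```{r}
m <- mpt_model(c("combined", "separate"), equal = list(b = "all", dA = "all"))
m
```

## Parameters that matter, units, defaults

* `guess_split` (`c`): the probability that a guess lands on the suspect,
  `1 / lineup size`. For the packaged six-member-lineup studies it is stored
  as the literal `0.16667`, not `1/6`: the reference analyses fixed the
  constant at that printed approximation, and reproducing their fits to the
  last digit requires using the same number. It is configurable for other
  lineup sizes, and degenerate values 0 and 1 are rejected — a lineup whose
  guesses always or never hit the suspect has no suspect/filler distinction
  to model.
* Equality constraints: the standard testable base model equates `b` and
  `dA` across conditions of one experiment (same photographs, hence
  comparable lineup fairness; no reason for absence detection to differ).
  Substantive hypotheses are then tested by *adding* constraints.
* All four model parameters are probabilities in `[0, 1]`; free-parameter
  indices are assigned in the fixed order `dP`, `dA`, `b`, `g` by condition
  declaration order, so a fit is reproducible run to run.

## Estimation

`fit_mpt()` maximizes the pooled multinomial log-likelihood
$\sum_{\text{trees}} \sum_{\text{cells}} n \log p(\theta)$ over the unit box
with `L-BFGS-B`, using the exact analytic gradient (the tree probabilities
are multilinear in the parameters, so the gradient is closed form). Ten
starts are used by default — one at 0.5 everywhere, nine from a seeded
uniform draw — and the best solution is kept; the spread of maximized
log-likelihoods across starts is stored in the fit so that multimodality
would be visible rather than silent. On the packaged datasets all starts
agree to far better than `1e-8`.

Goodness of fit is the likelihood-ratio statistic
$G^2 = 2\sum n \log(n / N\hat p)$ over positive-count cells (zero cells
contribute zero, the `n log n` limit convention), with degrees of freedom
`cells − trees − free parameters` — each observed tree spends one sum-to-one
constraint. `G²` is referred to the upper χ² tail; a saturated model
(`df = 0`) is assigned `p = 1`.

Two numerical points deserve emphasis:

* **Bounds.** Optimization runs on `[1e-8, 1 - 1e-8]` with probabilities
  floored at `1e-300` inside the objective, so boundary-seeking parameters
  (e.g. a `dA` near 0) are handled without `NaN`s. Estimates within `1e-6`
  of a bound are flagged as boundary estimates.
* **A `df = 0` model need not fit perfectly.** With `c` fixed, the map from
  the four parameters to the two observed simplices is not surjective: some
  frequency tables have their exact solution outside the unit box, in which
  case the boundary MLE leaves `G² > 0` at zero degrees of freedom. The
  package reports this honestly (the fit is flagged as boundary) instead of
  forcing the saturated identity.

### Standard errors

Standard errors are square roots of the diagonal of the inverse *observed*
information: the central-difference Hessian (step `1e-5`) of the negative
log-likelihood at the MLE, with parameters within `1e-6` of a bound nudged
inward before differentiation. Observed information is the standard choice
for ML software; whether the reference software used observed or expected
information is not documented, so the convention here is validated against
the published standard errors at their two-decimal precision — all of them
match. Boundary parameters' standard errors are approximate, and a singular
information matrix degrades to `NA` standard errors with a warning while the
point estimates are still returned (a flat direction means the data simply
do not identify that parameter's precision).

## Hypothesis tests on latent processes

`test_equality()` compares a general model with a restricted one in which a
parameter is additionally equated across conditions:
$\Delta G^2 = G^2_{\text{restricted}} - G^2_{\text{general}}$, referred to
χ² with the difference in free parameters as degrees of freedom. The
restricted model is refitted from the full multi-start grid *plus* the
general solution projected onto the constraint (shared slots averaged); this
extra start removes the main failure mode of likelihood-ratio testing in
practice, a spuriously large ΔG² caused by a restricted fit stuck in a worse
optimum. A ΔG² below `−1e-6` raises an error rather than being clipped
silently, because a nested model genuinely beating its parent can only be an
optimization failure worth knowing about.

`test_grouped_vs_rest()` covers the focused one-degree-of-freedom layout:
after a preliminary homogeneity test justifies pooling a set of conditions,
the focal condition's parameter is tested against the pooled value. This
two-step sequence is implemented exactly as in the packaged second
experiment: first `dP` is equated across the three conditions where the
hypothesized cueing mechanism is theoretically impossible (ΔG² with 2 df),
the pooled model becomes the new base, and the focal condition is then
tested against the pool (1 df). The three-degree-of-freedom guessing
homogeneity test is run from that fully pooled model — that is the sequence
under which the published value arises; running it from the original base
model gives a (slightly) different, equally valid statistic, and the package
follows the published sequence.

## Sensitivity and power

For χ²-distributed tests, power against an effect of size Cohen's `w` is the
noncentral χ² upper-tail mass beyond the central critical value, with
noncentrality `λ = n_obs · w²`. `sensitivity_w()` inverts this for the
smallest detectable effect. The crucial convention — documented prominently
because power tools differ silently on it — is that `n_obs` is the **total
number of responses entering the test**, participants × responses per
participant when each participant answers several lineups, not the number of
participants. With four lineup responses per participant this convention
reproduces both packaged sensitivity analyses at their printed two decimals.
The noncentral distribution is evaluated with R's `pchisq(ncp = )`; the test
suite cross-checks it against an independent Poisson-mixture series oracle.

## The synthetic-data generator

`simulate_responses()` draws each condition's culprit-present and
culprit-absent counts as independent multinomial samples of size
`n_participants × lineups` from the tree probabilities — precisely the
independence assumption the pooled MPT analysis itself makes. The default
study configuration (`exp1_design()`) is the first packaged experiment's:
382 and 384 participants, two culprit-present and two culprit-absent
lineups each, true parameters at the fitted values
(`dP = .30/.28`, `dA = .05`, `b = .06`, `g = .44/.42`).

What the generator deliberately does **not** emulate: within-participant
dependence of the four responses (MPT practice pools them as independent;
four responses from one witness plausibly share person-level memory
quality), stimulus-level idiosyncrasies of particular faces or videos,
attention-check exclusions, and counterbalancing at the photograph level.
Passing recovery and calibration tests therefore shows that the estimation
machinery is correct *under the model's own sampling assumptions* — it
cannot show that pooled `G²` calibration survives participant-level
heterogeneity in real data, which is untested here.

`recovery_study()` wraps the simulate–fit loop: a master seed spawns one
sub-seed per replicate, per-parameter bias, RMSE (`RMSE² = bias² +
variance`, population variance, an exact identity), empirical vs.
model-based SE, and Wald coverage are reported, and replicate-level fit
failures are a recorded rate rather than an abort. Supplying a truth that
violates the fitted constraints flags the run as a deliberate
misspecification study.

```{r, eval = FALSE}
d <- exp1_design()
m <- mpt_model(c("combined", "separate"), equal = list(b = "all", dA = "all"))
recovery_study(d$truth, d$design, m, n_replicates = 200, seed = 2026)
```

## Reproducing the packaged experiments

`run_experiment1()` and `run_experiment2()` execute the full published
analysis sequences on the shipped frequency tables and compare every
statistic at its printed precision — two decimals for estimates, standard
errors and `G²`/ΔG², three for p-values, rounding half-up (ties away from
zero), since base R's banker's rounding would disagree on exact `.xx5`
boundaries. Full-precision values are retained alongside the rounded ones,
and `write_report()` serializes a byte-identical JSON report on repeated
runs.

```{r}
rep1 <- run_experiment1()
rep1$table
```

## Problem sizes and simulation choices

The validation studies run at sizes chosen to make their statistical claims
meaningful at interactive cost: parameter recovery uses 200 replicates of
the full first-experiment design (enough to resolve a bias of 0.02 against
Monte-Carlo noise of about 0.001–0.002), and type-I calibration of the
one-df equality test uses 1,000 null replicates (the 5% rejection rate is
then estimated with a standard error of about 0.7%). Simulation fits use
three optimizer starts plus the truth-collapsed start instead of the
default ten: these are well-conditioned interior problems on which the
multi-start grid was observed to agree to `1e-8`, and the extra starts buy
nothing but time. Fits reported in the reproduction path always use the
full ten starts.

## Known limitations

* Only the 2-HT lineup trees are implemented, replicated over conditions;
  this is not a general MPT engine with user-defined topologies.
* No Bayesian, hierarchical (latent-class/beta-MPT) or bootstrap machinery;
  frequentist pooled-data ML only, as in the reproduced analyses.
* Standard errors near the boundary are approximate; the packaged `dA`
  estimate of one experiment sits close to zero with an SE of similar
  magnitude, and the package flags rather than censors such cases.
* The independence assumption of pooling four responses per participant is
  inherited, not tested; the generator could be extended with
  participant-level parameter heterogeneity to probe it, but no reference
  value constrains such an extension.
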