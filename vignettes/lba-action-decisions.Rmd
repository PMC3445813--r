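---
title: "Accumulator models of voluntary action decisions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accumulator models of voluntary action decisions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and numerical procedures implemented in
`lbadecide`, the choices made where the design was genuinely open, and what
the synthetic-data tests do and do not establish.

## The task and the model

The package models a finger-tapping paradigm in which each trial either cues
one specific finger (a *specified action*) or offers three of the four
fingers (a *choice action*), with 25% null events interleaved. The previous
action trial's response defines four conditions: choice trials in which the
previous action is among the three valid options (*repetition-available*) or
excluded (*repetition-absent*, the baseline), and specified trials cueing
the previous action (*repetition*) or a different one (*non-repetition*).
Sessions have 1008 trials (504/252/252), a 2.4 s trial duration, a 1 s cue,
an exact 50/50 repetition split within each action-trial type, and never
more than four consecutive trials of the same type.

Behaviour is described by a linear ballistic accumulator (LBA) race. Each
valid action has an accumulator whose activation starts at an independent
uniform draw from $[0, c_0]$ and grows linearly at a rate drawn from
$\mathcal N(\mu_i, \sigma_i^2)$; the first accumulator to reach the
threshold $b$ triggers its action, and the response time adds a constant
non-decision time $t_0$. Accumulators with non-positive sampled rates never
finish; if no valid accumulator finishes within the trial deadline the trial
is an omission. The baseline parameterization has 11 free parameters
($\mu_{1..4}$, $\sigma_{1..4}$, $b$, $c_0$, $t_0$).

Units: rates are evidence units per second, $b$ and $c_0$ are evidence
units, $t_0$ and RTs are seconds. Thresholds must exceed the start range;
rate SDs are strictly positive.

## The design space

Six binary features define the constrained model family:

1. `f1` — start range $c_0$ varies by accumulator (action bias);
2. `f2` — threshold modulated by condition;
3. `f3` — mean rates modulated by condition;
4. `f4` — non-decision time modulated by condition;
5. `f5` — rates equal across accumulators in specified conditions;
6. `f6` — condition modulations apply to all active accumulators rather
   than only the one matching the previous action.

Condition modulation is multiplicative: one ratio per non-baseline condition
per modulated parameter, shared across accumulators and across
previous-action identities, so each modulated parameter adds three free
ratios. The baseline (choice repetition-absent) has an implicit ratio of 1.

The features are not mutually independent, and the exact dependency rules
are a design decision of this package. We adopt two rules. First, `f6` is
interpretable only when at least one of `f2`/`f3`/`f4` is on — a scope for
parameter changes presupposes changes. Second, `f5` is interpretable only
when `f3` is on: with rates shared across conditions, forcing equality
across accumulators *only in specified trials* would itself be a
condition-dependent rate change, contradicting `f3` being off. Under these
rules exactly 46 of the 64 flag combinations are meaningful. Ordering the
designs by feature count and then lexicographically by feature indices
anchors the family: design 1 is the all-off model and designs 2–5 are the
four singleton designs (start-range bias, threshold, rate, non-decision
modulation), so the rate-modulation model — the one of principal scientific
interest, in which only the repetition alternative's mean rate changes — is
design 4 with 14 free parameters. The rules are exposed in
`model_design(..., normalize =)` and tested against a brute-force
enumeration oracle.

Parameter accounting under `f5` is the one place the counting was genuinely
ambiguous: we implement `f5` as replacing the ratio-modulated per-finger
means in each specified condition with one free condition-specific rate
mean (−2 ratios, +2 means), so the count is unchanged relative to `f3`
alone and the count function is monotone in the feature flags. `f6` changes
scope only and adds no parameters. Nominal counts are reported throughout;
the LBA's scale non-identifiability (jointly rescaling $\mu$, $\sigma$,
$b$, $c_0$ preserves all predictions) is not subtracted, which is why
recovery checks target scale-free quantities (modulation ratios, $t_0$,
predicted quantiles) rather than raw rates.

## Fitting

Each participant's responded trials are summarized per condition by RT
quantiles at levels 0.1/0.3/0.5/0.7/0.9 (R type-7 linear interpolation;
the convention had to be fixed, the data do not pin it) and, for choice
conditions, selection counts. Selection categories are defined *relative to
the previous action* — repetition vs the non-previous valid fingers in
index order — because the modulation ratios are shared across
previous-action identities: pooled absolute-finger marginals would be blind
to repetition suppression, leaving the choice ratio unidentified.

The objective is the likelihood-ratio chi-square
$G^2 = 2\sum_i O_i \ln(O_i/E_i)$, summed over the six RT bins delimited by
the five observed quantiles (observed masses 0.1/0.2/0.2/0.2/0.2/0.1 of
responded trials) and the selection categories of choice conditions.
Expected proportions come from model simulation — 100,000 trials per
condition by default, conditional on response — floored at $1/(2 n_{sim})$
so simulation zeros cannot produce infinities; zero-observed bins
contribute nothing. Omitted trials are excluded on both sides, mirroring
the behavioural exclusion of non-responses.

Minimization is Nelder–Mead simplex with multiple restarts: each restart
draws 100 candidate parameter sets uniformly from documented ranges
($\mu \in [0.5, 5]$, $\sigma \in [0.2, 2]$, $b \in [0.5, 3]$,
$c_0/b \in [0.02, 0.9]$, $t_0 \in [0.05, \min \text{RT})$, ratios
$\in [0.3, 3]$) and starts the simplex from the best candidate. A single
simplex run is not trusted: in 11–14 dimensions the simplex frequently
collapses and reports convergence far from a minimum, so within each
restart the simplex is re-initialized from its own endpoint until the
improvement falls below the relative tolerance of $10^{-4}$ or the
restart's total function-evaluation budget (10,000 by default, matching
the iteration cap) is spent. 20 restarts by default; the lowest final
$G^2$ wins. Parameters are optimized on an
unconstrained scale (logs for positive quantities; logistic transforms keep
$c_0 < b$ and $t_0$ below the fastest observed RT), so the simplex can
never step outside the invariant domain; the one remaining joint
constraint — threshold modulation must not push an effective threshold into
the start range — is enforced by a large penalty value the simplex can
traverse.

Because the objective is simulation-based, each restart fixes one set of
standardized random variates (standard normals and uniforms) and reuses it
for every objective evaluation: the candidate parameters scale and shift
the same draws, so the simplex sees a fixed deterministic surface (common
random numbers). Without this the simplex chases simulation noise and stall
detection is meaningless.

Fits are scored by the multinomial-deviance form
$\mathrm{BIC} = G^2 + k \ln n$, with $k$ the nominal free-parameter count
and $n$ the participant's responded trial count; group-level comparison
sums BIC over participants and ranks designs, with ties broken by fewer
parameters then design index. Post-hoc comparisons use the exact sign test
(doubling rule, zeros dropped) and the one-sample Wilcoxon signed-rank test
(zeros dropped, midranks for ties, exact signed-rank distribution for
$n \le 25$ without ties, otherwise a normal approximation with tie and
continuity corrections).

## Expected accumulated activity

For model-based fMRI the package computes, per responded trial, the
expected area under all valid accumulators' trajectories up to the decision
time $T = t - t_0$. Every accumulator starts on average at $c_0/2$. The
winner reached its threshold exactly at $T$, so its expected rate is
$E[\tilde\mu_W] = (b - c_0/2)/T$ and its area is the trapezoid
$\tfrac12 (b + c_0/2)\, T$. A loser's sampled rate lies below the winner's
realized rate, giving an upper-truncated normal with expectation
$\mu_L - \sigma_L\, \phi(z)/\Phi(z)$, $z = (E[\tilde\mu_W] - \mu_L)/\sigma_L$,
evaluated in the log domain so deep truncation ($z \ll 0$) stays stable.
Each loser's area is the signed integral of its expected linear trajectory,
$(c_0/2)\,T + \tfrac12 E[\tilde\mu_L]\, T^2$ — signed, because the truncated
expectation can be negative; such trials are flagged rather than floored,
since flooring would silently change the regressor's distribution. The
trial EAA sums the winner and loser areas; specified trials have one valid
accumulator and reduce to the winner term. Trials whose RT does not exceed
the fitted $t_0$ (possible because $t_0$ is fit per participant) are
excluded and counted, not zeroed. Each trial uses its condition-specific
effective parameters, including the ratio on the repetition accumulator.

The closed forms are pinned by two oracles in the test suite: numerical
quadrature of the expected trajectories (agreement to $10^{-8}$ over 1000
random parameter/RT draws) and rejection sampling of the truncated normal
($10^{-3}$ at $10^7$ draws). For the fMRI export, `residualize_eaa()`
projects the EAA on an intercept and single-trial RT and returns the
residual, and `write_events_tsv()` writes BIDS-style events with `eaa` and
`eaa_residual` as (optionally mean-centered) parametric modulators; HRF
convolution and GLM estimation are left to standard fMRI software.

## Synthetic data and recovery

`generate_session()` builds the task sequence by constrained sequential
sampling (types drawn proportionally to remaining counts, a type barred
once it has run four in a row, bounded restarts on dead ends) and assigns
exact repetition splits. The repetition relations depend on the *realized*
previous response, which for choice trials is unknown until behaviour is
simulated; the session therefore carries a self-consistent provisional
chain built with uniform-random placeholders, and `generate_behavior()`
re-derives every valid set and cue from the actual simulated responses
while preserving the planned condition labels. The first action trial has
no previous action; it receives a uniformly drawn pseudo-previous action,
is flagged, and is excluded from condition summaries. Omitted trials leave
the previous-response state unchanged. An omission rate above 35% of action
trials triggers the participant-exclusion warning.

The generator's default conditions are the study conditions: 1008 trials,
50/25/25 composition, 2.4 s deadline. The default generating parameters
($\mu = 1.5$, $\sigma = 0.5$, $b = 1$, $c_0 = 0.3$, $t_0 = 0.2$ s) were
chosen once to produce realistic behaviour — median RTs near 0.6 s,
omissions well under 1% — and the default modulation ratios (0.7 for the
choice repetition accumulator, 1.3/1.15 for specified repetition and
non-repetition) reproduce the qualitative pattern of interest: repetition
suppressed to roughly 20% against the 33.33% chance level, and faster
specified than choice responses. Recovery experiments jitter each synthetic
participant's rate means log-normally (SD 0.1) and $t_0$ normally (SD
0.02 s, truncated at 0.05 s) around the group truth, because the reference
procedure fits individuals, not a group average.

What passing recovery shows — and what it does not: synthetic behaviour is
exactly LBA-generated, stationary, and lag-1 Markov in its history
dependence. Real behaviour has commission errors (excluded, not modeled),
slow drifts of attention, longer-range sequential effects, and
non-stationary parameters; recovery on synthetic data validates the
estimation machinery, not the model's adequacy for any particular
participant.

## Problem sizes and numerical choices

The test suite and the analysis scripts run a desk-scale version of the
procedure: predictions from 20,000 simulations per condition and 5 restarts
(instead of 100,000 and 20), evaluation budgets of 3000 per restart for
parameter recovery and 1200 for the model-recovery sweep, 16 synthetic
participants for parameter recovery, and model recovery over designs
{1, 3, 4, 5} with 4 participants per cohort and 3 replicate cohorts. These
sizes are the package's desk-scale choices; the full-scale settings remain
the `fit_config()` defaults.

At the desk scale the recovered choice repetition ratio is biased downward
(median recovered ratio roughly 0.58–0.63 for a generating ratio of 0.7).
The bias is a property of the quantile-$G^2$ objective at this resolution,
not of the optimizer: the five RT quantiles leave the non-decision
time/shape trade-off weakly constrained, the fitted $t_0$ drifts toward
its upper bound (the fastest observed RT), the compensating increase in
relative rate noise dilutes selection differences, and a lower repetition
ratio is then needed to match the observed repetition frequency. Deeper
optimization lowers $G^2$ further but does not remove the drift, which is
why the recovery target is a ±0.15 band around the truth rather than
unbiasedness, and why recovery additionally checks the directional claim
(ratio below 1).

Other fixed numerical choices: empirical quantiles are type 7; the
objective's proportion floor is $1/(2 n_{sim})$; the penalty value for
infeasible parameter regions is $10^8$; random-number streams are derived
from the user seed by a documented integer map so every artifact
(sessions, behaviour, restarts, predictions) is reproducible bit-for-bit
from `(spec, params, seed)`.

## Known limitations

* The likelihood is approximated through quantile bins and selection
  categories; parameters that move probability within a bin are invisible
  to the objective.
* Nominal parameter counts ignore the LBA scale invariance, so BIC
  penalties are conservative for all designs equally; comparisons between
  designs are unaffected, absolute BIC values are not interpretable.
* The exact dependency rules generating the 46-design family, the `f5`
  accounting, and the Fig-4-style ordering beyond the anchored indices are
  package conventions; alternative conventions would renumber the
  non-anchored designs.
* Commission errors are flagged and excluded, never modeled.
* The sign test and signed-rank test follow the stated zero/tie
  conventions; other conventions (e.g. Pratt's zero handling) would give
  slightly different p-values near zero-heavy samples.
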