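---
title: "Valuing healthcare resource reallocations on the decision-making plane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing healthcare resource reallocations on the decision-making plane}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmplane)
```

## The decision problem

A healthcare decision maker with a fixed budget wants to fund a new program
A in place of its current alternative a. The additional resources
ΔC(A) = C_A − C_a must come from somewhere: an existing program B is
cancelled and replaced by a cheaper alternative b, releasing
ΔC(B) = C_B − C_b at a health cost of ΔE(B) = E_B − E_b. The reallocation
is an unambiguous improvement when ΔC(A) ≤ ΔC(B) (non-strict: breaking even
on resources is acceptable) and ΔE(A) > ΔE(B) (strict: there must be a real
health gain). This rule needs no cost-effectiveness threshold and makes no
divisibility or constant-returns assumptions about programs; it simply
compares what is gained with what is given up. `check_reallocation_rule()`
applies it; threshold/ICER-style rules are deliberately out of scope.

The **decision-making plane** displays the result: net effects
ΔE(A) − ΔE(B) on the horizontal axis, net costs ΔC(A) − ΔC(B) on the
vertical. Quadrant I (southeast: health gain, cost saving) is the efficient
region; II (southwest) and III (northwest) entail net health losses; IV
(northeast) gains health but exceeds the available resources.

All monetary amounts are carried in thousand USD, matching the scale on
which program budgets are typically tabulated; effects are in life years.
The scenario container holds exactly one funded/displaced pair (A/a) and
one cancelled/replacement pair (B/b) — the simplest complete reallocation;
wider portfolios can be analysed by summing increments into these slots.

## Uncertainty propagation

Program costs and effects are uncertain. Each program is modelled as a
bivariate normal — justified by the central limit theorem for program-level
totals — with means, SDs, and a within-program cost–effect correlation ρ
(default 0.5: better outcomes tend to cost more). Programs are mutually
independent; nothing is truncated, so sampled costs can in principle go
negative, exactly as the plain-normal model implies.

`sample_program()` draws via the closed-form 2×2 Cholesky transform
(C = μ_C + σ_C z₁, E = μ_E + σ_E(ρz₁ + √(1−ρ²) z₂)), which is exact for
normals and remains exact in the degenerate cases σ = 0 and |ρ| = 1.
`sample_dmp()` seeds a single RNG stream once and draws the programs in the
fixed order A, a, B, b, so a seed fully determines every downstream result.
The default simulation size is 10,000 draws, large enough that quadrant
proportions carry binomial standard errors of about half a percentage point.

Because the four programs are independent, the net outcome is itself
bivariate normal with variances equal to the *sum* of the four programs'
variances on each axis, and pooled correlation
ρ_net = Σ_j ρ_j σ_Cj σ_Ej / (σ_E σ_C). `dmp_moments()` computes these
exactly, and `quadrant_probabilities()` integrates the bivariate normal
over the four regions bounded by the plane's axes. The integration limits
are the axes *on the original scale* — in standardized coordinates
−μ_E/σ_E and −μ_C/σ_C — because the quadrants are defined by where net
costs and net effects change sign, not by the standardized origin. The
rectangle CDF is evaluated by one-dimensional quadrature of
φ(x)Φ((k−ρx)/√(1−ρ²)) with `stats::integrate()` (absolute error well below
1e−8); tests pin it to the closed forms Φ₂(0,0,ρ) = 1/4 + asin(ρ)/2π and
Φ(h)Φ(k) at ρ = 0, and to the Monte-Carlo proportions across randomized
scenarios. If one axis has zero total variance the orthants collapse to
univariate normal probabilities.

Boundary convention: a draw with net effect exactly 0 counts as "no gain"
(Quadrants II/III) and net cost exactly 0 as "saving" (I/II). This is
measure-zero for continuous inputs but makes classification deterministic
for degenerate scenarios. Credible ellipses (`credible_ellipse()`) are the
exact normal density contours: semi-axes √(λ_i q) with λ_i the covariance
eigenvalues and q the χ²(2) quantile of the level.

## Portfolio risk

Two reallocations can induce *identical* net-outcome distributions — the
net variances sum over all four programs — while differing in what they do
to the funded portfolio {A, b} versus {a, B}. The built-in
`demo_scenario("variance_decreasing")` and `("variance_increasing")` pair
is exactly such a mirror: same means everywhere, SD patterns swapped. A
risk-averse decision maker prefers the tighter portfolio, so the package
reports the change separately from the plane itself.

The directional verdict uses the exact parameter variances
(σ²_CA + σ²_Cb < σ²_Ca + σ²_CB, and the effect analogue): these are
statements about the scenario, not about a finite sample. The *magnitude*
is described by the quartile coefficient of dispersion
QCD = (Q3 − Q1)/(Q3 + Q1) of the portfolio's summed costs and effects,
computed from the same draws as the rest of the analysis. The QCD is
scale-invariant and robust to skew and tails (unlike the coefficient of
variation); quartiles use the standard linear-interpolation estimator
(`stats::quantile()` type 7 — any mainstream estimator agrees to well
within Monte-Carlo error at these sizes). For a normal portfolio the
population value is 0.6745·σ/μ, which the tests use as an independent
oracle for the sampled QCDs.

## The value function

Not every point in a quadrant is equally good or bad. The valuation maps
quadrant-specific gain and loss functions over the plane, applied to net
outcomes rescaled to commensurate units — by default costs per USD 10
million and effects per 10 life years, chosen so a "unit" on either axis is
a comparably consequential amount; without rescaling the monetary numbers
would dominate any power function. Rescaling never moves a point between
quadrants.

With x the rescaled net effect and y the rescaled net cost:

| Quadrant | gain | loss |
|---|---|---|
| I (SE) | \|y\|^(α₂β₁) + \|x\|^(α₁β₁) | 0 |
| II (SW) | \|y\|^(α₂β₁) | \|x\|^(α₁β₂) |
| III (NW) | 0 | \|y\|^(α₂β₂) + \|x\|^(α₁β₂) |
| IV (NE) | \|x\|^(α₁β₁) | \|y\|^(α₂β₂) |

α₁ and α₂ (> 0, default 2) shape how value accrues with distance from the
origin and encode the decision maker's risk attitude; β₁ and β₂ (> 0,
default 1) adjust gains and losses for the change in portfolio risk and
compose multiplicatively in the exponent. β₁ = β₂ = 1 recovers the
unadjusted α-only value function exactly. The mapping from a measured risk
change to numeric β values is a preference to be elicited from the decision
maker, not something the package computes; the demonstrations use
β₁ = 1.1, β₂ = 0.9 for a variance-decreasing reallocation and the reverse
for a variance-increasing one. Separate per-axis factors (β₁C, β₁E, β₂C,
β₂E) are supported for decision makers whose cost and effect risk attitudes
differ; they default to the shared values.

`expected_net_gain_loss()` aggregates quadrant by quadrant — conditional
mean times quadrant proportion, summed — which is algebraically the grand
per-draw mean; the decomposition is reported because the per-quadrant
contributions are themselves informative. Expected net gain and net loss
are reported separately rather than netted, since a risk-averse decision
maker may weigh them asymmetrically.

```{r valuation}
s <- sample_dmp(demo_scenario("variance_decreasing"), n = 10000, seed = 42)
expected_net_gain_loss(s, value_function_params())
expected_net_gain_loss(s, value_function_params(beta1 = 1.1, beta2 = 0.9))
```

## Design notes and numerical choices

- **Shared draws across β settings.** Valuations under different β reuse
  one sample set per scenario, so β comparisons are free of independent
  Monte-Carlo noise.
- **Determinism.** `run_full_analysis()` with a fixed seed is bit-for-bit
  reproducible; the report records `n` and `seed`.
- **Degenerate inputs.** Zero-SD programs sample as point masses; an
  all-degenerate scenario reproduces the deterministic analysis draw by
  draw. Zero variance on a net axis flags the net correlation as undefined
  and falls back to univariate probabilities. A QCD with Q1 + Q3 = 0 is an
  error, and a singular covariance has no credible ellipse.
- **Problem sizes.** Documented analyses and tests use 10,000 draws — the
  scale at which quadrant proportions are stable to ~0.5 percentage points
  — and property suites cross-check the simulator against the analytic
  orthants on 50 randomized scenarios at the same size.

## What the built-in scenarios do and do not show

The packaged scenarios are synthetic: four normal programs with a common
ρ = 0.5 and mirrored SD patterns, constructed so that the deterministic
rule verdict, the quadrant split, the dispersion table, and the valuation
all have known expected values. Passing tests therefore demonstrate
correctness of the propagation, integration, dispersion, and valuation
machinery — not that real program costs are normal, independent across
programs, or known without estimation error. In applications, program
parameters are usually *estimated*; the additional sampling variation in
those estimates inflates the credible ellipses and shifts quadrant
probabilities, and is not modelled here. Non-normal program distributions
and the elicitation of actual decision-maker preference functions (α, β)
are likewise outside the package's scope.
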