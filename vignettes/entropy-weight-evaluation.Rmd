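---
title: "Entropy-weight evaluation of water-fertilizer trials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-weight evaluation of water-fertilizer trials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewmtrial)
```

## The decision problem

A factorial irrigation × fertilization trial produces several replicate
plots per treatment and, after a season, a handful of indicators per
scheme: marketable yield, fruit sugar/acid ratio (SAR), irrigation water
use efficiency (IWUE), plough-layer salinity, and soil available N, P and
K. No scheme is best at everything — the scheme with the sweetest fruit is
rarely the highest-yielding — so choosing "the best" scheme is a
multi-criteria decision problem. `ewmtrial` implements the entropy weight
coefficient model for this choice, together with the classical
significance machinery (two-factor ANOVA, Duncan letter groups) used to
describe the same trials.

## The model

Let $R = (r_{ij})_{m \times n}$ collect $m$ schemes by $n$ indicators,
all entries strictly positive. Each indicator is either *benefit*
(larger preferred: yield, SAR, IWUE, nutrients) or *cost* (smaller
preferred: salinity).

1. **Shares.** $p_{ij} = r_{ij} / \sum_i r_{ij}$ — each indicator viewed
   as a distribution over schemes.
2. **Entropy.** $E_j = -\sum_i p_{ij} \ln p_{ij}$, with the limit
   convention $0 \ln 0 = 0$; scaled $e_j = E_j / \ln m \in [0, 1]$.
3. **Objective weights.** $\theta_j = (1 - e_j) / \sum_j (1 - e_j)$. An
   indicator that is nearly constant across schemes has $e_j \to 1$ and
   gets weight $\to 0$: it cannot inform the choice.
4. **Weight fusion.** With subjective weights $w_j$ supplied by the
   analyst, $\alpha_j = \theta_j w_j / \sum_j \theta_j w_j$.
5. **Normalization.** $d_{ij} = r_{ij}/r_j^*$ for benefit indicators
   ($r_j^* = \max_i r_{ij}$) and $d_{ij} = r_j^*/r_{ij}$ for cost
   indicators ($r_j^* = \min_i r_{ij}$); the per-indicator optimum scores
   exactly 1, ties included.
6. **Evaluation.** $\lambda_i = \sum_j \alpha_j d_{ij} \in (0, 1]$, with
   $\lambda_i = 1$ exactly when scheme $i$ is optimal in every indicator;
   schemes are ranked by descending $\lambda$.

The chain is invariant to rescaling any indicator column by a positive
constant (shares and normalized scores are ratios) and equivariant under
scheme permutations; these properties are enforced by randomized tests
against a loop-based transcription of the equations.

### Assumptions and scope

The model assumes a complete positive matrix — positivity is required both
by the entropy logarithm and by the cost normalization — and weights
additively with no interaction between indicators. It makes no
distributional assumption; uncertainty in the means that enter the matrix
is the business of the ANOVA stage, not of the ranking itself. No other
multi-criteria method (TOPSIS, AHP, grey relational analysis) is
implemented.

### Numerical and design choices

- **Entropy on raw shares.** The entropies are computed on shares of the
  *raw* values by default, the form the model equations state. Part of the
  literature computes them on the direction-normalized scores instead;
  `ew_evaluate(..., entropy_on = "normalized")` exposes that variant
  explicitly rather than hiding the choice. The two can differ materially
  when cost indicators are present.
- **Subjective weights renormalized on input.** Published weight tables
  are rounded (a 7-vector of 0.200/0.067 entries sums to 1.001); vectors
  are rescaled to unit sum with a message, keeping the $\sum \alpha = 1$
  invariant exact.
- **Fusion with rounded inputs.** Re-deriving comprehensive weights from
  *printed* (3-decimal) objective and subjective vectors can move a
  component by up to one unit in the third decimal relative to values
  fused from full-precision inputs; tests therefore compare such
  reproductions at $10^{-3}$ per component.
- **Ties.** All column optima score $d = 1$; ranking ties within an
  absolute $10^{-9}$ keep input order and set a flag instead of silently
  picking a winner.
- **Precision.** JSON output is full double precision; 3-decimal rounding
  is applied only in the human-readable report.
- **Degenerate inputs.** A matrix whose every column is constant has no
  discriminating information and is rejected (the $\theta$ denominator
  would vanish), as are non-positive entries, missing directions and
  missing indicator values — nothing is imputed.

## Trial statistics

The factorial arms are analysed with the classical balanced two-factor
fixed-effects ANOVA with interaction, fitted via `stats::aov`. The control
arm is excluded from the factorial fit — a conventional-practice arm using
a different fertilizer type is not a cell of the factorial — and appears
only in the letter display, fitted one-way across all schemes. Incomplete
factorials and single-replicate cells are rejected; no unbalanced-design
sums of squares are attempted. Significance classes follow the field
convention (`**` p < 0.01, `*` p < 0.05, `ns` otherwise).

Duncan's multiple range test uses, for a span of $k$ ordered means, the
critical range $q_{\alpha_k, k, \nu} \sqrt{\mathrm{MSE}/n}$ with
protection level $\alpha_k = 1 - (1-\alpha)^{k-1}$ on the studentized
range distribution (`stats::qtukey`). Letters come from the standard
overlapping-bar sweep over the descending means: maximal stretches of
mutually non-significant means each receive a letter, contained stretches
are dropped, so two schemes share a letter exactly when they do not differ
at level $\alpha$. Unequal group sizes are handled with the harmonic mean,
the standard Duncan practice. Critical ranges are non-decreasing in span,
and the letter assignment depends only on the means and the error
estimate, not on input order — both property-tested. The reference letter
fixtures were cross-checked once against an independent
studentized-range implementation and frozen.

Because the test statistics depend on replicate-level variation that a
published trial summarises away, the package makes no attempt to
reproduce any specific published F table; calibration is established
instead by simulation (type-I error within the binomial band of the
nominal 0.05 over 2,000 null trials; uniform null p-values).

## What the synthetic generator emulates — and what it does not

`trial_design()` describes a 3 × 3 factorial (drip irrigation quotas
150/180/210 m³/ha per event, 21 events; organic fertilizer 2,800/3,600/
4,400 kg/ha) with 3 replicates and an optional control arm, the layout of
the motivating tomato trial. Each indicator follows a linear response
surface on coded factor levels (intercept, irrigation slope, fertilizer
slope, interaction) with independent Gaussian plot noise. Defaults were
fixed once to span the ranges such trials report — yields ~90–120 t/ha,
SAR ~8–10, plough-layer salinity ~1.7–2.5 g/kg, available N/P/K around
140–170 / 17–20 / 118–141 mg/kg — with noise SDs of the magnitude of the
replicate SDs in published nutrient tables (e.g. 3 t/ha for yield, 6
mg/kg for N). Control-arm means are specified directly rather than
extrapolated from the surfaces, since the control uses a different
fertilizer type.

Two deliberate realism constraints: raw plot fields are generated, not
indicator values — total and BER yield are reconstructed from the drawn
marketable yield and incidence, sugar from the drawn SAR at a fixed acid
content of 0.45 % — so derived-indicator identities (IWUE exactly equals
yield over seasonal water) hold in synthetic data by construction; and
draws that would be non-positive are floored at a small positive value
with a message (unreachable under default noise, but it keeps extreme
designs valid inputs).

What the generator does **not** emulate: correlated noise between
indicators (plots good for yield are often good for IWUE beyond the
structural link), nonlinear/plateau dose responses (a linear surface puts
optima at design corners, whereas real yield can peak at the middle
irrigation level), spatial field effects, and any soil-water/salt
transport dynamics. Passing tests therefore demonstrate that the
*pipeline* recovers known ground truth — surfaces at zero noise, dominant
treatments under low noise, nominal type-I error under the null — not
that real trials satisfy these idealisations.

## The benchmark fixture

`benchmark_matrix()` reconstructs the 10 × 7 decision matrix of the
motivating trial. Cells published in the source (the full available-N/P/K
table; the optimal scheme's yield, SAR and IWUE; the control yield; the
minimum plough-layer salinity) are carried as reported; the control's SAR
and IWUE are derived from reported percentage gains; every other cell is a
synthetic stand-in chosen once to respect the trends the trial describes.
A `provenance` attribute flags each cell `reported`, `derived` or
`synthetic`. The fixture supports regression expectations — evaluating it
must rank I2F3 first — but its synthetic cells are never treated as
published ground truth.

## Problem sizes used in the test suite

Randomized checks run at fixed seeds with: 200 small matrices (≤ 4 × 4,
small-integer entries) for oracle equivalence at $10^{-12}$; 40 matrices
for scale invariance and permutation equivariance; 100 seeded trials for
dominance recovery; 2,000 null simulations of the 3 × 3 × 3 ANOVA for
type-I calibration; 400 simulations for the null p-value uniformity
(Kolmogorov–Smirnov) check. These sizes give comfortable statistical
resolution (the 3σ binomial band at 2,000 draws is ±1.5 percentage
points) while keeping the default suite fast.

## Known limitations

- Entropy weighting reflects dispersion in the *given* matrix: adding or
  removing a scheme changes the weights, so rankings are comparable only
  within one matrix.
- The fused weights inherit the subjectivity of $w_j$; the package takes
  them as input and provides no elicitation.
- The ANOVA machinery is strictly balanced fixed-effects; no mixed
  models, repeated measures, or unbalanced Type-II/III sums of squares.
- Duncan's test controls per-comparison error at protected levels, not
  the family-wise rate; it is reported because it is the display
  convention of this literature, not because it is the most conservative
  choice.
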