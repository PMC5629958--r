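# ewmtrial

Decision analysis for replicated factorial **water–fertilizer field
trials**, built around the **entropy weight coefficient model**. The package
is aimed at agronomists and irrigation researchers who run drip-irrigation ×
fertilization experiments (the motivating case is a greenhouse tomato trial
with three irrigation quotas × three organic-fertilizer amounts plus a
conventional-practice control) and want a reproducible path from plot-level
replicate measurements to a defensible "best scheme" decision.

## What it computes

**Agronomic indicators** per plot and per scheme:

- blossom-end rot (BER) incidence = 100 · BER yield / total yield (%)
- marketable yield = total − BER yield (t/ha)
- fruit sugar/acid ratio (SAR), mean of per-layer ratios
- irrigation water use efficiency IWUE = 1000 · yield / (quota · events) (kg/m³)
- plough-layer salinity and available N/P/K (pass-through soil measurements)

**Trial statistics**: balanced two-factor fixed-effects ANOVA with
interaction (control arm excluded — it is not a factorial cell), and
**Duncan's multiple range test** letter groups, using span-`k` critical
ranges `q(α_k, k, df_err)·√(MSE/n)` with Duncan's protection levels
`α_k = 1 − (1 − α)^(k−1)` on the studentized-range distribution.

**Entropy-weight evaluation.** For an `m × n` decision matrix `R = (r_ij)`
of schemes × indicators (all positive):

- column shares `p_ij = r_ij / Σ_i r_ij`
- Shannon entropy `E_j = −Σ_i p_ij ln p_ij`, scaled `e_j = E_j / ln m`
- objective weights `θ_j = (1 − e_j) / Σ_j (1 − e_j)` — indicators that
  discriminate between schemes weigh more
- comprehensive weights `α_j = θ_j w_j / Σ_j θ_j w_j`, fusing the
  decision-maker's subjective weights `w_j`
- direction-aware normalization `d_ij = r_ij / max_i r_ij` (benefit) or
  `min_i r_ij / r_ij` (cost), so the best scheme per indicator scores 1
- evaluation values `λ_i = Σ_j α_j d_ij ∈ (0, 1]`; the highest λ wins

A **synthetic-trial generator** with linear per-indicator response surfaces
and Gaussian plot noise provides ground-truthed data for every stage.

## Worked example

```r
library(ewmtrial)

trial <- generate_trial(trial_design(), seed = 42)   # 10 schemes x 3 plots
agg   <- aggregate_indicators(trial)

two_way_anova(derive_indicators(trial), "marketable_yield")
#> Two-way ANOVA of marketable_yield
#>   effect df     F        p signif
#> 1      I  2 48.08 6.02e-08     **
#> 2      F  2 64.84 5.93e-09     **
#> 3    I:F  4  1.57 2.24e-01     ns
#> Error df: 18  MSE: 8.211

ew_evaluate(scheme_matrix_from_indicators(agg),
            subjective = c(0.2, 0.2, 0.2, 0.2, 0.067, 0.067, 0.067))
#> Entropy-weight evaluation (10 schemes, 7 indicators; entropy on raw values)
#>
#> Weights:
#>               marketable_yield   sar  iwue salinity avail_n avail_p avail_k
#> subjective               0.200 0.200 0.200    0.200   0.067   0.067   0.067
#> objective                0.117 0.248 0.197    0.283   0.042   0.088   0.025
#> comprehensive            0.131 0.277 0.220    0.315   0.016   0.033   0.009
#>
#> Evaluation values (descending):
#>  I3F3  I1F3  I2F3  I2F2  I1F2  I3F2  I1F1  I2F1  I3F1    CK
#> 0.911 0.904 0.895 0.865 0.860 0.853 0.815 0.794 0.792 0.722
```

Both factors raise yield highly significantly with no interaction; the
entropy weights concentrate on the indicators that actually separate the
schemes in this draw (salinity, SAR, IWUE), and the high-fertilizer arms
top the ranking while the conventional control comes last. One call,
`run_full_analysis(trial, out_dir = "out")`, writes the scheme CSV (with
Duncan letters per indicator), ANOVA JSON, full-precision evaluation JSON
and a Markdown report.

`benchmark_matrix()` ships a 10 × 7 benchmark matrix anchored to the
published cells of the motivating tomato trial (nutrient table, optimal
scheme's yield 122.4 t/ha / SAR 9.2 / IWUE 32.4 kg/m³, control yield
95.6 t/ha, minimum salinity 1.66 g/kg), with all unpublished cells flagged
as synthetic stand-ins; evaluating it ranks I2F3 (180 m³/ha × 4,400 kg/ha)
first, matching the published conclusion.

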