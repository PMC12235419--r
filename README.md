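# biolumin

Model-based analysis of how circadian bioluminescence rhythms of luciferase
reporters are generated.

## The problem

In duckweed (*Lemna*), a luciferase reporter driven by a **constitutive**
promoter such as CaMV35S still shows a circadian bioluminescence rhythm.
Since the promoter is not clock-controlled, the rhythm must arise at one of
three post-transcriptional steps: the **production rate** of the enzyme, its
**degradation rate**, or the **luminescence efficiency** of the luciferase
reaction (set by cellular luciferin, Mg-ATP, O₂ and pH). `biolumin` is for
researchers who want to tell these apart by comparing the rhythms of two
luciferases of different stability (e.g. ELuc, half-life ≈ 10 h, vs
ELuc-PEST, half-life ≈ 3 h).

## The model

The luciferase amount x(t) is the state variable, luminescence L(t) the
output:

    dx/dt = k · m_prod(t) − γ · m_deg(t) · x
    L(t)  = E₀ · m_eff(t) · x(t)
    m(t)  = 1 − A · cos(ωt − φ),   0 ≤ A ≤ 1,   ω = 2π/26 rad h⁻¹

If only the efficiency is rhythmic, L/x at equilibrium equals the modulation
waveform itself, so after normalising each trace by its centred 26-h moving
average ("relative values") the rhythms of stable and unstable luciferases
are identical: amplitude ratio 1, phase difference 0. If the rhythm instead
passes through the amount x(t), the amount acts as a first-order low-pass
filter: the equilibrium relative amplitude is A·γ/√(γ²+ω²) and the peak lags
by arctan(ω/γ)/ω hours — both depend on γ, so the stable reporter comes out
more attenuated and more delayed. The stable/unstable amplitude ratio and
phase difference therefore discriminate "efficiency" from "amount-mediated"
rhythm generation.

The package provides the RK4 simulator with three independent analytic /
quadrature oracles, the relative-value analysis pipeline (26-h moving
average, 7-h zero-phase smoothing, quadratic sub-sample extremum
refinement, amplitude and phase extraction), the four standard scenarios
(`SIM_B` none, `SIM_C` efficiency, `SIM_D` production, `SIM_E`
degradation), single-cell intensity statistics (geometric means, KS /
Lilliefors log-normality tests), and a synthetic-data generator for
replicate photomultiplier traces and cell-intensity sets.

## Worked example

```r
library(biolumin)
simulation_table()
#> Circadian rhythm properties per scenario (StLUC gamma = 0.07, UnstLUC gamma = 0.23)
#>  analysis mean_st mean_unst mean_ratio amp_st amp_unst amp_ratio phase_st
#>     SIM_B    14.3       4.3        3.3     NA       NA        NA       NA
#>     SIM_C    14.3       4.4        3.3   0.22     0.22       1.0     19.0
#>     SIM_D    14.3       4.4        3.3   0.06     0.15       0.4     13.7
#>     SIM_E    14.3       4.4        3.2   0.06     0.15       0.4      0.7
#>  phase_unst phase_diff
#>          NA         NA
#>        19.0        0.0
#>        15.6       -2.0
#>         2.5       -1.9
```

Reading the table: raw luminescence levels differ ~3.3-fold between the
stable and unstable luciferase (their equilibrium amounts k/γ), but the
*relative* rhythms separate the scenarios. In `SIM_C` both reporters carry
the same relative amplitude (0.22 — the 0.25 modulation times the 0.885
smoothing attenuation) at the same phase. In `SIM_D`/`SIM_E` the stable
reporter's amplitude is 0.4× the unstable one's and its peak is ~2 h
delayed.

```r
pr <- run_scenario_pair("SIM_D")
classify_rhythm_factor(pr$amp_ratio, pr$phase_diff)
#> [1] "amount-mediated"

b <- gen_experiment_bundle("EXP", seed = 1)   # synthetic two-reporter study
r <- analyze_experiment_bundle(b)
sprintf("fold %.1f, amp ratio %.2f, phase diff %.1f h -> %s",
        r$fold, r$amp_ratio, r$phase_diff, r$label)
#> [1] "fold 3.5, amp ratio 0.82, phase diff -0.9 h -> efficiency"
```

The synthetic "EXP" bundle emulates the real experimental design (3 samples
× 3 experiments per reporter, noisy decaying traces, log-normal single-cell
intensities) with an efficiency-type rhythm; the pipeline recovers the
"efficiency" call end to end.

A command-line wrapper with subcommands `simulate`, `analyze`, `table1`,
`synth` and `cellstats` is installed as `exec/biolumin`; see
`?biolumin_cli`.

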