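# demicell

Thermodynamic analysis of bile-salt self-aggregation from isothermal
titration calorimetry (ITC) and tensiometry, for physical chemists
characterizing new surfactant derivatives (here: sodium cholate bearing
bulky hydrophobic or hydrophilic C3 substituents).

At its core is the closed mass-action model of micellization,

    n S  <=>  M_n ,      K = [M_n] / [S]^n ,

with the mass balance `S_tot = [S] + n K [S]^n`. From this the package
derives the exact linearization used to read aggregation numbers off ITC
dilution enthalpograms,

    d ln{ (d[S]/dS_tot)^-1 - 1 } / d ln S_tot
        = (n-1)/n + ((n-1)^2/n) * (d[S]/dS_tot) ,

where the degree of demicellization `x = (dH_i - dH_dil)/dH_demic`
estimates `d[S]/dS_tot` per injection. A fit of one titration yields the
aggregation number `n`, the demicellization and dilution enthalpies, the
cmc and the equilibrium constant. Downstream the package computes the
counterion-corrected state functions

    K_mic     = K [Na+]^(beta n)
    dG_demic  = (RT/n) ln K_mic
    dS_demic  = (dH_demic - dG_demic) / T
    dCp_demic = slope of dH_demic vs T

with the binding degree `beta` from Corrin–Harkins plots
(`log10 cmc = A - beta log10 [Na+]`), extracts cmc values from
surface-tension curves by continuous segmented least squares, and links
lipophilicity to aggregation through the calibration
`log P = 2.79 - 1.00 log10(cmc/mM)`. Seeded generators simulate every
input with known ground truth, so the whole pipeline is testable by
parameter recovery.

## Worked example

Simulate a titration of a derivative with `n = 10`, cmc 0.45 mM,
exothermic demicellization (`dH_demic = -5 kJ/mol`) on the default
38 x 2 µL schedule, then fit it back:

```r
library(demicell)

truth <- synthetic_truth(n = 10, cmc = 0.45, dH_demic = -5, dH_dil = -0.2,
                         noise_sd = 0)
ser <- gen_itc_experiment(truth, default_itc_schedule())
fit_demicellization(ser)
#> Mass-action demicellization fit
#>   n        = 10.000  (intercept-only 10.000, slope-only 10.000)
#>   dH_demic = -5 kJ/mol, dH_dil = -0.2 kJ/mol
#>   cmc      = 0.4497 mM,  K = 8.113 mM^(1-n)
#>   line: intercept 0.9000, slope 8.1001, r^2 = 1.000000  (4 points dropped)
```

The generating parameters are recovered essentially exactly: the
linearized plot has intercept `(n-1)/n = 0.9` and slope
`(n-1)^2/n = 8.1`, and the cmc lands within 0.1% of the truth (the
four dropped points sat on the plateaus, outside the informative
transition). The packaged reference tables for the three hydrophobic
cholate derivatives run through the same machinery:

```r
rep <- run_full_analysis()
rep$summaries$NaAdCH2C
#> Demicellization summary over 6 temperatures
#>   mean n = 10.8 +/- 1.5
#>   dCp_demic = 299 +/- 17 J mol-1 K-1

rep$logp_scores
#>    predictor mean_squared_residual    reliability
#> 1      iLOGP                1.2091 not_acceptable
#> 2     XLOGP3                0.7046     acceptable
#> 3      WLOGP                0.6247     acceptable
#> 4      MLOGP                2.4698 not_acceptable
#> 5 SILICOS_IT                1.2118 not_acceptable
#> 6    virtual                0.0435       reliable

rep$logp_from_cmc
#>   surfactant cmc_mM logp_predicted
#> 1      NaAdC  0.336          3.264
#> 2   NaAdCH2C  0.438          3.149
#> 3  NatButPhC  0.182          3.530
```

The positive heat capacities (around 300 J mol⁻¹ K⁻¹ here) mean
hydrophobic surface becomes water-exposed on demicellization — the
signature of back-to-back packing — and the predictor benchmark singles
out the molecular-lipophilicity-potential (`virtual`) method as the only
reliable log P predictor for bile salts. A tensiometry curve gives an
independent cmc:

```r
cv <- gen_surface_tension_curve(cmc = 0.40, pre_slope = -8, plateau = 53.4,
                                noise_sd = 0.2, seed = 3)
detect_cmc_breakpoint(cv)
#> Surface-tension breakpoint: cmc = 0.3997 mM (slopes -7.945 -> -0.079
#>   mN/m per ln unit, RSS 0.341, p = 2.49e-18)
```

See `vignettes/demicellization-methods.Rmd` for the model assumptions,
the numerics of the linearization, and every convention (cmc criterion,
water molarity, sign conventions) with its rationale.

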