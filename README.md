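# cmrt1

Quantitative T1 analysis for contrast-enhanced cardiovascular magnetic
resonance (CMR). The package covers the two workhorse experiments of
contrast-agent T1 mapping studies:

- **In vitro relaxometry.** Multi-TR saturation-recovery spin-echo series of
  a factorial dilution phantom (gadolinium contrast agent × a protein-binding
  co-medication × albumin) are fitted pixelwise with
  `S(TR) = S0 (1 − e^(−TR/T1))`, vial ROIs are averaged, and the relaxivity
  of each dilution series is estimated as the slope r1 of
  `1/T1 = 1/T1_0 + r1·[Gd]` (in mmol⁻¹ s⁻¹ l). Paired t-tests and Pearson
  correlations then quantify the albumin and co-medication effects.
- **In vivo MOLLI T1 mapping.** Modified Look-Locker inversion-recovery
  series (11 inversion times, TI = 100 + 80k ms) are fitted with the
  three-parameter model `S(TI) = A − B e^(−TI/T1*)` plus the Look-Locker
  correction `T1 = T1*(B/A − 1)`, including polarity restoration for
  magnitude data. Myocardial T1 is extracted over the six AHA mid-cavity
  segments (7–12) and a blood-pool ROI, giving the partition coefficient
  `λ = ΔR1_myocardium / ΔR1_blood` (with `ΔR1 = 1/T1_post − 1/T1_pre`) and,
  when hematocrit is available, the extracellular volume fraction
  `ECV = λ (1 − hct)`.
- **Reproducibility statistics** between two exams: paired t-tests,
  ICC(2,1) (two-way random effects, absolute agreement, single measures),
  Bland-Altman bias and limits of agreement, and linear mixed models on log
  T1 with exam, time and exam×time fixed effects.

Because raw scanner data for such studies are rarely shareable, a
synthetic-data module generates both inputs with known ground truth — the
50-vial factorial phantom and a two-exam, 13-time-point volunteer study with
a calibrated blood washout curve — so the entire pipeline is testable end to
end, including its statistical calibration under the null hypothesis of no
between-exam effect.

## Worked example

Simulate the 50-vial phantom at 1% noise, fit it end to end, and test the
co-medication (ibuprofen) effect on relaxivity:

```r
library(cmrt1)
ph  <- make_phantom(phantom_truth(), seed = 42)
res <- phantom_relaxivity(ph)   # pixelwise T1 map -> vial ROIs -> r1 table
res$table[, c("ibuprofen_conc", "albumin_present", "r1", "r_squared")]
#>    ibuprofen_conc albumin_present    r1 r_squared
#> 1            0.00           FALSE 7.282    0.9999
#> 2            0.48           FALSE 7.136    1.0000
#> ...
#> 6            0.00            TRUE 9.149    1.0000
#> 10           4.85            TRUE 9.199    1.0000
albumin_effect_test(res$table)
#> albumin arm 9.26 vs 7.21 mmol^-1 s^-1 l, paired t = 31.2, p = 6.3e-06
ibuprofen_correlation(res$table)
#>   albumin_present      r     p n
#> 1           FALSE  0.301 0.623 5
#> 2            TRUE -0.264 0.668 5
```

The generating truth used relaxivities 9.24 (with albumin) and 7.22
(without) and a zero ibuprofen effect: the albumin effect is recovered and
highly significant, the ibuprofen correlations are null, as simulated.

Simulate a two-exam volunteer study, fit the MOLLI series, and summarise
the partition-coefficient time course and its test–retest agreement:

```r
st <- make_invivo_study(study_truth(n_subjects = 4, seed = 1),
                        resolution = "roi", magnitude = FALSE)
tc <- study_timecourse(st)                  # MOLLI fits -> slice/blood T1
pt <- partition_timecourse(tc$records)
pt$summary[pt$summary$minutes %in% c(5, 60), ]
#>   exam minutes lambda lambda_sd n
#> 1    1       5  0.376    0.0122 4
#> 2    1      60  0.457    0.0061 4
#> 3    2       5  0.384    0.0146 4
#> 4    2      60  0.457    0.0159 4
l1 <- pt$records[pt$records$exam == 1, ]
l2 <- pt$records[pt$records$exam == 2, ]
agreement(l1$lambda, l2$lambda)
#> Agreement: ICC(2,1) = 0.8846, bias = -0.0002455, LoA [-0.02547, 0.02498] (n = 48)
```

λ rises from ≈0.38 at 5 min to ≈0.46 at 60 min (the generator's drift), and
the two exams — identical truth, independent noise — agree closely.

A file-based pipeline (`cmd_simulate()` / `cmd_analyze()`, NIfTI images +
CSV tables + JSON reports) and a thin command-line front-end
(`inst/cli/cmrt1.R`) wrap the same functions; see `?cmd_simulate`.

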