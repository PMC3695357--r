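# allokin

Virtual-screening filters and kinase-assay analytics for discovering
**allosteric inhibitors of the IGF1R receptor tyrosine kinase**, re-implemented
at desk scale as an R package.

Allosteric kinase inhibitors bind a pocket adjacent to — not inside — the ATP
site, so finding them takes a different playbook from classical ATP-competitive
screening. `allokin` implements that playbook end to end:

1. **Library triage (target arm)** — strong hydrogen-bond-donor SMARTS
   (an N–H that is neither amide-deactivated nor aromatic), aromatic-ring and
   H-bond-acceptor prerequisites, toxicophore blacklist, logP/logS property
   windows (`has_strong_donor()`, `passes_feature_prereqs()`,
   `medchem_flags()`, `property_flags()`, `filter_verdict()`).
2. **Pharmacophore search** — four feature kinds (donor, acceptor, aromatic
   ring, any-heavy) matched against a distance matrix with tolerance, over
   torsion-grid or stochastic conformer ensembles, with a forbidden-volume
   clash rule (`pharmacophore_model()`, `generate_conformers()`,
   `match_pharmacophore()`).
3. **Post-docking interaction filters** — hydrogen bond to the Val1063
   backbone carbonyl, aromatic stacking on the Met1054 and Met1079 sulfurs,
   plus at least one secondary contact (Lys1033, Asp1153, Glu1050, Arg1134)
   (`extract_pocket()`, `detect_interactions()`, `apply_allosteric_filter()`,
   `screen_poses()`).
4. **Markush selection (ligand arm)** — substructure series around a
   phenol/aniline–linker–aryl scaffold with witness mappings and series
   assignment (`match_markush()`, `assign_series()`).
5. **HTS plate statistics** — 384-well roles, % activity, signal window and
   Z′-factor QC (window ≥ 6, Z′ ≥ 0.6), mean − 3 SD hit calling
   (`plate_qc()`, `call_hits()`, `percent_activity()`, `zprime()`).
6. **Dose–response** — constrained two-parameter sigmoid fitted in
   log10(IC50), censoring and convergence flags, serial-dilution bookkeeping
   and fold-selectivity ratios (`fit_ic50()`, `dilution_series()`,
   `selectivity_ratio()`).
7. **Inhibition mechanism** — per-[I] Michaelis–Menten fits, trend tests on
   log Vmax / log Km, classification into competitive / non-competitive /
   uncompetitive / mixed, Lineweaver–Burk views (`fit_michaelis_menten()`,
   `classify_mechanism()`, `lineweaver_burk()`).
8. **Seeded synthetic data** — generators with planted ground truth for every
   stage (`gen_library()`, `gen_pose_scene()`, `gen_plate()`,
   `gen_dose_response()`, `gen_kinetics()`), so the whole pipeline is testable
   offline (`run_pipeline_demo()`).

Model-fitting functions return classed objects (`ic50_fit`, `mm_fit`,
`mechanism_call`) with the usual `print()`, `coef()`, `predict()`,
`residuals()` and `plot()` methods.

## Worked example

```r
library(allokin)

# Dose-response: 8-point 1:2 curve, quadruplicates, 5% noise, true IC50 25 uM
d <- gen_dose_response(seed = 11, ic50 = 25)
fit_ic50(data.frame(conc_uM = d$conc_uM, activity = d$activity))
#> Constrained sigmoidal dose-response fit (top 100%, bottom 0%)
#>   IC50: 22.96 uM   Hill slope: 0.9685
#>   RSS: 436.2   converged: TRUE

# A 384-well plate with 8 planted inhibitors
g <- gen_plate(seed = 3)
plate_qc(g$plate)[c("window", "zprime", "pass")]
#> $window
#> [1] 9.654
#> $zprime
#> [1] 0.7327
#> $pass
#> [1] TRUE
head(call_hits(g$plate)[call_hits(g$plate)$is_hit, ], 4)
#>   compound mean_rlu n_wells is_hit
#> 1 cmpd_265 4631.580       1   TRUE
#> 2 cmpd_185 4686.874       1   TRUE
#> 3 cmpd_320 4699.528       1   TRUE
#> 4 cmpd_028 4815.180       1   TRUE

# The whole pipeline on synthetic inputs with planted truth
run_pipeline_demo(seed = 1)
#> Synthetic screening pipeline run (seed 1)
#>   library: 12 molecules, 2 pass all filters, 5 Markush hits
#>   poses:   3/3 verdicts as planted
#>   plate:   Z' 0.735, 8/8 planted inhibitors recovered
#>   IC50:    26.01 uM fitted vs 25.00 true
#>   kinetics: non-competitive (true: non-competitive)
```

See the methods vignette (`vignettes/allokin-methods.Rmd`) for the science
behind each stage.

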