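# sbaselect

Antibody selectivity analysis for multiplexed suspension bead arrays
(SBA).

Affinity proteomics screens validate antibodies by coupling each one to a
color-coded bead population and exposing the multiplexed beads to lysates
that overexpress one epitope-tagged receptor per well, plus mock
(empty-vector) wells. The raw readout is a median fluorescence intensity
(MFI) per bead per well. For panels of closely related receptors — GPCR
subfamilies in particular — the hard question is whether an antibody
captures its intended receptor, an unintended one, both, or nothing.
`sbaselect` is for the people who run and analyze such screens: it takes
raw MFI and bead-count tables to quality control, expression assessment,
selectivity classification, cross-reactivity deconvolution,
paired-antibody agreement and antigen structural features, with a
synthetic-experiment generator that makes every stage testable without
assay data.

## The model

Per antibody, MFI values `x` over its panel's wells are converted to
robust Z-scores,

    R.Z_i = (x_i − median(x)) / (1.4826 · MAD(x)),

and an antibody-specific threshold is derived from the negative (non-
binding) bulk of that distribution:

    threshold = peak + k · σ_neg,   k = 12,

where `peak` is the mode of a Gaussian KDE of the scores and `σ_neg` is
the reflected-lower-tail robust SD around the peak (true binding only
inflates the upper tail). Antibodies are then classified `on_target`
(mean R.Z over wells expressing the intended receptor above threshold, no
other receptor's well above), `co_target` (intended plus any unintended
well above), `off_target` (unintended only) or `no_target`. Around that
core sit: a 32-event bead-count floor and per-bead coupling QC; mock-
contrasted expression testing (per-panel ANOVA, then Dunnett contrasts,
support requiring p < 0.05 *and* mean above mock); deconvolution of each
off-target event by the twofold expression-ratio line and a
Smith–Waterman/Karlin–Altschul E < 1 homology boundary; Pearson agreement
of antibodies sharing a target; and antigen profiles (pLDDT,
Shrake–Rupley relative solvent accessibility, dihedral secondary
structure) compared between selectivity classes. The methods vignette
(`vignettes/sba-selectivity.Rmd`) documents every estimator and default.

## Worked example

Simulate a screen (24 receptors in six subfamily panels, 40 antibodies,
four biological replicates against four mocks per panel), fit the
selectivity model and deconvolve the cross-reactivity:

```r
library(sbaselect)

ds  <- generate_dataset(sba_sim_config(seed = 1))
fit <- sba_selectivity(ds$assay, ds$antibodies, ds$samples,
                       coupling = ds$coupling)
fit
#> Suspension-bead-array selectivity fit
#>   39 antibodies scored (k = 12, 1 excluded by coupling QC)
#>   on-target 20 | co-target 1 | off-target 2 | no-target 16
#>   thresholds (R.Z): 3.1 to 18.9 (mean 9.6)

flt  <- filter_bead_counts(ds$assay)
expr <- assess_expression(flt$mfi, ds$samples, ds$library,
                          c(FLAG = "9001", HA = "9002"))
expression_summary(expr, ds$library)
#>         subfamily n_gpcrs n_expressed expressed_pct
#> 1 rhodopsin_alpha       5           5         100.0
#> 2  rhodopsin_beta       4           3          75.0
#> 3 rhodopsin_gamma       4           4         100.0
#> 4 rhodopsin_delta       4           3          75.0
#> 5            GSAF       4           4         100.0
#> 6           other       3           0           0.0
#> 7           total      24          19          79.2

crossreact_table(fit, ds$library, expr)[, c("antibody_id", "on_target",
  "off_target", "expression_ratio", "e_value", "cause", "consistent")]
#>  antibody_id on_target off_target expression_ratio  e_value              cause consistent
#>        AB005   GPRRA05    GPRRA04            3.967 1.21e-01 abundance+homology       TRUE
#>        AB017   GPRRD04    GPRRD02               NA 2.61e-20           homology       TRUE
#>        AB029   GPRRA05    GPRRA03            0.733 3.55e-38           homology       TRUE
```

Reading it: 39 of 40 planted antibodies passed coupling QC; 20 were called
on-target and every planted on-target antibody whose construct actually
expressed was recovered (20/20 here, and 11/11 planted no-binders). The
five-fold range of per-antibody thresholds is the point of the
antibody-specific construction. Of the three off-target events, one is
explained by a ~4-fold more abundant off-target, two by sequence homology
of the antigen to the cross-captured receptor (E-values around 1e-20 and
1e-38); the `NA` ratio marks an on-target construct whose expression was
not supported, so no ratio is claimed. `threshold_sweep(fit)` reproduces
the category-counts-versus-k curve behind the choice `k = 12`, and
`pair_correlations(fit)` / `pair_summary()` quantify agreement between
antibodies sharing a target.

A configured end-to-end run (`pipeline_simulate()`, `pipeline_run()`,
`pipeline_report()`, or the wrapper `inst/scripts/sba-pipeline.R`) writes
every table as TSV plus a JSON run manifest and a log of masked wells,
excluded beads and skipped pairs.

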