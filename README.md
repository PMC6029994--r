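# simekit

Non-invasive kinetic analysis of dynamic PET tracers with radiometabolites.

Quantifying receptor binding from dynamic PET requires the arterial input
function (AIF) — the metabolite-free parent tracer concentration in
arterial plasma — which is classically measured by serial arterial
sampling plus metabolite assays. `simekit` implements the *simultaneous
estimation* (SIME) family of alternatives, in which a parametric AIF is
fitted jointly with two-tissue-compartment (2-TC) kinetic parameters
across several brain regions of different binding:

* **original SIME** — AIF as a six-parameter bolus model
  (`C_P(t) = (A1·t − A2 − A3)e^{−λ1 t} + A2 e^{−λ2 t} + A3 e^{−λ3 t}`),
  no blood data at all (4m + 6 parameters for m regions);
* **constrained SIME** — an image-derived whole-blood curve anchors the
  AIF through the metabolite-correction identity
  `C_P(t) = C_WB(t) · f_Hill(t) · (d·t + e)` with the Hill parent
  fraction `f_Hill(t) = 1 − (1−a)t^b/(c + t^b)`, leaving five free AIF
  parameters (4m + 5);
* **gold-standard path** — metabolite-corrected AIF assembled from
  arterial samples (Hill fit + ratio line + interpolated whole blood).

Regional outputs are the macroparameters `V_T = K1/k2·(1 + k3/k4)` and
`BP_ND = (V_T − V_ND)/V_ND` (cerebellum reference). A fully seeded
synthetic-study generator (35-frame, 90-min schedule; four regions with
low/moderate/high binding; duration-scaled frame noise; test–retest
cohorts) makes every stage testable by parameter recovery, and
`icc()`, `percent_error()`, `paired_summary()` provide the evaluation
statistics (test–retest ICC in the `(BMS − WMS)/(BMS + WMS)` form).

Audience: PET methodologists and kinetic-modelling researchers who want a
reference implementation of constrained SIME, or a sandbox for input
function estimation experiments.

## Worked example

```r
library(simekit)

truth <- generate_truth("default")        # known AIF + 4 regional parameter sets
study <- generate_study(truth, noise = "none", seed = 1)

fit <- fit_sime(
  sime_problem(unname(study$tacs), mode = "constrained", wb = study$wb),
  sime_config(multistarts = 1, seed = 1))
print(fit)
#> sime_result (constrained mode): converged, cost 2.24932e-07
#>   V_T : cerebellum=2.599, parietal=3.691, hippocampus=4.938, striatum=11.696
#>   BP_ND (ref cerebellum):cerebellum=0.000, parietal=0.420, hippocampus=0.900, striatum=3.500

sapply(truth$kinetics, volume_of_distribution)
#> cerebellum    parietal hippocampus    striatum
#>      2.600       3.692       4.940      11.700
```

On noiseless data the constrained fit recovers every regional volume of
distribution to ~0.04% and the binding potentials 0.42 / 0.90 / 3.50
exactly match the generating design. The printed `cost` is the joint
sum-of-squares of Eq.-style frame residuals; `fit$aif_params` holds the
estimated Hill and ratio-line parameters, and `reconstruct_aif(fit, t)`
evaluates the recovered input function.

One important caveat, documented in the methods vignette
(`vignettes/constrained-sime.Rmd`): the constrained cost determines the
plasma-to-whole-blood ratio line only up to a scale that trades exactly
against every region's K1, so the intercept `e` is pinned at a
physiological prior (default 1.05) and absolute `V_T`/`K1` are reported
relative to that convention; `BP_ND` and the parent-fraction curve are
unaffected.

The full pipeline (simulate → fit → refit → metrics) is available as
`run_pipeline()` or from the command line:

```sh
Rscript inst/cli/simekit.R simulate --profile default --noise mid --seed 7 --out studydir/
Rscript inst/cli/simekit.R fit --mode constrained --tacs studydir/tacs.csv \
        --blood studydir/wb.csv --out result.json
Rscript inst/cli/simekit.R blood-aif --samples studydir/samples.csv \
        --metabolites studydir/pf.csv --out aif.csv
```

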