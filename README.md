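# twoconf

Quantitative pharmacology for receptors that adopt **two agonist-stabilised
conformations**, developed around the human β1-adrenoceptor.

Many β1-adrenoceptor ligands behave inconsistently across assays: a compound
that looks like a pure high-affinity antagonist in radioligand binding can
still stimulate a reporter-gene response — but only at concentrations
hundreds-fold above its measured KD, and that response resists antagonists
that easily block catecholamines. The parsimonious model is that the receptor
presents two activatable conformations:

- the **catecholamine conformation ensemble (CCE)** — the classical,
  high-affinity site; responses through it are readily antagonised; and
- the **secondary conformation ensemble (SCE)** — engaged at higher ligand
  concentrations through a distinct pocket; its responses are relatively
  antagonist-resistant, and they disappear when the three residues of that
  pocket (V189, L195, W199 in TM4) are mutated.

`twoconf` packages the complete analysis workflow for this problem:

| module | what it does |
|---|---|
| simulator | deterministic two-conformation assay generator (`ground_truth()`, `sim_config()`, `simulate_functional_curve()`, `simulate_binding_plate()`, `make_study_fixture()`) |
| binding | saturation and competition fits with Cheng–Prusoff correction and censoring (`fit_saturation()`, `fit_competition()`, `cheng_prusoff()`, `selectivity_ratio()`) |
| functional | one-site, two-site and inhibit-then-stimulate ("dip") curve fits with extra-sum-of-squares model selection (`fit_one_site()`, `fit_two_site_stim()`, `fit_dip()`, `select_cr_model()`) |
| antagonism | Gaddum dose-ratio KDs, Schild regression, Stephenson's matched-response method (`gaddum_kd()`, `schild_fit()`, `stephenson_kd()`, `conformation_ratio()`) |
| evidence | the four-point A–D rubric and compound classification (`evaluate_evidence()`, `classify_compound()`, `pool_evidence()`, `compare_lines()`) |
| io / pipeline | 96-well plate CSV dialect and a configuration-driven end-to-end run (`read_plate_csv()`, `write_plate_csv()`, `run_pipeline()`) |

## Worked example

Simulate a ligand with high CCE affinity, low SCE affinity, and agonism at
both conformations — the classic biphasic profile — then analyse it blind:

```r
library(twoconf)

gt <- ground_truth("cmpd", logKd_cce = -9.3, logKd_sce = -6.8,
                   efficacy_cce = 0.010, efficacy_sce = 0.035,
                   mode = "biphasic")
cfg <- sim_config(gt, receptor_expression = 42.7, noise_sd = 0.05,
                  n_replicates = 24L, seed = 42L, cell_line = "b1_luc")

curve <- normalize_plate(simulate_functional_curve(cfg, "cmpd"))
choice <- select_cr_model(curve)
print(choice)
print(choice$candidates$two_site)
```

```
<model_choice> two_site (F = 339, p = 1.74e-78)
<two_site_fit> cmpd: logEC1 -9.493, logEC2 -7.100, site1 45.3%, total 68.5%
```

The fitted first component sits near the binding KD (−9.3) while the second
emerges two log units later — the biphasic signature. Competition binding
sees only the high-affinity conformation:

```r
plate <- simulate_binding_plate(cfg, "cmpd", assay = "competition")
est <- cheng_prusoff(fit_competition(plate), plate$meta$radioligand_conc,
                     10^plate$meta$radioligand_logKd)
print(est)
```

```
<affinity_estimate> cmpd: logKd -9.295 +/- 0.015 (competition_cheng_prusoff, n=1)
```

## Study-level analysis

`make_study_fixture()` builds a full simulated study — 19 compounds across a
low-expression (CRE-luciferase) line, a high-expression (CRE-SPAP) line and a
TM4 triple-mutant line, with binding, functional, antagonist-shift and dip
plates — and `run_pipeline()` / `analyze_study()` takes it from raw signals to
classifications:

```r
res <- run_pipeline(list(mode = "simulate", seed = 1))
print(res)
```

```
<study_results> 69 affinity estimates, 53 curves, 19 classified compounds
      compound evidence     classification
A   alprenolol        C   biphasic_agonist
A1  bucindolol        C   biphasic_agonist
A2    CGP12177      ABD        sce_agonist
A3   cimaterol                 cce_agonist
A4  oxprenolol        C   biphasic_agonist
A5    pindolol        C   biphasic_agonist
A6   CGP20712A          neutral_antagonist
A7        VL01     ABCD   biphasic_agonist
A8        VL03          neutral_antagonist
A9        VL04     ABCD   biphasic_agonist
A10       VL05                 cce_agonist
A11       VL06                 cce_agonist
A12       VL07        A        cce_agonist
A13       VL08              no_interaction
A14       VL09     ABCD   biphasic_agonist
A15       VL10                 cce_agonist
A16       VL11              no_interaction
A17       VL12              no_interaction
A18       VL13              no_interaction
```

The evidence letters are the rubric's four criteria:

- **A** — the functional EC50 lies ≥ 10-fold above the CCE KD;
- **B** — a reference antagonist blocks the compound's response with far
  lower apparent affinity than it blocks the reference catecholamine;
- **C** — the concentration-response curve itself is biphasic;
- **D** — in the dip design, the compound first suppresses a reference
  response and then re-stimulates at higher concentrations.

The wild-type-versus-mutant contrast (`res$contrast`) reports which criteria
disappear in the TM4 triple mutant — the loss-of-function control for the
secondary conformation.

## License

MIT (see `LICENSE`).
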