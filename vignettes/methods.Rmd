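---
title: "Methods: the two-conformation model, the simulator, and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-conformation model, the simulator, and the analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the quantitative model behind `twoconf`, the scope
and assumptions of its simulator, the numerical choices in its fitting
routines, and the rationale for the evidence rubric. It is the reference for
*why* the package computes what it computes; the README shows *how* to use
it.

## 1. The receptor model

### 1.1 Hyperbolic transducer

Occupancy of an activatable conformation generates a stimulus `S`, and the
observed response is the saturating transducer function

```
R = S / (1 + S),          0 <= R < 1  (fraction of the system maximum)
```

For a single agonist at one conformation with dissociation constant `K` and
transducer slope `tau` (the product of intrinsic efficacy and the
receptor-expression scale), `S = tau * A / (A + K)`, which collapses to a
one-site hyperbola in `A` with the classical operational observables:

```
Emax = tau / (1 + tau)         (fraction of system max)
EC50 = K / (1 + tau)
```

High expression therefore raises plateaus **and** left-shifts EC50s — the
familiar receptor-reserve behaviour, and the reason the same ligand can look
like a weak partial agonist in a low-expression line and a strong agonist in
a high-expression line.

### 1.2 Two conformations

A ligand may bind and activate two conformations (CCE and SCE) with separate
affinities `K_c`, `K_s` and slopes `tau_c`, `tau_s`. The stimuli add:

```
S(A) = tau_c * A / (A + K_c) + tau_s * A / (A + K_s)
R(A) = S(A) / (1 + S(A))
```

Although `R(A)` is not itself a sum of two hyperbolae, it is *exactly*
expressible as one: the denominator of `R(A)` is a quadratic in `A`, and a
partial-fraction decomposition gives

```
R(A) = m1 * A / (A + a1) + m2 * A / (A + a2)
```

with `a1, a2` the roots of that quadratic and `m1, m2` fixed by matching the
`A -> 0` slope and the `A -> Inf` plateau. This closure is what makes the
empirical two-site fit (`fit_two_site_stim()`) the right descriptive model
for two-conformation agonists, and it is the oracle the test suite uses to
verify noiseless round trips: the simulator draws from the mechanistic form,
and the fitted `logEC1_50`/`logEC2_50` must equal `log10(a1)`/`log10(a2)`.

### 1.3 Competitive antagonism

A second ligand at concentration `B` binding a conformation with constant
`K_B` scales that conformation's stimulus by the Gaddum factor: the agonist
term becomes `tau * x / (1 + x + b)` with `x = A/K`, `b = B/K_B`, which
right-shifts the component's EC50 by `(1 + B/K_B)` without depressing its
plateau. Because the two conformations have *different* antagonist
affinities, a fixed antagonist concentration can abolish the CCE component
while barely moving the SCE component — the mechanistic origin of
"antagonist-resistant" agonism and of rubric criterion B.

## 2. The simulator

### 2.1 What is modelled

`simulate_functional_curve()` and `simulate_binding_plate()` emit plates of
raw plate-reader counts, not tidy responses:

- a basal level of 500 counts and an assay window of 4500 counts to the
  positive control (10 µM isoprenaline, modelled as a saturating full
  agonist, so its response fraction is `e/(1+e)` at expression `e`);
- test wells at `500 + 4500 * R(A)`;
- control wells (basal and positive; plus the reference-alone level for the
  dip design) on every plate;
- Gaussian noise with standard deviation `noise_sd * window * positive
  fraction`, i.e. noise scales with the usable signal range, matching the
  observation that reporter assays are quoted with percent-scale error;
- control wells replicate with the plate: a plate with `n_replicates` test
  wells per concentration carries `max(6, n_replicates)` wells per control.
  This matters statistically — at high replication the error of the
  *normalisation* (basal/positive means) would otherwise dominate the error
  of the curve itself and bias fitted parameters;
- binding plates: saturation (8 radioligand concentrations with matched
  nonspecific wells) and competition (fixed radioligand, nonspecific at 10%
  of total, IC50 at `K_cce * (1 + L/K_L)` by construction, so the
  Cheng–Prusoff inversion is exact on noiseless data);
- shift designs (fixed antagonist) and the dip design (fixed reference
  agonist at `C_ref`, where the test compound both inhibits the reference
  response with `IC50 = K_c * (1 + C_ref/EC50_ref)` and adds its own
  stimulus).

Determinism: every plate derives its random draws from a hash of the
configuration seed and the plate's own labels, so a bundle is reproducible
plate-by-plate and insensitive to generation order.

### 2.2 What is not modelled

No receptor desensitisation or time dependence, no depletion of ligand, no
plate-position (edge) effects, no inter-day variance components, no
non-competitive or allosteric interactions, and noise is homoscedastic
Gaussian on the count scale. These are deliberate: the simulator exists to
give the analysis code a ground truth with the *structure* of the real
experiments, not to emulate every nuisance of cell culture.

### 2.3 The bundled study fixture

`make_study_fixture()` assembles a 19-compound study across three cell lines
(low-expression CRE-luciferase, high-expression CRE-SPAP, and the
TM4 V189T/L195Q/W199Y triple mutant in which the SCE is absent).
Ground-truth parameters are anchored to literature-scale values:

- expression scalars are fixed by the reference full agonist's KD/EC50 gap
  per line (`tau = KD/EC50 - 1`);
- biphasic compounds are parameterised from their observed two-site curves
  by inverting the partial-fraction closure of section 1.2;
- partial agonists' efficacies are set from observed plateau percentages via
  `tau = f/(1-f)`;
- per-compound replication follows the study's pooled experiment counts
  (three wells per independent experiment), because resolving a small
  second component is a question of replication, not of luck.

The mutant line keeps each compound's CCE parameters (recalibrated to the
mutant's own reference-agonist scale) and deletes the SCE terms — the
loss-of-function contrast the rubric's validation leans on.

## 3. Numerical choices

- **All nonlinear fits are least squares on the percent scale with
  log10-parameterised concentrations** (logEC50, logIC50, logKd). The log
  scale is where errors are approximately symmetric and where the
  acceptance tolerances are stated.
- **Multi-start Levenberg–Marquardt** (`minpack.lm::nlsLM`) with a small
  lattice of starting values guards against local minima; the test suite
  additionally checks every fit against brute-force grid searches.
- **Linear parameters are profiled where possible** (the two-site total
  amplitude; the dip stimulus amplitude), shrinking the nonlinear search
  space.
- **Model selection is by extra-sum-of-squares F-tests** (flat vs one-site
  vs two-site; for dip plates, flat vs inhibition vs inhibit-then-stimulate,
  with both limbs required to be significant). Two practical guards prevent
  statistically-significant-but-meaningless verdicts: a two-site call needs
  both components to carry a minimum share of the total and a minimum log
  separation; collapsed fits (components merging at the boundary) revert to
  one-site.
- **Censoring instead of extrapolation**: competition curves that never
  cross 50% inhibition, and shift experiments with no measurable dose ratio,
  return one-sided bounds (`censored = list(direction, bound)`) that
  propagate through Cheng–Prusoff and into the rubric as indeterminate
  evidence, rather than fabricating a number.
- **Schild analysis**: `log10(DR - 1)` regressed on `log10 B`; points with
  `DR` below a minimum are excluded with a warning; competitiveness requires
  the slope's confidence interval to include 1. Because all dose ratios in
  one experiment share the control fit, the regression SE understates
  between-experiment spread; inference about slope bias should therefore be
  made across replicate experiments, which is how the acceptance suite
  frames it.
- **Stephenson's method** estimates a partial agonist's KD by comparing
  matched response levels of the full-agonist curve with and without the
  partial agonist present; it refuses plateaus at the system maximum (no
  partial agonism, nothing to match).

## 4. The evidence rubric and classification

Four criteria, each scored positive / negative / indeterminate per cell
line:

- **A (potency gap)** — the compound's own EC50 lies at least `gap_A` log
  units (default 1.0, i.e. ten-fold) *above* its CCE KD. Indeterminate when
  the response is too small to trust, biphasic (the one-site EC50 is then
  meaningless), or the CCE affinity is censored.
- **B (antagonist resistance)** — the reference antagonist's apparent KD
  against the compound is at least `gap_B` log units weaker than against the
  reference catecholamine agonist.
- **C (biphasic shape)** — the selected concentration-response model is
  two-site.
- **D (inhibit-then-stimulate)** — the dip design selects the composite
  model: suppression of the reference response followed by re-stimulation.

Classification walks a fixed decision order: no binding and no response →
`no_interaction`; binding without response → `neutral_antagonist`; C
positive → `biphasic_agonist`; A∧B or D → `sce_agonist`; otherwise
`cce_agonist`. Pooling across wild-type lines takes any positive over
negatives and negatives over indeterminates — a criterion demonstrated in
*any* line counts, which mirrors how expression-dependent phenomena must be
read (the low-expression line may genuinely lack the reserve to show a
second component). `compare_lines()` then reports which positives disappear
in the mutant, with `sce_lost` set when the secondary-conformation evidence
(A∧B or D) is gone.

Thresholds live in `study_thresholds()` and can be overridden from the
pipeline configuration; overrides are recorded in the run log so an analysis
is always reproducible from its artefacts.

## 5. Limitations

- The transducer is hyperbolic; steep (Hill slope ≠ 1) systems are out of
  scope, as are kinetic (non-equilibrium) readouts.
- The rubric's thresholds are pragmatic defaults, not estimated quantities;
  sensitivity to them should be explored with `run_pipeline()` overrides.
- Stephenson's method assumes the fixed ligand acts as a simple competitive
  partial agonist at the conformation driving the full agonist's response;
  it recovers that conformation's KD, not the other's.
- The simulator's noise model is a single Gaussian scale per plate; real
  plates show heavier tails and occasional systematic drift, so real-data
  power will be somewhat below simulated power at equal replication.
- Classification quality is bounded by design: criteria B and D need the
  corresponding shift/dip plates, and a compound assayed only functionally
  cannot be classified beyond its curve shape.
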