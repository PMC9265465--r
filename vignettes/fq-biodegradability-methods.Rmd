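---
title: "Methods: composite biodegradability scoring, QSAR validation, and composting-scenario analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite biodegradability scoring, QSAR validation, and composting-scenario analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fqbiodeg)
```

# The problem

Fluoroquinolone (FQ) antibiotics survive conventional wastewater treatment
and end up in sewage sludge. During the thermophilic stage of sludge
composting, heat-tolerant bacteria — *Thermus* sp., *Bacillus
licheniformis*, *Cellulomonas flavigena*, represented by their degradation
enzymes 1GKQ, 1OB0, and 5M0K — can break FQs down. Docking scores between
an FQ molecule and each enzyme proxy how degradable the compound is by that
organism. This package implements the quantitative analysis layer of such a
study: it turns per-enzyme docking scores into a single composite
biodegradability value per compound, validates structure-activity (3D-QSAR)
models built on molecular-field descriptors, screens candidate derivative
molecules for improved biodegradability and acceptable environmental
properties, analyzes composting-amendment and field-measure experiments as
two-level factorial designs on MM/PBSA binding energies, and checks the
bookkeeping identities of those binding-energy decompositions.

The docking and molecular-dynamics simulations themselves are out of scope:
their numeric outputs (score tables, binding energies) are the package's
inputs, and small published tables of them ship as fixtures (see
`fq_example()`).

# Entropy-weighted composite scoring

Given an $m \times n$ matrix of positive docking scores $v_{ij}$
($m$ compounds, $n$ receptors), the composite value is built in four steps:

1. **Influence proportions.** $P_{ij} = v_{ij} / \sum_i v_{ij}$, each
   receptor column a probability distribution over compounds.
2. **Normalized entropy.** $e_j = -\frac{1}{\ln m}\sum_i P_{ij}\ln P_{ij}$,
   with $0\ln 0 = 0$. A receptor that scores all compounds nearly equally
   has $e_j \approx 1$ and carries no discriminating information.
3. **Entropy weights.** $\omega_j = (1 - e_j) / \sum_j (1 - e_j)$, so
   $\sum_j \omega_j = 1$.
4. **Range normalization and aggregation.** Each column is affinely mapped
   onto $[1, 9]$ — the column minimum to 1, the maximum to 9,
   $a_{ij} = 1 + 8 (v_{ij} - v_j^{\min})/(v_j^{\max} - v_j^{\min})$ — and
   the composite is $b_i = \sum_j \omega_j a_{ij}$.

The direction of the affine map deserves a note: one occasionally sees the
anchors described with min and max "assigned as 9 and 1", which contradicts
the formula above; the formula (min to 1, max to 9, higher = more
degradable, scores treated as positive indicators) is the consistent
reading and is what the package implements.

Degenerate inputs are hard errors rather than silent repairs: nonpositive
or nonfinite scores (the proportions require positive column sums),
constant columns (the affine map is undefined), fewer than two compounds
($\ln m = 0$). All intermediates — proportions, entropies, weights,
normalized matrix, per-column ranges — are retained in the result for
audit.

```{r composite}
scores <- read_score_matrix(fq_example("fq_docking_scores.csv"))
cs <- composite_scores(scores)
cs
```

## The published composite column is a diagnostic

The packaged `fq_composite_reference.csv` holds the composite values as
published alongside the score matrix. Applying the documented pipeline to
the published score matrix gives composites that correlate with the
published column essentially perfectly but sit systematically higher
(mean offset about 0.67 units on the 1-9 scale):

```{r deviation}
dev <- composite_deviation(cs, read.csv(fq_example("fq_composite_reference.csv")))
c(max_abs_dev = dev$max_abs_dev, mean_abs_dev = dev$mean_abs_dev, cor = dev$cor)
```

The published column is therefore not exactly reproducible from the
published scores under this (or, as far as we can tell, any single
consistent) set of weights; `composite_deviation()` reports the
discrepancy instead of gating any test on agreement. Rankings are
unaffected (correlation > 0.99999).

# PLS and the QSAR validation statistics

The 3D-QSAR stage relates molecular-field descriptors to biodegradability
values by partial least squares (PLS1, NIPALS algorithm). Design choices:

* **Centering, no autoscaling by default.** Molecular-field blocks carry
  meaningful relative magnitudes between grid points, so columns are
  centered but not variance-scaled (the classical CoMFA convention);
  `scale = TRUE` enables autoscaling for generic descriptor tables.
* **Determinism.** NIPALS on centered data has no random element;
  identical inputs give bit-identical models. Rank exhaustion stops
  extraction early and the model records the count actually extracted.
* **Leave-one-out $q^2$.** $q^2 = 1 - \mathrm{PRESS} / \sum_i (y_i -
  \bar{y})^2$ with the denominator using the full training-set mean, fixed
  across folds. The component cap is $\min(s-2, p, 10)$.
* **Component selection.** The number of components is the most
  parsimonious count whose $q^2$ reaches the maximum. Real $q^2$ sequences
  never tie exactly; gains below a plateau tolerance (default 0.001 $q^2$
  units, well under any meaningful predictivity difference and well over
  numerically-driven creep, which we measured at about $10^{-4}$) are
  treated as ties and resolved toward the smaller model. `plateau_tol = 0`
  gives the strict argmax.
* **External validation.** $r^2_{pred} = 1 - \sum (y_i - \hat{y}_i)^2 /
  \sum (y_i - \bar{y}_{ref})^2$ over the test set. $\bar{y}_{ref}$ defaults
  to the training-set mean (the standard convention); `ref_mean = "test"`
  selects the literal external-set mean. The choice is recorded in every
  report.
* **Thresholds.** The conventional acceptance flags are strict:
  $q^2 > 0.5$, $r^2 > 0.8$, overfit index $(r^2 - q^2)/r^2 < 30\%$,
  $r^2_{pred} > 0.6$. A report without a test set marks $r^2_{pred}$
  absent rather than failing it.

The published models' field matrices are not recoverable (they require the
original commercial alignment and field engine), so their $q^2$/$r^2$
values enter this package only through the overfit-index arithmetic, which
is exactly reproducible from the printed pairs:

```{r overfit}
round(100 * overfit_index(0.984, 0.765), 2)  # published 1GKQ model: 22.26%
```

# Molecular-field descriptors

The `fields` functions rebuild CoMFA-style descriptors for pre-aligned
conformers on a rectangular lattice (default spacing 2.0 Å, margin 4.0 Å):

* **Steric:** 6-12 Lennard-Jones energy against an sp3-carbon probe
  (radius 1.7 Å, well depth 0.457 kJ/mol), summed over atoms.
* **Electrostatic:** Coulomb energy of a +1 e probe under a linear
  distance-dependent dielectric $\varepsilon(r) = r$, so pair energies fall
  off as $q_i q_p / r^2$ (units resolved by the Coulomb constant
  1389.35 kJ Å mol$^{-1}$ e$^{-2}$).
* **Clamping:** both fields are clamped to ±125.4 kJ/mol (30 kcal/mol),
  the conventional CoMFA threshold; grid points inside an atom are clamped,
  never infinite. Electrostatic values at sterically excluded points are
  replaced by the column mean over non-excluded molecules (toggleable to
  plain clamping).

The original study names only the field types and the 125.4 kJ/mol
threshold; probe identity, functional forms, and grid geometry are the
de-facto standards of the CoMFA family and are all configurable. This
module is therefore validated by its mathematical properties (clamp bounds,
translation equivariance, decay, scalar-formula oracles), not against
published numbers. Alignment and partial charges are input conditions —
the package computes neither.

# Derivative screening

Candidate derivatives of a parent compound (here moxifloxacin, MOX) are
evaluated as signed percent changes versus the parent,
$100 (x_{der} - x_{parent}) / x_{parent}$, for composite and per-receptor
biodegradability, genotoxicity (pLOEC), bioconcentration (logK~ow~), and
photodegradability (log t~1/2~). Reductions are negative numbers — prose
that quotes a "reduction of 129.47%" corresponds to a tabulated change of
−129.47. Changes are reported half-up to 2 decimals to match printed
tables; `round_half_up()` exists because banker's rounding (base
`round()`) disagrees with printed values exactly at the half-way cases
that occur in these tables (e.g. a mean of exactly 0.605).

The bioconcentration red line follows the persistent-pollutant convention:
logK~ow~ strictly greater than 5 fails. Ranking sorts by composite-value
improvement, ties alphabetically.

```{r screening}
rk <- rank_derivatives(read.csv(fq_example("mox_derivatives.csv")))
head(rk[, c("name", "cv_change", "logkow_change", "redline_pass")], 3)
```

The soil-survey summary is a plain per-element mean over sampling sites
(half-up rounding); the amendment levels fed to downstream simulations are
configuration, not derived from the means, and are carried as metadata.

# Factorial analysis of composting amendments and field measures

Binding energies are negative; improvement over a blank is the relative
gain in magnitude, $100(|G| - |G_0|)/|G_0|$. `scenario_report()` flags
groups with positive improvement as beneficial and, for
one-factor-at-a-time amendment designs, names the corresponding additives
from the design table. (Where a published narrative and its design table
disagree on a group-to-additive mapping, the design table is followed.)

For complete $2^k$ designs, `factorial_effects()` estimates
Yates-convention effects: levels coded −1/+1, the effect of a term being
the average coded contrast, so a main effect equals the difference of
marginal means between levels; replicates are averaged per cell first; the
estimates equal exactly twice the least-squares coefficients on ±1-coded
regressors. Incomplete designs are an error — the amendment table
(one additive per group) cannot support interaction estimation, which is
why published interaction estimates from unprinted replicate runs are not
reproduction targets here.

Significance screening offers three methods keyed to data shape:
fixed-effects ANOVA for replicated designs, Lenth's pseudo-standard-error
(the default) for unreplicated ones, and pooling of the highest-order
interactions as error. The Lenth screen reports both the individual margin
of error (used for per-effect verdicts at $p = 0.05$) and the simultaneous
margin (the correct yardstick for statements about all effects at once).

```{r factorial}
fm <- read_design_table(fq_example("field_measures.csv"))
marginal_mean(fm, "organic_fertilizer", 1)
factorial_effects(fm, max_order = 1)
```

# MM/PBSA bookkeeping

The energetics functions implement the end-point identities
$G_{bind} = G_{complex} - G_{protein} - G_{ligand}$ and, per species,
$G = E_{gas} - T S_{gas} + G_{polar} + G_{nonpolar}$ (energies kJ/mol,
entropy kJ/mol/K, temperatures of 308 K and 328 K as the thermophilic
presets). `validate_energy_record()` reports which identities hold and
with what residual, and never raises: it is a consistency check over
externally produced component tables. Published studies in this area print
only net binding energies, so component-level behavior is validated by
construction through the seeded generator.

# Synthetic data: what it emulates and what it does not

Every analysis stage has a seeded generator producing inputs with the
statistical structure that stage assumes; all generators restore the
session RNG state and are bit-reproducible under a seed.

* `sim_score_matrix()` draws positive truncated-normal scores with
  per-column means defaulting to a 70-120 spread and sd 10, mirroring the
  range of LibDock-style score tables. It does not mimic docking physics;
  scores are statistical stand-ins.
* `sim_qsar_dataset()` builds $X = T P' + \epsilon$ with a decaying latent
  spectrum (score sds $2^{k-j}$ — a dominant-to-minor factor structure) and
  $y = T q + \epsilon$ with every component's loading bounded away from
  zero ($|q_j| \in [0.5, 1.5]$ on unit-scaled scores). Both choices are
  deliberate: with a flat spectrum or a response that is a generic linear
  functional of $X$, PLS can capture the response in fewer than $k$
  components and "recover the latent dimension" is not a well-posed target.
  The implied coefficient vector ($y = X\beta$ in the noiseless limit) is
  stored for recovery tests.
* `sim_factorial_response()` enumerates a complete $2^k$ design and adds
  effects under the same ±1 coding the estimator uses, so $\sigma = 0$
  recovery is exact by construction.
* `sim_energy_records()` draws components and computes totals from them,
  making the decomposition identities hold exactly; a perturbation flag
  injects known residuals for detector tests.

Passing tests on these generators demonstrate correctness of the
estimators under their stated models — they do not demonstrate that real
docking scores are truncated-normal, that real field matrices have clean
low-rank structure, or that real composting responses are additive
Gaussian.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale: published
tables are used at their full printed size (49 compounds × 3 receptors,
10 derivatives, 12 survey sites, $2^3$ field-measure design), simulations
use tens of samples and tens to hundreds of seeds (e.g. 200-seed
permutation nulls at $s = 16$, 50-seed latent-dimension recovery at
$s = 30, p = 30$, 100-200-seed Lenth error-rate checks), sizes at which
each property is statistically decisive while the full suite completes in
well under a minute of compute. Tolerances follow the quantity: printed
percentages to ±0.01, oracle equivalences to $10^{-12}$ (one arithmetic
reordering), PLS-vs-OLS identities to $10^{-8}$ (matrix inversion),
simulation success rates at the documented thresholds.

# Known limitations

* The composite pipeline treats all receptors as positive indicators;
  cost-type criteria would need a reversed normalization that the study
  design never required.
* PLS is single-response (PLS1); multi-response fitting is out of scope.
* Lenth critical values use the standard t approximation rather than
  simulated exact quantiles — slightly conservative at small $m$.
* The field engine assumes rigid, pre-aligned, pre-charged conformers and
  evaluates only the two classical CoMFA fields; no hydrophobic or
  H-bond fields.
* `conformer_from_pdb()` requires the optional bio3d package and carries
  no charges (PDB has none); SDF input should be converted to coordinates
  plus a charge vector upstream.
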