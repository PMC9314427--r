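---
title: "Modeling overall stability constants with cascaded Gaussian process regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling overall stability constants with cascaded Gaussian process regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabcast)
library(dplyr)
```

## The problem

When a metal cation M and an organic ligand L are mixed in aqueous
solution, complexes M-L$_n$ form by stepwise ligand addition.  The
$n$-th *overall stability constant* $\beta_n$ (handled throughout on the
log$_{10}$ scale) is the sum of the stepwise log equilibrium constants,
$\beta_n = \sum_{i \le n} \log_{10} K_i$.  Stability constants control
the free-metal concentration in plating baths, metal-separation
processes and chelation chemistry, so predicting $\beta_n$ for arbitrary
(M, L) pairs — without measuring every candidate — is of direct
industrial interest.

stabcast implements a two-stage ("cascade") regression workflow:

1. a Gaussian-process model for the first constant $\beta_1$ built from
   cation element-level features, SMILES-derived ligand descriptors and
   the experimental conditions;
2. a second Gaussian-process model for the multi-order constants
   $\beta_n$ ($n \ge 2$) whose most important inputs are the *predicted*
   $\beta_1$ of the record's (M, L) pair and its 1$\sigma$ uncertainty,
   together with the complex charge (cation charge + ligand molecular
   charge), the number of ligands still to be added ($n-1$), and any
   ligand descriptors the final $\beta_1$ model did not use.

Because the stepwise constants decrease ($K_1 > K_2 > \cdots$), every
consistent family obeys the universal inequality

$$\beta_{n-1} < \beta_n < n\,\beta_1,$$

which the package exposes as a QC check (`check_inequality()`,
`check_records_inequality()`) and which the synthetic generator
satisfies by construction.

## Data model and curation

Records are plain tibbles with one measurement per row: cation symbol
and charge, ligand SMILES, ligand molecular charge in aqueous solution,
coordination count `n`, `beta` (log$_{10}$), temperature (°C), ionic
strength (mol/L) and a free-text source tag.  `parse_records()`
validates rows (SMILES must parse, `n ≥ 1`, finite `beta`, ionic
strength ≥ 0, cation charge ≥ +1) and canonicalizes SMILES so notation
variants of one ligand compare equal.

Two curation rules reflect how large stability-constant compilations
are cleaned in practice:

* **Exclusions** (`apply_exclusions()`): records whose cation is a
  heavy actinide (Am, Cm, Cf, Bk, Es, Fm, Md) or whose ligand contains
  Te, Se, As, Mn, Co, Fe, W, Mo, Cr or Re are dropped — molecular
  descriptors for these elements are unreliable.  Note the rule is
  asymmetric: Co$^{2+}$ is a perfectly good *cation*, but cobalt inside
  a *ligand* is excluded.
* **Duplicate resolution** (`resolve_duplicates()`): for each
  (cation, charge, ligand, n) key one record survives, chosen by
  condition priority — (1) 25 °C and I = 0.1 mol/L, (2) 25 °C at any I,
  (3) any T at I = 0.1, (4) everything else — and, within the winning
  tier, by the largest `beta`.  Tier membership uses
  |T − 25| ≤ 0.5 °C and |I − 0.1| ≤ 0.005 mol/L: reported conditions
  are rounded values, and exact equality would misclassify entries
  like "25.0" vs "25".  An exact tie on `beta` keeps the first-seen
  record, so resolution is deterministic given input order.

## Features

**Cations.** Twelve element-level features per cation species: charge,
atomic number, melting point, molar heat capacity, Shannon ionic radius
(6-coordination, charge-specific), atomic polarizability, electron
affinity, Pauling electronegativity, and the numbers of unfilled s, p,
d and f electrons of the ion.  The first eight are shipped as a
plain-text reference table (`cation_features()`); the unfilled-orbital
counts are derived in code from an aufbau configuration of the ion
(electrons removed from the highest shell first, with the standard
d/f filling exceptions; per angular momentum we count the vacancies of
the highest occupied subshell, or the full capacity if no subshell of
that kind is occupied).  The table covers 57 cation species; values are
rounded standard reference values, which is sufficient because they act
as regression inputs, not as thermodynamic constants.

**Ligands.** `ligand_descriptors()` computes 2-D compositional and
topological descriptors from SMILES via OpenBabel: molecular properties
(MW, logP, TPSA, molar refractivity, H-bond donor/acceptor counts),
element counts, ring counts, and SMARTS fragment counts named in the
atom-type fragment convention (`NssNH` = secondary-amine −NH−,
`NssO` = ether-type −O−, `NaaO` = aromatic O, ...).  Nitrogen and
oxygen fragments matter chemically: they are the usual coordination
sites.  The ligand's molecular charge in aqueous solution is appended
as a descriptor; it is an *input* — the package deliberately does not
attempt pK$_a$-based speciation.  No 3-D conformers are generated: the
complex's solution geometry is unknown, so only graph-derived features
are defensible.

**Pruning.** Descriptor sets are pruned in a fixed order:

1. `drop_degenerate()` removes columns that are constant or contain any
   missing value.  A descriptor failure is molecule-specific, so the
   *column* is removed rather than the row — silently shrinking the
   dataset would bias curation.
2. `correlation_filter()` scans ordered pairs (i before j) and drops j
   when |Pearson r| > 0.7.  The comparison is strict — a pair at
   exactly 0.7 survives — with a 10⁻¹⁰ guard absorbing last-bit
   floating-point rounding of the computed correlation.  The earlier
   column wins, making the filter deterministic in table order.
3. `vif_filter()` iteratively removes the column with the largest
   variance inflation factor until all VIF < 4, computing all VIFs at
   once from the inverse correlation matrix; exact collinearity yields
   VIF = ∞ (detected by pivoted QR) and is removed first.

`assemble_beta1_descriptor()` concatenates the 12 cation features, the
pruned ligand block (with molecular charge) and the two condition
columns, tagging each column's provenance (cation / ligand /
condition); the cascade stage adds columns tagged `cascade`.

## Gaussian process regression

The kernel is Matérn-3/2,
$k(x_i, x_j) = \sigma^2 (1 + \sqrt{3}r)\exp(-\sqrt{3}r)$, with the
automatic-relevance-determination (ARD) distance
$r = \left(\sum_m (x_{im} - x_{jm})^2 / l_m^2\right)^{1/2}$: each
feature has its own length scale $l_m$, and $1/l_m$ expresses how much
the fit lets that feature matter.  With all $l_m$ equal the kernel
reduces exactly to the isotropic form.

`fit_gpr()` chooses the hyperparameters — $\log\sigma$, $\log l_m$, and
a learned observation-noise standard deviation — by L-BFGS-B
maximization of the log marginal likelihood with analytic gradients.
Design choices worth stating:

* **Noise model.** Experimental $\beta$ values carry measurement error,
  so a learned Gaussian noise variance is included by default (exact
  interpolation of noisy data would be both wrong and numerically
  fragile); `noise = "fixed", noise_value = 0` recovers the
  interpolating GP for clean data.  A small diagonal jitter (10⁻⁸,
  escalated automatically if the optimum sits at a barely positive
  definite covariance) keeps the Cholesky factorization stable without
  spoiling noise-free interpolation.
* **Restarts.** The likelihood surface is multimodal; by default 5
  restarts are run, the first from neutral values
  ($\sigma = 1$, $l_m = \sqrt{d}$, noise 0.3 on the standardized
  target), the rest drawn log-uniformly around them under the
  configured seed, so fits are exactly reproducible.
* **Standardization.** Targets are z-scored internally and predictions
  de-standardized; features are z-scored with training statistics
  stored in the model, so prediction-time rows are always transformed
  with the *training* metadata.
* **Scale.** The covariance is dense; the practical ceiling of exact
  GPR is roughly 10⁴ rows.  `max_rows` provides a uniform subsampling
  switch (seeded) for larger inputs.

The predictive variance includes the noise variance, so far from all
training data the 1$\sigma$ band reverts to
$\sqrt{\sigma^2 + \text{noise}^2}$ — the model says "I don't know"
rather than extrapolating confidently.

## Relevance by KL sensitivity

Inverse length scales are a crude relevance measure; a fitted model can
hold a short length scale for a feature the posterior barely uses.  The
package instead perturbs each (standardized) feature by
$\delta = 0.001$ at every evaluation row and measures the
Kullback–Leibler divergence between the unperturbed and perturbed
univariate predictive Gaussians, averaged over rows
(`feature_relevance_kl()`).  Normalizing the per-feature means to sum
to one gives the *standardized relevance*.  Choices made where the
measure itself leaves room:

* direction KL(unperturbed ‖ perturbed), the most common form;
* $\delta$ applied in standardized units — in raw units a fixed
  perturbation is meaningless across heterogeneous descriptors;
* evaluation rows default to the training rows (self-sensitivity) and
  can be any held-out table;
* a single positive $\delta$ (not symmetric two-sided), since at
  $\delta = 0.001$ the divergence is locally quadratic and the sign is
  immaterial.

`optimize_feature_count()` refits the model on the top-$k$ features in
decreasing relevance order and evaluates MAE and $R^2$ on a validation
set, returning the full curve and the MAE-minimizing $k$ (ties to the
smaller $k$).  The default grid is every $k$ up to min(d, 20) plus
multiples of 5.

**Validation split.** Record-level cross-validation flatters this
problem: common ligands appear with many cations, so random folds leak
ligand identity.  `select_validation_ligands()` therefore holds out
whole ligands, chosen with awareness of the applicability domain: each
ligand's mean distance to the other ligands is computed in standardized
descriptor space (optionally under the fitted ARD metric), ligands are
stratified into distance quintiles, and the hold-out (default 20) is
sampled proportionally with at least 4 picks guaranteed from the most
distant stratum — validation deliberately includes the domain edge,
where generalization claims are earned.

## The cascade

`fit_cascade()` fits the $\beta_1$ model on the n = 1 stratum and the
$\beta_n$ model on the n ≥ 2 stratum.  The $\beta_n$ descriptor's
predicted-$\beta_1$ features are generated *out-of-fold* during
training: the n = 1 pairs are partitioned into 5 folds, and a pair's
$\beta_n$ rows receive predictions from a posterior conditioned only on
the other folds, so the $\beta_1$ model's in-sample fit never leaks
into the second stage.  Only the posterior is recomputed per fold —
hyperparameters come from the single full fit, which at these data
sizes changes nothing inferentially and keeps the cost of the fold loop
at five Cholesky factorizations.  At prediction time the full $\beta_1$
model is used, and the $\beta_1$ feature is always a *prediction*,
never a lookup of a measured value — many (M, L) pairs in the n ≥ 2
stratum have no measured $\beta_1$ at all.

One multi-order model is fitted with $n - 1$ as a feature; separate
per-n models would fragment the smaller high-order strata.

## The synthetic generator

Real curated stability-constant compilations are proprietary, so the
package ships a generator whose output exercises every pipeline stage:

* **Entities.** Cations are drawn from the bundled 57-species feature
  table.  Ligands come from a template grammar (functionalized alkyl
  backbones with amine/hydroxyl/carboxyl/thiol end groups and optional
  mid-chain substituents, plus polyamine, aminopolycarboxylate,
  hydroxy-acid, polyol and (hetero)aromatic chelator templates) — about
  3,000 distinct molecules using only H, C, N, O, S, so fragment
  descriptors such as −NH− and −O− counts vary meaningfully and no
  ligand trips the exclusion rules.  Aqueous charges follow a fixed
  rule: −1 per carboxyl (fully deprotonated), other groups neutral — a
  deliberate simplification of pH-dependent speciation.
* **Planted effect.**
  $\log K_1 = 1.5 + 3.0\,(EN_M - 1.5) + 1.2\,(q_M - 2) - 1.5\,q_L +
  0.8\,n_N + 0.5\,n_O\;[+\,0.4\,(EN_M-1.5)(n_N+n_O)] + \varepsilon$,
  dominated by electronegativity- and charge-like columns — the
  structure the relevance analysis should recover.  Noise
  ($\varepsilon$, default sd 0.3 log units, a realistic reproducibility
  figure for literature $\beta$ values) enters at the (M, L)-pair
  level.  $\log K_1$ is clipped below at 0.1: real datasets contain
  negative $\beta_1$ values, but positivity is required for the
  geometric construction below, and this simplification is accepted.
* **Higher orders.** $\log K_i = \rho^{\,i-1} \log K_1$ with
  $\rho \sim U(0.45, 0.85)$ per pair, so
  $\beta_n = \log K_1 (1-\rho^n)/(1-\rho)$.  With $\rho$ strictly
  inside (0, 1) and $\log K_1 > 0$, the universal inequality holds for
  every record *by construction*.  Maximum orders follow a long-tailed
  distribution (most pairs stop at n = 1, few reach 5–6), mirroring
  how sparse high-order measurements are in practice.
* **Conditions.** Records concentrate at 25 °C / 0.1 mol/L with 15 %
  off-condition; 5 % of records get an injected off-condition duplicate
  whose $\beta$ is perturbed downward by less than the family's minimum
  inequality gap, so the invariant survives even before duplicate
  resolution.
* **Defaults.** 57 cations, 2,706 ligands, 13,559 pairs — the scale of
  a serious compilation.  Tests and examples pass smaller sizes
  explicitly.

What passing tests on this generator does **not** show: real ligand
descriptors are far higher-dimensional and collinear than the grammar's
output; real $\beta_n$ families deviate from a clean geometric decay;
real charges are speciation-dependent.  The generator validates the
*machinery* (recovery of planted structure, inequality handling,
cascade value), not chemical accuracy on real data.

## Numerical choices and degenerate inputs

* Correlation-filter threshold comparisons carry a 10⁻¹⁰ tie guard
  (strict inequality otherwise).
* VIF of an exactly collinear column is +∞; pivoted QR identifies the
  dependent columns when the correlation matrix cannot be inverted.
* Zero-variance columns are an error at standardization time (they
  should have been removed by `drop_degenerate()`).
* Constant targets are fitted with unit target scale and yield constant
  predictions with variance bounded by the prior.
* Cholesky failures trigger jitter escalation and, if that fails, an
  informative error reporting the conditioning; the default jitter is
  10⁻⁸.
* Problem sizes used in the shipped tests and acceptance script are
  deliberately moderate (hundreds to ~2,000 records, descriptor
  dimensions of a few dozen) — large enough to exhibit every planted
  property, small enough to run routinely.

## Known limitations

* Exact GPR only; no sparse approximations, no Bayesian-optimization
  search loop.
* Monoatomic cations only (no NH$_4^+$ / UO$_2^{2+}$-type species).
* The bundled cation table covers 57 common species; unknown cations
  are a hard error, not an extrapolation.
* Ligand aqueous charge is taken as input, not computed from pK$_a$.
* The applicability-domain hold-out rule (distance quintiles with a
  guaranteed far-stratum quota) is one defensible formalization of
  "validate near the domain edge"; other formalizations exist.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(n_cations = 25, n_ligands = 120, n_pairs = 700,
                       seed = 7)
records <- generate_dataset(spec) |>
  parse_records() |>
  resolve_duplicates()

lig <- dplyr::distinct(records, smiles, ligand_charge)
ligand_tbl <- ligand_descriptors(lig$smiles, lig$ligand_charge) |>
  drop_degenerate() |> correlation_filter() |> vif_filter()

held <- select_validation_ligands(ligand_tbl, count = 20, seed = 1)
train <- dplyr::filter(records, !smiles %in% held)
test <- dplyr::filter(records, smiles %in% held)

cascade <- fit_cascade(train, ligand_tbl = ligand_tbl,
                       config = cascade_config(restarts = 2, seed = 0))
glance(cascade)

rel <- feature_relevance_kl(cascade$betan_model)
autoplot(rel)          # predicted beta_1 should rank first

pred <- predict(cascade, test)
plot_parity(test$beta, pred)
```
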