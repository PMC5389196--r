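---
title: "Methods: QSPR modelling of dioxin adsorption on C60"
author: "nanoqspr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSPR modelling of dioxin adsorption on C60}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoqspr)
```

## The problem

Halogenated dibenzo-*p*-dioxins (PXDDs, X = Br and/or Cl) form a congeneric
family of 1,701 symmetry-distinct molecules. Quantum-chemical calculation of
the adsorption energy of every congener on a C60 fullerene surface is
prohibitively expensive, so the workflow implemented here calibrates a
quantitative structure-property relationship (QSPR) on a small,
well-chosen subset and extrapolates to the full family:

1. enumerate all symmetry-distinct H/Cl/Br substitution patterns of the
   dibenzo-*p*-dioxin skeleton;
2. attach a 26-column molecular-descriptor table;
3. select 32 representative congeners (about 2%) with the Kennard–Stone
   algorithm and split them 24 training / 8 validation;
4. select descriptors with a genetic algorithm (GA) and fit partial least
   squares (PLS) regression of the adsorption energy;
5. validate internally (leave-one-out) and externally, assess the
   leverage-based applicability domain, and predict the remaining 1,669
   congeners.

## Congener enumeration

The planar tricyclic skeleton has eight substitutable carbon positions,
numbered 1,2,3,4,6,7,8,9. Its in-plane symmetry group has order 4:
the identity, the mirror across the long axis `(1 4)(2 3)(6 9)(7 8)`, the
mirror across the short in-plane axis `(1 6)(2 7)(3 8)(4 9)` and the
two-fold rotation `(1 9)(2 8)(3 7)(4 6)`. These permutations are forced by
requiring the lateral positions {2,3,7,8} and the axial positions {1,4,6,9}
to be the two position orbits. Burnside's lemma gives the orbit count over a
k-letter substituent alphabet as $(k^8 + 3k^4)/4$: 1,701 for {H, Cl, Br}
and 76 for {H, Cl}; `enumerate_congeners()` reproduces both by explicit
canonicalization, and the test suite cross-checks the brute-force count.

Canonical form is the lexicographic minimum of the orbit under H < Cl < Br,
and enumeration order is lexicographic over canonical tuples — both chosen
so congener indices are deterministic and reproducible across runs.
Display names instead follow IUPAC lowest-locant renumbering over the
orbit (ties resolved in favour of bromo, the substituent cited first
alphabetically), so that names like
`1,2,3,7,8-pentachlorodibenzo-p-dioxin` match the published usage even
though the stored canonical tuple places halogens at high positions.

## The synthetic data generator

The original descriptors were semi-empirical (PM6) quantities and the
reference adsorption energies came from dispersion-corrected DFT. Neither
is recomputable at desk scale, so the package ships a generator that
emulates exactly the structure the QSPR model assumes:

* `nH` — hydrogen count, $8 - n_\mathrm{Cl} - n_\mathrm{Br}$;
* `TE` — a strictly additive total energy,
  $12 a_C + 2 a_O + n_H a_H + n_{Cl} a_{Cl} + n_{Br} a_{Br}$, on an
  atomic-unit-like scale (defaults C −38, O −75, H −0.5, Cl −460,
  Br −2574), composition-only and hence constant on symmetry orbits;
* `Dx`, `Dy` — in-plane dipole components from a vector sum of bond
  dipoles over substituted positions. The long molecular axis through the
  ring oxygens is x; the short in-plane axis is y, with the axial
  positions 1,4,6,9 pointing along ±y and the lateral positions 2,3,7,8 at
  ±30° off x (an idealized planar geometry; the exact vectors are a
  configurable constant and are equivariant under the symmetry group).
  Bond-dipole magnitudes default to Cl 1.6 and Br 1.2 (debye-like), with
  the chlorine moment larger, consistent with the Pauling
  electronegativities (Cl 3.16 > Br 2.96) — so more chlorinated congeners
  carry the larger dipole;
* 22 nuisance descriptors `d05`…`d26` — seeded standard Gaussians with
  configurable correlation to the informative block (independent by
  default). Their names are generic because only their statistical role
  (decoys for descriptor selection) matters.

The ground-truth adsorption energy is linear plus noise,

$$E_\mathrm{ads} = c_0 + c_1\,\mathrm{nH} + c_2\,\mathrm{TE} +
  c_3\,D_x + c_4\,D_y + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma^2),$$

with defaults $c = (1.5, -2.9, 5\times10^{-4}, 1.2, -0.8)$ and
$\sigma = 0.5$ kcal/mol, inside the 0.3–0.7 kcal/mol error band commonly
quoted for the M06-2X functional the reference energies would come from.
These defaults were chosen so that

* generated energies span roughly −22 to +1 kcal/mol, negative
  (favourable) for hydrogen-rich, axially substituted congeners and near
  zero for fully chlorinated ones, with slightly positive values read as
  "practically no interaction";
* brominated congeners adsorb distinctly more strongly than their
  chlorinated counterparts (the Cl-vs-Br contrast enters through `TE`);
* each of the four informative descriptors carries a kcal-scale
  contribution, so descriptor selection is a meaningful planted-signal
  problem;
* laterally substituted (toxicologically potent) congeners have *higher*
  predicted energies, i.e. the lowest sorption potential, than axially
  substituted ones.

The sign convention is negative = favourable adsorption throughout.
(Hess's-law formulations that subtract the complex energy from the sum of
the separated molecules would make stable binders positive; this package
follows the dominant convention of the sorption literature instead.)

What the generator deliberately does **not** emulate: positional
(regiochemical) dependence of the total energy — TE here is
composition-only, so e.g. the 2,3,7,8- and 1,4,6,9-tetrachloro congeners
share identical descriptors and predictions, which real PM6 descriptors
would distinguish; nonlinearity of the structure-energy map; correlated
descriptor noise; and any temperature dependence. Passing tests therefore
demonstrate that the *pipeline* recovers a known ground truth under
realistic dimensions and noise, not that the physical model is correct.

## Kennard–Stone selection and the 24/8 split

Selection happens in the autoscaled space of **all 26** descriptors, since
in the workflow subset selection precedes descriptor selection.
Autoscaling uses the n−1 standard-deviation denominator and refuses
zero-variance columns. Kennard–Stone picks the two mutually farthest
compounds first, then repeatedly adds the compound maximizing the minimal
Euclidean distance to the already-selected set; all argmax ties break
toward the lowest row index so the selection is deterministic. There is
no canonical rule for dividing a Kennard-Stone selection into training and
validation sets; this package uses a deterministic systematic rule — every 4th
compound in selection order (ranks 4, 8, …, 32) goes to validation —
which spreads the validation set evenly across the selection sequence.

## GA-PLS

PLS1 is implemented as NIPALS with X-deflation, fit on autoscaled X and y;
the model stores weights, loadings, scores, the per-LV-count regression
vectors, and the coefficient vector back-transformed to the original
scale (intercept plus one term per descriptor), which is how the model
equation is exported. NIPALS was chosen over kernel/SIMPLS variants for
transparency: at full rank it reproduces the ordinary-least-squares
solution, which the tests assert against a normal-equations oracle at
1e-8.

Internal validation is leave-one-out: each fold recomputes the autoscaling
statistics (a deliberate decision — freezing them would leak the held-out
compound into the preprocessing), refits, and predicts the excluded
compound; $Q^2_{CV} = 1 - \mathrm{PRESS}/\mathrm{TSS}$ about the full
training mean and $\mathrm{RMSE}_{CV} = \sqrt{\mathrm{PRESS}/n}$. The
LV count is the minimizer of RMSE~CV~, ties toward fewer. External
validation uses the $Q^2_{F1}$ convention (denominator about the
*training* mean), the standard choice of the QSAR validation literature
when the criteria reference does not print a formula.

Descriptor selection is a binary-chromosome genetic algorithm: population
64, 100 generations, tournament selection of size 2, single-point
crossover at 0.8, bit-flip mutation at 1/p, elitism 2, all seeded. These
hyperparameters were sized for reliable recovery of a small planted subset at p = 26 candidates and
n = 24 training compounds. Fitness is the leave-one-out RMSE~CV~ of a PLS
fit on the encoded subset, with the LV count chosen by cross-validation
inside the evaluation (capped at min(|subset|, 8) — on 23-compound folds,
deeper models only fit noise, and the cap bounds the search cost), plus a
parsimony penalty of 0.1 kcal/mol per selected descriptor. The penalty
deserves a note: with pure RMSE~CV~ fitness, an intensive search at
n = 24 reliably discovers nuisance descriptors whose chance correlation
with the realized noise lowers the cross-validation error — the classic
selection-on-the-selection-criterion trap — and the resulting 10+-variable
models visibly degrade external validation. A penalty of 0.1 kcal/mol
(one fifth of the default noise level, far below any mechanistically
meaningful contribution) suppresses these chance gains while leaving the
genuinely informative descriptors untouchable; with it, the GA returns
exactly {nH, TE, Dx, Dy} across seeds at both 0.1 and 0.5 kcal/mol noise.
Setting `subset_size_penalty = 0` restores the pure-RMSE~CV~ fitness.

## Applicability domain

Leverage is computed in the autoscaled space of the model's selected
descriptors — not the latent-variable score space — with query rows scaled
by the training statistics: $h = x^\top (X^\top X)^{-1} x$ via a stable
solve. No intercept column is appended (X is column-centered by
autoscaling); the "+1" lives in the critical-leverage formula
$h^* = 3(p+1)/n$, which gives the conventional 0.625 at p = 4, n = 24.
The Insubria table pairs each congener's leverage with its predicted
energy and set membership, flagging `in_domain = h <= h*`; its CSV export
is the data behind an Insubria plot.

## Numerical and degenerate-input choices

* Autoscaling: n−1 denominator everywhere; zero-variance columns are an
  explicit error naming the column, including inside LOO folds.
* NIPALS declares a degenerate component (weight norm < 1e-12) an error —
  requesting more LVs than the rank of X is refused, not silently
  truncated.
* All argmax/argmin ties (Kennard–Stone, LV count, GA ranking) break
  toward the lowest index / fewer components.
* Every stochastic stage takes an explicit integer seed; the pipeline
  derives stage seeds from one master seed (generator = seed, noise =
  seed + 1, GA = seed + 2) and records them in the run log, so a rerun
  with the same configuration is numerically identical.
* The GA fitness cache may be shared across runs on the same data
  (fitness is a pure function of the subset); it must never be reused
  across data sets.

## Problem sizes used in the tests

The test suite exercises the full 1,701-congener enumeration and pipeline;
oracle comparisons (PLS vs OLS, Kennard–Stone vs exhaustive maximin,
leverage vs explicit inverse) run on 10–30-compound instances where the
brute-force reference is exact; the GA planted-signal experiment uses the
study dimensions (24 training compounds, 26 candidates) over 20 GA seeds
at 0.1 kcal/mol noise; and sample-size scaling of the coefficient error is
measured at n = 24, 100, 400 averaged over 20 seeded draws each.

## Known limitations

* Descriptors are composition- and idealized-geometry-based; symmetric
  substitution patterns with identical composition are indistinguishable,
  which real quantum-chemical descriptors would separate.
* The published reference statistics for this system (R² = 0.998,
  Q²ext = 0.956, RMSEp = 2.285, TCDD predicted 0.733) can only be
  reproduced from the reference study's supplementary descriptor tables,
  which are not redistributable with this package. The loading path for a user-supplied table
  (`read_descriptor_table()`, `run_config(descriptor_table = ...)`)
  implements the contract; the corresponding acceptance check fails
  honestly when the file is absent.
* Congener indices follow this package's canonical enumeration order and
  will not match orderings of other generator software; matching must go
  through names.
* Only leverage-based AD is implemented; a Williams plot would require
  experimental responses for the prediction set, which do not exist by
  construction.
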