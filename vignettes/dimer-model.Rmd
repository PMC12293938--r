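---
title: "The complete-filling dimer model and DNA charge inversion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The complete-filling dimer model and DNA charge inversion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerdna)
```

## The model and its assumptions

`dimerdna` treats rigid dimers adsorbed on a rectangular lattice in the
grand canonical ensemble. The assumptions are:

* dimers interact only through site exclusion (no dimer-dimer forces,
  no electrostatic interactions between adsorbed species);
* the lattice is rectangular with free (non-periodic) boundaries;
* the two-dimensional routes require *complete* filling (ν = 1, every site
  covered) — partial filling in 2D is not solvable within this framework
  and is out of scope;
* horizontal and vertical dimers may carry different activities
  `x = exp(-β(εx - μx))`, `y = exp(-β(εy - μy))`.

Monomers and vacancies enter only through the one-dimensional reduction:
the two-leg ladder seen edge-on is a chain in which the rung dimers act as
monomers, and coloring those monomers into two species (bound perpendicular
dimers, activity `z⊥`; empty backbone sites, activity `v`) converts the
ladder result into the dimer-monomer-vacancy chain. The binomial
degeneracy of the coloring makes this exact: the colored chain is the
one-color chain at monomer activity `z⊥ + v`.

## Why four routes

The partition function is computed four ways — trace-algebra expansion,
exhaustive matching enumeration, Pfaffian, and analytic closed form — and
the test suite requires them to agree to relative 1e-8 on every lattice
with `nr, nc ≤ 4` (even site count) plus 2×6 and 4×6, over a 5×5 grid of
activities spanning 0.25–4. The first two routes are exponential-cost
oracles that are "obviously correct"; the Pfaffian and closed form are the
production paths. This is the package's primary defense against sign and
convention errors, which are the dominant failure mode in Pfaffian methods.

Problem sizes were chosen so the whole cross-validation runs in seconds:
the symbolic expansion prunes its depth-first product so its cost is
proportional to the number of coverings (281 on 4×6) rather than to the
naive 4^N terms, and the enumeration recursion covers the lowest-numbered
free site first, which keeps the search tree tight.

## Conventions that required a decision

* **Serpentine numbering** is 1-based and starts at the upper-left corner,
  odd rows running left to right. Rows count downward, matching the matrix
  convention for element (1,1). Vertical links then always span an odd
  index difference, which is what makes every surviving trace term positive
  and the signed Pfaffian positive at positive activities (both are tested).
* **Block convention.** The activity matrix is block-tridiagonal with
  `nr` diagonal blocks of size `nc`; where a worked example's prose and its
  matrix disagree about which factor is rows and which is columns, the
  matrix (block dimensions) is followed.
* **Eigenvalues of the within-row block** are `λ_ω = 2ix sin(φ_ω)` — the
  activity factor is part of the eigenvalue (the difference equation fixes
  `λ/x = 2i sin φ`), and all angle quantizations use `nc + 1` (column
  count plus one) in the denominator. Both choices are verified numerically
  by eigen-residuals below 1e-12 up to `nc = 32`.
* **Lattice-gas entropy sign.** The grand-canonical entropy per site is
  evaluated as `S/kB = ln Σa − (Σ a ln a)/Σa`, the direct β-derivative of
  the free energy; this is the sign-consistent form (it gives `+ln 2` for
  two equal species and equals the Gibbs–Shannon entropy of the site
  distribution). The chain entropy uses the same definition, which
  reproduces the closed-form expression implemented in
  `entropy_site_chain()` and is cross-checked against a centered numerical
  β-derivative at 50 random parameter points (relative 1e-6).
* **Charge convention.** Physical charge bookkeeping (vacancy −1,
  perpendicular dimer +1, parallel dimer neutral) gives the signed net
  charge `n⊥ − nv`, the package default. The literal sum `n⊥ + nv` that the
  comparison figure's axis label suggests is available via
  `convention = "as_printed"`; the signed form is the one whose
  strong-binding plateau `(1 + 4 e^{-βμ})^{-1/2}` and weak-binding
  model-coincidence checks both hold, so it is treated as the intended
  quantity.
* **Vacancy activity** defaults to `v = 1` (a hole has neither binding
  energy nor chemical potential) and is held fixed under β-derivatives.

## Numerical choices

* **Pfaffian.** Direct signed-pairing expansion for orders ≤ 8; for larger
  orders a Parlett–Reid-style skew-symmetric elimination with partial
  pivoting (each pivot swap flips the sign), O(n³) and stable. Skew-symmetry
  is verified on input to relative 1e-12; `Pf² = det` is tested to relative
  1e-8 on random matrices of orders 2–12.
* **Closed-form products in log space.** The squared closed form multiplies
  `nr·nc` complex factors; `z_squared_closed()` accumulates log-magnitude
  and phase separately, asserts the residual phase is 0 or π, and restores
  the sign analytically, so 40×40 lattices do not overflow doubles. A
  factor whose magnitude falls below `1e-14 · (2x + 2y + 1)` is treated as
  an exact zero (it arises when both quantized cosines sit at their zero,
  i.e. odd×odd lattices, where no complete filling exists).
* **2D thermodynamic limit.** The double integral for the infinite-lattice
  free energy uses the analytic inner integral
  `∫₀^π ln(a + b cos s) ds = π ln[(a + √(a²−b²))/2]` and adaptive
  quadrature (`stats::integrate`, relative tolerance 1e-10) on the outer
  variable, integrating over the direction of the smaller activity. The
  `(1/4) ln 2` prefactor is kept so that `y = 0` reduces exactly to
  `(1/2) ln x` (rows decouple into packed chains); dropping it, as a
  per-site limit taken naively would, breaks that reduction. The value at
  `x = y = 1` is checked against Catalan's constant over π (series oracle)
  and against an independent Gauss–Legendre product rule of the raw double
  integral; finite `n×n` lattices (n = 8–32) approach it monotonically.
* **Zero activities.** `0 · ln 0 ≡ 0` throughout, so zero-activity species
  are legal inputs everywhere.
* **Dispatcher.** `partition_function(..., method = "closed")` uses the
  square-root-free closed form whenever one lattice direction is even
  (transposing and swapping activities if needed — the x↔y transposition
  symmetry is tested) and falls back to `sqrt(z_squared_closed())` only
  when impossible, i.e. never for an even site count.

## The DNA application

The sweep couples the perpendicular binding energy to half the parallel one
(`βε⊥ = βε‖/2`: one bound end instead of two), fixes all chemical
potentials to the solution value `βμ = 0.79` (physiological temperature;
temperature enters only through such dimensionless products), and sets
`v = 1`. The default range `βε‖ ∈ [−20, 10]` in steps of 0.1 covers both
asymptotic regimes — the entropy and charge plateaus are reached well
before −20 (the plateau is flat to 1e-3 kB between −30 and −40, which the
suite checks) — and the range is a package choice, since only the regimes,
not the axis limits, are physically fixed.

The lattice-gas baseline maps the parallel dimer to a point particle with
twice the single-end binding energy (activity `x‖`), exactly the
independent-site comparison the dimer geometry is being contrasted with.

Inputs to all validation are generated internally (small lattices, random
activity draws under fixed seeds); no external data exist for this purely
theoretical model. Consequently the tests demonstrate internal exactness
and asymptotic consistency, not agreement with any experiment: the model
itself neglects dimer-dimer electrostatics, solvent structure and sequence
heterogeneity, all of which affect real DNA condensation.

## Known limitations

* No periodic/toroidal boundaries (the four-Pfaffian torus construction is
  not implemented), no non-rectangular lattices, no 3D.
* No monomers in the two-dimensional routes: partial filling is exact only
  on the chain. The two-Pfaffian product form that would lift this is
  future work.
* The exponential oracles are usable to ~24 sites; beyond that only the
  Pfaffian (to a few thousand sites) and the closed form (any size, log
  space) apply.
* Entropies are reported in units of kB and charges in units of the
  elementary charge; no dimensional constants appear anywhere.
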