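---
title: "Phase seeding: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase seeding: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseseed)
```

## The model

A crystal's diffraction pattern fixes the amplitudes $|F(\mathbf h)|$ of
the Fourier coefficients of its electron density but not their phases
$\varphi(\mathbf h)$. Phase seeding studies how little phase information,
and how coarsely quantized, still suffices to solve a
non-centrosymmetric structure when the remaining work is delegated to
dual-space recycling. Its two knobs are:

* the **sampling density** $k \in \{2,3,4,6\}$: general-reflection
  phases are replaced by the nearest member of
  $\{360^\circ j/k,\ j = 0,\dots,k-1\}$. Symmetry-restricted (centric)
  reflections keep their own two allowed values $\varphi_0$ and
  $\varphi_0 + 180^\circ$, where $\varphi_0 = 180^\circ (\mathbf h \cdot
  \mathbf t) \bmod 180^\circ$ for the operator $(\mathbf R, \mathbf t)$
  with $\mathbf h \mathbf R = -\mathbf h$;
* the **seed size** `perc_seed`: that percentage of the $N_{\rm refl}$
  symmetry-independent reflections receives its *true* (discretized)
  phase; all others get random grid values.

Under this convention the expected pre-refinement mean phase error is
analytic: an empty seed gives $90^\circ$; a full seed on acentric data
gives the pure discretization error $90^\circ/k$; and in between the MPE
interpolates linearly,
$\mathrm{MPE}(p) \approx (1-p)\,90^\circ + p\,(1-c)\,90^\circ/k$
with $p$ the seed fraction and $c$ the centric fraction (seeded centrics
are exact, unseeded ones are right half the time, i.e. contribute
$90^\circ$ on average either way). These closed forms are the package's
primary self-checks: the simulated curves reproduce them to within
Monte-Carlo error and are linear with $R^2 > 0.999$.

## The phasing engine

`run_edm()` implements the classical dual-space cycle:

1. **Synthesis.** $\rho(\mathbf x) = V^{-1} \sum_{\mathbf h} F\,
   e^{-2\pi i \mathbf h \cdot \mathbf x}$ over the full sphere (symmetry
   expansion plus Friedel mates; $F(000)$ omitted), on an FFT grid with
   spacing $\le d_{\min}/3$ per axis.
2. **Modification.** All negative density is zeroed and only the top
   `keep_fraction` of grid points survives — the atomistic hypothesis as
   a truncation operator.
3. **Back-transformation.** The modified map is inverted; measured
   reflections keep $|F_{\rm obs}|$ (the amplitude constraint) and adopt
   the new, now continuous phase; centric phases snap to the nearest
   allowed value. Phase adoption is hard replacement — no $\sigma_A$-style
   weighting.
4. **Free lunch** (optional, default on): unmeasured lattice points with
   $0.8\,d_{\min} \le d < d_{\min}$ ride along with calculated amplitude
   and phase from the current map. They never enter MPE or Rf.

A run is **solved** when the final unweighted MPE is at most
$45^\circ$ — midway between random phases ($90^\circ$) and excellent
phases ($<20^\circ$). The source study never states its numeric
solved/not-solved rule, so this threshold is this package's convention;
it is configurable (`solved_mpe_threshold`).

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_cycles` | 200 | maximum EDM cycles |
| `keep_fraction` | 0.03 | fraction of grid points retained (use ~0.15 for protein-like maps) |
| `free_lunch`, `extension_factor` | on, 0.8 | extrapolation shell beyond $d_{\min}$ |
| `solved_mpe_threshold` | 45° | solved verdict |
| `grid_oversampling` | 3 | map spacing $d_{\min}/3$ |
| `converge_tol` | 0.05° | mean phase shift under which (3 cycles) the run stops early |

`keep_fraction = 0.03` matches a realistically sized small-molecule cell
(~1000 Å$^3$, where 3% of grid points comfortably covers all atoms). On
the very small test cells used in the unit tests (~200 Å$^3$, 10 atoms)
3% under-covers the atoms and 0.1 is the faithful setting; the tests say
so explicitly where they use it.

### Numerical choices and degenerate cases

* Phase convention $F = \sum f\,e^{+2\pi i \mathbf h\cdot\mathbf x}$;
  phases in degrees in $[0,360)$. Discretization ties break toward the
  smaller grid angle, making every assignment deterministic given the
  RNG state.
* MPE is unweighted and computed without origin or enantiomorph search:
  the seed anchors the origin, and under this convention the analytic
  pre-refinement estimates above hold exactly.
* With `keep_fraction = 1` the modification step is skipped entirely, so
  one cycle is exactly the identity (drift $< 10^{-6}\,^\circ$) — the
  engine's round-trip invariant. For any `keep_fraction < 1` the
  positivity clip alone sets a noise floor: omitting $F(000)$ makes the
  map zero-mean, so about half the grid points are small negative
  ripples, and zeroing them perturbs the phases of weak reflections.
  Starting from *true* phases the engine therefore settles about
  6–8° MPE away from the truth rather than at 0°, concentrated in
  reflections with small $E$; strong reflections stay within a few
  degrees.
* Divergence is declared after 10 consecutive cycles of Rf rising by
  more than $10^{-3}$; near the fixed point Rf fluctuates at the
  $10^{-4}$ level, which must not trigger the guard.
* Systematically absent reflections (screw axes, centring) are excluded
  at generation time. For absent centric reflections the restricted
  phase is not even well defined — different symmetry operators yield
  conflicting values — which is a second reason they never enter a set.
* E-values use 10 equal-population shells in $1/d^2$ with the
  $\epsilon$ weight; the shell count shrinks automatically (with a
  warning) when fewer than 3 reflections per shell remain.

## The synthetic-data generator

`generate_structure()` places `n_asym` atoms (C/N/O in 6 : 1 : 1.5
proportion, optionally one Ba/Mo/S heavy atom) by rejection sampling
with a 1.5 Å minimum contact distance, in a cell scaled to 55 non-H
atoms per 1000 Å$^3$ (~18 Å$^3$ per atom, a typical organic crystal
density), with axis ratios and angles fixed per lattice system. The
emulated regimes are: *small* (20 atoms, 0.85 Å), *medium* (150 atoms,
1.0 Å), *large* (350 atoms, 1.8 Å), and *powder* (small, heavy atom,
overlap-degraded amplitudes).

Two error models bracket real data quality:

* multiplicative Gaussian amplitude noise, $\sigma = 0.1$ giving
  Rf $\approx 8\%$ against truth — the single-crystal regime (reported
  measured-vs-true Rf for small structures is ~9%);
* **powder peak overlap**: reflections are sorted by
  $2\theta = 2\arcsin(\lambda/2d)$, chained into clusters wherever
  consecutive peaks are closer than `fwhm_2theta`, and each cluster's
  multiplicity-weighted intensity is equipartitioned among its members —
  the deterministic worst case of naive intensity extraction. The
  preset width of 1.2° was fixed once so that the resulting
  Rf(extracted, true) lands in the reported ~43% extraction-error
  regime; Rf saturates near 0.42–0.44 for widths above 1°, so the exact
  value is uncritical.

What the generator does **not** emulate: molecular connectivity (atoms
are uncorrelated hard spheres), solvent regions, anisotropic
displacement, anomalous scattering, twinning, and resolution-dependent
extraction-error structure in the powder mode. Passing tests therefore
demonstrate the phase-information logic of the protocol, not performance
on chemically realistic density features.

## The study protocol

`mpe_vs_seed_curve()` maps the pre-EDM MPE over `perc_seed` (no EDM);
`find_perc_lim()` walks the seed grid (default 10%, 20%, …, 100%)
upward and declares `Perc_lim` at the first value where a majority of
`n_repeats = 5` independent seeding + EDM runs solve, with `MPE_lim` the
mean pre-EDM MPE of those runs. A single deterministic run would be
cheaper, but this engine's outcomes are RNG-dependent; majority-of-5 is
the smallest stable rule. Unsolvable configurations carry `NA`
sentinels, which `aggregate_sweep()` counts but never silently drops.

Five seed-selection strategies are implemented; on synthetic cohorts
*E-random* (random among reflections with $E > 1$) needs the smallest
seeds and *Random* the largest, reproducing the strategy ordering of the
source study. The sweep sizes used in the tests and the acceptance
script — cohorts of ten 12-atom structures at 0.9 Å, $k = 3$, five
repeats — were chosen as the smallest cohorts for which that ordering is
stable run-to-run; they complete in a few minutes on one CPU.

Because the reference EDM implementation's cycle count, truncation level
and weighting are unpublished, quantitative `Perc_lim` agreement with
the published benchmark is approximate by construction: this engine
lands at `Perc_lim` ≈ 20–40% on 10–12-atom structures where the
published pipeline reports 10–30% for (larger, chemically real) small
structures. The *pre-EDM* quantities — the seeding MPE curves — are
implementation-independent and match the published values to within
±1°.

## Known limitations

* Six representative space groups, standard settings only; no
  centrosymmetric groups by design (the discretization problem is
  trivial there).
* No tangent-formula or Patterson bootstrap: an empty seed is genuinely
  uninformative here, which is exactly the baseline condition the
  protocol needs.
* Friedel pairs are assumed equal (no anomalous signal).
* The accession-based reference check uses a synthetic monoclinic
  stand-in (the published coordinates of the original small test
  structure cannot be redistributed with, or fetched by, this package);
  the pre-EDM MPE at fixed (k, seed) depends only on seed size, grid and
  centric fraction, which the stand-in reproduces.
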