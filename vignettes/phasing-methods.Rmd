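---
title: "Iterative transform phasing: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative transform phasing: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A crystal's electron density $\rho(\mathbf x)$ and its structure factors
$F(\mathbf h)$ are a Fourier pair; experiment gives only $|F_{obs}|$. The
package treats phasing as a feasibility problem with two constraint sets:

* **Fourier-space constraint** — the amplitudes of $F$ equal $|F_{obs}|$;
* **Real-space constraint** — the cell is partitioned into a protein region
  (a compact support occupying $1-f_{solv}$ of the volume, where density is
  protein-like) and a flat solvent region.

Each cycle applies, in order: magnitude projection onto the data → inverse
FFT → mask update → histogram matching inside the mask → HIO feedback
outside the mask → forward FFT. The solvent update is the Fienup hybrid
input–output form
$$\rho'_i = \begin{cases}\rho^{out}_i & i \in \text{mask}\\
\mathrm{clip}\!\left(\rho^{in}_i - \varepsilon\,\rho^{out}_i,\ \pm c\right) &
i \notin \text{mask},\end{cases}$$
where $\rho^{in}$ is the cycle's input density, $\rho^{out}$ the density
after magnitude projection, $\varepsilon$ the feedback coefficient and $c$
the clamp. The negative feedback integrates the residual solvent density
and drives the *output* solvent toward zero without the hard truncation of
plain solvent flattening; the clamp bounds the stored control signal, which
markedly improves stability.

The mask is not fixed: every cycle the current density (negatives zeroed)
is smoothed with a normalized, truncated Gaussian
$w(r)=e^{-r^2/2\sigma^2}$ ($r \le 3\sigma$, periodic minimum-image
distances) and the top volume fraction $(1-f_{solv})+\ell$ of voxels is
taken as protein. The mask therefore evolves with the solution — initially
it reflects the template (or noise), finally the true molecule.

### F(000) floats

The data never contain $F(000)$, so maps are conventionally zero-mean. But
a zero-mean map cannot have both a flat zero solvent and a positive protein
region — flattening would be inconsistent and the feedback integrator
diverges. The engine therefore lets the DC term float: it is carried like a
missing reflection, updated from the modified map each cycle. Solvent then
settles at zero while the protein keeps its positive density, and
$F(000)$ converges to the total cell content. This is also why the
reference histogram is *anchored to the solvent level*
(`reference_histogram()` subtracts the template map's solvent mean): the
histogram must live on the same scale the flattened map converges to.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 0.9 | HIO feedback coefficient (dimensionless) |
| `sigma_start`, `sigma_end` | 3→2 Å (template), 4→2 Å (random) | mask-kernel radius, linear in cycle |
| `initial_clamp`, `final_clamp` | 1.0, 0.01 e/Å³ | solvent clamp; geometric ramp over `clamp_window` cycles after `clamp_plateau` |
| `looseness` | 0.05 (≤ 0.08) | extra mask volume beyond $1-f_{solv}$ |
| `free_fraction` | 0.02 | held-out reflections for the free R |
| `n_low_res_replaced` | all d > 25 Å | measured low-resolution reflections handed to the calculated values |
| `d_min_extend` | 0.9 | the iteration runs at $0.9\,d_{min}$; the extra shell is carried as missing/calculated, giving the modification spectral headroom beyond the measured sphere |
| `oversample` | 3 (grid), 4 in the studies below | grid spacing ≤ `d_min`/oversample |

The clamp ramp is geometric rather than linear because the clamp spans two
orders of magnitude; a linear ramp would spend almost all of the window
above 0.1 e/Å³. After the ramp the solvent update degenerates to a gentle
flattening bounded by ±`final_clamp`, which still outperforms hard
flattening because the true solvent is not exactly constant.

## The synthetic study system

`make_toy_crystal()` builds a pseudo-protein as a residue chain: centres
follow a compact random walk with a 3.8 Å step (the Cα spacing) confined
to a ball, and each residue carries 8 carbon-like atoms scattered with a
1.6 Å spread. This gives density the chunky, tube-like character of real
protein at ~3 Å — important because a Gaussian mask kernel at σ = 3 Å
erases features much thinner than that. The confining radius is calibrated
(coarse scan + bisection, deterministic per seed) so the 2.5 Å-dilated
envelope occupies $1-f_{solv}$ of the cell within ±0.03. Atom count scales
with the protein volume at one atom per 6.75 Å³, the packing at which the
chain just fills its envelope; B = 50 Å² throughout, a typical value for
crystals diffracting to 3 Å. Amplitudes are noise-free by default; the true
phases are returned separately and never enter the observed set.

`degrade_template()` emulates a distant homolog: whole residues are
deleted (the unalignable segments stripped from search models) and the
survivors are displaced by a smooth along-chain field (segments move
coherently) plus ~1.5 Å per-atom jitter (wrong local conformations). The
smooth component preserves the envelope while the jitter scrambles
high-resolution phases — the signature of a real distant homolog.
`degrade_to_error()` bisects the displacement RMSD until the starting
phase error lands in a requested band (e.g. 65–75°, matching difficult
molecular-replacement starts).

What the toy does **not** emulate: measurement noise and incompleteness
(available via `noise_frac`, off by default), bulk solvent (the toy
solvent is vacuum, so template structure factors for synthetic work are
computed with `k_sol = 0` and the density contrast between protein and
solvent is several times larger than in real crystals), secondary
structure, anisotropy, and space groups other than P1. Passing tests on
the toy therefore demonstrate the mechanics and regime behaviour of the
algorithm, not its performance envelope on real data.

### Histogram matching in the synthetic study

Histogram matching is implemented and verified (`histogram_match()` is an
exact, idempotent, rank-preserving quantile map) and is applied whenever a
reference histogram is supplied. The synthetic template-recovery study
runs **without** it: measured directly, one application of the degraded
template's histogram to the *true* toy density already costs ~20° of phase
error, because a template distorted enough to start 65–75° away has a
visibly flatter histogram than the target — whereas real homologs, with
correct stereochemistry, have nearly universal histograms at fixed
resolution. On vacuum-solvent toys even an ideal library histogram gives
no net gain. This is a property of the study system, not of the method;
with real data the reference histogram should be supplied.

### Origin indeterminacy

In P1 the structure is defined only up to an arbitrary origin translation
(and enantiomorph). A weak template does not always pin the origin: runs
routinely converge to the correct structure shifted by a few Å, which
looks like failure (60–90° phase error) until the origin search is
applied. All phase errors in the studies are therefore reported after an
FFT translation/inversion search (`align_reference = TRUE`), exactly as
map-correlation tools perform origin searches. Template starts that keep
their origin are unaffected (the search returns a zero shift).

## Monitoring and convergence detection

The mean phase error is the $|F_{obs}|$-weighted mean of the absolute
phase difference wrapped to [0°, 180°]; the free R uses a least-squares
scale over the free set. `detect_convergence()` flags the first cycle
where the free R has fallen by ≥ 0.08 over the preceding 100 cycles and
stays below its pre-drop minimum thereafter. Including the starting level
in the pre-drop minimum suppresses false positives from the early settling
transient of random starts, whose free R briefly rises before levelling.

## Numerical choices

* Fourier convention: $F(\mathbf h) = (V/N)\sum \rho\,e^{+2\pi i\,
  \mathbf h\cdot\mathbf x}$; grids are FFT-friendly (prime factors ≤ 7);
  indices on Nyquist rows, which cannot carry a Friedel pair, are excluded.
* Atom shape: one isotropic Gaussian per atom with integral $Z$ electrons
  and variance $B/8\pi^2$ plus an anti-aliasing floor of
  $(0.8\,h_{max})^2$ — a deliberate simplification; the engine needs
  plausible density and phases, not scattering-accurate form factors.
* Quantile mapping uses R's type-7 interpolation, so equal counts
  reproduce the reference exactly; all rank ties break by column-major
  voxel index.
* Mask selection is by exact voxel count (`round(fraction * N)`), so the
  realized fraction errs by at most one voxel.
* The fixed-point property is verified at the *terminal* schedule values
  (σ = 2 Å, clamp 0.01): at full clamp the solvent stores a legitimate
  nonzero control signal, so the modified map is not expected to reproduce
  the true phases until HIO is turned off.

## Problem sizes

The studies use a 30 Å cubic P1 cell at $d_{min}=3$ Å (~2100 unique
reflections, 45³ grid at oversample 4 with the resolution extension),
500-cycle runs, five seeds for template recovery and eight seeds per
solvent content for the ab initio regime comparison. These sizes keep the
full study reproducible in minutes on a single CPU while preserving the
regime structure of the method: template starts at 65–75° recover to
< 45° in most seeds; random starts converge frequently at 75% solvent and
essentially never at 55%.

## Known limitations

* The engine operates strictly in P1; non-P1 data must be expanded with
  `expand_to_p1()` and no non-crystallographic symmetry averaging is
  performed.
* No sigma-weighting or maximum-likelihood map coefficients; projection
  imposes $|F_{obs}|$ directly.
* MTZ files are not read; reflections travel as SF-mmCIF or TSV.
* The convergence detector keys on the free R trace alone and inherits its
  ~100-cycle window resolution.
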