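---
title: "Diffuse scattering from TLS ensembles: model, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffuse scattering from TLS ensembles: model, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlsdiffuse)
```

## The model

Disorder in a crystal — any deviation of the unit-cell contents from the
lattice-average structure — redirects X-ray intensity from the Bragg peaks
into diffuse scattering. When the disorder is represented as an ensemble
of explicit unit-cell snapshots with structure factors $F_n(\mathbf{q})$,
the diffuse intensity is the ensemble variance of the complex structure
factor:

$$ I_D(\mathbf{q}) \;=\; \bigl\langle |F_n(\mathbf{q})|^2 \bigr\rangle_n
   \;-\; \bigl| \langle F_n(\mathbf{q}) \rangle_n \bigr|^2 . $$

`guinier_diffuse()` evaluates both terms with equal model weights and
subtracts. The key assumptions inherited by every result:

* **No correlation between unit cells.** Each snapshot is one cell;
  disorder spanning cells is representable only through the supercell
  ("copies") expansion with a model-assignment hook.
* **Per unit cell scale.** The lattice-count prefactor of the underlying
  theory multiplies everything equally and is set to 1; all comparisons in
  the package are correlation-based, which this scale cannot affect.
* **Protein-only signal.** No bulk solvent, no anomalous dispersion, and —
  by default — no per-atom B factors in $F_n$, so the diffuse map reflects
  only the coordinate spread of the ensemble. `use_b = TRUE` restores the
  isotropic Debye–Waller factor $\exp(-B_j s^2)$ per atom for users who
  want single-atom smearing folded in; both behaviors are exposed because
  either convention is defensible when an ensemble already encodes the
  disorder of interest.
* **P1 treatment.** Cell content is never symmetry-expanded; Friedel
  symmetry of $I_D$ is therefore an emergent, tested property rather than
  an assumption, and the full ±h,±k,±l sphere is enumerated.

Structure factors are computed by direct summation over atoms with
4-Gaussian Cromer–Mann form factors (16 common elements). Direct
summation, not an FFT, because exactness at arbitrary — including
fractional — indices is what the subsampling scheme relies on, and the
intended systems are desk-scale.

## TLS conventions

A TLS group carries the translation tensor $T$ (Å²), libration tensor $L$
(rad² internally; PDB headers use deg² and are converted on parse), screw
tensor $S$ (Å·rad internally; Å·deg in headers), an origin, and a residue
selection. Since $S$ enters the physics only through its off-trace part,
`tls_group()` re-centers it to $\mathrm{trace}(S)=0$ by subtracting
$\mathrm{trace}(S)/3$ from its diagonal.

The implied anisotropic displacement tensor at position $\mathbf r$ is

$$ U(\mathbf r) = T + A\,L\,A^{\mathsf T} + A\,S + S^{\mathsf T}A^{\mathsf T},
   \qquad A\mathbf w = \mathbf w \times (\mathbf r - \mathbf r_0), $$

implemented in `uij_from_tls()`. A physically meaningful group needs
non-negative eigenvalues of $T$ and $L$ (they are variances);
`validate_tls()` reports both eigensystems and a verdict, with tolerance
`tol = 1e-8` (Å² / rad²) chosen to absorb the rounding noise of 4-decimal
PDB tensor records. Most deposited TLS refinements fail this check, which
is why validation is a mandatory precursor to sampling
(`decompose_tls()` refuses non-physical groups).

## From tensors to motions

`decompose_tls()` resolves a valid group into elementary motions:

1. **Libration axes and variances** — the eigensystem of $L$ (right-handed
   triad).
2. **Screw pitches and axis offsets** — write $\tilde S = R^{\mathsf T} S R$
   in the libration eigenframe; row $i$ divided by the eigenvalue
   $\lambda_i$ is the translation correlated with libration $i$: its
   component along the axis is the screw pitch (Å/rad) and its
   perpendicular components locate the point the axis actually passes
   through.
3. **Vibrations** — the librating, displaced axes already generate a
   translation covariance $\sum_i \lambda_i \mathbf c_i \mathbf
   c_i^{\mathsf T}$; the eigensystem of the residual $T$ minus that term
   gives the independent vibration axes and variances.

The construction is fixed by two testable contracts rather than by any
particular published recipe: reassembling $T, L, S$ from the decomposition
reproduces the inputs to 1e−6 (`tls_reassemble()`), and the displacement
covariance of sampled ensembles converges to `uij_from_tls()` at every
atom. Residual vibration eigenvalues in $[-10^{-6}, 0)$ Å² are clamped to
zero (rounding-level inconsistency between $S$ and $T$); anything more
negative is an error, because it means the screw content demands more
translation variance than $T$ provides.

If $\lambda_i = 0$ but row $i$ of $\tilde S$ is non-zero, that screw row
is unrealizable (no libration to correlate with); it is dropped with a
warning.

## Sampling

`sample_displacement()` draws the three libration angles and three
vibration amplitudes as independent zero-mean Gaussians with the
decomposed variances, and composes them as *exact* finite rotations
(axis–angle) about the offset axes, each with its screw translation, in
axis order 1, 2, 3, followed by the vibration shift. Exact rotations keep
every sampled model a strict rigid body (pairwise distances preserved to
well below 1e−6 Å, a tested invariant); the linearized ADP formula is then
recovered only as the small-angle limit, which is exactly how it is
tested — at the fixture amplitudes (librations of a few degrees) the
Monte-Carlo covariance matches $U(\mathbf r)$ within 5% plus sampling
error.

`generate_ensemble()` applies one displacement per (model, group) pair and
reassembles complete models; atoms in no group are copied unchanged.
Reproducibility: each group gets its own RNG substream derived from the
master seed, so a fixed seed gives bitwise-identical coordinates.
Substreams are indexed by the group's position in the supplied list; any
given call signature is fully deterministic.

### Correlated inter-group motion

Two groups can be stepped deterministically instead of sampled:

* `parallel` — both groups move through the same grid of multiples of
  $\sigma$ along **all** their translation *and* libration eigenvectors,
  where $\sigma$ is the per-axis standard deviation from the
  decomposition. The default grid is 10 steps of $\sigma/2$:
  $-2.5\sigma, -2.0\sigma, \dots, +2.0\sigma$. A symmetric ±2.5σ span at
  σ/2 spacing would need 11 points; the package keeps the stated count of
  10 models and the stated step, accepting the half-step asymmetry at the
  top of the grid.
* `antiparallel` — identical, except the *translation* steps of the second
  group are negated; its librations are unchanged.

Two interpretation choices, both deliberate: the $\sigma$-grid is applied
to libration angles as well as translations (stepping "along every
eigenvector" of a rigid-body distribution is only well defined if the
rotational degrees of freedom step too), and each stepped libration uses
its full axis geometry — offset and screw pitch — because the axis *is*
the eigenvector of the motion, not a line through the origin. Both modes
ignore the seed entirely; re-running with any seed reproduces the same
coordinates, which the tests assert.

## Reciprocal-space map analytics

Maps are tibbles of (h, k, l, s, intensity) with the cell attached.
Conventions that matter:

* **Binning variable** is the scattering-vector length $|s| = 1/d$
  (Å⁻¹) with equal-width bins spanning $[0, \max|s|]$ — equal-width in
  $|s|$ keeps high-resolution shells populated evenly. Defaults: 50 bins
  for isotropic subtraction (a smooth radial estimate), 10 for binned
  correlations (enough points per bin for a stable CC); both
  configurable.
* **Anisotropic maps** (`subtract_isotropic()`) subtract each index's
  shell mean. Raw diffuse maps share a large spherically symmetric
  component, so correlations between raw maps overstate agreement;
  anisotropic maps isolate the directional signal that actually
  distinguishes disorder models. Shell means of the output vanish to
  numerical precision and the operation is idempotent — both tested
  identities. "Spherically symmetric" here operationally means *constant
  within each shell*: a component that varies smoothly inside a shell is
  removed only up to its within-shell spread.
* **Undefined bins** (fewer than 3 indices, or zero variance) are reported
  as `NA`, never 0, so trend plots are not biased toward "no correlation".
* `pearson_cc()` refuses zero-variance inputs rather than returning a
  conventional value.

## Sampling between Bragg points

The molecular transform between Bragg positions is reached by expanding
the cell in real space (`expand_system()`): *vacuum* mode grows the cell
edges by an integer factor $m$ around unchanged coordinates, making the
reciprocal lattice $m\times$ finer, with the exact identity
$F_{\text{exp}}(mh, mk, ml) = F(h,k,l)$ (tested to 1e−8); *copies* mode
tiles $m^3$ translated copies, which with identical contents extinguishes
all indices not divisible by $m$ and, with the `model_assign` hook, can
place different ensemble models in different copies to emulate
cross-cell disorder correlations. `fractional_diffuse()` divides the
expanded-grid indices by $m$ to express the map on the original lattice.

`collapse_to_bragg()` assigns each fractional index to its nearest integer
triple — the 1×1×1 voxel around each Bragg point — and averages. Half-way
ties round away from zero per component (deterministic and symmetric about
the origin). The origin voxel is retained so that total intensity is
conserved exactly (sum of voxel mean × voxel count equals the fractional
total, a tested identity); drop it before any comparison with data if the
beamstop region is excluded. The collapsed integer map is the default
output; the fractional map itself is available behind a flag.

Cell expansion cannot preserve screw-axis symmetry. All content here is
P1, so the package only *warns* when the input declares a screw-axis space
group (e.g. P2₁2₁2₁), flagging that comparison of such subsampled maps
with experimental data from that crystal form is unsupported; comparisons
between simulated maps remain valid.

## The synthetic generator

`make_toy_structure()` places atoms uniformly inside the cell, one atom
per residue, chains in disjoint slabs so each chain is a spatially
coherent rigid body. `make_random_tls()` builds groups from elementary
motions — eigenvalues and axes first, tensors assembled from them — so
physical validity holds by construction: at `amplitude_scale = 1`,
libration variances are uniform in $(0.2, 1)\times(3^\circ)^2$ and
vibration variances in $(0.2, 1)\times 0.05$ Å², i.e. librations up to
~3° sd and vibrations up to ~0.22 Å sd, the regime of modest rigid-body
disorder where TLS modeling is sensible and the linearized ADP check is
sharp. Screw pitches are chosen with $\sum_i \lambda_i p_i = 0$ so the
trace convention is satisfied exactly at generation time.

Default problem sizes (40 atoms, 30 Å cubic cell, d ≥ 3 Å, two groups,
1000 models) give maps of ~4100 indices with visible shell structure in
seconds per ensemble — large enough for stable map statistics, small
enough that the full test suite and the acceptance script each run in
about a minute or two on one CPU.

What the toys do *not* emulate: bonded geometry, secondary structure,
solvent, realistic packing, inter-group restraints. Passing tests
demonstrate the correctness of the machinery — the variance calculation,
the sampler's distributional fidelity, the exactness of the expansion
algebra — not that any particular protein's diffuse signal is predicted;
applying the pipeline to real systems additionally requires modeling the
other disorder sources (solvent above all) that dominate measured diffuse
intensity.

## Numerical choices, in one place

| Quantity | Value | Why |
|---|---|---|
| T/L eigenvalue tolerance | 1e−8 Å² / rad² | 4-decimal PDB tensor rounding |
| Residual vibration clamp | down to −1e−6 Å² | decomposition rounding vs genuine non-physicality |
| Negative-variance clamp on $I_D$ | −1e−9 × scale | floating-point cancellation in the two-term subtraction |
| Reassembly self-consistency | 1e−6 | test contract of the decomposition |
| PDB coordinate quantization | 3 decimals (Å) | fixed-width PDB format |
| Fractional-grid check in collapse | 1e−6 × factor | rejects off-grid indices before voxel assignment |
| Tie-break at half-integer indices | round away from zero | deterministic, origin-symmetric |

## Known limitations

* Only isotropic B factors are honored on input (no ANISOU); waters and
  non-'A' alternate conformers are dropped on read by default, and
  hydrogens too (flags exist for waters and hydrogens).
* No chemical restraints act between TLS groups: large-amplitude groups
  can interpenetrate, exactly as unrestrained rigid-body sampling allows.
* Direct summation scales as (atoms × indices × models); the package is
  sized for ensemble models of hundreds of atoms, not ribosomes.
* Fractional indices are reached only through cell expansion; evaluating
  F directly at arbitrary fractional indices (which would sidestep the
  screw-axis caveat) is out of scope.
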