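# tlsdiffuse

Simulating X-ray diffuse scattering from TLS structural ensembles.

## The problem

Bragg diffraction reports only the electron density averaged over all unit
cells of a crystal, so very different models of *correlated* motion — for
example, alternative segmentations of a protein into
translation–libration–screw (TLS) rigid bodies, or different assumed
couplings between those bodies — can fit the Bragg data equally well.
The diffuse scattering that appears between and under the Bragg peaks is
the variance of that density, and it *does* discriminate between such
models. `tlsdiffuse` is a toolbox for predicting this signal from explicit
multi-model ensembles and for comparing the resulting reciprocal-space
maps, aimed at crystallographers and methods developers who want to test
rigid-body disorder models against (eventually) measured diffuse data.

## The model

For an ensemble of unit-cell "snapshots" with complex structure factors
F<sub>n</sub>(**q**), the diffuse intensity is the ensemble variance
(Guinier's equation):

```
I_D(q) = ⟨ |F_n(q)|² ⟩_n  −  | ⟨ F_n(q) ⟩_n |²
```

Structure factors are evaluated by direct summation with tabulated
Cromer–Mann form factors, F(h) = Σ<sub>j</sub> occ<sub>j</sub>
f<sub>j</sub>(s) exp(2πi **h**·**x**<sub>j</sub>), which stays exact at
arbitrary — including fractional — Miller indices. Intensities are
reported per unit cell (the lattice-count prefactor is a global scale that
drops out of every correlation comparison).

Around this core the package provides:

* **TLS → ensemble conversion** — `validate_tls()` checks the eigenvalue
  physicality of T and L; `decompose_tls()` resolves the tensors into
  libration axes/variances, screw pitches, axis offsets and residual
  vibrations; `generate_ensemble()` samples them as exact rigid-body
  motions, either independently per group or as deterministic
  "parallel"/"antiparallel" σ-grid stepping of two groups.
  `uij_from_tls()` gives the closed-form anisotropic displacement
  parameters U(r) = T + A L Aᵀ + A S + Sᵀ Aᵀ used as the sampler's oracle.
* **Map analytics** — radial intensity profiles, subtraction of the
  spherically symmetric component ("anisotropic maps"), global and
  resolution-binned Pearson correlations, difference maps, ggplot2
  `autoplot()` methods.
* **Between-Bragg sampling** — real-space unit-cell expansion (vacuum
  padding or supercells of copies) for fractional-index maps, collapsed
  back onto the Bragg lattice by 1×1×1 voxel averaging.
* **Synthetic fixtures** — toy structures and always-physical random TLS
  groups, so the entire pipeline runs with no external data.
* **I/O** — multi-model PDB (MODEL/ENDMDL) with REMARK 3 TLS headers, and
  a plain-text `h k l intensity` map format.

## Worked example

Two rigid chains, each with its own physically valid TLS group; 1000-model
ensembles; diffuse maps to 3 Å; anisotropic-map correlation between two
independent realizations:

```r
library(tlsdiffuse)

bm <- make_two_group_benchmark(toy_spec(n_atoms = 40, seed = 11))
validate_tls(bm$groups[[1]])
#> <tls_validation> physical
#>   T eigenvalues (Å²):   0.03066  0.02760  0.02601
#>   L eigenvalues (rad²): 2.142e-03  1.849e-03  1.361e-03

ens <- generate_ensemble(bm$model, bm$cell, bm$groups, n_models = 1000, seed = 1)
glance(ens)
#>   n_models n_atoms elements  rmsf
#> 1     1000      40 C,N,O,S  0.658

map <- guinier_diffuse(ens, d_min = 3)
glance(map)
#>   n_indices d_min min_intensity max_intensity total_intensity anisotropic
#> 1      4144     3          27.2         1935.        2871113. FALSE

ens2 <- generate_ensemble(bm$model, bm$cell, bm$groups, n_models = 1000, seed = 2)
aniso  <- subtract_isotropic(map)
aniso2 <- subtract_isotropic(guinier_diffuse(ens2, d_min = 3))
pearson_cc(aniso, aniso2)
#> [1] 0.9899744
cc_by_resolution(aniso, aniso2, n_bins = 5)
#>     bin  s_min  s_max  s_mid     n    cc
#>   1   1 0      0.0667 0.0333    32 0.995
#>   2   2 0.0667 0.133  0.100    224 0.995
#>   3   3 0.133  0.200  0.167    668 0.993
#>   4   4 0.200  0.267  0.233   1184 0.989
#>   5   5 0.267  0.333  0.300   2036 0.990
```

The ensemble mean coordinate spread (`rmsf`, 0.66 Å) reflects the sampled
TLS amplitudes; at 1000 models the two independent realizations produce
anisotropic maps that agree to CC ≈ 0.99 in every resolution shell — the
sampling-convergence behavior that motivates the 1000-model default.
`autoplot(radial_profile(map))` and `plot_map_section(map)` give
quick-look figures.

A shell interface covering the same pipeline ships in `inst/cli/`:

```sh
tlsdiffuse fixtures make-toy --atoms 40 --groups 2 --seed 1 --out toy.pdb
tlsdiffuse tls-sample --pdb toy.pdb --n-models 1000 --mode independent --seed 7 --out ens.pdb
tlsdiffuse diffuse --ensemble ens.pdb --d-min 3.0 --out map.hkl
tlsdiffuse map-stats compare map_a.hkl map_b.hkl --anisotropic --bins 10
tlsdiffuse subsample --ensemble ens.pdb --factor 4 --d-min 3.0 --mode vacuum --out sub.hkl
```

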