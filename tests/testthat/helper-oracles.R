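# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the code paths they check: the diffuse oracle
# expands the ensemble variance as a double sum over atom pairs and models
# (the covariance formulation), evaluated scalar-by-scalar.

# random ensemble of unrelated small models (positions differ, roster fixed)
tiny_ensemble <- function(n_models = 3, n_atoms = 4, seed = 1,
                          cell = unit_cell(12, 14, 16, 90, 100, 90),
                          occ = NULL) {
  set.seed(seed)
  if (is.null(occ)) occ <- runif(n_atoms, 0.5, 1)
  elements <- rep(c("C", "N", "O", "S"), length.out = n_atoms)
  atoms <- do.call(rbind, lapply(seq_len(n_models), function(m) {
    data.frame(model = m, chain = "A", resno = seq_len(n_atoms), resname = "ALA",
               atom = "CA", element = elements,
               x = runif(n_atoms, 1, 10), y = runif(n_atoms, 1, 10),
               z = runif(n_atoms, 1, 10), occ = occ, b = 0)
  }))
  as_ensemble(atoms, cell)
}

# covariance-formulation diffuse intensity: I_D(h) as a double sum over
# atom pairs of ensemble covariances of the per-atom phase terms
brute_guinier <- function(ens, grid) {
  cell <- get_cell(ens)
  models <- split(as.data.frame(ens), ens$model)
  vapply(seq_len(nrow(grid)), function(r) {
    h <- as.numeric(grid[r, c("h", "k", "l")])
    s <- grid$s[r]
    ph <- lapply(models, function(m) {
      fr <- as.matrix(m[, c("x", "y", "z")]) %*% t(cell$frac)
      ff <- vapply(m$element, form_factor, numeric(1), s = s / 2)
      m$occ * ff * exp(2i * pi * as.vector(fr %*% h))
    })
    n_at <- nrow(models[[1]])
    tot <- 0 + 0i
    for (a in seq_len(n_at)) {
      pa <- vapply(ph, function(p) p[a], complex(1))
      for (b in seq_len(n_at)) {
        pb <- vapply(ph, function(p) p[b], complex(1))
        tot <- tot + (mean(pa * Conj(pb)) - mean(pa) * Conj(mean(pb)))
      }
    }
    Re(tot)
  }, numeric(1))
}

# all pairwise interatomic distances of a coordinate block
pair_dists <- function(xyz) as.numeric(stats::dist(xyz))

# build a diffuse_map directly from index/intensity vectors (test fixture)
manual_map <- function(h, k, l, intensity, cell = unit_cell(10, 10, 10), d_min = 1) {
  grid <- tlsdiffuse:::new_reciprocal_grid(
    tibble::tibble(h = h, k = k, l = l, s = s_length(cell, cbind(h, k, l))),
    cell, d_min)
  tlsdiffuse:::new_diffuse_map(grid, intensity)
}
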