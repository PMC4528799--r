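test_that("form factors reproduce electron counts and decrease with angle", {
  s <- seq(0, 1.2, by = 0.01)
  for (el in c("H", "C", "N", "O", "S", "Zn")) {
    f <- form_factor(el, s)
    expect_true(all(diff(f) <= 0))             # monotone non-increasing
    expect_lte(max(f), f[1] + 1e-12)
  }
  # f(0) = sum(a) + c = electron count to tabulation accuracy
  expect_equal(form_factor("C", 0), 6, tolerance = 1e-3)
  expect_equal(form_factor("H", 0), 1, tolerance = 1e-3)
  expect_equal(form_factor("O", 0), 8, tolerance = 1e-3)
  expect_equal(form_factor("Zn", 0), 30, tolerance = 0.02)
  expect_error(form_factor("Xq", 0.1), "tabulated symbols")
  expect_error(form_factor("C", -0.5), "non-negative")
})

test_that("structure factors: origin atom, Friedel mates and a two-atom lattice", {
  cell <- unit_cell(10, 10, 10)
  grid <- reciprocal_grid(cell, d_min = 2.5)
  one <- tibble::tibble(model = 1L, chain = "A", resno = 1L, resname = "ALA",
                        atom = "CA", element = "C", x = 0, y = 0, z = 0,
                        occ = 0.7, b = 0)
  F1 <- structure_factors(one, grid)
  expect_equal(Im(F1), rep(0, nrow(grid)), tolerance = 1e-12)
  expect_equal(Re(F1), 0.7 * form_factor("C", grid$s / 2), tolerance = 1e-12)

  set.seed(4)
  ens <- tiny_ensemble(n_models = 1, n_atoms = 4, seed = 4)
  Fm <- structure_factors(ens_model(ens, 1), reciprocal_grid(get_cell(ens), 3))
  g <- reciprocal_grid(get_cell(ens), 3)
  mate <- match(paste(-g$h, -g$k, -g$l), paste(g$h, g$k, g$l))
  expect_equal(Fm[mate], Conj(Fm), tolerance = 1e-12)

  # atoms at fractional x = 0 and 1/2: odd h extinct, even h doubled
  two <- dplyr::bind_rows(one, dplyr::mutate(one, resno = 2L, x = 5))
  two$occ <- 1
  gsub <- tlsdiffuse:::new_reciprocal_grid(
    tibble::tibble(h = c(1, 2), k = 0, l = 0, s = s_length(cell, cbind(c(1, 2), 0, 0))),
    cell, 2.5)
  F2 <- structure_factors(two, gsub)
  expect_equal(abs(F2[1]), 0, tolerance = 1e-12)
  expect_equal(F2[2], 2 * form_factor("C", gsub$s[2] / 2) + 0i, tolerance = 1e-12)
})

test_that("per-atom B factors attenuate F only when retention is enabled", {
  ens <- tiny_ensemble(n_models = 1, n_atoms = 1, seed = 11)
  ens$b <- 20
  grid <- reciprocal_grid(get_cell(ens), 4)
  f_plain <- structure_factors(ens_model(ens, 1), grid)
  f_b <- structure_factors(ens_model(ens, 1), grid, use_b = TRUE)
  # single atom: |F| scales by exp(-B (s/2)^2) exactly
  expect_equal(abs(f_b), abs(f_plain) * exp(-20 * (grid$s / 2)^2), tolerance = 1e-12)
  expect_true(all(abs(f_b) < abs(f_plain)))
  # and the default ignores B entirely
  ens0 <- ens; ens0$b <- 0
  expect_equal(structure_factors(ens_model(ens0, 1), grid), f_plain)
})

test_that("degenerate ensembles scatter no diffuse intensity", {
  ens1 <- tiny_ensemble(n_models = 1, n_atoms = 4, seed = 1)
  map1 <- guinier_diffuse(ens1, d_min = 3)
  expect_equal(map1$intensity, rep(0, nrow(map1)))

  # identical models
  m <- as.data.frame(ens_model(ens1, 1))
  atoms <- dplyr::bind_rows(lapply(1:4, function(i) dplyr::mutate(m, model = i)))
  ens_same <- as_ensemble(atoms, get_cell(ens1))
  expect_equal(guinier_diffuse(ens_same, d_min = 3)$intensity, rep(0, nrow(map1)))
})

test_that("the hand-worked two-model point scatterer gives I_D = f^2", {
  cell <- unit_cell(10, 10, 10)
  mk <- function(m, xfrac) tibble::tibble(model = m, chain = "A", resno = 1L,
                                          resname = "ALA", atom = "CA", element = "C",
                                          x = xfrac * 10, y = 0, z = 0, occ = 1, b = 0)
  ens <- as_ensemble(dplyr::bind_rows(mk(1L, 0), mk(2L, 0.5)), cell)
  grid <- tlsdiffuse:::new_reciprocal_grid(
    tibble::tibble(h = 1, k = 0, l = 0, s = s_length(cell, cbind(1, 0, 0))), cell, 10)
  map <- guinier_diffuse(ens, grid = grid)
  f <- form_factor("C", grid$s / 2)
  # F1 = f, F2 = -f: <|F|^2> = f^2, |<F>|^2 = 0
  expect_equal(map$intensity, f^2, tolerance = 1e-12)
  expect_equal(mean_bragg_intensity(ens, grid = grid)$intensity, 0, tolerance = 1e-12)
})

test_that("Guinier matches the brute-force covariance expansion", {
  for (seed in 1:5) {
    ens <- tiny_ensemble(n_models = sample(2:3, 1), n_atoms = sample(2:5, 1),
                         seed = seed)
    grid <- reciprocal_grid(get_cell(ens), 5)
    map <- guinier_diffuse(ens, grid = grid)
    oracle <- brute_guinier(ens, grid)
    expect_lt(max(abs(map$intensity - oracle)) / max(oracle), 1e-10)
  }
})

test_that("the variance decomposition identity holds exactly", {
  ens <- tiny_ensemble(n_models = 3, n_atoms = 5, seed = 6)
  grid <- reciprocal_grid(get_cell(ens), 4)
  i_d <- guinier_diffuse(ens, grid = grid)$intensity
  i_bragg <- mean_bragg_intensity(ens, grid = grid)$intensity
  mean_abs2 <- rowMeans(vapply(1:3, function(m) {
    abs(structure_factors(ens_model(ens, m), grid))^2
  }, numeric(nrow(grid))))
  expect_lt(max(abs(mean_abs2 - (i_d + i_bragg))) / max(mean_abs2), 1e-9)
})

test_that("rigid joint translation of all models leaves the map unchanged", {
  ens <- tiny_ensemble(n_models = 3, n_atoms = 4, seed = 7)
  grid <- reciprocal_grid(get_cell(ens), 4)
  ref <- guinier_diffuse(ens, grid = grid)
  moved <- dplyr::mutate(tibble::as_tibble(ens), x = x + 3.7, y = y - 1.2, z = z + 0.4)
  map2 <- guinier_diffuse(as_ensemble(moved, get_cell(ens)), grid = grid)
  expect_equal(map2$intensity, ref$intensity, tolerance = 1e-9)
})

test_that("pure-T ensembles match the closed-form smeared rigid body", {
  # isotropic translational disorder: I_D = |F0|^2 (1 - exp(-4 pi^2 t |s|^2))
  t_iso <- 0.01
  cell <- unit_cell(16, 16, 16)
  model <- make_toy_structure(toy_spec(n_atoms = 6, cell = cell, n_groups = 1, seed = 3))
  z <- matrix(0, 3, 3)
  g <- tls_group(diag(t_iso, 3), z, z, c(8, 8, 8),
                 dplyr::distinct(model[c("chain", "resno")]))
  ens <- generate_ensemble(model, cell, list(g), n_models = 2e4, seed = 10)
  grid <- reciprocal_grid(cell, d_min = 3)
  map <- guinier_diffuse(ens, grid = grid)
  F0 <- abs(structure_factors(model, grid))^2
  closed <- F0 * (1 - exp(-4 * pi^2 * t_iso * grid$s^2))
  # compare where the signal is appreciable; Monte-Carlo noise ~ sqrt(2/n)
  big <- closed > 0.05 * max(closed)
  rel <- abs(map$intensity[big] - closed[big]) / closed[big]
  expect_lt(stats::median(rel), 0.02)
  expect_lt(max(rel), 0.06)
})

test_that("hkl text maps round-trip, including fractional indices", {
  ens <- tiny_ensemble(n_models = 3, n_atoms = 4, seed = 9)
  map <- guinier_diffuse(ens, d_min = 4)
  path <- withr::local_tempfile(fileext = ".hkl")
  write_hkl(map, path)
  back <- read_hkl(path)
  expect_equal(back$h, map$h)
  expect_equal(back$intensity, map$intensity, tolerance = 1e-9)
  expect_equal(get_cell(back)$a, get_cell(map)$a)
  expect_equal(attr(back, "d_min"), attr(map, "d_min"))

  frac <- fractional_diffuse(ens, 2, d_min = 6)
  write_hkl(frac, path)
  back2 <- read_hkl(path)
  expect_equal(back2$h, frac$h, tolerance = 1e-4)
  expect_equal(back2$intensity, frac$intensity, tolerance = 1e-9)
})
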