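#' Structure factors of one model by direct summation
#'
#' F(h) = sum_j occ_j f_j(s) D_j(s) exp(2 pi i h . x_j), with x_j the
#' fractional coordinates of atom j and f_j its Cromer-Mann form factor at
#' s = sin(theta)/lambda = |s_vec|/2. Direct summation keeps the result
#' exact at arbitrary (including fractional) Miller indices; no FFT grid
#' is involved.
#'
#' The per-atom isotropic Debye-Waller factor D_j = exp(-B_j s^2) is
#' applied only when `use_b = TRUE`. By default B values are ignored
#' (D_j = 1) so that downstream diffuse intensity reflects ensemble spread
#' alone rather than uncorrelated single-atom smearing.
#'
#' @param model Atom table of a single model (tibble with `element`, `x`,
#'   `y`, `z`, `occ`, `b`).
#' @param grid A [reciprocal_grid()] (its cell defines fractionalization).
#' @param use_b Apply per-atom isotropic B factors.
#' @return Complex vector, one structure factor (electrons) per grid row.
#' @export
structure_factors <- function(model, grid, use_b = FALSE) {
  cell <- get_cell(grid)
  model <- tibble::as_tibble(model)
  if ("model" %in% names(model) && length(unique(model$model)) > 1) {
    rlang::abort("`model` must contain a single model; see ens_model()")
  }
  hkl <- as.matrix(grid[, c("h", "k", "l")])
  sf_engine(hkl, grid$s, cell,
            xyz = as.matrix(model[, c("x", "y", "z")]),
            element = model$element, occ = model$occ,
            b = if (use_b) model$b else NULL)
}

sf_engine <- function(hkl, s_len, cell, xyz, element, occ, b = NULL) {
  frac <- xyz %*% t(cell$frac)           # n_atoms x 3 fractional
  phase <- (2 * pi) * (hkl %*% t(frac))  # n_hkl x n_atoms
  E <- exp(1i * phase)
  if (!is.null(b)) {
    stheta2 <- (s_len / 2)^2
    E <- E * exp(-outer(stheta2, b))
  }
  Fh <- complex(length.out = nrow(hkl))
  s_half <- s_len / 2
  for (el in unique(element)) {
    j <- which(element == el)
    Fh <- Fh + form_factor(el, s_half) * as.vector(E[, j, drop = FALSE] %*% occ[j])
  }
  Fh
}

# first and second moments of F over the models of an ensemble
sf_moments <- function(ensemble, grid, use_b = FALSE) {
  models <- unique(ensemble$model)
  sum_abs2 <- numeric(nrow(grid))
  sum_f <- complex(length.out = nrow(grid))
  idx <- split(seq_len(nrow(ensemble)), ensemble$model)
  for (m in seq_along(idx)) {
    Fm <- structure_factors(ensemble[idx[[m]], , drop = FALSE], grid, use_b = use_b)
    sum_abs2 <- sum_abs2 + Re(Fm * Conj(Fm))
    sum_f <- sum_f + Fm
  }
  list(mean_abs2 = sum_abs2 / length(models), mean_f = sum_f / length(models),
       n = length(models))
}

new_diffuse_map <- function(grid, intensity, anisotropic = FALSE, n_models = NA_integer_) {
  out <- tibble::tibble(h = grid$h, k = grid$k, l = grid$l, s = grid$s,
                        intensity = intensity)
  attr(out, "cell") <- get_cell(grid)
  attr(out, "d_min") <- attr(grid, "d_min", exact = TRUE)
  attr(out, "anisotropic") <- anisotropic
  attr(out, "n_models") <- n_models
  class(out) <- c("diffuse_map", class(tibble::tibble()))
  out
}

#' Diffuse scattering of an ensemble via Guinier's equation
#'
#' The diffuse intensity at scattering vector q is the ensemble variance
#' of the complex structure factor,
#' I_D(q) = <|F_n(q)|^2>_n - |<F_n(q)>_n|^2,
#' averaged with equal weights over the n models ("snapshots") of the
#' ensemble. Intensities are reported per unit cell: the lattice-count
#' prefactor (number of unit cells in the crystal) is fixed to 1, a global
#' scale that drops out of every correlation-based comparison.
#'
#' @param ensemble An [as_ensemble()] object (n >= 1 models).
#' @param d_min Resolution limit in Å (used when `grid` is NULL).
#' @param grid Optional precomputed [reciprocal_grid()].
#' @param use_b Retain per-atom B factors in each F_n (default FALSE; see
#'   [structure_factors()]).
#' @return A `diffuse_map`: tibble with columns `h`, `k`, `l`, `s`
#'   (Å^-1) and `intensity` (electrons^2 per unit cell, non-negative),
#'   carrying the cell and `d_min` as attributes.
#' @examples
#' model <- make_toy_structure(toy_spec(n_atoms = 4, seed = 1))
#' ens <- as_ensemble(model, get_cell(model))
#' guinier_diffuse(ens, d_min = 8) # single model: all zero
#' @export
guinier_diffuse <- function(ensemble, d_min = 3, grid = NULL, use_b = FALSE) {
  stopifnot(is_ensemble(ensemble))
  if (n_models(ensemble) < 1) rlang::abort("ensemble is empty")
  if (is.null(grid)) grid <- reciprocal_grid(get_cell(ensemble), d_min)
  mom <- sf_moments(ensemble, grid, use_b = use_b)
  i_d <- mom$mean_abs2 - Re(mom$mean_f * Conj(mom$mean_f))
  scale <- max(mom$mean_abs2, 1)
  if (min(i_d) < -1e-9 * scale) {
    rlang::abort(sprintf("variance came out negative beyond tolerance (%.3e)", min(i_d)))
  }
  new_diffuse_map(grid, pmax(i_d, 0), n_models = mom$n)
}

#' Mean Bragg intensity of an ensemble
#'
#' The |<F_n>|^2 term of Guinier's equation — the Bragg component the
#' lattice-average structure would scatter. Together with the diffuse map
#' it reconstructs the total: <|F|^2> = I_D + |<F>|^2 exactly.
#'
#' @inheritParams guinier_diffuse
#' @return A `diffuse_map`-classed tibble whose `intensity` column holds
#'   |<F_n>|^2 per index.
#' @export
mean_bragg_intensity <- function(ensemble, d_min = 3, grid = NULL, use_b = FALSE) {
  stopifnot(is_ensemble(ensemble))
  if (n_models(ensemble) < 1) rlang::abort("ensemble is empty")
  if (is.null(grid)) grid <- reciprocal_grid(get_cell(ensemble), d_min)
  mom <- sf_moments(ensemble, grid, use_b = use_b)
  new_diffuse_map(grid, Re(mom$mean_f * Conj(mom$mean_f)), n_models = mom$n)
}

#' Summarize a diffuse map
#' @param x A `diffuse_map`.
#' @param ... Unused.
#' @return One-row tibble: number of indices, resolution limit, intensity
#'   range and total.
#' @export
glance.diffuse_map <- function(x, ...) {
  tibble::tibble(
    n_indices = nrow(x),
    d_min = attr(x, "d_min", exact = TRUE),
    min_intensity = min(x$intensity),
    max_intensity = max(x$intensity),
    total_intensity = sum(x$intensity),
    anisotropic = isTRUE(attr(x, "anisotropic", exact = TRUE))
  )
}

#' Read and write diffuse maps as plain text
#'
#' The interchange format is whitespace-delimited text with a two-line
#' header (`# cell a b c alpha beta gamma` and `# d_min x`) followed by
#' one record per index: `h k l intensity`. Integer indices are written as
#' integers; fractional indices to 4 decimals.
#'
#' @param map A `diffuse_map`.
#' @param path File path.
#' @return `write_hkl()` returns `path` invisibly; `read_hkl()` returns a
#'   `diffuse_map`.
#' @export
write_hkl <- function(map, path) {
  cell <- get_cell(map)
  fractional <- any(abs(map$h - round(map$h)) > 1e-9 | abs(map$k - round(map$k)) > 1e-9 |
                      abs(map$l - round(map$l)) > 1e-9)
  fmt_idx <- function(v) if (fractional) sprintf("%.4f", v) else sprintf("%d", as.integer(round(v)))
  lines <- c(
    sprintf("# cell %.6g %.6g %.6g %.6g %.6g %.6g", cell$a, cell$b, cell$c,
            cell$alpha, cell$beta, cell$gamma),
    sprintf("# d_min %.6g", attr(map, "d_min", exact = TRUE)),
    paste(fmt_idx(map$h), fmt_idx(map$k), fmt_idx(map$l),
          sprintf("%.10g", map$intensity))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_hkl
#' @export
read_hkl <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  header <- grep("^#", lines, value = TRUE)
  cell_line <- grep("^# cell", header, value = TRUE)
  dmin_line <- grep("^# d_min", header, value = TRUE)
  if (length(cell_line) == 0 || length(dmin_line) == 0) {
    rlang::abort("hkl file lacks the '# cell' / '# d_min' header lines")
  }
  cellv <- as.numeric(strsplit(trimws(sub("^# cell", "", cell_line[1])), "\\s+")[[1]])
  d_min <- as.numeric(trimws(sub("^# d_min", "", dmin_line[1])))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))), ncol = 4, byrow = TRUE)
  cell <- as_unit_cell(cellv)
  grid <- new_reciprocal_grid(
    tibble::tibble(h = m[, 1], k = m[, 2], l = m[, 3],
                   s = s_length(cell, m[, 1:3, drop = FALSE])),
    cell, d_min)
  new_diffuse_map(grid, m[, 4], anisotropic = any(m[, 4] < 0))
}
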