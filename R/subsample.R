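#' Expand the unit cell of an ensemble in real space
#'
#' Two expansion schemes support sampling the molecular transform between
#' Bragg points:
#'
#' * `vacuum`: the cell edges are multiplied by `factor` and the contents
#'   left in place (vacuum padding). Atom count and coordinates are
#'   unchanged; the reciprocal lattice becomes `factor` times finer, and
#'   F at expanded index (m h, m k, m l) equals F at (h, k, l) of the
#'   original cell exactly.
#' * `copies`: the expanded cell is tiled with `factor`^3 translated
#'   copies of the original contents (a supercell of copies). With
#'   identical contents per copy, F vanishes except at indices divisible
#'   by `factor` (lattice-sum extinction); assigning different ensemble
#'   models to different copies is the hook for modeling correlations
#'   that span unit cells.
#'
#' @param ensemble An [as_ensemble()] object.
#' @param factor Integer expansion factor m >= 1.
#' @param mode `"vacuum"` or `"copies"`.
#' @param model_assign Copies mode only: optional `function(copy, model)`
#'   returning the original-ensemble model number to place in that copy
#'   for that output model; default uses the same model in every copy.
#'   `copy` is a row of the integer translation table (i, j, k).
#' @return An `ensemble` in the expanded cell, with attributes
#'   `expand_factor` and `expand_mode`.
#' @export
expand_system <- function(ensemble, factor, mode = c("vacuum", "copies"),
                          model_assign = NULL) {
  mode <- match.arg(mode)
  stopifnot(is_ensemble(ensemble))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) rlang::abort("`factor` must be an integer >= 1")
  cell <- get_cell(ensemble)
  big <- unit_cell(cell$a * factor, cell$b * factor, cell$c * factor,
                   cell$alpha, cell$beta, cell$gamma)
  sg <- attr(ensemble, "spacegroup", exact = TRUE)
  if (mode == "vacuum") {
    out <- as_ensemble(tibble::as_tibble(ensemble), big, spacegroup = sg)
  } else {
    shifts <- as.matrix(tidyr::expand_grid(i = 0:(factor - 1), j = 0:(factor - 1),
                                           k = 0:(factor - 1)))
    tvec <- shifts %*% t(cell$orth)  # cartesian translation per copy
    models <- unique(ensemble$model)
    idx <- split(seq_len(nrow(ensemble)), ensemble$model)
    pieces <- vector("list", length(models) * nrow(shifts))
    p <- 0L
    for (m in seq_along(models)) {
      for (cpy in seq_len(nrow(shifts))) {
        src_model <- if (is.null(model_assign)) models[m] else {
          model_assign(shifts[cpy, ], models[m])
        }
        df <- ensemble[idx[[match(src_model, models)]], , drop = FALSE]
        df <- tibble::as_tibble(df)
        df$model <- m
        df$x <- df$x + tvec[cpy, 1]; df$y <- df$y + tvec[cpy, 2]; df$z <- df$z + tvec[cpy, 3]
        p <- p + 1L
        pieces[[p]] <- df
      }
    }
    out <- as_ensemble(dplyr::bind_rows(pieces), big, spacegroup = sg)
  }
  attr(out, "expand_factor") <- factor
  attr(out, "expand_mode") <- mode
  out
}

#' Diffuse intensity at fractional Miller indices via cell expansion
#'
#' Evaluates Guinier's equation on the integer reciprocal lattice of the
#' `factor`-expanded cell and re-expresses the indices on the original
#' lattice by dividing them by `factor`, yielding a subsampling of
#' `factor` x `factor` x `factor` points around each Bragg position. The
#' resolution limit refers to the original cell (the scattering-vector
#' length of an index is unchanged by the rescaling).
#'
#' Cell expansion does not preserve screw-axis symmetry. All content is
#' treated as P1 here, but if the ensemble's space-group symbol declares a
#' screw axis a warning flags that comparison with experimental data from
#' that crystal form is unsupported.
#'
#' @param ensemble An [as_ensemble()] object.
#' @param factor Integer subsampling factor (>= 2 for meaningful
#'   subsampling).
#' @param d_min Resolution limit in Å.
#' @param mode Expansion scheme, see [expand_system()].
#' @param use_b Retain per-atom B factors (see [structure_factors()]).
#' @return A `diffuse_map` on fractional indices of the original cell.
#' @export
fractional_diffuse <- function(ensemble, factor, d_min = 3, mode = "vacuum",
                               use_b = FALSE) {
  stopifnot(is_ensemble(ensemble))
  sg <- attr(ensemble, "spacegroup", exact = TRUE)
  if (has_screw_axis(sg)) {
    rlang::warn(paste0(
      "space group '", sg, "' contains a screw axis: unit-cell expansion does not ",
      "preserve screw symmetry, so comparisons of this map to experimental data are unsupported"))
  }
  expanded <- expand_system(ensemble, factor, mode = mode)
  map_big <- guinier_diffuse(expanded, d_min = d_min, use_b = use_b)
  cell <- get_cell(ensemble)
  grid <- new_reciprocal_grid(
    tibble::tibble(h = map_big$h / factor, k = map_big$k / factor,
                   l = map_big$l / factor, s = map_big$s),
    cell, d_min)
  new_diffuse_map(grid, map_big$intensity, n_models = attr(map_big, "n_models", exact = TRUE))
}

#' Collapse a fractional-index map onto the Bragg lattice
#'
#' Each fractional index is assigned to its nearest integer triple
#' (rounding half away from zero, per component) and the intensities
#' assigned to one integer index are arithmetically averaged — the average
#' diffuse intensity in the 1x1x1 voxel around each Bragg point. The voxel
#' around the origin is retained so that total intensity is conserved
#' exactly (sum over voxels of mean x count equals the fractional total).
#'
#' @param frac_map A `diffuse_map` whose indices lie on a 1/`factor` grid.
#' @param factor The subsampling factor of `frac_map`.
#' @return A `diffuse_map` on integer indices.
#' @export
collapse_to_bragg <- function(frac_map, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) rlang::abort("`factor` must be an integer >= 1")
  scaled <- cbind(frac_map$h, frac_map$k, frac_map$l) * factor
  if (max(abs(scaled - round(scaled))) > 1e-6 * factor) {
    rlang::abort("fractional indices do not lie on a 1/factor grid")
  }
  round_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  H <- round_away(frac_map$h); K <- round_away(frac_map$k); L <- round_away(frac_map$l)
  df <- tibble::tibble(h = H, k = K, l = L, intensity = frac_map$intensity)
  agg <- dplyr::summarise(dplyr::group_by(df, .data$h, .data$k, .data$l),
                          intensity = mean(.data$intensity), n = dplyr::n(),
                          .groups = "drop")
  agg <- dplyr::arrange(agg, .data$h, .data$k, .data$l)
  cell <- get_cell(frac_map)
  grid <- new_reciprocal_grid(
    tibble::tibble(h = agg$h, k = agg$k, l = agg$l,
                   s = s_length(cell, as.matrix(agg[, c("h", "k", "l")]))),
    cell, attr(frac_map, "d_min", exact = TRUE))
  out <- new_diffuse_map(grid, agg$intensity,
                         anisotropic = isTRUE(attr(frac_map, "anisotropic", exact = TRUE)),
                         n_models = attr(frac_map, "n_models", exact = TRUE))
  attr(out, "voxel_count") <- agg$n
  out
}
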