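#' Construct a crystallographic unit cell
#'
#' A unit cell is described by its three edge lengths (Å) and three angles
#' (degrees). The object carries the orthogonalization matrix used to move
#' between fractional and orthogonal (Cartesian) coordinates, and the
#' reciprocal-basis matrix used to compute scattering-vector lengths and
#' d-spacings for (possibly fractional) Miller indices.
#'
#' @param a,b,c Cell edges in Å; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees; must lie in (0, 180), and
#'   jointly define a positive-definite metric (a realizable cell).
#' @return An object of class `unit_cell`: a list with elements `a`, `b`,
#'   `c`, `alpha`, `beta`, `gamma`, the 3x3 orthogonalization matrix `orth`
#'   (fractional -> Cartesian), its inverse `frac`, and the matrix `recip`
#'   whose columns are the reciprocal basis vectors a*, b*, c* in Å^-1.
#' @examples
#' cell <- unit_cell(30, 40, 50)
#' d_spacing(cell, cbind(1, 0, 0)) # == 30
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  edges <- c(a = a, b = b, c = c)
  angles <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (!all(is.finite(edges)) || any(edges <= 0)) {
    rlang::abort("unit cell edges must be positive and finite")
  }
  if (!all(is.finite(angles)) || any(angles <= 0) || any(angles >= 180)) {
    rlang::abort("unit cell angles must lie strictly between 0 and 180 degrees")
  }
  ca <- cospi(alpha / 180); cb <- cospi(beta / 180); cg <- cospi(gamma / 180)
  sg <- sinpi(gamma / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) {
    rlang::abort("unit cell angles do not define a realizable (positive-volume) cell")
  }
  # standard PDB orthogonalization: x along a, y in the a-b plane
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * sqrt(v2) / sg
  ), nrow = 3, byrow = TRUE)
  frac <- solve(orth)
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         orth = orth, frac = frac, recip = t(frac)),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.3f b=%.3f c=%.3f Å  alpha=%.2f beta=%.2f gamma=%.2f°  V=%.1f Å³\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

#' @rdname unit_cell
#' @param x Object to test or convert.
#' @export
is_unit_cell <- function(x) inherits(x, "unit_cell")

#' Cell volume in Å^3
#' @param cell A [unit_cell()].
#' @export
cell_volume <- function(cell) abs(det(cell$orth))

as_unit_cell <- function(x) {
  if (is_unit_cell(x)) return(x)
  if (is.numeric(x) && length(x) == 6) {
    return(unit_cell(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]], x[[6]]))
  }
  rlang::abort("cannot interpret `cell`: supply a unit_cell or numeric length-6 (a,b,c,alpha,beta,gamma)")
}

#' Scattering-vector lengths and d-spacings for Miller indices
#'
#' `s_length()` returns |s| = |h a* + k b* + l c*| in Å^-1 for each index
#' row; `d_spacing()` returns d = 1/|s| in Å. Indices may be fractional.
#'
#' @param cell A [unit_cell()].
#' @param hkl Numeric matrix (or data frame) with three columns h, k, l.
#' @return Numeric vector, one value per row of `hkl`.
#' @export
s_length <- function(cell, hkl) {
  hkl <- as.matrix(hkl[, 1:3, drop = FALSE])
  sqrt(rowSums((hkl %*% t(cell$recip))^2))
}

#' @rdname s_length
#' @export
d_spacing <- function(cell, hkl) 1 / s_length(cell, hkl)

#' Enumerate the reciprocal lattice inside a resolution limit
#'
#' Builds the full sphere of integer Miller indices (h, k, l) with
#' d(hkl) >= d_min, excluding the origin (0, 0, 0). Because every model is
#' treated as P1 cell content, both Friedel mates are present; their
#' intensity symmetry is then a testable property of the calculation rather
#' than an assumption.
#'
#' @param cell A [unit_cell()] (or numeric length 6).
#' @param d_min Resolution limit in Å ("to 3.0 Å" keeps all d >= 3.0 Å).
#' @return A tibble with integer columns `h`, `k`, `l` and numeric `s`
#'   (scattering-vector length, Å^-1), of class `reciprocal_grid`, carrying
#'   the cell and `d_min` as attributes.
#' @examples
#' grid <- reciprocal_grid(unit_cell(20, 20, 20), d_min = 5)
#' range(1 / grid$s) # all d-spacings >= 5
#' @export
reciprocal_grid <- function(cell, d_min) {
  cell <- as_unit_cell(cell)
  if (!is.numeric(d_min) || d_min <= 0) rlang::abort("`d_min` must be a positive resolution in Å")
  # exact bounds: h = s . a so |h| <= a / d_min (and likewise k, l)
  hmax <- floor(c(cell$a, cell$b, cell$c) / d_min)
  grid <- tidyr::expand_grid(
    h = seq.int(-hmax[1], hmax[1]),
    k = seq.int(-hmax[2], hmax[2]),
    l = seq.int(-hmax[3], hmax[3])
  )
  grid$s <- s_length(cell, grid)
  grid <- dplyr::filter(grid, .data$s <= 1 / d_min, .data$h != 0 | .data$k != 0 | .data$l != 0)
  new_reciprocal_grid(grid, cell, d_min)
}

new_reciprocal_grid <- function(df, cell, d_min) {
  out <- tibble::as_tibble(df)
  attr(out, "cell") <- cell
  attr(out, "d_min") <- d_min
  class(out) <- c("reciprocal_grid", class(out))
  out
}

#' Retrieve the unit cell attached to a grid, map or ensemble
#' @param x A `reciprocal_grid`, `diffuse_map` or `ensemble` object.
#' @export
get_cell <- function(x) {
  cell <- attr(x, "cell", exact = TRUE)
  if (is.null(cell)) rlang::abort("object carries no unit cell attribute")
  cell
}
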