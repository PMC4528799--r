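#' Specification for a synthetic toy system
#'
#' The toy generator exists so that every operation in the package — TLS
#' validation, ensemble sampling, diffuse calculation, map analytics,
#' subsampling — can be exercised end to end without any external data.
#' Defaults are desk-scale: tens of atoms in a 30 Å cell resolve to 3 Å in
#' seconds under direct summation while still producing maps with shell
#' structure.
#'
#' @param n_atoms Number of atoms (>= 1); one atom per residue.
#' @param elements Chemical symbols to cycle through.
#' @param cell A [unit_cell()].
#' @param n_groups Number of chains / TLS groups the atoms are split into.
#' @param amplitude_scale Dimensionless multiplier (> 0) on the variances
#'   of generated TLS tensors; 1 gives librations up to ~3 degrees sd and
#'   vibrations up to ~0.22 Å sd.
#' @param seed Integer seed; every generator below is deterministic under
#'   it.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(n_atoms = 40, elements = c("C", "N", "O", "S"),
                     cell = unit_cell(30, 30, 30), n_groups = 2,
                     amplitude_scale = 1, seed = 1) {
  if (n_atoms < 1) rlang::abort("n_atoms must be >= 1")
  if (amplitude_scale < 0) rlang::abort("amplitude_scale must be > 0 (0 allowed for degenerate checks)")
  structure(list(n_atoms = as.integer(n_atoms), elements = elements,
                 cell = as_unit_cell(cell), n_groups = as.integer(n_groups),
                 amplitude_scale = amplitude_scale, seed = as.integer(seed)),
            class = "toy_spec")
}

#' Generate a random toy structure
#'
#' Places `n_atoms` atoms uniformly at random strictly inside the cell,
#' split into `n_groups` chains (A, B, ...) that occupy separate slabs of
#' the cell so each chain is a spatially coherent rigid body. Residue
#' numbers run 1..k within each chain (one atom per residue), so TLS
#' selections can address contiguous blocks.
#'
#' @param spec A [toy_spec()].
#' @return A single-model atom tibble with the cell attached as the
#'   `cell` attribute (retrieve with [get_cell()]).
#' @export
make_toy_structure <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  with_seed(spec$seed, {
    n <- spec$n_atoms
    g <- spec$n_groups
    chain_of <- rep(LETTERS[seq_len(g)], length.out = n)
    chain_of <- sort(chain_of)
    # fractional coordinates: chains in disjoint slabs along a, margin 0.05
    slab <- match(chain_of, LETTERS)
    fx <- stats::runif(n, (slab - 1) / g + 0.05 / g, slab / g - 0.05 / g)
    fy <- stats::runif(n, 0.05, 0.95)
    fz <- stats::runif(n, 0.05, 0.95)
    xyz <- cbind(fx, fy, fz) %*% t(spec$cell$orth)
    atoms <- tibble::tibble(
      model = 1L,
      chain = chain_of,
      resno = unlist(lapply(table(chain_of), seq_len), use.names = FALSE),
      resname = "ALA",
      atom = "CA",
      element = rep(spec$elements, length.out = n),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occ = 1, b = 15
    )
    attr(atoms, "cell") <- spec$cell
    atoms
  })
}

# random right-handed orthonormal triad
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Generate a physically valid random TLS group
#'
#' Builds the group from elementary motions rather than raw tensors, so
#' validity holds by construction: L = R diag(lambda) R' with lambda >= 0,
#' screw pitches chosen so trace(S) = 0 exactly, axis offsets within a few
#' Å of the origin, and T assembled as the vibration tensor (eigenvalues
#' >= 0) plus the translation covariance induced by the displaced axes.
#' [validate_tls()] always passes, and [decompose_tls()] recovers a
#' self-consistent sampler with a non-negative vibration residual.
#'
#' At `amplitude_scale = 1`, libration variances are uniform in
#' (0.2, 1) x (3 deg)^2 and vibration variances uniform in
#' (0.2, 1) x 0.05 Å^2 (within the small-amplitude regime where sampled
#' covariances match the linearized ADP formula closely).
#'
#' @param selection Data frame of (chain, resno) pairs the group moves.
#' @param origin Length-3 orthogonal point in Å.
#' @param amplitude_scale Multiplier on the tensor variances (0 gives the
#'   zero group).
#' @param seed Integer seed.
#' @return A [tls_group()].
#' @export
make_random_tls <- function(selection, origin, amplitude_scale = 1, seed = 1) {
  with_seed(seed, {
    lam <- stats::runif(3, 0.2, 1) * (3 * pi / 180)^2 * amplitude_scale
    vib <- stats::runif(3, 0.2, 1) * 0.05 * amplitude_scale
    R <- random_rotation()
    V <- random_rotation()
    # correlated-translation rows (eigenframe): perpendicular parts from
    # axis offsets, diagonal parts are screw pitches with zero trace(S)
    cmat <- matrix(stats::runif(9, -0.5, 0.5), 3, 3)
    cmat[1, 1] <- stats::runif(1, -0.5, 0.5)
    cmat[2, 2] <- stats::runif(1, -0.5, 0.5)
    cmat[3, 3] <- -(lam[1] * cmat[1, 1] + lam[2] * cmat[2, 2]) / max(lam[3], 1e-12)
    if (amplitude_scale == 0) cmat[] <- 0
    L <- R %*% diag(lam) %*% t(R)
    c_cart <- R %*% t(cmat)
    S <- matrix(0, 3, 3); T_corr <- matrix(0, 3, 3)
    for (i in 1:3) {
      S <- S + lam[i] * tcrossprod(R[, i], c_cart[, i])
      T_corr <- T_corr + lam[i] * tcrossprod(c_cart[, i])
    }
    T_ <- V %*% diag(vib) %*% t(V) + T_corr
    tls_group(T = T_, L = L, S = S, origin = origin, selection = selection)
  })
}

#' Two-chain benchmark: a structure plus one TLS group per chain
#'
#' The standing fixture for comparing independent, parallel and
#' antiparallel inter-group sampling: two disjoint chains that jointly
#' cover all atoms, each with its own valid random TLS group centered on
#' the chain centroid.
#'
#' @param spec A [toy_spec()] (its `n_groups` must be 2).
#' @return A list with `model` (single-model atom tibble, cell attached),
#'   `cell`, and `groups` (list of two [tls_group()]s).
#' @export
make_two_group_benchmark <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  if (spec$n_groups != 2) rlang::abort("make_two_group_benchmark needs n_groups = 2")
  model <- make_toy_structure(spec)
  groups <- lapply(1:2, function(g) {
    ch <- LETTERS[g]
    sel <- dplyr::distinct(model[model$chain == ch, c("chain", "resno")])
    centroid <- colMeans(model[model$chain == ch, c("x", "y", "z")])
    make_random_tls(sel, centroid, amplitude_scale = spec$amplitude_scale,
                    seed = spec$seed + 100L * g)
  })
  list(model = model, cell = get_cell(model), groups = groups)
}
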