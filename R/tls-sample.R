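#' Decompose a TLS group into an explicit rigid-body sampler
#'
#' Turns the T, L, S tensors into the elementary motions they encode, in a
#' form that can be sampled:
#'
#' * libration axes and variances: the eigensystem of L (rad^2);
#' * screw pitches (Å/rad) and libration-axis offset points: from the rows
#'   of L-eigenframe S divided by the corresponding L eigenvalue;
#' * vibration axes and variances: the eigensystem of the residual
#'   translation tensor, i.e. T minus the translation covariance induced
#'   by the displaced/screwed libration axes.
#'
#' Reassembling T, L and S from the decomposition reproduces the input
#' tensors (see [tls_reassemble()]); sampling it reproduces the analytic
#' ADPs of [uij_from_tls()] in the small-amplitude limit.
#'
#' @param group A physically valid [tls_group()] ([validate_tls()] must
#'   pass; otherwise an error asks for validation first).
#' @param tol Negative residual vibration variances down to `-tol` are
#'   clamped to zero silently; anything more negative is a hard error
#'   (the screw content is inconsistent with T).
#' @return An object of class `tls_sampler` with fields `group`,
#'   `libration_axes` (columns), `libration_variances` (rad^2),
#'   `screw_pitches` (Å/rad), `axis_offsets` (columns, Å),
#'   `vibration_axes` (columns), `vibration_variances` (Å^2).
#' @export
decompose_tls <- function(group, tol = 1e-6) {
  rep_ <- validate_tls(group)
  if (!rep_$is_physical) {
    rlang::abort("TLS group is not physical (negative T or L eigenvalues); run validate_tls() and fix the tensors first")
  }
  eL <- eigen(group$L, symmetric = TRUE)
  lam <- pmax(eL$values, 0)
  R <- eL$vectors
  if (det(R) < 0) R[, 3] <- -R[, 3]  # right-handed axis triad

  S_frame <- t(R) %*% group$S %*% R
  cmat <- matrix(0, 3, 3)   # row i: correlated-translation vector of axis i (eigenframe)
  for (i in 1:3) {
    if (lam[i] > 1e-12) {
      cmat[i, ] <- S_frame[i, ] / lam[i]
    } else if (max(abs(S_frame[i, ])) > 1e-8) {
      rlang::warn(sprintf("screw row %d of S has no supporting libration variance; ignored", i))
    }
  }
  pitches <- diag(cmat)
  offsets <- matrix(0, 3, 3)
  for (i in 1:3) {
    e <- diag(3)[, i]
    c_perp <- cmat[i, ] - pitches[i] * e
    # axis i passes through w_i with e_i x (origin - w_i) = c_perp
    offsets[, i] <- group$origin - R %*% crossprod3(c_perp, e)
  }
  # translation covariance already supplied by the librating axes
  c_cart <- R %*% t(cmat)  # column i = c_i in cartesian
  T_corr <- matrix(0, 3, 3)
  for (i in 1:3) T_corr <- T_corr + lam[i] * tcrossprod(c_cart[, i])
  T_resid <- group$T - T_corr
  eT <- eigen((T_resid + t(T_resid)) / 2, symmetric = TRUE)
  v <- eT$values
  if (min(v) < -tol) {
    rlang::abort(sprintf(
      "residual vibration tensor has negative eigenvalue %.3e Å² (beyond tolerance): S is too large for T", min(v)))
  }
  V <- eT$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  structure(
    list(group = group,
         libration_axes = R, libration_variances = lam,
         screw_pitches = pitches, axis_offsets = offsets,
         vibration_axes = V, vibration_variances = pmax(v, 0)),
    class = "tls_sampler"
  )
}

# cross product a x b
crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Reassemble T, L, S from a sampler (self-consistency check)
#'
#' @param sampler A [decompose_tls()] result.
#' @return List with matrices `T`, `L`, `S` in the internal units of
#'   [tls_group()]; equal to the decomposed group's tensors up to the
#'   clamping tolerance.
#' @export
tls_reassemble <- function(sampler) {
  R <- sampler$libration_axes
  lam <- sampler$libration_variances
  L <- R %*% diag(lam) %*% t(R)
  # per-axis correlated translation vectors
  cmat <- matrix(0, 3, 3)
  for (i in 1:3) {
    e <- diag(3)[, i]
    v_frame <- t(R) %*% (sampler$group$origin - sampler$axis_offsets[, i])
    cmat[i, ] <- crossprod3(e, as.numeric(v_frame)) + sampler$screw_pitches[i] * e
  }
  c_cart <- R %*% t(cmat)
  S <- matrix(0, 3, 3)
  T_corr <- matrix(0, 3, 3)
  for (i in 1:3) {
    S <- S + lam[i] * tcrossprod(R[, i], c_cart[, i])
    T_corr <- T_corr + lam[i] * tcrossprod(c_cart[, i])
  }
  T_ <- sampler$vibration_axes %*% diag(sampler$vibration_variances) %*%
    t(sampler$vibration_axes) + T_corr
  list(T = T_, L = L, S = S)
}

#' @export
print.tls_sampler <- function(x, ...) {
  cat("<tls_sampler>\n  libration sd (deg):",
      paste(sprintf("%.3f", sqrt(x$libration_variances) * 180 / pi), collapse = "  "),
      "\n  vibration sd (Å):  ",
      paste(sprintf("%.4f", sqrt(x$vibration_variances)), collapse = "  "),
      "\n  screw pitches (Å/rad):",
      paste(sprintf("%.3f", x$screw_pitches), collapse = "  "), "\n")
  invisible(x)
}

#' Tidy the elementary motions of a TLS sampler
#' @param x A `tls_sampler`.
#' @param ... Unused.
#' @return A tibble with one row per elementary axis (3 librations, 3
#'   vibrations): kind, axis components, variance, screw pitch.
#' @export
tidy.tls_sampler <- function(x, ...) {
  tibble::tibble(
    kind = rep(c("libration", "vibration"), each = 3),
    axis_x = c(x$libration_axes[1, ], x$vibration_axes[1, ]),
    axis_y = c(x$libration_axes[2, ], x$vibration_axes[2, ]),
    axis_z = c(x$libration_axes[3, ], x$vibration_axes[3, ]),
    variance = c(x$libration_variances, x$vibration_variances),
    screw_pitch = c(x$screw_pitches, rep(NA_real_, 3))
  )
}

# Rodrigues rotation matrix about unit axis e by angle theta (rad)
rotation_matrix <- function(e, theta) {
  K <- matrix(c(0, -e[3], e[2], e[3], 0, -e[1], -e[2], e[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Draw one rigid-body displacement from a TLS sampler
#'
#' Each libration angle is Normal(0, lambda_i) about axis i through its
#' offset point, carrying a screw translation pitch_i * angle_i along the
#' axis; each vibration is Normal(0, v_j) along vibration axis j; all six
#' draws are independent. Rotations are applied as exact finite rotations
#' (axis-angle), not linearized, composed in axis order 1, 2, 3 and
#' followed by the vibration translation.
#'
#' @param sampler A [decompose_tls()] result.
#' @param z Optional length-6 vector of standard normal deviates (the
#'   three libration angles then the three vibrations, in units of their
#'   standard deviation); drawn from the current RNG stream if omitted.
#' @return A `rigid_displacement`: list with rotation matrix `R` and
#'   vector `v` acting as p -> R p + v, plus the draw in `z`.
#' @export
sample_displacement <- function(sampler, z = stats::rnorm(6)) {
  stopifnot(length(z) == 6)
  angles <- z[1:3] * sqrt(sampler$libration_variances)
  shifts <- z[4:6] * sqrt(sampler$vibration_variances)
  R_tot <- diag(3); v_tot <- c(0, 0, 0)
  for (i in 1:3) {
    if (angles[i] == 0) next
    e <- sampler$libration_axes[, i]
    w <- sampler$axis_offsets[, i]
    Ri <- rotation_matrix(e, angles[i])
    vi <- w - Ri %*% w + sampler$screw_pitches[i] * angles[i] * e
    # compose p -> Ri p + vi after current map
    v_tot <- as.numeric(Ri %*% v_tot + vi)
    R_tot <- Ri %*% R_tot
  }
  v_tot <- v_tot + as.numeric(sampler$vibration_axes %*% shifts)
  structure(list(R = R_tot, v = v_tot, z = z), class = "rigid_displacement")
}

#' Apply a rigid displacement to coordinates
#' @param disp A `rigid_displacement`.
#' @param coords n x 3 matrix of orthogonal coordinates (Å).
#' @return Displaced n x 3 matrix.
#' @export
apply_displacement <- function(disp, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(disp$R), 2, disp$v, "+")
}

#' Axis-angle vector of a rigid displacement
#' @param disp A `rigid_displacement`.
#' @return Length-3 rotation vector (direction = axis, magnitude = angle
#'   in rad).
#' @export
rotation_vector <- function(disp) {
  R <- disp$R
  cth <- (sum(diag(R)) - 1) / 2
  theta <- acos(max(-1, min(1, cth)))
  if (theta < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(theta))
  ax * theta
}

#' Specify how TLS groups move relative to one another
#'
#' `independent` draws every group's displacement from its own random
#' stream (the default and the assumption behind uncorrelated-group
#' simulations). `parallel` steps all groups deterministically through the
#' same grid of multiples of sigma along every translation and libration
#' eigenvector; `antiparallel` does the same but reverses the direction of
#' the second group's translation steps.
#'
#' @param mode One of "independent", "parallel", "antiparallel".
#' @param n_steps Number of grid steps (models) in the correlated modes.
#' @param step_size Grid spacing in units of sigma. The default grid of 10
#'   steps of sigma/2 runs from -2.5 sigma to +2.0 sigma.
#' @return A `correlation_mode` list.
#' @export
correlation_mode <- function(mode = c("independent", "parallel", "antiparallel"),
                             n_steps = 10, step_size = 0.5) {
  mode <- match.arg(mode)
  if (n_steps < 1 || step_size <= 0) rlang::abort("n_steps >= 1 and step_size > 0 required")
  structure(list(mode = mode, n_steps = as.integer(n_steps), step_size = step_size),
            class = "correlation_mode")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a structural ensemble from TLS groups
#'
#' Realizes the rigid-body disorder encoded by one or more TLS groups as
#' an explicit multi-model ensemble: each group is sampled separately and
#' the displaced pieces are re-assembled into complete models. Atoms
#' covered by no group are copied unchanged.
#'
#' In `independent` mode every (model, group) pair receives its own random
#' displacement; per-group substreams are derived from `seed` so results
#' do not depend on group evaluation order. In `parallel`/`antiparallel`
#' mode (exactly two groups) the ensemble is the deterministic sigma-grid
#' described in [correlation_mode()] and `seed` is ignored.
#'
#' @param base A single-model atom table (tibble with the [as_ensemble()]
#'   columns, `model` optional) giving the mean structure.
#' @param cell A [unit_cell()] (or NULL to use the `cell` attribute of
#'   `base`).
#' @param groups List of [tls_group()] objects with disjoint selections;
#'   every selected residue must exist in `base`.
#' @param n_models Number of models (ignored in correlated modes, which
#'   use `mode$n_steps`).
#' @param mode A [correlation_mode()] (or its mode string).
#' @param seed Integer master seed.
#' @return An [as_ensemble()] object.
#' @export
generate_ensemble <- function(base, cell = NULL, groups, n_models = 1000,
                              mode = "independent", seed = 1) {
  if (is.character(mode)) mode <- correlation_mode(mode)
  base <- tibble::as_tibble(base)
  if ("model" %in% names(base) && length(unique(base$model)) > 1) {
    rlang::abort("`base` must be a single model")
  }
  if (is.null(cell)) cell <- get_cell(base)
  cell <- as_unit_cell(cell)

  sel_keys <- purrr::map(groups, function(g) paste(g$selection$chain, g$selection$resno))
  all_sel <- unlist(sel_keys)
  if (anyDuplicated(all_sel)) {
    rlang::abort(paste0("TLS group selections overlap at residue ", all_sel[duplicated(all_sel)][1]))
  }
  base_key <- paste(base$chain, base$resno)
  missing <- setdiff(all_sel, base_key)
  if (length(missing) > 0) {
    rlang::abort(paste0("selected residue(s) absent from base model: ",
                        paste(utils::head(missing, 3), collapse = "; ")))
  }
  group_rows <- purrr::map(sel_keys, function(k) which(base_key %in% k))
  samplers <- purrr::map(groups, decompose_tls)

  if (mode$mode == "independent") {
    n <- n_models
    zs <- purrr::imap(samplers, function(s, g) {
      with_seed(seed + 7919L * g, matrix(stats::rnorm(6L * n), ncol = 6))
    })
  } else {
    if (length(groups) != 2) {
      rlang::abort(paste0("mode '", mode$mode, "' requires exactly 2 TLS groups, got ", length(groups)))
    }
    n <- mode$n_steps
    alphas <- (seq_len(n) - 1 - n / 2) * mode$step_size
    zs <- purrr::imap(samplers, function(s, g) {
      z <- cbind(alphas, alphas, alphas, alphas, alphas, alphas)
      if (mode$mode == "antiparallel" && g == 2) z[, 4:6] <- -z[, 4:6]
      z
    })
  }

  xyz0 <- as.matrix(base[, c("x", "y", "z")])
  n_atoms <- nrow(base)
  coords <- matrix(NA_real_, n_atoms * n, 3)
  for (m in seq_len(n)) {
    xyz <- xyz0
    for (g in seq_along(samplers)) {
      rows <- group_rows[[g]]
      disp <- sample_displacement(samplers[[g]], zs[[g]][m, ])
      xyz[rows, ] <- apply_displacement(disp, xyz0[rows, , drop = FALSE])
    }
    coords[(m - 1L) * n_atoms + seq_len(n_atoms), ] <- xyz
  }
  atoms <- base[rep(seq_len(n_atoms), n), , drop = FALSE]
  atoms$model <- rep(seq_len(n), each = n_atoms)
  atoms$x <- coords[, 1]; atoms$y <- coords[, 2]; atoms$z <- coords[, 3]
  as_ensemble(atoms, cell, spacegroup = attr(base, "spacegroup", exact = TRUE))
}
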