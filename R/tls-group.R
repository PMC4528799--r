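#' A TLS rigid-body disorder group
#'
#' Translation-libration-screw (TLS) parameterization describes the
#' harmonic rigid-body disorder of a group of atoms with 20 parameters:
#' the symmetric translation tensor T (Å^2), the symmetric libration
#' tensor L (rad^2 internally; PDB headers carry deg^2), the screw tensor
#' S (Å rad internally) whose trace is fixed to zero by convention, and an
#' origin. The implied anisotropic displacement at position r is
#' U(r) = T + A L A' + A S + S' A' with A the skew matrix of (r - origin).
#'
#' The constructor symmetrizes T and L (an error if they are asymmetric
#' beyond `tol`), and re-centers S to trace zero by subtracting trace(S)/3
#' from its diagonal.
#'
#' @param T,L,S 3x3 tensors: T in Å^2, L in rad^2, S in Å rad.
#' @param origin Length-3 orthogonal point in Å.
#' @param selection Data frame with columns `chain` and `resno` naming the
#'   residues the group moves.
#' @param tol Symmetry tolerance for T and L.
#' @return An object of class `tls_group`.
#' @export
tls_group <- function(T, L, S, origin, selection, tol = 1e-6) {
  T <- as.matrix(T); L <- as.matrix(L); S <- as.matrix(S)
  stopifnot(all(dim(T) == 3), all(dim(L) == 3), all(dim(S) == 3), length(origin) == 3)
  for (nm in c("T", "L")) {
    m <- get(nm)
    if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
      rlang::abort(paste0(nm, " tensor is not symmetric within tolerance"))
    }
  }
  S <- S - diag(sum(diag(S)) / 3, 3)  # trace convention
  if (!all(c("chain", "resno") %in% names(selection))) {
    rlang::abort("`selection` needs columns chain and resno")
  }
  selection <- tibble::tibble(chain = as.character(selection$chain),
                              resno = as.integer(selection$resno))
  structure(
    list(T = (T + t(T)) / 2, L = (L + t(L)) / 2, S = S,
         origin = as.numeric(origin),
         selection = dplyr::distinct(selection[c("chain", "resno")])),
    class = "tls_group"
  )
}

#' @export
print.tls_group <- function(x, ...) {
  cat(sprintf("<tls_group> %d residue(s) in chain(s) %s; origin (%.2f, %.2f, %.2f)\n",
              nrow(x$selection), paste(unique(x$selection$chain), collapse = ","),
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  trace T = %.4f Å², trace L = %.4f rad², trace S = %.1e Å·rad\n",
              sum(diag(x$T)), sum(diag(x$L)), sum(diag(x$S))))
  invisible(x)
}

#' Tidy the tensor elements of a TLS group
#'
#' @param x A [tls_group()].
#' @param ... Unused.
#' @return A tibble with columns `tensor` (T/L/S), `i`, `j` and `value`
#'   (internal units: Å^2, rad^2, Å rad).
#' @export
tidy.tls_group <- function(x, ...) {
  one <- function(name) {
    m <- x[[name]]
    tibble::tibble(tensor = name, i = rep(1:3, each = 3), j = rep(1:3, 3),
                   value = as.numeric(t(m)))
  }
  dplyr::bind_rows(one("T"), one("L"), one("S"))
}

#' Check a TLS group for physical plausibility
#'
#' The eigenvalues of T and L are the variances of the group's vibration
#' and libration along their principal axes, so a physically meaningful
#' group must have non-negative eigenvalues in both. Roughly 85% of
#' TLS-refined PDB depositions violate this, so checking is a required
#' first step before converting tensors into an ensemble.
#'
#' @param group A [tls_group()].
#' @param tol Eigenvalues above `-tol` count as non-negative (numerical
#'   noise from 4-decimal PDB tensors); default 1e-8 (Å^2 for T, rad^2
#'   for L).
#' @return A `tls_validation` list: `t_eigenvalues` and `l_eigenvalues`
#'   (each sorted descending), `is_physical`, and `messages`.
#' @export
validate_tls <- function(group, tol = 1e-8) {
  stopifnot(inherits(group, "tls_group"))
  te <- sort(eigen(group$T, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  le <- sort(eigen(group$L, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  msgs <- character()
  if (min(te) < -tol) msgs <- c(msgs, sprintf("T has negative eigenvalue %.3e Å²", min(te)))
  if (min(le) < -tol) msgs <- c(msgs, sprintf("L has negative eigenvalue %.3e rad²", min(le)))
  tr_s <- sum(diag(group$S))
  msgs <- c(msgs, sprintf("trace(S) deviation from zero: %.3e Å·rad", tr_s))
  structure(
    list(t_eigenvalues = te, l_eigenvalues = le,
         is_physical = min(te) >= -tol && min(le) >= -tol,
         messages = msgs),
    class = "tls_validation"
  )
}

#' @export
print.tls_validation <- function(x, ...) {
  cat("<tls_validation>", if (x$is_physical) "physical" else "NOT physical", "\n")
  cat("  T eigenvalues (Å²):  ", paste(sprintf("%.5f", x$t_eigenvalues), collapse = "  "), "\n")
  cat("  L eigenvalues (rad²):", paste(sprintf("%.3e", x$l_eigenvalues), collapse = "  "), "\n")
  for (m in x$messages) cat("  -", m, "\n")
  invisible(x)
}

#' Anisotropic displacement tensor implied by a TLS group
#'
#' Closed form U(r) = T + A L A' + A S + S' A', where A is the skew matrix
#' acting as A w = w x (r - origin). This is the analytic counterpart of
#' the displacement covariance that ensemble sampling realizes, and serves
#' as the oracle for the sampler's parameter-recovery property.
#'
#' @param group A [tls_group()].
#' @param position Length-3 orthogonal point in Å.
#' @return Symmetric 3x3 matrix in Å^2.
#' @export
uij_from_tls <- function(group, position) {
  d <- as.numeric(position) - group$origin
  # A w = w x d  (so A = -skew(d))
  A <- matrix(c(0, d[3], -d[2],
                -d[3], 0, d[1],
                d[2], -d[1], 0), nrow = 3, byrow = TRUE)
  U <- group$T + A %*% group$L %*% t(A) + A %*% group$S + t(group$S) %*% t(A)
  (U + t(U)) / 2
}
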