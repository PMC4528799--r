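#' Structural ensembles as tidy atom tables
#'
#' An ensemble is an ordered collection of conformer models ("snapshots")
#' that share one atom roster and one unit cell. It is stored as a tibble
#' with one row per atom per model and columns:
#'
#' * `model`   — integer model number (>= 1)
#' * `chain`   — chain identifier
#' * `resno`   — residue number
#' * `resname` — residue name
#' * `atom`    — atom name (e.g. `"CA"`)
#' * `element` — chemical symbol, must have a tabulated form factor
#' * `x`, `y`, `z` — orthogonal coordinates in Å
#' * `occ`     — occupancy in \[0, 1\]
#' * `b`       — isotropic displacement parameter in Å^2
#'
#' Only positions may differ between models; identifiers, elements,
#' occupancies and B values are fixed across the ensemble, and the row
#' order within each model is identical.
#'
#' @param atoms A data frame with the columns above (`model` defaults to 1
#'   if absent; `resname`, `occ`, `b` get defaults `"ALA"`, 1, 0).
#' @param cell A [unit_cell()] or numeric length-6 vector.
#' @param spacegroup Optional space-group symbol string (kept for the
#'   screw-axis warning in [fractional_diffuse()]; content is always
#'   treated as P1).
#' @return A tibble of class `ensemble` with `cell` and `spacegroup`
#'   attributes.
#' @export
as_ensemble <- function(atoms, cell, spacegroup = NULL) {
  cell <- as_unit_cell(cell)
  atoms <- tibble::as_tibble(atoms)
  if (!"model" %in% names(atoms)) atoms$model <- 1L
  if (!"resname" %in% names(atoms)) atoms$resname <- "ALA"
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 0
  needed <- c("model", "chain", "resno", "resname", "atom", "element", "x", "y", "z", "occ", "b")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    rlang::abort(paste0("ensemble atoms lack column(s): ", paste(missing, collapse = ", ")))
  }
  atoms <- dplyr::arrange(atoms[needed], .data$model)
  out <- validate_ensemble(atoms)
  attr(out, "cell") <- cell
  attr(out, "spacegroup") <- spacegroup
  class(out) <- c("ensemble", class(tibble::tibble()))
  out
}

validate_ensemble <- function(atoms) {
  models <- unique(atoms$model)
  if (length(models) < 1) rlang::abort("an ensemble needs at least one model")
  unknown <- setdiff(unique(atoms$element), known_elements())
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown element(s) with no tabulated form factor: ",
                        paste(unknown, collapse = ", ")))
  }
  if (any(atoms$occ < 0 | atoms$occ > 1)) rlang::abort("occupancies must lie in [0, 1]")
  idx <- split(seq_len(nrow(atoms)), atoms$model)
  roster <- function(rows) atoms[rows, c("chain", "resno", "atom", "element", "occ", "b")]
  first <- roster(idx[[1]])
  for (m in seq_along(idx)[-1]) {
    cur <- roster(idx[[m]])
    if (nrow(cur) != nrow(first)) {
      rlang::abort(sprintf("model %s has %d atoms but model %s has %d: rosters must match",
                           names(idx)[m], nrow(cur), names(idx)[1], nrow(first)))
    }
    if (!isTRUE(all.equal(as.list(cur), as.list(first), check.attributes = FALSE))) {
      i <- which(cur$chain != first$chain | cur$resno != first$resno | cur$atom != first$atom)
      i <- if (length(i) > 0) i[1] else 1L
      rlang::abort(sprintf(
        "atom roster mismatch at row %d of model %s: (%s %s %s) vs (%s %s %s) in model %s",
        i, names(idx)[m], cur$chain[i], cur$resno[i], cur$atom[i],
        first$chain[i], first$resno[i], first$atom[i], names(idx)[1]))
    }
  }
  atoms
}

#' @rdname as_ensemble
#' @param x Object to test.
#' @export
is_ensemble <- function(x) inherits(x, "ensemble")

#' Number of models in an ensemble
#' @param ensemble An [as_ensemble()] object.
#' @export
n_models <- function(ensemble) length(unique(ensemble$model))

#' Extract one model of an ensemble as an atom table
#' @param ensemble An [as_ensemble()] object.
#' @param model Model number to extract (default: the first).
#' @return A tibble of atoms (single model), retaining the cell attribute.
#' @export
ens_model <- function(ensemble, model = NULL) {
  if (is.null(model)) model <- ensemble$model[1]
  out <- dplyr::filter(tibble::as_tibble(ensemble), .data$model == !!model)
  attr(out, "cell") <- attr(ensemble, "cell", exact = TRUE)
  out
}

#' @export
print.ensemble <- function(x, ...) {
  cell <- get_cell(x)
  cat(sprintf("<ensemble> %d model(s) x %d atoms\n", n_models(x), as.integer(nrow(x) / n_models(x))))
  print(cell)
  NextMethod()
}

#' Summary statistics for an ensemble
#'
#' @param x An `ensemble`.
#' @param ... Unused.
#' @return A one-row tibble: models, atoms per model, elements used and the
#'   root-mean-square coordinate spread about the per-atom mean (Å).
#' @export
glance.ensemble <- function(x, ...) {
  per_atom <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$chain, .data$resno, .data$atom),
    msd = mean((.data$x - mean(.data$x))^2 + (.data$y - mean(.data$y))^2 +
                 (.data$z - mean(.data$z))^2),
    .groups = "drop"
  )
  tibble::tibble(
    n_models = n_models(x),
    n_atoms = nrow(x) / n_models(x),
    elements = paste(sort(unique(x$element)), collapse = ","),
    rmsf = sqrt(mean(per_atom$msd))
  )
}
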