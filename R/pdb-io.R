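#' Read a multi-model PDB file into an ensemble
#'
#' Parses CRYST1, MODEL/ENDMDL and ATOM/HETATM records. The atom order of
#' the first model fixes the roster; atoms of subsequent models are matched
#' by the identifier tuple (chain, residue number, atom name) so that
#' renumbered MODEL blocks still align. A file with no MODEL records is
#' read as a single-model ensemble.
#'
#' Waters (residue name HOH/WAT) are dropped by default: the ensemble
#' itself is the disorder model and solvent is deliberately excluded from
#' the scattering calculation. For the same reason only blank or 'A'
#' alternate-location indicators are kept. Hydrogens are dropped by default.
#'
#' @param path Path to a PDB file containing a CRYST1 record.
#' @param keep_waters,keep_hydrogens Retain waters / hydrogen atoms.
#' @return An [as_ensemble()] tibble with the cell and any space-group
#'   symbol from CRYST1 attached.
#' @export
read_pdb_multimodel <- function(path, keep_waters = FALSE, keep_hydrogens = FALSE) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst) == 0) rlang::abort("PDB file has no CRYST1 record; a unit cell is required")
  cr <- cryst[1]
  cell <- unit_cell(
    as.numeric(substr(cr, 7, 15)), as.numeric(substr(cr, 16, 24)),
    as.numeric(substr(cr, 25, 33)), as.numeric(substr(cr, 34, 40)),
    as.numeric(substr(cr, 41, 47)), as.numeric(substr(cr, 48, 54))
  )
  spacegroup <- trimws(substr(cr, 56, 66))
  if (!nzchar(spacegroup)) spacegroup <- NULL

  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  model_id <- cumsum(grepl("^MODEL", lines))
  if (length(model_starts) == 0) model_id <- rep(1L, length(lines))
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]
  if (length(atom_lines) == 0) rlang::abort("PDB file contains no ATOM/HETATM records")
  if (any(atom_model == 0)) rlang::abort("ATOM records found before the first MODEL record")

  atoms <- parse_atom_lines(atom_lines)
  atoms$model <- atom_model
  if (!keep_waters) atoms <- atoms[!atoms$resname %in% c("HOH", "WAT"), , drop = FALSE]
  atoms <- atoms[atoms$altloc %in% c("", "A"), , drop = FALSE]
  if (!keep_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (nrow(atoms) == 0) rlang::abort("no atoms left after filtering")
  unknown <- setdiff(unique(atoms$element), known_elements())
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown element(s) in PDB file: ", paste(unknown, collapse = ", ")))
  }

  models <- sort(unique(atoms$model))
  key <- function(df) paste(df$chain, df$resno, df$atom, sep = "\r")
  first <- atoms[atoms$model == models[1], , drop = FALSE]
  reordered <- purrr::map(seq_along(models), function(i) {
    cur <- atoms[atoms$model == models[i], , drop = FALSE]
    idx <- match(key(first), key(cur))
    if (anyNA(idx) || nrow(cur) != nrow(first)) {
      miss <- which(is.na(idx))[1]
      what <- if (!is.na(miss)) {
        sprintf("model %d lacks atom (%s %d %s) present in model 1",
                i, first$chain[miss], first$resno[miss], first$atom[miss])
      } else {
        extra <- setdiff(key(cur), key(first))[1]
        sprintf("model %d has extra atom (%s) absent from model 1",
                i, gsub("\r", " ", extra))
      }
      rlang::abort(paste0("atom roster mismatch: ", what))
    }
    cur <- cur[idx, , drop = FALSE]
    cur$model <- i  # renumber sequentially
    cur
  })
  atoms <- dplyr::bind_rows(reordered)
  atoms$altloc <- NULL
  as_ensemble(atoms, cell, spacegroup = spacegroup)
}

parse_atom_lines <- function(lines) {
  # pad so fixed-column extraction is safe on short lines
  ln <- formatC(lines, width = 80, flag = "-")
  element <- trimws(substr(ln, 77, 78))
  name <- trimws(substr(ln, 13, 16))
  # fall back to the atom-name convention when the element field is blank
  guess <- toupper(substr(gsub("[0-9']", "", name), 1, 1))
  element <- ifelse(nzchar(element), element, guess)
  element <- paste0(toupper(substr(element, 1, 1)), tolower(substr(element, 2, 10)))
  tibble::tibble(
    chain = trimws(substr(ln, 22, 22)),
    resno = as.integer(substr(ln, 23, 26)),
    resname = trimws(substr(ln, 18, 20)),
    atom = name,
    altloc = trimws(substr(ln, 17, 17)),
    element = element,
    x = as.numeric(substr(ln, 31, 38)),
    y = as.numeric(substr(ln, 39, 46)),
    z = as.numeric(substr(ln, 47, 54)),
    occ = as.numeric(substr(ln, 55, 60)),
    b = as.numeric(substr(ln, 61, 66))
  )
}

#' Write an ensemble as a multi-model PDB file
#'
#' Emits CRYST1 (with any space-group symbol carried by the ensemble),
#' optional REMARK 3 TLS blocks, and one MODEL/ENDMDL block per model with
#' coordinates to 3 decimals.
#'
#' @param ensemble An [as_ensemble()] object.
#' @param path Output file path.
#' @param tls Optional list of [tls_group()] objects to embed as REMARK 3
#'   header blocks (tensors are written in the PDB convention: L in deg^2,
#'   S in Å deg).
#' @return `path`, invisibly.
#' @export
write_pdb_multimodel <- function(ensemble, path, tls = NULL) {
  stopifnot(is_ensemble(ensemble))
  cell <- get_cell(ensemble)
  sg <- attr(ensemble, "spacegroup", exact = TRUE)
  out <- c(
    sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
            cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma,
            if (is.null(sg)) "P 1" else sg, 1L)
  )
  if (!is.null(tls)) out <- c(out, format_tls_records(tls))
  models <- unique(ensemble$model)
  for (m in models) {
    df <- ensemble[ensemble$model == m, , drop = FALSE]
    name4 <- ifelse(nchar(df$atom) < 4 & nchar(df$element) == 1,
                    paste0(" ", df$atom), df$atom)
    out <- c(out,
             sprintf("MODEL     %4d", match(m, models)),
             sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     seq_len(nrow(df)) %% 100000L, name4, "", df$resname, df$chain,
                     df$resno, "", df$x, df$y, df$z, df$occ, df$b,
                     toupper(df$element)),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

format_tls_records <- function(groups) {
  rad2deg2 <- (180 / pi)^2
  rad2deg <- 180 / pi
  out <- c("REMARK   3  TLS DETAILS",
           sprintf("REMARK   3   NUMBER OF TLS GROUPS  : %4d", length(groups)))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    out <- c(out, sprintf("REMARK   3   TLS GROUP : %5d", i))
    sel <- g$selection
    for (ch in unique(sel$chain)) {
      rs <- sort(sel$resno[sel$chain == ch])
      # contiguous runs -> RESIDUE RANGE lines
      brk <- c(0, which(diff(rs) != 1), length(rs))
      for (j in seq_len(length(brk) - 1)) {
        lo <- rs[brk[j] + 1]; hi <- rs[brk[j + 1]]
        out <- c(out, sprintf("REMARK   3    RESIDUE RANGE :   %1s %5d        %1s %5d", ch, lo, ch, hi))
      }
    }
    out <- c(out,
      sprintf("REMARK   3    ORIGIN FOR THE GROUP (A): %9.4f %9.4f %9.4f",
              g$origin[1], g$origin[2], g$origin[3]),
      "REMARK   3    T TENSOR",
      sprintf("REMARK   3      T11: %9.4f T22: %9.4f", g$T[1, 1], g$T[2, 2]),
      sprintf("REMARK   3      T33: %9.4f T12: %9.4f", g$T[3, 3], g$T[1, 2]),
      sprintf("REMARK   3      T13: %9.4f T23: %9.4f", g$T[1, 3], g$T[2, 3]),
      "REMARK   3    L TENSOR",
      sprintf("REMARK   3      L11: %9.4f L22: %9.4f", g$L[1, 1] * rad2deg2, g$L[2, 2] * rad2deg2),
      sprintf("REMARK   3      L33: %9.4f L12: %9.4f", g$L[3, 3] * rad2deg2, g$L[1, 2] * rad2deg2),
      sprintf("REMARK   3      L13: %9.4f L23: %9.4f", g$L[1, 3] * rad2deg2, g$L[2, 3] * rad2deg2),
      "REMARK   3    S TENSOR",
      sprintf("REMARK   3      S11: %9.4f S12: %9.4f S13: %9.4f",
              g$S[1, 1] * rad2deg, g$S[1, 2] * rad2deg, g$S[1, 3] * rad2deg),
      sprintf("REMARK   3      S21: %9.4f S22: %9.4f S23: %9.4f",
              g$S[2, 1] * rad2deg, g$S[2, 2] * rad2deg, g$S[2, 3] * rad2deg),
      sprintf("REMARK   3      S31: %9.4f S32: %9.4f S33: %9.4f",
              g$S[3, 1] * rad2deg, g$S[3, 2] * rad2deg, g$S[3, 3] * rad2deg))
  }
  out
}

#' Parse REMARK 3 TLS blocks from a PDB file
#'
#' Reads the standard PDB/REFMAC REMARK 3 TLS dialect (T11..T23, L11..L23,
#' S11..S33 token lines, ORIGIN, RESIDUE RANGE). Tensor element lines may
#' appear in any order within a block. On load, T and L are symmetrized, L
#' is converted from deg^2 to rad^2, S from Å deg to Å rad, and S is
#' re-centered to trace zero (S is only determined up to its trace).
#'
#' @param path Path to a PDB file.
#' @return A list of [tls_group()] objects (empty if the file carries no
#'   TLS blocks).
#' @export
parse_tls_records <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rem <- grepl("^REMARK   3", lines)
  starts <- grep("TLS GROUP\\s*:", lines)
  starts <- starts[rem[starts]]
  if (length(starts) == 0) return(list())
  ends <- c(starts[-1] - 1L, max(which(rem)))
  purrr::map2(starts, ends, function(from, to) {
    block <- lines[from:to]
    lineno <- from:to
    tokens <- list()
    for (j in seq_along(block)) {
      mm <- gregexpr("([TLS][1-3][1-3]):\\s*(-?[0-9.eE+]+|\\S+)", block[j])[[1]]
      if (mm[1] == -1) next
      for (k in seq_along(mm)) {
        frag <- substr(block[j], mm[k], mm[k] + attr(mm, "match.length")[k] - 1)
        key <- substr(frag, 1, 3)
        val <- suppressWarnings(as.numeric(trimws(sub("^[TLS][1-3][1-3]:", "", frag))))
        if (is.na(val)) {
          rlang::abort(sprintf("malformed TLS tensor element '%s' at line %d of %s",
                               key, lineno[j], path))
        }
        tokens[[key]] <- val
      }
    }
    need_sym <- c("11", "22", "33", "12", "13", "23")
    for (pre in c("T", "L")) {
      missing <- paste0(pre, need_sym)[!paste0(pre, need_sym) %in% names(tokens)]
      if (length(missing) > 0) {
        rlang::abort(paste0("TLS block starting at line ", from, " lacks element(s): ",
                            paste(missing, collapse = ", ")))
      }
    }
    sym33 <- function(pre) {
      m <- diag(c(tokens[[paste0(pre, "11")]], tokens[[paste0(pre, "22")]], tokens[[paste0(pre, "33")]]))
      m[1, 2] <- m[2, 1] <- tokens[[paste0(pre, "12")]]
      m[1, 3] <- m[3, 1] <- tokens[[paste0(pre, "13")]]
      m[2, 3] <- m[3, 2] <- tokens[[paste0(pre, "23")]]
      m
    }
    Smat <- matrix(0, 3, 3)
    for (r in 1:3) for (cc in 1:3) {
      key <- sprintf("S%d%d", r, cc)
      if (key %in% names(tokens)) Smat[r, cc] <- tokens[[key]]
    }
    origin_line <- grep("ORIGIN", block, value = TRUE)
    if (length(origin_line) == 0) {
      rlang::abort(paste0("TLS block starting at line ", from, " has no ORIGIN line"))
    }
    nums <- regmatches(origin_line[1], gregexpr("-?[0-9]+\\.[0-9]+", origin_line[1]))[[1]]
    origin <- as.numeric(nums[1:3])

    sel <- tibble::tibble(chain = character(), resno = integer())
    for (rl in grep("RESIDUE RANGE", block, value = TRUE)) {
      tok <- strsplit(trimws(sub(".*RESIDUE RANGE\\s*:", "", rl)), "\\s+")[[1]]
      if (length(tok) >= 4) {
        sel <- dplyr::bind_rows(sel, tibble::tibble(
          chain = tok[1], resno = seq.int(as.integer(tok[2]), as.integer(tok[4]))))
      }
    }
    if (nrow(sel) == 0) {
      rlang::warn(paste0("TLS block starting at line ", from,
                         " has an empty selection; group retained"))
    }
    deg2rad <- pi / 180
    tls_group(T = sym33("T"), L = sym33("L") * deg2rad^2, S = Smat * deg2rad,
              origin = origin, selection = dplyr::distinct(sel))
  })
}

# TRUE when a space-group symbol contains a screw-axis operator (e.g. 21,
# 31, 32, 41, ..., 65). Unit-cell expansion cannot preserve screw symmetry,
# so downstream subsampling warns on such input.
has_screw_axis <- function(spacegroup) {
  if (is.null(spacegroup) || !nzchar(spacegroup)) return(FALSE)
  grepl("\\b(21|31|32|41|42|43|61|62|63|64|65)\\b", spacegroup)
}
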