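#' Radial (spherically averaged) intensity profile of a diffuse map
#'
#' Assigns every index to one of `n_bins` equal-width bins in
#' scattering-vector length |s| = 1/d spanning \[0, max(s)\], and averages
#' the intensity within each bin. |s| (not d) is the bin variable so that
#' shells stay uniformly populated at high resolution.
#'
#' @param map A `diffuse_map`.
#' @param n_bins Number of resolution bins (>= 1).
#' @return A tibble of class `radial_profile` with columns `bin`, `s_min`,
#'   `s_max`, `s_mid` (Å^-1), `mean_intensity` and `count`; empty bins
#'   carry mean 0 and count 0.
#' @export
radial_profile <- function(map, n_bins = 50) {
  if (nrow(map) == 0) rlang::abort("map is empty")
  if (n_bins < 1) rlang::abort("n_bins must be >= 1")
  shell <- s_bin(map$s, n_bins)
  edges <- attr(shell, "edges")
  means <- rep(0, n_bins); counts <- rep(0L, n_bins)
  tab <- tapply(map$intensity, factor(shell, levels = seq_len(n_bins)), mean)
  cnt <- tapply(rep(1L, nrow(map)), factor(shell, levels = seq_len(n_bins)), sum)
  means[!is.na(tab)] <- tab[!is.na(tab)]
  counts[!is.na(cnt)] <- cnt[!is.na(cnt)]
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    s_min = edges[-(n_bins + 1)], s_max = edges[-1],
    s_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    mean_intensity = means, count = counts
  )
  class(out) <- c("radial_profile", class(out))
  out
}

# equal-width |s| bins over [0, max(s)]; returns bin index with edges attr
s_bin <- function(s, n_bins) {
  top <- max(s) * (1 + 1e-12)
  edges <- seq(0, top, length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1L), n_bins)
  attr(idx, "edges") <- edges
  idx
}

#' Remove the spherically symmetric component of a diffuse map
#'
#' Subtracts from each intensity the mean of its |s| bin, leaving an
#' "anisotropic map" that isolates the directional diffuse signal.
#' Spherically symmetric diffuse scattering dominates the raw intensity
#' and is shared between otherwise different models, so correlations
#' between raw maps overestimate their agreement; anisotropic maps are the
#' meaningful comparison. Output values may be negative; within every bin
#' the output mean is zero (to numerical precision), and the operation is
#' idempotent.
#'
#' @param map A `diffuse_map`.
#' @param n_bins Number of |s| bins for the radial estimate (default 50).
#' @return A `diffuse_map`-classed tibble flagged anisotropic.
#' @export
subtract_isotropic <- function(map, n_bins = 50) {
  if (nrow(map) == 0) rlang::abort("map is empty")
  bin <- s_bin(map$s, n_bins)
  out <- map
  out$intensity <- map$intensity - stats::ave(map$intensity, bin)
  attr(out, "anisotropic") <- TRUE
  out
}

# align two maps on their (h, k, l) sets; hard error on any mismatch
align_maps <- function(map_a, map_b) {
  key <- function(m) sprintf("%.6f %.6f %.6f", m$h, m$k, m$l)
  ka <- key(map_a); kb <- key(map_b)
  idx <- match(ka, kb)
  if (anyNA(idx) || nrow(map_a) != nrow(map_b)) {
    off <- if (anyNA(idx)) ka[which(is.na(idx))[1]] else setdiff(kb, ka)[1]
    rlang::abort(paste0("maps are on different grids; first offending index: (", off, ")"))
  }
  list(a = map_a, b = map_b[idx, , drop = FALSE])
}

#' Global Pearson correlation between two diffuse maps
#'
#' Standard Pearson coefficient over paired intensities; both maps must
#' cover exactly the same set of Miller indices (in any order).
#'
#' @param map_a,map_b `diffuse_map` objects on identical index sets.
#' @return A single correlation in \[-1, 1\].
#' @export
pearson_cc <- function(map_a, map_b) {
  al <- align_maps(map_a, map_b)
  if (stats::sd(al$a$intensity) == 0 || stats::sd(al$b$intensity) == 0) {
    rlang::abort("Pearson correlation undefined: an input map has zero intensity variance")
  }
  stats::cor(al$a$intensity, al$b$intensity)
}

#' Pearson correlation per resolution bin
#'
#' Computes the Pearson correlation of two maps within each equal-width
#' |s| bin, plus the global coefficient over all indices. Bins with fewer
#' than 3 points or zero variance in either map are reported as `NA`
#' (never as 0, which would bias trend plots).
#'
#' @param map_a,map_b `diffuse_map` objects on identical index sets.
#' @param n_bins Number of |s| bins (default 10).
#' @return A tibble of class `binned_cc` with columns `bin`, `s_min`,
#'   `s_max`, `s_mid`, `n` and `cc`; the global value is carried as the
#'   `global_cc` attribute (see [glance.binned_cc()]).
#' @export
cc_by_resolution <- function(map_a, map_b, n_bins = 10) {
  al <- align_maps(map_a, map_b)
  a <- al$a$intensity; b <- al$b$intensity
  shell <- s_bin(al$a$s, n_bins)
  edges <- attr(shell, "edges")
  counts <- tabulate(shell, n_bins)
  cc <- vapply(seq_len(n_bins), function(i) {
    j <- shell == i
    if (sum(j) < 3) return(NA_real_)
    if (stats::sd(a[j]) == 0 || stats::sd(b[j]) == 0) return(NA_real_)
    stats::cor(a[j], b[j])
  }, numeric(1))
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    s_min = edges[-(n_bins + 1)], s_max = edges[-1],
    s_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    n = as.integer(counts),
    cc = cc
  )
  attr(out, "global_cc") <- pearson_cc(map_a, map_b)
  class(out) <- c("binned_cc", class(tibble::tibble()))
  out
}

#' @rdname cc_by_resolution
#' @param x A `binned_cc`.
#' @param ... Unused.
#' @return `glance()`: one-row tibble with the global CC, the number of
#'   bins and how many were defined.
#' @export
glance.binned_cc <- function(x, ...) {
  tibble::tibble(global_cc = attr(x, "global_cc", exact = TRUE),
                 n_bins = nrow(x), n_defined = sum(!is.na(x$cc)))
}

#' Signed difference of two diffuse maps
#'
#' Elementwise `map_a - map_b` on the shared index set, preserving sign —
#' positive where the first map is stronger, negative where the second is.
#'
#' @param map_a,map_b `diffuse_map` objects on identical index sets.
#' @return A `diffuse_map`-classed tibble (values may be negative).
#' @export
difference_map <- function(map_a, map_b) {
  al <- align_maps(map_a, map_b)
  out <- al$a
  out$intensity <- al$a$intensity - al$b$intensity
  attr(out, "anisotropic") <- TRUE
  out
}
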