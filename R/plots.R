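#' Plot a radial diffuse intensity profile
#'
#' Mean diffuse intensity per resolution shell against scattering-vector
#' length, the standard one-dimensional summary for comparing maps.
#'
#' @param object A [radial_profile()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radial_profile <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_mid, y = .data$mean_intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression("|s| (" * ring(A)^-1 * ")"),
                  y = expression("mean diffuse intensity (" * e^2 * ")")) +
    ggplot2::theme_minimal()
}

#' Plot Pearson correlation across resolution bins
#'
#' @param object A [cc_by_resolution()] tibble; undefined bins are left as
#'   gaps. The global CC is drawn as a dashed reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_cc <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_mid, y = .data$cc)) +
    ggplot2::geom_hline(yintercept = attr(object, "global_cc", exact = TRUE),
                        linetype = "dashed", color = "grey50") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = expression("|s| (" * ring(A)^-1 * ")"),
                  y = "Pearson CC") +
    ggplot2::theme_minimal()
}

#' Plot a central section of a diffuse map
#'
#' Tiles the intensities of one reciprocal-lattice plane (constant index
#' along `axis`), the quick-look analog of a map cross-section. Signed
#' (anisotropic or difference) maps get a diverging palette.
#'
#' @param map A `diffuse_map` on integer indices.
#' @param axis Which index is held fixed: "l" (default), "h" or "k".
#' @param level Fixed value of that index (default 0).
#' @return A ggplot object.
#' @export
plot_map_section <- function(map, axis = c("l", "h", "k"), level = 0) {
  axis <- match.arg(axis)
  df <- tibble::as_tibble(map)
  df <- df[abs(df[[axis]] - level) < 1e-9, , drop = FALSE]
  if (nrow(df) == 0) rlang::abort("no indices in the requested section")
  other <- setdiff(c("h", "k", "l"), axis)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[other[1]]], y = .data[[other[2]]],
                                        fill = .data$intensity)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("section ", axis, " = ", level)) +
    ggplot2::theme_minimal()
  if (isTRUE(attr(map, "anisotropic", exact = TRUE))) {
    p + ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white", high = "darkgreen")
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
}
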