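#' Plot a contact map
#'
#' Raster plot of contact probabilities (or signed probability differences
#' for a difference map), with the masked near-diagonal band left blank.
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_map <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(df, dplyr::rename(df, i = "j", j = "i"))
  p <- ggplot2::ggplot(df2, ggplot2::aes(x = .data$i, y = .data$j,
                                         fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue i", y = "residue j",
                  fill = if (isTRUE(object$difference)) "dP" else "P") +
    ggplot2::theme_minimal()
  if (isTRUE(object$difference)) {
    p + ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red")
  } else {
    p + ggplot2::scale_fill_gradient(low = "white", high = "black",
                                     limits = c(0, 1))
  }
}

#' Plot computed vs experimental Rg
#'
#' Scatter of the scored sequences against the identity line.
#'
#' @param object An `rg_score`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rg_score <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$experimental, y = .data$computed,
                               label = .data$name)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "experimental Rg (A)", y = "computed Rg (A)") +
    ggplot2::theme_minimal()
}

#' Plot a (normalized) Rg distribution
#'
#' @param x A `cg_trajectory`/`cg_ensemble` or a numeric vector of Rg
#'   values.
#' @param n_residues Chain length; when given, the distribution is plotted
#'   over `Rg / flory_rg(n_residues)`.
#' @param equilibration_steps Equilibration prefix to drop (trajectory
#'   input only).
#' @return A ggplot.
#' @export
plot_rg_distribution <- function(x, n_residues = NULL, equilibration_steps = 0) {
  rg <- if (is.numeric(x)) x else rg_series(x, equilibration_steps)$rg
  if (is.null(n_residues)) {
    df <- tibble::tibble(value = rg)
    xl <- "Rg (A)"
  } else {
    df <- tibble::tibble(value = rg / flory_rg(n_residues))
    xl <- "Rg / Rg_Flory"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey60", colour = "grey30") +
    ggplot2::labs(x = xl, y = "density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
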