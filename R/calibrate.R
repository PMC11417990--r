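#' Calibrate a contact strength by linear rescaling
#'
#' His0 contact strengths are set by linearly rescaling reference binding
#' energies onto the contact strengths of established pairs of the same
#' interaction class: the His0-His0 (pi-pi) strength is fitted against the
#' aromatic pi-pi series (Phe-Phe, Phe-Tyr, Phe-Trp, Tyr-Tyr, Tyr-Trp,
#' Trp-Trp) and the His0-Arg (cation-pi) strength against the Arg-Phe,
#' Arg-Tyr, Arg-Trp series. An ordinary least-squares line is fitted from
#' the reference energies to the existing model strengths and evaluated at
#' the query pair's reference energy.
#'
#' @param series Data frame with columns `pair` (label), `qm_energy`
#'   (reference mean binding energy) and `target_epsilon` (existing model
#'   contact strength, reduced energy units). At least 3 rows.
#' @param qm_value Reference energy of the pair being calibrated.
#' @return A `pair_calibration` object with elements `epsilon` (the
#'   calibrated strength), `slope`, `intercept`, `r_squared`, `series`, and
#'   `qm_value`. Has [tidy()] and [glance()] methods.
#' @examples
#' s <- data.frame(pair = c("a", "b", "c"), qm_energy = 1:3,
#'                 target_epsilon = c(3, 5, 7))
#' calibrate_pair_strength(s, 2.5)$epsilon  # exactly on the line: 6
#' @export
calibrate_pair_strength <- function(series, qm_value) {
  stopifnot(all(c("pair", "qm_energy", "target_epsilon") %in% names(series)))
  if (nrow(series) < 3) {
    rlang::abort("calibration needs at least 3 reference pairs")
  }
  if (length(series$qm_energy) != length(series$target_epsilon)) {
    rlang::abort("qm_energies and target_epsilons must have the same length")
  }
  if (stats::var(series$qm_energy) == 0) {
    rlang::abort("degenerate calibration series: all reference energies equal")
  }
  fit <- stats::lm(target_epsilon ~ qm_energy, data = series)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((series$target_epsilon - mean(series$target_epsilon))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  eps <- unname(stats::predict(fit, newdata = data.frame(qm_energy = qm_value)))
  structure(list(
    epsilon = eps,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    series = tibble::as_tibble(series),
    qm_value = qm_value,
    fit = fit
  ), class = "pair_calibration")
}

#' @export
print.pair_calibration <- function(x, ...) {
  cat("<pair_calibration> epsilon =", signif(x$epsilon, 5),
      "(slope", signif(x$slope, 4), ", intercept", signif(x$intercept, 4),
      ", R^2", signif(x$r_squared, 4), ")\n")
  invisible(x)
}

#' @rdname calibrate_pair_strength
#' @param x A `pair_calibration` object.
#' @param ... Unused.
#' @export
tidy.pair_calibration <- function(x, ...) {
  dplyr::mutate(x$series,
                fitted_epsilon = x$intercept + x$slope * .data$qm_energy,
                residual = .data$target_epsilon - .data$fitted_epsilon)
}

#' @rdname calibrate_pair_strength
#' @export
glance.pair_calibration <- function(x, ...) {
  tibble::tibble(epsilon = x$epsilon, slope = x$slope,
                 intercept = x$intercept, r_squared = x$r_squared,
                 n = nrow(x$series))
}
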