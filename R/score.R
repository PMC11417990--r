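#' Mean squared error of computed vs experimental Rg
#'
#' `MSE = mean((computed - experimental)^2)` over the paired sequences,
#' in squared Angstrom.
#'
#' @param computed,experimental Equal-length numeric vectors (Angstrom).
#' @return MSE in Angstrom^2.
#' @examples
#' rg_mse(c(14, 12), c(13, 13))  # 1
#' @export
rg_mse <- function(computed, experimental) {
  if (length(computed) != length(experimental)) {
    rlang::abort("computed and experimental vectors differ in length")
  }
  mean((computed - experimental)^2)
}

#' Chi-squared error of computed vs experimental Rg
#'
#' `chi2 = sum(((computed - experimental) / errors)^2)`, weighting each
#' squared deviation by the squared experimental uncertainty. With unit
#' errors (the default when none are reported) this reduces to
#' `n * MSE`.
#'
#' @inheritParams rg_mse
#' @param errors Positive experimental uncertainties (Angstrom); recycled.
#' @return Dimensionless chi-squared.
#' @export
rg_chi2 <- function(computed, experimental, errors = 1) {
  if (length(computed) != length(experimental)) {
    rlang::abort("computed and experimental vectors differ in length")
  }
  errors <- rep_len(errors, length(computed))
  if (any(errors <= 0)) rlang::abort("experimental uncertainties must be positive")
  sum(((computed - experimental) / errors)^2)
}

#' Score computed Rg values against an experimental table
#'
#' @param data Data frame with columns `name`, `computed`, `experimental`
#'   (Angstrom) and optionally `error` (experimental uncertainty).
#' @return An `rg_score` with [tidy()] (per-sequence table with residuals)
#'   and [glance()] (`mse`, `chi2`, Pearson `r`, `n`) methods.
#' @export
score_rg <- function(data) {
  stopifnot(all(c("name", "computed", "experimental") %in% names(data)))
  err <- if ("error" %in% names(data)) data$error else rep(1, nrow(data))
  structure(list(
    table = tibble::tibble(name = data$name, computed = data$computed,
                           experimental = data$experimental, error = err),
    mse = rg_mse(data$computed, data$experimental),
    chi2 = rg_chi2(data$computed, data$experimental, err),
    r = if (nrow(data) > 2) stats::cor(data$computed, data$experimental) else NA_real_
  ), class = "rg_score")
}

#' @export
print.rg_score <- function(x, ...) {
  cat("<rg_score> n =", nrow(x$table), " MSE =", signif(x$mse, 4),
      "A^2, chi2 =", signif(x$chi2, 4), "\n")
  invisible(x)
}

#' @rdname score_rg
#' @param x An `rg_score`.
#' @param ... Unused.
#' @export
tidy.rg_score <- function(x, ...) {
  dplyr::mutate(x$table, residual = .data$computed - .data$experimental)
}

#' @rdname score_rg
#' @export
glance.rg_score <- function(x, ...) {
  tibble::tibble(mse = x$mse, chi2 = x$chi2, r = x$r, n = nrow(x$table))
}
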