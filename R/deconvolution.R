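#' Deconvolute a component's isotopologue distribution from its spectrum
#'
#' A measured component spectrum is (up to noise) a non-negative linear
#' combination of the theoretical unit-mass patterns of its D0..Dmax
#' isotopologues. `deconvolve()` recovers the isotopologue mole fractions
#' by non-negative least squares against that basis,
#' \deqn{\min_{f \ge 0} \|B f - y\|_2,}
#' followed by projection onto the unit simplex (renormalization to sum 1)
#' — the standard natural-abundance-correction approach in isotope-tracing
#' metabolomics, and parameter-free. MS1 intensities carry no positional
#' information, so isotopomers (same label count, different positions)
#' are indistinguishable here by construction.
#'
#' @param spectrum An `ms_fingerprint` (unit-mass peak list) of the
#'   component.
#' @param basis Basis matrix from [isotopologue_basis()] (bins x
#'   isotopologues, rownames = integer bins), or a `chem_formula`, in
#'   which case the basis is built with `d_max`.
#' @param d_max Highest deuteration level when `basis` is a formula.
#' @inheritParams isotopologue_basis
#' @return An object of class `isotopologue_fit` with components
#'   `fractions` (simplex-normalized), `coef_raw` (NNLS solution),
#'   `residual` (relative L2 misfit \eqn{\|Bf - y\|/\|y\|}),
#'   `fitted` (reconstructed spectrum), `condition` (basis condition
#'   number diagnostic). Methods: `print`, `summary`, `coef`, `fitted`,
#'   `residuals`.
#' @export
#' @examples
#' base <- monomer_formula()
#' B <- isotopologue_basis(base, 5)
#' y <- component_spectrum(c(0, 0, 0.2, 0.8), basis = B)
#' fit <- deconvolve(y, B)
#' coef(fit)
deconvolve <- function(spectrum, basis, d_max = NULL,
                       table = default_isotope_table(),
                       prune = getOption("isocoder.prune", 1e-10)) {
  stopifnot(inherits(spectrum, "ms_fingerprint"))
  if (inherits(basis, "chem_formula")) {
    if (is.null(d_max)) stop("d_max required when basis is given as a formula")
    basis <- isotopologue_basis(basis, d_max, table, prune)
  }
  bins <- as.integer(rownames(basis))
  grid <- sort(unique(c(bins, spectrum$mz)))
  B <- matrix(0, length(grid), ncol(basis), dimnames = list(as.character(grid),
                                                            colnames(basis)))
  B[match(bins, grid), ] <- basis
  y <- numeric(length(grid))
  y[match(spectrum$mz, grid)] <- spectrum$intensity
  ynorm <- sqrt(sum(y^2))
  if (ynorm == 0) stop("zero spectrum")
  fit <- pracma::lsqnonneg(B, y / ynorm)
  f <- fit$x
  if (all(f <= 0))
    stop("deconvolution failed: spectrum is orthogonal to the isotopologue basis")
  residual <- sqrt(max(fit$resid.norm, 0))   # ||Bf - y||/||y|| on unit-scaled y
  fractions <- f / sum(f)
  names(fractions) <- colnames(basis)
  fitted_y <- as.vector(B %*% f) * ynorm
  structure(list(
    fractions = fractions,
    coef_raw = f * ynorm,
    residual = residual,
    fitted = ms_fingerprint(grid[fitted_y > 0], fitted_y[fitted_y > 0]),
    observed = spectrum,
    condition = kappa(crossprod(B), exact = FALSE),
    grid = grid
  ), class = "isotopologue_fit")
}

#' @export
print.isotopologue_fit <- function(x, ...) {
  top <- order(x$fractions, decreasing = TRUE)
  top <- top[x$fractions[top] > 0.005][1:min(4, sum(x$fractions > 0.005))]
  cat(sprintf("<isotopologue_fit> relative misfit %.3g; major isotopologues: %s\n",
              x$residual,
              paste(sprintf("%s %.1f%%", names(x$fractions)[top],
                            100 * x$fractions[top]), collapse = ", ")))
  invisible(x)
}

#' @export
summary.isotopologue_fit <- function(object, ...) {
  cat("Isotopologue deconvolution (non-negative least squares)\n")
  cat(sprintf("  isotopologues: %d (D0..D%d)\n", length(object$fractions),
              length(object$fractions) - 1))
  cat(sprintf("  relative L2 misfit: %.4g\n", object$residual))
  cat(sprintf("  basis condition number: %.3g\n", object$condition))
  nz <- object$fractions[object$fractions > 1e-6]
  cat("  fractions > 1e-6:\n")
  print(round(nz, 4))
  invisible(object)
}

#' @export
coef.isotopologue_fit <- function(object, ...) object$fractions

#' @export
fitted.isotopologue_fit <- function(object, ...) object$fitted

#' @export
residuals.isotopologue_fit <- function(object, ...) {
  obs <- numeric(length(object$grid))
  obs[match(object$observed$mz, object$grid)] <- object$observed$intensity
  fit <- numeric(length(object$grid))
  fit[match(object$fitted$mz, object$grid)] <- object$fitted$intensity
  stats::setNames(obs - fit, object$grid)
}
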