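#' Mixtures on a proportion grid
#'
#' A mixture is an unordered assignment of components to proportions on a
#' fixed grid: each part is a positive integer number of grid units of
#' `increment` percent, and the units sum to `100 / increment` (so no
#' component sits at 0% and proportions total 100%). Proportions are held
#' as integers internally so that enumeration and hashing are exact.
#'
#' @param parts Named integer vector: component id -> grid units (>= 1).
#' @param increment Grid step in percent (must divide 100).
#' @return A `mixture` object.
#' @export
#' @examples
#' mixture(c(D0 = 3, D24 = 1), increment = 25)  # 75% D0 + 25% D24
mixture <- function(parts, increment) {
  if (!length(parts) || is.null(names(parts)) || any(!nzchar(names(parts))))
    stop("parts must be a named vector of grid units")
  if (anyDuplicated(names(parts))) stop("duplicate component id in mixture")
  if (100 %% increment != 0) stop("100 must be divisible by increment")
  units <- vapply(parts, as.integer, integer(1))
  if (any(units < 1)) stop("every component must occupy at least one grid unit")
  m <- 100L %/% as.integer(increment)
  if (sum(units) != m)
    stop("grid units must sum to ", m, " (", 100, "% at ", increment, "% per unit)")
  structure(list(parts = units, increment = as.integer(increment)),
            class = "mixture")
}

#' @export
print.mixture <- function(x, ...) {
  cat("<mixture>", format(x), "\n")
  invisible(x)
}

#' @export
format.mixture <- function(x, ...) {
  paste(sprintf("%s:%d%%", names(x$parts), x$parts * x$increment),
        collapse = ",")
}

#' Mixture fractions as proportions
#'
#' @param m A `mixture`.
#' @return Named numeric vector summing to 1.
#' @export
mixture_fractions <- function(m) {
  stopifnot(inherits(m, "mixture"))
  m$parts * m$increment / 100
}

#' Fingerprint of a component mixture
#'
#' The MS fingerprint is the linear combination of the component spectra
#' weighted by the mixing fractions, on the union of the component grids.
#' `fractions` may be given directly (possibly off-grid, e.g. from
#' [perturb_mixture()]) instead of a `mixture`.
#'
#' @param m A `mixture`, or a named numeric vector of fractions summing
#'   to 1.
#' @param components A `component_library` resolving every id in `m`.
#' @inheritParams isotopologue_basis
#' @return An `ms_fingerprint`.
#' @export
mixture_fingerprint <- function(m, components,
                                table = default_isotope_table(),
                                prune = getOption("isocoder.prune", 1e-10)) {
  stopifnot(inherits(components, "component_library"))
  fr <- if (inherits(m, "mixture")) mixture_fractions(m) else m
  if (!length(fr) || is.null(names(fr))) stop("mixture must name its components")
  if (abs(sum(fr) - 1) > 1e-9) stop("mixture fractions must sum to 1")
  missing <- setdiff(names(fr), names(components))
  if (length(missing))
    stop("unknown component id(s): ", paste(missing, collapse = ", "))
  cm <- component_matrix(components[names(fr)], table, prune)
  y <- as.vector(fr %*% cm$S)
  keep <- y > 0
  ms_fingerprint(cm$bins[keep], y[keep])
}
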