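#' Components: physical substances with isotopologue distributions
#'
#' A *component* is a synthesized substance targeting one deuteration level
#' but, because positional deuterium incorporation is below 100%, actually
#' containing a mole-fraction distribution over neighbouring isotopologues
#' D0..Dmax. An *ideal* component has fraction 1 at exactly one Dn.
#'
#' @param id Short label, e.g. `"1a"`.
#' @param fractions Numeric vector of isotopologue mole fractions over
#'   D0, D1, ... (length defines Dmax + 1); non-negative, summing to 1.
#' @param base_formula `chem_formula` of the unlabeled molecule.
#' @return A `component` object.
#' @export
component <- function(id, fractions, base_formula) {
  stopifnot(inherits(base_formula, "chem_formula"))
  if (!is.character(id) || length(id) != 1 || !nzchar(id)) stop("invalid component id")
  if (any(fractions < 0)) stop("negative isotopologue fraction")
  s <- sum(fractions)
  if (abs(s - 1) > 1e-9) stop("isotopologue fractions must sum to 1 (got ", s, ")")
  if (length(fractions) - 1 > labelable_hydrogens(base_formula))
    stop("fraction vector implies more labels than hydrogens in the formula")
  structure(list(id = id, fractions = as.numeric(fractions),
                 base_formula = base_formula),
            class = "component")
}

#' @export
print.component <- function(x, ...) {
  top <- order(x$fractions, decreasing = TRUE)[1:min(3, length(x$fractions))]
  cat(sprintf("<component> %s (%s): major isotopologues %s\n",
              x$id, format(x$base_formula),
              paste(sprintf("D%d %.1f%%", top - 1, 100 * x$fractions[top]),
                    collapse = ", ")))
  invisible(x)
}

#' Unit-mass patterns of the D0..Dmax isotopologues of a formula
#'
#' Column `n + 1` is the unit-mass isotope pattern of the Dn isotopologue
#' on a shared integer grid; columns each sum to 1. This matrix is both the
#' linear map from isotopologue fractions to component spectra and the
#' basis inverted by [deconvolve()].
#'
#' @param base_formula `chem_formula` of the unlabeled molecule.
#' @param d_max Highest deuteration level.
#' @param table Isotope table.
#' @param prune Pruning threshold for the pattern engine.
#' @return A numeric matrix (bins x isotopologues); rownames are integer
#'   unit-mass bins, colnames `D0..Dmax`.
#' @export
isotopologue_basis <- function(base_formula, d_max,
                               table = default_isotope_table(),
                               prune = getOption("isocoder.prune", 1e-10)) {
  stopifnot(inherits(base_formula, "chem_formula"))
  if (d_max > labelable_hydrogens(base_formula))
    stop("d_max exceeds the hydrogen count of the formula")
  # memoize: the basis is a pure function of (formula, d_max, table, prune)
  # and is requested for every fingerprint built on the same scaffold
  key <- paste(format.chem_formula(base_formula), base_formula$n_label, d_max,
               format(prune, digits = 17),
               format(sum(vapply(table, function(m)
                 sum(m[, "mass"] * (1 + m[, "abundance"])), numeric(1))),
                 digits = 17),
               sep = "|")
  hit <- .basis_cache[[key]]
  if (!is.null(hit)) return(hit)
  pats <- lapply(0:d_max, function(n) {
    f <- chem_formula(base_formula$counts, n_label = n)
    to_unit_mass(pattern_for_formula(f, table, prune))
  })
  bins <- sort(unique(unlist(lapply(pats, `[[`, "bin"))))
  B <- matrix(0, length(bins), d_max + 1,
              dimnames = list(as.character(bins), paste0("D", 0:d_max)))
  for (n in seq_along(pats))
    B[match(pats[[n]]$bin, bins), n] <- pats[[n]]$abundance
  .basis_cache[[key]] <- B
  B
}

.basis_cache <- new.env(parent = emptyenv())

#' Spectrum of a component from its isotopologue fractions
#'
#' The component fingerprint is the fraction-weighted sum of the unit-mass
#' patterns of its isotopologues:
#' \eqn{y = \sum_n f_n \, p_{D_n}}.
#'
#' @param fractions Isotopologue fraction vector over D0.. (sums to 1), or
#'   a `component`.
#' @param base_formula `chem_formula`; ignored when `fractions` is a
#'   `component`.
#' @param basis Optional precomputed [isotopologue_basis()] (saves the
#'   pattern computation when building many components of one formula).
#' @inheritParams isotopologue_basis
#' @return An `ms_fingerprint`.
#' @export
component_spectrum <- function(fractions, base_formula = NULL, basis = NULL,
                               table = default_isotope_table(),
                               prune = getOption("isocoder.prune", 1e-10)) {
  if (inherits(fractions, "component")) {
    base_formula <- fractions$base_formula
    fractions <- fractions$fractions
  }
  if (any(fractions < 0)) stop("negative isotopologue fraction")
  if (is.null(basis)) {
    if (is.null(base_formula)) stop("base_formula (or basis) required")
    basis <- isotopologue_basis(base_formula, length(fractions) - 1, table, prune)
  }
  if (ncol(basis) < length(fractions))
    stop("fraction vector longer than basis")
  y <- as.vector(basis[, seq_along(fractions), drop = FALSE] %*% fractions)
  keep <- y > 0
  ms_fingerprint(as.integer(rownames(basis))[keep], y[keep])
}

#' Component libraries
#'
#' A component library is a named list of [component()]s sharing a base
#' formula — the alphabet from which mixtures are composed.
#'
#' `ideal_components()` builds the theoretical D0..Dmax set (each component
#' a single pure isotopologue); `component_library()` wraps an explicit
#' list.
#'
#' @param components List of `component` objects with distinct ids.
#' @return A `component_library` (named list of components).
#' @export
component_library <- function(components) {
  if (!length(components)) stop("empty component library")
  if (!all(vapply(components, inherits, logical(1), "component")))
    stop("all entries must be components")
  ids <- vapply(components, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate component ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(stats::setNames(components, ids), class = "component_library")
}

#' @param base_formula `chem_formula` of the unlabeled molecule.
#' @param d_max Highest deuteration level (library size `d_max + 1`).
#' @param ids Component labels; default `"D0".."Dmax"`.
#' @rdname component_library
#' @export
ideal_components <- function(base_formula, d_max = 24,
                             ids = paste0("D", 0:d_max)) {
  stopifnot(length(ids) == d_max + 1)
  component_library(lapply(0:d_max, function(n) {
    fr <- numeric(d_max + 1); fr[n + 1] <- 1
    component(ids[n + 1], fr, base_formula)
  }))
}

#' @export
`[.component_library` <- function(x, i) {
  component_library(unclass(x)[i])
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("<component_library> %d components (%s), formula %s\n",
              length(x), paste(utils::head(names(x), 6), collapse = ", "),
              format(x[[1]]$base_formula)))
  invisible(x)
}

#' Stack of component spectra on a shared grid
#'
#' @param components A `component_library`.
#' @inheritParams isotopologue_basis
#' @return List with `S` (components x bins intensity matrix, rows
#'   normalized to total 1) and `bins` (integer grid).
#' @export
component_matrix <- function(components, table = default_isotope_table(),
                             prune = getOption("isocoder.prune", 1e-10)) {
  stopifnot(inherits(components, "component_library"))
  d_max <- max(vapply(components, function(cp) length(cp$fractions), integer(1))) - 1
  basis <- isotopologue_basis(components[[1]]$base_formula, d_max, table, prune)
  S <- t(vapply(components, function(cp) {
    fr <- c(cp$fractions, numeric(d_max + 1 - length(cp$fractions)))
    as.vector(basis %*% fr)
  }, numeric(nrow(basis))))
  rownames(S) <- names(components)
  list(S = S, bins = as.integer(rownames(basis)))
}

#' Reference monomer of the package's worked examples
#'
#' The 8-acetamido-4,6-bis(3'-methoxypropyl)quinoline-2-carboxylic acid
#' scaffold, C20H26N2O5: 26 hydrogens of which 24 are non-labile and
#' replaceable by deuterium (the amide N-H and carboxylic O-H exchange in
#' protic media and cannot hold a label).
#'
#' @return A `chem_formula`.
#' @export
monomer_formula <- function() parse_formula("C20H26N2O5")

#' @rdname monomer_formula
#' @export
decamer_formula <- function() parse_formula("C182H224N20O32")
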