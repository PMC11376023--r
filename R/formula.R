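#' Chemical formulas with deuterium labels
#'
#' A `chem_formula` stores the elemental composition of the *unlabeled*
#' molecule together with `n_label`, the number of hydrogens replaced by
#' deuterium. The effective composition used by the pattern engine is
#' H: `counts["H"] - n_label`, D: `n_label`. Exchangeable (labile)
#' hydrogens are ordinary H: they never count towards `n_label`.
#'
#' `parse_formula()` accepts Hill-style element tokens with optional integer
#' counts (`"C20H26N2O5"`). A `D` token is read as a deuterium label: it
#' increments both the total hydrogen count and `n_label`, so
#' `"C20H2D24N2O5"` is the D24 isotopologue of `"C20H26N2O5"`.
#'
#' @param text Formula string.
#' @param n_label Number of hydrogens replaced by deuterium (added on top of
#'   any `D` tokens in `text`).
#' @param table Isotope table used to validate element symbols.
#' @return A `chem_formula` object: list with `counts` (named integer
#'   vector) and `n_label`.
#' @export
#' @examples
#' parse_formula("C20H26N2O5")
#' parse_formula("C20H26N2O5", n_label = 5)  # the D5 isotopologue
parse_formula <- function(text, n_label = 0L, table = default_isotope_table()) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text))
    stop("formula must be a non-empty string")
  tokens <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  matched <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE))[[1]]
  if (sum(nchar(matched)) != nchar(text))
    stop("malformed formula '", text, "': unparseable characters near '",
         substr(text, 1, 12), "'")
  counts <- integer(0)
  n_d <- 0L
  for (tok in matched) {
    el <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (el == "D") {
      n_d <- n_d + n
      el <- "H"
    } else if (!el %in% names(table)) {
      stop("unknown element symbol '", el, "' in formula '", text, "'")
    }
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  chem_formula(counts, n_label = n_d + as.integer(n_label), table = table)
}

#' @param counts Named non-negative integer vector of atom counts for the
#'   unlabeled molecule.
#' @rdname parse_formula
#' @export
chem_formula <- function(counts, n_label = 0L, table = default_isotope_table()) {
  counts <- counts[counts != 0]
  if (length(counts) && (is.null(names(counts)) || any(!nzchar(names(counts)))))
    stop("counts must be a named vector")
  bad <- setdiff(names(counts), names(table))
  bad <- setdiff(bad, "D")
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if ("D" %in% names(counts)) {
    n_label <- n_label + counts[["D"]]
    counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + counts[["D"]]
    counts <- counts[names(counts) != "D"]
  }
  counts <- vapply(counts, as.integer, integer(1))
  if (any(counts < 0)) stop("negative atom count")
  n_label <- as.integer(n_label)
  if (n_label < 0) stop("n_label must be non-negative")
  h <- if ("H" %in% names(counts)) counts[["H"]] else 0L
  if (n_label > h)
    stop("n_label (", n_label, ") exceeds hydrogen count (", h, ")")
  structure(list(counts = counts, n_label = n_label), class = "chem_formula")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula>", format(x), "\n")
  invisible(x)
}

#' @export
format.chem_formula <- function(x, ...) {
  eff <- effective_counts(x)
  ord <- c(intersect(c("C", "H", "D"), names(eff)),
           sort(setdiff(names(eff), c("C", "H", "D"))))
  if (!length(ord)) return("(empty)")
  paste0(vapply(ord, function(el)
    paste0(el, if (eff[[el]] != 1) eff[[el]] else ""), character(1)),
    collapse = "")
}

#' Effective isotopic composition of a labeled formula
#'
#' Splits the hydrogen count into remaining `H` and label `D`.
#'
#' @param f A `chem_formula`.
#' @return Named integer vector including a `D` entry when `n_label > 0`.
#' @export
effective_counts <- function(f) {
  stopifnot(inherits(f, "chem_formula"))
  counts <- f$counts
  if (f$n_label > 0) {
    counts["H"] <- counts[["H"]] - f$n_label
    counts["D"] <- f$n_label
  }
  counts[counts != 0]
}

#' Formula arithmetic
#'
#' Addition merges atom counts and label counts; subtraction errors on any
#' negative resulting count.
#'
#' @param e1,e2 `chem_formula` objects.
#' @name formula-arith
#' @rdname formula-arith
#' @export
#' @examples
#' parse_formula("C20H26N2O5") + parse_formula("C11H11N") - parse_formula("H2O")
`+.chem_formula` <- function(e1, e2) {
  counts <- .merge_counts(e1$counts, e2$counts, `+`)
  chem_formula(counts, n_label = e1$n_label + e2$n_label)
}

#' @rdname formula-arith
#' @export
`-.chem_formula` <- function(e1, e2) {
  counts <- .merge_counts(e1$counts, e2$counts, `-`)
  if (any(counts < 0))
    stop("formula subtraction yields negative count for: ",
         paste(names(counts)[counts < 0], collapse = ", "))
  n_label <- e1$n_label - e2$n_label
  if (n_label < 0) stop("formula subtraction yields negative label count")
  chem_formula(counts, n_label = n_label)
}

.merge_counts <- function(a, b, op) {
  els <- union(names(a), names(b))
  out <- vapply(els, function(el) {
    av <- if (el %in% names(a)) a[[el]] else 0L
    bv <- if (el %in% names(b)) b[[el]] else 0L
    op(av, bv)
  }, integer(1))
  names(out) <- els
  out
}

#' Monoisotopic mass of a formula
#'
#' Sum of the lightest-isotope masses, with each deuterium label
#' contributing the mass of \eqn{^2}H.
#'
#' @param f A `chem_formula`.
#' @param table Isotope table.
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(f, table = default_isotope_table()) {
  eff <- effective_counts(f)
  sum(vapply(names(eff), function(el) {
    if (!el %in% names(table)) stop("element '", el, "' missing from isotope table")
    table[[el]][1, "mass"] * eff[[el]]
  }, numeric(1)))
}

#' Number of hydrogens available for deuterium labeling
#'
#' @param f A `chem_formula`.
#' @param n_labile Number of exchangeable hydrogens to exclude (they revert
#'   to H in protic media and cannot hold a stable label).
#' @return Integer count.
#' @export
labelable_hydrogens <- function(f, n_labile = 0L) {
  h <- if ("H" %in% names(f$counts)) f$counts[["H"]] else 0L
  max(h - as.integer(n_labile), 0L)
}
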