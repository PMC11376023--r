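#' Isotope patterns
#'
#' An `iso_pattern` is a list of `(mass, abundance)` peaks in canonical
#' normalized form: masses strictly increasing, abundances summing to 1.
#' Patterns come in two resolutions: `"fine"` (every resolved isotope
#' composition kept as its own peak, e.g. the \eqn{^2}H vs \eqn{^{13}}C
#' fine structure, 0.0029 Da apart) and `"unit"` (peaks aggregated into
#' nearest-integer mass bins, the representation mass fingerprints use).
#'
#' @param mass Numeric vector of peak masses (Da).
#' @param abundance Numeric vector of relative abundances.
#' @param resolution `"fine"` or `"unit"`.
#' @param normalize Rescale abundances to sum to 1.
#' @return An `iso_pattern`: data frame with columns `mass` and
#'   `abundance` and a `resolution` attribute.
#' @export
iso_pattern <- function(mass, abundance, resolution = c("fine", "unit"),
                        normalize = TRUE) {
  resolution <- match.arg(resolution)
  if (length(mass) != length(abundance)) stop("mass/abundance length mismatch")
  if (!length(mass)) stop("empty pattern")
  if (any(abundance < 0)) stop("negative abundance")
  o <- order(mass)
  mass <- mass[o]; abundance <- abundance[o]
  if (normalize) {
    s <- sum(abundance)
    if (s <= 0) stop("pattern has zero total abundance")
    abundance <- abundance / s
  }
  structure(data.frame(mass = mass, abundance = abundance),
            resolution = resolution, class = c("iso_pattern", "data.frame"))
}

#' @export
print.iso_pattern <- function(x, n = 10, ...) {
  cat(sprintf("<iso_pattern> %s resolution, %d peaks, mass %.4f..%.4f\n",
              attr(x, "resolution"), nrow(x), min(x$mass), max(x$mass)))
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more peaks\n", sep = "")
  invisible(x)
}

pattern_resolution <- function(p) attr(p, "resolution")

# Merge peaks closer than `tol` Da (abundance-weighted mean mass), then drop
# peaks below `prune` relative to the base peak. Plain numeric in/out for speed.
.merge_prune <- function(mass, abundance, prune, tol = 1e-6) {
  o <- order(mass)
  mass <- mass[o]; abundance <- abundance[o]
  grp <- cumsum(c(TRUE, diff(mass) > tol))
  if (grp[length(grp)] < length(mass)) {
    ab <- rowsum(abundance, grp)
    wm <- rowsum(mass * abundance, grp) / ab
    mass <- as.vector(wm); abundance <- as.vector(ab)
  }
  if (prune > 0) {
    keep <- abundance >= prune * max(abundance)
    mass <- mass[keep]; abundance <- abundance[keep]
  }
  list(mass = mass, abundance = abundance)
}

#' Convolve two isotope patterns
#'
#' The pattern of a combined composition is the convolution of the parts'
#' patterns: every pair of peaks contributes a peak at the summed mass with
#' the product abundance. Peaks closer than `tol` Da are merged and peaks
#' below `prune` (relative to the base peak) dropped.
#'
#' @param p,q Fine-resolution `iso_pattern`s.
#' @param prune Relative-abundance pruning threshold in `[0, 1)`.
#' @param tol Mass merge tolerance in Da.
#' @param normalize Renormalize the result to total abundance 1.
#' @return A fine-resolution `iso_pattern`.
#' @export
convolve_patterns <- function(p, q, prune = getOption("isocoder.prune", 1e-10),
                              tol = 1e-6, normalize = TRUE) {
  m <- outer(p$mass, q$mass, `+`)
  a <- outer(p$abundance, q$abundance)
  r <- .merge_prune(as.vector(m), as.vector(a), prune, tol)
  iso_pattern(r$mass, r$abundance, "fine", normalize = normalize)
}

#' Isotope pattern of `count` atoms of one element
#'
#' The `count`-fold self-convolution of the element's single-atom natural
#' distribution, computed by binary exponentiation with pruning.
#'
#' @param element Element symbol present in `table` (including the
#'   deuterium pseudo-element `"D"`).
#' @param count Non-negative atom count.
#' @param table Isotope table, see [default_isotope_table()].
#' @param prune Relative-abundance pruning threshold in `[0, 1)`.
#' @return A fine-resolution `iso_pattern`; for `count = 0` the neutral
#'   pattern (single peak at mass 0).
#' @export
element_pattern <- function(element, count, table = default_isotope_table(),
                            prune = getOption("isocoder.prune", 1e-10)) {
  if (!element %in% names(table))
    stop("element '", element, "' missing from isotope table")
  if (count < 0) stop("count must be non-negative")
  if (prune < 0 || prune >= 1) stop("prune must be in [0, 1)")
  ent <- table[[element]]
  base <- iso_pattern(ent[, "mass"], ent[, "abundance"], "fine")
  res <- iso_pattern(0, 1, "fine")
  n <- as.integer(count)
  while (n > 0) {
    if (n %% 2L == 1L) res <- convolve_patterns(res, base, prune)
    n <- n %/% 2L
    if (n > 0) base <- convolve_patterns(base, base, prune)
  }
  res
}

#' Fine-resolution isotope pattern of a chemical formula
#'
#' Convolves the element patterns of the effective composition; deuterium
#' labels form a pure-\eqn{^2}H block. The monoisotopic peak sits at the sum
#' of lightest-isotope masses.
#'
#' @param f A `chem_formula`.
#' @param table Isotope table.
#' @param prune Relative-abundance pruning threshold.
#' @return A fine-resolution `iso_pattern` with total abundance 1.
#' @export
#' @examples
#' p <- pattern_for_formula(parse_formula("C20H26N2O5"))
#' head(p)
pattern_for_formula <- function(f, table = default_isotope_table(),
                                prune = getOption("isocoder.prune", 1e-10)) {
  stopifnot(inherits(f, "chem_formula"))
  eff <- effective_counts(f)
  res <- iso_pattern(0, 1, "fine")
  for (el in names(eff))
    res <- convolve_patterns(res, element_pattern(el, eff[[el]], table, prune),
                             prune)
  iso_pattern(res$mass, res$abundance, "fine")
}

#' Aggregate a fine pattern into unit-mass bins
#'
#' Peaks whose accurate masses round to the same nearest integer are summed;
#' the reported mass of each bin is the abundance-weighted mean mass. Total
#' abundance is conserved. This is the merge that makes \eqn{^2}H and
#' \eqn{^{13}}C substitutions, which unit-resolution fingerprints cannot
#' separate, fall into a common bin.
#'
#' @param p A fine-resolution `iso_pattern`.
#' @return A unit-resolution `iso_pattern` with an integer `bin` column.
#' @export
to_unit_mass <- function(p) {
  stopifnot(inherits(p, "iso_pattern"))
  bin <- round(p$mass)
  ab <- rowsum(p$abundance, bin)
  wm <- rowsum(p$mass * p$abundance, bin) / ab
  out <- iso_pattern(as.vector(wm), as.vector(ab), "unit", normalize = FALSE)
  out$bin <- as.integer(rownames(ab))
  out
}

#' Write / read a pattern as two-column CSV
#'
#' @param p An `iso_pattern`.
#' @param path Output path; the file has a `mass,abundance` header.
#' @return `path` (write) or an `iso_pattern` (read).
#' @export
write_pattern <- function(p, path) {
  utils::write.csv(data.frame(mass = p$mass, abundance = p$abundance),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param resolution Resolution tag to attach on read.
#' @rdname write_pattern
#' @export
read_pattern <- function(path, resolution = c("fine", "unit")) {
  d <- utils::read.csv(path)
  if (!all(c("mass", "abundance") %in% names(d)))
    stop("pattern CSV needs 'mass' and 'abundance' columns")
  iso_pattern(d$mass, d$abundance, match.arg(resolution), normalize = FALSE)
}
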