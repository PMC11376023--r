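#' Natural isotope masses and abundances
#'
#' The package ships a pinned table of isotope masses (Da) and natural
#' abundances (mole fractions) for the elements commonly found in small
#' organic molecules, following the IUPAC/CIAAW 2021 representative values.
#' Deuterium is carried as the pseudo-element `"D"` with abundance 1 at the
#' mass of \eqn{^2}H, so that a deuterium label contributes no natural
#' spread of its own.
#'
#' All pattern and fingerprint computations take the table as an argument so
#' that an alternative table (e.g. enriched media) can be supplied; the
#' similarity values quoted in the documentation assume the default table.
#'
#' @return A named list; each entry is a two-column matrix with columns
#'   `mass` and `abundance`, rows sorted by increasing mass, abundances
#'   summing to 1.
#' @seealso [read_isotope_table()] to load a table from JSON.
#' @export
#' @examples
#' tab <- default_isotope_table()
#' tab$C
default_isotope_table <- function() {
  .isocoder_default_table
}

.make_entry <- function(mass, abundance) {
  stopifnot(length(mass) == length(abundance))
  o <- order(mass)
  m <- cbind(mass = mass[o], abundance = abundance[o])
  if (abs(sum(abundance) - 1) > 1e-9)
    stop("isotope abundances must sum to 1")
  m
}

.isocoder_default_table <- list(
  H  = .make_entry(c(1.00782503207, 2.01410177785), c(0.999885, 0.000115)),
  D  = .make_entry(2.01410177785, 1),
  C  = .make_entry(c(12.0, 13.00335483521), c(0.9893, 0.0107)),
  N  = .make_entry(c(14.00307400425, 15.00010889827), c(0.99636, 0.00364)),
  O  = .make_entry(c(15.99491461926, 16.99913175595, 17.99915961214),
                   c(0.99757, 0.00038, 0.00205)),
  F  = .make_entry(18.99840316207, 1),
  Na = .make_entry(22.98976928195, 1),
  Si = .make_entry(c(27.97692653442, 28.97649466434, 29.973770137),
                   c(0.92223, 0.04685, 0.03092)),
  P  = .make_entry(30.97376199768, 1),
  S  = .make_entry(c(31.97207117354, 32.97145890862, 33.967867011, 35.96708070),
                   c(0.9499, 0.0075, 0.0425, 0.0001)),
  Cl = .make_entry(c(34.968852694, 36.965902584), c(0.7576, 0.2424)),
  K  = .make_entry(c(38.9637064848, 39.963998165, 40.9618252561),
                   c(0.932581, 0.000117, 0.067302)),
  Br = .make_entry(c(78.9183376, 80.9162897), c(0.5069, 0.4931)),
  I  = .make_entry(126.9044719, 1)
)

#' Read an isotope table from a JSON file
#'
#' The file format is a JSON object mapping element symbols to arrays of
#' `[mass, abundance]` pairs, e.g.
#' `{"C": [[12.0, 0.9893], [13.003355, 0.0107]]}`.
#' Abundances of each element must sum to 1 (tolerance 1e-9).
#'
#' @param path Path to the JSON file.
#' @return A table in the format of [default_isotope_table()].
#' @export
read_isotope_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == ""))
    stop("isotope table JSON must be an object keyed by element symbol")
  out <- lapply(names(raw), function(el) {
    m <- raw[[el]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 2, byrow = TRUE)
    if (ncol(m) != 2)
      stop("element ", el, ": expected [mass, abundance] pairs")
    .make_entry(m[, 1], m[, 2])
  })
  names(out) <- names(raw)
  out
}

#' Write an isotope table to JSON
#'
#' @param table An isotope table as returned by [default_isotope_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotope_table <- function(table, path) {
  obj <- lapply(table, function(m) unname(lapply(seq_len(nrow(m)), function(i) m[i, ])))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
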