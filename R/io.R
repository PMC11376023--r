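#' Read a peak list into a fingerprint
#'
#' Accepts either a CSV with header `mz,intensity` or an MSP-style block
#' (`Num Peaks: n` followed by `mz intensity` pairs). Accurate masses are
#' binned to the nearest integer; duplicate bins are summed. Malformed
#' rows are reported with their line number.
#'
#' @param path Input file.
#' @return An `ms_fingerprint`.
#' @export
read_peaklist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_trim <- trimws(lines)
  nonblank <- which(nzchar(lines_trim))
  if (!length(nonblank)) stop("empty peak list file: ", path)
  first <- lines_trim[nonblank[1]]
  if (grepl("^Num Peaks", first, ignore.case = TRUE) ||
      any(grepl("^Num Peaks", lines_trim, ignore.case = TRUE))) {
    return(.read_msp(lines_trim, path))
  }
  if (!grepl("^mz[,;\t]intensity", first, ignore.case = TRUE))
    stop(path, ": line ", nonblank[1],
         ": expected header 'mz,intensity', got '", first, "'")
  mz <- numeric(0); int <- numeric(0)
  for (i in nonblank[-1]) {
    fields <- strsplit(lines_trim[i], "[,;\t]")[[1]]
    if (length(fields) != 2)
      stop(path, ": line ", i, ": expected two fields, got '", lines_trim[i], "'")
    v <- suppressWarnings(as.numeric(fields))
    if (any(is.na(v)))
      stop(path, ": line ", i, ": non-numeric value in '", lines_trim[i], "'")
    if (v[2] < 0)
      stop(path, ": line ", i, ": negative intensity ", v[2])
    mz <- c(mz, v[1]); int <- c(int, v[2])
  }
  if (!length(mz)) stop(path, ": no peaks after header")
  ms_fingerprint(round(mz), int)
}

.read_msp <- function(lines, path) {
  start <- grep("^Num Peaks", lines, ignore.case = TRUE)[1]
  mz <- numeric(0); int <- numeric(0)
  for (i in seq(start + 1, length(lines))) {
    if (!nzchar(lines[i])) break
    fields <- strsplit(lines[i], "[[:space:];,]+")[[1]]
    v <- suppressWarnings(as.numeric(fields))
    if (length(v) < 2 || any(is.na(v[1:2])))
      stop(path, ": line ", i, ": bad MSP peak row '", lines[i], "'")
    if (v[2] < 0) stop(path, ": line ", i, ": negative intensity ", v[2])
    mz <- c(mz, v[1]); int <- c(int, v[2])
  }
  if (!length(mz)) stop(path, ": MSP block contains no peaks")
  ms_fingerprint(round(mz), int)
}

#' Write a fingerprint as a peak-list CSV
#'
#' Two columns `mz,intensity` with header; intensities as stored.
#'
#' @param fp An `ms_fingerprint`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(fp, path) {
  stopifnot(inherits(fp, "ms_fingerprint"))
  utils::write.csv(data.frame(mz = fp$mz, intensity = fp$intensity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Component library files
#'
#' JSON format: an object with `formula` (base formula string) and
#' `components`, an array of `{id, fractions}` where `fractions` is the
#' isotopologue mole-fraction vector over D0... A long-format CSV
#' (columns `id, formula, d, fraction`) is accepted too.
#'
#' @param path File path.
#' @return A `component_library` (read) / `path` invisibly (write).
#' @export
read_component_library <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    d <- utils::read.csv(path)
    need <- c("id", "formula", "d", "fraction")
    if (!all(need %in% names(d)))
      stop("component CSV needs columns: ", paste(need, collapse = ", "))
    d_max <- max(d$d)
    comps <- lapply(split(d, d$id), function(g) {
      fr <- numeric(d_max + 1)
      fr[g$d + 1] <- g$fraction
      component(as.character(g$id[1]), fr, parse_formula(g$formula[1]))
    })
    # preserve file order of first appearance
    return(component_library(comps[unique(as.character(d$id))]))
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$formula) || is.null(obj$components))
    stop("component JSON needs 'formula' and 'components'")
  base <- parse_formula(obj$formula)
  cs <- obj$components
  if (is.data.frame(cs)) {
    comps <- lapply(seq_len(nrow(cs)), function(i)
      component(cs$id[i], unlist(cs$fractions[i]), base))
  } else {
    comps <- lapply(cs, function(e) component(e$id, unlist(e$fractions), base))
  }
  component_library(comps)
}

#' @param components A `component_library`.
#' @rdname read_component_library
#' @export
write_component_library <- function(components, path) {
  stopifnot(inherits(components, "component_library"))
  obj <- list(
    formula = format.chem_formula(
      chem_formula(components[[1]]$base_formula$counts)),
    components = lapply(unname(unclass(components)), function(cp)
      list(id = jsonlite::unbox(cp$id), fractions = cp$fractions))
  )
  obj$formula <- jsonlite::unbox(obj$formula)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Mixture recipe files
#'
#' JSON format: `{"increment": 10, "parts": {"c0": 9, "c5": 1}}` — grid
#' units per component id.
#'
#' @param path File path.
#' @return A [mixture()] (read) / `path` invisibly (write).
#' @export
read_mixture_recipe <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$increment) || is.null(obj$parts))
    stop("mixture recipe JSON needs 'increment' and 'parts'")
  mixture(unlist(obj$parts), obj$increment)
}

#' @param m A [mixture()].
#' @rdname read_mixture_recipe
#' @export
write_mixture_recipe <- function(m, path) {
  stopifnot(inherits(m, "mixture"))
  jsonlite::write_json(list(increment = jsonlite::unbox(m$increment),
                            parts = as.list(m$parts)),
                       path, digits = NA)
  invisible(path)
}

#' Report writers
#'
#' `write_audit_report()` saves a [audit_code()] result as JSON
#' (`count`, `max_ndp`, `argmax_pair`, `pairs_above_threshold`, ...);
#' `write_decode_report()` saves a [decode()] result as TSV with columns
#' `rank`, `mixture`, `ndp`.
#'
#' @param audit A `code_audit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit_report <- function(audit, path) {
  stopifnot(inherits(audit, "code_audit"))
  jsonlite::write_json(list(
    count = audit$count, searched = audit$searched,
    max_ndp = audit$max_ndp,
    argmax_pair = vapply(audit$pair, format, character(1)),
    pairs_above_threshold = audit$pairs_above_threshold,
    threshold = audit$threshold, mode = audit$mode,
    lower_bound = audit$lower_bound, variant = audit$variant
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param res A `decode_result`.
#' @rdname write_audit_report
#' @export
write_decode_report <- function(res, path) {
  stopifnot(inherits(res, "decode_result"))
  utils::write.table(as.data.frame(res), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
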