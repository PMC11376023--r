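#' MS fingerprints on a unit-mass grid
#'
#' A fingerprint is the object the normalized dot product compares: a
#' non-negative intensity vector over ordered integer unit-mass bins. It is
#' scale-free — any positive rescaling represents the same fingerprint —
#' but for storage the base peak is conventionally set to 100.
#'
#' @param mz Integer unit-mass bins (need not be contiguous).
#' @param intensity Non-negative intensities, same length as `mz`;
#'   duplicate bins are summed.
#' @return An `ms_fingerprint`: data frame with integer `mz` and numeric
#'   `intensity`, sorted by `mz`.
#' @export
ms_fingerprint <- function(mz, intensity) {
  if (length(mz) != length(intensity)) stop("mz/intensity length mismatch")
  if (!length(mz)) stop("empty fingerprint")
  if (any(intensity < 0)) stop("negative intensity")
  if (any(mz != round(mz))) stop("fingerprint bins must be integer unit masses")
  ab <- rowsum(as.numeric(intensity), as.integer(round(mz)))
  out <- data.frame(mz = as.integer(rownames(ab)), intensity = as.vector(ab))
  out <- out[out$intensity > 0, , drop = FALSE]
  if (!nrow(out)) stop("fingerprint has no positive intensity")
  rownames(out) <- NULL
  structure(out, class = c("ms_fingerprint", "data.frame"))
}

#' @export
print.ms_fingerprint <- function(x, ...) {
  cat(sprintf("<ms_fingerprint> %d bins, m/z %d..%d, base peak at %d\n",
              nrow(x), min(x$mz), max(x$mz), x$mz[which.max(x$intensity)]))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Convert a pattern to a fingerprint
#'
#' Fine patterns are unit-binned first; intensities are scaled so the base
#' peak is 100.
#'
#' @param p An `iso_pattern`.
#' @return An `ms_fingerprint`.
#' @export
as_fingerprint <- function(p) {
  stopifnot(inherits(p, "iso_pattern"))
  if (pattern_resolution(p) == "fine") p <- to_unit_mass(p)
  bins <- if (!is.null(p$bin)) p$bin else as.integer(round(p$mass))
  fp <- ms_fingerprint(bins, p$abundance)
  fp$intensity <- 100 * fp$intensity / max(fp$intensity)
  fp
}

#' Align fingerprints on the union grid
#'
#' @param ... `ms_fingerprint` objects (or one list of them).
#' @return A matrix with one row per fingerprint, columns the union of
#'   integer bins (as column names), missing bins filled with 0.
#' @export
align_fingerprints <- function(...) {
  fps <- list(...)
  if (length(fps) == 1 && !inherits(fps[[1]], "ms_fingerprint")) fps <- fps[[1]]
  grid <- sort(unique(unlist(lapply(fps, `[[`, "mz"))))
  m <- matrix(0, length(fps), length(grid),
              dimnames = list(NULL, as.character(grid)))
  for (i in seq_along(fps))
    m[i, match(fps[[i]]$mz, grid)] <- fps[[i]]$intensity
  m
}

#' Normalized dot product between two fingerprints
#'
#' Similarity in `[0, 1]` between two intensity vectors aligned on the
#' union of their unit-mass grids (missing bins zero-filled). With aligned
#' vectors \eqn{u, v}:
#' \deqn{\mathrm{NDP}_{\cos} = \frac{u \cdot v}{\|u\|\,\|v\|}, \qquad
#'       \mathrm{NDP}_{\cos^2} = \left(\frac{u \cdot v}{\|u\|\,\|v\|}\right)^2.}
#' Both conventions circulate under the name "normalized dot product" in
#' spectral library search; the package default is the plain cosine, fixed
#' by regression against the reference monomer code audits (see the
#' methods vignette). NDP is symmetric and invariant to positive rescaling
#' of either fingerprint. No m/z or intensity-power weighting is applied.
#'
#' @param a,b `ms_fingerprint` objects.
#' @param variant `"cosine"` (default) or `"sqcosine"`.
#' @return A similarity in `[0, 1]`.
#' @export
#' @examples
#' d0 <- as_fingerprint(pattern_for_formula(parse_formula("C20H26N2O5")))
#' ndp(d0, d0)
ndp <- function(a, b, variant = getOption("isocoder.ndp_variant", "cosine")) {
  variant <- match.arg(variant, c("cosine", "sqcosine"))
  stopifnot(inherits(a, "ms_fingerprint"), inherits(b, "ms_fingerprint"))
  m <- align_fingerprints(a, b)
  nu <- sqrt(sum(m[1, ]^2)); nv <- sqrt(sum(m[2, ]^2))
  if (nu == 0 || nv == 0) stop("NDP undefined for a zero fingerprint")
  s <- sum(m[1, ] * m[2, ]) / (nu * nv)
  s <- min(max(s, 0), 1)
  if (variant == "sqcosine") s^2 else s
}

# cosine similarity matrix machinery used by the codespace module:
# rows of X are intensity vectors on a shared grid.
.row_normalize <- function(X) {
  n <- sqrt(rowSums(X^2))
  if (any(n == 0)) stop("zero fingerprint row")
  X / n
}

.apply_variant <- function(s, variant) {
  if (variant == "sqcosine") s^2 else s
}
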