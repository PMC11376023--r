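#' Code-space specification
#'
#' A code space is the set of all admissible mixtures of a component
#' alphabet: every mixture uses between `k_min` and `k_max` distinct
#' components, each at a positive multiple of the `increment` grid step,
#' proportions summing to 100%. Its coding quality is the largest pairwise
#' NDP between member fingerprints; two fingerprints with NDP below the
#' distinguishability `threshold` (default 0.9990, the similarity a
#' routine LC-MS readout can still tell apart) count as reliably readable.
#'
#' When `k_max` exceeds `100 / increment` it is capped: a mixture cannot
#' hold more components than grid units.
#'
#' @param n_components Alphabet size (e.g. 25 for a D0..D24 set).
#' @param k_min,k_max Allowed number of distinct components per mixture.
#' @param increment Grid step in percent; must divide 100.
#' @param threshold Distinguishability benchmark on the NDP scale.
#' @return A `code_spec` object.
#' @export
#' @examples
#' code_spec(25, 2, 2, increment = 25)   # the 900-mixture binary code
code_spec <- function(n_components, k_min, k_max, increment,
                      threshold = 0.9990) {
  if (100 %% increment != 0) stop("100 must be divisible by increment")
  m <- 100L %/% as.integer(increment)
  n <- as.integer(n_components)
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (n < 1) stop("n_components must be positive")
  if (k_min < 1 || k_max < k_min) stop("need 1 <= k_min <= k_max")
  if (k_min > min(n, m)) stop("k_min exceeds alphabet size or grid capacity")
  structure(list(n_components = n, k_min = k_min,
                 k_max = min(k_max, n, m), increment = as.integer(increment),
                 grid_units = m, threshold = threshold),
            class = "code_spec")
}

#' @export
print.code_spec <- function(x, ...) {
  cat(sprintf(
    "<code_spec> %d components, k = %d..%d, %d%% increment (%s mixtures), threshold %.4f\n",
    x$n_components, x$k_min, x$k_max, x$increment,
    format(count_mixtures(x), big.mark = " "), x$threshold))
  invisible(x)
}

#' Number of admissible mixtures in a code space
#'
#' Closed form: choosing `k` of `n` components and a composition of
#' `m = 100/increment` grid units into `k` positive parts gives
#' \deqn{\sum_{k=k_{min}}^{k_{max}} \binom{n}{k} \binom{m-1}{k-1}.}
#'
#' @param spec A [code_spec()].
#' @return A count (numeric; exact for all desk-scale codes).
#' @export
#' @examples
#' count_mixtures(code_spec(25, 2, 2, 25))    # 900
#' count_mixtures(code_spec(25, 1, 10, 10))   # 131128140
count_mixtures <- function(spec) {
  stopifnot(inherits(spec, "code_spec"))
  ks <- spec$k_min:spec$k_max
  sum(choose(spec$n_components, ks) * choose(spec$grid_units - 1, ks - 1))
}

# all compositions of m into k positive parts, lexicographic columns (k x P)
.compositions <- function(m, k) {
  if (k == 1) return(matrix(m, 1, 1))
  cols <- lapply(1:(m - k + 1), function(u)
    rbind(u, .compositions(m - u, k - 1)))
  do.call(cbind, cols)
}

#' Enumerate the mixtures of a code space
#'
#' Mixtures are produced in a fixed lexicographic order: increasing
#' component count `k`, then component tuples in [utils::combn()] order,
#' then compositions in lexicographic order. This order defines the
#' deterministic tie-break used by [decode()].
#'
#' @param spec A [code_spec()].
#' @param ids Component labels (length `n_components`); default
#'   `"C1".."Cn"`.
#' @param limit Refuse to materialize more than this many mixtures.
#' @return A list of [mixture()] objects.
#' @export
enumerate_mixtures <- function(spec, ids = NULL, limit = 1e5) {
  stopifnot(inherits(spec, "code_spec"))
  n <- spec$n_components
  if (is.null(ids)) ids <- paste0("C", seq_len(n))
  if (length(ids) != n) stop("ids must have length n_components")
  total <- count_mixtures(spec)
  if (total > limit)
    stop("code space has ", total, " mixtures (> limit = ", limit,
         "); enumerate blocks instead")
  out <- vector("list", total)
  pos <- 0L
  for (k in spec$k_min:spec$k_max) {
    combs <- utils::combn(n, k)
    comps <- .compositions(spec$grid_units, k)
    for (i in seq_len(ncol(combs))) for (j in seq_len(ncol(comps))) {
      pos <- pos + 1L
      out[[pos]] <- mixture(stats::setNames(comps[, j], ids[combs[, i]]),
                            spec$increment)
    }
  }
  out
}

# Walk the code space in blocks. For each block calls
# fn(W, index0, meta) where W is (rows x n) fraction-weight matrix,
# index0 the 0-based global offset of the block's first mixture, and meta
# a list(k, combo_cols, comp_cols) identifying each row.
.walk_code_blocks <- function(spec, fn, chunk = 50000L) {
  n <- spec$n_components
  m <- spec$grid_units
  index0 <- 0
  for (k in spec$k_min:spec$k_max) {
    combs <- utils::combn(n, k)
    comps <- .compositions(m, k) / m   # fractions
    nc <- ncol(combs); np <- ncol(comps)
    step <- max(1L, chunk %/% np)
    for (c0 in seq(1L, nc, by = step)) {
      c1 <- min(c0 + step - 1L, nc)
      ncb <- c1 - c0 + 1L
      rows <- ncb * np
      i_vec <- rep(c0:c1, each = np)
      j_vec <- rep(seq_len(np), ncb)
      W <- matrix(0, rows, n)
      for (t in seq_len(k))
        W[cbind(seq_len(rows), combs[t, i_vec])] <- comps[t, j_vec]
      fn(W, index0, list(k = k, combo_cols = i_vec, comp_cols = j_vec))
      index0 <- index0 + rows
    }
  }
  invisible(NULL)
}

# k-combination of 1..n at 1-based lexicographic rank i (combn order)
.comb_unrank <- function(n, k, i) {
  out <- integer(k)
  x <- 0L
  for (t in seq_len(k)) {
    for (v in (x + 1L):n) {
      cnt <- choose(n - v, k - t)
      if (i <= cnt) { out[t] <- v; x <- v; break }
      i <- i - cnt
    }
  }
  out
}

# composition of m into k positive parts at 1-based lexicographic rank j
# (the order .compositions() generates)
.comp_unrank <- function(m, k, j) {
  out <- integer(k)
  for (t in seq_len(k)) {
    if (t == k) { out[t] <- m; break }
    for (u in 1L:(m - (k - t))) {
      cnt <- choose(m - u - 1, k - t - 1)
      if (j <= cnt) { out[t] <- u; m <- m - u; break }
      j <- j - cnt
    }
  }
  out
}

# Reconstruct the mixture at 1-based global enumeration index `idx`.
.mixture_at <- function(spec, idx, ids = NULL) {
  n <- spec$n_components
  if (is.null(ids)) ids <- paste0("C", seq_len(n))
  off <- idx
  for (k in spec$k_min:spec$k_max) {
    nc <- choose(n, k); np <- choose(spec$grid_units - 1, k - 1)
    if (off <= nc * np) {
      i <- (off - 1) %/% np + 1
      j <- (off - 1) %% np + 1
      comb <- .comb_unrank(n, k, i)
      comp <- .comp_unrank(spec$grid_units, k, j)
      return(mixture(stats::setNames(comp, ids[comb]), spec$increment))
    }
    off <- off - nc * np
  }
  stop("index out of range")
}

# Fingerprint matrix of a whole code space (rows = mixtures, L2-normalized).
.code_fingerprints <- function(spec, S) {
  N <- count_mixtures(spec)
  B <- ncol(S)
  F <- matrix(0, N, B)
  .walk_code_blocks(spec, function(W, index0, meta) {
    F[index0 + seq_len(nrow(W)), ] <<- W %*% S
  })
  .row_normalize(F)
}

#' Audit a code space for its most-alike fingerprint pair
#'
#' Computes, over every pair of mixture fingerprints in the code, the
#' maximum NDP, the pair attaining it, and the number of pairs at or above
#' the distinguishability threshold. Fingerprints are stacked as an
#' N x bins matrix, L2-row-normalized, and the maximum off-diagonal cosine
#' found from chunked Gram blocks (upper triangle only), which makes the
#' ~10^4-10^5-fingerprint audits minutes-scale jobs.
#'
#' In `"restricted"` mode only the sub-family with at most `k_restrict`
#' components is searched and the result is a lower bound on the true
#' maximum — the mode for spaces beyond exhaustive pairwise reach (the
#' most-alike mixtures of large mixed-`k` codes are empirically the
#' small-`k` ones).
#'
#' @param spec A [code_spec()].
#' @param components A `component_library` with at least
#'   `spec$n_components` entries; the first `n_components` are used, in
#'   library order.
#' @param mode `"exact"` or `"restricted"`.
#' @param k_restrict Largest component count searched in restricted mode.
#' @param max_fingerprints Exact-mode budget; exceeding it errors.
#' @param chunk Rows per Gram block.
#' @param variant NDP variant, see [ndp()].
#' @inheritParams isotopologue_basis
#' @return A `code_audit`: list with `count`, `max_ndp`, `pair` (the two
#'   mixtures), `pairs_above_threshold`, `lower_bound`, `mode`.
#' @export
audit_code <- function(spec, components, mode = c("exact", "restricted"),
                       k_restrict = 2L, max_fingerprints = 2e5, chunk = 2000L,
                       variant = getOption("isocoder.ndp_variant", "cosine"),
                       table = default_isotope_table(),
                       prune = getOption("isocoder.prune", 1e-10)) {
  mode <- match.arg(mode)
  variant <- match.arg(variant, c("cosine", "sqcosine"))
  stopifnot(inherits(spec, "code_spec"), inherits(components, "component_library"))
  if (length(components) < spec$n_components)
    stop("library smaller than spec$n_components")
  search_spec <- spec
  lower_bound <- FALSE
  if (mode == "restricted" && spec$k_max > k_restrict) {
    search_spec <- code_spec(spec$n_components, spec$k_min,
                             min(k_restrict, spec$k_max), spec$increment,
                             spec$threshold)
    lower_bound <- TRUE
  }
  N <- count_mixtures(search_spec)
  if (N > max_fingerprints)
    stop("audit over ", N, " fingerprints exceeds the exact-mode budget (",
         max_fingerprints, "); use mode = \"restricted\" or raise the budget")
  ids <- names(components)[seq_len(spec$n_components)]
  cm <- component_matrix(components[ids], table, prune)
  F <- .code_fingerprints(search_spec, cm$S)
  if (nrow(F) < 2) stop("audit needs at least two fingerprints")
  thr_cos <- if (variant == "sqcosine") sqrt(spec$threshold) else spec$threshold
  best <- -1; best_pair <- c(NA, NA); n_above <- 0
  Nf <- nrow(F)
  for (a0 in seq(1L, Nf, by = chunk)) {
    a1 <- min(a0 + chunk - 1L, Nf)
    if (a1 == Nf && a0 == Nf) break   # last single row has no partner above it
    G <- F[a0:a1, , drop = FALSE] %*% t(F)
    for (r in seq_len(a1 - a0 + 1L)) {
      gi <- a0 + r - 1L
      if (gi >= Nf) next
      s <- G[r, (gi + 1L):Nf]
      n_above <- n_above + sum(s >= thr_cos)
      mx <- max(s)
      if (mx > best) {
        best <- mx
        best_pair <- c(gi, gi + which.max(s))
      }
    }
  }
  structure(list(
    count = count_mixtures(spec),
    searched = N,
    max_ndp = .apply_variant(min(max(best, 0), 1), variant),
    pair = lapply(best_pair, .mixture_at, spec = search_spec, ids = ids),
    pairs_above_threshold = n_above,
    threshold = spec$threshold,
    lower_bound = lower_bound,
    mode = mode,
    variant = variant
  ), class = "code_audit")
}

#' @export
print.code_audit <- function(x, ...) {
  cat(sprintf("<code_audit> %s mixtures%s\n",
              format(x$count, big.mark = " "),
              if (x$lower_bound)
                sprintf(" (restricted search over %s: lower bound)",
                        format(x$searched, big.mark = " ")) else ""))
  cat(sprintf("  max NDP %.4f between %s and %s\n", x$max_ndp,
              format(x$pair[[1]]), format(x$pair[[2]])))
  cat(sprintf("  pairs at/above threshold %.4f: %d\n",
              x$threshold, x$pairs_above_threshold))
  invisible(x)
}

#' Decode fingerprints against the calculated code-space library
#'
#' Scores a query fingerprint against the calculated fingerprint of every
#' mixture in the code space and returns the `top_k` most similar
#' compositions. The space is scanned in blocks (weights x component
#' spectra), so the full fingerprint library is never materialized. Ties
#' are broken by enumeration order.
#'
#' `decode_batch()` scans the space once for a whole set of queries —
#' the economical way to decode many measurements.
#'
#' @param query An `ms_fingerprint` (or for `decode_batch` a list of
#'   them).
#' @param spec A [code_spec()].
#' @param components A `component_library`; the first
#'   `spec$n_components` entries form the alphabet.
#' @param top_k Number of candidates to report.
#' @param chunk Mixtures scored per block.
#' @param variant NDP variant, see [ndp()].
#' @inheritParams isotopologue_basis
#' @return `decode()`: a `decode_result` data frame with columns `rank`,
#'   `mixture` (formatted), `ndp`, plus the mixture objects in
#'   `attr(, "mixtures")`. `decode_batch()`: a list of `decode_result`s.
#' @export
decode <- function(query, spec, components, top_k = 5L, chunk = 50000L,
                   variant = getOption("isocoder.ndp_variant", "cosine"),
                   table = default_isotope_table(),
                   prune = getOption("isocoder.prune", 1e-10)) {
  decode_batch(list(query), spec, components, top_k, chunk, variant,
               table, prune)[[1]]
}

#' @rdname decode
#' @export
decode_batch <- function(query, spec, components, top_k = 5L, chunk = 50000L,
                         variant = getOption("isocoder.ndp_variant", "cosine"),
                         table = default_isotope_table(),
                         prune = getOption("isocoder.prune", 1e-10)) {
  variant <- match.arg(variant, c("cosine", "sqcosine"))
  stopifnot(inherits(spec, "code_spec"), inherits(components, "component_library"))
  if (inherits(query, "ms_fingerprint")) query <- list(query)
  if (!length(query)) stop("no query fingerprints")
  if (!all(vapply(query, inherits, logical(1), "ms_fingerprint")))
    stop("queries must be ms_fingerprint objects")
  if (count_mixtures(spec) == 0) stop("empty code space")
  ids <- names(components)[seq_len(spec$n_components)]
  cm <- component_matrix(components[ids], table, prune)
  # union grid of component bins and query bins
  grid <- sort(unique(c(cm$bins, unlist(lapply(query, `[[`, "mz")))))
  S <- matrix(0, nrow(cm$S), length(grid))
  S[, match(cm$bins, grid)] <- cm$S
  Q <- matrix(0, length(query), length(grid))
  for (i in seq_along(query))
    Q[i, match(query[[i]]$mz, grid)] <- query[[i]]$intensity
  Q <- .row_normalize(Q)
  nq <- length(query)
  top_s <- matrix(-Inf, top_k, nq)
  top_i <- matrix(NA_real_, top_k, nq)
  .walk_code_blocks(spec, function(W, index0, meta) {
    F <- W %*% S
    rn <- sqrt(rowSums(F^2))
    sc <- (F %*% t(Q)) / rn                 # rows x nq cosines
    for (qi in seq_len(nq)) {
      s <- sc[, qi]
      cand <- which(s > top_s[top_k, qi])
      if (!length(cand)) next
      all_s <- c(top_s[, qi], s[cand])
      all_i <- c(top_i[, qi], index0 + cand)
      ord <- order(-all_s, all_i)[seq_len(top_k)]
      top_s[, qi] <<- all_s[ord]
      top_i[, qi] <<- all_i[ord]
    }
  }, chunk = chunk)
  lapply(seq_len(nq), function(qi) {
    keep <- is.finite(top_s[, qi])
    idx <- top_i[keep, qi]
    mixes <- lapply(idx, .mixture_at, spec = spec, ids = ids)
    res <- data.frame(rank = seq_along(idx),
                      mixture = vapply(mixes, format, character(1)),
                      ndp = .apply_variant(pmin(pmax(top_s[keep, qi], 0), 1),
                                           variant))
    attr(res, "mixtures") <- mixes
    class(res) <- c("decode_result", "data.frame")
    res
  })
}

#' @export
print.decode_result <- function(x, ...) {
  cat("<decode_result> best match:", x$mixture[1],
      sprintf("(NDP %.4f)\n", x$ndp[1]))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
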