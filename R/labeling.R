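#' Deuteration labeling schemes
#'
#' A labeling scheme describes which hydrogen positions of a molecule a
#' synthesis attempts to deuterate, grouped by building block: each group
#' has a multiplicity (number of equivalent positions) and a per-position
#' incorporation efficiency — the probability that one specific position
#' actually carries D in the product. The cumulative (global)
#' incorporation of a group is `efficiency ^ multiplicity`.
#'
#' @param groups Data frame (or list coercible to one) with columns
#'   `group` (label), `multiplicity` (positive integer) and `efficiency`
#'   (in `[0, 1]`).
#' @return A `labeling_scheme`.
#' @export
#' @examples
#' # a deutero-acetylation introducing a CD3 at 94% per position
#' sc <- labeling_scheme(data.frame(group = "acetyl", multiplicity = 3,
#'                                  efficiency = 0.94))
#' isotopologue_distribution(sc)[4]  # D3 fraction, 0.94^3 ~ 0.83
labeling_scheme <- function(groups) {
  groups <- as.data.frame(groups)
  need <- c("group", "multiplicity", "efficiency")
  if (!all(need %in% names(groups)))
    stop("groups needs columns: ", paste(need, collapse = ", "))
  if (nrow(groups)) {
    if (any(groups$multiplicity < 1 | groups$multiplicity != round(groups$multiplicity)))
      stop("multiplicity must be a positive integer")
    if (any(groups$efficiency < 0 | groups$efficiency > 1))
      stop("efficiency must be in [0, 1]")
  }
  structure(list(groups = groups), class = "labeling_scheme")
}

#' @export
print.labeling_scheme <- function(x, ...) {
  g <- x$groups
  cat(sprintf("<labeling_scheme> %d positions in %d groups\n",
              sum(g$multiplicity), nrow(g)))
  if (nrow(g)) {
    g$cumulative <- g$efficiency^g$multiplicity
    print(g, row.names = FALSE)
  }
  invisible(x)
}

#' Total number of labeled positions of a scheme
#' @param scheme A `labeling_scheme`.
#' @export
n_positions <- function(scheme) {
  stopifnot(inherits(scheme, "labeling_scheme"))
  as.integer(sum(scheme$groups$multiplicity))
}

#' Isotopologue distribution implied by a labeling scheme
#'
#' Each attempted position carries D independently with its per-position
#' efficiency; the number of deuteriums in a molecule is therefore
#' Poisson-binomial. The distribution is computed by dynamic-programming
#' convolution of the per-position Bernoulli outcomes:
#' `fractions[j + 1]` is the probability that exactly `j` positions carry
#' D. With 5 positions at 99% efficiency the intended D5 species is only
#' ~95% of the product, the remainder mostly D4 — the reason synthesized
#' components are distributions, not pure isotopologues.
#'
#' @param scheme A `labeling_scheme`.
#' @param d_max Pad (or validate) the output to length `d_max + 1`.
#' @return Numeric vector over D0..Dmax summing to 1.
#' @export
isotopologue_distribution <- function(scheme, d_max = NULL) {
  stopifnot(inherits(scheme, "labeling_scheme"))
  p <- rep(scheme$groups$efficiency, scheme$groups$multiplicity)
  dist <- 1
  for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
  if (!is.null(d_max)) {
    if (length(dist) - 1 > d_max)
      stop("scheme labels ", length(dist) - 1, " positions > d_max = ", d_max)
    dist <- c(dist, numeric(d_max + 1 - length(dist)))
  }
  dist
}

#' Synthesize a component from a labeling scheme
#'
#' Builds the [component()] a synthesis with the given scheme would
#' produce: isotopologue fractions from [isotopologue_distribution()],
#' padded over D0..Dmax of the base formula.
#'
#' @param scheme A `labeling_scheme`.
#' @param base_formula `chem_formula` of the unlabeled molecule.
#' @param id Component label.
#' @param d_max Isotopologue range of the component set (default: number
#'   of positions in the scheme).
#' @return A `component`.
#' @export
synth_component <- function(scheme, base_formula, id = "synthetic",
                            d_max = NULL) {
  if (is.null(d_max)) d_max <- n_positions(scheme)
  fr <- isotopologue_distribution(scheme, d_max)
  component(id, fr, base_formula)
}

#' Typical per-position deuteration efficiencies of the reference monomer
#'
#' The reference monomer's 24 labelable positions, grouped by the building
#' block that installs them, with the per-position incorporation
#' efficiencies typical of the corresponding chemistry: side-chain
#' methoxy CD3 (99%), side-chain ether CD2 (98%), quinoline core (96%),
#' side-chain saturation CH2 positions (94%), deutero-acetyl CD3 (94%,
#' or 97% with exchange of labile protons before acylation).
#'
#' @param improved_acetylation Use the improved 97% acetyl efficiency.
#' @return Data frame with columns `group`, `multiplicity`, `efficiency`,
#'   in the fixed priority order used by [synthetic_component_library()].
#' @export
monomer_position_pool <- function(improved_acetylation = FALSE) {
  data.frame(
    group = c("core", "acetyl", "methoxy_a", "methoxy_b",
              "ether_a", "ether_b", "saturation"),
    multiplicity = c(3L, 3L, 3L, 3L, 2L, 2L, 8L),
    efficiency = c(0.96, if (improved_acetylation) 0.97 else 0.94,
                   0.99, 0.99, 0.98, 0.98, 0.94)
  )
}

#' Synthetic component library emulating an imperfect D0..Dmax synthesis
#'
#' Generates the full D0..Dmax component set a real synthesis campaign
#' would produce: the Dn component labels the first `n` positions of the
#' fixed position pool (in pool order), each with its per-position
#' efficiency, so every component is a Poisson-binomial isotopologue
#' distribution centred slightly below its target level. This is the
#' fixture generator behind the decode and deconvolution robustness
#' tests.
#'
#' @param base_formula `chem_formula`; default the reference monomer.
#' @param d_max Highest target deuteration level.
#' @param pool Position pool as from [monomer_position_pool()].
#' @param ids Component labels; default `"c0".."c<d_max>"`.
#' @return A `component_library` of `d_max + 1` components.
#' @export
#' @examples
#' lib <- synthetic_component_library(d_max = 5)
#' lib[["c5"]]$fractions
synthetic_component_library <- function(base_formula = monomer_formula(),
                                        d_max = 24,
                                        pool = monomer_position_pool(),
                                        ids = paste0("c", 0:d_max)) {
  stopifnot(length(ids) == d_max + 1)
  effs <- rep(pool$efficiency, pool$multiplicity)
  grps <- rep(pool$group, pool$multiplicity)
  if (d_max > length(effs))
    stop("d_max exceeds the position pool (", length(effs), " positions)")
  component_library(lapply(0:d_max, function(n) {
    if (n == 0) {
      sc <- labeling_scheme(data.frame(group = character(0),
                                       multiplicity = integer(0),
                                       efficiency = numeric(0)))
    } else {
      take <- seq_len(n)
      sc <- labeling_scheme(stats::aggregate(
        list(multiplicity = take),
        by = list(group = grps[take], efficiency = effs[take]),
        FUN = length))
    }
    synth_component(sc, base_formula, id = ids[n + 1], d_max = d_max)
  }))
}

#' Scheme file IO
#'
#' A scheme file is a JSON array of objects with fields `group`,
#' `multiplicity` and `efficiency`.
#'
#' @param path File path.
#' @return A `labeling_scheme` (read) / `path` invisibly (write).
#' @export
read_scheme <- function(path) {
  labeling_scheme(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @param scheme A `labeling_scheme`.
#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  jsonlite::write_json(scheme$groups, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
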