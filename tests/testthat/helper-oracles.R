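# Independent oracles and shared fixtures for the test suite.

# Exhaustive isotope-assignment oracle: enumerate every way of assigning an
# isotope to every atom and aggregate (mass, probability). Feasible for
# molecules with <= ~6 atoms; completely independent of the convolution
# engine.
oracle_pattern <- function(eff_counts, table = default_isotope_table(),
                           tol = 1e-6) {
  atoms <- rep(names(eff_counts), unlist(eff_counts))
  idx <- expand.grid(lapply(atoms, function(el) seq_len(nrow(table[[el]]))))
  mass <- rep(0, nrow(idx)); prob <- rep(1, nrow(idx))
  for (a in seq_along(atoms)) {
    ent <- table[[atoms[a]]]
    mass <- mass + ent[idx[[a]], "mass"]
    prob <- prob * ent[idx[[a]], "abundance"]
  }
  o <- order(mass); mass <- mass[o]; prob <- prob[o]
  grp <- cumsum(c(TRUE, diff(mass) > tol))
  data.frame(mass = as.vector(tapply(mass * prob, grp, sum) / tapply(prob, grp, sum)),
             abundance = as.vector(tapply(prob, grp, sum)))
}

# Brute-force Poisson-binomial via enumeration of all 2^n label outcomes.
oracle_poisson_binomial <- function(p) {
  n <- length(p)
  out <- numeric(n + 1)
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    out[sum(bits) + 1] <- out[sum(bits) + 1] +
      prod(ifelse(bits == 1, p, 1 - p))
  }
  out
}

# Naive O(N^2) most-alike-pair search straight through ndp().
naive_audit <- function(fps, threshold = 0.9990, variant = "cosine") {
  best <- -1; pair <- c(NA, NA); n_above <- 0
  for (i in seq_along(fps)) for (j in seq_along(fps)) {
    if (j <= i) next
    s <- ndp(fps[[i]], fps[[j]], variant = variant)
    if (s >= threshold) n_above <- n_above + 1
    if (s > best) { best <- s; pair <- c(i, j) }
  }
  list(max_ndp = best, pair = pair, pairs_above_threshold = n_above)
}

# Tempfile that is cleaned up when the calling test finishes.
withr_local_tempfile <- function(ext = "", env = parent.frame()) {
  withr::local_tempfile(fileext = ext, .local_envir = env)
}

random_fingerprint <- function(n_bins = 8, offset = 100) {
  ms_fingerprint(offset + sort(sample(0:40, n_bins)),
                 stats::runif(n_bins, 0.01, 100))
}

# Lazily built shared fixtures (pattern computation is memoized in the
# package, but keep single objects per test run anyway).
.fixtures <- new.env()

ideal_monomer_lib <- function() {
  if (is.null(.fixtures$ideal)) .fixtures$ideal <- ideal_components(monomer_formula(), 24)
  .fixtures$ideal
}

synth_monomer_lib <- function() {
  if (is.null(.fixtures$synth)) .fixtures$synth <- synthetic_component_library(d_max = 24)
  .fixtures$synth
}

# Random on-grid mixture from a code spec (uniform k, uniform composition
# via multinomial surplus).
draw_random_mixture <- function(spec, ids) {
  k <- sample(spec$k_min:spec$k_max, 1)
  comps <- sort(sample(spec$n_components, k))
  units <- as.vector(stats::rmultinom(1, spec$grid_units - k, rep(1, k))) + 1
  mixture(stats::setNames(units, ids[comps]), spec$increment)
}
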