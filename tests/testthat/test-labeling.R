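test_that("Poisson-binomial DP matches exhaustive enumeration of label outcomes", {
  set.seed(41)
  for (i in 1:8) {
    n <- sample(2:10, 1)
    p <- stats::runif(n)
    sc <- labeling_scheme(data.frame(group = paste0("g", seq_len(n)),
                                     multiplicity = 1L, efficiency = p))
    got <- isotopologue_distribution(sc)
    expect_equal(got, oracle_poisson_binomial(p), tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    # mean label count equals the sum of efficiencies, exactly
    expect_equal(sum(got * 0:n), sum(p), tolerance = 1e-12)
  }
})

test_that("perfect incorporation gives a pure isotopologue", {
  sc <- labeling_scheme(data.frame(group = "all", multiplicity = 7, efficiency = 1))
  d <- isotopologue_distribution(sc)
  expect_equal(d, c(rep(0, 7), 1))
})

test_that("typical deuteration chemistries land at their cumulative incorporations", {
  base <- monomer_formula()
  d3 <- function(eff) {
    cp <- synth_component(labeling_scheme(data.frame(
      group = "acetyl", multiplicity = 3, efficiency = eff)), base, d_max = 24)
    cp$fractions[4]
  }
  expect_equal(d3(0.94), 0.94^3, tolerance = 1e-12)     # ~0.83
  expect_equal(round(100 * d3(0.94)), 83)
  expect_equal(round(100 * d3(0.97)), 91)               # improved acetylation

  sat <- labeling_scheme(data.frame(group = "sat", multiplicity = 8, efficiency = 0.94))
  expect_equal(round(100 * isotopologue_distribution(sat)[9]), 61)

  cd3 <- labeling_scheme(data.frame(group = "methoxy", multiplicity = 5, efficiency = 0.99))
  expect_equal(round(100 * isotopologue_distribution(cd3)[6]), 95)
})

test_that("the synthetic component library emulates an imperfect D0..D24 synthesis", {
  lib <- synth_monomer_lib()
  expect_length(lib, 25L)
  for (n in 0:24) {
    fr <- lib[[paste0("c", n)]]$fractions
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    expect_equal(which.max(fr) - 1L, n)          # mode at the target level
    if (n > 0) expect_lt(fr[n + 1], 1)           # but never pure
  }
  # a scheme with no labeled positions is the ideal D0 component
  expect_equal(lib[["c0"]]$fractions[1], 1)
})

test_that("synthetic measurements are deterministic in the seed and honest at zero noise", {
  lib <- synth_monomer_lib()
  fp <- mixture_fingerprint(mixture(c(c0 = 3, c8 = 1), 25), lib)
  silent <- noise_model(0, 0, 0, seed = 5)
  out <- synth_measurement(fp, silent)
  expect_equal(out$mz, fp$mz)
  expect_equal(out$intensity, 100 * fp$intensity / max(fp$intensity),
               tolerance = 1e-12)

  nm <- noise_model(seed = 99)
  a <- synth_measurement(fp, nm)
  b <- synth_measurement(fp, nm)
  expect_identical(a, b)
  c2 <- synth_measurement(fp, noise_model(seed = 100))
  expect_false(identical(a, c2))
})

test_that("1% intensity noise keeps true-vs-measured NDP in the instrument band", {
  lib <- ideal_monomer_lib()
  fp <- mixture_fingerprint(mixture(c(D2 = 1, D9 = 3), 25), lib)
  ndps <- vapply(1:100, function(s)
    ndp(fp, synth_measurement(fp, noise_model(sigma_rel = 0.01, seed = s))),
    numeric(1))
  expect_gte(mean(ndps > 0.999), 0.95)
})

test_that("mixing-error perturbation stays on the simplex", {
  m <- mixture(stats::setNames(rep(1, 10), paste0("c", 0:9)), 10)
  exact <- perturb_mixture(m, noise_model(0, 0, 0, seed = 2))
  expect_equal(unname(exact), rep(0.1, 10), tolerance = 1e-12)
  for (s in 1:20) {
    fr <- perturb_mixture(m, noise_model(seed = s))
    expect_equal(sum(fr), 1, tolerance = 1e-12)
    expect_true(all(fr > 0))
  }
})

test_that("a 10-component mixture survives mixing error: decode among its densest neighbours", {
  lib <- synth_monomer_lib()
  ids <- paste0("c", c(0, 2, 5, 7, 10, 13, 16, 19, 22, 24))
  m <- mixture(stats::setNames(rep(1L, 10), ids), 10)
  queries <- lapply(1:50, function(s)
    synth_mixture_measurement(m, lib, noise_model(seed = 3000 + s)))
  # candidate family: every 10-component equal-parts mixture (the true
  # mixture's nearest on-grid competitors)
  spec <- code_spec(25, 10, 10, 10)
  res <- decode_batch(queries, spec, lib, top_k = 1, chunk = 100000)
  hits <- vapply(res, function(r) r$mixture[1] == format(m), logical(1))
  expect_true(all(hits))
})
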