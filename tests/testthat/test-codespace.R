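test_that("counting matches exhaustive enumeration on small code spaces", {
  for (n in 3:5) for (inc in c(25, 20)) for (kmax in 1:3) {
    spec <- code_spec(n, 1, kmax, inc)
    mixes <- enumerate_mixtures(spec)
    expect_equal(length(mixes), count_mixtures(spec))
    sig <- vapply(mixes, format, character(1))
    expect_equal(anyDuplicated(sig), 0L)
    units <- vapply(mixes, function(m) sum(m$parts), integer(1))
    expect_true(all(units == spec$grid_units))
  }
})

test_that("the smallest nontrivial binary code has exactly three mixtures", {
  mixes <- enumerate_mixtures(code_spec(2, 2, 2, 25))
  expect_equal(length(mixes), 3L)
  expect_equal(vapply(mixes, format, character(1)),
               c("C1:25%,C2:75%", "C1:50%,C2:50%", "C1:75%,C2:25%"))
})

test_that("k_max is capped at the grid capacity", {
  # at 20% per unit only 5 components fit, whatever k_max says
  spec <- code_spec(25, 1, 10, 20)
  expect_equal(spec$k_max, 5L)
  expect_error(code_spec(25, 1, 2, 30), "divisible")
})

test_that("mixture unranking reproduces the enumeration order", {
  spec <- code_spec(5, 1, 3, 20)
  mixes <- enumerate_mixtures(spec)
  for (idx in seq_along(mixes)) {
    expect_equal(format(isocoder:::.mixture_at(spec, idx)), format(mixes[[idx]]))
  }
})

test_that("blocked audit agrees with the naive all-pairs oracle", {
  lib <- ideal_components(monomer_formula(), 5, ids = paste0("D", 0:5))
  spec <- code_spec(6, 1, 2, 25, threshold = 0.90)
  mixes <- enumerate_mixtures(spec, ids = names(lib))
  fps <- lapply(mixes, mixture_fingerprint, components = lib)
  ref <- naive_audit(fps, threshold = 0.90)

  audit <- audit_code(spec, lib, chunk = 7)   # deliberately awkward chunking
  expect_equal(audit$max_ndp, ref$max_ndp, tolerance = 1e-12)
  expect_equal(audit$pairs_above_threshold, ref$pairs_above_threshold)
  expect_equal(format(audit$pair[[1]]), format(mixes[[ref$pair[1]]]))
  expect_equal(format(audit$pair[[2]]), format(mixes[[ref$pair[2]]]))
})

test_that("duplicate components give a degenerate audit maximum of 1", {
  base <- monomer_formula()
  lib <- component_library(list(component("a", c(1, 0), base),
                                component("b", c(1, 0), base)))
  audit <- audit_code(code_spec(2, 1, 1, 50), lib)
  expect_equal(audit$max_ndp, 1, tolerance = 1e-12)
})

test_that("no pair of ideal-monomer fingerprints reaches the 0.9990 benchmark", {
  audit <- audit_code(code_spec(25, 1, 2, 25), ideal_monomer_lib())
  expect_equal(audit$pairs_above_threshold, 0)
  expect_lt(audit$max_ndp, 0.9990)
})

test_that("decode self-retrieves every mixture of the binary 25% code", {
  lib <- ideal_monomer_lib()
  spec <- code_spec(25, 2, 2, 25)
  mixes <- enumerate_mixtures(spec, ids = names(lib))
  fps <- lapply(mixes, mixture_fingerprint, components = lib)
  res <- decode_batch(fps, spec, lib, top_k = 2)
  hit <- vapply(seq_along(mixes), function(i)
    res[[i]]$mixture[1] == format(mixes[[i]]) &&
      abs(res[[i]]$ndp[1] - 1) < 1e-9, logical(1))
  expect_true(all(hit))
  # rank-1/rank-2 separation always positive
  gaps <- vapply(res, function(r) r$ndp[1] - r$ndp[2], numeric(1))
  expect_true(all(gaps > 0))
})

test_that("decode ties break by enumeration order", {
  base <- monomer_formula()
  lib <- component_library(list(component("a", c(1, 0), base),
                                component("b", c(1, 0), base)))
  spec <- code_spec(2, 1, 1, 100)
  res <- decode(component_spectrum(lib[["b"]]), spec, lib, top_k = 2)
  expect_equal(res$ndp, c(1, 1), tolerance = 1e-12)
  expect_equal(res$mixture, c("a:100%", "b:100%"))
})

test_that("exact audits beyond the fingerprint budget are refused", {
  expect_error(audit_code(code_spec(25, 1, 4, 10), ideal_monomer_lib(),
                          max_fingerprints = 1e4),
               "restricted")
})
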