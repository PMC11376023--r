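test_that("the identity reaction leaves fingerprints untouched", {
  lib <- ideal_components(monomer_formula(), 4, ids = paste0("D", 0:4))
  m <- mixture(c(D0 = 1, D4 = 3), 25)
  plain <- mixture_fingerprint(m, lib)
  tagged <- tagged_fingerprint(m, lib, tag_reaction())
  expect_equal(tagged$mz, plain$mz)
  expect_equal(tagged$intensity, plain$intensity, tolerance = 1e-12)
})

test_that("amide tagging equals fine-structure convolution with the reagent", {
  base <- monomer_formula()
  rxn <- tag_reaction(gain = "C11H11N", loss = "H2O")
  lib <- ideal_components(base, 3, ids = paste0("D", 0:3))
  m <- mixture(c(D0 = 1, D2 = 2, D3 = 1), 25)

  route_a <- tagged_fingerprint(m, lib, rxn)

  # independent route: convolve each isotopologue of (base - H2O) with the
  # amine's fine pattern, unit-bin, then combine with the mixing weights
  stripped <- base - parse_formula("H2O")
  amine <- pattern_for_formula(parse_formula("C11H11N"))
  fr <- mixture_fractions(m)
  dn <- c(D0 = 0, D2 = 2, D3 = 3)
  acc <- list()
  for (id in names(fr)) {
    fine <- convolve_patterns(
      pattern_for_formula(chem_formula(stripped$counts, n_label = dn[[id]])),
      amine)
    u <- to_unit_mass(fine)
    acc[[id]] <- data.frame(mz = u$bin, y = fr[[id]] * u$abundance)
  }
  all_bins <- sort(unique(unlist(lapply(acc, `[[`, "mz"))))
  y <- numeric(length(all_bins))
  for (id in names(acc))
    y[match(acc[[id]]$mz, all_bins)] <- y[match(acc[[id]]$mz, all_bins)] + acc[[id]]$y
  route_b <- ms_fingerprint(all_bins[y > 0], y[y > 0])

  ab <- align_fingerprints(route_a, route_b)
  ab <- ab / rowSums(ab)
  # pruning inside the two routes differs slightly below 1e-8
  expect_equal(ab[1, ], ab[2, ], tolerance = 1e-7)
  expect_equal(ndp(route_a, route_b), 1, tolerance = 1e-12)
})

test_that("tagging shifts every cluster by the product mass delta", {
  base <- monomer_formula()
  rxn <- tag_reaction(gain = "C11H11N", loss = "H2O")
  lib <- ideal_components(base, 2, ids = paste0("D", 0:2))
  m <- mixture(c(D0 = 2, D2 = 2), 25)
  plain <- mixture_fingerprint(m, lib)
  tagged <- tagged_fingerprint(m, lib, rxn)
  delta <- monoisotopic_mass(parse_formula("C11H11N")) -
    monoisotopic_mass(parse_formula("H2O"))
  expect_equal(min(tagged$mz) - min(plain$mz), round(delta))
  expect_equal(tagged$mz[which.max(tagged$intensity)] -
                 plain$mz[which.max(plain$intensity)], round(delta))
})

test_that("tagging preserves the rank order of pairwise similarities", {
  lib <- ideal_monomer_lib()
  rxn <- tag_reaction(gain = "C11H11N", loss = "H2O")
  set.seed(51)
  spec <- code_spec(25, 2, 2, 25)
  mixes <- lapply(sample(count_mixtures(spec), 12),
                  function(i) isocoder:::.mixture_at(spec, i, ids = names(lib)))
  before <- lapply(mixes, mixture_fingerprint, components = lib)
  after <- lapply(mixes, tagged_fingerprint, components = lib, rxn = rxn)
  pairs <- utils::combn(12, 2)
  s_before <- apply(pairs, 2, function(ij) ndp(before[[ij[1]]], before[[ij[2]]]))
  s_after <- apply(pairs, 2, function(ij) ndp(after[[ij[1]]], after[[ij[2]]]))
  expect_gt(stats::cor(s_before, s_after, method = "spearman"), 0.995)
})

test_that("growing the scaffold compresses the code: decamer > monomer max NDP", {
  spec <- code_spec(6, 2, 2, 25)
  mono <- audit_code(spec, ideal_components(monomer_formula(), 5))
  deca <- audit_code(spec, ideal_components(decamer_formula(), 5))
  expect_gt(deca$max_ndp, mono$max_ndp)
})

test_that("reactions that would remove absent atoms are rejected", {
  base <- monomer_formula()
  lib <- ideal_components(base, 1, ids = c("D0", "D1"))
  m <- mixture(c(D0 = 2, D1 = 2), 25)
  expect_error(tagged_fingerprint(m, lib, tag_reaction(loss = "S2")), "negative")
  expect_error(tag_reaction(gain = "C2D3"), "label")
})
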