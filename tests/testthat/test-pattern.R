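test_that("single-element patterns reduce to the table and to the neutral element", {
  tab <- default_isotope_table()
  p1 <- element_pattern("O", 1)
  expect_equal(p1$mass, unname(tab$O[, "mass"]))
  expect_equal(p1$abundance, unname(tab$O[, "abundance"]))

  p0 <- element_pattern("C", 0)
  expect_equal(nrow(p0), 1L)
  expect_equal(p0$mass, 0)
  expect_equal(p0$abundance, 1)

  expect_error(element_pattern("Zz", 2), "missing from isotope table")
})

test_that("H2 pattern matches exhaustive enumeration, incl. the all-2H peak", {
  tab <- default_isotope_table()
  p <- element_pattern("H", 2, prune = 0)
  o <- oracle_pattern(list(H = 2))
  expect_equal(p$mass, o$mass, tolerance = 1e-12)
  expect_equal(p$abundance, o$abundance, tolerance = 1e-12)
  # heaviest outcome: both hydrogens are 2H
  expect_equal(p$abundance[nrow(p)], unname(tab$H[2, "abundance"])^2,
               tolerance = 1e-15)
})

test_that("formula patterns agree with the exhaustive isotope-assignment oracle", {
  cases <- list(list(H = 2, O = 1),          # water
                list(C = 1, H = 4),          # methane
                list(C = 2, O = 2),
                list(N = 1, O = 2),
                list(C = 1, S = 1, O = 1))
  for (cs in cases) {
    f <- chem_formula(unlist(cs))
    p <- pattern_for_formula(f, prune = 0)
    o <- oracle_pattern(cs)
    expect_equal(p$mass, o$mass, tolerance = 1e-10)
    expect_equal(p$abundance, o$abundance, tolerance = 1e-12)
  }
})

test_that("convolution is commutative, associative, and a formula homomorphism", {
  pa <- pattern_for_formula(parse_formula("CH2"))
  pb <- pattern_for_formula(parse_formula("NO"))
  pc <- pattern_for_formula(parse_formula("O2"))

  ab <- convolve_patterns(pa, pb)
  ba <- convolve_patterns(pb, pa)
  expect_equal(ab$mass, ba$mass, tolerance = 1e-12)
  expect_equal(ab$abundance, ba$abundance, tolerance = 1e-12)

  abc1 <- convolve_patterns(convolve_patterns(pa, pb), pc)
  abc2 <- convolve_patterns(pa, convolve_patterns(pb, pc))
  expect_equal(abc1$mass, abc2$mass, tolerance = 1e-10)
  expect_equal(abc1$abundance, abc2$abundance, tolerance = 1e-10)

  # pattern(f1 + f2) == pattern(f1) * pattern(f2)
  f1 <- parse_formula("C3H5N", n_label = 2)
  f2 <- parse_formula("C2H2O3")
  direct <- pattern_for_formula(f1 + f2)
  conv <- convolve_patterns(pattern_for_formula(f1), pattern_for_formula(f2))
  expect_equal(direct$mass, conv$mass, tolerance = 1e-9)
  expect_equal(direct$abundance, conv$abundance, tolerance = 1e-9)
})

test_that("patterns normalize to total abundance 1 and prune monotonically", {
  set.seed(4)
  for (i in 1:10) {
    counts <- stats::setNames(sample(0:8, 4, replace = TRUE), c("C", "H", "N", "O"))
    f <- chem_formula(counts)
    p <- pattern_for_formula(f)
    expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
    expect_true(all(diff(p$mass) > 0))
    # lowering the prune threshold only adds peaks
    loose <- to_unit_mass(pattern_for_formula(f, prune = 1e-4))
    tight <- to_unit_mass(pattern_for_formula(f, prune = 1e-12))
    expect_true(all(loose$bin %in% tight$bin))
  }
})

test_that("deuteration shifts the monoisotopic peak by n x (m2H - m1H)", {
  tab <- default_isotope_table()
  d0 <- pattern_for_formula(parse_formula("C20H26N2O5"))
  d24 <- pattern_for_formula(parse_formula("C20H26N2O5", n_label = 24))
  dm <- unname(tab$D[1, "mass"] - tab$H[1, "mass"])
  expect_equal(d24$mass[1] - d0$mass[1], 24 * dm, tolerance = 1e-9)
  # most-abundant peak of the pure isotopologue sits at the monoisotopic position
  expect_equal(which.max(d24$abundance) , 1L)
  # A+1 relative abundance against the closed-form one-substitution sum
  u <- to_unit_mass(d24)
  r_expected <- unname(
    20 * (tab$C[2, "abundance"] / tab$C[1, "abundance"]) +
    2 * (tab$H[2, "abundance"] / tab$H[1, "abundance"]) +
    2 * (tab$N[2, "abundance"] / tab$N[1, "abundance"]) +
    5 * (tab$O[2, "abundance"] / tab$O[1, "abundance"]))
  expect_equal(u$abundance[2] / u$abundance[1], r_expected, tolerance = 1e-4)
})

test_that("unit-mass binning merges bins and conserves abundance", {
  p <- iso_pattern(c(375.19, 375.20, 376.21), c(0.6, 0.3, 0.1), "fine",
                   normalize = FALSE)
  u <- to_unit_mass(p)
  expect_equal(u$bin, c(375L, 376L))
  expect_equal(u$abundance, c(0.9, 0.1))
  expect_equal(sum(u$abundance), sum(p$abundance), tolerance = 1e-12)
  # weighted mean mass within the bin
  expect_equal(u$mass[1], (375.19 * 0.6 + 375.20 * 0.3) / 0.9, tolerance = 1e-12)

  single <- iso_pattern(100.5, 1, "fine")
  expect_equal(nrow(to_unit_mass(single)), 1L)
})
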