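---
title: "Methods: isotope ratio encoding and its numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope ratio encoding and its numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocoder)
```

This vignette records the model and every numerical convention the package
commits to, so that the values quoted in the README and pinned in the test
suite can be traced to explicit choices rather than incidental defaults.

## 1. The encoding model

Take a scaffold molecule with $n_H$ chemically addressable hydrogens — the
package's running example is the monomer C20H26N2O5 with 24 of its 26
hydrogens considered labelable (`monomer_formula()`,
`labelable_hydrogens()`). Its deuterated isotopologues D0..D24 form an
alphabet of 25 *components*. A codeword is a mixture of $k$ components at
molar fractions on a grid of increment $r\%$; the physical readout of a
codeword is its unit-mass MS1 intensity profile, the **fingerprint**.

The model stack is strictly linear:

1. **Isotope patterns.** The fine-structure pattern of a formula is the
   convolution of per-element multinomial patterns, computed by binary
   exponentiation of single-atom distributions (`pattern_for_formula()`).
   A deuterium label is carried as a pseudo-element "D" (abundance 1 at
   the ²H mass), so D$n$ means: $n$ hydrogens replaced, the remaining
   $26 - n$ keeping their natural ²H spread.
2. **Fingerprints.** Fine patterns are binned to the nearest integer mass
   (`to_unit_mass()`), matching a unit-resolution readout
   (`ms_fingerprint()`).
3. **Mixtures.** A mixture fingerprint is the fraction-weighted sum of its
   component fingerprints (`mixture_fingerprint()`); superposition holds
   because MS1 intensities of co-ionizing isotopologues add.

## 2. Similarity: which NDP, and why

Two "normalized dot product" conventions circulate in spectral-library
work: the plain cosine
$\mathrm{NDP}(u,v) = \frac{u \cdot v}{\lVert u\rVert\,\lVert v\rVert}$
and its square. The package had to commit to one, because every audited
maximum and every decode margin depends on it. We calibrated against the
four deterministic code audits of the ideal D0–D24 monomer codes (see §4):
only the **plain cosine** reproduces all four reference values
(0.9573 / 0.9945 / 0.8994 / 0.8538) simultaneously; the squared variant
misses them systematically. Plain cosine is therefore the default
everywhere; the squared form remains available as
`ndp(..., variant = "sqcosine")` or `options(isocoder.ndp_variant =
"sqcosine")` for comparison studies.

## 3. Audit-set convention

For a code restricted to exactly $k$ components, the audit searches all
pairs of exactly-$k$ fingerprints. For the *binary* codes we adopt a
deliberate exception: the audit set is $k \le 2$, i.e. the 25
single-component fingerprints are included alongside the binary mixtures.
The rationale is practical — a decoder facing a binary code must also
reject near-misses against pure components, and the worst-case pair in the
binary 25 % code is in fact a pure/binary pair:

```{r audit-binary}
audit_code(code_spec(25, 1, 2, 25), ideal_components(monomer_formula(), 24))
```

With singles excluded the binary 25 % maximum drops to about 0.929; with
them included it is 0.9573. The package pins the inclusive convention for
binary audits (`k_min = 1, k_max = 2`) and the exactly-$k$ convention for
ternary and quaternary audits, and the acceptance tests encode exactly
that. `code_spec()` makes the choice explicit in every call, so neither
convention is hidden.

## 4. The reference audits

The four deterministic regressions, recomputable at any time with
`scripts/acceptance.R`:

| code (ideal D0–D24, C20H26N2O5) | fingerprints | max NDP |
|---|---|---|
| binary, 25 % grid (incl. singles) | 925 | 0.9573 |
| binary, 10 % grid (incl. singles) | 2 725 | 0.9945 |
| ternary, 25 % grid | 6 900 | 0.8993 |
| quaternary, 25 % grid | 12 650 | 0.8536 |

All stay below 0.999, the reproducibility level of replicate measurements,
so every codeword in these spaces is readable in principle. The audit is a
blocked Gram-matrix search: fingerprints are stacked row-wise, L2-row-
normalized, and the upper triangle of $F F^\top$ is scanned in chunks —
identical to the naive all-pairs loop (tested against it) but vectorized.
For spaces too large to audit exhaustively (the 131 128 140-codeword
decamer space), `audit_code(mode = "restricted")` searches a $k \le
k_\mathrm{restrict}$ subset and reports an explicit `lower_bound = TRUE`
flag; the decamer values 0.9992 (10 % grid) and 0.9966 (20 % grid) are
such lower bounds, never presented as exact maxima.

## 5. Isotope table, pruning, binning

* **Isotope table**: pinned IUPAC/CIAAW 2021 representative masses and
  abundances (`default_isotope_table()`), shipped also as
  `inst/extdata/isotopes.json`. Audited NDPs at the fourth decimal depend
  on these constants, so the table is versioned data, not a runtime lookup.
* **Pruning**: peaks below a relative abundance of 1e-10 are dropped
  during convolution and the pattern renormalized
  (`options(isocoder.prune = ...)`). This perturbs retained abundances by
  less than about 1e-10 relative — far below the 0.002 audit tolerance —
  and keeps pattern sizes bounded.
* **Merging/binning**: fine-structure peaks closer than 1e-6 Da are merged
  (abundance-weighted mass); unit-mass binning uses `round(mass)`. All
  quoted NDPs are on unit-mass fingerprints.

## 6. The labeling and noise generator

The synthetic generator exists to ask one question honestly: *does
decoding survive realistic imperfection?* Its assumptions:

* **Incorporation.** Each labeling chemistry (group of positions) has an
  efficiency $p$; positions are independent Bernoulli trials, so a
  component's isotopologue distribution is Poisson-binomial
  (`isotopologue_distribution()`, computed by the standard DP recursion
  and tested against exhaustive $2^n$ enumeration). The default position
  pool (`monomer_position_pool()`) mirrors common deuteration
  chemistries: CD3 methoxylation at 0.99, acetylation at 0.94 (0.97 in the
  improved variant), ring/ether exchange at 0.98, olefin saturation at
  0.94 — giving, e.g., a D5 abundance of $0.99^5 \approx 95\%$ and a D8
  abundance of $0.94^8 \approx 61\%$.
* **Instrument noise**: multiplicative Gaussian per bin,
  $\sigma_\mathrm{rel} = 0.01$ (1 %), plus optional additive baseline
  (default 0). This matches the observation that replicate NDPs sit at or
  above 0.999.
* **Mixing error**: lognormal-style jitter of the molar fractions with
  $\sigma_\mathrm{mix} = 0.005$, renormalized to the simplex.
* **Determinism**: the seed lives in the `noise_model()` object; the
  global RNG state is saved and restored around every draw, so synthetic
  data are reproducible and side-effect-free.

These defaults are *study conditions*: they were fixed from the stated
chemistry efficiencies and instrument reproducibility before the decoding
experiments were run, not tuned to make tests pass.

## 7. Problem sizes

The shipped experiments use the 25-component monomer alphabet with
increments 25 %, 20 %, and 10 %, and $k$ up to 4 (exhaustive) or 10
(restricted / family-limited). These sizes keep every exhaustive
computation within a desktop-minute budget: the largest exhaustive audit
(12 650 fingerprints) takes seconds, and a batch decode against the full
1 148 125-codeword $k \le 4$, 10 % space runs in a few seconds. The
combinatorics themselves (`count_mixtures()`) are closed-form and exact at
any size.

## 8. Deconvolution

`deconvolve()` solves $\min_{f \ge 0} \lVert B f - y \rVert$ with
`pracma::lsqnonneg` on the isotopologue basis $B$ (columns = unit-mass
patterns of D0..D$d_\max$), then renormalizes $f$ to the simplex. The
query is scaled to unit norm first, so the reported `residual` is a
relative misfit; the condition number of $B^\top B$ is reported because
adjacent isotopologue columns overlap through their natural-abundance
tails. Noiseless inversions are exact to solver tolerance (tested over
1 000 random simplex points); at 1 % intensity noise the D5 fraction of
the $5 \times 0.99$ scheme is recovered within ±0.02 of its true 0.951.

## 9. Tagging

`tag_reaction(gain, loss)` models a covalent derivatization as formula
arithmetic on the *unlabeled* skeleton (labels are untouched; a reaction
cannot add or remove deuterium labels, and the constructor rejects "D" in
the reagent formulas). Because patterns convolve under formula addition,
the tagged fingerprint equals the untagged isotopologue pattern convolved
with the tag's fine pattern — verified in the tests by computing both
routes independently. Tagging preserves the rank order of pairwise code
similarities while shifting the mass window, which is what makes
tag-then-read protocols workable.
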