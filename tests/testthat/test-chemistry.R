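# Elemental-formula arithmetic, mass modes and modifications.

test_that("formula parsing round-trips and rejects malformed input", {
  f <- parse_formula("H2O")
  expect_equal(unname(unclass(f)[c("H", "O")]), c(2L, 1L))
  f2 <- parse_formula("C6H13NO3")
  expect_equal(unname(unclass(f2)[c("C", "H", "N", "O")]), c(6L, 13L, 1L, 3L))
  expect_error(parse_formula("C6H13X3"), "unknown element")
  expect_error(parse_formula("C6h13"), "malformed")
  # round trip for every registry formula
  reg <- monomer_registry()
  for (txt in reg$formula) {
    expect_identical(format_formula(parse_formula(txt)), txt)
  }
  expect_identical(format_formula(chem_formula()), "")
})

test_that("formula masses reproduce reference values in every mode", {
  expect_equal(as.numeric(formula_mass("C5H8O2", "nominal")), 100)
  expect_equal(as.numeric(formula_mass("H2O", "monoisotopic")), 18.0106,
               tolerance = 1e-5)
  for (mode in c("monoisotopic", "average", "nominal")) {
    expect_equal(as.numeric(formula_mass(chem_formula(), mode)), 0)
  }
})

test_that("mass is additive over formula addition", {
  set.seed(11)
  for (i in 1:50) {
    f1 <- chem_formula(c(C = sample(0:20, 1), H = sample(0:40, 1),
                         N = sample(0:5, 1), O = sample(0:10, 1),
                         S = sample(0:2, 1)))
    f2 <- chem_formula(c(C = sample(0:20, 1), H = sample(0:40, 1),
                         I = sample(0:2, 1)))
    for (mode in c("monoisotopic", "average", "nominal")) {
      expect_equal(as.numeric(formula_mass(f1 + f2, mode)),
                   as.numeric(formula_mass(f1, mode)) +
                     as.numeric(formula_mass(f2, mode)),
                   tolerance = 1e-9)
    }
  }
  expect_error(parse_formula("H2O") - parse_formula("H3O"), "negative")
})

test_that("ion m/z handles protonation, deprotonation and charge", {
  m <- formula_mass("C6H13NO3", "nominal")
  expect_equal(ion_mz(m, "M_plus_H"), 148)
  expect_equal(ion_mz(formula_mass(monomer_formula("8"), "nominal"),
                      "M_minus_H"), 228)
  expect_error(ion_mz(m, "M_plus_H", charge = 0), "charge")
  mono <- formula_mass("C6H13NO3", "monoisotopic")
  expect_equal(ion_mz(mono, "M_plus_H", charge = 2),
               (as.numeric(mono) + 2 * 1.00727647) / 2, tolerance = 1e-6)
})

test_that("printed low-resolution ESI values are reproduced from the registry", {
  # free hydroxy-acid scaffold, positive mode
  expect_equal(ion_mz(formula_mass("C6H13NO3", "nominal"), "M_plus_H"), 148)
  # synthesized hydroxy acids, negative mode
  printed <- c("8" = 228, "9" = 242, "10" = 256, "11" = 296,
               "13" = 188, "15" = 291, "16" = 215)
  for (id in names(printed)) {
    expect_equal(
      ion_mz(formula_mass(monomer_formula(id), "nominal"), "M_minus_H"),
      unname(printed[id]), info = id)
  }
})

test_that("residue masses follow the condensation rule", {
  expect_equal(as.numeric(residue_mass("G")), 57.0215, tolerance = 1e-4)
  expect_equal(as.numeric(residue_mass("14")), 148.0524, tolerance = 1e-4)
  reg <- monomer_registry()
  for (id in reg$id) {
    expect_equal(as.numeric(residue_mass(id)),
                 as.numeric(formula_mass(monomer_formula(id))) - 18.010565,
                 tolerance = 1e-6, info = id)
  }
})

test_that("mode consistency guards hold across the registry", {
  reg <- monomer_registry()
  for (id in reg$id) {
    mono <- formula_mass(monomer_formula(id), "monoisotopic")
    avg <- formula_mass(monomer_formula(id), "average")
    nom <- formula_mass(monomer_formula(id), "nominal")
    # monoisotopic below average for CHNOS-scale species
    expect_lt(as.numeric(mono), as.numeric(avg))
    # rounded monoisotopic ion agrees with the nominal ion (entry guard)
    expect_equal(round(ion_mz(mono, "M_plus_H")), ion_mz(nom, "M_plus_H"),
                 info = id)
  }
  expect_error(mass_value(1, "monoisotopic") + mass_value(1, "average"),
               "mixed-mode")
  expect_error(mass_value(1.5, "nominal"), "integer")
})

test_that("modification deltas apply element-wise with a negative-count guard", {
  bock_oh <- monomer_formula("6")
  lighter <- apply_modification(bock_oh, "boc_loss")
  expect_equal(as.numeric(formula_mass(bock_oh, "nominal")) -
                 as.numeric(formula_mass(lighter, "nominal")), 100)
  expect_equal(modification_shift("boc_loss", "nominal"), -100)
  # -N2 +H2 = -28.006148 + 2.015650
  expect_equal(modification_shift("azide_reduction", "monoisotopic"),
               -25.990498, tolerance = 1e-5)
  pazf <- monomer_formula("5")
  reduced <- apply_modification(pazf, "azide_reduction")
  expect_equal(as.numeric(formula_mass(pazf)) -
                 as.numeric(formula_mass(reduced)), 25.990498,
               tolerance = 1e-5)
  # glycine has a single nitrogen: no azide to reduce
  expect_error(apply_modification(monomer_formula("G"), "azide_reduction"),
               "negative")
})
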