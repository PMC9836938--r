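# Template instantiation, species masses, hydrolysis, carrier proteins.

demo_template <- macrocycle_template("demo", c("L", "A", "V", "B", "C"))

test_that("ester count follows the scheme's monomer chemistry", {
  # two hydroxy acids -> two ester bonds
  expect_length(instantiate(demo_template,
                            reassignment_scheme("rs5"))$ester_positions, 2L)
  # one hydroxy acid, one ncAA -> one ester bond
  expect_length(instantiate(demo_template,
                            reassignment_scheme("rs4"))$ester_positions, 1L)
  # two canonical amino acids -> none
  canonical <- reassignment_scheme("cc", monomer_A = "K", monomer_B = "F")
  expect_length(instantiate(demo_template, canonical)$ester_positions, 0L)
})

test_that("instantiation is deterministic and scheme-swappable", {
  s1 <- instantiate(demo_template, reassignment_scheme("rs1"))
  s3 <- instantiate(demo_template, reassignment_scheme("rs3"))
  differs <- which(s1$monomers != s3$monomers)
  expect_equal(sort(differs), which(demo_template$slots %in% c("A", "B")))
  expect_identical(s1$monomers,
                   instantiate(demo_template,
                               reassignment_scheme("rs1"))$monomers)
})

test_that("template validation enforces placeholder structure", {
  expect_error(macrocycle_template("x", c("A", "B")), "length >= 3")
  expect_error(macrocycle_template("x", c("L", "A", "V")), "exactly one")
  expect_error(macrocycle_template("x", c("A", "A", "B")), "exactly one")
})

test_that("species masses follow residue-sum accounting", {
  expect_equal(as.numeric(species_mass(rep("G", 5), cyclic = TRUE)),
               285.1073, tolerance = 1e-4)
  # cyclization costs exactly one water, for peptides and depsipeptides
  for (ids in list(c("L", "A", "V"), c("L", "7", "V", "12", "C"))) {
    expect_equal(as.numeric(species_mass(ids, cyclic = TRUE)),
                 as.numeric(species_mass(ids, cyclic = FALSE)) - 18.010565,
                 tolerance = 1e-6)
  }
  # a single-monomer chain weighs the free monomer
  expect_equal(as.numeric(species_mass("6", cyclic = FALSE)),
               as.numeric(formula_mass(monomer_formula("6"))))
  expect_error(species_mass(c("L", "zz")), "missing from registry")
  # independent oracle from free-monomer masses
  ids <- c("L", "7", "V", "12", "C")
  expect_equal(as.numeric(species_mass(ids, cyclic = TRUE)),
               oracle_chain_mass(ids, cyclic = TRUE), tolerance = 1e-4)
})

test_that("adding a monomer strictly increases species mass", {
  base <- c("L", "A", "V")
  for (extra in c("G", "A", "14", "6", "15")) {
    expect_gt(as.numeric(species_mass(c(base, extra))),
              as.numeric(species_mass(base)))
  }
})

test_that("hydrolysis products obey count and conservation rules", {
  one_ester <- instantiate(demo_template, reassignment_scheme("rs4"))
  prods <- hydrolysis_products(one_ester)
  expect_length(prods, 1L)
  expect_identical(prods[[1]]$type, "linear")
  cyc <- as.numeric(species_mass(one_ester))
  expect_equal(as.numeric(prods[[1]]$mass), cyc + 18.010565,
               tolerance = 1e-6)
  # the opened chain starts at the hydroxy acid
  expect_identical(prods[[1]]$monomers[1], "7")

  no_ester <- cyclic_species(c("L", "A", "V"))
  expect_length(hydrolysis_products(no_ester), 0L)

  two_ester <- instantiate(demo_template, reassignment_scheme("rs5"))
  prods2 <- hydrolysis_products(two_ester)
  types <- vapply(prods2, `[[`, character(1), "type")
  expect_equal(sum(types == "linear"), 2L)
  expect_equal(sum(types == "fragment_pair"), 1L)
  cyc2 <- as.numeric(species_mass(two_ester))
  pair <- prods2[[which(types == "fragment_pair")]]
  expect_equal(as.numeric(pair$mass[[1]]) + as.numeric(pair$mass[[2]]),
               cyc2 + 2 * 18.010565, tolerance = 1e-6)
  # complementary fragments partition the ring
  expect_setequal(c(pair$monomers[[1]], pair$monomers[[2]]),
                  two_ester$monomers)
})

test_that("carrier-protein substitution masses behave like ester chemistry", {
  carrier <- "MSKGEELFTGVVPILVELDGDVNGHKFSVRGEG"  # synthetic toy carrier
  intact <- protein_variant_mass(carrier, 3, "6", mode = "average")
  frags <- protein_variant_mass(carrier, 3, "6", hydrolysed_at_ester = TRUE,
                                mode = "average")
  # fragment masses sum to intact + H2O
  expect_equal(as.numeric(frags$n_terminal) + as.numeric(frags$c_terminal),
               as.numeric(intact) + 18.015, tolerance = 1e-3)
  # C-terminal fragment carries the hydroxy acid
  frags7 <- protein_variant_mass(carrier, 3, "7", hydrolysed_at_ester = TRUE,
                                 mode = "average")
  # Boc vs Alloc side chains differ by exactly CH4
  expect_equal(as.numeric(frags$c_terminal) - as.numeric(frags7$c_terminal),
               as.numeric(formula_mass("CH4", "average")), tolerance = 1e-9)
  # N-terminal fragments are identical
  expect_equal(as.numeric(frags$n_terminal), as.numeric(frags7$n_terminal))
  # hydrolysis at an amide position is refused
  expect_error(protein_variant_mass(carrier, 3, "1",
                                    hydrolysed_at_ester = TRUE),
               "amide")
  expect_error(protein_variant_mass(carrier, 99, "6"), "out of range")
})

test_that("species reports tabulate mass and ester bookkeeping", {
  rep_tab <- species_report(list(demo_template),
                            list(reassignment_scheme("rs4"),
                                 reassignment_scheme("rs5")))
  expect_equal(nrow(rep_tab), 2L)
  expect_equal(rep_tab$ester_count, c(1L, 2L))
  expect_equal(rep_tab$mz_MH, rep_tab$monoisotopic + 1.00727647,
               tolerance = 1e-6)
})
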