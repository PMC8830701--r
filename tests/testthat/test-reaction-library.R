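# Candidate reaction libraries: parsing, enumeration, stoichiometry,
# serialization.

test_that("reaction strings parse, format and round-trip", {
  sp <- species_set(c("P", "Y"))
  r1 <- parse_reaction("Y -> 2 Y", sp)
  expect_equal(r1$reactants, c(Y = 1L))
  expect_equal(r1$products, c(Y = 2L))
  r2 <- parse_reaction("P + Y -> 2 P", sp)
  expect_equal(r2$reactants, c(P = 1L, Y = 1L))
  expect_equal(r2$products, c(P = 2L))
  # unspaced coefficients and species with digits in the name
  sp2 <- species_set(c("P2", "gP2"))
  r3 <- parse_reaction("2P2 -> gP2", sp2)
  expect_equal(r3$reactants, c(P2 = 2L))
  for (txt in c("Y -> 2 Y", "P + Y -> 2 P", "P -> 0", "0 -> Y")) {
    expect_identical(format(parse_reaction(txt, sp)), txt)
  }
})

test_that("invalid reactions are rejected", {
  sp <- species_set(c("X", "Y"))
  expect_error(parse_reaction("X -> X", sp), "no net")
  expect_error(parse_reaction("Z -> X", sp), "unknown species")
  expect_error(parse_reaction("2 X + Y -> X", sp), "order exceeds 2")
  expect_error(parse_reaction("X -> 3 X", sp), "coefficient")
  expect_error(species_set(c("A", "A")), "unique")
})

test_that("stoichiometric matrix rows equal product minus reactant counts", {
  lib <- library_preset("lv-table1")
  S <- build_stoichiometric_matrix(lib)
  expect_equal(unname(S[match("Y -> 2 Y", reaction_strings(lib)), ]),
               c(0L, 1L))
  expect_equal(unname(S[match("P + Y -> 2 P", reaction_strings(lib)), ]),
               c(1L, -1L))
  expect_equal(unname(S[match("P -> 0", reaction_strings(lib)), ]),
               c(-1L, 0L))
  # naive recount oracle over every reaction
  for (d in seq_len(n_reactions(lib))) {
    rx <- lib$reactions[[d]]
    naive <- setNames(numeric(2), lib$species$names)
    for (nm in names(rx$products)) naive[nm] <- naive[nm] + rx$products[nm]
    for (nm in names(rx$reactants)) naive[nm] <- naive[nm] - rx$reactants[nm]
    expect_equal(unname(S[d, ]), unname(as.integer(naive)))
  }
  expect_true(all(S >= -2 & S <= 2))
})

test_that("the Lotka-Volterra preset holds 16 distinct candidates including the generating system", {
  lib <- library_preset("lv-table1")
  expect_equal(n_reactions(lib), 16L)
  strs <- reaction_strings(lib)
  expect_false(anyDuplicated(strs) > 0)
  expect_true(all(c("Y -> 2 Y", "P + Y -> 2 P", "P -> 0") %in% strs))
})

test_that("template enumeration is exhaustive, deduplicated and order-2 bounded", {
  sp <- species_set(c("A", "B"))
  lib <- enumerate_ansatz(sp, c("autocatalysis", "decay"))
  expect_equal(n_reactions(lib), 4L)  # 2 species x 2 one-placeholder templates
  expect_setequal(reaction_strings(lib),
                  c("A -> 2 A", "B -> 2 B", "A -> 0", "B -> 0"))
  # a two-placeholder template needs two distinct species
  expect_error(enumerate_ansatz(species_set("A"), "A + B -> 2A"),
               "no reactions")
  expect_error(enumerate_ansatz(sp, character(0)), "empty")
  # every instantiation respects the order bound and dedup invariant
  big <- enumerate_ansatz(species_set(c("A", "B", "C")),
                          c("conversion", "binding", "dimerization",
                            "predation", "dissociation"))
  expect_false(anyDuplicated(reaction_strings(big)) > 0)
  for (rx in big$reactions) {
    expect_lte(sum(rx$reactants), 2L)
    expect_lte(sum(rx$products), 2L)
  }
})

test_that("enumeration is invariant to species input order up to relabeling", {
  l1 <- enumerate_ansatz(species_set(c("A", "B", "C")),
                         c("conversion", "decay"))
  l2 <- enumerate_ansatz(species_set(c("C", "A", "B")),
                         c("conversion", "decay"))
  expect_setequal(reaction_strings(l1), reaction_strings(l2))
})

test_that("library files round-trip byte-identically and reject bad input", {
  lib <- library_preset("lv-table1")
  f1 <- tempfile(fileext = ".txt")
  f2 <- tempfile(fileext = ".txt")
  save_library(lib, f1)
  reloaded <- load_library(f1)
  expect_equal(reaction_strings(reloaded), reaction_strings(lib))
  expect_equal(n_reactions(reloaded), 16L)
  save_library(reloaded, f2)
  expect_identical(readLines(f1), readLines(f2))
  # duplicate line is rejected with its line number
  writeLines(c("species: A, B", "A -> B", "A -> B"), f1)
  expect_error(load_library(f1), "line 3.*duplicate")
  # no reactions at all
  writeLines("species: A, B", f1)
  expect_error(load_library(f1), "no reactions")
  expect_error(ansatz_library(species_set(c("A", "B")), list()),
               "at least one")
  expect_error(ansatz_library(species_set(c("A", "B")),
                              list("A -> B", "A -> B")), "duplicate")
})

test_that("the auto-regulation presets match the published system", {
  truth <- library_preset("autoreg-true")
  expect_equal(n_reactions(truth), 8L)
  expect_equal(truth$species$names, c("g", "P2", "gP2", "r", "P"))
  reduced <- library_preset("autoreg-reduced")
  expect_equal(reaction_strings(reduced)[1:8], reaction_strings(truth))
  expect_gt(n_reactions(reduced), 35L)
  expect_lt(n_reactions(reduced), 50L)
})
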