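test_that("stoichiometry solver finds minimal coefficients under the cap", {
  expect_identical(solve_stoichiometry(parse_reaction("N#N>>N", "plain2")),
                   c(1L, 2L))
  expect_null(solve_stoichiometry(parse_reaction("CCCCCCC>>C", "plain2")))
  # already balanced: all ones is the minimal solution
  expect_identical(
    solve_stoichiometry(parse_reaction("CC(=O)O.CO>>COC(C)=O.O", "plain2")),
    c(1L, 1L, 1L, 1L))
})

test_that("stoichiometry solver agrees with the exhaustive grid oracle", {
  set.seed(101)
  n_mismatch <- 0
  for (i in 1:200) {
    sys <- random_ev_system()
    mine <- rxncomplete:::solve_stoich_evs(sys$lhs, sys$rhs, max_coeff = 6L)
    oracle <- grid_solve_oracle(sys$lhs, sys$rhs, max_coeff = 6L)
    if (!identical(mine, oracle)) n_mismatch <- n_mismatch + 1
  }
  expect_identical(n_mismatch, 0)
})

test_that("help species complete simple byproduct deficits", {
  rec <- parse_reaction("CC(=O)O.CO>>COC(C)=O", "plain2")
  out <- complete_with_help_species(rec, side = "rhs")
  expect_identical(out$status, "COMPLETE_HELP")
  expect_identical(out$added_rhs[[1]]$smiles, canonical_smiles("O"))
  expect_true(all(out$completed$stoichiometry == 1L))
  expect_true(reaction_imbalance(out$completed)$balanced)

  # an element absent from every library species cannot be supplied
  si <- reaction_record("C[Si](C)C", "C", canonicalize = FALSE)
  expect_null(complete_with_help_species(si, side = "rhs"))
})

test_that("minimal-addition rule prefers acetic acid over 2x carbon monoxide", {
  p <- parse_reaction("Nc1ccc(O)cc1.CC(=O)OC(C)=O>>CC(=O)Nc1ccc(O)cc1", "plain2")
  out <- complete_with_help_species(p, side = "rhs")
  expect_identical(out$added_rhs[[1]]$smiles, canonical_smiles("CC(=O)O"))
  expect_true(all(out$completed$stoichiometry == 1L))
})

test_that("candidate promotion ranks by scorer and skips ranking for one candidate", {
  rec <- reaction_record(reactants = "CC#N", products = "CC(=O)OC",
                         agents = c("CO", "Cc1ccccc1"), id = "pinner")
  promo <- complete_with_candidates(rec, scorer = fallback_score)
  expect_identical(promo$candidate, canonical_smiles("CO"))
  expect_true(promo$confidence > 0)

  single <- complete_with_candidates(rec, candidates = "CO")
  expect_identical(single$candidate, "CO")
  expect_true(is.na(single$confidence))

  empty <- reaction_record(reactants = "C", products = "CO", canonicalize = FALSE)
  expect_null(complete_with_candidates(empty))
})

test_that("fallback score is the element-coverage fraction", {
  expect_equal(fallback_score(reaction_record("C", "C", canonicalize = FALSE)), 1)
  expect_equal(fallback_score(reaction_record("C", "CO", canonicalize = FALSE)), 0.5)
  r <- reaction_record("C", "CO", canonicalize = FALSE)
  r$reactants <- character(0)
  expect_equal(fallback_score(r), 0)
})

test_that("classify_and_balance walks the full loop on the worked examples", {
  expect_identical(
    classify_and_balance(parse_reaction("CC(=O)O.CO>>COC(C)=O.O", "plain2"))$status,
    "COMPLETE_ORIGINAL")

  stoich <- classify_and_balance(parse_reaction("N#N>>N", "plain2"))
  expect_identical(stoich$status, "COMPLETE_STOICH")
  expect_identical(stoich$completed$stoichiometry, c(1L, 2L))

  p <- parse_reaction("Nc1ccc(O)cc1.CC(=O)OC(C)=O>>CC(=O)Nc1ccc(O)cc1", "plain2")
  help <- classify_and_balance(p)
  expect_identical(help$status, "COMPLETE_HELP")
  expect_identical(vapply(help$added_rhs, `[[`, "", "smiles"),
                   canonical_smiles("CC(=O)O"))

  pinner <- reaction_record(reactants = "CC#N", products = "CC(=O)OC",
                            agents = "CO", id = "pinner")
  out <- classify_and_balance(pinner)
  expect_identical(out$status, "COMPLETE_REAGENT")
  expect_setequal(vapply(out$added_lhs, `[[`, "", "smiles"),
                  canonical_smiles(c("CO", "O")))
  expect_identical(vapply(out$added_rhs, `[[`, "", "smiles"), canonical_smiles("N"))
  expect_true(all(out$completed$stoichiometry == 1L))

  # RHS-only surplus with no recorded candidates: a reactant is missing and
  # help species are not licensed on the LHS
  missing_reactant <- parse_reaction("C>>CO", "plain2")
  expect_identical(classify_and_balance(missing_reactant)$status, "LHS_INSUFFICIENT")
})

test_that("every complete outcome passes exact conservation", {
  recs <- generate_reactions(30, seed = 7)
  for (rec in recs) {
    for (strategy in c("drop_byproduct", "drop_reactant")) {
      cor <- corrupt_reaction(rec, strategy, seed = 11)
      out <- classify_and_balance(cor$record)
      if (startsWith(out$status, "COMPLETE")) {
        expect_true(reaction_imbalance(out$completed)$balanced)
        expect_false(is.null(out$completed$stoichiometry))
      } else {
        expect_null(out$completed)
      }
    }
  }
})

test_that("classification is deterministic and monotone in the library", {
  recs <- generate_reactions(10, seed = 21)
  small_lib <- default_help_species()[1:5]
  for (rec in recs) {
    cor <- corrupt_reaction(rec, "drop_byproduct")
    a <- classify_and_balance(cor$record)
    b <- classify_and_balance(cor$record)
    expect_identical(a$status, b$status)
    small <- classify_and_balance(cor$record, library = small_lib)
    if (startsWith(small$status, "COMPLETE"))
      expect_true(startsWith(classify_and_balance(cor$record)$status, "COMPLETE"))
  }
})

test_that("help library order breaks exact ties", {
  # a Cl deficit of 1: HCl is the first chlorine source in the library
  rec <- parse_reaction("CCCl.CN>>CNCC", "plain2")
  out <- classify_and_balance(rec)
  expect_identical(out$status, "COMPLETE_HELP")
  expect_identical(out$added_rhs[[1]]$smiles, canonical_smiles("Cl"))
})
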