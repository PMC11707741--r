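pemetrexed <- function() {
  lib <- parent_library()
  lib[lib$name == "pemetrexed", ]
}

test_that("pemetrexed disodium hemipentahydrate-style forms reduce to the parent", {
  p <- pemetrexed()
  # 2 dianions + 4 sodium + 5 waters, the classic multi-component salt form
  adm <- paste(c(rep(p$anion_smiles, 2), rep("[Na+]", 4), rep("O", 5)),
               collapse = ".")
  expect_identical(get_parent(adm), p$smiles)
  # ditromethamine dihydrate variant
  trom <- salt_whitelist()
  adm2 <- paste(c(p$anion_smiles,
                  rep(trom$smiles[trom$name == "tromethamine cation"], 2),
                  rep("O", 2)), collapse = ".")
  expect_identical(get_parent(adm2), p$smiles)
  # free acid passes through unchanged
  expect_identical(get_parent(p$smiles), p$smiles)
})

test_that("solvate stripping removes solvents, keeps counterions, preserves order invariants", {
  drug_hcl_2h2o <- "CCN(CC)CC(=O)Nc1c(C)cccc1C.Cl.O.O"
  stripped <- strip_solvates(drug_hcl_2h2o)
  expect_equal(n_components(stripped), 2L)
  expect_true(grepl("Cl", stripped))
  # idempotent
  expect_identical(strip_solvates(stripped), stripped)
  # solvent-free salt unchanged (modulo canonicalization)
  salt <- canonical_smiles("CCN(CC)CC(=O)Nc1c(C)cccc1C.Cl")
  expect_identical(strip_solvates(salt), salt)
  # everything-solvent input errors
  expect_error(strip_solvates("O.O"), "no component left")
})

test_that("get_parent is idempotent and component counts are monotone", {
  corp <- small_corpus()
  subs <- corp$substances
  parents <- get_parent(subs$administered)
  expect_identical(get_parent(parents), parents)
  desolv <- strip_solvates(subs$administered)
  expect_true(all(n_components(parents) == 1L))
  expect_true(all(n_components(desolv) <= n_components(subs$administered)))
  expect_true(all(n_components(desolv) >= 1L))
})

test_that("get_parent recovers the planted truth parent on the whole corpus", {
  corp <- small_corpus()
  subs <- corp$substances
  expect_identical(get_parent(subs$administered), subs$truth_parent)
  desolv <- strip_solvates(subs$administered)
  drop <- n_components(subs$administered) - n_components(desolv)
  expect_equal(drop, subs$truth_n_solvent)
  expect_equal(count_parent_copies(desolv, subs$truth_parent),
               subs$truth_n_parent_copies)
})

test_that("whitelist removing everything raises a parent error", {
  expect_error(get_parent("Cl.O"), "no parent component")
})

test_that("the longest-SMILES component is selected as active", {
  expect_identical(identify_active_component("CCCCCCCCCC.[Cl-]"),
                   "CCCCCCCCCC")
  expect_identical(identify_active_component("CCO"), "CCO")
  # ties break lexicographically and are messaged
  expect_message(res <- identify_active_component("CCN.CCO"),
                 "lexicographically")
  expect_identical(res, "CCN")
  # a huge non-whitelisted coformer can win over the drug: flagged by warning
  big_coformer <- paste(rep("C", 60), collapse = "")
  expect_warning(
    p <- get_parent(paste0("CCN.", big_coformer)),
    "longest SMILES")
  expect_identical(p, big_coformer)
})

test_that("formula weight divides desolvated mass by parent copies", {
  p <- pemetrexed()
  free <- formula_weight(p$smiles, 1L)
  expect_equal(free, molecular_weight(p$smiles), tolerance = 1e-9)
  dimer_salt <- paste(c(rep(p$anion_smiles, 2), rep("[Na+]", 4)),
                      collapse = ".")
  expect_equal(formula_weight(dimer_salt, 2L),
               molecular_weight(dimer_salt) / 2, tolerance = 1e-9)
  # mass conservation: salt-inclusive weight never below the parent's
  expect_gte(formula_weight(dimer_salt, 2L), molecular_weight(p$smiles))
  expect_error(formula_weight("CCO", 0), ">= 1")
})

test_that("the size filter retains at and excludes above the cutoff", {
  fake <- tibble::tibble(name = c("a", "b"),
                         parent = c("CCO", paste(rep("C", 75), collapse = "")))
  out <- apply_size_filter(fake, cutoff = 1000)
  expect_equal(out$name, "a")
  expect_equal(attr(out, "excluded")$name, "b")
  # boundary: exactly at cutoff is retained
  mw <- molecular_weight("CCO")
  expect_equal(nrow(apply_size_filter(fake[1, ], cutoff = mw)), 1L)
  expect_equal(nrow(apply_size_filter(fake[1, ], cutoff = mw - 0.01)), 0L)
  # the corpus plants exactly three oversized products
  corp <- small_corpus()
  res <- apply_size_filter(
    tibble::tibble(parent = corp$substances$truth_parent))
  expect_equal(nrow(attr(res, "excluded")), 3L)
})

test_that("identifier resolution round-trips the synthetic dictionary", {
  corp <- small_corpus()
  res <- resolve_identifiers(corp$dictionary$name, corp$dictionary)
  expect_true(all(res$resolved))
  expect_identical(res$parent, corp$substances$truth_parent)
  # case-insensitive; absent names go to the review queue without error
  res2 <- resolve_identifiers(c(toupper(corp$dictionary$name[1]), "no such"),
                              corp$dictionary)
  expect_true(res2$resolved[1])
  expect_false(res2$resolved[2])
  expect_equal(attr(res2, "review_queue"), "no such")
  # conflicting rows raise
  bad_map <- tibble::tibble(name = c("x", "X"), inchikey = c("a", "b"),
                            smiles = c("CCO", "CCC"))
  expect_error(resolve_identifiers("x", bad_map), "conflicting")
})
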