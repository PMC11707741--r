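test_that("Fa dataset assembly takes the per-drug maximum and drops dotted parents", {
  drugs <- tibble::tibble(
    drug_id = c("D1", "D2", "D3", "D4", "D5"),
    parent = c("CCO", "CCO", "CCN", "CC(=O)O.[Na+]", "CCC"))
  formulations <- tibble::tibble(
    formulation_id = paste0("F", 1:5),
    product_id = paste0("P", 1:5),
    drug_id = c("D1", "D2", "D3", "D4", "D5"),
    routes = c("oral", "oral", "oral", "oral", "intravenous"),
    fa = c(0.5, 0.7, 0.5, 0.9, 0.8))
  db <- structure(list(drugs = drugs, formulations = formulations),
                  class = "pharm_db")
  fa <- assemble_fa_dataset(db)
  expect_equal(nrow(fa), 1L + 1L) # CCO (max of salt forms) + CCN
  expect_equal(fa$fa[fa$parent == "CCO"], 0.7) # greater value taken
  expect_false(any(grepl(".", fa$parent, fixed = TRUE)))
  expect_equal(attr(fa, "exclusion_log")$parent, "CC(=O)O.[Na+]")
  # boundary inclusive: fa = 0.8 is the positive class
  expect_true(assemble_fa_dataset(db, cutoff = 0.7)$class[
    fa$parent == "CCO"])
})

test_that("shared Fa across salt forms collapses to one record", {
  drugs <- tibble::tibble(drug_id = paste0("D", 1:4), parent = "CCCCN")
  formulations <- tibble::tibble(
    formulation_id = paste0("F", 1:4), product_id = paste0("P", 1:4),
    drug_id = drugs$drug_id, routes = "oral", fa = 0.5)
  db <- structure(list(drugs = drugs, formulations = formulations),
                  class = "pharm_db")
  fa <- assemble_fa_dataset(db)
  expect_equal(nrow(fa), 1L)
  expect_equal(fa$fa, 0.5)
})

test_that("MODI hits its closed-form extremes", {
  sep <- rbind(matrix(0, 5, 2), matrix(10, 5, 2)) +
    matrix(runif(20, 0, 0.1), 10, 2)
  y <- rep(c(FALSE, TRUE), each = 5)
  expect_equal(modelability_index(sep, y)$value, 1.0)
  inter <- matrix(c(0, 1, 2, 3), 4, 1)
  expect_equal(modelability_index(inter, c(TRUE, FALSE, TRUE, FALSE))$value,
               0.0)
  expect_error(modelability_index(sep, rep(TRUE, 10)), "both classes")
})

test_that("MODI equals the O(n^2) brute-force oracle and is label/column invariant", {
  set.seed(21)
  for (rep in 1:8) {
    X <- matrix(rnorm(40 * 5), 40, 5)
    y <- runif(40) < 0.4
    if (length(unique(y)) < 2) next
    got <- modelability_index(X, y)$value
    expect_equal(got, oracle_modi(X, y), tolerance = 1e-12)
    expect_equal(modelability_index(X, !y)$value, got, tolerance = 1e-12)
    expect_equal(modelability_index(X[, 5:1], y)$value, got,
                 tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("feature matrices honour their shape contracts and determinism", {
  smi <- c("CCO", "CCO", "CC(=O)Oc1ccccc1C(=O)O")
  ec <- featurize(smi, "ecfp6")
  expect_equal(ncol(ec), 2048L)
  expect_true(all(ec %in% c(0, 1)))
  expect_identical(ec[1, ], ec[2, ])
  hb <- featurize(smi, "hbflex18")
  expect_equal(ncol(hb), 18L)
  expect_equal(attr(hb, "roster"), colnames(hb))
  p2 <- featurize(smi, "phys2d")
  expect_gt(ncol(p2), 30L)
  expect_identical(p2[1, ], p2[2, ])
  expect_error(featurize("CCO.Cl", "maccs"), "single-component")
})

test_that("3D shape descriptors come from one conformer and duplicate rows agree", {
  smi <- c("CC(=O)Oc1ccccc1C(=O)O", "CC(=O)Oc1ccccc1C(=O)O", "CCCCCCCC")
  p3 <- featurize(smi, "phys3d")
  expect_true(all(c("rg", "npr1", "npr2") %in% colnames(p3)))
  expect_equal(p3[1, ], p3[2, ], tolerance = 1e-9)
  # an extended chain is more rod-like than a compact aromatic
  expect_gt(p3[3, "shape_anisotropy"], p3[1, "shape_anisotropy"])
  expect_false(any(attr(p3, "failed_3d")))
})

test_that("classification metrics reproduce the reference confusion matrix", {
  m <- classification_metrics(tp = 17, fn = 3, tn = 3, fp = 2)
  expect_equal(m$sensitivity, 0.85)
  expect_equal(m$specificity, 0.60)
  expect_equal(m$balanced_accuracy, 0.725)
  expect_equal(m$ppv, 0.8947, tolerance = 1e-4)
  expect_equal(m$npv, 0.50)
  expect_true(m$acceptable)
  perfect <- classification_metrics(10, 0, 10, 0)
  expect_true(all(unlist(perfect[1:5]) == 1))
  # constant-positive on balanced data: BA 0.5, not acceptable
  cp <- classification_metrics(tp = 10, fn = 0, tn = 0, fp = 10)
  expect_equal(cp$balanced_accuracy, 0.5)
  expect_false(cp$acceptable)
  # BA identity to machine precision
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2,
               tolerance = 1e-12)
})

test_that("the protocol solves a separable problem and is seed-reproducible", {
  set.seed(5)
  # two point-clusters with no within-class spread: every split-based
  # learner must place its boundary strictly between the classes
  X <- rbind(matrix(0, 30, 2), matrix(10, 30, 2))
  colnames(X) <- c("f1", "f2")
  y <- rep(c(FALSE, TRUE), each = 30)
  rep1 <- suppressWarnings(run_protocol(X, y, seed = 42, folds = 5))
  expect_true(all(rep1$test_ba == 1))
  expect_true(all(rep1$acceptable))
  rep2 <- suppressWarnings(run_protocol(X, y, seed = 42, folds = 5))
  expect_equal(tidy(rep1), tidy(rep2))
  g <- glance(rep1)
  expect_equal(g$test_ba, 1)
  expect_equal(g$seed, 42)
})

test_that("permuted labels drive cross-validated accuracy to chance", {
  set.seed(6)
  X <- matrix(rnorm(60 * 4), 60, 4)
  colnames(X) <- paste0("f", 1:4)
  y <- rep(c(TRUE, FALSE), 30)
  null <- permutation_null_ba(X, y, n_perm = 10, folds = 5, seed = 9)
  expect_lt(abs(null$mean - 0.5), 0.15)
})

test_that("a minority class smaller than the fold count reduces folds with warning", {
  X <- matrix(rnorm(40), 20, 2)
  y <- c(rep(TRUE, 17), rep(FALSE, 3))
  expect_warning(
    cv <- cv_balanced_accuracy(X, y, "decision_tree",
                               list(criterion = "gini", maxdepth = 3L,
                                    minsplit = 2L, minbucket = 1L),
                               folds = 10),
    "reducing folds")
  expect_true(is.finite(cv$mean))
})
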