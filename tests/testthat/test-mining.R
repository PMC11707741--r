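test_that("apriori reproduces the worked four-transaction example", {
  fi <- mine_frequent_itemsets(list(c("A", "B"), c("A", "B"), c("A", "C"),
                                    c("B", "C")), min_support = 0.5)
  key <- vapply(fi$items, paste, character(1), collapse = "")
  sup <- setNames(fi$support, key)
  expect_equal(sup[["A"]], 0.75)
  expect_equal(sup[["B"]], 0.75)
  expect_equal(sup[["C"]], 0.5)
  expect_equal(sup[["AB"]], 0.5)
  expect_length(key, 4L)
})

test_that("min_support 1 keeps only itemsets present in every transaction", {
  fi <- mine_frequent_itemsets(list(c("A", "B", "C"), c("A", "B"), c("A")),
                               min_support = 1)
  expect_equal(vapply(fi$items, paste, character(1), collapse = ""), "A")
  expect_error(mine_frequent_itemsets(list(), 0.5), "no transactions")
})

test_that("apriori equals power-set enumeration on random small universes", {
  set.seed(7)
  for (rep in 1:10) {
    n_items <- sample(4:8, 1)
    items <- letters[seq_len(n_items)]
    tx <- replicate(sample(8:20, 1), {
      k <- sample(seq_len(n_items), 1)
      sample(items, k)
    }, simplify = FALSE)
    ms <- sample(c(0.1, 0.2, 0.3), 1)
    got <- mine_frequent_itemsets(tx, ms)
    want <- oracle_powerset_itemsets(tx, ms)
    got_keys <- sort(vapply(got$items, paste, character(1), collapse = ","))
    want_keys <- sort(vapply(want, function(w) paste(w$items, collapse = ","),
                             character(1)))
    expect_identical(got_keys, want_keys)
    want_sup <- setNames(vapply(want, `[[`, numeric(1), "support"),
                         vapply(want, function(w) paste(w$items,
                                                        collapse = ","),
                                character(1)))
    got_sup <- setNames(got$support,
                        vapply(got$items, paste, character(1),
                               collapse = ","))
    expect_equal(got_sup[names(want_sup)], want_sup, tolerance = 1e-12)
    # anti-monotonicity across the mined lattice
    for (i in seq_len(nrow(got))) {
      it <- got$items[[i]]
      if (length(it) < 2) next
      for (drop in seq_along(it)) {
        parent_sup <- got_sup[[paste(it[-drop], collapse = ",")]]
        expect_gte(parent_sup, got$support[i])
      }
    }
  }
})

test_that("rule derivation matches the hand computation and the equation identities", {
  fi <- mine_frequent_itemsets(list(c("A", "B"), c("A", "B"), c("A", "C"),
                                    c("B", "C")), min_support = 0.25)
  rules <- derive_rules(fi, min_confidence = 0, min_lift = 0)
  ab <- rules[vapply(rules$antecedent, identical, logical(1), "A") &
                vapply(rules$consequent, identical, logical(1), "B"), ]
  expect_equal(ab$confidence, 2 / 3, tolerance = 1e-12)
  expect_equal(ab$lift, (2 / 3) / 0.75, tolerance = 1e-12)
  sup <- setNames(fi$support,
                  vapply(fi$items, paste, character(1), collapse = ","))
  for (i in seq_len(nrow(rules))) {
    X <- rules$antecedent[[i]]; Y <- rules$consequent[[i]]
    s_xy <- sup[[paste(sort(c(X, Y)), collapse = ",")]]
    expect_equal(rules$confidence[i], s_xy / sup[[paste(X, collapse = ",")]],
                 tolerance = 1e-12)
    expect_equal(rules$lift[i],
                 rules$confidence[i] / sup[[paste(Y, collapse = ",")]],
                 tolerance = 1e-12)
    # lift symmetry: lift(X => Y) = lift(Y => X)
    rev_i <- which(vapply(rules$antecedent, identical, logical(1), Y) &
                     vapply(rules$consequent, identical, logical(1), X))
    if (length(rev_i)) {
      expect_equal(rules$lift[i], rules$lift[rev_i], tolerance = 1e-12)
    }
  }
})

test_that("independent items yield no high-lift rules; planted rules are recovered", {
  null_cfg <- synthetic_config(n_products = 2000, excipient_vocab_size = 10,
                               planted_rules = list(),
                               background_item_prob = 0.3, seed = 19)
  tx <- synth_transactions(2000, null_cfg)$transactions$items
  fi <- mine_frequent_itemsets(tx, min_support = 0.01)
  rules <- derive_rules(fi, min_confidence = 0, min_lift = 0)
  pairs <- rules[lengths(rules$antecedent) == 1 &
                   lengths(rules$consequent) == 1, ]
  expect_gt(nrow(pairs), 0L)
  expect_true(all(pairs$lift > 0.8 & pairs$lift < 1.2))
  # planted rules at the reference targets
  cfg <- synthetic_config(n_products = 2000, seed = 23)
  gen <- synth_transactions(2000, cfg)
  fi2 <- mine_frequent_itemsets(gen$transactions$items, min_support = 0.01)
  rules2 <- derive_rules(fi2, min_confidence = 0.5, min_lift = 1)
  for (r in cfg$planted_rules) {
    hit <- rules2[vapply(rules2$antecedent, identical, logical(1),
                         r$antecedent) &
                    vapply(rules2$consequent, identical, logical(1),
                           r$consequent), ]
    expect_equal(nrow(hit), 1L)
    expect_lt(abs(hit$confidence - r$target_confidence), 0.05)
    expect_lt(abs(hit$support - r$target_support),
              3 * sqrt(r$target_support * (1 - r$target_support) / 2000))
  }
})

test_that("rule subnetworks keep the planted topology", {
  empty <- rule_subnetwork(derive_rules(
    mine_frequent_itemsets(list("a"), 0.5), 0.9, 5), "a")
  expect_equal(igraph::vcount(empty), 0L)
  one <- tibble::tibble(antecedent = list("A"), consequent = list("B"),
                        support = 0.3, confidence = 0.9, lift = 2)
  class(one) <- c("assoc_rules", class(one))
  g <- rule_subnetwork(one, "A")
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)
  expect_true(igraph::are_adjacent(g, "A", "B"))
  # planted star: hub implies five satellites
  sats <- paste0("s", 1:5)
  star <- dplyr::bind_rows(lapply(sats, function(s) {
    tibble::tibble(antecedent = list("hub"), consequent = list(s),
                   support = 0.2, confidence = 0.9, lift = 3)
  }))
  class(star) <- c("assoc_rules", class(star))
  gs <- rule_subnetwork(star, "hub")
  expect_equal(igraph::vcount(gs), 6L)
  expect_equal(igraph::ecount(gs), 5L)
  expect_equal(unname(igraph::degree(gs, "hub", mode = "out")), 5)
})

test_that("Benjamini-Hochberg equals the step-up definition on random vectors", {
  expect_equal(benjamini_hochberg(c(0.2, 0.2, 0.2)), rep(0.2, 3))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (rep in 1:30) {
    p <- round(runif(sample(1:8, 1)), 3)
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_equal(order(adj[order(p)]), seq_along(p)) # monotone in p
  }
})

test_that("the descriptor screen reproduces exact small-sample p-values", {
  # groups {1,2,3} vs {4,5,6}: exact two-sided p = 0.1 by enumeration
  expect_equal(oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  membership <- tibble::tibble(
    drug_id = paste0("d", 1:3), excipient_id = "exc")
  descr <- tibble::tibble(drug_id = paste0("d", 1:6),
                          val = c(1, 2, 3, 4, 5, 6))
  res <- excipient_descriptor_screen(descr, membership, min_n = 3)
  expect_equal(nrow(res), 1L)
  # normal approximation must sit near the exact enumeration value
  expect_lt(abs(res$p_value - 0.1), 0.05)
  expect_equal(res$direction, -1)
  # identical groups: p close to 1
  descr2 <- tibble::tibble(drug_id = paste0("d", 1:6),
                           val = c(1, 2, 3, 1, 2, 3))
  res2 <- excipient_descriptor_screen(descr2, membership, min_n = 3)
  expect_gt(res2$p_value, 0.9)
  # adjusted p never below raw
  expect_true(all(res2$p_adjusted >= res2$p_value - 1e-12))
})

test_that("screen over the corpus database tests eligible excipients only", {
  db <- small_db()
  drugs <- db$drugs
  desc <- compute_descriptors(drugs$parent)
  desc$drug_id <- drugs$drug_id
  membership <- dplyr::inner_join(
    formulation_excipients(db),
    db$formulations[, c("formulation_id", "drug_id")],
    by = "formulation_id")[, c("drug_id", "excipient_id")]
  membership <- dplyr::distinct(membership)
  res <- excipient_descriptor_screen(desc, membership, min_n = 10)
  counts <- table(membership$excipient_id)
  eligible <- names(counts)[counts >= 10]
  expect_setequal(unique(res$excipient_id), eligible)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
  expect_true(all(res$p_adjusted <= 1))
})
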