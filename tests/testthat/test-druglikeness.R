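test_that("descriptors take hand-countable values on tiny molecules", {
  d <- compute_descriptors(c("CCO", "c1ccccc1"))
  expect_equal(d$hbd, c(1L, 0L))
  expect_equal(d$hba, c(1L, 0L))
  expect_equal(d$rbc, c(0L, 0L))
  expect_equal(d$tpsa[2], 0)
  expect_error(compute_descriptors("CCO.Cl"), "single-component")
})

test_that("ruleset evaluation is boundary-inclusive and counts violations", {
  rs <- default_rulesets()
  boundary <- c(mw = 500, logp = 5, hbd = 5, hba = 10)
  res <- evaluate_ruleset(boundary, rs$ro5)
  expect_true(res$pass)
  expect_equal(res$violations, 0L)
  res2 <- evaluate_ruleset(c(mw = 600, logp = 6, hbd = 2, hba = 4), rs$ro5)
  expect_false(res2$pass)
  expect_equal(res2$violations, 2L)
  all_inf <- tibble::tibble(descriptor = c("mw", "logp"),
                            lower = -Inf, upper = Inf)
  expect_true(evaluate_ruleset(c(mw = 1e6, logp = 50), all_inf)$pass)
  expect_error(evaluate_ruleset(c(mw = 1), rs$ro5), "unknown descriptor")
})

test_that("conformance percentages are plain arithmetic, order-invariant", {
  tbl <- tibble::tibble(
    mw = c(300, 400, 450, 600), logp = c(1, 2, 3, 6),
    hbd = c(1, 1, 1, 1), hba = c(2, 2, 2, 2),
    rbc = c(3, 3, 3, 3), tpsa = c(60, 60, 60, 60))
  s <- conformance_summary(tbl)
  expect_equal(unname(s$percent_conforming["ro5"]), 75.0)
  s_rev <- conformance_summary(tbl[4:1, ])
  expect_equal(s$percent_conforming, s_rev$percent_conforming)
  all_ok <- conformance_summary(tbl[1:3, ])
  expect_true(all(all_ok$percent_conforming == 100))
  expect_equal(all_ok$n_multi_ro5_violators, 0L)
  # the two molecular-weight definitions are counted separately
  s2 <- conformance_summary(tbl, molwt1 = c(550, 550, 400, 700))
  expect_equal(s2$n_over_500_molwt1, 3L)
  expect_equal(s2$n_over_500_molwt2, 1L)
})

test_that("Tanimoto distances match a set-arithmetic oracle", {
  f1 <- c(1, 1, 0, 0, 1)
  expect_equal(tanimoto_distance_matrix(rbind(f1, f1))[1, 2], 0)
  disjoint <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(tanimoto_distance_matrix(disjoint)[1, 2], 1)
  zeros <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(tanimoto_distance_matrix(zeros)[1, 2], 0)
  set.seed(42)
  for (rep in 1:5) {
    F <- matrix(rbinom(6 * 10, 1, 0.4), 6, 10)
    D <- tanimoto_distance_matrix(F)
    expect_true(isSymmetric(D))
    expect_true(all(diag(D) == 0))
    expect_true(all(D >= 0 & D <= 1))
    for (i in 1:6) for (j in 1:6) {
      expect_equal(D[i, j], oracle_tanimoto(F[i, ], F[j, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("MACCS fingerprints have 166 keys and separate unlike molecules", {
  fp <- maccs_fingerprints(c("CCO", "CCO", "c1ccccc1C(=O)O"))
  expect_equal(ncol(fp), 166L)
  expect_identical(fp[1, ], fp[2, ])
  D <- tanimoto_distance_matrix(fp)
  expect_equal(D[1, 2], 0)
  expect_gt(D[1, 3], 0)
})

test_that("PCA embedding degenerates correctly and preserves planar geometry", {
  line <- cbind(1:10, 2 * (1:10) + 3)
  emb <- embed_chemical_space(line, "pca")
  ev <- attr(emb, "explained_variance")
  expect_equal(ev[1], 1, tolerance = 1e-9)
  expect_equal(sum(ev), 1, tolerance = 1e-9)
  # three points in a plane: pairwise distances survive the 2D projection
  tri <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  e2 <- embed_chemical_space(tri, "pca")
  d_orig <- as.matrix(dist(tri))
  d_emb <- as.matrix(dist(cbind(e2$x, e2$y)))
  expect_equal(d_emb, d_orig, tolerance = 1e-9)
  expect_error(embed_chemical_space(line[1:2, ], "pca"), "at least 3")
  # z-scored input: component variances sum to 1 of total
  set.seed(1)
  Z <- scale(matrix(rnorm(60), 20, 3))
  ez <- embed_chemical_space(Z, "pca")
  expect_equal(sum(attr(ez, "explained_variance")), 1, tolerance = 1e-9)
})

test_that("t-SNE is reproducible under a fixed seed and reports its KL", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  D <- as.matrix(dist(X))
  e1 <- embed_chemical_space(D, "tsne", seed = 7, perplexity = 8,
                             max_iter = 250)
  e2 <- embed_chemical_space(D, "tsne", seed = 7, perplexity = 8,
                             max_iter = 250)
  expect_identical(e1$x, e2$x)
  kl <- attr(e1, "kl_divergence")
  expect_true(is.finite(kl) && kl >= 0)
  # two far-apart clusters stay separated in the embedding
  grp <- rep(1:2, each = 20)
  within1 <- dist(cbind(e1$x, e1$y)[grp == 1, ])
  centroids <- rowsum(cbind(e1$x, e1$y), grp) / 20
  expect_gt(dist(centroids)[1], median(within1))
})

test_that("embedding plots build without error", {
  set.seed(4)
  Z <- matrix(rnorm(30), 10, 3)
  p <- ggplot2::autoplot(embed_chemical_space(Z, "pca"))
  expect_s3_class(p, "ggplot")
  desc <- compute_descriptors(parent_library()$smiles[1:5])
  expect_s3_class(plot_ruleset_conformance(desc), "ggplot")
})
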