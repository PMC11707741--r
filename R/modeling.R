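# Oral fraction-absorbed classification: dataset assembly under the oral /
# max-Fa / single-component filters, the modelability index, and the
# stratified split / 10-fold grid-search / single-test-evaluation protocol
# over four tree-based model families.

#' Assemble the Fa classification dataset from a database
#'
#' Selects orally administered formulations with an Fa value, takes the
#' greatest Fa per parent drug across formulations and salt forms, and
#' excludes drugs whose parent structure still contains a component
#' separator (the SMILES dot). The class label is `fa >= cutoff`.
#'
#' @param db A `pharm_db`.
#' @param cutoff Fa class boundary (default 0.8, boundary inclusive).
#' @return A tibble with columns `parent`, `drug_id`, `fa`, `class`;
#'   attribute `exclusion_log`.
#' @export
assemble_fa_dataset <- function(db, cutoff = 0.8) {
  f <- db$formulations
  oral <- vapply(pipe_split(f$routes), function(r) "oral" %in% r, logical(1))
  f <- f[oral & !is.na(f$fa), , drop = FALSE]
  d <- dplyr::inner_join(f[, c("drug_id", "fa")],
                         db$drugs[, c("drug_id", "parent")], by = "drug_id")
  agg <- d |>
    dplyr::group_by(.data$parent) |>
    dplyr::summarise(fa = max(.data$fa), drug_id = .data$drug_id[1],
                     .groups = "drop")
  dotted <- grepl(".", agg$parent, fixed = TRUE)
  out <- agg[!dotted, c("parent", "drug_id", "fa")]
  out$class <- out$fa >= cutoff
  attr(out, "exclusion_log") <- tibble::tibble(
    parent = agg$parent[dotted], reason = "parent contains component separator")
  out
}

#' Modelability index of a labelled feature matrix
#'
#' The mean, over the two classes, of the fraction of samples whose single
#' nearest neighbour (excluding self) carries the same class. Real-valued
#' sets are z-scored when `scale = TRUE` and compared by Euclidean
#' distance; binary fingerprints use Tanimoto distance. Nearest-neighbour
#' ties are broken by the lowest index.
#'
#' @param X Feature matrix.
#' @param y Logical or 0/1 class vector.
#' @param scale Z-score columns first (for real-valued sets).
#' @param metric "euclidean" or "tanimoto".
#' @return A list with `value` (in [0, 1]), `scaled`, `metric`.
#' @export
modelability_index <- function(X, y, scale = FALSE,
                               metric = c("euclidean", "tanimoto")) {
  metric <- match.arg(metric)
  y <- as.logical(y)
  if (length(unique(y)) < 2L) {
    stop("modelability index needs both classes present", call. = FALSE)
  }
  m <- as.matrix(X)
  storage.mode(m) <- "double"
  if (scale) {
    m <- base::scale(m)
    m[!is.finite(m)] <- 0
  }
  D <- if (metric == "euclidean") {
    as.matrix(stats::dist(m))
  } else {
    tanimoto_distance_matrix(m)
  }
  diag(D) <- Inf
  nn <- apply(D, 1L, which.min) # ties: lowest index
  same <- y[nn] == y
  value <- mean(vapply(c(FALSE, TRUE), function(k) mean(same[y == k]),
                       numeric(1)))
  list(value = value, scaled = scale, metric = metric)
}

#' Classification metrics and the acceptability rule
#'
#' Sensitivity, specificity, balanced accuracy, positive and negative
#' predictive value from a confusion matrix. Metrics with a zero
#' denominator are `NA`. A model is acceptable iff balanced accuracy is at
#' least 0.6 and sensitivity, specificity, PPV and NPV are all at least
#' 0.5.
#'
#' @param tp,fn,tn,fp Nonnegative confusion-matrix counts.
#' @return A one-row tibble: `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `ppv`, `npv`, `acceptable`.
#' @export
#' @examples
#' classification_metrics(tp = 17, fn = 3, tn = 3, fp = 2)
classification_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn < 1 || tn + fp < 1) {
    stop("need at least one positive and one negative", call. = FALSE)
  }
  safe_div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  ba <- (sens + spec) / 2
  ok <- !anyNA(c(sens, spec, ppv, npv)) && ba >= 0.6 &&
    all(c(sens, spec, ppv, npv) >= 0.5)
  tibble::tibble(sensitivity = sens, specificity = spec,
                 balanced_accuracy = ba, ppv = ppv, npv = npv,
                 acceptable = ok)
}

# ---- model families ----------------------------------------------------

model_grids <- function(p) {
  list(
    decision_tree = expand.grid(
      criterion = c("gini", "information"), maxdepth = c(3L, 5L, 8L),
      minsplit = c(2L, 8L, 16L), minbucket = c(1L, 4L),
      stringsAsFactors = FALSE),
    random_forest = expand.grid(
      num_trees = 300L,
      mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 5)))),
      min_node_size = c(1L, 5L)),
    ada_boost = expand.grid(
      n_rounds = c(50L, 100L), tree_depth = c(1L, 2L),
      shrinkage = c(1, 0.5)),
    gradient_boosting = expand.grid(
      nrounds = c(50L, 150L), max_depth = c(2L, 4L), eta = c(0.1, 0.3))
  )
}

as_model_frame <- function(X) {
  df <- as.data.frame(X)
  colnames(df) <- make.names(colnames(df), unique = TRUE)
  df
}

# AdaBoost (SAMME with depth-limited CART base learners). No boosting
# implementation for classification trees is available among the package's
# dependencies, so the classic reweighting scheme is implemented here.
fit_adaboost <- function(df, y, n_rounds, tree_depth, shrinkage) {
  n <- nrow(df)
  w <- rep(1 / n, n)
  yy <- ifelse(y, 1, -1)
  learners <- list()
  alphas <- numeric()
  dat <- cbind(df, .y = factor(yy, levels = c(-1, 1)))
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = tree_depth, minsplit = 2,
                          minbucket = 1, cp = 0, xval = 0))
    pred <- ifelse(predict(fit, dat, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5) break
    alpha <- shrinkage * 0.5 * log((1 - err) / err)
    learners[[length(learners) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err <= 1e-9) break
  }
  structure(list(learners = learners, alphas = alphas), class = "ada_samme")
}

predict_adaboost <- function(object, df) {
  if (length(object$learners) == 0) return(rep(TRUE, nrow(df)))
  score <- rep(0, nrow(df))
  for (i in seq_along(object$learners)) {
    p <- ifelse(predict(object$learners[[i]], df, type = "class") == "1",
                1, -1)
    score <- score + object$alphas[i] * p
  }
  score >= 0
}

fit_family <- function(family, X, y, params, seed) {
  df <- as_model_frame(X)
  switch(family,
    decision_tree = {
      dat <- cbind(df, .y = factor(ifelse(y, "pos", "neg")))
      rpart::rpart(.y ~ ., data = dat, method = "class",
                   parms = list(split = params$criterion),
                   control = rpart::rpart.control(
                     maxdepth = params$maxdepth, minsplit = params$minsplit,
                     minbucket = params$minbucket, cp = 0, xval = 0))
    },
    random_forest = ranger::ranger(
      x = df, y = factor(ifelse(y, "pos", "neg")),
      num.trees = params$num_trees, mtry = min(params$mtry, ncol(df)),
      min.node.size = params$min_node_size, seed = seed,
      num.threads = 1L),
    ada_boost = fit_adaboost(df, y, params$n_rounds, params$tree_depth,
                             params$shrinkage),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(as.matrix(df), label = as.numeric(y)),
      nrounds = params$nrounds, verbose = 0)
  )
}

predict_family <- function(family, fit, X) {
  df <- as_model_frame(X)
  switch(family,
    decision_tree = predict(fit, df, type = "class") == "pos",
    random_forest = predict(fit, df, num.threads = 1L)$predictions == "pos",
    ada_boost = predict_adaboost(fit, df),
    gradient_boosting = predict(fit, xgboost::xgb.DMatrix(as.matrix(df))) >= 0.5
  )
}

balanced_accuracy <- function(truth, pred) {
  tp <- sum(truth & pred); fn <- sum(truth & !pred)
  tn <- sum(!truth & !pred); fp <- sum(!truth & pred)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  (sens + spec) / 2
}

# stratified fold assignment; reduces fold count with a warning when the
# minority class is smaller than the requested number of folds
stratified_folds <- function(y, folds, seed) {
  minority <- min(table(y))
  if (minority < folds) {
    warning("minority class smaller than fold count; reducing folds to ",
            minority, call. = FALSE)
    folds <- max(2L, minority)
  }
  assign <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

stratified_split <- function(y, test_size, seed) {
  test <- logical(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      n_test <- max(1L, round(length(idx) * test_size))
      test[sample(idx, n_test)] <- TRUE
    }
  })
  test
}

impute_median <- function(X_train, X_apply) {
  med <- apply(X_train, 2, function(col) {
    m <- stats::median(col[is.finite(col)])
    if (is.finite(m)) m else 0
  })
  fix <- function(M) {
    for (j in seq_len(ncol(M))) {
      bad <- !is.finite(M[, j])
      if (any(bad)) M[bad, j] <- med[j]
    }
    M
  }
  list(train = fix(X_train), apply = fix(X_apply))
}

#' Cross-validated balanced accuracy of one model configuration
#'
#' Stratified k-fold cross-validation; per-fold median imputation of
#' non-finite values is fitted on the training folds only.
#'
#' @param X Feature matrix.
#' @param y Logical labels.
#' @param family One of `"decision_tree"`, `"random_forest"`,
#'   `"ada_boost"`, `"gradient_boosting"`.
#' @param params Named list / one-row data frame of hyperparameters.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return A list with `mean`, `sd`, `per_fold`.
#' @export
cv_balanced_accuracy <- function(X, y, family, params, folds = 10L,
                                 seed = 42L) {
  assign <- stratified_folds(y, folds, seed)
  k <- max(assign)
  bas <- vapply(seq_len(k), function(fold) {
    tr <- assign != fold
    # a degenerate fold (single-class training partition) carries no signal
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
      return(NA_real_)
    }
    imp <- impute_median(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
    fit <- fit_family(family, imp$train, y[tr], params, seed + fold)
    pred <- predict_family(family, fit, imp$apply)
    balanced_accuracy(y[!tr], pred)
  }, numeric(1))
  list(mean = mean(bas, na.rm = TRUE), sd = stats::sd(bas), per_fold = bas)
}

#' Run the full Fa classification protocol
#'
#' Stratified 80/20 train/test split, 10-fold stratified grid-search
#' cross-validation per model family (decision tree, random forest,
#' adaptive boosting, gradient boosting) selecting on mean cross-validated
#' balanced accuracy, refit of the winning configuration on the full
#' training set, and a single test-set evaluation.
#'
#' @param X Feature matrix (from [featurize()] or any numeric matrix).
#' @param y Logical labels (`TRUE` = Fa at or above the cutoff).
#' @param seed Integer seed controlling split, folds and model
#'   initialisation (default 42).
#' @param test_size Test proportion (default 0.2).
#' @param folds Cross-validation folds (default 10).
#' @param families Model families to search.
#' @return A `fa_protocol` tibble: one row per family with the selected
#'   hyperparameters, CV mean/SD balanced accuracy, train and test
#'   balanced accuracy, sensitivity, specificity, PPV, NPV and the
#'   acceptability flag. Sorted by CV balanced accuracy.
#' @export
run_protocol <- function(X, y, seed = 42L, test_size = 0.2, folds = 10L,
                         families = c("decision_tree", "random_forest",
                                      "ada_boost", "gradient_boosting")) {
  y <- as.logical(y)
  stopifnot(length(unique(y)) == 2L, nrow(X) == length(y))
  if (min(table(y)) < 5L) {
    stop("minority class has fewer than 5 samples; a stratified ",
         "split-and-cross-validate protocol is not meaningful", call. = FALSE)
  }
  test <- stratified_split(y, test_size, seed)
  Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
  Xte <- X[test, , drop = FALSE]; yte <- y[test]
  grids <- model_grids(ncol(X))
  reports <- lapply(families, function(fam) {
    grid <- grids[[fam]]
    cvres <- lapply(seq_len(nrow(grid)), function(g) {
      cv_balanced_accuracy(Xtr, ytr, fam, as.list(grid[g, , drop = FALSE]),
                           folds = folds, seed = seed)
    })
    means <- vapply(cvres, `[[`, numeric(1), "mean")
    best <- which.max(means)
    params <- as.list(grid[best, , drop = FALSE])
    imp <- impute_median(Xtr, Xte)
    fit <- fit_family(fam, imp$train, ytr, params, seed)
    pred_tr <- predict_family(fam, fit, imp$train)
    pred_te <- predict_family(fam, fit, imp$apply)
    mets <- classification_metrics(
      tp = sum(yte & pred_te), fn = sum(yte & !pred_te),
      tn = sum(!yte & !pred_te), fp = sum(!yte & pred_te))
    tibble::tibble(
      family = fam, best_params = list(params),
      cv_ba_mean = means[best], cv_ba_sd = cvres[[best]]$sd,
      train_ba = balanced_accuracy(ytr, pred_tr),
      test_ba = mets$balanced_accuracy,
      sensitivity = mets$sensitivity, specificity = mets$specificity,
      ppv = mets$ppv, npv = mets$npv, acceptable = mets$acceptable)
  })
  out <- dplyr::bind_rows(reports)
  out <- out[order(-out$cv_ba_mean), ]
  attr(out, "seed") <- seed
  attr(out, "n_train") <- sum(!test)
  attr(out, "n_test") <- sum(test)
  class(out) <- c("fa_protocol", class(out))
  out
}

#' Permutation-null balanced accuracy
#'
#' Repeats cross-validation with randomly permuted labels to estimate the
#' chance-level balanced accuracy of a model family on this feature
#' matrix.
#'
#' @param X Feature matrix.
#' @param y Logical labels.
#' @param family Model family (default decision tree).
#' @param params Hyperparameters (default: a shallow tree).
#' @param n_perm Number of permutations.
#' @param folds,seed Cross-validation controls.
#' @return A list with `mean`, `per_perm`.
#' @export
permutation_null_ba <- function(X, y, family = "decision_tree",
                                params = list(criterion = "gini",
                                              maxdepth = 5L, minsplit = 8L,
                                              minbucket = 2L),
                                n_perm = 10L, folds = 5L, seed = 42L) {
  y <- as.logical(y)
  bas <- vapply(seq_len(n_perm), function(i) {
    yp <- withr::with_seed(seed + i, sample(y))
    cv_balanced_accuracy(X, yp, family, params, folds = folds,
                         seed = seed + i)$mean
  }, numeric(1))
  list(mean = mean(bas), per_perm = bas)
}

#' @method tidy fa_protocol
#' @export
tidy.fa_protocol <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$best_params <- vapply(out$best_params, function(p) {
    paste(names(p), unlist(p), sep = "=", collapse = ", ")
  }, character(1))
  out
}

#' @method glance fa_protocol
#' @export
glance.fa_protocol <- function(x, ...) {
  best <- x[1, ]
  tibble::tibble(
    best_family = best$family, cv_ba_mean = best$cv_ba_mean,
    train_ba = best$train_ba, test_ba = best$test_ba,
    acceptable = best$acceptable,
    n_train = attr(x, "n_train"), n_test = attr(x, "n_test"),
    seed = attr(x, "seed")
  )
}
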