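# Synthetic product corpus with retained ground truth: substances decorated
# with salts/solvates, excipient transactions with planted association
# rules, Fa labels from a known monotone descriptor signal, and rendered
# SmPC-style documents. Every random draw is governed by the config seed.

#' Define a planted association rule
#'
#' Describes an excipient co-occurrence pattern the generator plants into
#' transactions: whenever the antecedent item set is drawn (with probability
#' `target_support / target_confidence`), the consequent is added with
#' probability `target_confidence`, so the realized support of the combined
#' itemset concentrates on `target_support` and the realized confidence on
#' `target_confidence`.
#'
#' @param antecedent,consequent Disjoint character vectors of excipient
#'   canonical IDs.
#' @param target_support,target_confidence Proportions with
#'   `0 < target_support <= target_confidence <= 1`.
#' @param consequent_background Probability that the consequent also appears
#'   in transactions without the antecedent (keeps lift finite).
#' @return An object of class `planted_rule`.
#' @export
planted_rule <- function(antecedent, consequent, target_support,
                         target_confidence, consequent_background = 0.05) {
  stopifnot(length(antecedent) >= 1, length(consequent) >= 1)
  if (length(intersect(antecedent, consequent)) > 0) {
    stop("antecedent and consequent must be disjoint", call. = FALSE)
  }
  if (!(target_support > 0 && target_support <= target_confidence &&
        target_confidence <= 1)) {
    stop("need 0 < target_support <= target_confidence <= 1", call. = FALSE)
  }
  structure(list(antecedent = antecedent, consequent = consequent,
                 target_support = target_support,
                 target_confidence = target_confidence,
                 consequent_background = consequent_background),
            class = "planted_rule")
}

default_planted_rules <- function() {
  list(
    planted_rule("hypromellose_acetate_succinate", "croscarmellose_sodium",
                 target_support = 0.05, target_confidence = 0.70),
    planted_rule("sorbitan_monolaurate", "copovidone",
                 target_support = 0.02, target_confidence = 0.90,
                 consequent_background = 0.06)
  )
}

default_fa_coefficients <- function() {
  c(mw = -0.6, logp = 1.0, tpsa = -1.2, hbd = -0.8)
}

#' Configuration of the synthetic corpus
#'
#' Collects every knob of the generator. The defaults are the package's
#' reference study conditions: a 200-product register, a 40-item excipient
#' universe with two planted rules echoing the hypromellose acetate
#' succinate / croscarmellose sodium and sorbitan monolaurate / copovidone
#' associations, roughly a third of substances administered as salts and a
#' sixth as solvates, and an Fa signal that is a logistic function of
#' z-scored parent descriptors (negative in molecular weight, TPSA and HBD,
#' positive in logP) with a small Gaussian disturbance on the logit scale.
#'
#' @param n_products Number of products in the register.
#' @param excipient_vocab_size Number of canonical excipients in the
#'   transaction universe (taken from the shipped vocabulary).
#' @param planted_rules List of [planted_rule()] objects.
#' @param salt_fraction,solvate_fraction Proportions of substances receiving
#'   a counterion / solvent decoration.
#' @param background_item_prob Independent inclusion probability of each
#'   non-planted excipient.
#' @param fa_coefficients Named numeric vector of logit-scale weights on
#'   z-scored descriptor columns.
#' @param fa_intercept Logit-scale intercept.
#' @param fa_noise_sd Standard deviation of the Gaussian logit disturbance.
#' @param seed Integer seed; fully determines the corpus.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_products = 200L,
                             excipient_vocab_size = 40L,
                             planted_rules = default_planted_rules(),
                             salt_fraction = 0.35,
                             solvate_fraction = 0.15,
                             background_item_prob = 0.12,
                             fa_coefficients = default_fa_coefficients(),
                             fa_intercept = 2.8,
                             fa_noise_sd = 0.1,
                             seed = 1L) {
  stopifnot(n_products >= 0, excipient_vocab_size >= 1,
            salt_fraction >= 0, salt_fraction <= 1,
            solvate_fraction >= 0, solvate_fraction <= 1,
            background_item_prob >= 0, background_item_prob <= 1,
            fa_noise_sd >= 0, !is.null(names(fa_coefficients)))
  largest <- if (length(planted_rules)) {
    max(vapply(planted_rules,
               function(r) length(r$antecedent) + length(r$consequent),
               integer(1)))
  } else 0L
  if (excipient_vocab_size < largest) {
    stop("excipient_vocab_size smaller than the largest planted itemset",
         call. = FALSE)
  }
  total_support <- sum(vapply(planted_rules, `[[`, numeric(1),
                              "target_support"))
  if (total_support > 1) {
    stop("planted rule supports sum to more than 1; targets unachievable",
         call. = FALSE)
  }
  structure(list(n_products = as.integer(n_products),
                 excipient_vocab_size = as.integer(excipient_vocab_size),
                 planted_rules = planted_rules,
                 salt_fraction = salt_fraction,
                 solvate_fraction = solvate_fraction,
                 background_item_prob = background_item_prob,
                 fa_coefficients = fa_coefficients,
                 fa_intercept = fa_intercept,
                 fa_noise_sd = fa_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# solvate decorations: component smiles, how many copies, name suffix
solvate_menu <- function() {
  tibble::tibble(
    name = c("monohydrate", "dihydrate", "trihydrate", "ethanolate"),
    smiles = c("O", "O", "O", "CCO"),
    copies = c(1L, 2L, 3L, 1L)
  )
}

#' Generate synthetic administered substances
#'
#' Samples parent molecules from the embedded library and decorates a
#' proportion of them with counterion components (hydrochloride-style
#' neutral acids for basic drugs, sodium salts of the stored anion form for
#' acids) and solvent components, producing a multi-component administered
#' SMILES per record. The stored truth is the parent structure, the number
#' of solvent components and the number of parent copies.
#'
#' @param n Number of substance records.
#' @param salt_fraction,solvate_fraction Decoration probabilities.
#' @param seed Integer seed.
#' @param include_oversized Number of additional records drawn from the
#'   oversized (>1000 g/mol) mock parents, appended at the end.
#' @return A tibble with one row per record: `substance_id`, `name`,
#'   `parent_name`, `administered`, `salt_name`, `solvate_name`,
#'   `truth_parent`, `truth_n_solvent`, `truth_n_parent_copies`, `inchikey`.
#' @export
synth_substances <- function(n, salt_fraction = 0.35, solvate_fraction = 0.15,
                             seed = 1L, include_oversized = 0L) {
  if (n < 0) stop("n must be nonnegative", call. = FALSE)
  lib <- parent_library()
  core <- lib[!lib$oversized, ]
  acids <- core[!is.na(core$anion_smiles) & nzchar(core$anion_smiles), ]
  basics <- core[core$basic_amine, ]
  saltable <- unique(rbind(acids, basics))
  neutral_acid_salts <- c("hydrochloride", "hydrobromide", "mesylate",
                          "tosylate")
  salts <- salt_whitelist()
  solv <- solvate_menu()
  empty <- tibble::tibble(
    substance_id = character(), name = character(), parent_name = character(),
    administered = character(), salt_name = character(),
    solvate_name = character(), truth_parent = character(),
    truth_n_solvent = integer(), truth_n_parent_copies = integer(),
    inchikey = character()
  )
  if (n + include_oversized == 0) return(empty)
  withr::with_seed(seed, {
    rows <- vector("list", n + include_oversized)
    for (i in seq_len(n)) {
      is_salt <- stats::runif(1) < salt_fraction
      parent_row <- if (is_salt) {
        saltable[sample.int(nrow(saltable), 1L), ]
      } else {
        core[sample.int(nrow(core), 1L), ]
      }
      comps <- parent_row$smiles
      copies <- 1L
      salt_name <- NA_character_
      if (is_salt) {
        use_metal <- !is.na(parent_row$anion_smiles) &&
          nzchar(parent_row$anion_smiles) &&
          (!parent_row$basic_amine || stats::runif(1) < 0.5)
        if (use_metal) {
          # divalent anions are written as the doubled formula unit (two
          # equivalent drug anions), the pemetrexed-disodium convention; a
          # substance name therefore always maps to one structure string
          copies <- if (parent_row$anion_charge == 2L) 2L else 1L
          k <- parent_row$anion_charge * copies
          comps <- c(rep(parent_row$anion_smiles, copies), rep("[Na+]", k))
          salt_name <- if (parent_row$anion_charge == 2L) "disodium"
                       else "sodium"
        } else {
          sname <- sample(neutral_acid_salts, 1L)
          comps <- c(comps, salts$smiles[salts$name == sname])
          salt_name <- sname
        }
      }
      solvate_name <- NA_character_
      n_solvent <- 0L
      if (stats::runif(1) < solvate_fraction) {
        srow <- solv[sample.int(nrow(solv), 1L), ]
        comps <- c(comps, rep(srow$smiles, srow$copies))
        solvate_name <- srow$name
        n_solvent <- srow$copies
      }
      nm <- paste(stats::na.omit(c(parent_row$name, salt_name, solvate_name)),
                  collapse = " ")
      rows[[i]] <- tibble::tibble(
        substance_id = sprintf("SUB%04d", i), name = nm,
        parent_name = parent_row$name,
        administered = paste(comps, collapse = "."),
        salt_name = salt_name, solvate_name = solvate_name,
        truth_parent = parent_row$smiles, truth_n_solvent = n_solvent,
        truth_n_parent_copies = copies,
        inchikey = synthetic_inchikey(nm)
      )
    }
    big <- lib[lib$oversized, ]
    for (j in seq_len(include_oversized)) {
      parent_row <- big[(j - 1L) %% nrow(big) + 1L, ]
      i <- n + j
      rows[[i]] <- tibble::tibble(
        substance_id = sprintf("SUB%04d", i), name = parent_row$name,
        parent_name = parent_row$name, administered = parent_row$smiles,
        salt_name = NA_character_, solvate_name = NA_character_,
        truth_parent = parent_row$smiles, truth_n_solvent = 0L,
        truth_n_parent_copies = 1L,
        inchikey = synthetic_inchikey(parent_row$name)
      )
    }
    dplyr::bind_rows(rows)
  })
}

# item universe for transactions: planted items first, then the remaining
# canonical excipients of the shipped vocabulary
transaction_universe <- function(config) {
  planted <- unique(unlist(lapply(config$planted_rules,
                                  function(r) c(r$antecedent, r$consequent))))
  canon <- unique(excipient_vocabulary()$canonical_id)
  pool <- c(planted, setdiff(canon, planted))
  if (length(pool) < config$excipient_vocab_size) {
    stop("shipped vocabulary smaller than requested universe", call. = FALSE)
  }
  pool[seq_len(config$excipient_vocab_size)]
}

#' Generate synthetic excipient transactions
#'
#' Each transaction is the excipient set of one formulation. Non-planted
#' items enter independently with `background_item_prob`, so their pairwise
#' lifts concentrate on 1; planted rules are activated as described in
#' [planted_rule()]. Empty draws are redrawn (transactions are non-empty by
#' construction).
#'
#' @param n_products Number of transactions.
#' @param config A [synthetic_config()].
#' @return A list with `transactions` (a tibble of `transaction_id`,
#'   `items` list-column) and `truth` (per-rule realized support and
#'   confidence).
#' @export
synth_transactions <- function(n_products, config = synthetic_config()) {
  universe <- transaction_universe(config)
  planted_items <- unique(unlist(lapply(config$planted_rules,
                                        function(r) c(r$antecedent,
                                                      r$consequent))))
  background <- setdiff(universe, planted_items)
  rules <- config$planted_rules
  if (n_products == 0) {
    return(list(transactions = tibble::tibble(transaction_id = character(),
                                              items = list()),
                truth = tibble::tibble()))
  }
  withr::with_seed(config$seed + 1L, {
    items_list <- vector("list", n_products)
    for (i in seq_len(n_products)) {
      repeat {
        items <- background[stats::runif(length(background)) <
                              config$background_item_prob]
        for (r in rules) {
          p_x <- r$target_support / r$target_confidence
          if (stats::runif(1) < p_x) {
            items <- c(items, r$antecedent)
            if (stats::runif(1) < r$target_confidence) {
              items <- c(items, r$consequent)
            }
          } else if (stats::runif(1) < r$consequent_background) {
            items <- c(items, r$consequent)
          }
        }
        items <- unique(items)
        if (length(items) > 0) break
      }
      items_list[[i]] <- items
    }
    tx <- tibble::tibble(transaction_id = sprintf("TX%05d",
                                                  seq_len(n_products)),
                         items = items_list)
    truth <- dplyr::bind_rows(lapply(rules, function(r) {
      both <- vapply(items_list, function(it) {
        all(c(r$antecedent, r$consequent) %in% it)
      }, logical(1))
      ante <- vapply(items_list, function(it) all(r$antecedent %in% it),
                     logical(1))
      tibble::tibble(
        antecedent = paste(r$antecedent, collapse = "|"),
        consequent = paste(r$consequent, collapse = "|"),
        target_support = r$target_support,
        target_confidence = r$target_confidence,
        realized_support = mean(both),
        realized_confidence = if (any(ante)) sum(both) / sum(ante) else NA_real_
      )
    }))
    list(transactions = tx, truth = truth)
  })
}

#' Generate synthetic oral fraction absorbed values
#'
#' Computes `Fa = logistic(intercept + b * z(x) + e)` with
#' `e ~ Normal(0, fa_noise_sd)`, where `z(x)` are the column-z-scored
#' descriptors named by `fa_coefficients`. The class label is
#' `Fa >= cutoff` (cutoff 0.8).
#'
#' @param descriptor_matrix Numeric matrix or data frame whose column names
#'   cover `names(config$fa_coefficients)`.
#' @param config A [synthetic_config()].
#' @param cutoff Class cutoff on Fa.
#' @return A tibble with columns `fa`, `class` (logical), `logit_signal`
#'   (the noiseless linear predictor).
#' @export
synth_fa <- function(descriptor_matrix, config = synthetic_config(),
                     cutoff = 0.8) {
  dmat <- as.data.frame(descriptor_matrix)
  missing_cols <- setdiff(names(config$fa_coefficients), colnames(dmat))
  if (length(missing_cols)) {
    stop("descriptor matrix lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(dmat[, names(config$fa_coefficients), drop = FALSE])
  Z <- scale(X)
  Z[!is.finite(Z)] <- 0 # constant columns carry no signal
  lp <- drop(config$fa_intercept + Z %*% config$fa_coefficients)
  withr::with_seed(config$seed + 2L, {
    eps <- stats::rnorm(nrow(X), 0, config$fa_noise_sd)
    fa <- stats::plogis(lp + eps)
    fa <- pmin(pmax(fa, 0), 1)
    tibble::tibble(fa = fa, class = fa >= cutoff, logit_signal = lp)
  })
}
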