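# Frequent-itemset mining over excipient transactions and the
# descriptor/excipient hypothesis screen. The levelwise apriori search and
# the support/confidence/lift arithmetic are implemented here directly:
# they are the analytical core of the module, and the test suite holds them
# against an exhaustive power-set oracle.

# transactions: list of character vectors, or a tibble with an `items`
# list-column. Returns the incidence matrix and item labels.
transaction_matrix <- function(transactions) {
  items_list <- if (is.data.frame(transactions)) transactions$items
                else transactions
  if (length(items_list) == 0) stop("no transactions", call. = FALSE)
  items_list <- lapply(items_list, unique)
  labels <- sort(unique(unlist(items_list)))
  m <- matrix(FALSE, nrow = length(items_list), ncol = length(labels),
              dimnames = list(NULL, labels))
  for (i in seq_along(items_list)) {
    m[i, match(items_list[[i]], labels)] <- TRUE
  }
  m
}

itemset_support <- function(m, cols) {
  if (length(cols) == 1L) mean(m[, cols]) else mean(rowSums(m[, cols]) ==
                                                      length(cols))
}

#' Mine frequent itemsets with the apriori algorithm
#'
#' Levelwise search with anti-monotone pruning: level-k candidates are
#' joins of frequent (k-1)-itemsets sharing their first k-2 items, pruned
#' if any (k-1)-subset is infrequent, then support-counted against the
#' transactions. An itemset is returned iff its support (the proportion of
#' transactions containing it) is at least `min_support`; by construction
#' every subset of a returned itemset is also returned.
#'
#' @param transactions A list of item character vectors, or a tibble with
#'   an `items` list-column.
#' @param min_support Minimum support, in (0, 1].
#' @return A tibble with columns `items` (list-column, sorted), `size`,
#'   `support`, ordered by size then support.
#' @export
#' @examples
#' mine_frequent_itemsets(list(c("a","b"), c("a","b"), c("a","c"),
#'                             c("b","c")), min_support = 0.5)
mine_frequent_itemsets <- function(transactions, min_support) {
  stopifnot(min_support > 0, min_support <= 1)
  m <- transaction_matrix(transactions)
  labels <- colnames(m)
  sup1 <- colMeans(m)
  frequent <- list()
  level <- lapply(which(sup1 >= min_support), function(j) j)
  for (s in level) {
    frequent[[length(frequent) + 1L]] <-
      list(cols = s, support = sup1[s])
  }
  while (length(level) > 0) {
    k <- length(level[[1]]) + 1L
    prev_keys <- vapply(level, paste, character(1), collapse = ",")
    cand <- list()
    # join step: pairs sharing the first k-2 items
    for (a in seq_along(level)) {
      for (b in seq_along(level)) {
        if (b <= a) next
        ia <- level[[a]]; ib <- level[[b]]
        if (k > 2 && !identical(ia[-(k - 1L)], ib[-(k - 1L)])) next
        if (ia[k - 1L] >= ib[k - 1L]) next
        c_new <- c(ia, ib[k - 1L])
        # prune: every (k-1)-subset must be frequent
        ok <- all(vapply(seq_along(c_new), function(drop) {
          paste(c_new[-drop], collapse = ",") %in% prev_keys
        }, logical(1)))
        if (ok) cand[[length(cand) + 1L]] <- c_new
      }
    }
    nxt <- list()
    for (cc in cand) {
      s <- itemset_support(m, cc)
      if (s >= min_support) {
        nxt[[length(nxt) + 1L]] <- cc
        frequent[[length(frequent) + 1L]] <- list(cols = cc, support = s)
      }
    }
    level <- nxt
  }
  if (length(frequent) == 0) {
    return(tibble::tibble(items = list(), size = integer(),
                          support = numeric()))
  }
  out <- tibble::tibble(
    items = lapply(frequent, function(f) labels[f$cols]),
    size = vapply(frequent, function(f) length(f$cols), integer(1)),
    support = vapply(frequent, function(f) f$support, numeric(1))
  )
  out[order(out$size, -out$support), ]
}

#' Derive association rules from frequent itemsets
#'
#' Evaluates every nonempty bipartition X => Y of each frequent itemset of
#' size two or more. Support is the proportion of transactions containing
#' X and Y together; confidence is support(X u Y) / support(X); lift is
#' confidence / support(Y). A rule is kept iff its confidence is at least
#' `min_confidence` and its lift exceeds `min_lift`.
#'
#' @param itemsets Output of [mine_frequent_itemsets()] (closed under
#'   subsets, so every support needed is available exactly).
#' @param min_confidence Minimum confidence (default 0.6).
#' @param min_lift Rules must have lift strictly above this (default 1).
#' @return A tibble with columns `antecedent`, `consequent` (list-columns),
#'   `support`, `confidence`, `lift`; class `assoc_rules`.
#' @export
derive_rules <- function(itemsets, min_confidence = 0.6, min_lift = 1) {
  sup_lookup <- stats::setNames(
    itemsets$support,
    vapply(itemsets$items, function(it) paste(sort(it), collapse = ","),
           character(1)))
  get_sup <- function(it) {
    s <- sup_lookup[[paste(sort(it), collapse = ",")]]
    if (is.null(s)) NA_real_ else s
  }
  rows <- list()
  big <- itemsets[itemsets$size >= 2L, , drop = FALSE]
  for (r in seq_len(nrow(big))) {
    it <- big$items[[r]]
    s_all <- big$support[r]
    k <- length(it)
    for (mask in seq_len(2^k - 2L)) {
      sel <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
      X <- it[sel]; Y <- it[!sel]
      s_x <- get_sup(X); s_y <- get_sup(Y)
      conf <- s_all / s_x
      lift <- conf / s_y
      if (!is.na(conf) && conf >= min_confidence &&
          !is.na(lift) && lift > min_lift) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          antecedent = list(sort(X)), consequent = list(sort(Y)),
          support = s_all, confidence = conf, lift = lift)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(antecedent = list(), consequent = list(),
                   support = numeric(), confidence = numeric(),
                   lift = numeric())
  }
  out <- out[order(-out$lift), ]
  class(out) <- c("assoc_rules", class(out))
  out
}

#' Mine association rules from a database
#'
#' Convenience wrapper: restricts formulations to oral immediate-release
#' tablets (the default mining scope), treats each formulation's excipient
#' list as a transaction, and runs [mine_frequent_itemsets()] plus
#' [derive_rules()].
#'
#' @param db A `pharm_db`.
#' @param min_support,min_confidence,min_lift Thresholds (defaults 0.01,
#'   0.6, 1).
#' @param oral_ir_only Restrict to oral immediate-release tablets.
#' @return An `assoc_rules` tibble; attribute `n_transactions`.
#' @export
mine_formulation_rules <- function(db, min_support = 0.01,
                                   min_confidence = 0.6, min_lift = 1,
                                   oral_ir_only = TRUE) {
  f <- db$formulations
  if (oral_ir_only) {
    oral <- vapply(pipe_split(f$routes), function(r) "oral" %in% r,
                   logical(1))
    f <- f[oral & f$dosage_form %in% "tablet" & !f$modified_release, ,
           drop = FALSE]
  }
  tx <- pipe_split(f$excipient_ids)
  tx <- tx[lengths(tx) > 0]
  itemsets <- mine_frequent_itemsets(tx, min_support)
  rules <- derive_rules(itemsets, min_confidence, min_lift)
  attr(rules, "n_transactions") <- length(tx)
  rules
}

#' Build the neighbourhood network of rules around focus items
#'
#' Keeps rules with at most `max_antecedent` antecedent and
#' `max_consequent` consequent items that involve a focus item, collects
#' the items of those rules as the node set, and then also includes rules
#' entirely between retained nodes. Edges point from antecedent to
#' consequent and carry confidence and lift.
#'
#' @param rules An `assoc_rules` tibble.
#' @param focus_items Character vector of item IDs of interest.
#' @param max_antecedent,max_consequent Maximum itemset sizes (default 1).
#' @return An igraph directed graph with edge attributes `confidence`,
#'   `lift`, `support`.
#' @export
rule_subnetwork <- function(rules, focus_items, max_antecedent = 1L,
                            max_consequent = 1L) {
  small <- rules[lengths(rules$antecedent) <= max_antecedent &
                   lengths(rules$consequent) <= max_consequent, ,
                 drop = FALSE]
  involves <- vapply(seq_len(nrow(small)), function(i) {
    any(focus_items %in% c(small$antecedent[[i]], small$consequent[[i]]))
  }, logical(1))
  seedset <- small[involves, , drop = FALSE]
  nodes <- unique(unlist(c(seedset$antecedent, seedset$consequent)))
  within <- vapply(seq_len(nrow(small)), function(i) {
    all(c(small$antecedent[[i]], small$consequent[[i]]) %in% nodes)
  }, logical(1))
  keep <- small[involves | within, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(igraph::make_empty_graph(directed = TRUE))
  }
  edges <- tibble::tibble(
    from = vapply(keep$antecedent, paste, character(1), collapse = "+"),
    to = vapply(keep$consequent, paste, character(1), collapse = "+"),
    confidence = keep$confidence, lift = keep$lift, support = keep$support
  )
  igraph::graph_from_data_frame(edges, directed = TRUE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min_{j >= i} ( m p_(j) / j )`, capped at 1, mapped back to
#' the input order.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  if (m == 0) return(numeric())
  o <- order(pvalues)
  scaled <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Screen excipient membership against drug descriptors
#'
#' For every excipient formulated with at least `min_n` of the supplied
#' drugs, compares each descriptor's distribution between drugs formulated
#' with and without the excipient using a two-sided Mann-Whitney U test
#' (tie-corrected normal approximation), then adjusts all p-values jointly
#' with Benjamini-Hochberg.
#'
#' @param descriptor_table A tibble with a `drug_id` column and numeric
#'   descriptor columns.
#' @param membership A tibble with columns `drug_id`, `excipient_id` (one
#'   row per pairing).
#' @param descriptors Character vector of descriptor column names to test
#'   (default: all numeric columns).
#' @param min_n Minimum drugs formulated with the excipient (default 10).
#' @param alpha Significance threshold applied to adjusted p (default
#'   0.05).
#' @return A tibble: `excipient_id`, `descriptor`, `n_with`, `n_without`,
#'   `statistic` (U for the with-group), `p_value`, `p_adjusted`,
#'   `significant`, `direction` (sign of the with-group median shift).
#' @export
excipient_descriptor_screen <- function(descriptor_table, membership,
                                        descriptors = NULL, min_n = 10L,
                                        alpha = 0.05) {
  stopifnot("drug_id" %in% names(descriptor_table))
  if (is.null(descriptors)) {
    descriptors <- names(descriptor_table)[vapply(descriptor_table,
                                                  is.numeric, logical(1))]
  }
  counts <- table(membership$excipient_id[
    membership$drug_id %in% descriptor_table$drug_id])
  eligible <- names(counts)[counts >= min_n]
  rows <- list()
  for (e in eligible) {
    with_ids <- membership$drug_id[membership$excipient_id == e]
    in_grp <- descriptor_table$drug_id %in% with_ids
    if (sum(in_grp) == 0 || sum(!in_grp) == 0) next
    for (d in descriptors) {
      x <- descriptor_table[[d]][in_grp]
      y <- descriptor_table[[d]][!in_grp]
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                           correct = TRUE))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        excipient_id = e, descriptor = d,
        n_with = length(x), n_without = length(y),
        statistic = unname(wt$statistic), p_value = wt$p.value,
        direction = sign(stats::median(x) - stats::median(y))
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(excipient_id = character(),
                          descriptor = character(), n_with = integer(),
                          n_without = integer(), statistic = numeric(),
                          p_value = numeric(), p_adjusted = numeric(),
                          significant = logical(), direction = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- benjamini_hochberg(out$p_value)
  out$significant <- out$p_adjusted < alpha
  out[order(out$p_adjusted, out$p_value), ]
}
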