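# Independent oracles used across the suite. Each deliberately takes the
# dumbest correct route (enumeration, direct formula, explicit loops) and
# shares no code with the implementation it checks.

# -- molecular weight from a molecular formula and an atomic-mass table ----

oracle_atomic_masses <- c(
  H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994, F = 18.9984032,
  Na = 22.98977, Mg = 24.305, P = 30.973762, S = 32.065, Cl = 35.453,
  K = 39.0983, Ca = 40.078, Br = 79.904, I = 126.90447
)

# "C9H8O4" -> 180.16; element symbols are one capital + optional lower
oracle_formula_mass <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)
  parts <- regmatches(formula, m)[[1]]
  total <- 0
  for (p in parts) {
    g <- regmatches(p, regexec("([A-Z][a-z]?)([0-9]*)", p))[[1]]
    n <- if (nzchar(g[3])) as.integer(g[3]) else 1L
    mass <- oracle_atomic_masses[[g[2]]]
    if (is.null(mass)) stop("oracle has no mass for ", g[2])
    total <- total + n * mass
  }
  total
}

# -- exhaustive frequent-itemset enumeration -------------------------------

oracle_powerset_itemsets <- function(transactions, min_support) {
  items <- sort(unique(unlist(transactions)))
  stopifnot(length(items) <= 12)
  out <- list()
  for (k in seq_along(items)) {
    combos <- utils::combn(items, k, simplify = FALSE)
    for (s in combos) {
      sup <- mean(vapply(transactions, function(t) all(s %in% t),
                         logical(1)))
      if (sup >= min_support) {
        out[[length(out) + 1L]] <- list(items = s, support = sup)
      }
    }
  }
  out
}

# -- Benjamini-Hochberg directly from the definition -----------------------

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (rank_i in seq_len(m)) {
    candidates <- vapply(rank_i:m, function(j) m * p[o[j]] / j, numeric(1))
    adj[o[rank_i]] <- min(1, min(candidates))
  }
  adj
}

# -- MODI with explicit O(n^2) loops ---------------------------------------

oracle_modi <- function(X, y) {
  n <- nrow(X)
  same <- logical(n)
  for (i in seq_len(n)) {
    best <- Inf; best_j <- NA_integer_
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (d < best) { best <- d; best_j <- j }
    }
    same[i] <- y[best_j] == y[i]
  }
  mean(c(mean(same[y]), mean(same[!y])))
}

# -- Tanimoto distance from explicit bit sets ------------------------------

oracle_tanimoto <- function(a, b) {
  sa <- which(a == 1); sb <- which(b == 1)
  u <- length(union(sa, sb))
  if (u == 0) return(0)
  1 - length(intersect(sa, sb)) / u
}

# -- exact two-sided Mann-Whitney p by enumeration (tiny n) ----------------

oracle_mw_exact_p <- function(x, y) {
  nx <- length(x); all_v <- c(x, y)
  u_stat <- function(ix) {
    xx <- all_v[ix]; yy <- all_v[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_stat(seq_len(nx))
  combos <- utils::combn(length(all_v), nx, simplify = FALSE)
  us <- vapply(combos, u_stat, numeric(1))
  mu <- nx * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}
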