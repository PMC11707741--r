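# Drug-likeness: the six rule descriptors, named rulesets, conformance
# summaries, MACCS Tanimoto distances and 2D chemical-space projections.

lipinski_smarts <- c(
  hbd = "[#7,#8;!H0]",   # N or O carrying at least one hydrogen
  hba = "[#7,#8]",       # simple Lipinski acceptor convention: N + O count
  rbc = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]" # non-ring single bonds, no terminals
)

#' Compute the six rule descriptors for parent structures
#'
#' Molecular weight, Wildman-Crippen logP, H-bond donor and acceptor counts
#' (simple Lipinski convention: OH/NH donors, N+O acceptors), rotatable
#' bond count and topological polar surface area. Inputs must be
#' single-component structures (the parent form).
#'
#' @param parents Character vector of single-component SMILES.
#' @return A tibble with columns `smiles`, `mw`, `logp`, `hbd`, `hba`,
#'   `rbc`, `tpsa`.
#' @export
#' @examples
#' compute_descriptors("CCO")
compute_descriptors <- function(parents) {
  if (any(n_components(parents) > 1L, na.rm = TRUE)) {
    stop("descriptors are defined on single-component parent structures",
         call. = FALSE)
  }
  props <- ob_properties(parents)
  if (any(is.na(props$mw))) {
    stop("unparseable structure(s): ",
         paste(utils::head(parents[is.na(props$mw)], 5), collapse = ", "),
         call. = FALSE)
  }
  counts <- smarts_counts(parents, lipinski_smarts)
  tibble::tibble(
    smiles = parents, mw = props$mw, logp = props$logp,
    hbd = as.integer(counts$hbd), hba = as.integer(counts$hba),
    rbc = as.integer(counts$rbc), tpsa = props$tpsa
  )
}

#' Named drug-likeness rulesets
#'
#' Bounds for the Rule of Five, Veber's rules, and the extended and
#' contemporary extensions of the Rule of Five. Ro5 and Veber bounds are
#' the classic published values; the eRo5 and cRo5 bounds are transcribed
#' from their original publications (`origin = "from-citation"`) and are
#' plain data, editable by passing a modified list to the evaluation
#' functions. All bounds are inclusive.
#'
#' @return A named list of rulesets; each ruleset is a tibble with columns
#'   `descriptor`, `lower`, `upper`.
#' @export
default_rulesets <- function() {
  rs <- function(...) {
    b <- list(...)
    tibble::tibble(
      descriptor = names(b),
      lower = vapply(b, `[[`, numeric(1), 1L),
      upper = vapply(b, `[[`, numeric(1), 2L)
    )
  }
  list(
    ro5   = rs(mw = c(-Inf, 500), logp = c(-Inf, 5), hbd = c(-Inf, 5),
               hba = c(-Inf, 10)),
    veber = rs(rbc = c(-Inf, 10), tpsa = c(-Inf, 140)),
    ero5  = rs(mw = c(-Inf, 1000), logp = c(-2, 10), hbd = c(-Inf, 6),
               hba = c(-Inf, 15), tpsa = c(-Inf, 250), rbc = c(-Inf, 20)),
    cro5  = rs(mw = c(-Inf, 700), logp = c(-2, 7.5), hbd = c(-Inf, 5),
               hba = c(-Inf, 10), tpsa = c(-Inf, 200), rbc = c(-Inf, 20))
  )
}

#' Evaluate one descriptor vector against one ruleset
#'
#' Bounds are inclusive: a compound sitting exactly on a limit passes.
#'
#' @param descriptors A named numeric vector (or 1-row data frame) holding
#'   at least the descriptors the ruleset bounds.
#' @param ruleset A tibble with columns `descriptor`, `lower`, `upper`.
#' @return A list with `per_criterion` (named logical, TRUE = satisfied),
#'   `pass` (all criteria satisfied) and `violations` (count of failures).
#' @export
evaluate_ruleset <- function(descriptors, ruleset) {
  if (is.data.frame(descriptors)) {
    stopifnot(nrow(descriptors) == 1L)
    descriptors <- unlist(descriptors[vapply(descriptors, is.numeric,
                                             logical(1))])
  }
  missing_d <- setdiff(ruleset$descriptor, names(descriptors))
  if (length(missing_d)) {
    stop("ruleset bounds unknown descriptor(s): ",
         paste(missing_d, collapse = ", "), call. = FALSE)
  }
  v <- descriptors[ruleset$descriptor]
  ok <- v >= ruleset$lower & v <= ruleset$upper
  names(ok) <- ruleset$descriptor
  list(per_criterion = ok, pass = all(ok), violations = sum(!ok))
}

# vectorized violation counts for a descriptor table against one ruleset
ruleset_violations <- function(tbl, ruleset) {
  m <- as.matrix(tbl[, ruleset$descriptor, drop = FALSE])
  lower <- matrix(ruleset$lower, nrow(m), ncol(m), byrow = TRUE)
  upper <- matrix(ruleset$upper, nrow(m), ncol(m), byrow = TRUE)
  rowSums(!(m >= lower & m <= upper))
}

#' Summarize ruleset conformance over a compound set
#'
#' Reports, per ruleset, the percentage of compounds conforming to every
#' criterion (rounded to 0.1), the number of compounds violating more than
#' one Rule-of-Five criterion, and how many compounds exceed 500 g/mol
#' under the two molecular-weight definitions: the salt-inclusive formula
#' weight of the desolvated substance per parent molecule (`molwt1`) and
#' the parent molecular weight (`molwt2`, the `mw` column).
#'
#' @param descriptors A descriptor tibble from [compute_descriptors()].
#' @param rulesets A named list of rulesets, default [default_rulesets()].
#' @param molwt1 Optional numeric vector of formula weights aligned with
#'   `descriptors`.
#' @return A list with `percent_conforming` (named numeric),
#'   `violation_counts` (per-compound Ro5 violation counts),
#'   `n_multi_ro5_violators`, `n_over_500_molwt1`, `n_over_500_molwt2`.
#' @export
conformance_summary <- function(descriptors, rulesets = default_rulesets(),
                                molwt1 = NULL) {
  stopifnot(nrow(descriptors) >= 1L)
  n <- nrow(descriptors)
  pct <- vapply(rulesets, function(rs) {
    round(100 * mean(ruleset_violations(descriptors, rs) == 0), 1L)
  }, numeric(1))
  ro5_viol <- if ("ro5" %in% names(rulesets)) {
    ruleset_violations(descriptors, rulesets$ro5)
  } else {
    rep(NA_integer_, n)
  }
  list(
    n = n,
    percent_conforming = pct,
    violation_counts = ro5_viol,
    n_multi_ro5_violators = sum(ro5_viol > 1, na.rm = TRUE),
    n_over_500_molwt1 = if (is.null(molwt1)) NA_integer_
                        else sum(molwt1 > 500, na.rm = TRUE),
    n_over_500_molwt2 = sum(descriptors$mw > 500, na.rm = TRUE)
  )
}

#' MACCS fingerprints for a set of structures
#'
#' @param smiles Character vector of SMILES.
#' @return Integer 0/1 matrix with 166 columns.
#' @export
maccs_fingerprints <- function(smiles) {
  ob_fingerprints(smiles, "MACCS")
}

#' Pairwise Tanimoto distance matrix of binary fingerprints
#'
#' `d(i,j) = 1 - |Fi & Fj| / |Fi | Fj|`; a pair of all-zero fingerprints is
#' assigned distance 0.
#'
#' @param fingerprints A 0/1 matrix, one fingerprint per row.
#' @return A symmetric numeric matrix with zero diagonal, values in [0,1].
#' @export
tanimoto_distance_matrix <- function(fingerprints) {
  m <- as.matrix(fingerprints)
  if (any(is.na(m))) stop("fingerprints contain NA", call. = FALSE)
  storage.mode(m) <- "numeric"
  inter <- m %*% t(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0 # all-zero vs all-zero
  d[!is.finite(d)] <- 0
  diag(d) <- 0
  unname((d + t(d)) / 2)
}

#' Project compounds into a 2D chemical-space map
#'
#' `method = "pca"` expects a numeric descriptor matrix (z-score it first,
#' or set `scale = TRUE`) and returns the first two principal components
#' with explained-variance ratios. `method = "tsne"` expects a precomputed
#' symmetric distance matrix and a seed, and returns stochastic-neighbour
#' coordinates with the final Kullback-Leibler divergence.
#'
#' @param data Numeric matrix (pca) or distance matrix (tsne).
#' @param method "pca" or "tsne".
#' @param scale For pca, z-score columns first.
#' @param seed,perplexity,max_iter t-SNE controls.
#' @return A tibble with columns `id`, `x`, `y`; attribute
#'   `explained_variance` (pca, full ratio vector) or `kl_divergence`
#'   (tsne). Class `chem_space` for [autoplot.chem_space()].
#' @export
embed_chemical_space <- function(data, method = c("pca", "tsne"),
                                 scale = FALSE, seed = 42L, perplexity = 30,
                                 max_iter = 500L) {
  method <- match.arg(method)
  if (nrow(data) < 3L) stop("need at least 3 points", call. = FALSE)
  if (method == "pca") {
    m <- as.matrix(data)
    if (scale) {
      m <- base::scale(m)
      m <- m[, apply(is.finite(m), 2, all), drop = FALSE]
    }
    p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    ev <- p$sdev^2 / sum(p$sdev^2)
    out <- tibble::tibble(id = seq_len(nrow(m)),
                          x = p$x[, 1], y = p$x[, 2])
    attr(out, "explained_variance") <- ev
  } else {
    ts <- tsne_embed(as.matrix(data), perplexity = perplexity,
                     max_iter = max_iter, seed = seed)
    out <- tibble::tibble(id = seq_len(nrow(ts$coords)),
                          x = ts$coords[, 1], y = ts$coords[, 2])
    attr(out, "kl_divergence") <- ts$kl
  }
  attr(out, "method") <- method
  class(out) <- c("chem_space", class(out))
  out
}
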