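# Structure curation: from the administered (salt/solvate) form of an active
# substance down to the desolvated form and the single-component neutral
# parent. Removal order is fixed: solvents first, then counterions; the
# whitelists are the same data files the synthetic corpus generator uses.

# Net formal charge of a single-component SMILES, by scanning bracket atoms.
net_formal_charge <- function(smiles) {
  vapply(smiles, function(s) {
    brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    total <- 0L
    for (b in brackets) {
      ch <- regmatches(b, regexec("([+-])([0-9]*)\\]$", b))[[1]]
      if (length(ch)) {
        mag <- if (nzchar(ch[3])) as.integer(ch[3]) else 1L
        total <- total + if (ch[2] == "+") mag else -mag
      } else {
        # runs like [O--] or [Ca++]
        run <- regmatches(b, regexec("(\\++|-+)\\]$", b))[[1]]
        if (length(run)) {
          total <- total + nchar(run[2]) *
            (if (substr(run[2], 1, 1) == "+") 1L else -1L)
        }
      }
    }
    total
  }, integer(1), USE.NAMES = FALSE)
}

# Neutralize protonation-state charges in a SMILES component: anions gain a
# hydrogen, protonated amines lose one. Only components with a nonzero net
# formal charge are touched, so internally charge-separated groups (nitro,
# N-oxides, zwitterion-balanced forms) pass through unchanged.
neutralize_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    q <- net_formal_charge(s)
    if (q < 0) {
      s <- gsub("[O-]", "O", s, fixed = TRUE)
      s <- gsub("[S-]", "S", s, fixed = TRUE)
      s <- gsub("[N-]", "N", s, fixed = TRUE)
      s <- gsub("[n-]", "[nH]", s, fixed = TRUE)
    } else if (q > 0) {
      s <- gsub("[NH+]", "N", s, fixed = TRUE)
      s <- gsub("[NH2+]", "N", s, fixed = TRUE)
      s <- gsub("[NH3+]", "N", s, fixed = TRUE)
      s <- gsub("[nH+]", "[nH]", s, fixed = TRUE)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

# Canonical forms of whitelist entries, including their neutralized
# variants, so that e.g. mesylate matches whether drawn as the free acid or
# the anion.
whitelist_canon <- function(tbl) {
  unique(c(tbl$smiles, canonical_smiles(neutralize_smiles(tbl$smiles))))
}

#' Standardize a structure string
#'
#' Canonicalizes each structure (multi-component strings keep their
#' components) so that equal molecules yield equal strings. Idempotent.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES.
#' @export
standardize_structure <- function(smiles) {
  canonical_smiles(smiles)
}

#' Remove solvent components from a structure
#'
#' Drops every component that matches the shared solvent whitelist (water,
#' ethanol, ...), keeping counterions and the drug. Idempotent; charge is
#' untouched. Errors if nothing would remain.
#'
#' @param smiles Character vector of (possibly multi-component) SMILES.
#' @return Character vector of desolvated canonical SMILES.
#' @export
#' @examples
#' strip_solvates("CCN(CC)CC(=O)Nc1c(C)cccc1C.Cl.O.O") # drops the waters
strip_solvates <- function(smiles) {
  solv <- solvent_whitelist()$smiles
  vapply(smiles, function(s) {
    comps <- canonical_smiles(smiles_components(canonical_smiles(s))[[1]])
    keep <- comps[!comps %in% solv]
    if (length(keep) == 0L) {
      stop("no component left after solvent removal: ", s, call. = FALSE)
    }
    canonical_smiles(paste(keep, collapse = "."))
  }, character(1), USE.NAMES = FALSE)
}

#' Derive the parent molecule of an administered structure
#'
#' Removes solvent components, then counterion components (both per the
#' shared whitelists), neutralizes protonation-state charges on what
#' remains, deduplicates identical components (a disodium salt drawn as two
#' equivalent anions collapses to one parent), and returns the single
#' remaining component. If several distinct components remain, the one with
#' the longest SMILES string is selected and a warning is emitted, since an
#' unusually large counterion or coformer could be mistaken for the drug.
#' Idempotent. Errors if the whitelists remove everything.
#'
#' @param smiles Character vector of (possibly multi-component) SMILES.
#' @return Character vector of single-component neutral canonical SMILES.
#' @export
get_parent <- function(smiles) {
  salts <- whitelist_canon(salt_whitelist())
  solv <- whitelist_canon(solvent_whitelist())
  vapply(smiles, function(s) {
    comps <- canonical_smiles(smiles_components(canonical_smiles(s))[[1]])
    comps <- comps[!comps %in% solv]
    comps <- comps[!comps %in% salts]
    if (length(comps) == 0L) {
      stop("no parent component: whitelists removed every component of ", s,
           call. = FALSE)
    }
    comps <- unique(canonical_smiles(neutralize_smiles(comps)))
    if (length(comps) > 1L) {
      picked <- identify_active_component(paste(comps, collapse = "."))
      warning("multiple distinct components after stripping; ",
              "selected longest SMILES: ", picked, call. = FALSE)
      comps <- picked
    }
    comps
  }, character(1), USE.NAMES = FALSE)
}

#' Select the active component of a multi-component structure
#'
#' Returns the component with the longest SMILES string, the working rule
#' for picking the drug out of a salt. Ties are broken lexicographically
#' (and logged via message).
#'
#' @param smiles A single (possibly multi-component) SMILES string.
#' @return A single-component SMILES string.
#' @export
identify_active_component <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  comps <- smiles_components(smiles)[[1]]
  if (length(comps) == 0L) stop("empty structure", call. = FALSE)
  len <- nchar(comps)
  cand <- comps[len == max(len)]
  if (length(cand) > 1L) {
    cand <- sort(cand)
    message("tie on component length; broke lexicographically: ", cand[1])
  }
  cand[1]
}

#' Formula weight of a desolvated substance per parent molecule
#'
#' Total average molecular weight of every component of the desolvated
#' structure (drug plus any counterions), divided by the number of parent
#' drug molecules present. This is the salt-inclusive molecular weight used
#' alongside the parent molecular weight in drug-likeness summaries.
#'
#' @param desolvated Character vector of desolvated SMILES.
#' @param n_parent_copies Positive integer vector (recycled) of parent
#'   copies per structure string.
#' @return Numeric vector in g/mol.
#' @export
formula_weight <- function(desolvated, n_parent_copies = 1L) {
  n <- vctrs_recycle(n_parent_copies, length(desolvated))
  if (any(!is.finite(n) | n < 1)) {
    stop("n_parent_copies must be >= 1", call. = FALSE)
  }
  molecular_weight(desolvated) / n
}

vctrs_recycle <- function(x, n) {
  if (length(x) == 1L) rep(x, n) else {
    stopifnot(length(x) == n)
    x
  }
}

#' Count parent copies in a desolvated structure
#'
#' Number of components of `desolvated` whose neutralized canonical form
#' equals the parent structure.
#'
#' @param desolvated Character vector of desolvated SMILES.
#' @param parent Character vector (recycled) of parent SMILES.
#' @return Integer vector, at least 1.
#' @export
count_parent_copies <- function(desolvated, parent) {
  parent <- vctrs_recycle(parent, length(desolvated))
  parent <- canonical_smiles(parent)
  vapply(seq_along(desolvated), function(i) {
    comps <- canonical_smiles(
      neutralize_smiles(smiles_components(canonical_smiles(desolvated[i]))[[1]])
    )
    max(1L, sum(comps == parent[i]))
  }, integer(1))
}

#' Filter a substance table on parent molecular weight
#'
#' Retains rows whose parent molecular weight is at or below `cutoff`
#' (default 1000 g/mol). Exclusions are reported in the `excluded`
#' attribute.
#'
#' @param records A data frame with a `parent` SMILES column.
#' @param cutoff Molecular-weight cutoff in g/mol.
#' @return The retained rows, with attribute `excluded` holding the others
#'   (with their weights).
#' @export
apply_size_filter <- function(records, cutoff = 1000) {
  stopifnot(is.data.frame(records), "parent" %in% names(records))
  mw <- molecular_weight(records$parent)
  keep <- !is.na(mw) & mw <= cutoff
  out <- tibble::as_tibble(records[keep, , drop = FALSE])
  excl <- tibble::as_tibble(records[!keep, , drop = FALSE])
  excl$parent_mw <- mw[!keep]
  attr(out, "excluded") <- excl
  out
}

#' Resolve substance names against an identifier dictionary
#'
#' Case-insensitive lookup of substance names in a dictionary table mapping
#' names to identifier and structure, building the administered/desolvated/
#' parent structure set for each hit. Unmatched names are collected in a
#' review queue rather than raising; conflicting dictionary rows for one
#' name raise an error listing them.
#'
#' @param names Character vector of substance names.
#' @param map A data frame with columns `name`, `inchikey`, `smiles`.
#' @return A tibble with one row per input name: `name`, `inchikey`,
#'   `administered`, `desolvated`, `parent`, `n_parent_copies`, `resolved`.
#'   Unresolved rows have `resolved = FALSE`; the attribute `review_queue`
#'   lists them.
#' @export
resolve_identifiers <- function(names, map) {
  stopifnot(all(c("name", "inchikey", "smiles") %in% names(map)))
  key <- tolower(trimws(map$name))
  dup <- unique(key[duplicated(key)])
  for (d in dup) {
    rows <- unique(map$smiles[key == d])
    if (length(rows) > 1L) {
      stop("conflicting dictionary rows for '", d, "': ",
           paste(rows, collapse = " vs "), call. = FALSE)
    }
  }
  q <- tolower(trimws(names))
  i <- match(q, key)
  administered <- ifelse(is.na(i), NA_character_,
                         canonical_smiles(map$smiles[i], strict = FALSE))
  out <- tibble::tibble(
    name = names,
    inchikey = ifelse(is.na(i), NA_character_, map$inchikey[i]),
    administered = administered,
    resolved = !is.na(i) & !is.na(administered)
  )
  out$desolvated <- NA_character_
  out$parent <- NA_character_
  out$n_parent_copies <- NA_integer_
  if (any(out$resolved)) {
    r <- which(out$resolved)
    out$desolvated[r] <- strip_solvates(out$administered[r])
    out$parent[r] <- suppressWarnings(get_parent(out$administered[r]))
    out$n_parent_copies[r] <- count_parent_copies(out$desolvated[r],
                                                  out$parent[r])
  }
  attr(out, "review_queue") <- out$name[!out$resolved]
  out
}
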