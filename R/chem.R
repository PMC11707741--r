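# Thin batch-oriented layer over Open Babel (via ChemmineOB/ChemmineR).
# All higher modules talk SMILES character vectors to these helpers; nothing
# else in the package touches the chemistry toolkit directly.

# Open Babel prints conversion chatter to stderr; silence it around calls.
ob_quiet <- function(expr) {
  suppressWarnings(suppressMessages(expr))
}

no_ob_options <- data.frame(names = character(), args = character(),
                            stringsAsFactors = FALSE)

#' Split a SMILES string into its disconnected components
#'
#' The dot character in SMILES is the component separator (it cannot occur
#' inside a bracket atom), so splitting is purely lexical.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A list of character vectors, one per input string.
#' @export
#' @examples
#' smiles_components("CCO.O.O")
smiles_components <- function(smiles) {
  stopifnot(is.character(smiles))
  strsplit(smiles, ".", fixed = TRUE)
}

#' Count disconnected components of a SMILES string
#'
#' @inheritParams smiles_components
#' @return Integer vector of component counts.
#' @export
n_components <- function(smiles) {
  lengths(smiles_components(smiles))
}

# Run one batched Open Babel conversion keyed by an index title so that
# molecules the toolkit fails to parse can be mapped back to their inputs.
# Returns a character vector aligned with `smiles`, NA where parsing failed.
ob_canonicalize <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  src <- paste0(smiles[idx], "\t", idx, "\n", collapse = "")
  res <- tryCatch(
    ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", src,
                                       options = no_ob_options)),
    error = function(e) ""
  )
  if (!nzchar(res)) return(out)
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2) {
      i <- suppressWarnings(as.integer(trimws(p[2])))
      if (!is.na(i)) out[i] <- trimws(p[1])
    }
  }
  out
}

#' Canonicalize SMILES strings
#'
#' Converts each structure to the toolkit's canonical SMILES so that equal
#' molecules yield equal strings. Multi-component inputs keep their component
#' separator. Unparseable inputs raise an error carrying the offending
#' strings unless `strict = FALSE`, in which case they become `NA`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict Error on unparseable input? Default `TRUE`.
#' @return Character vector of canonical SMILES.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "C(C)O")) # both ethanol
canonical_smiles <- function(smiles, strict = TRUE) {
  out <- ob_canonicalize(smiles)
  bad <- is.na(out) & !is.na(smiles)
  if (strict && any(bad)) {
    stop("unparseable SMILES: ",
         paste(utils::head(smiles[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Test whether SMILES strings are parseable
#'
#' @inheritParams smiles_components
#' @return Logical vector.
#' @export
smiles_valid <- function(smiles) {
  !is.na(ob_canonicalize(smiles))
}

# Batched molecular properties from Open Babel: average molecular weight,
# molecular formula, Wildman-Crippen logP, TPSA, molar refractivity, and the
# toolkit's H-bond donor/acceptor counts. One row per input, NA rows where
# parsing failed.
ob_properties <- function(smiles) {
  n <- length(smiles)
  empty <- tibble::tibble(
    smiles = smiles, formula = NA_character_, mw = NA_real_,
    logp = NA_real_, tpsa = NA_real_, mr = NA_real_,
    hbd = NA_real_, hba = NA_real_
  )
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(empty)
  idx <- which(ok)
  src <- paste0(smiles[idx], "\t", idx, "\n", collapse = "")
  rows <- ob_quiet(ChemmineOB::forEachMol("SMILES", src,
                                          function(m) ChemmineOB::prop_OB(m)))
  for (r in rows) {
    i <- suppressWarnings(as.integer(r$title))
    if (is.na(i)) next
    empty$formula[i] <- r$formula
    empty$mw[i] <- r$MW
    empty$logp[i] <- r$logP
    empty$tpsa[i] <- r$TPSA
    empty$mr[i] <- r$MR
    empty$hbd[i] <- r$HBD
    empty$hba[i] <- r$HBA2
  }
  empty
}

#' Average molecular weight of a structure
#'
#' Sum of average atomic masses over every component of the (possibly
#' multi-component) structure.
#'
#' @inheritParams smiles_components
#' @return Numeric vector in g/mol, `NA` where the structure does not parse.
#' @export
#' @examples
#' molecular_weight("O") # water, about 18.02
molecular_weight <- function(smiles) {
  ob_properties(smiles)$mw
}

# Count unique SMARTS matches per molecule. `patterns` is a named character
# vector; result is a tibble with one column per pattern name.
smarts_counts <- function(smiles, patterns) {
  stopifnot(!is.null(names(patterns)), all(nzchar(names(patterns))))
  n <- length(smiles)
  out <- matrix(NA_real_, nrow = n, ncol = length(patterns),
                dimnames = list(NULL, names(patterns)))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (any(ok)) {
    idx <- which(ok)
    src <- paste0(smiles[idx], "\t", idx, "\n", collapse = "")
    rows <- ob_quiet(ChemmineOB::forEachMol("SMILES", src, function(m) {
      cnt <- vapply(patterns, function(p) {
        as.numeric(ChemmineOB::smartsSearch_OB(list(m), p,
                                               uniqueMatches = TRUE))
      }, numeric(1))
      ttl <- ChemmineOB::prop_OB(m)$title
      list(title = ttl, counts = cnt)
    }))
    for (r in rows) {
      i <- suppressWarnings(as.integer(r$title))
      if (!is.na(i)) out[i, ] <- r$counts
    }
  }
  tibble::as_tibble(out)
}

# Batched binary fingerprints. type "MACCS" yields the 166 structural keys
# (Open Babel pads its MACCS vector to 256 bits; the tail is all zero and is
# dropped), "ECFP6" yields a 4096-bit circular fingerprint of radius 3 that
# is OR-folded down to `fold_bits`.
ob_fingerprints <- function(smiles, type = c("MACCS", "ECFP6"),
                            fold_bits = 2048L) {
  type <- match.arg(type)
  width <- if (type == "MACCS") 166L else as.integer(fold_bits)
  out <- matrix(NA_integer_, nrow = length(smiles), ncol = width)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (any(ok)) {
    idx <- which(ok)
    src <- paste0(smiles[idx], "\t", idx, "\n", collapse = "")
    rows <- ob_quiet(ChemmineOB::forEachMol("SMILES", src, function(m) {
      bits <- ChemmineOB::fingerprint_OB(list(m), type)
      list(title = ChemmineOB::prop_OB(m)$title, bits = as.integer(bits))
    }))
    for (r in rows) {
      i <- suppressWarnings(as.integer(r$title))
      if (is.na(i)) next
      bits <- r$bits
      if (type == "MACCS") {
        out[i, ] <- bits[seq_len(166L)]
      } else {
        folded <- integer(width)
        pos <- which(bits != 0L)
        if (length(pos)) folded[unique((pos - 1L) %% width + 1L)] <- 1L
        out[i, ] <- folded
      }
    }
  }
  colnames(out) <- paste0(tolower(type), "_", seq_len(width))
  out
}

# Generate one 3D conformer per molecule with seeded distance-geometry
# embedding followed by MMFF94 minimization (at most `max_iters`
# iterations), via the RDKit toolkit in a subprocess. Deterministic for a
# given seed; duplicates share coordinates. Returns a list (one entry per
# input) of data frames with columns element, x, y, z; NULL where embedding
# failed.
ob_conformer_coords <- function(smiles, seed = 42L) {
  out <- vector("list", length(smiles))
  uniq <- unique(smiles[!is.na(smiles) & nzchar(smiles)])
  if (length(uniq) == 0) return(out)
  script <- system.file("python", "embed3d.py", package = "pharmforge",
                        mustWork = TRUE)
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".csv")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste0(uniq, "\t", seq_along(uniq)), infile)
  status <- suppressWarnings(
    system2("python", c(script, infile, outfile, seed),
            stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(outfile)) {
    warning("3D embedding subprocess failed; coordinates missing",
            call. = FALSE)
    return(out)
  }
  coords <- utils::read.csv(outfile, stringsAsFactors = FALSE)
  per_uniq <- split(coords[, c("element", "x", "y", "z")], coords$id)
  hit <- match(smiles, uniq)
  for (i in seq_along(smiles)) {
    if (!is.na(hit[i])) {
      block <- per_uniq[[as.character(hit[i])]]
      if (!is.null(block)) {
        out[[i]] <- data.frame(block, row.names = NULL)
      }
    }
  }
  out
}

# Parse a batch of SMILES into a ChemmineR SDFset (2D, hydrogens implicit),
# titled by input index; used for ring perception and the heavy-atom graph.
ob_sdfset <- function(smiles) {
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  src <- paste0(smiles[idx], "\t", idx, "\n", collapse = "")
  sdf <- tryCatch(
    ob_quiet(ChemmineOB::convertFormat("SMI", "SDF", src,
                                       options = no_ob_options)),
    error = function(e) ""
  )
  if (!nzchar(sdf)) return(NULL)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(sdf, tf)
  tryCatch(ob_quiet(ChemmineR::read.SDFset(tf)), error = function(e) NULL)
}
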