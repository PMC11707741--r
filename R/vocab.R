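# Controlled vocabularies and the embedded parent library. Everything ships
# as editable CSV under inst/extdata; loaders canonicalize SMILES once per
# session and cache the result.

the_vocab_cache <- new.env(parent = emptyenv())

vocab_path <- function(file) {
  system.file("extdata", file, package = "pharmforge", mustWork = TRUE)
}

read_vocab_csv <- function(file) {
  readr::read_csv(vocab_path(file), show_col_types = FALSE, progress = FALSE)
}

cached <- function(key, builder) {
  if (!exists(key, envir = the_vocab_cache)) {
    assign(key, builder(), envir = the_vocab_cache)
  }
  get(key, envir = the_vocab_cache)
}

#' Embedded library of drug-like parent structures
#'
#' A hand-curated set of parent molecules (single-component, neutral SMILES)
#' used by the synthetic corpus generator. A few deliberately oversized
#' (>1000 g/mol) mock structures are included to exercise the size filter;
#' these carry `oversized = TRUE`. For acids, a pre-deprotonated anion form
#' is stored for building metal salts. `inchikey` is a synthetic,
#' deterministic identifier in InChIKey format (no hashing of the actual
#' structure is performed); it serves purely as a join key.
#'
#' @return A tibble with columns `name`, `smiles` (canonical), `anion_smiles`,
#'   `anion_charge`, `basic_amine`, `oversized`, `mw`, `inchikey`.
#' @export
parent_library <- function() {
  cached("parents", function() {
    tbl <- read_vocab_csv("parent_library.csv")
    tbl$smiles <- canonical_smiles(tbl$smiles)
    has_anion <- !is.na(tbl$anion_smiles) & nzchar(tbl$anion_smiles)
    tbl$anion_smiles[has_anion] <- canonical_smiles(tbl$anion_smiles[has_anion])
    tbl$mw <- molecular_weight(tbl$smiles)
    tbl$inchikey <- synthetic_inchikey(tbl$name)
    tibble::as_tibble(tbl)
  })
}

#' Salt counterion and solvent whitelists
#'
#' The shared whitelists that drive both the synthetic salt/solvate
#' decoration and the stripping logic in structure curation: the same list
#' defines what the generator may add and what curation may remove.
#'
#' @return A tibble with columns `name`, `smiles` (canonical) and, for
#'   counterions, `charge`.
#' @export
salt_whitelist <- function() {
  cached("salts", function() {
    tbl <- read_vocab_csv("salt_counterions.csv")
    tbl$smiles <- canonical_smiles(tbl$smiles)
    tibble::as_tibble(tbl)
  })
}

#' @rdname salt_whitelist
#' @export
solvent_whitelist <- function() {
  cached("solvents", function() {
    tbl <- read_vocab_csv("solvents.csv")
    tbl$smiles <- canonical_smiles(tbl$smiles)
    tibble::as_tibble(tbl)
  })
}

#' Excipient controlled vocabulary
#'
#' Maps surface forms seen in section 6.1 text (synonyms, grades,
#' viscosity/molecular-weight-annotated polymer names) to canonical
#' excipient identifiers. Polymer classes that differ only by chain length
#' or viscosity grade (e.g. the macrogols) share one canonical identifier.
#'
#' @return A tibble with columns `surface` (lower case), `canonical_id`,
#'   `canonical_name`.
#' @export
excipient_vocabulary <- function() {
  cached("excipients", function() {
    tbl <- read_vocab_csv("excipient_vocabulary.csv")
    tbl$surface <- tolower(trimws(tbl$surface))
    tibble::as_tibble(tbl)
  })
}

#' Dosage form controlled vocabulary
#'
#' Maps pharmaceutical-form phrases from section 3 to a canonical dosage
#' form, its licensed routes (pipe-delimited), and whether the phrase
#' implies a modified-release profile.
#'
#' @return A tibble with columns `surface`, `canonical_form`, `routes`,
#'   `modified_release`.
#' @export
dosage_form_vocabulary <- function() {
  cached("forms", function() {
    tbl <- read_vocab_csv("dosage_forms.csv")
    tbl$surface <- tolower(trimws(tbl$surface))
    tibble::as_tibble(tbl)
  })
}

#' Allowed route terms
#' @return Character vector of canonical route terms.
#' @export
route_vocabulary <- function() {
  sort(unique(unlist(strsplit(dosage_form_vocabulary()$routes, "|",
                              fixed = TRUE))))
}

#' Deterministic synthetic InChIKey-format identifiers
#'
#' Generates identifiers with the 14-10-1 uppercase-letter layout of an
#' InChIKey from a name, by arithmetic on the name's bytes. These are
#' synthetic join keys, not structure hashes, and are used where a real
#' registry lookup is out of scope.
#'
#' @param name Character vector.
#' @return Character vector of 27-character identifiers.
#' @export
#' @examples
#' synthetic_inchikey("pemetrexed")
synthetic_inchikey <- function(name) {
  vapply(name, function(nm) {
    bytes <- utf8ToInt(toupper(nm))
    # simple rolling hash into 24 letters
    h <- numeric(24)
    acc <- 7
    for (i in seq_along(bytes)) {
      acc <- (acc * 31 + bytes[i]) %% 2147483563
      h[(i - 1L) %% 24L + 1L] <- (h[(i - 1L) %% 24L + 1L] + acc) %% 26
    }
    # mix positions so short names still fill all letters
    for (j in seq_len(24)) {
      acc <- (acc * 69069 + j) %% 2147483563
      h[j] <- (h[j] + acc) %% 26
    }
    letters24 <- intToUtf8(h + 65L, multiple = TRUE)
    paste0(paste(letters24[1:14], collapse = ""), "-",
           paste(letters24[15:24], collapse = ""), "-N")
  }, character(1), USE.NAMES = FALSE)
}
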