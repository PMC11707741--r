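# The five-table relational CSV schema: drugs, excipients, products,
# formulations (junction), iv_pk. Multi-valued cells (routes, excipient
# lists) are serialized as pipe-delimited strings inside one CSV field; a
# fully normalized export of the formulation-excipient junction is also
# provided.

db_tables <- c("drugs", "excipients", "products", "formulations", "iv_pk")

db_col_types <- list(
  drugs = readr::cols(
    drug_id = "c", name = "c", administered = "c", desolvated = "c",
    parent = "c", inchikey = "c", parent_inchikey = "c",
    n_parent_copies = "i", formula_weight = "d", parent_mw = "d", atc = "c"
  ),
  excipients = readr::cols(excipient_id = "c", name = "c"),
  products = readr::cols(product_id = "c", name = "c", domain = "c",
                         substance_class = "c"),
  formulations = readr::cols(
    formulation_id = "c", product_id = "c", drug_id = "c",
    dosage_form = "c", routes = "c", modified_release = "l",
    dose_mg = "d", form_of_drug = "c", excipient_ids = "c",
    fa = "d", fa_flag = "c", f_abs = "d", f_flag = "c", tmax = "d"
  ),
  iv_pk = readr::cols(inchikey = "c", vdss_l_kg = "d", cl_ml_min_kg = "d",
                      fu = "d", mrt_h = "d", thalf_h = "d")
)

new_pharm_db <- function(tables) {
  stopifnot(all(db_tables %in% names(tables)))
  structure(tables[db_tables], class = "pharm_db")
}

#' @export
print.pharm_db <- function(x, ...) {
  cat("<pharm_db>\n")
  for (nm in db_tables) {
    cat(sprintf("  %-13s %5d rows x %d cols\n", nm, nrow(x[[nm]]),
                ncol(x[[nm]])))
  }
  invisible(x)
}

#' Serialize / split pipe-delimited list cells
#'
#' @param x A list of character vectors, or a character vector of
#'   pipe-delimited strings.
#' @return `pipe_join()`: character vector; `pipe_split()`: list.
#' @export
pipe_join <- function(x) {
  vapply(x, function(v) paste(v, collapse = "|"), character(1))
}

#' @rdname pipe_join
#' @export
pipe_split <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), "|", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

#' Assemble a database from parsed documents and an identifier dictionary
#'
#' Resolves the active substances of the retained register rows against the
#' dictionary, curates each administered structure down to its desolvated
#' and parent forms, applies the parent molecular-weight size filter
#' (default 1000 g/mol; affected products lose their formulations, logged),
#' and assembles the five relational tables. Combination products listed
#' with several pipe-delimited active substances are split into one
#' formulation row per component; `drop_components` removes named
#' (product, substance) pairs whose partner is already marketed separately.
#'
#' @param parsed Output of [parse_corpus()].
#' @param dictionary A tibble with columns `name`, `inchikey`, `smiles`.
#' @param size_cutoff Parent molecular-weight cutoff in g/mol.
#' @param drop_components Optional tibble with columns `product`,
#'   `substance` naming components to drop.
#' @return A `pharm_db` object; attribute `build_log` records exclusions.
#' @export
build_database <- function(parsed, dictionary, size_cutoff = 1000,
                           drop_components = NULL) {
  products <- tibble::tibble(
    product_id = parsed$products$product_name,
    name = parsed$products$product_name,
    domain = parsed$products$domain,
    substance_class = parsed$products$substance_class
  )
  actives <- tibble::tibble(
    product_id = parsed$products$product_name,
    substance = parsed$products$active_substances
  ) |>
    dplyr::mutate(substance = pipe_split(.data$substance)) |>
    tidyr::unnest("substance")
  if (!is.null(drop_components)) {
    actives <- dplyr::anti_join(
      actives, drop_components,
      by = c(product_id = "product", substance = "substance"))
  }
  resolved <- resolve_identifiers(unique(actives$substance), dictionary)
  curated <- resolved[resolved$resolved, , drop = FALSE]
  curated <- apply_size_filter(curated, cutoff = size_cutoff)
  oversize_log <- attr(curated, "excluded")
  curated$drug_id <- sprintf("DRG%04d", seq_len(nrow(curated)))
  curated$formula_weight <- formula_weight(curated$desolvated,
                                           curated$n_parent_copies)
  curated$parent_mw <- molecular_weight(curated$parent)
  curated$parent_inchikey <- synthetic_inchikey(curated$parent)
  drugs <- tibble::tibble(
    drug_id = curated$drug_id, name = curated$name,
    administered = curated$administered, desolvated = curated$desolvated,
    parent = curated$parent, inchikey = curated$inchikey,
    parent_inchikey = curated$parent_inchikey,
    n_parent_copies = curated$n_parent_copies,
    formula_weight = curated$formula_weight,
    parent_mw = curated$parent_mw, atc = NA_character_
  )
  actives$drug_id <- drugs$drug_id[match(actives$substance, drugs$name)]
  actives <- actives[!is.na(actives$drug_id), , drop = FALSE]
  fml <- parsed$formulations
  fml_rows <- dplyr::inner_join(
    tibble::tibble(
      product_id = fml$brand,
      dosage_form = fml$dosage_form,
      routes = pipe_join(fml$routes),
      modified_release = fml$modified_release,
      dose_mg = vapply(fml$doses, function(d) {
        if (is.null(d) || nrow(d) == 0) NA_real_ else d$dose_mg[1]
      }, numeric(1)),
      form_of_drug = vapply(fml$doses, function(d) {
        if (is.null(d) || nrow(d) == 0) NA_character_ else d$form_of_drug[1]
      }, character(1)),
      excipient_ids = pipe_join(fml$excipient_ids),
      fa = fml$fa, fa_flag = fml$fa_flag, f_abs = fml$f_abs,
      f_flag = fml$f_flag, tmax = fml$tmax
    ),
    actives[, c("product_id", "drug_id")], by = "product_id",
    relationship = "many-to-many"
  )
  dropped_products <- setdiff(fml$brand, fml_rows$product_id)
  fml_rows$formulation_id <- sprintf("FML%04d", seq_len(nrow(fml_rows)))
  fml_rows <- fml_rows[, c("formulation_id", "product_id", "drug_id",
                           "dosage_form", "routes", "modified_release",
                           "dose_mg", "form_of_drug", "excipient_ids",
                           "fa", "fa_flag", "f_abs", "f_flag", "tmax")]
  vocab <- excipient_vocabulary()
  used <- sort(unique(unlist(pipe_split(fml_rows$excipient_ids))))
  excipients <- tibble::tibble(
    excipient_id = used,
    name = vocab$canonical_name[match(used, vocab$canonical_id)]
  )
  excipients$name[is.na(excipients$name)] <- excipients$excipient_id[
    is.na(excipients$name)]
  iv_pk <- tibble::tibble(inchikey = character(), vdss_l_kg = numeric(),
                          cl_ml_min_kg = numeric(), fu = numeric(),
                          mrt_h = numeric(), thalf_h = numeric())
  db <- new_pharm_db(list(drugs = drugs, excipients = excipients,
                          products = products, formulations = fml_rows,
                          iv_pk = iv_pk))
  attr(db, "build_log") <- list(
    unresolved = attr(resolved, "review_queue"),
    oversized = oversize_log,
    products_without_formulations = dropped_products
  )
  db
}

#' Write a database to five CSV files
#'
#' UTF-8, comma-delimited, header row, empty string for missing values.
#'
#' @param db A `pharm_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_database <- function(db, dir) {
  stopifnot(inherits(db, "pharm_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in db_tables) {
    readr::write_csv(db[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
  }
  invisible(dir)
}

#' Load a database from a directory of five CSV files
#'
#' Missing files are fatal; rows violating column types are collected and
#' reported with row numbers via the `parse_problems` attribute, never
#' silently skipped.
#'
#' @param dir Directory containing `drugs.csv`, `excipients.csv`,
#'   `products.csv`, `formulations.csv`, `iv_pk.csv`.
#' @return A `pharm_db`.
#' @export
load_database <- function(dir) {
  tables <- list()
  problems <- list()
  for (nm in db_tables) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      stop("missing database file: ", path, call. = FALSE)
    }
    tbl <- suppressWarnings(
      readr::read_csv(path, col_types = db_col_types[[nm]], na = "",
                      progress = FALSE)
    )
    pr <- readr::problems(tbl)
    if (nrow(pr) > 0) problems[[nm]] <- pr
    tables[[nm]] <- tbl
  }
  db <- new_pharm_db(tables)
  attr(db, "parse_problems") <- problems
  db
}

#' Validate a database against its schema invariants
#'
#' Checks referential integrity (every foreign key resolves), controlled
#' vocabularies (dosage forms and routes), value ranges (`fa` in [0, 1]),
#' identifier format, and uniqueness of (product, dosage form) pairs.
#' Violations are returned as data, never thrown; the database is not
#' modified.
#'
#' @param db A `pharm_db`.
#' @return A tibble of violations (`table`, `row`, `column`, `message`);
#'   zero rows iff the database is valid.
#' @export
validate_database <- function(db) {
  stopifnot(inherits(db, "pharm_db"))
  v <- list()
  add <- function(table, row, column, message) {
    v[[length(v) + 1L]] <<- tibble::tibble(table = table,
                                           row = as.integer(row),
                                           column = column, message = message)
  }
  f <- db$formulations
  bad <- which(!f$product_id %in% db$products$product_id)
  for (i in bad) add("formulations", i, "product_id",
                     paste0("unknown product: ", f$product_id[i]))
  bad <- which(!f$drug_id %in% db$drugs$drug_id)
  for (i in bad) add("formulations", i, "drug_id",
                     paste0("unknown drug: ", f$drug_id[i]))
  exc <- pipe_split(f$excipient_ids)
  for (i in seq_along(exc)) {
    missing_e <- setdiff(exc[[i]], db$excipients$excipient_id)
    for (e in missing_e) add("formulations", i, "excipient_ids",
                             paste0("unknown excipient: ", e))
  }
  forms <- unique(dosage_form_vocabulary()$canonical_form)
  bad <- which(!is.na(f$dosage_form) & !f$dosage_form %in% forms)
  for (i in bad) add("formulations", i, "dosage_form",
                     paste0("form not in vocabulary: ", f$dosage_form[i]))
  routes <- route_vocabulary()
  rl <- pipe_split(f$routes)
  for (i in seq_along(rl)) {
    for (r in setdiff(rl[[i]], routes)) {
      add("formulations", i, "routes",
          paste0("route not in vocabulary: ", r))
    }
  }
  bad <- which(!is.na(f$fa) & (f$fa < 0 | f$fa > 1))
  for (i in bad) add("formulations", i, "fa",
                     paste0("fa outside [0,1]: ", f$fa[i]))
  key <- paste(f$product_id, f$drug_id, f$dosage_form)
  dup <- which(duplicated(key))
  for (i in dup) add("formulations", i, "dosage_form",
                     paste0("duplicate (product, drug, dosage form): ",
                            key[i]))
  ik_pat <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"
  bad <- which(!is.na(db$drugs$inchikey) &
                 !grepl(ik_pat, db$drugs$inchikey))
  for (i in bad) add("drugs", i, "inchikey", "malformed InChIKey")
  bad <- which(!grepl(ik_pat, db$iv_pk$inchikey))
  for (i in bad) add("iv_pk", i, "inchikey", "malformed InChIKey")
  if (length(v) == 0) {
    tibble::tibble(table = character(), row = integer(),
                   column = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Attach intravenous PK parameters to the drugs table
#'
#' Left join of a formulation-independent IV parameter table (volume of
#' distribution at steady state, clearance, fraction unbound, mean
#' residence time, terminal half-life) onto the drugs table by parent
#' InChIKey. Drugs without a match keep missing values; nothing is imputed.
#'
#' @param db A `pharm_db`.
#' @param iv_table A tibble with columns `inchikey`, `vdss_l_kg`,
#'   `cl_ml_min_kg`, `fu`, `mrt_h`, `thalf_h`.
#' @return The database with its `iv_pk` table replaced by the rows that
#'   matched a drug, and the drugs carrying the joined values in columns
#'   `vdss_l_kg` ... `thalf_h`.
#' @export
attach_iv_pk <- function(db, iv_table) {
  stopifnot(inherits(db, "pharm_db"))
  dup <- unique(iv_table$inchikey[duplicated(iv_table$inchikey)])
  if (length(dup)) {
    stop("duplicate InChIKey(s) in IV table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  drugs <- dplyr::left_join(db$drugs, iv_table,
                            by = c(parent_inchikey = "inchikey"))
  db$drugs <- drugs
  db$iv_pk <- iv_table[iv_table$inchikey %in% db$drugs$parent_inchikey, ,
                       drop = FALSE]
  db
}

#' @rdname attach_iv_pk
#' @export
detach_iv_pk <- function(db) {
  stopifnot(inherits(db, "pharm_db"))
  keep <- setdiff(names(db$drugs),
                  c("vdss_l_kg", "cl_ml_min_kg", "fu", "mrt_h", "thalf_h"))
  db$drugs <- db$drugs[, keep]
  db$iv_pk <- db$iv_pk[0, , drop = FALSE]
  db
}

#' Fully normalized formulation-excipient junction table
#'
#' @param db A `pharm_db`.
#' @return A tibble with one row per (formulation, excipient) pair.
#' @export
formulation_excipients <- function(db) {
  tibble::tibble(
    formulation_id = db$formulations$formulation_id,
    excipient_id = pipe_split(db$formulations$excipient_ids)
  ) |>
    tidyr::unnest("excipient_id")
}

#' Generate a synthetic intravenous PK table
#'
#' Lognormal draws with realistic centres (Vdss around 1 L/kg, clearance
#' around 5 mL/min/kg, fraction unbound uniform, MRT consistent with
#' Vdss/Cl, half-life proportional to MRT) keyed by InChIKey, for a random
#' subset of the supplied keys.
#'
#' @param inchikeys Character vector of keys to sample from.
#' @param fraction Proportion of keys that receive a row.
#' @param seed Integer seed.
#' @return A tibble in `iv_pk` schema.
#' @export
synth_iv_pk <- function(inchikeys, fraction = 0.4, seed = 1L) {
  withr::with_seed(seed, {
    keys <- unique(inchikeys)
    keys <- keys[stats::runif(length(keys)) < fraction]
    n <- length(keys)
    vdss <- stats::rlnorm(n, log(1), 0.8)
    cl <- stats::rlnorm(n, log(5), 0.9)
    mrt <- vdss / (cl * 60 / 1e3) / 1 # h, from L/kg over L/h/kg
    tibble::tibble(
      inchikey = keys, vdss_l_kg = round(vdss, 3),
      cl_ml_min_kg = round(cl, 3),
      fu = round(stats::runif(n, 0.01, 0.99), 3),
      mrt_h = round(mrt, 2), thalf_h = round(mrt * 0.693, 2)
    )
  })
}
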