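# Rendering SmPC-style documents from structured product records, and the
# end-to-end corpus builder that ties substances, transactions, Fa labels
# and documents together with a single truth object.

dose_label <- function(mg) {
  if (mg >= 1000 && mg %% 1000 == 0) paste0(mg / 1000, " g") else paste0(mg, " mg")
}

form_unit <- function(canonical_form) {
  switch(canonical_form,
         tablet = "tablet", capsule = "capsule",
         oral_solution = "ml", oral_suspension = "ml",
         solution_for_infusion = "vial", solution_for_injection = "vial",
         "unit")
}

pk_paragraph <- function(dialect, fa_pct, f_pct, tmax) {
  sent <- switch(dialect,
    point_f = sprintf("The absolute bioavailability is %d%%.", f_pct),
    range_f = sprintf("The absolute bioavailability is %d to %d%%.",
                      f_pct - 5L, f_pct + 5L),
    point_fa = sprintf("Approximately %d%% of an oral dose is absorbed.",
                       fa_pct),
    range_fa = sprintf("%d to %d%% of an oral dose is absorbed.",
                       fa_pct - 5L, fa_pct + 5L),
    lower_bound = sprintf(
      "At least %d%% of the dose is absorbed from the gastrointestinal tract.",
      fa_pct),
    mass_balance = sprintf(
      "Following oral administration of a radiolabelled dose, %d%% of the dose was recovered in urine.",
      fa_pct),
    combo = sprintf(
      "Approximately %d%% of an oral dose is absorbed. The absolute bioavailability is %d%%.",
      fa_pct, f_pct),
    none = "Not applicable."
  )
  if (!is.na(tmax)) {
    sent <- paste(sent, sprintf(
      "Maximum plasma concentrations are reached approximately %s hours after oral administration.",
      format(tmax)))
  }
  sent
}

# expected parse result for a rendered pk paragraph
pk_truth <- function(dialect, fa_pct, f_pct, tmax) {
  fa <- NA_real_; fa_flag <- NA_character_
  f <- NA_real_; f_flag <- NA_character_
  if (dialect %in% c("point_fa", "combo")) { fa <- fa_pct / 100; fa_flag <- "point" }
  if (dialect == "range_fa") { fa <- fa_pct / 100; fa_flag <- "range_mean" }
  if (dialect == "lower_bound") { fa <- fa_pct / 100; fa_flag <- "lower_bound" }
  if (dialect == "mass_balance") { fa <- fa_pct / 100; fa_flag <- "inferred_mass_balance" }
  if (dialect %in% c("point_f", "combo")) { f <- f_pct; f_flag <- "point" }
  if (dialect == "range_f") { f <- f_pct; f_flag <- "range_mean" }
  tibble::tibble(fa = fa, fa_flag = fa_flag, f_abs = f, f_flag = f_flag,
                 tmax = tmax)
}

render_smpc <- function(brand, strength_mg, substance_name, salt_name,
                        form_surface, canonical_form, excipient_surfaces,
                        pk_text) {
  unit <- form_unit(canonical_form)
  as_clause <- if (!is.na(salt_name)) sprintf(" (as %s)", salt_name) else ""
  composition <- sprintf("Each %s contains %s of %s%s.", unit,
                         dose_label(strength_mg), substance_name, as_clause)
  form_line <- paste0(toupper(substring(form_surface, 1, 1)),
                      substring(form_surface, 2), ".")
  paste(c(
    "1. NAME OF THE MEDICINAL PRODUCT", "",
    sprintf("%s %s %s", brand, dose_label(strength_mg), form_surface), "",
    "2. QUALITATIVE AND QUANTITATIVE COMPOSITION", "",
    composition, "",
    "For the full list of excipients, see section 6.1.", "",
    "3. PHARMACEUTICAL FORM", "",
    form_line, "",
    "4. CLINICAL PARTICULARS", "",
    "4.1 Therapeutic indications", "",
    "Not applicable.", "",
    "5. PHARMACOLOGICAL PROPERTIES", "",
    "5.1 Pharmacodynamic properties", "",
    "Not applicable.", "",
    "5.2 Pharmacokinetic properties", "",
    pk_text, "",
    "5.3 Preclinical safety data", "",
    "Not applicable.", "",
    "6. PHARMACEUTICAL PARTICULARS", "",
    "6.1 List of excipients", "",
    excipient_surfaces, "",
    "6.2 Incompatibilities", "",
    "Not applicable.", ""
  ), collapse = "\n")
}

#' Render the product-information document for one product
#'
#' Produces one plain-text document containing one SmPC block per
#' formulation, with numbered section headers for composition (2),
#' pharmaceutical form (3), pharmacokinetics (5.2) and excipients (6.1).
#' The inverse of [split_into_smpcs()] plus [extract_sections()].
#'
#' @param product A list with elements `brand`, `substance_name`,
#'   `salt_name` (NA for free drugs) and `formulations`, a data frame with
#'   columns `strength_mg`, `form_surface`, `canonical_form`,
#'   `excipient_surfaces` (list-column), `pk_text`.
#' @return A single character string.
#' @export
render_product_information <- function(product) {
  f <- product$formulations
  if (is.null(f) || nrow(f) == 0) {
    stop("product has no formulations", call. = FALSE)
  }
  blocks <- vapply(seq_len(nrow(f)), function(i) {
    render_smpc(product$brand, f$strength_mg[i], product$substance_name,
                product$salt_name, f$form_surface[i], f$canonical_form[i],
                f$excipient_surfaces[[i]], f$pk_text[i])
  }, character(1))
  paste(blocks, collapse = "\n")
}

# pick a rendering surface form for each canonical excipient id (seeded by
# the caller's RNG state)
surface_for <- function(canonical_ids) {
  vocab <- excipient_vocabulary()
  vapply(canonical_ids, function(id) {
    ss <- vocab$surface[vocab$canonical_id == id]
    if (length(ss) == 0) id else ss[sample.int(length(ss), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

strength_ladder <- c(5L, 10L, 20L, 25L, 40L, 50L, 100L, 200L, 250L, 500L,
                     1000L)

#' Generate the full synthetic corpus
#'
#' Runs the substance, transaction and Fa generators, assembles products
#' (forms, strengths, excipient lists, pharmacokinetic statements), renders
#' one document per product, and builds the register including veterinary
#' and biological decoy rows that the register filter must remove. The
#' returned `truth` object retains every planted value so that parsing,
#' curation, mining and modeling can each be checked field-for-field.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional directory; when given, writes `register.csv`,
#'   `substances.csv`, `documents/*.txt` and `truth.json`.
#' @return A list with `register`, `substances`, `documents` (named
#'   character vector), `dictionary` (name to identifier/structure map) and
#'   `truth`.
#' @export
synthesize_corpus <- function(config = synthetic_config(), dir = NULL) {
  n <- config$n_products
  n_over <- if (n >= 20L) 3L else 0L
  n_core <- n - n_over
  subs <- synth_substances(n_core, config$salt_fraction,
                           config$solvate_fraction, seed = config$seed,
                           include_oversized = n_over)
  # per-parent descriptors and true Fa
  parents <- unique(subs[, c("parent_name", "truth_parent")])
  desc <- compute_descriptors(parents$truth_parent)
  fa_tbl <- synth_fa(desc, config)
  parents$fa_true <- fa_tbl$fa
  parents$fa_class <- fa_tbl$class

  withr::with_seed(config$seed + 3L, {
    # product-level form assignment
    cats <- sample(c("ir_tablet", "mr_tablet", "capsule", "infusion"),
                   size = n, replace = TRUE,
                   prob = c(0.60, 0.10, 0.15, 0.15))
    cats[subs$substance_id %in% utils::tail(subs$substance_id, n_over)] <-
      "ir_tablet" # oversized decoys stay oral so they reach curation
    form_surface <- character(n)
    canonical_form <- character(n)
    mr <- logical(n)
    for (i in seq_len(n)) {
      fs <- switch(cats[i],
        ir_tablet = sample(c("film-coated tablet", "tablet",
                             "orodispersible tablet"), 1,
                           prob = c(0.6, 0.3, 0.1)),
        mr_tablet = sample(c("prolonged-release tablet",
                             "gastro-resistant tablet"), 1),
        capsule = sample(c("capsule, hard", "hard capsule"), 1),
        infusion = "solution for infusion")
      form_surface[i] <- fs
      fv <- dosage_form_vocabulary()
      row <- fv[fv$surface == tolower(fs), ]
      canonical_form[i] <- row$canonical_form[1]
      mr[i] <- row$modified_release[1]
    }
    solid_oral <- cats %in% c("ir_tablet", "mr_tablet", "capsule")
    tx <- synth_transactions(sum(solid_oral), config)
    tx_items <- vector("list", n)
    tx_items[solid_oral] <- tx$transactions$items
    tx_items[!solid_oral] <- list(c("water_for_injections", "sodium_chloride",
                                    "sodium_hydroxide"))
    # strengths, pk dialects, rendering
    brands <- sprintf("Brand%03d", seq_len(n))
    is_mined <- cats == "ir_tablet"
    documents <- stats::setNames(character(n), brands)
    prod_rows <- vector("list", n)
    form_rows <- vector("list", n)
    for (i in seq_len(n)) {
      n_str <- sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
      strengths <- sort(sample(strength_ladder, n_str))
      p_i <- match(subs$parent_name[i], parents$parent_name)
      fa_pct <- as.integer(round(parents$fa_true[p_i] * 100))
      fa_pct <- min(max(fa_pct, 8L), 94L)
      f_pct <- as.integer(round(fa_pct * stats::runif(1, 0.5, 0.95)))
      f_pct <- min(max(f_pct, 6L), 94L)
      tmax <- if (stats::runif(1) < 0.8) {
        sample(c(0.5, 1, 1.5, 2, 3, 4, 6), 1)
      } else NA_real_
      dialect <- if (cats[i] == "infusion") "none" else {
        sample(c("point_f", "range_f", "point_fa", "range_fa",
                 "lower_bound", "mass_balance", "combo"), 1,
               prob = c(0.25, 0.15, 0.2, 0.1, 0.1, 0.1, 0.1))
      }
      if (dialect == "lower_bound") fa_pct <- max(5L, fa_pct - 10L)
      pk_text <- pk_paragraph(dialect, fa_pct, f_pct,
                              if (cats[i] == "infusion") NA_real_ else tmax)
      truthpk <- pk_truth(dialect, fa_pct, f_pct,
                          if (cats[i] == "infusion") NA_real_ else tmax)
      surfaces <- surface_for(tx_items[[i]])
      fml <- tibble::tibble(
        strength_mg = strengths,
        form_surface = form_surface[i],
        canonical_form = canonical_form[i],
        excipient_surfaces = rep(list(surfaces), n_str),
        pk_text = pk_text
      )
      as_parts <- stats::na.omit(c(subs$salt_name[i], subs$solvate_name[i]))
      as_annotation <- if (length(as_parts)) paste(as_parts, collapse = " ")
                       else NA_character_
      documents[i] <- render_product_information(list(
        brand = brands[i], substance_name = subs$parent_name[i],
        salt_name = as_annotation, formulations = fml
      ))
      prod_rows[[i]] <- tibble::tibble(
        brand = brands[i], substance_id = subs$substance_id[i],
        substance_name = subs$name[i], parent_name = subs$parent_name[i],
        category = cats[i], dosage_form = canonical_form[i],
        form_surface = form_surface[i],
        modified_release = mr[i], mined = is_mined[i],
        oversized = subs$parent_name[i] %in%
          parent_library()$name[parent_library()$oversized]
      )
      form_rows[[i]] <- tibble::tibble(
        brand = brands[i], strength_mg = strengths,
        dose_truth = strengths, dose_substance = subs$parent_name[i],
        form_of_drug = as_annotation,
        excipient_ids = rep(list(tx_items[[i]]), n_str),
        fa = truthpk$fa, fa_flag = truthpk$fa_flag,
        f_abs = truthpk$f_abs, f_flag = truthpk$f_flag, tmax = truthpk$tmax
      )
    }
    products <- dplyr::bind_rows(prod_rows)
    formulations_truth <- dplyr::bind_rows(form_rows)
    # register with decoys
    register <- tibble::tibble(
      product_name = brands, domain = "human", substance_class = "chemical",
      active_substances = subs$name, document = paste0(brands, ".txt")
    )
    decoys <- tibble::tibble(
      product_name = c("VetoBrand01", "VetoBrand02", "BioBrand01",
                       "BioBrand02"),
      domain = c("veterinary", "veterinary", "human", "human"),
      substance_class = c("chemical", "chemical", "biological", "biological"),
      active_substances = "decoy substance",
      document = NA_character_
    )
    register <- dplyr::bind_rows(register, decoys)
    register <- register[sample.int(nrow(register)), ]
    dictionary <- tibble::tibble(
      name = subs$name, inchikey = subs$inchikey, smiles = subs$administered
    )
    truth <- list(
      substances = subs, parents = parents,
      products = products, formulations = formulations_truth,
      rules = tx$truth, retained_products = brands,
      highest_strength = formulations_truth |>
        dplyr::group_by(.data$brand) |>
        dplyr::summarise(highest_mg = max(.data$strength_mg),
                         .groups = "drop")
    )
    out <- list(register = register, substances = subs,
                documents = documents, dictionary = dictionary,
                truth = truth, config = config)
    if (!is.null(dir)) write_corpus(out, dir)
    out
  })
}

write_corpus <- function(corpus, dir) {
  dir.create(file.path(dir, "documents"), recursive = TRUE,
             showWarnings = FALSE)
  readr::write_csv(corpus$register, file.path(dir, "register.csv"), na = "")
  readr::write_csv(corpus$substances, file.path(dir, "substances.csv"),
                   na = "")
  readr::write_csv(corpus$dictionary, file.path(dir, "dictionary.csv"),
                   na = "")
  for (nm in names(corpus$documents)) {
    writeLines(corpus$documents[[nm]],
               file.path(dir, "documents", paste0(nm, ".txt")))
  }
  truth <- corpus$truth
  truth$formulations$excipient_ids <-
    vapply(truth$formulations$excipient_ids, paste, character(1),
           collapse = "|")
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null")
  invisible(dir)
}
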