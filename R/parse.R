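# Document processing: register filtering, SmPC splitting, line-anchored
# section extraction, controlled-vocabulary normalisation of excipients and
# dosage forms, dose parsing and oral-PK extraction.

#' Filter a product register
#'
#' Keeps entries whose domain and substance class are among the allowed
#' values, preserving order. Removed entries and the reason for each
#' removal are returned in the `removed` attribute.
#'
#' @param entries A data frame with columns `domain` and `substance_class`.
#' @param domains,substance_classes Allowed values.
#' @return The retained rows (a tibble) with attribute `removed`.
#' @export
filter_register <- function(entries, domains = "human",
                            substance_classes = "chemical") {
  stopifnot(all(c("domain", "substance_class") %in% names(entries)))
  bad_domain <- !entries$domain %in% domains
  bad_class <- !entries$substance_class %in% substance_classes
  keep <- !bad_domain & !bad_class
  removed <- tibble::as_tibble(entries[!keep, , drop = FALSE])
  removed$removal_reason <- dplyr::case_when(
    bad_domain[!keep] & bad_class[!keep] ~ "domain and substance class",
    bad_domain[!keep] ~ "domain not allowed",
    TRUE ~ "substance class not allowed"
  )
  out <- tibble::as_tibble(entries[keep, , drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Split a product-information document into its SmPC blocks
#'
#' A new SmPC starts at every line beginning with the top-level header
#' `1.`. Text before the first header is ignored; if no header is found an
#' empty list is returned with a warning.
#'
#' @param document A single character string (the whole document).
#' @return A list of character strings, one per SmPC.
#' @export
split_into_smpcs <- function(document) {
  stopifnot(is.character(document), length(document) == 1L)
  lines <- strsplit(document, "\n", fixed = TRUE)[[1]]
  starts <- grep("^\\s{0,3}1\\.\\s", lines)
  if (length(starts) == 0L) {
    warning("no SmPC header found in document", call. = FALSE)
    return(list())
  }
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    paste(lines[starts[i]:ends[i]], collapse = "\n")
  })
}

# locate numbered section headers; line-anchored, number followed by a dot
# (top level) or containing a dot (subsections), then whitespace and text.
header_table <- function(lines) {
  m <- regmatches(lines, regexec("^\\s{0,3}(\\d+(?:\\.\\d+)*)(\\.)?\\s+\\S",
                                 lines))
  rows <- lapply(seq_along(m), function(i) {
    if (length(m[[i]]) == 0) return(NULL)
    num <- m[[i]][2]
    trailing_dot <- nzchar(m[[i]][3])
    # a bare integer with no trailing dot is prose ("6 tablets daily")
    if (!grepl(".", num, fixed = TRUE) && !trailing_dot) return(NULL)
    data.frame(line = i, number = num,
               depth = length(strsplit(num, ".", fixed = TRUE)[[1]]))
  })
  do.call(rbind, rows)
}

#' Extract the key sections of one SmPC
#'
#' Pulls the payload of sections 2 (composition), 3 (pharmaceutical form),
#' 5.2 (pharmacokinetics) and 6.1 (excipients). A section's payload is the
#' text strictly between its header line and the next header of equal or
#' higher level. Missing sections are flagged, never silently empty;
#' duplicated section numbers keep the first occurrence and are recorded in
#' the `conflicts` attribute.
#'
#' @param smpc A single SmPC text block.
#' @return A one-row tibble with columns `s2_composition`, `s3_form`,
#'   `s5_2_pk`, `s6_1_excipients` and logical `missing_*` flags; attribute
#'   `conflicts` lists duplicated headers.
#' @export
extract_sections <- function(smpc) {
  lines <- strsplit(smpc, "\n", fixed = TRUE)[[1]]
  hdr <- header_table(lines)
  wanted <- c(s2_composition = "2", s3_form = "3", s5_2_pk = "5.2",
              s6_1_excipients = "6.1")
  out <- list()
  conflicts <- character()
  for (field in names(wanted)) {
    num <- wanted[[field]]
    hits <- if (is.null(hdr)) integer() else which(hdr$number == num)
    if (length(hits) == 0L) {
      out[[field]] <- NA_character_
      next
    }
    if (length(hits) > 1L) conflicts <- c(conflicts, num)
    h <- hits[1]
    depth <- hdr$depth[h]
    later <- which(seq_len(nrow(hdr)) > h & hdr$depth <= depth)
    end_line <- if (length(later)) hdr$line[min(later)] - 1L else length(lines)
    start_line <- hdr$line[h] + 1L
    body <- if (end_line >= start_line) lines[start_line:end_line] else character()
    payload <- trimws(paste(body, collapse = "\n"))
    out[[field]] <- if (nzchar(payload)) payload else NA_character_
  }
  res <- tibble::tibble(
    s2_composition = out$s2_composition, s3_form = out$s3_form,
    s5_2_pk = out$s5_2_pk, s6_1_excipients = out$s6_1_excipients,
    missing_s2 = is.na(out$s2_composition),
    missing_s3 = is.na(out$s3_form),
    missing_s5_2 = is.na(out$s5_2_pk),
    missing_s6_1 = is.na(out$s6_1_excipients)
  )
  attr(res, "conflicts") <- unique(conflicts)
  res
}

#' Normalize a section 6.1 excipient list to canonical identifiers
#'
#' Maps each non-empty line through the controlled vocabulary
#' (case-insensitive), deduplicates while preserving order of first
#' appearance, and collects unmapped lines for manual review in the
#' `unmapped` attribute. Idempotent on its own output (canonical IDs map to
#' themselves).
#'
#' @param s6_1 Section text (one excipient per line) or `NA`.
#' @param vocabulary A vocabulary tibble, default [excipient_vocabulary()].
#' @return Character vector of canonical IDs with attribute `unmapped`.
#' @export
normalize_excipients <- function(s6_1, vocabulary = excipient_vocabulary()) {
  if (is.na(s6_1)) {
    return(structure(character(), unmapped = character()))
  }
  lines <- trimws(strsplit(s6_1, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines) & tolower(lines) != "not applicable."]
  key <- tolower(lines)
  i <- match(key, vocabulary$surface)
  # canonical ids pass through unchanged so the mapping is idempotent
  self <- match(key, unique(vocabulary$canonical_id))
  ids <- ifelse(!is.na(i), vocabulary$canonical_id[i],
                ifelse(!is.na(self), key, NA_character_))
  unmapped <- lines[is.na(ids)]
  structure(unique(ids[!is.na(ids)]), unmapped = unmapped)
}

mr_keywords <- "prolonged-release|modified-release|gastro-resistant|sustained-release|extended-release"

#' Parse the pharmaceutical form section
#'
#' Maps the form phrase through the dosage-form vocabulary to a canonical
#' form and its licensed routes; the modified-release flag is true iff a
#' release-modifying keyword is present (or the vocabulary marks the form
#' as modified release). Unmappable forms are flagged for manual review.
#'
#' @param s3 Section 3 text.
#' @param vocabulary Dosage-form vocabulary tibble.
#' @return A one-row tibble: `form`, `routes` (list-column),
#'   `modified_release`, `needs_review`.
#' @export
parse_dosage_form_and_routes <- function(s3,
                                         vocabulary = dosage_form_vocabulary()) {
  phrase <- tolower(trimws(sub("\\.\\s*$", "", strsplit(
    ifelse(is.na(s3), "", s3), "\n")[[1]][1])))
  i <- match(phrase, vocabulary$surface)
  if (is.na(i)) {
    return(tibble::tibble(form = NA_character_, routes = list(character()),
                          modified_release = grepl(mr_keywords, phrase),
                          needs_review = TRUE))
  }
  tibble::tibble(
    form = vocabulary$canonical_form[i],
    routes = list(strsplit(vocabulary$routes[i], "|", fixed = TRUE)[[1]]),
    modified_release = vocabulary$modified_release[i] ||
      grepl(mr_keywords, phrase),
    needs_review = FALSE
  )
}

#' Parse doses from the composition section
#'
#' Recognizes statements of the form "Each <unit> contains <amount> <unit>
#' of <substance> (as <form>)". Amounts are standardized to milligrams;
#' the "(as ...)" clause is captured as the form-of-drug annotation.
#' Unparseable composition text yields zero rows and is flagged via the
#' `unparsed` attribute rather than guessed.
#'
#' @param s2 Section 2 text.
#' @return A tibble with columns `substance`, `dose_mg`, `form_of_drug`.
#' @export
parse_doses <- function(s2) {
  empty <- tibble::tibble(substance = character(), dose_mg = numeric(),
                          form_of_drug = character())
  if (is.na(s2)) return(structure(empty, unparsed = TRUE))
  pat <- paste0("[Cc]ontains\\s+([0-9]+(?:\\.[0-9]+)?)\\s*",
                "(mg|g|micrograms?)\\s+of\\s+",
                "([A-Za-z][A-Za-z0-9 -]*?)",
                "(?:\\s+\\(as ([a-z][a-z ]*)\\))?\\s*\\.")
  m <- gregexpr(pat, s2, perl = TRUE)
  hits <- regmatches(s2, m)[[1]]
  if (length(hits) == 0L) return(structure(empty, unparsed = TRUE))
  rows <- lapply(hits, function(h) {
    g <- regmatches(h, regexec(pat, h, perl = TRUE))[[1]]
    amount <- as.numeric(g[2])
    unit <- g[3]
    mg <- switch(unit, g = amount * 1000,
                 mg = amount,
                 amount / 1000) # micrograms
    tibble::tibble(substance = trimws(g[4]), dose_mg = mg,
                   form_of_drug = ifelse(nzchar(g[5]), g[5], NA_character_))
  })
  structure(dplyr::bind_rows(rows), unparsed = FALSE)
}

#' Keep the highest-strength formulation per brand and dosage form
#'
#' Within each (brand, dosage form) group the record maximizing the dose of
#' the first listed active substance is kept; ties keep the first
#' occurrence and are recorded in the `ties` attribute.
#'
#' @param formulations A tibble with columns `brand`, `dosage_form` and a
#'   `doses` list-column of dose tibbles (per [parse_doses()]).
#' @return The reduced tibble with attribute `ties`.
#' @export
select_highest_strength <- function(formulations) {
  if (nrow(formulations) == 0) return(formulations)
  first_dose <- vapply(formulations$doses, function(d) {
    if (is.null(d) || nrow(d) == 0) return(NA_real_)
    d$dose_mg[1]
  }, numeric(1))
  key <- paste(formulations$brand, formulations$dosage_form, sep = "\r")
  keep <- logical(nrow(formulations))
  ties <- character()
  for (k in unique(key)) {
    idx <- which(key == k)
    dmax <- suppressWarnings(max(first_dose[idx], na.rm = TRUE))
    if (!is.finite(dmax)) { keep[idx[1]] <- TRUE; next }
    winners <- idx[!is.na(first_dose[idx]) & first_dose[idx] == dmax]
    if (length(winners) > 1L) ties <- c(ties, sub("\r", "/", k))
    keep[winners[1]] <- TRUE
  }
  out <- formulations[keep, , drop = FALSE]
  attr(out, "ties") <- ties
  out
}

# regexes for the oral PK dialects; applied case-insensitively
pk_patterns <- list(
  fa_range = "([0-9]+(?:\\.[0-9]+)?)\\s+to\\s+([0-9]+(?:\\.[0-9]+)?)%\\s+of\\s+(?:an|the)\\s+oral\\s+dose\\s+is\\s+absorbed",
  fa_point = "(?:approximately\\s+)?([0-9]+(?:\\.[0-9]+)?)%\\s+of\\s+(?:an|the)\\s+oral\\s+dose\\s+is\\s+absorbed",
  fa_lower = "at\\s+least\\s+([0-9]+(?:\\.[0-9]+)?)%\\s+of\\s+the\\s+dose\\s+is\\s+absorbed",
  fa_mass  = "([0-9]+(?:\\.[0-9]+)?)%\\s+of\\s+the\\s+dose\\s+was\\s+recovered\\s+in\\s+urine",
  f_range  = "absolute\\s+bioavailability\\s+is\\s+([0-9]+(?:\\.[0-9]+)?)\\s+to\\s+([0-9]+(?:\\.[0-9]+)?)%",
  f_point  = "absolute\\s+bioavailability\\s+is\\s+(?:approximately\\s+)?([0-9]+(?:\\.[0-9]+)?)%",
  tmax     = "reached\\s+(?:approximately\\s+)?([0-9]+(?:\\.[0-9]+)?)\\s+hours?"
)

pk_capture <- function(text, pattern) {
  m <- regexec(paste0("(?i)", pattern), text, perl = TRUE)
  g <- regmatches(text, m)[[1]]
  if (length(g) == 0) NULL else g
}

#' Extract oral pharmacokinetic values from section 5.2 text
#'
#' Point values are captured as stated. A range "X to Y%" yields the
#' arithmetic mean of the limits with flag `range_mean`; "at least X%"
#' yields X with flag `lower_bound`; absorption stated only through urinary
#' recovery of a radiolabelled dose yields the recovered percentage with
#' flag `inferred_mass_balance`. Fraction absorbed is reported as a
#' proportion, absolute bioavailability as a percentage, Tmax in hours.
#' Wording that conflates absorption with bioavailability is never
#' auto-resolved; each value keeps its own flag.
#'
#' @param s5_2 Section 5.2 text (may be `NA`).
#' @return A one-row tibble: `fa`, `fa_flag`, `f_abs`, `f_flag`, `tmax`,
#'   `source_span`.
#' @export
extract_oral_pk <- function(s5_2) {
  out <- tibble::tibble(fa = NA_real_, fa_flag = NA_character_,
                        f_abs = NA_real_, f_flag = NA_character_,
                        tmax = NA_real_, source_span = NA_character_)
  if (is.na(s5_2) || !nzchar(trimws(s5_2))) return(out)
  spans <- character()
  g <- pk_capture(s5_2, pk_patterns$fa_range)
  if (!is.null(g)) {
    out$fa <- (as.numeric(g[2]) + as.numeric(g[3])) / 2 / 100
    out$fa_flag <- "range_mean"; spans <- c(spans, g[1])
  } else if (!is.null(g <- pk_capture(s5_2, pk_patterns$fa_point))) {
    out$fa <- as.numeric(g[2]) / 100
    out$fa_flag <- "point"; spans <- c(spans, g[1])
  } else if (!is.null(g <- pk_capture(s5_2, pk_patterns$fa_lower))) {
    out$fa <- as.numeric(g[2]) / 100
    out$fa_flag <- "lower_bound"; spans <- c(spans, g[1])
  } else if (!is.null(g <- pk_capture(s5_2, pk_patterns$fa_mass))) {
    out$fa <- as.numeric(g[2]) / 100
    out$fa_flag <- "inferred_mass_balance"; spans <- c(spans, g[1])
  }
  g <- pk_capture(s5_2, pk_patterns$f_range)
  if (!is.null(g)) {
    out$f_abs <- (as.numeric(g[2]) + as.numeric(g[3])) / 2
    out$f_flag <- "range_mean"; spans <- c(spans, g[1])
  } else if (!is.null(g <- pk_capture(s5_2, pk_patterns$f_point))) {
    out$f_abs <- as.numeric(g[2])
    out$f_flag <- "point"; spans <- c(spans, g[1])
  }
  g <- pk_capture(s5_2, pk_patterns$tmax)
  if (!is.null(g)) {
    out$tmax <- as.numeric(g[2]); spans <- c(spans, g[1])
  }
  if (length(spans)) out$source_span <- paste(spans, collapse = " ... ")
  out
}

#' Parse a corpus of product-information documents
#'
#' The full document-processing pipeline: filter the register, split each
#' retained document into SmPCs, extract and normalize the four key
#' sections, and reduce to the highest strength per (brand, dosage form).
#'
#' @param register A register tibble (see [filter_register()]).
#' @param documents Named character vector of document texts keyed by
#'   product name, or a directory containing `<product>.txt` files.
#' @param keep_all_strengths Keep every SmPC block instead of reducing to
#'   the highest strength.
#' @return A list with `products` (retained register rows), `formulations`
#'   (one row per kept SmPC: brand, dosage form, routes, modified-release
#'   flag, doses, excipient IDs, oral PK fields) and `log` (removed
#'   register rows, unmapped excipients, unparsed sections).
#' @export
parse_corpus <- function(register, documents, keep_all_strengths = FALSE) {
  retained <- filter_register(register)
  get_doc <- function(nm) {
    if (is.character(documents) && length(documents) == 1 &&
        dir.exists(documents)) {
      path <- file.path(documents, paste0(nm, ".txt"))
      if (!file.exists(path)) return(NA_character_)
      paste(readLines(path, warn = FALSE), collapse = "\n")
    } else {
      if (!nm %in% names(documents)) return(NA_character_)
      documents[[nm]]
    }
  }
  rows <- list()
  unmapped_log <- list()
  for (i in seq_len(nrow(retained))) {
    nm <- retained$product_name[i]
    doc <- get_doc(nm)
    if (is.na(doc)) next
    blocks <- split_into_smpcs(doc)
    for (b in seq_along(blocks)) {
      sec <- extract_sections(blocks[[b]])
      form <- parse_dosage_form_and_routes(sec$s3_form)
      doses <- parse_doses(sec$s2_composition)
      exc <- normalize_excipients(sec$s6_1_excipients)
      if (length(attr(exc, "unmapped"))) {
        unmapped_log[[length(unmapped_log) + 1L]] <-
          tibble::tibble(brand = nm, line = attr(exc, "unmapped"))
      }
      pk <- extract_oral_pk(sec$s5_2_pk)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        brand = nm, smpc_index = b,
        dosage_form = form$form, routes = form$routes,
        modified_release = form$modified_release,
        form_needs_review = form$needs_review,
        doses = list(doses), excipient_ids = list(as.character(exc)),
        fa = pk$fa, fa_flag = pk$fa_flag, f_abs = pk$f_abs,
        f_flag = pk$f_flag, tmax = pk$tmax, pk_span = pk$source_span
      )
    }
  }
  formulations <- dplyr::bind_rows(rows)
  if (!keep_all_strengths && nrow(formulations) > 0) {
    formulations <- select_highest_strength(formulations)
  }
  list(products = retained, formulations = formulations,
       log = list(removed = attr(retained, "removed"),
                  unmapped_excipients = dplyr::bind_rows(unmapped_log),
                  ties = attr(formulations, "ties")))
}
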