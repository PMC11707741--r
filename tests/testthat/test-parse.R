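test_that("the register filter keeps human chemical products, with reasons", {
  reg <- tibble::tibble(
    product_name = paste0("P", 1:5),
    domain = c("human", "human", "human", "veterinary", "veterinary"),
    substance_class = "chemical")
  out <- filter_register(reg)
  expect_equal(nrow(out), 3L)
  expect_equal(out$product_name, paste0("P", 1:3)) # order preserved
  expect_equal(attr(out, "removed")$removal_reason,
               rep("domain not allowed", 2))
  biol <- tibble::tibble(product_name = "B", domain = "human",
                         substance_class = "biological")
  out2 <- filter_register(biol)
  expect_equal(nrow(out2), 0L)
  expect_equal(nrow(attr(out2, "removed")), 1L)
  expect_equal(nrow(filter_register(reg[0, ])), 0L)
})

test_that("splitting returns the body unchanged for a single SmPC and [] without headers", {
  doc <- "1. NAME OF THE MEDICINAL PRODUCT\n\nBrand 10 mg tablet\n\n2. COMPOSITION\n\nstuff"
  blocks <- split_into_smpcs(doc)
  expect_length(blocks, 1L)
  expect_identical(trimws(blocks[[1]]), trimws(doc))
  expect_warning(empty <- split_into_smpcs("no headers here\njust prose"),
                 "no SmPC header")
  expect_length(empty, 0L)
})

test_that("section extraction is line-anchored and immune to in-prose numbers", {
  smpc <- paste(
    "1. NAME", "", "Brand", "",
    "2. QUALITATIVE AND QUANTITATIVE COMPOSITION", "",
    "Each tablet contains 10 mg of drugx. See section 6.1 for details.",
    "A dose of 6.1 mg was studied.", "",
    "3. PHARMACEUTICAL FORM", "", "Tablet.", "",
    "5. PHARMACOLOGICAL PROPERTIES", "",
    "5.2 Pharmacokinetic properties", "", "Approximately 50% of an oral dose is absorbed.", "",
    "6. PHARMACEUTICAL PARTICULARS", "",
    "6.1 List of excipients", "", "talc", "",
    "6.2 Incompatibilities", "", "None.",
    sep = "\n")
  sec <- extract_sections(smpc)
  expect_match(sec$s2_composition, "6.1 mg was studied", fixed = TRUE)
  expect_identical(sec$s6_1_excipients, "talc")
  expect_false(sec$missing_s5_2)
  expect_identical(sec$s3_form, "Tablet.")
})

test_that("missing and duplicated sections are flagged, not silently dropped", {
  smpc <- paste("1. NAME", "", "2. COMPOSITION", "", "Each tablet contains 1 mg of x.",
                "", "3. FORM", "", "Tablet.", "",
                "3. FORM", "", "Capsule.", sep = "\n")
  sec <- extract_sections(smpc)
  expect_true(sec$missing_s5_2)
  expect_true(sec$missing_s6_1)
  expect_identical(sec$s3_form, "Tablet.") # first occurrence wins
  expect_equal(attr(sec, "conflicts"), "3")
})

test_that("excipient normalization groups polymer synonyms and is idempotent", {
  ids <- normalize_excipients("macrogol 4000\npolyethylene glycol 6000\ntalc")
  expect_equal(as.character(ids), c("macrogol", "talc"))
  again <- normalize_excipients(paste(ids, collapse = "\n"))
  expect_equal(as.character(again), as.character(ids))
  expect_length(normalize_excipients(NA_character_), 0L)
  unk <- normalize_excipients("talc\nunobtainium dust")
  expect_equal(attr(unk, "unmapped"), "unobtainium dust")
  expect_equal(as.character(unk), "talc")
})

test_that("dosage forms map to canonical terms, routes and release flags", {
  fc <- parse_dosage_form_and_routes("Film-coated tablet.")
  expect_equal(fc$form, "tablet")
  expect_false(fc$modified_release)
  pr <- parse_dosage_form_and_routes("Prolonged-release tablet.")
  expect_true(pr$modified_release)
  inf <- parse_dosage_form_and_routes("Solution for infusion.")
  expect_true("intravenous" %in% inf$routes[[1]])
  odd <- parse_dosage_form_and_routes("Magic lozenge.")
  expect_true(odd$needs_review)
})

test_that("doses standardize to milligrams and capture the form of drug", {
  d <- parse_doses("Each tablet contains 500 mg of drugx.")
  expect_equal(d$dose_mg, 500)
  d2 <- parse_doses("Each capsule contains 1 g of drugy (as hydrochloride).")
  expect_equal(d2$dose_mg, 1000)
  expect_equal(d2$form_of_drug, "hydrochloride")
  d3 <- parse_doses("Each tablet contains 250 micrograms of drugz.")
  expect_equal(d3$dose_mg, 0.25)
  bad <- parse_doses("Contains an adequate amount of drug.")
  expect_equal(nrow(bad), 0L)
  expect_true(attr(bad, "unparsed"))
})

test_that("highest-strength selection is per dosage form with logged ties", {
  doses <- function(mg) list(tibble::tibble(substance = "x", dose_mg = mg,
                                            form_of_drug = NA_character_))
  f <- tibble::tibble(
    brand = "B",
    dosage_form = c("tablet", "tablet", "tablet", "capsule", "tablet"),
    doses = c(doses(10), doses(20), doses(40), doses(20), doses(40)))
  out <- select_highest_strength(f)
  kept <- vapply(out$doses, function(d) d$dose_mg[1], numeric(1))
  expect_equal(sort(kept), c(20, 40))
  expect_equal(nrow(out), 2L) # tablet 40 (first of the tie) + capsule 20
  expect_match(attr(out, "ties"), "B/tablet")
})

test_that("PK extraction applies the range-mean, lower-bound and mass-balance rules", {
  r <- extract_oral_pk("The absolute bioavailability is 50 to 60%.")
  expect_equal(r$f_abs, 55)
  expect_equal(r$f_flag, "range_mean")
  lb <- extract_oral_pk(
    "At least 70% of the dose is absorbed from the gastrointestinal tract.")
  expect_equal(lb$fa, 0.70)
  expect_equal(lb$fa_flag, "lower_bound")
  combo <- extract_oral_pk(paste(
    "Approximately 60% of an oral dose is absorbed.",
    "The absolute bioavailability is 2%."))
  expect_equal(combo$fa, 0.60)
  expect_equal(combo$f_abs, 2)
  mb <- extract_oral_pk(
    "Following oral administration of a radiolabelled dose, 85% of the dose was recovered in urine.")
  expect_equal(mb$fa, 0.85)
  expect_equal(mb$fa_flag, "inferred_mass_balance")
  tm <- extract_oral_pk(
    "Maximum plasma concentrations are reached approximately 1.5 hours after oral administration.")
  expect_equal(tm$tmax, 1.5)
  none <- extract_oral_pk("Not applicable.")
  expect_true(is.na(none$fa) && is.na(none$f_abs) && is.na(none$tmax))
})

test_that("the register filter recovers exactly the planted truth set", {
  corp <- small_corpus()
  out <- filter_register(corp$register)
  expect_setequal(out$product_name, corp$truth$retained_products)
})
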