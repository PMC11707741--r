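# Shared corpora, generated once per test run. The large corpus matches the
# package's reference study conditions (200 products, seed 11); the small
# one keeps per-module tests fast.

the_test_cache <- new.env(parent = emptyenv())

with_cache <- function(key, builder) {
  if (!exists(key, envir = the_test_cache)) {
    assign(key, builder(), envir = the_test_cache)
  }
  get(key, envir = the_test_cache)
}

reference_corpus <- function() {
  with_cache("reference", function() {
    synthesize_corpus(synthetic_config(n_products = 200L, seed = 11L))
  })
}

reference_parsed <- function() {
  with_cache("reference_parsed", function() {
    corp <- reference_corpus()
    parse_corpus(corp$register, corp$documents, keep_all_strengths = TRUE)
  })
}

small_corpus <- function() {
  with_cache("small", function() {
    synthesize_corpus(synthetic_config(n_products = 40L, seed = 5L))
  })
}

small_db <- function() {
  with_cache("small_db", function() {
    corp <- small_corpus()
    parsed <- parse_corpus(corp$register, corp$documents)
    build_database(parsed, corp$dictionary)
  })
}
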