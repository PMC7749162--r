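test_that("lexicon loading normalizes names and merges duplicate entries", {
  skip_if_not_installed("withr")
  path <- tmp_lexicon_file(tibble::tibble(
    source_id = c("MESH", "MESH", "MEDDRA"),
    preferred_name = c("Diabetes  Mellitus ", "diabetes mellitus", "Asthma"),
    identifier = c("D1", "D2", "M1")))
  lex <- read_lexicon(path)
  mesh <- dplyr::filter(lex, source_id == "MESH")
  expect_equal(nrow(mesh), 1)
  expect_equal(mesh$term_norm, "diabetes mellitus")
  expect_equal(mesh$identifiers[[1]], c("D1", "D2"))
})

test_that("empty and malformed lexicon files are handled", {
  skip_if_not_installed("withr")
  empty <- tmp_lexicon_file(tibble::tibble(
    source_id = character(), preferred_name = character(),
    identifier = character()))
  expect_equal(nrow(read_lexicon(empty)), 0)

  bad <- tmp_lexicon_file(tibble::tibble(
    source_id = c("MESH", NA), preferred_name = c("x", "y"),
    identifier = c("1", "2")))
  err <- expect_error(read_lexicon(bad), class = "ctg_load_error")
  expect_match(conditionMessage(err), "2")
})

test_that("the bundled fixture lexicon loads with a stable shape", {
  lex <- ctg_fixture_lexicon()
  expect_setequal(unique(lex$source_id), c("MESH", "MEDDRA", "SNOMEDCT"))
  expect_equal(nrow(lex), 117)  # 118 raw rows, one duplicate name merged
  aspirin <- dplyr::filter(lex, source_id == "MESH", term_norm == "aspirin")
  expect_length(aspirin$identifiers[[1]], 2)
})

test_that("matching is per-occurrence and union accounting is consistent", {
  lex <- ctg_fixture_lexicon()
  tab <- match_terms(c("diabetes mellitus", "Diabetes Mellitus",
                       "no such thing"), lex)
  mesh <- dplyr::filter(tab, source_id == "MESH")
  expect_equal(mesh$matched, 2)        # bag semantics: both occurrences
  union_row <- dplyr::filter(tab, source_id == "union")
  expect_equal(union_row$matched + union_row$unmatched,
               union_row$total_values)
  expect_gte(union_row$matched, max(tab$matched[tab$source_id != "union"]))

  empty <- match_terms(character(), lex)
  expect_true(all(empty$matched == 0) && all(empty$total_values == 0))
})

test_that("matching is invariant under the declared normalization", {
  lex <- ctg_fixture_lexicon()
  a <- match_terms(c("ASTHMA", "  asthma  ", "asthma"), lex)
  b <- match_terms(rep("Asthma", 3), lex)
  expect_equal(a$matched, b$matched)
  # strict-case mode distinguishes them
  strict <- ctg_fixture_lexicon(strict_case = TRUE)
  tab <- match_terms(c("ASTHMA", "Asthma"), strict, strict_case = TRUE)
  expect_equal(dplyr::filter(tab, source_id == "union")$matched, 1)
})

test_that("adding a lexicon never decreases union coverage", {
  lex <- ctg_fixture_lexicon()
  values <- c("Asthma", "Aspirin", "unmapped term", "Hypertension")
  small <- match_terms(values, dplyr::filter(lex, source_id == "MEDDRA"))
  full <- match_terms(values, lex)
  expect_gte(dplyr::filter(full, source_id == "union")$matched,
             dplyr::filter(small, source_id == "union")$matched)
  restricted <- match_terms(values, lex, restrict_to = "MEDDRA")
  expect_equal(restricted$matched, small$matched)
})

test_that("match_terms agrees with a naive per-value linear scan", {
  lex <- ctg_fixture_lexicon()
  set.seed(4)
  pool <- c(unique(lex$term_norm), sprintf("novel term %d", 1:40))
  values <- sample(pool, 120, replace = TRUE)
  tab <- match_terms(values, lex)
  for (s in unique(lex$source_id)) {
    naive <- sum(vapply(values, function(v) {
      any(lex$source_id == s & lex$term_norm == normalize_term(v))
    }, logical(1)))
    expect_equal(dplyr::filter(tab, source_id == s)$matched, naive, label = s)
  }
  naive_union <- sum(vapply(values, function(v) {
    any(lex$term_norm == normalize_term(v))
  }, logical(1)))
  expect_equal(dplyr::filter(tab, source_id == "union")$matched, naive_union)
})

test_that("stratified coverage partitions totals by intervention type", {
  gen <- generate_corpus(corpus_config(
    44, seed = 5,
    lexicon_membership = list(intervention = 22)))
  cov <- coverage_by_stratum(gen$records, "intervention",
                             ctg_fixture_lexicon(),
                             stratifier = "intervention_type")
  all_row <- dplyr::filter(cov, stratum == "all", source_id == "union")
  per <- dplyr::filter(cov, stratum != "all", source_id == "union")
  expect_equal(sum(per$total_values), all_row$total_values)
  expect_equal(sum(per$matched), all_row$matched)
  expect_equal(all_row$matched, 22)

  expect_error(
    coverage_by_stratum(gen$records, "condition", ctg_fixture_lexicon(),
                        stratifier = "intervention_type"),
    class = "ctg_config_error")
})
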