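test_that("canonical blocks parse into inclusion and exclusion lists", {
  cl <- classify_criteria(
    "Inclusion Criteria:\n- age > 18\nExclusion Criteria:\n- pregnancy")
  expect_equal(cl$format_class, "correct")
  expect_equal(cl$inclusion[[1]], "age > 18")
  expect_equal(cl$exclusion[[1]], "pregnancy")
  expect_false(cl$multi_group_suspected)

  # bullet variants and blank lines
  cl <- classify_criteria(paste0(
    "Inclusion Criteria\n\n* consenting adult\n1. literate\n",
    "Exclusion criteria:\n- none"))
  expect_equal(cl$format_class, "correct")
  expect_equal(cl$inclusion[[1]], c("consenting adult", "literate"))
})

test_that("paragraph lines under correct headers give headers_only", {
  cl <- classify_criteria(paste0(
    "Inclusion Criteria:\n",
    "Patients will be eligible if they are over 18.\n",
    "Exclusion Criteria:\n- pregnancy"))
  expect_equal(cl$format_class, "headers_only")
  expect_equal(cl$error_codes[[1]], "NONBULLETED_BODY")
  expect_length(cl$inclusion[[1]], 0)
})

test_that("missing and malformed headers are distinguished", {
  expect_equal(classify_criteria("")$format_class, "missing")
  expect_equal(classify_criteria("   \n ")$format_class, "missing")
  expect_equal(classify_criteria(NA)$format_class, "missing")

  for (txt in c("Key Inclusion Criteria:\n- a\nExclusion Criteria:\n- b",
                "INCLUSION:\n- a\nEXCLUSION:\n- b",
                "Inclusion Criteria:\n- a")) {
    cl <- classify_criteria(txt)
    expect_equal(cl$format_class, "malformed_headers", label = txt)
    expect_equal(cl$error_codes[[1]], "MISSING_OR_MALFORMED_HEADERS")
  }
})

test_that("classification is total over arbitrary text", {
  set.seed(9)
  pieces <- c("Inclusion Criteria:", "Exclusion Criteria", "- bullet",
              "prose sentence here.", "", "2) numbered", "INCLUSION:",
              "Inclusion criteria for donors:")
  for (i in 1:50) {
    txt <- paste(sample(pieces, sample(1:6, 1), replace = TRUE),
                 collapse = "\n")
    cl <- classify_criteria(txt)
    expect_true(cl$format_class %in%
                  c("correct", "headers_only", "malformed_headers", "missing"))
  }
})

test_that("multi-group criteria are flagged by headers with qualifiers", {
  expect_true(detect_multi_group(
    "Inclusion Criteria - Cohort A:\n- a\nInclusion Criteria - Cohort B:\n- b"))
  expect_true(detect_multi_group(paste0(
    "Inclusion criteria for healthy volunteers:\n- fit\n",
    "Inclusion criteria for patients:\n- diagnosed")))
  # four plain headers exceed the two expected
  expect_true(detect_multi_group(paste0(
    "Inclusion Criteria:\n- a\nExclusion Criteria:\n- b\n",
    "Inclusion Criteria:\n- c\nExclusion Criteria:\n- d")))
  expect_false(detect_multi_group(
    "Inclusion Criteria:\n- a\nExclusion Criteria:\n- b"))
  cl <- classify_criteria(
    "Inclusion criteria for healthy volunteers:\n- fit\nInclusion criteria for patients:\n- ill")
  expect_equal(cl$format_class, "malformed_headers")
  expect_true(cl$multi_group_suspected)
})

test_that("splitting into separate fields removes header error codes", {
  blocks <- c(
    "Inclusion Criteria:\nProse line.\n- b\nExclusion Criteria:\n- c",
    "Inclusion Criteria:\n- a\nExclusion Criteria:\n- b",
    "Key Inclusion Criteria:\n- a\nExclusion Criteria:\n- b")
  for (txt in blocks) {
    parts <- split_criteria_fields(txt)
    for (part in purrr::compact(parts)) {
      cl <- classify_criteria(part, headers_required = FALSE)
      expect_false("MISSING_OR_MALFORMED_HEADERS" %in% cl$error_codes[[1]],
                   label = part)
    }
  }
  # a clean split of a correct block is correct in headerless mode
  parts <- split_criteria_fields(blocks[2])
  expect_equal(
    classify_criteria(parts$inclusion, headers_required = FALSE)$format_class,
    "correct")
})

test_that("extrapolation reproduces the Wilson interval and point estimate", {
  ex <- extrapolate(55, 400, 117906)
  expect_equal(ex$proportion, 0.1375)
  expect_equal(ex$point_estimate, 16212)
  expect_equal(signif(ex$point_estimate, 3), 16200)

  # oracle: solve the score equations numerically rather than via the
  # closed form used by the implementation
  z <- qnorm(0.975)
  p_hat <- 55 / 400
  score_root <- function(sign) {
    uniroot(function(p) p_hat - p + sign * z * sqrt(p * (1 - p) / 400),
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  expect_equal(ex$ci_low, score_root(-1), tolerance = 1e-6)
  expect_equal(ex$ci_high, score_root(1), tolerance = 1e-6)

  zero <- extrapolate(0, 400, 117906)
  expect_equal(zero$point_estimate, 0)
  expect_equal(zero$ci_low, 0)
  expect_true(zero$ci_high > 0)

  expect_error(extrapolate(5, 4, 100), class = "ctg_value_error")
  expect_error(extrapolate(1, 400, 10), class = "ctg_value_error")

  td <- tidy(ex)
  expect_equal(td$point_estimate, 16212)
  expect_equal(glance(ex)$sample_size, 400)
})

test_that("sample-size arithmetic matches the normal-approximation bound", {
  expect_equal(sample_size_for_margin(0.95, 0.05), 385L)
  # the bound holds at n and fails at n - 1
  z <- qnorm(0.975)
  expect_lte(z^2 * 0.25 / 385, 0.05^2)
  expect_gt(z^2 * 0.25 / 384, 0.05^2)
  expect_lt(sample_size_for_margin(0.95, 0.05, 0.14),
            sample_size_for_margin(0.95, 0.05, 0.5))
  expect_gt(sample_size_for_margin(0.95, 0.01), sample_size_for_margin(0.95, 0.05))
  expect_error(sample_size_for_margin(0.95, 0), class = "ctg_value_error")
})
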