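test_that("sensitivity is coverage of the relevant set", {
  case <- fixture_case()
  # 4 of the 5 relevant anamnestic questions asked
  log <- log_from_actions(case, data.frame(
    section = "a", item_id = c("a1", "a2", "a3", "a4")))
  expect_equal(section_sensitivity(case, log, "a"), 0.8)
  # repeats never add coverage
  log2 <- log_from_actions(case, data.frame(
    section = "a", item_id = c("a1", "a1", "a1")))
  expect_equal(section_sensitivity(case, log2, "a"), 0.2)
})

test_that("precision counts distinct items, repeats collapse", {
  case <- fixture_case()
  # same relevant medical test twice plus one irrelevant test
  log <- log_from_actions(case, data.frame(
    section = "m", item_id = c("m1", "m1", "mx1")))
  expect_equal(section_precision(case, log, "m"), 0.5)
  # 4 relevant of 10 total distinct selections
  log2 <- log_from_actions(case, data.frame(
    section = "s",
    item_id = c("s1", "s2", "s3", "s4", "sx1", "sx2", "sx3",
                "ax1", "px1", "mx2")))
  expect_equal(section_precision(case, log2, "s"), 0.4)
  # zero actions in a section: precision defined as 0
  expect_equal(section_precision(case, log2, "p"), 0)
})

test_that("binary analysis scores only first attempts", {
  case <- fixture_case()  # 6 reference pairs
  ref <- case$binary_reference
  key <- function(i) paste(ref$factor_id[i], ref$hypothesis_id[i], sep = "|")
  wrong <- function(i) setdiff(ba_anchors(), ref$anchor[i])[1]
  # pairs 1-4 correct on attempt 1; pair 5 wrong then corrected on
  # attempt 2; pair 6 never executed
  actions <- data.frame(
    section = "b",
    item_id = c(vapply(1:5, key, character(1)), key(5)),
    attempt = c(1L, 1L, 1L, 1L, 1L, 2L),
    payload = c(ref$anchor[1:4], wrong(5), ref$anchor[5]))
  log <- log_from_actions(case, actions)
  expect_equal(section_sensitivity(case, log, "b"), 4 / 6)
  expect_equal(section_precision(case, log, "b"), 4 / 5)
})

test_that("F1 is the harmonic mean with the zero case defined as 0", {
  expect_equal(section_f1(1, 1), 1)
  expect_equal(section_f1(0, 0.7), 0)
  expect_equal(section_f1(0.8, 0.4), 2 * 0.8 * 0.4 / 1.2)
  expect_equal(section_f1(0, 0), 0)
  expect_error(section_f1(1.2, 0.5), "\\[0, 1\\]")
  # harmonic-mean bound when both components are positive
  set.seed(41)
  for (i in 1:50) {
    s <- runif(1, 0.01, 1)
    p <- runif(1, 0.01, 1)
    f <- section_f1(s, p)
    expect_gte(f, min(s, p))
    expect_lte(f, max(s, p))
  }
})

test_that("a perfect log scores 1 everywhere and an empty log 0", {
  case <- fixture_case()
  scores <- score_all_sections(case, perfect_log(case))
  expect_identical(scores$section, section_codes())
  expect_equal(scores$f1, rep(1, 7))
  empty <- score_all_sections(case, action_log("x", "fix1"))
  expect_equal(empty$f1, rep(0, 7))
  expect_equal(empty$sensitivity, rep(0, 7))
  expect_equal(empty$precision, rep(0, 7))
})

test_that("a section with an empty relevant set is flagged not assessable", {
  case <- fixture_case()
  case$relevant_items$m <- character(0)
  case <- validate_case(case)
  log <- log_from_actions(case, data.frame(section = "s", item_id = "s1"))
  scores <- score_all_sections(case, log)
  m_row <- scores[scores$section == "m", ]
  expect_false(m_row$assessable)
  expect_true(is.na(m_row$f1))
  # excluded from the composite averages, which still work
  expect_identical(composite_scores(scores)$assessable_sections,
                   setdiff(section_codes(), "m"))
})

test_that("section scores equal an independent brute-force recount", {
  set.seed(2024)
  for (i in 1:60) {
    fx <- random_fixture(max_items = 10)
    scores <- score_all_sections(fx$case, fx$log)
    for (sec in section_codes()) {
      o <- oracle_section_counts(fx$case, fx$log, sec)
      row <- scores[scores$section == sec, ]
      expect_identical(row$n_relevant_total, o$n_total)
      expect_identical(row$n_relevant_found, o$n_found)
      expect_identical(row$n_actions, o$n_actions)
      if (o$n_total > 0) {
        expect_equal(row$sensitivity, o$n_found / o$n_total)
        expect_equal(row$precision,
                     if (o$n_actions == 0) 0 else o$n_found / o$n_actions)
      }
    }
  }
})

test_that("metrics respond monotonically to added actions", {
  set.seed(7)
  case <- fixture_case()
  base_actions <- data.frame(section = c("a", "a", "a"),
                             item_id = c("a1", "a2", "ax1"))
  base <- score_all_sections(case, log_from_actions(case, base_actions))
  a_row <- function(s) s[s$section == "a", ]

  # adding an unseen relevant action: sensitivity and f1 never decrease
  more_rel <- rbind(base_actions, data.frame(section = "a", item_id = "a3"))
  with_rel <- score_all_sections(case, log_from_actions(case, more_rel))
  expect_gte(a_row(with_rel)$sensitivity, a_row(base)$sensitivity)
  expect_gte(a_row(with_rel)$f1, a_row(base)$f1)

  # adding an unseen irrelevant action: precision never increases
  more_noise <- rbind(base_actions, data.frame(section = "a", item_id = "ax2"))
  with_noise <- score_all_sections(case, log_from_actions(case, more_noise))
  expect_lte(a_row(with_noise)$precision, a_row(base)$precision)
})
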