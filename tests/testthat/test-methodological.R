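test_that("the execution string encodes actions as section codes", {
  case <- fixture_case()
  # 3 scenario factors, 2 anamnestic questions, 2 physical examinations
  log <- log_from_actions(case, data.frame(
    section = c("s", "s", "s", "a", "a", "p", "p"),
    item_id = c("s1", "s2", "s3", "a1", "a2", "p1", "p2")))
  es <- build_execution_string(log)
  expect_identical(es$raw, "sssaapp")
  expect_identical(es$collapsed, "sap")

  # alternation survives collapsing
  log2 <- log_from_actions(case, data.frame(
    section = c("s", "a", "s", "a"), item_id = c("s1", "a1", "s2", "a2")))
  expect_identical(build_execution_string(log2)$collapsed, "sasa")

  # empty log gives empty strings
  es0 <- build_execution_string(action_log("x", "fix1"))
  expect_identical(es0$raw, "")
  expect_identical(es0$collapsed, "")
})

test_that("critical-act mode restricts the string to bound actions", {
  case <- fixture_case()
  log <- log_from_actions(case, data.frame(
    section = c("s", "a", "a", "p", "m", "r"),
    item_id = c("s1", "a1", "a2", "p1", "m1", "h1")))
  # critical acts are bound to s1, p1, p2, m1, h1 only
  expect_identical(build_execution_string(log, "critical", case)$raw, "spmr")
  expect_error(build_execution_string(log, "critical"), "requires the case")
})

test_that("collapse_runs removes contiguous repeats and is idempotent", {
  expect_identical(collapse_runs("sssaapp"), "sap")
  expect_identical(collapse_runs("sap"), "sap")
  expect_identical(collapse_runs("aabbaa"), "aba")
  expect_identical(collapse_runs(""), "")
  set.seed(5)
  for (i in 1:50) {
    raw <- paste(sample(section_codes(), sample(0:12, 1), replace = TRUE),
                 collapse = "")
    phi <- collapse_runs(raw)
    expect_identical(collapse_runs(phi), phi)
    expect_lte(nchar(phi), nchar(raw))
    chars <- strsplit(phi, "")[[1]]
    if (length(chars) > 1) expect_true(all(chars[-1] != chars[-length(chars)]))
  }
})

test_that("levenshtein similarity matches its definition and is symmetric", {
  expect_equal(levenshtein_similarity("sap", "sap"), 1)
  expect_equal(levenshtein_similarity("asp", "sap"), 1 / 3)
  expect_equal(levenshtein_similarity("hr", "br"), 0.5)
  expect_equal(levenshtein_similarity("", ""), 1)
  expect_equal(levenshtein_similarity("", "br"), 0)
  set.seed(99)
  for (i in 1:100) {
    x <- paste(sample(section_codes(), sample(0:7, 1), replace = TRUE),
               collapse = "")
    y <- paste(sample(section_codes(), sample(0:7, 1), replace = TRUE),
               collapse = "")
    expect_equal(levenshtein_similarity(x, y), levenshtein_similarity(y, x))
    # independent oracle: generalized edit distance in C (utils::adist)
    expect_identical(levenshtein_distance(x, y),
                     as.integer(utils::adist(x, y)))
  }
})

test_that("the five workflow parameters match their definitions", {
  # p1: prefix conformance to scenario -> anamnesis -> examination
  expect_equal(compute_p1("saphmbr"), 1)
  expect_equal(compute_p1("sa"), 2 / 3)
  expect_equal(compute_p1(""), 0)
  # p2: suffix conformance to binary analysis -> result
  expect_equal(compute_p2("saphmbr"), 1)
  expect_equal(compute_p2("saphmhr"), 0.5)
  expect_equal(compute_p2(""), 0)
  # p3: hypothesis before medical test
  expect_equal(compute_p3("saphmbr"), 1)
  expect_equal(compute_p3("sampbhr"), 0)
  expect_equal(compute_p3("sapbhr"), 1)   # no test ordered: no violation
  expect_equal(compute_p3("sampbr"), 0)   # tests without any hypothesis
  # p4: section coverage out of 7
  expect_equal(compute_p4("sapr"), 4 / 7)
  expect_equal(compute_p4("saphmbr"), 1)
  expect_equal(compute_p4("s"), 1 / 7)
  # p5: revisit penalty 1 / (1 + R)
  expect_equal(compute_p5("saphmbr"), 1)
  expect_equal(compute_p5("sapas"), 1 / 3)
  expect_equal(compute_p5(""), 1)
})

test_that("the methodological score is the Euclidean norm of p1..p5", {
  case <- fixture_case()
  m <- methodological_score(perfect_log(case))
  expect_identical(m$phi, "saphmbr")
  expect_equal(c(m$p1, m$p2, m$p3, m$p4, m$p5), rep(1, 5))
  expect_equal(m$score, sqrt(5))
  expect_equal(m$normalized, 1)

  # empty log: documented degenerate vector (0, 0, 1, 0, 1), score sqrt(2)
  m0 <- methodological_score(action_log("x", "fix1"))
  expect_equal(c(m0$p1, m0$p2, m0$p3, m0$p4, m0$p5), c(0, 0, 1, 0, 1))
  expect_equal(m0$score, sqrt(2))

  # norm identity on arbitrary logs
  set.seed(17)
  for (i in 1:20) {
    fx <- random_fixture(max_items = 6)
    m <- methodological_score(fx$log)
    expect_equal(m$score^2,
                 m$p1^2 + m$p2^2 + m$p3^2 + m$p4^2 + m$p5^2,
                 tolerance = 1e-12)
    expect_gte(m$score, 0)
    expect_lte(m$score, sqrt(5) + 1e-12)
  }
})

test_that("an extra back-and-forth revisit strictly lowers p5 and the score", {
  case <- fixture_case()
  base <- perfect_actions(case)
  revisit <- rbind(base, data.frame(section = "a", item_id = "a1",
                                    payload = NA_character_))
  m_base <- methodological_score(log_from_actions(case, base))
  m_rev <- methodological_score(log_from_actions(case, revisit))
  expect_identical(m_rev$phi, "saphmbra")
  expect_lt(m_rev$p5, m_base$p5)
  expect_lt(m_rev$score, m_base$score)
})
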