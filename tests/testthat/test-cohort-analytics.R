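test_that("cohort report summarizes per-student scores with sample SD", {
  case <- generate_case(seed = 21)
  logs <- generate_cohort(case, 12, seed = 21)
  rep <- cohort_report(case, logs)
  expect_identical(rep$n, 12L)
  expect_identical(nrow(rep$students), 12L)

  x <- rep$students$overall
  expect_equal(rep$class_mean, sum(x) / length(x))
  # sample (n-1) standard deviation, computed from the definition
  expect_equal(rep$class_sd,
               sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
  expect_gte(rep$class_mean, min(x))
  expect_lte(rep$class_mean, max(x))

  # ranks are competition ranks over the cohort
  expect_identical(rep$students$overall_rank, rank_scores(x))

  # identical perfect students: mean 1, SD 0, one occupied histogram bin
  perfect <- lapply(1:4, function(i) perfect_log(fixture_case(),
                                                 sprintf("p%d", i)))
  prep <- cohort_report(fixture_case(), perfect)
  expect_equal(prep$class_mean, 1)
  expect_equal(prep$class_sd, 0)
  expect_identical(sum(prep$histogram$count > 0), 1L)
  expect_identical(prep$histogram$count[20], 4L)  # 1.0 lands in [0.95, 1]
})

test_that("the histogram uses 20 right-open 0.05 bins that conserve counts", {
  case <- generate_case(seed = 8)
  logs <- generate_cohort(case, 30, seed = 8)
  rep <- cohort_report(case, logs)
  h <- rep$histogram
  expect_identical(nrow(h), 20L)
  expect_equal(h$bin_high - h$bin_low, rep(0.05, 20))
  expect_equal(h$bin_low, seq(0, 0.95, by = 0.05))
  expect_identical(sum(h$count), 30L)
})

test_that("radar data pairs each student with the class-mean ring", {
  case <- generate_case(seed = 5)
  logs <- generate_cohort(case, 6, seed = 5)
  rep <- cohort_report(case, logs)
  rd <- radar_data(rep, "stu003")
  expect_identical(rd$section, section_codes())
  expect_equal(rd$student_f1, as.numeric(rep$section_f1["stu003", ]))
  expect_equal(rd$class_mean_f1,
               as.numeric(colMeans(rep$section_f1)))  # column means
  expect_error(radar_data(rep, "nobody"), "unknown student")

  # class of one: both rings identical
  solo <- cohort_report(case, logs[3])
  rd1 <- radar_data(solo, "stu003")
  expect_equal(rd1$student_f1, rd1$class_mean_f1)

  # a perfect student's ring is constant at 1
  pcase <- fixture_case()
  prep <- cohort_report(pcase, list(perfect_log(pcase)))
  expect_equal(radar_data(prep, "perfect")$student_f1, rep(1, 7))
})

test_that("spearman validation handles concordance, ties and deletion", {
  x <- stats::setNames(1:10 / 10, paste0("s", 1:10))
  y_conc <- stats::setNames(21:30, paste0("s", 1:10))
  expect_equal(spearman_validation(x, y_conc)$rho, 1)
  y_disc <- stats::setNames(rev(unname(y_conc)), names(y_conc))
  expect_equal(spearman_validation(x, y_disc)$rho, -1)

  # ties: agree with R's own Spearman machinery (average ranks, t approx)
  set.seed(31)
  for (i in 1:20) {
    n <- sample(8:25, 1)
    a <- stats::setNames(sample(1:6, n, replace = TRUE), paste0("s", 1:n))
    b <- stats::setNames(sample(20:33, n, replace = TRUE), paste0("s", 1:n))
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    v <- spearman_validation(a, b)
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                           exact = FALSE))
    expect_equal(v$rho, unname(ct$estimate))
    expect_equal(v$p_value, ct$p.value, tolerance = 1e-12)
    expect_identical(v$n, n)
  }

  # students missing either value are dropped pairwise, n reported
  x_miss <- stats::setNames(c(1, 2, NA, 4, 5, 6), paste0("s", 1:6))
  y_miss <- stats::setNames(c(6, 5, 4, 3, 2, 1), paste0("s", c(1:5, 7)))
  v <- spearman_validation(x_miss, y_miss)
  expect_identical(v$n, 4L)  # s3 is NA, s6 unmatched
  expect_equal(v$rho, -1)

  expect_error(spearman_validation(x[1:2], y_conc[1:2]), "at least 3")
  v_const <- spearman_validation(stats::setNames(rep(1, 5), paste0("s", 1:5)),
                                 y_conc[1:5])
  expect_false(v_const$defined)
  expect_true(is.na(v_const$rho))
})

test_that("validate_metrics reports one Spearman row per main metric", {
  case <- generate_case(seed = 3)
  logs <- generate_cohort(case, 15, seed = 3)
  rep <- cohort_report(case, logs)
  # external score perfectly concordant with the overall score
  external <- data.frame(student_id = rep$students$student_id,
                         score = rep$students$overall * 33)
  val <- validate_metrics(rep, external)
  expect_identical(val$metric,
                   c("overall", "collection", "analytical", "methodological"))
  expect_equal(val$rho[val$metric == "overall"], 1)
  expect_identical(val$n, rep(15L, 4))
})

test_that("a cohort report writes the full directory of exports", {
  case <- generate_case(seed = 12)
  logs <- generate_cohort(case, 8, seed = 12)
  rep <- cohort_report(case, logs)
  dir <- withr::local_tempdir()
  external <- data.frame(student_id = rep$students$student_id,
                         score = sample(20:33, 8, replace = TRUE))
  write_cohort_report(rep, dir, external = external)
  for (f in c("students.csv", "histogram.csv", "radar.csv", "paths.csv",
              "validation.csv", "summary.json")) {
    expect_true(file.exists(file.path(dir, f)), info = f)
  }
  students <- read.csv(file.path(dir, "students.csv"))
  expect_identical(nrow(students), 8L)
  radar <- read.csv(file.path(dir, "radar.csv"))
  expect_identical(nrow(radar), 8L * 7L)
  paths <- read.csv(file.path(dir, "paths.csv"))
  expect_identical(sum(paths$count), 8L)
  summ <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(summ$class_mean_overall, rep$class_mean)
})
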