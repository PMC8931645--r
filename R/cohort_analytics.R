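#' Score a whole cohort and assemble the class report
#'
#' Runs the full per-student pipeline (section F1 values, composite
#' overall/collection/analytical scores with competition ranks,
#' methodological components, critical-act path) over every log, then adds
#' class-level summaries: mean and sample (n-1) standard deviation of the
#' overall score, its histogram over \[0, 1\] in 20 bins of width 0.05
#' (right-open, the last bin closed so 1.0 is counted), the per-section
#' class-mean F1 vector used as the radar-chart baseline, and the path
#' frequency table. Scoring is fully deterministic given the logs.
#'
#' @param case A `simulation_case`.
#' @param logs List of `action_log` objects (at least one).
#' @param phi_mode Execution-string mode for the methodological score,
#'   `"all"` (default) or `"critical"`; see [build_execution_string()].
#' @param weights Optional section weights passed to the composite scores.
#' @return List of class `cohort_report`: `students` (one row per student
#'   with all scores and ranks), `section_f1` (student x section matrix),
#'   `class_mean`, `class_sd`, `histogram`, `radar_baseline`, `paths`
#'   (list of `student_path`, `NULL` when the case declares no critical
#'   acts), `path_table`, `case_id`, `n`.
#' @export
cohort_report <- function(case, logs, phi_mode = c("all", "critical"),
                          weights = NULL) {
  stopifnot(inherits(case, "simulation_case"))
  phi_mode <- match.arg(phi_mode)
  if (length(logs) == 0) stop("empty cohort", call. = FALSE)
  stopifnot(all(vapply(logs, inherits, logical(1), "action_log")))

  n <- length(logs)
  ids <- vapply(logs, function(l) l$student_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate student_id(s) in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  section_tabs <- lapply(logs, function(l) score_all_sections(case, l))
  f1_mat <- t(vapply(section_tabs, function(s) s$f1, numeric(7)))
  colnames(f1_mat) <- section_codes()
  rownames(f1_mat) <- ids

  comp <- lapply(section_tabs, composite_scores, weights = weights)
  meth <- lapply(logs, methodological_score, mode = phi_mode, case = case)

  have_acts <- nrow(case$critical_acts) > 0
  paths <- if (have_acts) lapply(logs, function(l) extract_path(case, l))
           else NULL

  students <- data.frame(
    student_id = ids,
    overall = vapply(comp, `[[`, numeric(1), "overall"),
    collection = vapply(comp, `[[`, numeric(1), "collection"),
    analytical = vapply(comp, `[[`, numeric(1), "analytical"),
    stringsAsFactors = FALSE)
  students$overall_rank <- rank_scores(students$overall)
  students$collection_rank <- rank_scores(students$collection)
  students$analytical_rank <- rank_scores(students$analytical)
  students$phi <- vapply(meth, `[[`, character(1), "phi")
  for (pn in c("p1", "p2", "p3", "p4", "p5")) {
    students[[pn]] <- vapply(meth, `[[`, numeric(1), pn)
  }
  students$revisits <- vapply(meth, function(m) as.integer(m$R), integer(1))
  students$methodological <- vapply(meth, `[[`, numeric(1), "score")
  students$methodological_normalized <-
    vapply(meth, `[[`, numeric(1), "normalized")
  students$methodological_rank <- rank_scores(students$methodological)
  if (have_acts) {
    students$path <- vapply(paths, `[[`, character(1), "path")
    students$matches_desired <-
      vapply(paths, `[[`, logical(1), "matches_desired")
    students$includes_all_acts <-
      vapply(paths, `[[`, logical(1), "includes_all_acts")
  }

  structure(list(
    case_id = case$case_id,
    n = n,
    students = students,
    section_f1 = f1_mat,
    class_mean = mean(students$overall),
    class_sd = if (n > 1) stats::sd(students$overall) else 0,
    histogram = score_histogram(students$overall),
    radar_baseline = colMeans(f1_mat),
    paths = paths,
    path_table = if (have_acts) cohort_path_table(paths) else NULL
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> case %s, n = %d students\n", x$case_id, x$n))
  cat(sprintf("  overall score: mean %.3f, SD %.3f\n",
              x$class_mean, x$class_sd))
  cat("  class-mean section F1:",
      paste(sprintf("%s=%.2f", names(x$radar_baseline), x$radar_baseline),
            collapse = " "), "\n")
  if (!is.null(x$path_table)) {
    top <- x$path_table[1, ]
    cat(sprintf("  %d distinct critical-act paths; most common \"%s\" (%d students, %d%%)\n",
                nrow(x$path_table), top$path, top$count, top$percent_label))
  }
  invisible(x)
}

# Histogram of scores over [0,1]: 20 bins of width 0.05, right-open
# except the last (so a perfect 1.0 lands in [0.95, 1]).
score_histogram <- function(x, bin_width = 0.05) {
  breaks <- seq(0, 1, by = bin_width)
  bins <- cut(x, breaks = breaks, right = FALSE, include.lowest = TRUE)
  counts <- as.integer(table(bins))
  data.frame(bin_low = breaks[-length(breaks)],
             bin_high = breaks[-1],
             count = counts)
}

#' Radar-chart data for one student against the class
#'
#' The seven section F1 values of one student paired with the class-mean
#' F1 per section, in canonical section order — the two rings of the
#' radar chart comparing an individual with the class.
#'
#' @param report A `cohort_report`.
#' @param student_id A student present in the report.
#' @return Data frame with columns `section`, `student_f1`,
#'   `class_mean_f1`.
#' @export
radar_data <- function(report, student_id) {
  stopifnot(inherits(report, "cohort_report"))
  if (!student_id %in% rownames(report$section_f1)) {
    stop("unknown student_id: ", student_id, call. = FALSE)
  }
  data.frame(section = section_codes(),
             student_f1 = as.numeric(report$section_f1[student_id, ]),
             class_mean_f1 = as.numeric(report$radar_baseline),
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation of a simulator metric with an external score
#'
#' Validation of a simulator metric against an independent measure (e.g. a
#' curricular examination score). Rho is the Pearson correlation of
#' average ranks (ties get the mean rank); the two-sided p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2
#' degrees of freedom, adequate at class sizes of a few dozen. Students
#' missing either value are dropped pairwise and the retained n is
#' reported. If either variable is constant on the retained pairs, rho is
#' undefined and the result is flagged.
#'
#' @param metric_values Named numeric vector (names = student ids) of the
#'   simulator metric.
#' @param external_scores Named numeric vector of the external score.
#' @param metric_name Label carried into the result.
#' @return List of class `validation_result`: `metric`, `rho`, `p_value`,
#'   `n`, `defined`.
#' @export
spearman_validation <- function(metric_values, external_scores,
                                metric_name = "metric") {
  if (is.null(names(metric_values)) || is.null(names(external_scores))) {
    stop("metric_values and external_scores must be named by student id",
         call. = FALSE)
  }
  common <- intersect(names(metric_values), names(external_scores))
  x <- metric_values[common]
  y <- external_scores[common]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    stop("need at least 3 complete (metric, external) pairs; got ", n,
         call. = FALSE)
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(structure(list(metric = metric_name, rho = NA_real_,
                          p_value = NA_real_, n = n, defined = FALSE),
                     class = "validation_result"))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  structure(list(metric = metric_name, rho = rho, p_value = p, n = n,
                 defined = TRUE),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("<validation> %s: rho undefined (constant values), n = %d\n",
                x$metric, x$n))
  } else {
    cat(sprintf("<validation> %s: rho = %.3f, p = %.4f, n = %d\n",
                x$metric, x$rho, x$p_value, x$n))
  }
  invisible(x)
}

#' Validate the four main metrics against an external score table
#'
#' Correlates the overall, collection, analytical and methodological
#' scores of a cohort report with an external per-student score, one
#' Spearman test per metric.
#'
#' @param report A `cohort_report`.
#' @param external Data frame with columns `student_id` and `score`.
#' @return Data frame with one row per metric: `metric`, `rho`, `p_value`,
#'   `n`.
#' @export
validate_metrics <- function(report, external) {
  stopifnot(inherits(report, "cohort_report"))
  if (!is.data.frame(external) ||
      !all(c("student_id", "score") %in% names(external))) {
    stop("external must be a data frame with columns student_id, score",
         call. = FALSE)
  }
  ext <- stats::setNames(external$score, external$student_id)
  st <- report$students
  metrics <- c(overall = "overall", collection = "collection",
               analytical = "analytical", methodological = "methodological")
  rows <- lapply(names(metrics), function(mn) {
    v <- spearman_validation(stats::setNames(st[[metrics[[mn]]]],
                                             st$student_id),
                             ext, metric_name = mn)
    data.frame(metric = v$metric, rho = v$rho, p_value = v$p_value,
               n = v$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a cohort report to a directory of CSV files
#'
#' Emits `students.csv` (all per-student metrics and ranks),
#' `histogram.csv` (0.05-wide bins of the overall score), `radar.csv`
#' (per-student and class-mean section F1, long format), `paths.csv`
#' (critical-act path frequencies, when the case declares acts),
#' `validation.csv` (when an external score table is given) and
#' `summary.json` (class-level numbers, machine readable).
#'
#' @param report A `cohort_report`.
#' @param dir Output directory (created if needed).
#' @param external Optional external score table for [validate_metrics()].
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(report, dir, external = NULL) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$students, file.path(dir, "students.csv"),
                   row.names = FALSE)
  utils::write.csv(report$histogram, file.path(dir, "histogram.csv"),
                   row.names = FALSE)
  radar <- do.call(rbind, lapply(rownames(report$section_f1), function(id) {
    cbind(student_id = id, radar_data(report, id))
  }))
  utils::write.csv(radar, file.path(dir, "radar.csv"), row.names = FALSE)
  if (!is.null(report$path_table)) {
    utils::write.csv(report$path_table, file.path(dir, "paths.csv"),
                     row.names = FALSE)
  }
  if (!is.null(external)) {
    utils::write.csv(validate_metrics(report, external),
                     file.path(dir, "validation.csv"), row.names = FALSE)
  }
  summary <- list(case_id = report$case_id, n = report$n,
                  class_mean_overall = report$class_mean,
                  class_sd_overall = report$class_sd,
                  radar_baseline = as.list(report$radar_baseline))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
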