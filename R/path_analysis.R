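#' Extract a student's critical-diagnostic-act path
#'
#' Each case declares a small set of critical diagnostic acts (uppercase
#' one-letter ids bound to concrete actions, e.g. S = reading the input
#' scenario, P = abdominal palpation) and a desired execution path over
#' them. The student's path is the act ids ordered by the sequence index
#' of each act's first execution; acts never executed are absent, and
#' re-executions do not move an act from its first position. Non-critical
#' actions interleaved anywhere in the log never change the path.
#'
#' @param case A `simulation_case` declaring at least one critical act.
#' @param log An `action_log`.
#' @return List of class `student_path`: `student_id`, `path` (string of
#'   act ids), `matches_desired`, `includes_all_acts`.
#' @export
extract_path <- function(case, log) {
  stopifnot(inherits(case, "simulation_case"), inherits(log, "action_log"))
  acts <- case$critical_acts
  if (nrow(acts) == 0) {
    stop("case declares no critical acts", call. = FALSE)
  }
  rec <- log$records
  first_seq <- vapply(seq_len(nrow(acts)), function(i) {
    hit <- rec$section == acts$section[i] & rec$item_id == acts$item_id[i]
    if (any(hit)) min(rec$seq[hit]) else NA_integer_
  }, integer(1))
  executed <- !is.na(first_seq)
  ord <- order(first_seq[executed])
  path <- paste(acts$act_id[executed][ord], collapse = "")
  structure(list(student_id = log$student_id,
                 path = path,
                 matches_desired = nzchar(case$desired_path) &&
                   identical(path, case$desired_path),
                 includes_all_acts = all(executed)),
            class = "student_path")
}

#' @export
print.student_path <- function(x, ...) {
  cat(sprintf("<student_path> %s: \"%s\"%s%s\n", x$student_id, x$path,
              if (x$matches_desired) " [desired]" else "",
              if (x$includes_all_acts) "" else " [incomplete]"))
  invisible(x)
}

#' Cohort path frequency table
#'
#' Aggregates students' critical-act paths into distinct rows with counts
#' and cohort fractions — the data behind a flow diagram whose arrow widths
#' are proportional to how many students followed each path. `percent` is
#' the exact fraction; `percent_label` is the half-up integer percent used
#' in human-readable output (3 of 36 prints as 8%).
#'
#' @param paths List of `student_path` objects (one per student).
#' @return Data frame with columns `path`, `count`, `percent`,
#'   `percent_label`, `is_desired`, ordered by decreasing count. Counts
#'   sum to the cohort size.
#' @export
cohort_path_table <- function(paths) {
  if (length(paths) == 0) stop("empty cohort", call. = FALSE)
  stopifnot(all(vapply(paths, inherits, logical(1), "student_path")))
  p <- vapply(paths, function(x) x$path, character(1))
  desired <- vapply(paths, function(x) x$matches_desired, logical(1))
  tab <- table(p)
  out <- data.frame(path = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- out$count / length(p)
  out$percent_label <- floor(out$percent * 100 + 0.5)
  out$is_desired <- out$path %in% unique(p[desired])
  out <- out[order(-out$count, out$path), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count students whose path satisfies an act-presence query
#'
#' Generalizes questions such as "how many students reached the final
#' diagnosis without performing a physical examination" as configurable
#' predicates over the path: all acts in `present` executed, none of the
#' acts in `absent` executed.
#'
#' @param paths List of `student_path` objects.
#' @param present Character vector of act ids that must appear in the path.
#' @param absent Character vector of act ids that must not appear.
#' @return List with `count`, `n`, `percent` (exact fraction) and
#'   `percent_label` (half-up integer percent).
#' @export
path_query <- function(paths, present = character(0), absent = character(0)) {
  if (length(paths) == 0) stop("empty cohort", call. = FALSE)
  p <- vapply(paths, function(x) x$path, character(1))
  has <- function(path, act) grepl(act, path, fixed = TRUE)
  ok <- vapply(p, function(path) {
    all(vapply(present, has, logical(1), path = path)) &&
      !any(vapply(absent, has, logical(1), path = path))
  }, logical(1))
  count <- sum(ok)
  list(count = count, n = length(p), percent = count / length(p),
       percent_label = floor(count / length(p) * 100 + 0.5))
}
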