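#' Construct a student action log
#'
#' One log is the ordered stream of everything a student did during a
#' simulation. Each record carries a 1-based sequence index, the section
#' the action belongs to, the id of the item acted on, a relevance flag
#' (does the action match an author-declared correct action), an attempt
#' counter, and an optional free-text payload. For binary-analysis records
#' the item id is the `"factor|hypothesis"` pair key, the payload is the
#' submitted anchor, and attempts beyond 1 record later revisions of the
#' same pair; all other sections only ever use attempt 1. Only action
#' order and counts matter to the metrics; wall-clock time is never used.
#'
#' @param student_id,case_id Character scalars.
#' @param records Data frame with columns `seq` (strictly increasing
#'   integers), `section`, `item_id`, `relevant` (logical), `attempt`
#'   (positive integer) and optionally `payload`.
#' @param case Optional `simulation_case`: when supplied the case is
#'   authoritative and the `relevant` flags are recomputed from it (with a
#'   warning when a stored flag disagreed).
#' @return An object of class `action_log`.
#' @export
action_log <- function(student_id, case_id, records = NULL, case = NULL) {
  stopifnot(is.character(student_id), length(student_id) == 1L,
            is.character(case_id), length(case_id) == 1L)
  if (is.null(records) || nrow(as.data.frame(records)) == 0) {
    records <- data.frame(seq = integer(0), section = character(0),
                          item_id = character(0), relevant = logical(0),
                          attempt = integer(0), payload = character(0))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"payload" %in% names(records)) records$payload <- NA_character_
  needed <- c("seq", "section", "item_id", "relevant", "attempt", "payload")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[needed]
  records$seq <- as.integer(records$seq)
  records$attempt <- as.integer(records$attempt)
  records$relevant <- as.logical(records$relevant)
  records$payload <- as.character(records$payload)

  log <- structure(list(student_id = student_id, case_id = case_id,
                        records = records),
                   class = "action_log")
  validate_log(log, case = case)
}

#' Validate an action log
#'
#' Checks that sequence indices are strictly increasing, section codes are
#' in the closed 7-code set, attempts are positive and only section `b`
#' uses attempts above 1. When a case is supplied, also checks the case id
#' matches and recomputes every `relevant` flag from the case (the stored
#' flags are a cache; the case is authoritative). A disagreeing stored
#' flag is overwritten with a warning.
#'
#' @param log An `action_log`.
#' @param case Optional `simulation_case`.
#' @return The validated (possibly re-flagged) log.
#' @export
validate_log <- function(log, case = NULL) {
  stopifnot(inherits(log, "action_log"))
  rec <- log$records
  if (nrow(rec) > 0) {
    if (any(is.na(rec$seq)) || any(diff(rec$seq) <= 0)) {
      stop("record seq indices must be strictly increasing", call. = FALSE)
    }
    assert_section(rec$section)
    if (any(is.na(rec$attempt)) || any(rec$attempt < 1L)) {
      stop("attempt must be a positive integer", call. = FALSE)
    }
    if (any(rec$attempt > 1L & rec$section != "b")) {
      stop("attempt > 1 is only permitted in section b (binary analysis)",
           call. = FALSE)
    }
  }
  if (!is.null(case)) {
    stopifnot(inherits(case, "simulation_case"))
    if (log$case_id != case$case_id) {
      stop(sprintf("log case_id '%s' does not match case '%s'",
                   log$case_id, case$case_id), call. = FALSE)
    }
    flags <- derive_relevance(case, rec)
    disagree <- which(!is.na(rec$relevant) & rec$relevant != flags)
    if (length(disagree) > 0) {
      warning(sprintf(
        "%d stored relevance flag(s) disagreed with the case and were recomputed (seq %s)",
        length(disagree), paste(rec$seq[disagree], collapse = ", ")),
        call. = FALSE)
    }
    log$records$relevant <- flags
  }
  log
}

# Relevance from the answer key: membership in the section's relevant set;
# for binary analysis additionally the submitted anchor must equal the
# reference anchor for that pair.
derive_relevance <- function(case, records) {
  n <- nrow(records)
  if (n == 0) return(logical(0))
  flags <- logical(n)
  ba <- case$binary_reference
  ba_ref <- stats::setNames(ba$anchor, ba_pair_key(ba$factor_id,
                                                   ba$hypothesis_id))
  for (i in seq_len(n)) {
    sec <- records$section[i]
    id <- records$item_id[i]
    if (sec == "b") {
      flags[i] <- !is.na(ba_ref[id]) &&
        !is.na(records$payload[i]) && records$payload[i] == ba_ref[[id]]
    } else {
      flags[i] <- id %in% case_relevant_set(case, sec)
    }
  }
  flags
}

#' @export
print.action_log <- function(x, ...) {
  cat(sprintf("<action_log> student %s on case %s: %d actions\n",
              x$student_id, x$case_id, nrow(x$records)))
  if (nrow(x$records) > 0) {
    tab <- table(factor(x$records$section, levels = section_codes()))
    cat("  actions per section:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Read an action log file
#'
#' Log files are line-delimited JSON: the first line is a header object
#' `{"student_id": ..., "case_id": ...}` and each following line is one
#' action record. The stream layout means cohort logs can be appended to
#' and parsed without loading more than a line at a time.
#'
#' @param path Path to a log file.
#' @param case Optional `simulation_case` for cross-validation; when given,
#'   relevance flags are recomputed from the case.
#' @return A validated `action_log`.
#' @export
read_log <- function(path, case = NULL) {
  if (!file.exists(path)) stop("log file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty log file: ", path, call. = FALSE)
  header <- jsonlite::fromJSON(lines[[1]])
  if (is.null(header$student_id) || is.null(header$case_id)) {
    stop("log header must carry student_id and case_id: ", path,
         call. = FALSE)
  }
  if (length(lines) > 1) {
    recs <- lapply(lines[-1], jsonlite::fromJSON)
    records <- data.frame(
      seq = vapply(recs, function(r) as.integer(r$seq), integer(1)),
      section = vapply(recs, function(r) as.character(r$section),
                       character(1)),
      item_id = vapply(recs, function(r) as.character(r$item_id),
                       character(1)),
      relevant = vapply(recs, function(r) as.logical(r$relevant),
                        logical(1)),
      attempt = vapply(recs, function(r) as.integer(r$attempt), integer(1)),
      payload = vapply(recs, function(r) {
        if (is.null(r$payload)) NA_character_ else as.character(r$payload)
      }, character(1)),
      stringsAsFactors = FALSE)
  } else {
    records <- NULL
  }
  action_log(header$student_id, header$case_id, records, case = case)
}

#' Write an action log file
#'
#' Inverse of [read_log()]: emits the line-delimited JSON schema, one
#' record per line after the header.
#'
#' @param log A validated `action_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path) {
  validate_log(log)
  header <- jsonlite::toJSON(list(student_id = log$student_id,
                                  case_id = log$case_id),
                             auto_unbox = TRUE)
  rec <- log$records
  lines <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    row <- list(seq = rec$seq[i], section = rec$section[i],
                item_id = rec$item_id[i], relevant = rec$relevant[i],
                attempt = rec$attempt[i])
    if (!is.na(rec$payload[i])) row$payload <- rec$payload[i]
    lines[i] <- jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA)
  }
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Read every log in a directory
#'
#' @param dir Directory containing `*.jsonl` log files.
#' @param case Optional `simulation_case` passed to [read_log()].
#' @return List of `action_log` objects, ordered by file name.
#' @export
read_log_dir <- function(dir, case = NULL) {
  files <- sort(list.files(dir, pattern = "\\.jsonl$", full.names = TRUE))
  if (length(files) == 0) stop("no .jsonl log files in ", dir, call. = FALSE)
  lapply(files, read_log, case = case)
}
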