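#' Per-section sensitivity
#'
#' Sensitivity is coverage of the answer key: the fraction of the section's
#' author-declared relevant items the student acted on at least once.
#' Repeats of the same item count once (coverage of the reference set;
#' repetition is penalized by the methodological score, not here). For the
#' binary-analysis section the numerator counts (factor, hypothesis) pairs
#' whose first-attempt anchor equals the reference anchor and the
#' denominator is the total number of reference pairs; later attempts are
#' recorded but never scored.
#'
#' @param case A `simulation_case`.
#' @param log An `action_log`.
#' @param section One section code.
#' @return Fraction in \[0, 1\], or `NA` when the case declares no
#'   relevant items for the section (the section is "not assessable").
#' @export
section_sensitivity <- function(case, log, section) {
  score_section(case, log, section)$sensitivity
}

#' Per-section precision
#'
#' Precision is focus: the fraction of the distinct items the student acted
#' on in a section that are relevant per the answer key. A student with no
#' actions in the section gets precision 0 (inactivity is maximally
#' penalized so that scores stay total and bounded). For binary analysis
#' both numerator and denominator range over first-attempt pairs only.
#'
#' @inheritParams section_sensitivity
#' @return Fraction in \[0, 1\] (`NA` for a not-assessable section).
#' @export
section_precision <- function(case, log, section) {
  score_section(case, log, section)$precision
}

#' Harmonic-mean F1 of sensitivity and precision
#'
#' `2 s p / (s + p)`, the standard F1; defined as 0 when both components
#' are 0 so a fully inactive section scores 0 rather than NaN. 1 means
#' perfect sensitivity and perfect precision.
#'
#' @param sensitivity,precision Fractions in \[0, 1\].
#' @return Fraction in \[0, 1\]; `NA` if either input is `NA`.
#' @export
section_f1 <- function(sensitivity, precision) {
  if (length(sensitivity) != 1L || length(precision) != 1L) {
    stop("section_f1 is scalar; use score_all_sections for vectors",
         call. = FALSE)
  }
  if (is.na(sensitivity) || is.na(precision)) return(NA_real_)
  if (sensitivity < 0 || sensitivity > 1 || precision < 0 || precision > 1) {
    stop("sensitivity and precision must lie in [0, 1]", call. = FALSE)
  }
  if (sensitivity + precision == 0) return(0)
  2 * sensitivity * precision / (sensitivity + precision)
}

# One section's full score record. Relevance is always recomputed from the
# case so scores are a pure function of (case, raw actions).
score_section <- function(case, log, section) {
  stopifnot(inherits(case, "simulation_case"), inherits(log, "action_log"))
  assert_section(section)
  rec <- log$records[log$records$section == section, , drop = FALSE]
  relevant_set <- case_relevant_set(case, section)
  n_rel_total <- length(relevant_set)

  if (section == "b") {
    rec <- rec[rec$attempt == 1L, , drop = FALSE]
    rec <- rec[!duplicated(rec$item_id), , drop = FALSE]
    executed <- rec$item_id[rec$item_id %in% relevant_set]
    ba <- case$binary_reference
    ref <- stats::setNames(ba$anchor, ba_pair_key(ba$factor_id,
                                                  ba$hypothesis_id))
    hit <- rec$item_id[rec$item_id %in% relevant_set &
                         !is.na(rec$payload) &
                         rec$payload == unname(ref[rec$item_id])]
    n_actions <- length(executed)
    n_found <- length(hit)
  } else {
    acted <- unique(rec$item_id)
    hit <- intersect(acted, relevant_set)
    n_actions <- length(acted)
    n_found <- length(hit)
  }

  assessable <- n_rel_total > 0
  sens <- if (assessable) n_found / n_rel_total else NA_real_
  prec <- if (!assessable) NA_real_ else if (n_actions == 0) 0 else
    n_found / n_actions
  list(section = section,
       sensitivity = sens,
       precision = prec,
       f1 = if (assessable) section_f1(sens, prec) else NA_real_,
       n_relevant_total = n_rel_total,
       n_relevant_found = n_found,
       n_actions = n_actions,
       assessable = assessable)
}

#' Score all seven sections of one student's log
#'
#' @param case A `simulation_case`.
#' @param log An `action_log` for that case.
#' @return Data frame with one row per section in canonical order
#'   (`s, a, p, m, h, b, r`) and columns `section`, `sensitivity`,
#'   `precision`, `f1`, `n_relevant_total`, `n_relevant_found`,
#'   `n_actions`, `assessable`. Sections whose relevant set is empty are
#'   flagged not assessable (`NA` scores) and are excluded from the
#'   composite averages.
#' @seealso [composite_scores()], [methodological_score()]
#' @export
score_all_sections <- function(case, log) {
  if (log$case_id != case$case_id) {
    stop(sprintf("log case_id '%s' does not match case '%s'",
                 log$case_id, case$case_id), call. = FALSE)
  }
  rows <- lapply(section_codes(), function(s) {
    as.data.frame(score_section(case, log, s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
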