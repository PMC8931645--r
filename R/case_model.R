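#' Section codes of a simulated clinical encounter
#'
#' A virtual-patient simulation is divided into seven phases ("sections"),
#' each identified by a one-character code: `s` input scenario, `a`
#' anamnesis (history taking), `p` physical examination, `m` medical tests,
#' `h` diagnostic hypothesis generation, `b` binary analysis, `r` result
#' (final diagnosis). All scoring functions use this canonical order.
#'
#' @return Character vector of the 7 section codes in canonical order.
#' @export
section_codes <- function() c("s", "a", "p", "m", "h", "b", "r")

#' Sections grouped by skill
#'
#' The four data-gathering sections (`s`, `a`, `p`, `m`) form the
#' "collection" group; the three reasoning sections (`h`, `b`, `r`) form
#' the "analytical" group.
#'
#' @return Named list with elements `collection` and `analytical`.
#' @export
section_groups <- function() {
  list(collection = c("s", "a", "p", "m"), analytical = c("h", "b", "r"))
}

#' Human-readable section names
#' @return Named character vector keyed by section code.
#' @export
section_labels <- function() {
  c(s = "input scenario", a = "anamnesis", p = "physical examination",
    m = "medical test", h = "diagnostic hypothesis", b = "binary analysis",
    r = "final diagnosis")
}

#' The three binary-analysis anchors
#'
#' In the binary-analysis exercise the student labels each diagnostic
#' factor / diagnostic hypothesis pair by whether the factor increases,
#' decreases, or does not change (neutral) the hypothesis's likelihood.
#'
#' @return Character vector `c("increase", "neutral", "decrease")`.
#' @export
ba_anchors <- function() c("increase", "neutral", "decrease")

assert_section <- function(x, what = "section") {
  bad <- setdiff(unique(x), section_codes())
  if (length(bad) > 0) {
    stop(sprintf("invalid %s code(s): %s (must be one of %s)",
                 what, paste(bad, collapse = ", "),
                 paste(section_codes(), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

ba_pair_key <- function(factor_id, hypothesis_id) {
  paste(factor_id, hypothesis_id, sep = "|")
}

#' Construct a simulation case (the author's answer key)
#'
#' A `simulation_case` holds everything the case author declared correct:
#' the relevant items of each section, the hypothesis list (with the
#' reasonable subset and the correct final diagnosis), the binary-analysis
#' reference matrix, the critical diagnostic acts, and the desired
#' execution path over those acts. Every metric in the package is a pure
#' function of a case and an action log.
#'
#' @param case_id Character scalar identifying the case.
#' @param relevant_items Named list with character vectors of relevant item
#'   ids for sections `s`, `a`, `p`, `m` (missing sections default to
#'   empty). Hypothesis and final-diagnosis relevance come from
#'   `hypotheses`; binary-analysis relevance comes from `binary_reference`.
#' @param hypotheses Data frame with columns `id`, `label`, `reasonable`
#'   (logical: part of the author's reasonable differential) and
#'   `is_correct_final` (logical: acceptable final diagnosis).
#' @param binary_reference Data frame with columns `factor_id`,
#'   `hypothesis_id`, `anchor`; one row per (factor, hypothesis) pair, the
#'   anchor one of [ba_anchors()].
#' @param critical_acts Data frame with columns `act_id` (single uppercase
#'   character), `description`, `section`, `item_id`: each act is bound to
#'   a concrete relevant item so path extraction needs no text matching.
#' @param desired_path Character scalar: act_ids in the expected execution
#'   order, each at most once.
#' @param decoy_items Optional named list of per-section irrelevant item
#'   ids available in the simulation (used by the synthetic generator and
#'   by log validation; never by scoring).
#'
#' @return An object of class `simulation_case`.
#' @seealso [load_case()], [save_case()], [score_all_sections()]
#' @export
simulation_case <- function(case_id, relevant_items = list(),
                            hypotheses = NULL, binary_reference = NULL,
                            critical_acts = NULL, desired_path = "",
                            decoy_items = list()) {
  stopifnot(is.character(case_id), length(case_id) == 1L, nzchar(case_id))

  items <- stats::setNames(vector("list", 4L), c("s", "a", "p", "m"))
  for (sec in names(items)) items[[sec]] <- character(0)
  if (length(relevant_items) > 0) {
    assert_section(names(relevant_items), "relevant_items section")
    extra <- intersect(names(relevant_items), c("h", "b", "r"))
    if (length(extra) > 0) {
      stop("relevant items for sections h, b, r are derived from ",
           "'hypotheses' and 'binary_reference'; do not list them directly",
           call. = FALSE)
    }
    for (sec in names(relevant_items)) {
      items[[sec]] <- as.character(relevant_items[[sec]])
    }
  }

  if (is.null(hypotheses)) {
    hypotheses <- data.frame(id = character(0), label = character(0),
                             reasonable = logical(0),
                             is_correct_final = logical(0))
  }
  hypotheses <- as.data.frame(hypotheses, stringsAsFactors = FALSE)
  needed <- c("id", "label", "reasonable", "is_correct_final")
  missing_cols <- setdiff(needed, names(hypotheses))
  if (length(missing_cols) > 0) {
    stop("hypotheses is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  hypotheses <- hypotheses[needed]

  if (is.null(binary_reference)) {
    binary_reference <- data.frame(factor_id = character(0),
                                   hypothesis_id = character(0),
                                   anchor = character(0))
  }
  binary_reference <- as.data.frame(binary_reference,
                                    stringsAsFactors = FALSE)
  needed <- c("factor_id", "hypothesis_id", "anchor")
  missing_cols <- setdiff(needed, names(binary_reference))
  if (length(missing_cols) > 0) {
    stop("binary_reference is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  binary_reference <- binary_reference[needed]

  if (is.null(critical_acts)) {
    critical_acts <- data.frame(act_id = character(0),
                                description = character(0),
                                section = character(0),
                                item_id = character(0))
  }
  critical_acts <- as.data.frame(critical_acts, stringsAsFactors = FALSE)
  needed <- c("act_id", "description", "section", "item_id")
  missing_cols <- setdiff(needed, names(critical_acts))
  if (length(missing_cols) > 0) {
    stop("critical_acts is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  critical_acts <- critical_acts[needed]

  decoys <- stats::setNames(vector("list", 7L), section_codes())
  for (sec in section_codes()) decoys[[sec]] <- character(0)
  if (length(decoy_items) > 0) {
    assert_section(names(decoy_items), "decoy_items section")
    for (sec in names(decoy_items)) {
      decoys[[sec]] <- as.character(decoy_items[[sec]])
    }
  }

  case <- structure(
    list(case_id = case_id, relevant_items = items,
         hypotheses = hypotheses, binary_reference = binary_reference,
         critical_acts = critical_acts,
         desired_path = as.character(desired_path),
         decoy_items = decoys),
    class = "simulation_case")
  validate_case(case)
}

#' Validate a simulation case
#'
#' Checks every structural invariant of the answer key: unique ids within
#' each section and table, anchors restricted to the three binary-analysis
#' values, each (factor, hypothesis) pair appearing exactly once, at least
#' one correct final diagnosis when hypotheses exist, a desired path that
#' only references declared acts (each at most once), and at least one
#' non-empty relevant set overall.
#'
#' @param case A `simulation_case`.
#' @return The case, invisibly usable, after passing all checks.
#' @export
validate_case <- function(case) {
  stopifnot(inherits(case, "simulation_case"))

  for (sec in names(case$relevant_items)) {
    ids <- case$relevant_items[[sec]]
    if (anyDuplicated(ids)) {
      stop(sprintf("duplicate relevant item id(s) in section '%s': %s",
                   sec, paste(unique(ids[duplicated(ids)]), collapse = ", ")),
           call. = FALSE)
    }
  }

  hyp <- case$hypotheses
  if (anyDuplicated(hyp$id)) {
    stop("duplicate hypothesis id(s): ",
         paste(unique(hyp$id[duplicated(hyp$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(hyp) > 0 && !any(hyp$is_correct_final)) {
    stop("at least one hypothesis must have is_correct_final = TRUE",
         call. = FALSE)
  }

  ba <- case$binary_reference
  bad_anchor <- setdiff(unique(ba$anchor), ba_anchors())
  if (length(bad_anchor) > 0) {
    stop("binary_reference anchor(s) outside {increase, neutral, decrease}: ",
         paste(bad_anchor, collapse = ", "), call. = FALSE)
  }
  keys <- ba_pair_key(ba$factor_id, ba$hypothesis_id)
  if (anyDuplicated(keys)) {
    stop("binary_reference lists (factor, hypothesis) pair(s) more than once: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ba) > 0) {
    unknown_h <- setdiff(unique(ba$hypothesis_id), hyp$id)
    if (length(unknown_h) > 0) {
      stop("binary_reference references unknown hypothesis id(s): ",
           paste(unknown_h, collapse = ", "), call. = FALSE)
    }
  }

  acts <- case$critical_acts
  if (nrow(acts) > 0) {
    if (any(nchar(acts$act_id) != 1L) || any(acts$act_id != toupper(acts$act_id))) {
      stop("critical act_id must be a single uppercase character",
           call. = FALSE)
    }
    if (anyDuplicated(acts$act_id)) {
      stop("duplicate critical act id(s): ",
           paste(unique(acts$act_id[duplicated(acts$act_id)]), collapse = ", "),
           call. = FALSE)
    }
    assert_section(acts$section, "critical act section")
  }

  if (nzchar(case$desired_path)) {
    path_acts <- strsplit(case$desired_path, "", fixed = TRUE)[[1]]
    if (anyDuplicated(path_acts)) {
      stop("desired_path repeats act id(s): ",
           paste(unique(path_acts[duplicated(path_acts)]), collapse = ", "),
           call. = FALSE)
    }
    undeclared <- setdiff(path_acts, acts$act_id)
    if (length(undeclared) > 0) {
      stop("desired_path uses undeclared act id(s): ",
           paste(undeclared, collapse = ", "), call. = FALSE)
    }
  }

  any_rel <- any(lengths(case$relevant_items) > 0) ||
    any(hyp$reasonable %in% TRUE) || any(hyp$is_correct_final %in% TRUE) ||
    nrow(ba) > 0
  if (!any_rel) {
    stop("case defines no relevant items in any section", call. = FALSE)
  }
  case
}

#' Relevant item ids of one section
#'
#' Returns the reference set the sensitivity denominator counts: the
#' author-listed relevant items for `s`, `a`, `p`, `m`; the reasonable
#' hypotheses for `h`; the (factor, hypothesis) pair keys for `b`; and the
#' correct final diagnoses for `r`.
#'
#' @param case A `simulation_case`.
#' @param section One section code.
#' @return Character vector of relevant ids (possibly empty).
#' @export
case_relevant_set <- function(case, section) {
  stopifnot(inherits(case, "simulation_case"))
  assert_section(section)
  switch(section,
    h = case$hypotheses$id[case$hypotheses$reasonable %in% TRUE],
    r = case$hypotheses$id[case$hypotheses$is_correct_final %in% TRUE],
    b = ba_pair_key(case$binary_reference$factor_id,
                    case$binary_reference$hypothesis_id),
    case$relevant_items[[section]])
}

#' @export
print.simulation_case <- function(x, ...) {
  cat(sprintf("<simulation_case> %s\n", x$case_id))
  n_rel <- vapply(section_codes(), function(s) length(case_relevant_set(x, s)),
                  integer(1))
  cat("  relevant items per section:",
      paste(sprintf("%s=%d", section_codes(), n_rel), collapse = " "), "\n")
  cat(sprintf("  hypotheses: %d (%d reasonable, %d correct final)\n",
              nrow(x$hypotheses), sum(x$hypotheses$reasonable %in% TRUE),
              sum(x$hypotheses$is_correct_final %in% TRUE)))
  cat(sprintf("  binary reference pairs: %d\n", nrow(x$binary_reference)))
  cat(sprintf("  critical acts: %s; desired path: %s\n",
              paste(x$critical_acts$act_id, collapse = ""),
              if (nzchar(x$desired_path)) x$desired_path else "<none>"))
  invisible(x)
}

case_to_list <- function(case) {
  list(
    case_id = case$case_id,
    relevant_items = case$relevant_items,
    hypotheses = case$hypotheses,
    binary_reference = case$binary_reference,
    critical_acts = case$critical_acts,
    desired_path = case$desired_path,
    decoy_items = case$decoy_items
  )
}

#' Read a case-definition file
#'
#' The case format is a single UTF-8 JSON document holding the fields of
#' [simulation_case()]; [save_case()] writes it and `load_case()` is its
#' inverse, re-running the full validation on read.
#'
#' @param path Path to a case JSON file.
#' @return A validated `simulation_case`.
#' @export
load_case <- function(path) {
  if (!file.exists(path)) stop("case file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  needed <- c("case_id", "relevant_items", "hypotheses", "binary_reference",
              "critical_acts", "desired_path")
  missing_fields <- setdiff(needed, names(raw))
  if (length(missing_fields) > 0) {
    stop("case file is missing field(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  as_df <- function(x, cols) {
    if (is.null(x) || length(x) == 0) {
      return(stats::setNames(
        as.data.frame(replicate(length(cols), character(0),
                                simplify = FALSE)), cols))
    }
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  hyp <- as_df(raw$hypotheses, c("id", "label", "reasonable",
                                 "is_correct_final"))
  if (nrow(hyp) > 0) {
    hyp$reasonable <- as.logical(hyp$reasonable)
    hyp$is_correct_final <- as.logical(hyp$is_correct_final)
  }
  rel <- raw$relevant_items
  rel <- rel[vapply(rel, length, integer(1)) > 0]
  rel <- lapply(rel, as.character)
  dec <- raw$decoy_items
  if (is.null(dec)) dec <- list()
  dec <- dec[vapply(dec, length, integer(1)) > 0]
  dec <- lapply(dec, as.character)
  simulation_case(
    case_id = raw$case_id,
    relevant_items = rel,
    hypotheses = hyp,
    binary_reference = as_df(raw$binary_reference,
                             c("factor_id", "hypothesis_id", "anchor")),
    critical_acts = as_df(raw$critical_acts,
                          c("act_id", "description", "section", "item_id")),
    desired_path = if (length(raw$desired_path) == 0) "" else raw$desired_path,
    decoy_items = dec
  )
}

#' Write a case-definition file
#'
#' @param case A validated `simulation_case`.
#' @param path Output path; the file is UTF-8 JSON readable by
#'   [load_case()].
#' @return `path`, invisibly.
#' @export
save_case <- function(case, path) {
  validate_case(case)
  jsonlite::write_json(case_to_list(case), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
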