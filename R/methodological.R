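#' Build the execution string of a log
#'
#' The ordered sequence of section codes of a student's actions, encoded
#' one character per action: a student who picks 3 scenario factors, asks
#' 2 anamnestic questions and performs 2 physical examinations produces the
#' raw string `"sssaapp"`. Collapsing runs of contiguous identical
#' characters gives the simplified execution string Phi (`"sap"` here),
#' the object all five methodological parameters are computed on.
#'
#' By default every logged action contributes a character. With
#' `mode = "critical"` only actions bound to the case's critical
#' diagnostic acts contribute (their sections, in execution order), which
#' treats Phi as a summary of the key workflow steps alone.
#'
#' @param log An `action_log`.
#' @param mode `"all"` (default) or `"critical"`.
#' @param case Required when `mode = "critical"`.
#' @return List of class `execution_string` with `raw` and `collapsed`
#'   (Phi).
#' @export
build_execution_string <- function(log, mode = c("all", "critical"),
                                   case = NULL) {
  stopifnot(inherits(log, "action_log"))
  mode <- match.arg(mode)
  rec <- log$records
  if (mode == "critical") {
    if (is.null(case)) {
      stop("mode = \"critical\" requires the case", call. = FALSE)
    }
    acts <- case$critical_acts
    keep <- paste(rec$section, rec$item_id) %in%
      paste(acts$section, acts$item_id)
    rec <- rec[keep, , drop = FALSE]
  }
  raw <- paste(rec$section, collapse = "")
  structure(list(raw = raw, collapsed = collapse_runs(raw)),
            class = "execution_string")
}

#' @export
print.execution_string <- function(x, ...) {
  cat(sprintf("<execution_string> raw \"%s\" -> Phi \"%s\"\n",
              x$raw, x$collapsed))
  invisible(x)
}

#' Collapse runs of contiguous identical characters
#'
#' `"sssaapp"` becomes `"sap"`. Idempotent; never lengthens a string.
#'
#' @param raw Character scalar.
#' @return Character scalar with no two equal adjacent characters.
#' @export
collapse_runs <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) return("")
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  keep <- c(TRUE, chars[-1] != chars[-length(chars)])
  paste(chars[keep], collapse = "")
}

#' Unit-cost Levenshtein edit distance
#'
#' Classic dynamic program over insertions, deletions and substitutions,
#' each at cost 1.
#'
#' @param x,y Character scalars (empty allowed).
#' @return Non-negative integer distance.
#' @export
levenshtein_distance <- function(x, y) {
  stopifnot(is.character(x), length(x) == 1L,
            is.character(y), length(y) == 1L)
  a <- strsplit(x, "", fixed = TRUE)[[1]]
  b <- strsplit(y, "", fixed = TRUE)[[1]]
  n <- length(a)
  m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L,            # deletion
                         cur[j] + 1L,                  # insertion
                         prev[j] + (a[i] != b[j]))     # substitution
    }
    prev <- cur
  }
  as.integer(prev[m + 1L])
}

#' Normalized Levenshtein similarity
#'
#' `1 - d(x, y) / max(|x|, |y|)`, clamped to \[0, 1\], with the similarity
#' of two empty strings defined as 1. This is the standard length-normalized
#' form, bounded like the other methodological parameters.
#'
#' @param x,y Character scalars.
#' @return Fraction in \[0, 1\]. Symmetric in its arguments.
#' @export
levenshtein_similarity <- function(x, y) {
  denom <- max(nchar(x), nchar(y))
  if (denom == 0L) return(1)
  max(0, min(1, 1 - levenshtein_distance(x, y) / denom))
}

#' Methodological parameter p1: opening-workflow conformance
#'
#' Levenshtein similarity between the first three characters of Phi and
#' the reference opening `"sap"` (scenario, then history taking, then
#' physical examination). When Phi is shorter than three characters the
#' available prefix is compared, so truncated workflows are penalized
#' proportionally; an empty Phi scores 0.
#'
#' @param phi Collapsed execution string.
#' @return Fraction in \[0, 1\].
#' @export
compute_p1 <- function(phi) {
  levenshtein_similarity(substr(phi, 1L, 3L), "sap")
}

#' Methodological parameter p2: closing-workflow conformance
#'
#' Levenshtein similarity between the last two characters of Phi and the
#' reference closing `"br"` (binary analysis of the collected data, then
#' final diagnosis selection — the hypothetico-deductive closing steps).
#'
#' @inheritParams compute_p1
#' @return Fraction in \[0, 1\].
#' @export
compute_p2 <- function(phi) {
  n <- nchar(phi)
  levenshtein_similarity(substr(phi, max(1L, n - 1L), n), "br")
}

#' Methodological parameter p3: hypothesis-before-test ordering
#'
#' 1 if the first occurrence of `h` (hypothesis generation) precedes the
#' first occurrence of `m` (medical test) in Phi, else 0. Medical tests
#' should only be ordered once at least one hypothesis exists; a log with
#' no medical-test action commits no ordering violation and scores 1,
#' while tests without any hypothesis score 0.
#'
#' @inheritParams compute_p1
#' @return 0 or 1.
#' @export
compute_p3 <- function(phi) {
  m_pos <- regexpr("m", phi, fixed = TRUE)[1]
  if (m_pos == -1L) return(1)
  h_pos <- regexpr("h", phi, fixed = TRUE)[1]
  if (h_pos == -1L) return(0)
  as.numeric(h_pos < m_pos)
}

#' Methodological parameter p4: section coverage
#'
#' The fraction of the 7 sections present in Phi: `Phi = "sapr"` gives
#' 4/7. Rewards a comprehensive assessment that skips no phase of the
#' encounter.
#'
#' @inheritParams compute_p1
#' @return Fraction k/7, k in 0..7.
#' @export
compute_p4 <- function(phi) {
  length(unique(strsplit(phi, "", fixed = TRUE)[[1]])) / 7
}

#' Methodological parameter p5: repetition penalty
#'
#' `1 / (1 + R)` where `R` is the number of repetitions in Phi, counted as
#' `nchar(Phi) - number of distinct characters`: contiguous repeats are
#' already collapsed, so each remaining repeat is a genuine return to a
#' previously visited section. Favors a linear pass through the case over
#' back-and-forth movement.
#'
#' @inheritParams compute_p1
#' @return Fraction in (0, 1]; 1 when Phi has no revisits (including empty
#'   Phi).
#' @export
compute_p5 <- function(phi) {
  1 / (1 + phi_repetitions(phi))
}

phi_repetitions <- function(phi) {
  chars <- strsplit(phi, "", fixed = TRUE)[[1]]
  length(chars) - length(unique(chars))
}

#' Methodological score of one student's log
#'
#' Builds Phi from the log, computes the five workflow parameters —
#' opening conformance to scenario-anamnesis-examination (p1), closing
#' conformance to binary-analysis-result (p2), hypothesis-before-test
#' ordering (p3), section coverage (p4) and the revisit penalty (p5) —
#' and combines them as the Euclidean norm
#' `sqrt(p1^2 + p2^2 + p3^2 + p4^2 + p5^2)`. The score therefore lives in
#' \[0, sqrt(5)\], attaining sqrt(5) exactly for a perfect linear workflow
#' (Phi `"saphmbr"`); `normalized` rescales by sqrt(5) onto \[0, 1\] for
#' reporting. An empty log yields the degenerate vector (0, 0, 1, 0, 1)
#' and score sqrt(2).
#'
#' @param log An `action_log`.
#' @param mode,case Passed to [build_execution_string()].
#' @return List of class `methodological_components`: `phi`, `raw`,
#'   `p1`..`p5`, `R`, `score`, `normalized`.
#' @export
methodological_score <- function(log, mode = c("all", "critical"),
                                 case = NULL) {
  es <- build_execution_string(log, mode = mode, case = case)
  phi <- es$collapsed
  p <- c(p1 = compute_p1(phi), p2 = compute_p2(phi), p3 = compute_p3(phi),
         p4 = compute_p4(phi), p5 = compute_p5(phi))
  structure(
    c(list(phi = phi, raw = es$raw), as.list(p),
      list(R = phi_repetitions(phi),
           score = sqrt(sum(p^2)),
           normalized = sqrt(sum(p^2)) / sqrt(5))),
    class = "methodological_components")
}

#' @export
print.methodological_components <- function(x, ...) {
  cat(sprintf("<methodological> Phi \"%s\" | p = (%.3f, %.3f, %.0f, %.3f, %.3f) | R = %d | score %.4f (normalized %.4f)\n",
              x$phi, x$p1, x$p2, x$p3, x$p4, x$p5, x$R, x$score,
              x$normalized))
  invisible(x)
}
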