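#' Composite overall, collection and analytical scores
#'
#' The seven section F1 values are combined into a single overall score,
#' plus two sub-scores: "collection" over the four data-gathering sections
#' (scenario, anamnesis, physical examination, medical tests) and
#' "analytical" over the three reasoning sections (hypotheses, binary
#' analysis, final diagnosis). The combination is the unweighted arithmetic
#' mean by default; `weights` (named by section code) exposes the
#' combination rule as a hook. Sections flagged not assessable are dropped
#' from every average, with the assessable subset reported.
#'
#' @param scores Data frame from [score_all_sections()].
#' @param weights Optional named numeric vector of non-negative section
#'   weights (default: uniform). Names must be section codes; not all may
#'   be zero among assessable sections.
#' @return List of class `composite_scores` with `overall`, `collection`,
#'   `analytical` and `assessable_sections`.
#' @export
composite_scores <- function(scores, weights = NULL) {
  check_scores_frame(scores)
  grp <- section_groups()
  list_out <- structure(
    list(overall = weighted_block_mean(scores, section_codes(), weights),
         collection = weighted_block_mean(scores, grp$collection, weights),
         analytical = weighted_block_mean(scores, grp$analytical, weights),
         assessable_sections = scores$section[scores$assessable]),
    class = "composite_scores")
  list_out
}

#' @export
print.composite_scores <- function(x, ...) {
  cat(sprintf("<composite_scores> overall %.4f | collection %.4f | analytical %.4f (sections: %s)\n",
              x$overall, x$collection, x$analytical,
              paste(x$assessable_sections, collapse = "")))
  invisible(x)
}

#' Overall score: mean F1 over all assessable sections
#' @inheritParams composite_scores
#' @return Fraction in \[0, 1\].
#' @export
overall_score <- function(scores, weights = NULL) {
  check_scores_frame(scores)
  weighted_block_mean(scores, section_codes(), weights)
}

#' Collection score: mean F1 over sections s, a, p, m
#' @inheritParams composite_scores
#' @return Fraction in \[0, 1\].
#' @export
collection_score <- function(scores, weights = NULL) {
  check_scores_frame(scores)
  weighted_block_mean(scores, section_groups()$collection, weights)
}

#' Analytical score: mean F1 over sections h, b, r
#' @inheritParams composite_scores
#' @return Fraction in \[0, 1\].
#' @export
analytical_score <- function(scores, weights = NULL) {
  check_scores_frame(scores)
  weighted_block_mean(scores, section_groups()$analytical, weights)
}

check_scores_frame <- function(scores) {
  needed <- c("section", "f1", "assessable")
  if (!is.data.frame(scores) || !all(needed %in% names(scores))) {
    stop("scores must be the data frame returned by score_all_sections()",
         call. = FALSE)
  }
  invisible(scores)
}

weighted_block_mean <- function(scores, block, weights) {
  keep <- scores$section %in% block & scores$assessable
  if (!any(keep)) {
    stop("case defines no relevant items in section block ",
         paste(block, collapse = ""), call. = FALSE)
  }
  f1 <- scores$f1[keep]
  if (is.null(weights)) return(mean(f1))
  if (is.null(names(weights)) || !all(scores$section[keep] %in% names(weights))) {
    stop("weights must be named by section code and cover all assessable sections",
         call. = FALSE)
  }
  w <- weights[scores$section[keep]]
  if (any(w < 0) || sum(w) == 0) {
    stop("weights must be non-negative and not all zero", call. = FALSE)
  }
  sum(w * f1) / sum(w)
}

#' Competition ranks, best first
#'
#' Rank 1 is the best score; ties share the best rank and the following
#' rank is skipped ("1224" competition ranking), matching ordinary
#' class-ranking language. `NA` scores get `NA` ranks.
#'
#' @param x Numeric vector of scores (higher is better).
#' @return Integer vector of ranks.
#' @export
rank_scores <- function(x) {
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x)
  out[ok] <- vapply(x[ok], function(v) 1L + sum(x[ok] > v), integer(1))
  out
}
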