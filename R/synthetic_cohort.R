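#' A synthetic student's behavior profile
#'
#' Four parameters control the simulated student, chosen to span the
#' behaviors the metrics are designed to discriminate:
#' \describe{
#'   \item{theta}{thoroughness in \[0, 1\]: the probability that each
#'     relevant item of a section is acted on (and, in the final-diagnosis
#'     section, that the correct diagnosis is selected). Drives
#'     sensitivity.}
#'   \item{lambda}{noise rate >= 0: the expected number of irrelevant
#'     actions per section, drawn Poisson from the case's per-section decoy
#'     pool. Drives precision down.}
#'   \item{beta}{binary-analysis accuracy in \[0, 1\]: the probability a
#'     first-attempt anchor is correct; wrong first attempts may be
#'     corrected on a later attempt, which the metrics deliberately
#'     ignore.}
#'   \item{delta}{discipline in \[0, 1\]: the probability the student works
#'     through the sections in the canonical clinical order
#'     scenario-anamnesis-examination-hypotheses-tests-analysis-diagnosis
#'     without revisits; with probability 1 - delta the section blocks are
#'     shuffled and extra back-and-forth revisits are injected (a
#'     geometric count, mean 2). Drives the methodological score
#'     independently of content skill.}
#' }
#'
#' @param theta,lambda,beta,delta See above. Defaults describe a mid-level
#'   student.
#' @param seed Integer seed making the student reproducible.
#' @return List of class `student_profile`.
#' @export
student_profile <- function(theta = 0.6, lambda = 2, beta = 0.6,
                            delta = 0.6, seed = 1L) {
  stopifnot(theta >= 0, theta <= 1, lambda >= 0, beta >= 0, beta <= 1,
            delta >= 0, delta <= 1)
  structure(list(theta = theta, lambda = lambda, beta = beta,
                 delta = delta, seed = as.integer(seed)),
            class = "student_profile")
}

# Canonical clinical workflow a disciplined student follows: hypotheses
# before medical tests, analysis and diagnosis last.
workflow_order <- function() c("s", "a", "p", "h", "m", "b", "r")

#' Generate a random simulation case
#'
#' Builds a fully populated, valid answer key: relevant items for the four
#' collection sections, a hypothesis list (reasonable differential plus
#' unreasonable decoys, one correct final diagnosis), a complete random
#' binary-analysis reference over every (scenario factor, hypothesis)
#' pair, per-section decoy pools for the noise model, and 3-5 critical
#' acts with a desired execution path (start at the scenario, key
#' examination/test steps, end at the correct final diagnosis).
#'
#' @param n_items_per_section Named integer vector of relevant item counts
#'   for sections `s`, `a`, `p`, `m` (all >= 1).
#' @param n_hypotheses Number of reasonable hypotheses (>= 1).
#' @param n_decoys Decoy pool size per section.
#' @param seed Integer seed; the same seed reproduces the same case.
#' @param case_id Identifier for the generated case.
#' @return A validated `simulation_case`.
#' @export
generate_case <- function(n_items_per_section = c(s = 5, a = 8, p = 6, m = 6),
                          n_hypotheses = 4, n_decoys = 6, seed = 1L,
                          case_id = sprintf("synthetic-case-%d", seed)) {
  stopifnot(all(c("s", "a", "p", "m") %in% names(n_items_per_section)),
            all(n_items_per_section >= 1), n_hypotheses >= 1)
  set.seed(seed)

  rel <- lapply(c(s = "s", a = "a", p = "p", m = "m"), function(sec) {
    sprintf("%s%02d", sec, seq_len(n_items_per_section[[sec]]))
  })

  n_bad_hyp <- max(2L, ceiling(n_hypotheses / 2))
  hyp_ids <- sprintf("h%02d", seq_len(n_hypotheses + n_bad_hyp))
  hypotheses <- data.frame(
    id = hyp_ids,
    label = sprintf("hypothesis %s", hyp_ids),
    reasonable = c(rep(TRUE, n_hypotheses), rep(FALSE, n_bad_hyp)),
    is_correct_final = c(TRUE, rep(FALSE, n_hypotheses + n_bad_hyp - 1L)),
    stringsAsFactors = FALSE)

  pairs <- expand.grid(factor_id = rel$s, hypothesis_id = hyp_ids,
                       stringsAsFactors = FALSE)
  pairs$anchor <- sample(ba_anchors(), nrow(pairs), replace = TRUE)

  decoys <- list(
    s = sprintf("sx%02d", seq_len(n_decoys)),
    a = sprintf("ax%02d", seq_len(n_decoys)),
    p = sprintf("px%02d", seq_len(n_decoys)),
    m = sprintf("mx%02d", seq_len(n_decoys)),
    h = hyp_ids[!hypotheses$reasonable],
    r = hyp_ids[!hypotheses$is_correct_final])

  # one act per section, sections in workflow order, so a fully disciplined
  # thorough student's act order can reproduce the desired path
  n_acts <- sample(3:5, 1)
  mid_sections <- switch(n_acts - 2L, "p", c("p", "m"), c("a", "p", "m"))
  acts <- data.frame(
    act_id = LETTERS[seq_len(n_acts)],
    description = character(n_acts),
    section = c("s", mid_sections, "r"),
    item_id = NA_character_,
    stringsAsFactors = FALSE)
  used <- list(p = character(0), m = character(0))
  for (i in seq_len(n_acts)) {
    sec <- acts$section[i]
    acts$item_id[i] <- switch(sec,
      s = rel$s[1],
      r = hypotheses$id[hypotheses$is_correct_final][1],
      {
        pool <- setdiff(rel[[sec]], used[[sec]])
        pick <- sample(pool, 1)
        used[[sec]] <- c(used[[sec]], pick)
        pick
      })
    acts$description[i] <- sprintf("critical act %s: %s %s",
                                   acts$act_id[i], section_labels()[[sec]],
                                   acts$item_id[i])
  }

  simulation_case(
    case_id = case_id,
    relevant_items = rel,
    hypotheses = hypotheses,
    binary_reference = pairs,
    critical_acts = acts,
    desired_path = paste(acts$act_id, collapse = ""),
    decoy_items = decoys)
}

#' Generate one student's action log
#'
#' Simulates a student working through the case under a
#' [student_profile()]: each relevant item of each section is acted on
#' with probability `theta`; a Poisson(`lambda`) number of irrelevant
#' decoy actions is added per section; every attempted binary-analysis
#' pair gets a correct first-attempt anchor with probability `beta`
#' (wrong first attempts are sometimes corrected on attempt 2, which the
#' metrics ignore); and with probability `delta` the section blocks come
#' in the canonical clinical order with no revisits, otherwise they are
#' shuffled and split by extra revisits. At `theta = 1, lambda = 0,
#' beta = 1, delta = 1` the log is perfect: every section F1 is 1 and the
#' methodological score is sqrt(5).
#'
#' @param case A `simulation_case` (needs decoy pools when `lambda > 0`).
#' @param profile A `student_profile`.
#' @param student_id Id recorded in the log.
#' @return A validated `action_log`.
#' @export
generate_log <- function(case, profile, student_id = "synthetic-student") {
  stopifnot(inherits(case, "simulation_case"),
            inherits(profile, "student_profile"))
  set.seed(profile$seed)

  blocks <- list()
  for (sec in workflow_order()) {
    if (sec == "b") {
      blocks[[sec]] <- simulate_ba_block(case, profile)
      next
    }
    rel_set <- case_relevant_set(case, sec)
    hits <- rel_set[stats::runif(length(rel_set)) < profile$theta]
    decoy_pool <- case$decoy_items[[sec]]
    n_noise <- min(stats::rpois(1, profile$lambda), length(decoy_pool))
    noise <- if (n_noise > 0) sample(decoy_pool, n_noise) else character(0)
    items <- c(hits, noise)
    if (length(items) == 0) next
    items <- sample(items)  # interleave relevant and irrelevant actions
    blocks[[sec]] <- data.frame(
      section = sec, item_id = items,
      relevant = items %in% rel_set,
      attempt = 1L, payload = NA_character_,
      stringsAsFactors = FALSE)
  }

  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  disciplined <- stats::runif(1) < profile$delta
  if (!disciplined && length(blocks) > 1) {
    blocks <- blocks[sample(length(blocks))]
    n_revisits <- stats::rgeom(1, prob = 1 / 3)  # mean 2 extra revisits
    for (k in seq_len(n_revisits)) {
      sizes <- vapply(blocks, nrow, integer(1))
      splittable <- which(sizes >= 2)
      if (length(splittable) == 0) break
      i <- if (length(splittable) == 1) splittable else sample(splittable, 1)
      cut_at <- sample(sizes[i] - 1L, 1)
      head_part <- blocks[[i]][seq_len(cut_at), , drop = FALSE]
      tail_part <- blocks[[i]][(cut_at + 1L):sizes[i], , drop = FALSE]
      blocks[[i]] <- head_part
      insert_at <- sample(setdiff(seq_len(length(blocks) + 1L), i + 1L), 1)
      blocks <- append(blocks, list(tail_part), after = insert_at - 1L)
    }
  }

  records <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  if (is.null(records) || nrow(records) == 0) {
    return(action_log(student_id, case$case_id))
  }
  records <- cbind(seq = seq_len(nrow(records)), records)
  action_log(student_id, case$case_id, records, case = case)
}

# Binary-analysis block: each reference pair attempted with probability
# theta; the first-attempt anchor is correct with probability beta; half of
# the wrong first attempts get a corrective second attempt.
simulate_ba_block <- function(case, profile) {
  ba <- case$binary_reference
  if (nrow(ba) == 0) return(NULL)
  attempted <- which(stats::runif(nrow(ba)) < profile$theta)
  if (length(attempted) == 0) return(NULL)
  rows <- list()
  for (i in attempted) {
    key <- ba_pair_key(ba$factor_id[i], ba$hypothesis_id[i])
    correct <- stats::runif(1) < profile$beta
    anchor <- if (correct) ba$anchor[i] else
      sample(setdiff(ba_anchors(), ba$anchor[i]), 1)
    rows[[length(rows) + 1L]] <- data.frame(
      section = "b", item_id = key, relevant = correct, attempt = 1L,
      payload = anchor, stringsAsFactors = FALSE)
    if (!correct && stats::runif(1) < 0.5) {
      rows[[length(rows) + 1L]] <- data.frame(
        section = "b", item_id = key, relevant = TRUE, attempt = 2L,
        payload = ba$anchor[i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic cohort of action logs
#'
#' One log per student. Each student's seed is derived deterministically
#' from the cohort seed and the student index, so student k's log does not
#' depend on the cohort size. Profile parameters may be scalars (shared)
#' or length-`n_students` vectors (heterogeneous cohort).
#'
#' @param case A `simulation_case`.
#' @param n_students Cohort size.
#' @param theta,lambda,beta,delta As in [student_profile()]; scalar or
#'   per-student vectors.
#' @param seed Cohort seed.
#' @return List of `action_log` objects with ids `stu001`, `stu002`, ...
#' @export
generate_cohort <- function(case, n_students, theta = 0.6, lambda = 2,
                            beta = 0.6, delta = 0.6, seed = 1L) {
  stopifnot(n_students >= 1)
  par <- lapply(list(theta = theta, lambda = lambda, beta = beta,
                     delta = delta),
                function(v) rep_len(v, n_students))
  lapply(seq_len(n_students), function(i) {
    prof <- student_profile(theta = par$theta[i], lambda = par$lambda[i],
                            beta = par$beta[i], delta = par$delta[i],
                            seed = student_seed(seed, i))
    generate_log(case, prof, student_id = sprintf("stu%03d", i))
  })
}

# Deterministic per-student stream seed, independent of cohort size.
student_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483647)
}
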