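# Hand-built answer key used across the test files: 5 scenario factors,
# 5 anamnestic questions, 2 physical examinations, 2 medical tests,
# 2 reasonable hypotheses (h1 the correct final diagnosis), a 6-pair
# binary-analysis reference over factors s1/s2, and the 5 critical acts
# S-P-M-U-D with desired path "SPMUD".
fixture_case <- function() {
  simulation_case(
    case_id = "fix1",
    relevant_items = list(
      s = paste0("s", 1:5),
      a = paste0("a", 1:5),
      p = c("p1", "p2"),
      m = c("m1", "m2")),
    hypotheses = data.frame(
      id = c("h1", "h2", "h3"),
      label = c("cholecystitis", "appendicitis", "gastritis"),
      reasonable = c(TRUE, TRUE, FALSE),
      is_correct_final = c(TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE),
    binary_reference = data.frame(
      factor_id = rep(c("s1", "s2"), each = 3),
      hypothesis_id = rep(c("h1", "h2", "h3"), 2),
      anchor = c("increase", "neutral", "decrease",
                 "decrease", "increase", "neutral"),
      stringsAsFactors = FALSE),
    critical_acts = data.frame(
      act_id = c("S", "P", "M", "U", "D"),
      description = c("read scenario", "abdominal palpation", "Murphy sign",
                      "abdominal ultrasound", "final diagnosis"),
      section = c("s", "p", "p", "m", "r"),
      item_id = c("s1", "p1", "p2", "m1", "h1"),
      stringsAsFactors = FALSE),
    desired_path = "SPMUD",
    decoy_items = list(s = paste0("sx", 1:3), a = paste0("ax", 1:3),
                       p = paste0("px", 1:3), m = paste0("mx", 1:3),
                       h = "h3", r = c("h2", "h3")))
}

# Build a validated log from a bare (section, item_id[, attempt, payload])
# action table; seq and relevance are derived.
log_from_actions <- function(case, actions, student_id = "stu") {
  actions <- as.data.frame(actions, stringsAsFactors = FALSE)
  if (nrow(actions) == 0) return(action_log(student_id, case$case_id))
  if (!"attempt" %in% names(actions)) actions$attempt <- 1L
  if (!"payload" %in% names(actions)) actions$payload <- NA_character_
  actions$seq <- seq_len(nrow(actions))
  actions$relevant <- NA
  action_log(student_id, case$case_id, actions, case = case)
}

# A log that performs exactly every relevant action once, in the canonical
# clinical workflow order, with every binary-analysis anchor correct on
# attempt 1: the analytic maximum of the whole scoring stack.
perfect_actions <- function(case) {
  ba <- case$binary_reference
  part <- function(section, ids, payload = NA_character_) {
    if (length(ids) == 0) return(NULL)
    data.frame(section = section, item_id = ids, payload = payload,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    part("s", case$relevant_items$s),
    part("a", case$relevant_items$a),
    part("p", case$relevant_items$p),
    part("h", case_relevant_set(case, "h")),
    part("m", case$relevant_items$m),
    part("b", paste(ba$factor_id, ba$hypothesis_id, sep = "|"), ba$anchor),
    part("r", case_relevant_set(case, "r"))))
}

perfect_log <- function(case, student_id = "perfect") {
  log_from_actions(case, perfect_actions(case), student_id)
}

# Random small case + log for oracle-equivalence properties: actions drawn
# with replacement from relevant items and decoys (so duplicates and
# irrelevant actions occur), binary-analysis payloads random anchors with
# random repeated attempts.
random_fixture <- function(max_items = 10) {
  n_items <- c(s = sample(max_items, 1), a = sample(max_items, 1),
               p = sample(max_items, 1), m = sample(max_items, 1))
  case <- generate_case(n_items_per_section = n_items,
                        n_hypotheses = sample(2:4, 1),
                        n_decoys = 4,
                        seed = sample.int(1e6, 1))
  rows <- list()
  for (sec in c("s", "a", "p", "m", "h", "r")) {
    pool <- c(case_relevant_set(case, sec), case$decoy_items[[sec]])
    k <- sample(0:(2 * length(pool)), 1)
    if (k == 0) next
    rows[[sec]] <- data.frame(section = sec,
                              item_id = sample(pool, k, replace = TRUE),
                              attempt = 1L, payload = NA_character_,
                              stringsAsFactors = FALSE)
  }
  ba <- case$binary_reference
  keys <- paste(ba$factor_id, ba$hypothesis_id, sep = "|")
  n_ba <- sample(0:nrow(ba), 1)
  if (n_ba > 0) {
    picked <- sample(keys, n_ba)
    ba_rows <- lapply(picked, function(k) {
      n_att <- sample(1:2, 1)
      data.frame(section = "b", item_id = k, attempt = seq_len(n_att),
                 payload = sample(ba_anchors(), n_att, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    rows$b <- do.call(rbind, ba_rows)
  }
  actions <- do.call(rbind, rows)
  if (is.null(actions)) {
    actions <- data.frame(section = "s",
                          item_id = case$relevant_items$s[1],
                          attempt = 1L, payload = NA_character_,
                          stringsAsFactors = FALSE)
  }
  actions <- actions[sample(nrow(actions)), , drop = FALSE]
  # keep multi-attempt b records ordered by attempt within pair
  actions <- actions[order(match(paste(actions$section, actions$item_id),
                                 unique(paste(actions$section,
                                              actions$item_id))),
                           actions$attempt), , drop = FALSE]
  list(case = case, log = log_from_actions(case, actions, "rand"))
}

# Plain recount of one section's counts, written with explicit loops and
# no shared code with score_section(): the independent oracle.
oracle_section_counts <- function(case, log, sec) {
  rec <- log$records[log$records$section == sec, , drop = FALSE]
  if (sec == "b") {
    ref <- case$binary_reference
    ref_keys <- paste(ref$factor_id, ref$hypothesis_id, sep = "|")
    seen <- character(0)
    executed <- 0L
    correct <- 0L
    for (i in seq_len(nrow(rec))) {
      if (rec$attempt[i] != 1L) next
      key <- rec$item_id[i]
      if (key %in% seen || !(key %in% ref_keys)) next
      seen <- c(seen, key)
      executed <- executed + 1L
      if (!is.na(rec$payload[i]) &&
          rec$payload[i] == ref$anchor[match(key, ref_keys)]) {
        correct <- correct + 1L
      }
    }
    list(n_total = nrow(ref), n_found = correct, n_actions = executed)
  } else {
    relevant <- case_relevant_set(case, sec)
    acted <- character(0)
    for (i in seq_len(nrow(rec))) {
      if (!(rec$item_id[i] %in% acted)) acted <- c(acted, rec$item_id[i])
    }
    found <- 0L
    for (id in acted) if (id %in% relevant) found <- found + 1L
    list(n_total = length(relevant), n_found = found,
         n_actions = length(acted))
  }
}
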