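#' Episodic-memory score battery
#'
#' Scoring turns one session log into the full variable battery of classical
#' list-learning assessment: per-trial correct counts, learning slope,
#' error profiles (intrusions, perseverations, omissions), semantic and
#' serial clustering against chance expectation, serial-position (primacy /
#' middle / recency) percentages, proactive and retroactive interference,
#' recognition hits, false positives by distractor type, discriminability
#' and d-prime, and response-latency summaries. Scoring is a pure function
#' of the log: rescoring is bit-identical.
#'
#' @name scoring
#' @keywords internal
NULL

phase_label <- function(kind, list_ref, trial_index) {
  switch(kind,
         immediate_free_recall = paste0(tolower(list_ref), trial_index),
         short_delay_free_recall = "sdfr",
         short_delay_cued_recall = "sdcr",
         long_delay_free_recall = "ldfr",
         long_delay_cued_recall = "ldcr",
         recognition = "recog",
         `break` = "break")
}

phase_responses <- function(log, phase_id) {
  e <- log$events
  e[e$phase_id == phase_id & e$kind == "response", ]
}

#' Score a single recall phase
#'
#' Applies the standard counting rules: each distinct target-list word among
#' the responses counts once toward `correct`; every extra occurrence of an
#' already-recalled correct word is a perseveration; every response not on
#' the phase's target list is an intrusion (counted with multiplicity). The
#' recall sequence preserves first-occurrence order of the distinct correct
#' words.
#'
#' @param log An `ll_session_log`.
#' @param phase_id A recall phase's id in the log's schedule.
#' @return A list with `correct`, `intrusions`, `perseverations`,
#'   `recall_sequence` (character vector).
#' @export
trial_recall <- function(log, phase_id) {
  sched <- log$schedule
  row <- which(sched$phase_id == phase_id)
  if (length(row) != 1 || !is_recall_kind(sched$phase_kind[row])) {
    abort_argument(paste0("Phase ", phase_id, " is not a recall phase."))
  }
  target <- phase_target_list(sched$phase_kind[row], sched$list_ref[row],
                              log$lists)
  resp <- phase_responses(log, phase_id)$word
  on_list <- resp %in% target$word
  correct_words <- unique(resp[on_list])
  list(
    correct = length(correct_words),
    intrusions = sum(!on_list),
    perseverations = sum(on_list) - length(correct_words),
    recall_sequence = correct_words
  )
}

#' Learning slope across immediate trials
#'
#' Ordinary least-squares slope of correct count against trial number —
#' the operationalisation of learning rate in items gained per trial.
#'
#' @param counts Numeric vector of per-trial correct counts (trials 1..k).
#' @return The OLS slope.
#' @export
#' @examples
#' learning_slope(c(5, 7, 9))  # 2
learning_slope <- function(counts) {
  x <- seq_along(counts)
  unname(stats::coef(stats::lm(counts ~ x))[2])
}

#' Semantic clustering against chance expectation
#'
#' Observed is the number of adjacent same-category pairs in the recall
#' sequence. The chance expectation under a uniform random permutation of
#' the recalled words is `sum_k m_k (m_k - 1) / r`, where `m_k` is the
#' number of recalled words in category `k` and `r` the total recalled.
#' The index is the observed minus expected difference, which stays
#' well-defined at low recall counts. With fewer than two recalls all three
#' values are zero.
#'
#' @param recall_sequence Character vector of distinct recalled words.
#' @param category_of Named character vector mapping word to category.
#' @return A list with `observed`, `expected`, `index`.
#' @export
#' @examples
#' semantic_clustering(c("w1", "w2", "w3", "w4"),
#'                     c(w1 = "A", w2 = "A", w3 = "B", w4 = "B"))
semantic_clustering <- function(recall_sequence, category_of) {
  r <- length(recall_sequence)
  if (r <= 1) return(list(observed = 0, expected = 0, index = 0))
  cats <- unname(category_of[recall_sequence])
  if (any(is.na(cats))) {
    abort_data(paste0("No category known for word(s): ",
                      paste(recall_sequence[is.na(cats)], collapse = ", ")))
  }
  observed <- sum(cats[-1] == cats[-r])
  m <- table(cats)
  expected <- sum(m * (m - 1)) / r
  list(observed = observed, expected = expected, index = observed - expected)
}

# All permutations of a vector (used for exact serial-clustering baselines).
all_permutations <- function(v) {
  n <- length(v)
  if (n <= 1) return(list(v))
  out <- vector("list", factorial(n))
  k <- 0
  for (i in seq_len(n)) {
    for (p in all_permutations(v[-i])) {
      k <- k + 1
      out[[k]] <- c(v[i], p)
    }
  }
  out
}

count_forward_adjacent <- function(pos) {
  if (length(pos) <= 1) return(0L)
  sum(pos[-1] == pos[-length(pos)] + 1)
}

#' Serial clustering against chance expectation
#'
#' Observed is the number of recall transitions following presentation
#' order (position of the next recalled word is the previous one's plus
#' one). The chance expectation is the mean observed count over random
#' orders of the recalled positions: exact (exhaustive enumeration) for up
#' to 7 recalls, seeded Monte Carlo with at least 10,000 permutations
#' beyond that. The index is observed minus expected.
#'
#' @param recall_sequence Character vector of distinct recalled words.
#' @param position_of Named integer vector mapping word to presentation
#'   position.
#' @param seed Seed for the Monte Carlo baseline.
#' @param n_mc Monte Carlo sample size (minimum 10,000).
#' @return A list with `observed`, `expected`, `index`.
#' @export
serial_clustering <- function(recall_sequence, position_of, seed = 1L,
                              n_mc = 10000) {
  r <- length(recall_sequence)
  if (r <= 1) return(list(observed = 0, expected = 0, index = 0))
  pos <- unname(position_of[recall_sequence])
  if (any(is.na(pos))) {
    abort_data(paste0("No presentation position known for word(s): ",
                      paste(recall_sequence[is.na(pos)], collapse = ", ")))
  }
  observed <- count_forward_adjacent(pos)
  if (r <= 7) {
    perms <- all_permutations(pos)
    expected <- mean(vapply(perms, count_forward_adjacent, numeric(1)))
  } else {
    n_mc <- max(n_mc, 10000)
    expected <- with_seed(check_seed(seed), {
      perms <- replicate(n_mc, sample(pos))
      mean(colSums(perms[-1, , drop = FALSE] ==
                     perms[-r, , drop = FALSE] + 1))
    })
  }
  list(observed = observed, expected = expected, index = observed - expected)
}

#' Serial-position percentages (primacy / middle / recency)
#'
#' Pools recall positions across the main-list immediate trials and reports
#' the percentage falling in the primacy (positions 1–4), middle (5–12) and
#' recency (13–16) regions — the 25/50/25 convention. With no recalls the
#' result is flagged degenerate and the percentages are `NA`.
#'
#' @param positions Integer vector of pooled recall positions (1..16).
#' @return A list with `primacy_pct`, `middle_pct`, `recency_pct`,
#'   `degenerate`.
#' @export
primacy_recency <- function(positions) {
  positions <- positions[!is.na(positions)]
  if (length(positions) == 0) {
    return(list(primacy_pct = NA_real_, middle_pct = NA_real_,
                recency_pct = NA_real_, degenerate = TRUE))
  }
  n <- length(positions)
  list(
    primacy_pct = 100 * sum(positions <= 4) / n,
    middle_pct = 100 * sum(positions >= 5 & positions <= 12) / n,
    recency_pct = 100 * sum(positions >= 13) / n,
    degenerate = FALSE
  )
}

#' Proactive and retroactive interference scores
#'
#' Difference-score form: proactive interference is the interference-list
#' first-trial count minus the main list's first-trial count (prior
#' learning impairing new-list recall); retroactive interference is the
#' short-delay free-recall count minus the last immediate-trial count (new
#' learning impairing old-list recall).
#'
#' @param a1,b1,a3,sdfr Correct counts for the respective phases.
#' @return A list with `proactive`, `retroactive`.
#' @export
interference_scores <- function(a1, b1, a3, sdfr) {
  list(proactive = b1 - a1, retroactive = sdfr - a3)
}

#' Recognition scores
#'
#' Hits are "yes" answers to targets; misses their complement; false
#' positives are "yes" answers to any distractor, tallied by distractor
#' type. Unanswered items are scored "no". Discriminability is
#' `(1 - (misses + false positives) / n_items) * 100` over all recognition
#' items; d-prime uses the log-linear correction (0.5 added to each cell, 1
#' to each denominator), which keeps it finite at ceiling or floor rates.
#'
#' @param log An `ll_session_log` containing exactly one recognition phase.
#' @param recognition_list The `ll_recognition_list` administered.
#' @return A list with `hits`, `misses`, `fp_total`, `fp_by_type` (named),
#'   `discriminability_pct`, `d_prime`.
#' @export
recognition_scores <- function(log, recognition_list = log$lists$C) {
  sched <- log$schedule
  pid <- sched$phase_id[sched$phase_kind == "recognition"]
  if (length(pid) != 1) abort_argument("Log must contain exactly one recognition phase.")
  resp <- phase_responses(log, pid)
  if (anyDuplicated(resp$word)) {
    abort_protocol("Multiple recognition responses for a single item.")
  }
  items <- recognition_list
  answer <- resp$answer[match(items$word, resp$word)]
  answer[is.na(answer)] <- FALSE
  is_target <- items$item_type == "target_A"
  hits <- sum(answer & is_target)
  misses <- sum(is_target) - hits
  fp_vec <- tapply(answer[!is_target], items$item_type[!is_target], sum)
  distractor_types <- setdiff(RECOGNITION_TYPES, "target_A")
  fp_by_type <- stats::setNames(as.integer(fp_vec[distractor_types]),
                                distractor_types)
  fp_by_type[is.na(fp_by_type)] <- 0L
  fp_total <- sum(fp_by_type)
  n <- nrow(items)
  n_distract <- sum(!is_target)
  d_prime <- stats::qnorm((hits + 0.5) / (sum(is_target) + 1)) -
    stats::qnorm((fp_total + 0.5) / (n_distract + 1))
  list(hits = hits, misses = misses, fp_total = fp_total,
       fp_by_type = fp_by_type,
       discriminability_pct = (1 - (misses + fp_total) / n) * 100,
       d_prime = d_prime)
}

latency_summary <- function(latencies) {
  latencies <- latencies[!is.na(latencies)]
  if (length(latencies) == 0) {
    return(list(mean = NA_real_, median = NA_real_, sd = NA_real_))
  }
  list(mean = mean(latencies), median = stats::median(latencies),
       sd = if (length(latencies) > 1) stats::sd(latencies) else NA_real_)
}

#' Compute the full score battery for one session
#'
#' Scores every phase of a (valid) session log against the administered
#' lists and returns the battery as a single-row tibble with a stable,
#' documented column layout: per-trial counts and omissions, learning
#' slope, total over the main-list immediate trials, delayed and cued
#' counts, intrusions and perseverations per phase, semantic and serial
#' clustering (observed / expected / index) per free-recall phase,
#' serial-position percentages, interference scores, recognition scores and
#' per-phase latency summaries.
#'
#' @param log An `ll_session_log`.
#' @param lists The administered lists; defaults to those embedded in the
#'   log.
#' @return A one-row tibble (class `ll_battery`).
#' @export
compute_battery <- function(log, lists = log$lists) {
  viol <- validate_log(log)
  if (nrow(viol) > 0) {
    abort_validation(paste0("Invalid session log: ",
                            paste(viol$message, collapse = "; ")))
  }
  sched <- log$schedule
  labels <- vapply(seq_len(nrow(sched)), function(i) {
    phase_label(sched$phase_kind[i], sched$list_ref[i], sched$trial_index[i])
  }, character(1))

  out <- list()
  recall_info <- list()
  for (i in seq_len(nrow(sched))) {
    kind <- sched$phase_kind[i]
    lab <- labels[i]
    if (is_recall_kind(kind)) {
      tr <- trial_recall(log, sched$phase_id[i])
      recall_info[[lab]] <- tr
      out[[lab]] <- tr$correct
      out[[paste0("omissions_", lab)]] <- 16L - tr$correct
      out[[paste0("intrusions_", lab)]] <- tr$intrusions
      out[[paste0("perseverations_", lab)]] <- tr$perseverations
      target <- phase_target_list(kind, sched$list_ref[i], lists)
      cat_of <- stats::setNames(target$category, target$word)
      pos_of <- stats::setNames(target$position, target$word)
      if (!grepl("cued", kind)) {
        sem <- semantic_clustering(tr$recall_sequence, cat_of)
        ser <- serial_clustering(tr$recall_sequence, pos_of,
                                 seed = derive_seed(log$seed, i))
        out[[paste0("sem_obs_", lab)]] <- sem$observed
        out[[paste0("sem_exp_", lab)]] <- sem$expected
        out[[paste0("sem_idx_", lab)]] <- sem$index
        out[[paste0("ser_obs_", lab)]] <- ser$observed
        out[[paste0("ser_exp_", lab)]] <- ser$expected
        out[[paste0("ser_idx_", lab)]] <- ser$index
      }
    }
    if (kind != "break") {
      lat <- latency_summary(phase_responses(log, sched$phase_id[i])$latency)
      out[[paste0("latency_mean_", lab)]] <- lat$mean
      out[[paste0("latency_median_", lab)]] <- lat$median
      out[[paste0("latency_sd_", lab)]] <- lat$sd
    }
  }

  a_counts <- c(out[["a1"]] %||% NA, out[["a2"]] %||% NA, out[["a3"]] %||% NA)
  out$total_A <- sum(a_counts)
  out$learning_slope <- if (anyNA(a_counts)) NA_real_ else learning_slope(a_counts)

  a_pos <- unlist(lapply(c("a1", "a2", "a3"), function(lab) {
    tr <- recall_info[[lab]]
    if (is.null(tr)) return(integer())
    stats::setNames(lists$A$position, lists$A$word)[tr$recall_sequence]
  }))
  pr <- primacy_recency(a_pos)
  out$primacy_pct <- pr$primacy_pct
  out$middle_pct <- pr$middle_pct
  out$recency_pct <- pr$recency_pct
  out$serial_position_degenerate <- pr$degenerate

  intf <- interference_scores(out[["a1"]], out[["b1"]], out[["a3"]],
                              out[["sdfr"]])
  out$proactive_interference <- intf$proactive
  out$retroactive_interference <- intf$retroactive

  rec <- recognition_scores(log, lists$C)
  out$recog_hits <- rec$hits
  out$recog_misses <- rec$misses
  out$recog_fp_total <- rec$fp_total
  for (ty in names(rec$fp_by_type)) {
    out[[paste0("recog_fp_", ty)]] <- rec$fp_by_type[[ty]]
  }
  out$discriminability_pct <- rec$discriminability_pct
  out$d_prime <- rec$d_prime

  battery <- tibble::as_tibble(out)
  structure(battery, class = c("ll_battery", class(battery)))
}
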