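#' Behavioral cohort simulator
#'
#' A generative model of list-learning behavior by diagnostic group (healthy
#' controls, mild cognitive impairment, Alzheimer's disease). Each subject
#' is a draw of behavioral parameters from a group preset; a responder built
#' from those parameters plays the administration protocol, producing recall
#' orders with learning, forgetting, cue benefit, serial-position boosts,
#' semantic clustering tendency, intrusions, perseverations, recognition
#' false alarms by distractor type, and lognormal latencies. The simulator
#' is the synthetic stand-in for human players that makes the scoring and
#' validation pipeline testable end to end; it is a behavioral surrogate,
#' not a cognitive process model.
#'
#' @name simulate
#' @keywords internal
NULL

PROB_FIELDS <- c("p_base", "learn_rate", "cue_boost", "primacy_boost",
                 "recency_boost", "cluster_tendency", "persev_prob",
                 "recog_hit", "fa_shared_B", "fa_nonshared_B",
                 "fa_prototype_A", "fa_phonetic_A", "fa_unrelated",
                 "retention")

#' Default group presets
#'
#' Mean and spread of every behavioral parameter per diagnostic group,
#' calibrated qualitatively to the clinical ordering (healthy > MCI > AD in
#' recall, learning and recognition; the reverse in intrusions and false
#' alarms; false-alarm rates ordered shared-category > prototype > phonetic
#' > unrelated distractors). All values are overridable; they are
#' documented defaults of the surrogate model, not estimates from human
#' data.
#'
#' @return A named list of presets (`HC`, `MCI`, `AD`), each with `group`,
#'   `means` and `sds` (named numeric vectors) and `demographics` (means/sds
#'   of ordinal scales).
#' @export
group_presets <- function() {
  mk <- function(group, means, demo_means) {
    list(
      group = group,
      means = means,
      sds = c(p_base = 0.03, learn_rate = 0.015, retention = 0.04,
              cue_boost = 0.02, primacy_boost = 0.03, recency_boost = 0.03,
              cluster_tendency = 0.1, intrusion_rate = 0.12,
              persev_prob = 0.02, recog_hit = 0.025, fa_shared_B = 0.04,
              fa_nonshared_B = 0.04, fa_prototype_A = 0.03,
              fa_phonetic_A = 0.03, fa_unrelated = 0.02,
              latency_logmean = 0.08, latency_logsd = 0.05,
              aux_ability = 0.25),
      demographics = list(means = demo_means,
                          sds = c(age = 7, education = 0.8, ict_use = 0.8,
                                  game_use = 0.7, socialization = 0.8,
                                  exercise = 0.8))
    )
  }
  list(
    HC = mk("HC",
            c(p_base = 0.45, learn_rate = 0.15, retention = 0.90,
              cue_boost = 0.10, primacy_boost = 0.10, recency_boost = 0.10,
              cluster_tendency = 0.60, intrusion_rate = 0.3,
              persev_prob = 0.02, recog_hit = 0.95, fa_shared_B = 0.10,
              fa_nonshared_B = 0.08, fa_prototype_A = 0.06,
              fa_phonetic_A = 0.04, fa_unrelated = 0.02,
              latency_logmean = log(1.2), latency_logsd = 0.40,
              aux_ability = 2),
            c(age = 68, education = 3.5, ict_use = 3, game_use = 1.5,
              socialization = 4, exercise = 3.5)),
    MCI = mk("MCI",
             c(p_base = 0.30, learn_rate = 0.07, retention = 0.65,
               cue_boost = 0.07, primacy_boost = 0.08, recency_boost = 0.08,
               cluster_tendency = 0.40, intrusion_rate = 1.0,
               persev_prob = 0.06, recog_hit = 0.80, fa_shared_B = 0.25,
               fa_nonshared_B = 0.20, fa_prototype_A = 0.18,
               fa_phonetic_A = 0.12, fa_unrelated = 0.06,
               latency_logmean = log(1.8), latency_logsd = 0.50,
               aux_ability = 0),
             c(age = 75, education = 3, ict_use = 3, game_use = 2,
               socialization = 3, exercise = 2.5)),
    AD = mk("AD",
            c(p_base = 0.15, learn_rate = 0.02, retention = 0.35,
              cue_boost = 0.03, primacy_boost = 0.05, recency_boost = 0.05,
              cluster_tendency = 0.20, intrusion_rate = 2.0,
              persev_prob = 0.12, recog_hit = 0.60, fa_shared_B = 0.45,
              fa_nonshared_B = 0.40, fa_prototype_A = 0.35,
              fa_phonetic_A = 0.25, fa_unrelated = 0.12,
              latency_logmean = log(2.5), latency_logsd = 0.60,
              aux_ability = -2),
            c(age = 76, education = 2.5, ict_use = 1, game_use = 1,
              socialization = 2, exercise = 2))
  )
}

#' Sample one subject's behavioral parameters
#'
#' Gaussian draws around the preset means, with probability-like fields
#' clipped into \[0, 1\], the intrusion rate floored at 0, and ordinal
#' demographic scales rounded and clipped into 1..5. Deterministic per
#' seed.
#'
#' @param preset One element of [group_presets()].
#' @param seed Integer seed.
#' @return A named list of parameters (class `ll_subject_params`) including
#'   `group` and `demographics`.
#' @export
sample_subject <- function(preset, seed = 1L) {
  seed <- check_seed(seed)
  with_seed(seed, {
    m <- preset$means
    s <- preset$sds[names(m)]
    vals <- stats::rnorm(length(m), m, s)
    names(vals) <- names(m)
    vals[PROB_FIELDS] <- clip01(vals[PROB_FIELDS])
    vals["intrusion_rate"] <- max(0, vals["intrusion_rate"])
    vals["latency_logsd"] <- max(0.01, vals["latency_logsd"])
    dm <- preset$demographics$means
    ds <- preset$demographics$sds[names(dm)]
    demo <- stats::rnorm(length(dm), dm, ds)
    names(demo) <- names(dm)
    demo[names(demo) != "age"] <- pmin(5, pmax(1, round(demo[names(demo) != "age"])))
    demo["age"] <- round(demo["age"])
    structure(c(as.list(vals), list(group = preset$group, demographics = demo)),
              class = "ll_subject_params")
  })
}

# Recall probability for the items of one phase.
recall_probs <- function(params, positions, trial, delay, cued) {
  p <- params$p_base + params$learn_rate * (trial - 1) +
    params$primacy_boost * (positions <= 4) +
    params$recency_boost * (positions >= 13) +
    params$cue_boost * cued
  clip01(p) * params$retention^delay
}

#' Build a behavioral responder from subject parameters
#'
#' Returns a responder usable with [administer()]. In each free- or
#' cued-recall phase of trial `t` at delay `d` (0 immediate, 1 short, 2
#' long), item `i` at presentation position `pos` is recalled with
#' probability `clip(p_base + learn_rate (t - 1) + primacy/recency boosts +
#' cue_boost [cued]) * retention^d`. Recalled items are output in
#' category-blocked order with probability `cluster_tendency`, otherwise
#' uniformly shuffled; intrusions are Poisson with the subject's rate,
#' drawn preferentially (probability 0.7) from the other learning list;
#' perseverations re-insert already-recalled words with probability
#' `persev_prob` each; recognition answers are Bernoulli per item type and
#' latencies lognormal.
#'
#' @param params An `ll_subject_params`.
#' @param lists The administered lists (`A`, `B`, `C`).
#' @param seed Integer seed; each phase uses a substream derived from it.
#' @return A responder function `function(phase, target, cues)`.
#' @export
behavioral_responder <- function(params, lists, seed = 1L) {
  seed <- check_seed(seed)
  presentations <- new.env(parent = emptyenv())
  presentations$A <- 0L
  presentations$B <- 0L

  function(phase, target, cues) {
    if (phase$phase_kind == "break") return(NULL)
    phase_seed <- derive_seed(seed, phase$phase_id)
    with_seed(phase_seed, {
      if (phase$phase_kind == "recognition") {
        p_yes <- ifelse(target$item_type == "target_A", params$recog_hit,
                        unlist(params[paste0("fa_", target$item_type)]))
        ans <- stats::runif(nrow(target)) < p_yes
        return(tibble::tibble(
          word = target$word, answer = ans,
          latency = stats::rlnorm(nrow(target), params$latency_logmean,
                                  params$latency_logsd)))
      }
      list_ref <- phase$list_ref
      if (phase$phase_kind == "immediate_free_recall") {
        presentations[[list_ref]] <- presentations[[list_ref]] + 1L
      }
      trial <- max(1L, presentations[[list_ref]])
      delay <- if (grepl("^short_delay", phase$phase_kind)) 1
               else if (grepl("^long_delay", phase$phase_kind)) 2 else 0
      cued <- grepl("cued", phase$phase_kind)
      p <- recall_probs(params, target$position, trial, delay, cued)
      recalled <- target[stats::runif(nrow(target)) < p, ]

      if (nrow(recalled) > 0) {
        if (stats::runif(1) < params$cluster_tendency) {
          cat_order <- sample(unique(recalled$category))
          recalled <- recalled[order(match(recalled$category, cat_order),
                                     sample.int(nrow(recalled))), ]
        } else {
          recalled <- recalled[sample.int(nrow(recalled)), ]
        }
      }
      words <- recalled$word

      n_int <- stats::rpois(1, params$intrusion_rate)
      if (n_int > 0) {
        other <- if (list_ref == "A") lists$B else lists$A
        intr <- vapply(seq_len(n_int), function(k) {
          if (stats::runif(1) < 0.7) sample(other$word, 1)
          else paste0("neverword", sample.int(9999, 1))
        }, character(1))
        for (w in intr) {
          at <- sample.int(length(words) + 1, 1)
          words <- append(words, w, after = at - 1)
        }
      }

      if (length(words) > 0 && params$persev_prob > 0) {
        correct_words <- words[words %in% target$word]
        rep_words <- correct_words[stats::runif(length(correct_words)) <
                                     params$persev_prob]
        for (w in rep_words) {
          first <- match(w, words)
          at <- if (first >= length(words)) length(words) + 1
                else sample(seq(first + 1, length(words) + 1), 1)
          words <- append(words, w, after = at - 1)
        }
      }

      if (length(words) == 0) return(NULL)
      tibble::tibble(
        word = words,
        latency = stats::rlnorm(length(words), params$latency_logmean,
                                params$latency_logsd))
    })
  }
}

generate_session_lists <- function(seed, lexicon_args, list_args, max_tries = 10) {
  for (k in seq_len(max_tries)) {
    s <- derive_seed(seed, 1000 + k)
    res <- tryCatch({
      lex <- do.call(synth_lexicon, c(lexicon_args, list(seed = s)))
      pair <- do.call(generate_list_pair, c(list(lexicon = lex, seed = s),
                                            list_args))
      C <- build_recognition_list(pair$A, pair$B, lex, seed = s)
      list(lexicon = lex, A = pair$A, B = pair$B, C = C)
    }, ll_error_infeasible = function(e) NULL,
       ll_error_capacity = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  abort_capacity("Could not generate a feasible list set within the retry budget.")
}

#' Simulate a labeled cohort
#'
#' For each subject: draws behavioral parameters from the group preset,
#' generates a fresh lexicon and list set (a new collection per session, so
#' no two subjects see the same lists), administers the schedule to the
#' subject's behavioral responder, and attaches an auxiliary feature block
#' (the break mini-games' surrogate): `n_aux` features equal to the
#' subject's latent `aux_ability` (group-separated, scaled by
#' `aux_separation`) plus Gaussian noise. Each subject runs on an RNG
#' substream derived from the master seed and subject index, so the cohort
#' is reproducible and insertion-order independent.
#'
#' @param composition Named integer vector of subjects per group, e.g.
#'   `c(HC = 8, MCI = 3, AD = 5)` (the default, matching a small pilot-scale
#'   cohort).
#' @param presets Group presets (see [group_presets()]).
#' @param seed Master integer seed.
#' @param schedule Administration schedule.
#' @param n_aux Size of the auxiliary feature block.
#' @param aux_noise_sd Noise standard deviation of auxiliary features.
#' @param aux_separation Multiplier on the latent ability's group means.
#' @param lexicon_args,list_args Arguments forwarded to [synth_lexicon()]
#'   and [generate_list_pair()] for the per-subject list sets.
#' @return An `ll_cohort`: list with `subjects` (tibble: id, group,
#'   parameters, demographics, aux features), `logs` (one `ll_session_log`
#'   per subject), `seed`; batteries are added by [score_cohort()].
#' @export
simulate_cohort <- function(composition = c(HC = 8, MCI = 3, AD = 5),
                            presets = group_presets(), seed = 1L,
                            schedule = default_schedule(), n_aux = 12,
                            aux_noise_sd = 0.3, aux_separation = 1,
                            lexicon_args = list(n_categories = 10,
                                                words_per_category = 16),
                            list_args = list()) {
  seed <- check_seed(seed)
  composition <- composition[composition > 0]
  if (length(composition) == 0) {
    abort_argument("Cohort composition is empty.")
  }
  if (!all(names(composition) %in% names(presets))) {
    abort_argument("Composition names must match preset groups.")
  }
  groups <- rep(names(composition), times = composition)
  subjects <- list()
  logs <- list()
  for (i in seq_along(groups)) {
    g <- groups[i]
    s_i <- derive_seed(seed, i)
    sess <- generate_session_lists(s_i, lexicon_args, list_args)
    params <- sample_subject(presets[[g]], seed = derive_seed(s_i, 2))
    aux <- with_seed(derive_seed(s_i, 3), {
      stats::setNames(params$aux_ability * aux_separation +
                        stats::rnorm(n_aux, 0, aux_noise_sd),
                      paste0("aux_", seq_len(n_aux)))
    })
    responder <- behavioral_responder(params, sess, seed = derive_seed(s_i, 4))
    log <- administer(schedule, sess[c("A", "B", "C")], responder,
                      seed = derive_seed(s_i, 5),
                      subject_id = sprintf("s%02d", i), aux_features = aux)
    par_fields <- params[setdiff(names(params), c("group", "demographics"))]
    subjects[[i]] <- tibble::as_tibble(c(
      list(subject_id = sprintf("s%02d", i), group = g),
      par_fields, as.list(params$demographics), as.list(aux)))
    logs[[i]] <- log
  }
  structure(list(subjects = dplyr::bind_rows(subjects), logs = logs,
                 batteries = NULL, seed = seed),
            class = "ll_cohort")
}

#' @export
print.ll_cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s), seed %d%s\n",
              nrow(x$subjects),
              paste(names(table(x$subjects$group)),
                    table(x$subjects$group), sep = ":", collapse = ", "),
              x$seed,
              if (is.null(x$batteries)) ", unscored" else ", scored"))
  invisible(x)
}

#' Score every subject of a cohort
#'
#' Runs [compute_battery()] on each session log and stores the stacked
#' batteries on the cohort.
#'
#' @param cohort An `ll_cohort`.
#' @return The cohort with a `batteries` tibble (one row per subject).
#' @export
score_cohort <- function(cohort) {
  bats <- purrr::map_dfr(seq_along(cohort$logs), function(i) {
    dplyr::bind_cols(
      tibble::tibble(subject_id = cohort$subjects$subject_id[i]),
      compute_battery(cohort$logs[[i]]))
  })
  cohort$batteries <- bats
  cohort
}

#' Write a cohort to a directory
#'
#' Writes a manifest CSV (labels, demographics, auxiliary features), the
#' battery CSV when scored, and one JSON-Lines session log per subject.
#'
#' @param cohort An `ll_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$subjects, file.path(dir, "cohort_manifest.csv"),
                   progress = FALSE)
  if (!is.null(cohort$batteries)) {
    readr::write_csv(cohort$batteries, file.path(dir, "batteries.csv"),
                     progress = FALSE)
  }
  for (i in seq_along(cohort$logs)) {
    write_session_log(cohort$logs[[i]],
                      file.path(dir, paste0("log_",
                                            cohort$subjects$subject_id[i],
                                            ".jsonl")))
  }
  invisible(dir)
}
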