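#' Administration protocol
#'
#' The administration schedule is a tibble of phases (kind, list, trial
#' index, nominal duration) driven by [administer()] over any responder — a
#' behavioral simulator or an adapter for human input. Administration emits
#' a validated session log: a time-stamped event stream (phase boundaries,
#' stimulus presentations, responses with latencies) in simulated time, so
#' the whole protocol is headless and host-invariant.
#'
#' @name protocol
#' @keywords internal
NULL

PHASE_KINDS <- c("immediate_free_recall", "short_delay_free_recall",
                 "short_delay_cued_recall", "break", "long_delay_free_recall",
                 "long_delay_cued_recall", "recognition")

new_schedule <- function(phases, name) {
  structure(tibble::as_tibble(phases), schedule_name = name,
            class = c("ll_schedule", class(tibble::tibble())))
}

#' The default administration schedule
#'
#' Three immediate free-recall trials of List A, one of List B, short-delay
#' free then cued recall of A, a 15-minute break (during which auxiliary
#' mini-games may be played), long-delay free then cued recall of A, and the
#' yes/no recognition phase over List C — nine phases in total. The break's
#' nominal duration forces the delay between short- and long-term recall.
#'
#' @return An `ll_schedule` tibble with columns `phase_id`, `phase_kind`,
#'   `list_ref`, `trial_index`, `nominal_duration` (minutes).
#' @export
#' @examples
#' default_schedule()
default_schedule <- function() {
  phases <- tibble::tribble(
    ~phase_kind,               ~list_ref, ~trial_index, ~nominal_duration,
    "immediate_free_recall",   "A",       1L,           2,
    "immediate_free_recall",   "A",       2L,           2,
    "immediate_free_recall",   "A",       3L,           2,
    "immediate_free_recall",   "B",       1L,           2,
    "short_delay_free_recall", "A",       1L,           2,
    "short_delay_cued_recall", "A",       1L,           2,
    "break",                   NA,        1L,           15,
    "long_delay_free_recall",  "A",       1L,           2,
    "long_delay_cued_recall",  "A",       1L,           2,
    "recognition",             "C",       1L,           5
  )
  phases <- dplyr::bind_cols(tibble::tibble(phase_id = seq_len(nrow(phases))),
                             phases)
  new_schedule(phases, "default")
}

validate_schedule <- function(schedule) {
  if (!is.data.frame(schedule) || nrow(schedule) == 0) {
    abort_argument("Schedule must be a non-empty phase table.")
  }
  if (!all(schedule$phase_kind %in% PHASE_KINDS)) {
    abort_argument("Schedule contains unknown phase kinds.")
  }
  if (sum(schedule$phase_kind == "recognition") != 1) {
    abort_argument("Schedule must contain exactly one recognition phase.")
  }
  rec <- which(schedule$phase_kind == "recognition")
  if (!identical(schedule$list_ref[rec], "C")) {
    abort_argument("The recognition phase must reference List C.")
  }
  long_idx <- which(grepl("^long_delay", schedule$phase_kind))
  brk <- which(schedule$phase_kind == "break")
  if (length(long_idx) > 0 && (length(brk) == 0 || min(brk) > min(long_idx))) {
    abort_argument("A break phase must precede any long-delay phase.")
  }
  invisible(schedule)
}

phase_target_list <- function(kind, list_ref, lists) {
  switch(kind,
         recognition = lists$C,
         `break` = NULL,
         lists[[list_ref]])
}

is_recall_kind <- function(kind) {
  kind %in% setdiff(PHASE_KINDS, c("break", "recognition"))
}

#' Run the administration protocol over a responder
#'
#' Walks the schedule as a state machine, presenting stimuli at a fixed
#' simulated cadence and collecting the responder's responses, and emits a
#' session log. The responder is a function
#' `function(phase, target_list, cues)` returning, for recall phases, a
#' tibble with columns `word` and `latency` (seconds), and for the
#' recognition phase columns `word`, `answer` (logical yes/no) and
#' `latency`; it must return no rows for break phases. Unknown response
#' tokens are recorded verbatim — they become intrusions at scoring time,
#' not errors. Time is simulated: stimuli advance the clock by `cadence`
#' seconds each, responses by their latencies, and the break by its nominal
#' duration, so logs are identical across hosts.
#'
#' @param schedule An `ll_schedule` (see [default_schedule()]).
#' @param lists A list with elements `A`, `B` (stimulus lists) and `C`
#'   (recognition list).
#' @param responder The response-producing function described above.
#' @param seed Integer seed recorded in the log (and passed to the
#'   responder via the `phase$seed` field for deterministic behavior).
#' @param cadence Seconds per presented stimulus (default 2).
#' @param subject_id Identifier stored in the log.
#' @param aux_features Optional named numeric vector attached at the break
#'   phase (auxiliary mini-game feature block).
#' @return An `ll_session_log`: list with `subject_id`, `schedule`, `lists`,
#'   `events` (tibble: `t`, `phase_id`, `kind`, `word`, `modality`,
#'   `answer`, `latency`), `aux_features`, `seed`.
#' @export
administer <- function(schedule, lists, responder, seed = 1L, cadence = 2,
                       subject_id = "subject", aux_features = NULL) {
  validate_schedule(schedule)
  seed <- check_seed(seed)
  ev <- list()
  t <- 0
  add <- function(t, phase_id, kind, word = NA_character_,
                  modality = NA_character_, answer = NA, latency = NA_real_) {
    ev[[length(ev) + 1]] <<- tibble::tibble(
      t = t, phase_id = phase_id, kind = kind, word = word,
      modality = modality, answer = answer, latency = latency)
  }
  for (i in seq_len(nrow(schedule))) {
    ph <- schedule[i, ]
    add(t, ph$phase_id, "phase_start")
    target <- phase_target_list(ph$phase_kind, ph$list_ref, lists)
    cues <- NULL
    if (ph$phase_kind == "break") {
      resp <- responder(as.list(ph), NULL, NULL)
      if (!is.null(resp) && nrow(resp) > 0) {
        abort_protocol("Responder emitted responses during a break phase.")
      }
      t <- t + ph$nominal_duration * 60
      add(t, ph$phase_id, "phase_end")
      next
    }
    if (ph$phase_kind == "immediate_free_recall") {
      # learning presentation precedes recall
      for (w in target$word) {
        t <- t + cadence
        add(t, ph$phase_id, "stimulus_shown", word = w, modality = "item")
      }
    }
    if (grepl("cued", ph$phase_kind)) {
      cues <- unique(lists$A$category)
      for (cue in cues) {
        t <- t + cadence
        add(t, ph$phase_id, "stimulus_shown", word = cue, modality = "cue")
      }
    }
    if (ph$phase_kind == "recognition") {
      resp <- responder(as.list(ph), target, NULL)
      if (is.null(resp)) {
        resp <- tibble::tibble(word = character(), answer = logical(),
                               latency = numeric())
      }
      if (anyDuplicated(resp$word)) {
        abort_protocol("Multiple recognition responses for a single item.")
      }
      resp <- resp[match(target$word, resp$word), , drop = FALSE]
      for (j in seq_len(nrow(target))) {
        t <- t + cadence
        add(t, ph$phase_id, "stimulus_shown", word = target$word[j],
            modality = "recognition_item")
        lat <- resp$latency[j]
        if (!is.na(resp$word[j] %||% NA)) {
          t <- t + lat
          add(t, ph$phase_id, "response", word = target$word[j],
              answer = isTRUE(resp$answer[j]), latency = lat)
        }
      }
    } else {
      resp <- responder(as.list(ph), target, cues)
      if (!is.null(resp) && nrow(resp) > 0) {
        for (j in seq_len(nrow(resp))) {
          t <- t + resp$latency[j]
          add(t, ph$phase_id, "response", word = resp$word[j],
              latency = resp$latency[j])
        }
      }
    }
    add(t, ph$phase_id, "phase_end")
  }
  log <- structure(
    list(subject_id = subject_id, schedule = schedule, lists = lists,
         events = dplyr::bind_rows(ev), aux_features = aux_features,
         seed = seed),
    class = "ll_session_log")
  viol <- validate_log(log)
  if (nrow(viol) > 0) {
    abort_validation(paste0("Administered log failed validation: ",
                            paste(viol$message, collapse = "; ")))
  }
  log
}

#' @export
print.ll_session_log <- function(x, ...) {
  cat(sprintf("<session log> subject %s, %d phases, %d events, seed %d\n",
              x$subject_id, nrow(x$schedule), nrow(x$events), x$seed))
  invisible(x)
}

#' Validate a session log
#'
#' Reports (never raises) every invariant violation: non-decreasing
#' timestamps, one start/end pair per scheduled phase, responses contained
#' within their phase window, events referencing scheduled phases only.
#'
#' @param log An `ll_session_log`.
#' @return A tibble of violations (`phase_id`, `type`, `message`); zero rows
#'   when the log is valid.
#' @export
validate_log <- function(log) {
  v <- list()
  note <- function(phase_id, type, message) {
    v[[length(v) + 1]] <<- tibble::tibble(phase_id = phase_id, type = type,
                                          message = message)
  }
  e <- log$events
  if (any(diff(e$t) < 0)) {
    note(NA_integer_, "ordering", "timestamps decrease within the log")
  }
  if (any(!e$phase_id %in% log$schedule$phase_id)) {
    note(NA_integer_, "schedule", "event references an unscheduled phase")
  }
  for (pid in log$schedule$phase_id) {
    pe <- e[e$phase_id == pid, ]
    starts <- which(pe$kind == "phase_start")
    ends <- which(pe$kind == "phase_end")
    if (length(starts) != 1 || length(ends) != 1) {
      note(pid, "structure", sprintf("phase %d lacks a unique start/end pair", pid))
      next
    }
    t0 <- pe$t[starts]
    t1 <- pe$t[ends]
    inner <- pe[pe$kind %in% c("stimulus_shown", "response"), ]
    if (nrow(inner) > 0 && (any(inner$t < t0) || any(inner$t > t1))) {
      note(pid, "containment",
           sprintf("phase %d has events outside its start/end window", pid))
    }
    kind <- log$schedule$phase_kind[log$schedule$phase_id == pid]
    if (kind == "break" && any(pe$kind == "response")) {
      note(pid, "protocol", sprintf("break phase %d contains responses", pid))
    }
  }
  if (length(v) == 0) {
    tibble::tibble(phase_id = integer(), type = character(), message = character())
  } else {
    dplyr::bind_rows(v)
  }
}

#' Simulated duration of a schedule
#'
#' The deterministic simulated-time budget: stimulus cadence times item
#' counts plus nominal break duration; independent of wall clock and host.
#'
#' @param schedule An `ll_schedule`.
#' @param cadence Seconds per stimulus.
#' @param n_items Items per learning list.
#' @param n_recognition Items in the recognition list.
#' @return Duration in seconds (responses excluded).
#' @export
schedule_duration <- function(schedule, cadence = 2, n_items = 16,
                              n_recognition = 44) {
  stim <- vapply(seq_len(nrow(schedule)), function(i) {
    kind <- schedule$phase_kind[i]
    if (kind == "immediate_free_recall") n_items * cadence
    else if (grepl("cued", kind)) 4 * cadence
    else if (kind == "recognition") n_recognition * cadence
    else 0
  }, numeric(1))
  brk <- sum(schedule$nominal_duration[schedule$phase_kind == "break"]) * 60
  sum(stim) + brk
}

#' Write a session log as JSON Lines
#'
#' First line is a header object (subject, seed, schedule name, list
#' digests); each subsequent line is one event.
#'
#' @param log An `ll_session_log`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  header <- list(
    subject_id = log$subject_id, seed = log$seed,
    schedule = attr(log$schedule, "schedule_name") %||% "custom",
    list_digests = list(A = rlang::hash(log$lists$A$word),
                        B = rlang::hash(log$lists$B$word),
                        C = rlang::hash(log$lists$C$word)))
  lines <- c(jsonlite::toJSON(header, auto_unbox = TRUE),
             vapply(seq_len(nrow(log$events)), function(i) {
               as.character(jsonlite::toJSON(as.list(log$events[i, ]),
                                             auto_unbox = TRUE, na = "null"))
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
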