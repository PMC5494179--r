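# Shared fixtures, memoised so expensive simulations run once per suite.

.ll_cache <- new.env(parent = emptyenv())

ll_cached <- function(name, expr) {
  if (!exists(name, envir = .ll_cache)) {
    assign(name, force(expr), envir = .ll_cache)
  }
  get(name, envir = .ll_cache)
}

# A lexicon + list set generated at a fixed seed, reused across tests.
fixture_session <- function() {
  ll_cached("session", {
    lex <- synth_lexicon(10, 16, seed = 11)
    pair <- generate_list_pair(lex, seed = 11)
    C <- build_recognition_list(pair$A, pair$B, lex, seed = 11)
    list(lexicon = lex, A = pair$A, B = pair$B, C = C,
         lists = list(A = pair$A, B = pair$B, C = C))
  })
}

# Responder that recalls every list item in presentation order and answers
# recognition perfectly, with unit latencies.
perfect_responder <- function(phase, target, cues) {
  if (phase$phase_kind == "break") return(NULL)
  if (phase$phase_kind == "recognition") {
    return(tibble::tibble(word = target$word,
                          answer = target$item_type == "target_A",
                          latency = 1))
  }
  tibble::tibble(word = target$word, latency = 1)
}

mute_responder <- function(phase, target, cues) NULL

# Responder producing a fixed token sequence in every free-recall phase.
scripted_responder <- function(script) {
  function(phase, target, cues) {
    if (phase$phase_kind == "break") return(NULL)
    if (phase$phase_kind == "recognition") {
      return(tibble::tibble(word = target$word,
                            answer = target$item_type == "target_A",
                            latency = 1))
    }
    tibble::tibble(word = script, latency = 1)
  }
}

fixture_perfect_log <- function() {
  ll_cached("perfect_log", {
    administer(default_schedule(), fixture_session()$lists,
               perfect_responder, seed = 1)
  })
}

# The pilot-scale cohort used by the classification tests (8 HC, 3 MCI,
# 5 AD; default presets; master seed 42), scored.
fixture_pilot_cohort <- function() {
  ll_cached("pilot_cohort", score_cohort(simulate_cohort(seed = 42)))
}

# A balanced medium cohort for distributional properties (group ordering,
# retention and cue effects, parameter recovery).
fixture_balanced_cohort <- function() {
  ll_cached("balanced_cohort", {
    score_cohort(simulate_cohort(composition = c(HC = 12, MCI = 12, AD = 12),
                                 seed = 7))
  })
}

# Separable synthetic feature table for classifier sanity checks: three
# tight clusters far apart.
synthetic_features <- function(n_per = 5, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    g <- rep(c("HC", "MCI", "AD"), each = n_per)
    mu <- c(HC = gap, MCI = 0, AD = -gap)[g]
    out <- tibble::tibble(
      subject_id = sprintf("t%02d", seq_along(g)), group = g,
      f1 = mu + stats::rnorm(length(g), 0, 0.5),
      f2 = mu + stats::rnorm(length(g), 0, 0.5),
      f3 = stats::rnorm(length(g)),
      f4 = stats::rnorm(length(g)))
    structure(out, class = c("ll_features", class(tibble::tibble())))
  })
}

# Independent oracle: all permutations of a vector, written separately from
# the package's enumerator.
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(oracle_perms(v[-i]), function(p) c(v[i], p))
  }))
}
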