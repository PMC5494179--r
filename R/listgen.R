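#' Stimulus list generation
#'
#' Learning lists A (main) and B (interference) are 16-item lists drawn from
#' 4 semantic categories (4 items each), sharing exactly 2 categories, with
#' disjoint word sets, each matched to a target mean usage frequency. The
#' 44-item recognition list C combines all of A with typed distractors from
#' B, category prototypes, phonetic neighbours and unrelated words.
#'
#' @name listgen
#' @keywords internal
NULL

new_stimulus_list <- function(items, role, target, achieved, seed) {
  structure(
    tibble::as_tibble(items),
    role = role,
    target_frequency = target,
    achieved_frequency = achieved,
    list_categories = unique(items$category),
    seed = seed,
    class = c("ll_stimulus_list", class(tibble::tibble()))
  )
}

#' @export
print.ll_stimulus_list <- function(x, ...) {
  cat(sprintf("<stimulus list %s>  target freq %.6g, achieved %.6g (seed %d)\n",
              attr(x, "role"), attr(x, "target_frequency"),
              attr(x, "achieved_frequency"), attr(x, "seed")))
  NextMethod()
}

# All 4-subsets per category pool with their frequency sums.
category_combos <- function(pool) {
  idx <- utils::combn(nrow(pool), 4)
  sums <- colSums(matrix(pool$frequency[idx], nrow = 4))
  list(idx = idx, sums = sums)
}

# Pick 4 words from each of 4 category pools so that the 16-item mean
# frequency is as close to `target` as possible. Exact for small pools
# (meet-in-the-middle over per-category 4-subset sums), otherwise seeded
# randomized search with a candidate budget. Deterministic tie-breaking,
# lexicographic by word set among examined optima.
select_matched_items <- function(pools, target, budget, max_half = 250000) {
  combos <- lapply(pools, category_combos)
  n12 <- length(combos[[1]]$sums) * length(combos[[2]]$sums)
  n34 <- length(combos[[3]]$sums) * length(combos[[4]]$sums)
  if (n12 <= max_half && n34 <= max_half) {
    s12 <- outer(combos[[1]]$sums, combos[[2]]$sums, `+`)
    s34 <- outer(combos[[3]]$sums, combos[[4]]$sums, `+`)
    ord34 <- order(s34)
    s34s <- as.vector(s34)[ord34]
    want <- 16 * target - as.vector(s12)
    lo <- pmax(1L, pmin(length(s34s), findInterval(want, s34s)))
    hi <- pmin(length(s34s), lo + 1L)
    dev_lo <- abs(as.vector(s12) + s34s[lo] - 16 * target)
    dev_hi <- abs(as.vector(s12) + s34s[hi] - 16 * target)
    dev <- pmin(dev_lo, dev_hi)
    best_dev <- min(dev)
    cand12 <- which(dev <= best_dev + 1e-18)
    pick_words <- function(i12, i34flat) {
      ij <- arrayInd(i12, dim(s12))
      kl <- arrayInd(ord34[i34flat], dim(s34))
      c(pools[[1]]$word[combos[[1]]$idx[, ij[1]]],
        pools[[2]]$word[combos[[2]]$idx[, ij[2]]],
        pools[[3]]$word[combos[[3]]$idx[, kl[1]]],
        pools[[4]]$word[combos[[4]]$idx[, kl[2]]])
    }
    sets <- lapply(cand12, function(i) {
      i34 <- if (dev_lo[i] <= dev_hi[i]) lo[i] else hi[i]
      pick_words(i, i34)
    })
    keys <- vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
    return(list(words = sets[[order(keys)[1]]], deviation = best_dev / 16 / target))
  }
  freqs <- lapply(pools, function(p) p$frequency)
  sizes <- vapply(pools, nrow, integer(1))
  best_dev <- Inf
  best_idx <- list()
  for (i in seq_len(budget)) {
    idx <- lapply(seq_along(pools), function(k) sample.int(sizes[k], 4))
    tot <- sum(vapply(seq_along(pools),
                      function(k) sum(freqs[[k]][idx[[k]]]), numeric(1)))
    dev <- abs(tot / 16 - target)
    if (dev < best_dev - 1e-18) {
      best_dev <- dev
      best_idx <- list(idx)
    } else if (abs(dev - best_dev) <= 1e-18) {
      best_idx <- c(best_idx, list(idx))
    }
  }
  words_of <- function(idx) {
    unlist(lapply(seq_along(pools), function(k) pools[[k]]$word[idx[[k]]]))
  }
  keys <- vapply(best_idx, function(s) paste(sort(words_of(s)), collapse = "|"),
                 character(1))
  list(words = words_of(best_idx[[order(keys)[1]]]), deviation = best_dev / target)
}

#' Generate the frequency-matched learning list pair
#'
#' Selects 6 semantic categories (2 shared, 2 exclusive to each list) and,
#' for each list, 4 words per category so that the 16-item mean frequency
#' approximates the list's target. The per-list selection minimises the
#' absolute deviation from the target over a seeded search (exhaustive for
#' small pools, randomized with `budget` candidates otherwise) and must land
#' within the relative `tolerance`; otherwise an infeasibility error reports
#' the best deviation achieved. A and B have disjoint word sets, and each
#' list's presentation order avoids adjacent same-category items so that
#' semantic-clustering scores are interpretable.
#'
#' @param lexicon A lexicon tibble with at least 6 categories of >= 8 words.
#' @param target_freq_A,target_freq_B Target mean relative frequencies.
#'   Defaults are the reference main-list and interference-list values.
#' @param tolerance Maximum relative deviation `|achieved - target|/target`.
#' @param seed Integer seed; regeneration with the same lexicon and seed is
#'   identical, different seeds give fresh list versions (anti-practice
#'   effect).
#' @param budget Candidate budget for the randomized search.
#' @return A list with elements `A` and `B`, each an `ll_stimulus_list`.
#' @export
generate_list_pair <- function(lexicon, target_freq_A = 0.000368,
                               target_freq_B = 0.0000845,
                               tolerance = 0.15, seed = 1L, budget = 5000) {
  lexicon <- validate_lexicon(lexicon)
  seed <- check_seed(seed)
  if (target_freq_A <= 0 || target_freq_B <= 0) {
    abort_argument("Target frequencies must be positive.")
  }
  sizes <- table(lexicon$category)
  eligible <- names(sizes)[sizes >= 8]
  if (length(eligible) < 6) {
    abort_capacity(paste0(
      "Need at least 6 categories with >= 8 words each; found ",
      length(eligible), "."))
  }
  with_seed(seed, {
    cats <- sample(eligible, 6)
    shared <- cats[1:2]
    only_A <- cats[3:4]
    only_B <- cats[5:6]
    cats_A <- c(shared, only_A)
    cats_B <- c(shared, only_B)

    pools_A <- lapply(cats_A, function(ct) {
      dplyr::filter(lexicon, .data$category == ct)
    })
    sel_A <- select_matched_items(pools_A, target_freq_A, budget)
    if (sel_A$deviation > tolerance) {
      abort_infeasible(sprintf(
        "List A frequency matching infeasible: best relative deviation %.4g exceeds tolerance %.4g.",
        sel_A$deviation, tolerance), best_deviation = sel_A$deviation)
    }
    pools_B <- lapply(cats_B, function(ct) {
      dplyr::filter(lexicon, .data$category == ct, !.data$word %in% sel_A$words)
    })
    if (any(vapply(pools_B, nrow, integer(1)) < 4)) {
      abort_capacity("A shared category has fewer than 4 words left for List B.")
    }
    sel_B <- select_matched_items(pools_B, target_freq_B, budget)
    if (sel_B$deviation > tolerance) {
      abort_infeasible(sprintf(
        "List B frequency matching infeasible: best relative deviation %.4g exceeds tolerance %.4g.",
        sel_B$deviation, tolerance), best_deviation = sel_B$deviation)
    }

    items_A <- lexicon[match(sel_A$words, lexicon$word), ]
    items_B <- lexicon[match(sel_B$words, lexicon$word), ]
    ord_A <- arrange_presentation_order(items_A, seed = derive_seed(seed, 1L))
    ord_B <- arrange_presentation_order(items_B, seed = derive_seed(seed, 2L))
    list(
      A = new_stimulus_list(ord_A, "A", target_freq_A, mean_frequency(ord_A), seed),
      B = new_stimulus_list(ord_B, "B", target_freq_B, mean_frequency(ord_B), seed)
    )
  })
}

#' Arrange a presentation order without category runs
#'
#' Draws a uniform random permutation of the selected items, subject to no
#' two adjacent items sharing a semantic category (rejection sampling,
#' 10,000 attempt budget). Presentation must not be pre-clustered, otherwise
#' recall clustering scores are meaningless.
#'
#' @param items A data frame of selected entries with `word` and `category`.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget.
#' @return `items` reordered, with a `position` column prepended.
#' @export
arrange_presentation_order <- function(items, seed = 1L, max_attempts = 10000) {
  seed <- check_seed(seed)
  n <- nrow(items)
  if (n == 0) abort_argument("No items to arrange.")
  counts <- table(items$category)
  if (max(counts) > ceiling(n / 2)) {
    abort_ll(paste0(
      "No adjacency-free order exists: category '", names(which.max(counts)),
      "' holds ", max(counts), " of ", n, " items."), "ll_error_arrangement")
  }
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      perm <- sample.int(n)
      cats <- items$category[perm]
      if (n == 1 || all(cats[-1] != cats[-n])) {
        out <- items[perm, ]
        return(tibble::as_tibble(dplyr::bind_cols(
          tibble::tibble(position = seq_len(n)), out)))
      }
    }
    abort_ll("Could not find an adjacency-free order within the attempt budget.",
             "ll_error_arrangement")
  })
}

RECOGNITION_TYPES <- c("target_A", "shared_B", "nonshared_B", "prototype_A",
                       "phonetic_A", "unrelated")
RECOGNITION_COUNTS <- c(target_A = 16L, shared_B = 4L, nonshared_B = 4L,
                        prototype_A = 4L, phonetic_A = 8L, unrelated = 8L)

#' Build the 44-item yes/no recognition list
#'
#' Follows the classical recognition-list recipe: all 16 List-A targets; 8
#' List-B items (2 from each shared category, 2 from each B-exclusive
#' category); 4 category prototypes of A's categories (the
#' highest-frequency prototypical lexicon entries outside A and B, one per
#' category); 8 phonetic neighbours of A words; and 8 unrelated words with
#' no category overlap with A or B and no phonetic-key match to any A word.
#' The final order is a seeded shuffle. The correct answer is "yes" exactly
#' for the 16 targets.
#'
#' @param A,B Stimulus lists from [generate_list_pair()].
#' @param lexicon The lexicon both lists were drawn from.
#' @param seed Integer seed.
#' @return An `ll_recognition_list` tibble of 44 rows with columns
#'   `position`, `word`, `category`, `frequency`, `item_type`,
#'   `correct_answer`.
#' @export
build_recognition_list <- function(A, B, lexicon, seed = 1L) {
  lexicon <- validate_lexicon(lexicon)
  seed <- check_seed(seed)
  used <- c(A$word, B$word)
  if (anyDuplicated(used)) abort_argument("A and B must be word-disjoint.")
  cats_A <- attr(A, "list_categories")
  cats_B <- attr(B, "list_categories")
  shared <- intersect(cats_A, cats_B)
  excl_B <- setdiff(cats_B, cats_A)
  a_keys <- stats::na.omit(lexicon$phonetic_key[match(A$word, lexicon$word)])

  with_seed(seed, {
    take <- function(pool, k, label) {
      if (nrow(pool) < k) {
        abort_capacity(paste0("Recognition pool '", label, "' has only ",
                              nrow(pool), " candidates; need ", k, "."))
      }
      pool[sample.int(nrow(pool), k), ]
    }
    entry_cols <- function(x) {
      tibble::tibble(word = x$word, category = x$category, frequency = x$frequency)
    }

    targets <- entry_cols(A) |> dplyr::mutate(item_type = "target_A")
    shared_b <- purrr::map_dfr(shared, function(ct) {
      take(entry_cols(dplyr::filter(B, .data$category == ct)), 2,
           paste0("shared_B (", ct, ")"))
    }) |> dplyr::mutate(item_type = "shared_B")
    nonshared_b <- purrr::map_dfr(excl_B, function(ct) {
      take(entry_cols(dplyr::filter(B, .data$category == ct)), 2,
           paste0("nonshared_B (", ct, ")"))
    }) |> dplyr::mutate(item_type = "nonshared_B")

    taken <- c(targets$word, shared_b$word, nonshared_b$word)
    protos <- purrr::map_dfr(cats_A, function(ct) {
      pool <- lexicon |>
        dplyr::filter(.data$category == ct, .data$prototypical,
                      !.data$word %in% used, !.data$word %in% taken) |>
        dplyr::arrange(dplyr::desc(.data$frequency), .data$word)
      if (nrow(pool) == 0) {
        abort_capacity(paste0("Recognition pool 'prototype_A (", ct,
                              ")' is empty."))
      }
      entry_cols(pool[1, ])
    }) |> dplyr::mutate(item_type = "prototype_A")
    taken <- c(taken, protos$word)

    phon_pool <- lexicon |>
      dplyr::filter(.data$phonetic_key %in% a_keys,
                    !.data$word %in% used, !.data$word %in% taken)
    phonetic <- take(entry_cols(phon_pool), 8, "phonetic_A") |>
      dplyr::mutate(item_type = "phonetic_A")
    taken <- c(taken, phonetic$word)

    unrel_pool <- lexicon |>
      dplyr::filter(!.data$category %in% c(cats_A, cats_B),
                    !.data$phonetic_key %in% a_keys,
                    !.data$word %in% used, !.data$word %in% taken)
    unrelated <- take(entry_cols(unrel_pool), 8, "unrelated") |>
      dplyr::mutate(item_type = "unrelated")

    all_items <- dplyr::bind_rows(targets, shared_b, nonshared_b, protos,
                                  phonetic, unrelated)
    all_items <- all_items[sample.int(nrow(all_items)), ]
    out <- dplyr::bind_cols(tibble::tibble(position = seq_len(nrow(all_items))),
                            all_items) |>
      dplyr::mutate(correct_answer = .data$item_type == "target_A")
    structure(out, seed = seed,
              class = c("ll_recognition_list", class(tibble::tibble())))
  })
}

#' Validate a stimulus list
#'
#' Returns a character vector of invariant violations (empty when valid):
#' 16 items, exactly 4 items in each of exactly 4 categories, no duplicate
#' words, no two adjacent same-category items, and frequency tolerance when
#' one is supplied.
#'
#' @param x An `ll_stimulus_list`.
#' @param tolerance Optional relative tolerance to check `achieved` against
#'   `target`.
#' @return Character vector of violation messages.
#' @export
validate_stimulus_list <- function(x, tolerance = NULL) {
  v <- character()
  if (nrow(x) != 16) v <- c(v, sprintf("expected 16 items, found %d", nrow(x)))
  counts <- table(x$category)
  if (length(counts) != 4 || any(counts != 4)) {
    v <- c(v, "items are not 4 per each of exactly 4 categories")
  }
  if (anyDuplicated(x$word)) v <- c(v, "duplicate words")
  if (nrow(x) > 1 && any(x$category[-1] == x$category[-nrow(x)])) {
    v <- c(v, "adjacent same-category items in presentation order")
  }
  if (!is.null(tolerance)) {
    tgt <- attr(x, "target_frequency")
    ach <- attr(x, "achieved_frequency")
    if (!is.null(tgt) && abs(ach - tgt) / tgt > tolerance + 1e-12) {
      v <- c(v, sprintf("achieved frequency %.4g outside tolerance of target %.4g",
                        ach, tgt))
    }
  }
  v
}

#' Validate a recognition list
#'
#' Returns violations of the 44-item composition (16 targets, 4 shared-B, 4
#' nonshared-B, 4 prototypes, 8 phonetic, 8 unrelated), word uniqueness,
#' answer-key consistency, and disjointness of distractor pools from A and B.
#'
#' @param x An `ll_recognition_list`.
#' @param A,B Optionally, the learning lists, to check distractor
#'   disjointness.
#' @return Character vector of violation messages.
#' @export
validate_recognition_list <- function(x, A = NULL, B = NULL) {
  v <- character()
  if (nrow(x) != 44) v <- c(v, sprintf("expected 44 items, found %d", nrow(x)))
  counts <- table(factor(x$item_type, levels = RECOGNITION_TYPES))
  bad <- RECOGNITION_TYPES[counts != RECOGNITION_COUNTS[RECOGNITION_TYPES]]
  if (length(bad) > 0) {
    v <- c(v, paste0("wrong count for item type(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(x$word)) v <- c(v, "duplicate words")
  if (!all(x$correct_answer == (x$item_type == "target_A"))) {
    v <- c(v, "correct_answer inconsistent with item_type")
  }
  if (!is.null(A) && !is.null(B)) {
    distract <- x$word[x$item_type %in% c("prototype_A", "phonetic_A", "unrelated")]
    if (any(distract %in% c(A$word, B$word))) {
      v <- c(v, "distractor items overlap A or B")
    }
  }
  v
}

#' Category correspondence between the classical test and the game setting
#'
#' The classical verbal test's semantic categories are mapped onto
#' ecological categories that fit an urban virtual walk. The mapping is a
#' fixed constant: for List A, tools correspond to vehicles, herbs to shops,
#' fruits to professions and clothes to urban furniture; for List B, cooking
#' utensils to vehicles, fruits to buildings, fishes to urban furniture and
#' herbs to tools.
#'
#' @param direction `"cvlt_to_game"` (default) or `"game_to_cvlt"`.
#' @return A tibble with columns `list`, `from`, `to`.
#' @export
#' @examples
#' m <- cvlt_category_map()
#' dplyr::filter(m, list == "A", from == "tools")$to  # "vehicles"
cvlt_category_map <- function(direction = c("cvlt_to_game", "game_to_cvlt")) {
  direction <- tryCatch(match.arg(direction),
                        error = function(e) abort_argument(
                          "`direction` must be 'cvlt_to_game' or 'game_to_cvlt'."))
  m <- tibble::tibble(
    list = rep(c("A", "B"), each = 4),
    cvlt = c("tools", "herbs", "fruits", "clothes",
             "cooking utensils", "fruits", "fishes", "herbs"),
    game = c("vehicles", "shops", "professions", "urban furniture",
             "vehicles", "buildings", "urban furniture", "tools")
  )
  if (direction == "cvlt_to_game") {
    dplyr::rename(m, from = "cvlt", to = "game")
  } else {
    dplyr::rename(m, from = "game", to = "cvlt")
  }
}

#' Serialize a stimulus or recognition list to JSON
#'
#' Writes role/seed/frequency metadata and the ordered items with stable key
#' order.
#'
#' @param x An `ll_stimulus_list` or `ll_recognition_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_list_json <- function(x, path) {
  payload <- if (inherits(x, "ll_stimulus_list")) {
    list(kind = "stimulus_list", role = attr(x, "role"),
         seed = attr(x, "seed"),
         target_frequency = attr(x, "target_frequency"),
         achieved_frequency = attr(x, "achieved_frequency"),
         items = tibble::as_tibble(x))
  } else if (inherits(x, "ll_recognition_list")) {
    list(kind = "recognition_list", seed = attr(x, "seed"),
         items = tibble::as_tibble(x))
  } else {
    abort_argument("`x` must be a stimulus or recognition list.")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
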