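#' Lexicon objects
#'
#' A lexicon is the vocabulary pool from which all stimulus lists are drawn:
#' a tibble with one row per word carrying its semantic category, relative
#' corpus usage frequency, a prototypicality flag and an optional phonetic
#' key used for phonetic-similarity matching. Frequencies are stored exactly
#' as given (relative, dimensionless, in the open interval (0, 1)) and are
#' never re-normalised: list generation matches raw corpus frequencies.
#'
#' @name lexicon
#' @keywords internal
NULL

LEXICON_COLUMNS <- c("word", "category", "frequency", "prototypical", "phonetic_key")

new_lexicon <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)[LEXICON_COLUMNS]
  structure(tbl, class = c("ll_lexicon", class(tibble::tibble())))
}

#' Validate a lexicon table
#'
#' Checks the lexicon invariants: unique non-empty words, non-empty
#' categories, strictly positive numeric frequencies.
#'
#' @param tbl A data frame with columns `word`, `category`, `frequency` and
#'   optionally `prototypical`, `phonetic_key`.
#' @return The validated lexicon (invisibly classed), or a classed
#'   validation error.
#' @export
validate_lexicon <- function(tbl) {
  if (!all(c("word", "category", "frequency") %in% names(tbl))) {
    missing <- setdiff(c("word", "category", "frequency"), names(tbl))
    abort_format(paste0("Lexicon is missing mandatory column(s): ",
                        paste(missing, collapse = ", "), "."))
  }
  if (!"prototypical" %in% names(tbl)) tbl$prototypical <- FALSE
  if (!"phonetic_key" %in% names(tbl)) tbl$phonetic_key <- NA_character_
  tbl$prototypical <- as.logical(tbl$prototypical)
  if (any(is.na(tbl$word)) || any(!nzchar(tbl$word))) {
    abort_validation("Lexicon contains empty word tokens.")
  }
  dup <- tbl$word[duplicated(tbl$word)]
  if (length(dup) > 0) {
    abort_validation(paste0("Duplicate word(s) in lexicon: ",
                            paste(unique(dup), collapse = ", "), "."))
  }
  if (any(is.na(tbl$category)) || any(!nzchar(tbl$category))) {
    abort_validation("Lexicon contains empty category labels.")
  }
  bad <- which(is.na(tbl$frequency) | !is.finite(tbl$frequency) | tbl$frequency <= 0)
  if (length(bad) > 0) {
    abort_validation(paste0("Non-positive or non-numeric frequency at row(s): ",
                            paste(bad, collapse = ", "), "."))
  }
  new_lexicon(tbl)
}

#' Read a lexicon from a TSV file
#'
#' The file must be UTF-8 tab-separated with a header naming at least
#' `word`, `category` and `frequency` ("." decimal separator); the optional
#' columns `prototypical` (0/1) and `phonetic_key` are picked up when
#' present. Unknown extra columns are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @return A validated lexicon tibble.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("word\tcategory\tfrequency",
#'              "bus\tvehicles\t0.0004",
#'              "taxi\tvehicles\t0.0002"), tf)
#' read_lexicon(tf)
read_lexicon <- function(path) {
  if (!file.exists(path)) abort_format(paste0("Lexicon file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  extra <- setdiff(names(raw), LEXICON_COLUMNS)
  if (length(extra) > 0) {
    rlang::warn(paste0("Ignoring unknown lexicon column(s): ",
                       paste(extra, collapse = ", "), "."))
    raw <- raw[intersect(names(raw), LEXICON_COLUMNS)]
  }
  if (!all(c("word", "category", "frequency") %in% names(raw))) {
    missing <- setdiff(c("word", "category", "frequency"), names(raw))
    abort_format(paste0("Lexicon is missing mandatory column(s): ",
                        paste(missing, collapse = ", "), "."))
  }
  freq <- suppressWarnings(as.numeric(raw$frequency))
  bad <- which(is.na(freq) | freq <= 0)
  if (length(bad) > 0) {
    abort_validation(paste0("Non-positive or non-numeric frequency at row(s): ",
                            paste(bad, collapse = ", "), "."))
  }
  raw$frequency <- freq
  if ("prototypical" %in% names(raw)) {
    raw$prototypical <- as.integer(raw$prototypical) > 0
  }
  validate_lexicon(raw)
}

#' Write a lexicon to a TSV file
#'
#' Inverse of [read_lexicon()]: writing then reading reproduces the lexicon
#' field for field.
#'
#' @param lexicon A lexicon tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  lexicon <- validate_lexicon(lexicon)
  out <- tibble::as_tibble(lexicon)
  out$prototypical <- as.integer(out$prototypical)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# Deterministic pseudo-word from a positive index: CV syllables in mixed radix.
pseudo_word <- function(i) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t")
  vow <- c("a", "e", "i", "o", "u")
  i <- i - 1
  s1 <- paste0(cons[(i %% 12) + 1], vow[((i %/% 12) %% 5) + 1])
  j <- i %/% 60
  s2 <- paste0(cons[(j %% 12) + 1], vow[((j %/% 12) %% 5) + 1])
  k <- j %/% 60
  tail <- if (k > 0) paste0(cons[((k - 1) %% 12) + 1], "o") else ""
  paste0(s1, s2, tail)
}

#' Synthesize a lexicon
#'
#' Builds a deterministic synthetic word pool for testing and simulation:
#' `n_categories` semantic categories of `words_per_category` pseudo-words
#' each, with Zipf-like relative frequencies assigned per category
#' (`frequency = freq_scale * rank^-freq_exponent` over a seeded
#' within-category rank permutation, times a small lognormal jitter,
#' clipped into (0,1)) so that every category spans the same frequency
#' decades and frequency-matched selection is feasible for any category
#' choice, the top `ceiling(prototype_fraction * words_per_category)` words
#' of each category flagged prototypical, and short synthetic phonetic keys shared
#' by small cross-category word groups so that every word has at least one
#' phonetically related neighbour in a different category while plenty of
#' words remain phonetically unrelated to any given list.
#'
#' @param n_categories Number of semantic categories (>= 1).
#' @param words_per_category Words per category (>= 1).
#' @param freq_exponent Zipf exponent of the per-category frequency law.
#' @param freq_scale Scale of the frequency law (frequency of rank 1).
#' @param freq_jitter Lognormal sigma of the per-word frequency jitter.
#' @param prototype_fraction Proportion of each category flagged prototypical.
#' @param seed Integer seed; output is bitwise-reproducible per seed.
#' @return A validated lexicon tibble.
#' @export
#' @examples
#' lex <- synth_lexicon(8, 12, seed = 7)
#' nrow(lex)          # 96
#' dplyr::count(lex, category)
synth_lexicon <- function(n_categories, words_per_category,
                          freq_exponent = 1.3, freq_scale = 0.0015,
                          freq_jitter = 0.15, prototype_fraction = 0.375,
                          seed = 1L) {
  seed <- check_seed(seed)
  if (n_categories < 1 || words_per_category < 1) {
    abort_argument("`n_categories` and `words_per_category` must be >= 1.")
  }
  base_categories <- c(
    "urban furniture", "vehicles", "professions", "shops", "buildings",
    "tools", "fruits", "herbs", "animals", "clothing", "instruments",
    "flowers", "fishes", "cooking utensils", "furniture", "beverages"
  )
  categories <- if (n_categories <= length(base_categories)) {
    base_categories[seq_len(n_categories)]
  } else {
    c(base_categories,
      paste0("category ", seq_len(n_categories - length(base_categories))))
  }
  n <- n_categories * words_per_category
  tbl <- tibble::tibble(
    word = vapply(seq_len(n), pseudo_word, character(1)),
    category = rep(categories, each = words_per_category)
  )
  with_seed(seed, {
    ranks <- as.vector(vapply(seq_len(n_categories),
                              function(i) sample.int(words_per_category),
                              integer(words_per_category)))
    jitter <- exp(stats::rnorm(n, 0, freq_jitter))
    tbl$frequency <- pmin(freq_scale * ranks^(-freq_exponent) * jitter,
                          1 - 1e-12)
  })
  n_proto <- ceiling(prototype_fraction * words_per_category)
  tbl <- tbl |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(prototypical = rank(-.data$frequency, ties.method = "first") <= n_proto) |>
    dplyr::ungroup()
  # Phonetic keys: walk words round-robin across categories and give each
  # consecutive group of three one consonant-skeleton key; the trailing
  # remainder (< 3 words) is merged into the final group. With >= 3
  # categories each group spans distinct categories, so every word has a
  # cross-category key neighbour.
  ord <- order(rep(seq_len(words_per_category), times = n_categories) * n_categories +
                 rep(seq_len(n_categories) - 1L, each = words_per_category))
  grp <- ceiling(seq_len(n) / 3)
  if (n %% 3 != 0 && n > 3) grp[grp == max(grp)] <- max(grp) - 1L
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t")
  key_of <- function(g) {
    paste0(cons[(g %% 12) + 1], cons[((g %/% 12) %% 12) + 1],
           cons[((g %/% 144) %% 12) + 1])
  }
  keys <- toupper(vapply(grp, key_of, character(1)))
  tbl$phonetic_key <- NA_character_
  tbl$phonetic_key[ord] <- keys
  validate_lexicon(tbl)
}

#' Mean relative frequency of a set of words
#'
#' The arithmetic mean of the `frequency` column; the quantity matched when
#' generating lists with the same average usage frequency as a reference
#' list.
#'
#' @param words A data frame of lexicon entries (needs a `frequency`
#'   column), or a numeric vector of frequencies.
#' @return A single numeric mean frequency.
#' @export
mean_frequency <- function(words) {
  f <- if (is.data.frame(words)) words$frequency else words
  if (is.null(f) || length(f) == 0) {
    abort_argument("Cannot take the mean frequency of an empty word set.")
  }
  mean(as.numeric(f))
}
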