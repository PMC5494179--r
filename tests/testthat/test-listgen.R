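# Small lexicon with every frequency equal: any selection hits the target.
flat_lexicon <- function(freq = 0.0003, n_cat = 6, wpc = 8) {
  validate_lexicon(tibble::tibble(
    word = paste0("w", seq_len(n_cat * wpc)),
    category = rep(paste0("cat", seq_len(n_cat)), each = wpc),
    frequency = freq))
}

test_that("generated lists satisfy the structural invariants", {
  s <- fixture_session()
  expect_length(validate_stimulus_list(s$A, tolerance = 0.15), 0)
  expect_length(validate_stimulus_list(s$B, tolerance = 0.15), 0)
  shared <- intersect(attr(s$A, "list_categories"), attr(s$B, "list_categories"))
  expect_length(shared, 2)
  expect_length(intersect(s$A$word, s$B$word), 0)
})

test_that("an all-equal-frequency lexicon matches its target exactly", {
  pair <- generate_list_pair(flat_lexicon(), target_freq_A = 0.0003,
                             target_freq_B = 0.0003, tolerance = 0,
                             seed = 2)
  expect_equal(attr(pair$A, "achieved_frequency"), 0.0003)
  expect_equal(attr(pair$B, "achieved_frequency"), 0.0003)
})

test_that("unreachable targets raise an infeasibility error with the best deviation", {
  err <- expect_error(
    generate_list_pair(flat_lexicon(freq = 0.0003), target_freq_A = 0.9,
                       tolerance = 0.01, seed = 1),
    class = "ll_error_infeasible")
  expect_true(is.numeric(err$best_deviation))
  expect_gt(err$best_deviation, 0.01)
})

test_that("the selected frequency match is optimal on small pools", {
  # exhaustive oracle over one list: enumerate all 4-of-5 subsets per
  # category and find the minimal achievable deviation
  set.seed(41)
  lex <- validate_lexicon(tibble::tibble(
    word = paste0("w", 1:48),
    category = rep(paste0("c", 1:6), each = 8),
    frequency = round(stats::runif(48, 1e-4, 9e-4), 6)))
  target <- 0.0004
  pair <- generate_list_pair(lex, target_freq_A = target,
                             target_freq_B = 0.0005, tolerance = 1,
                             seed = 9)
  cats_A <- attr(pair$A, "list_categories")
  per_cat_sums <- lapply(cats_A, function(ct) {
    f <- lex$frequency[lex$category == ct]
    colSums(utils::combn(f, 4))
  })
  grid <- expand.grid(per_cat_sums)
  best_oracle <- min(abs(rowSums(grid) / 16 - target))
  expect_equal(abs(attr(pair$A, "achieved_frequency") - target),
               best_oracle, tolerance = 1e-12)
})

test_that("presentation orders avoid same-category adjacency", {
  for (seed in 1:20) {
    items <- tibble::tibble(
      word = paste0("w", 1:16),
      category = rep(letters[1:4], each = 4))[sample.int(16), ]
    ord <- arrange_presentation_order(items, seed = seed)
    # independent adjacency check
    expect_false(any(ord$category[-1] == ord$category[-16]))
    expect_setequal(ord$word, items$word)
  }
})

test_that("impossible compositions raise an arrangement error", {
  items <- tibble::tibble(word = paste0("w", 1:16),
                          category = c(rep("a", 9), rep("b", 7)))
  expect_error(arrange_presentation_order(items, seed = 1),
               class = "ll_error_arrangement")
  one <- tibble::tibble(word = "w1", category = "a")
  expect_equal(arrange_presentation_order(one, seed = 1)$word, "w1")
})

test_that("regeneration is deterministic per seed and fresh across seeds", {
  lex <- synth_lexicon(10, 16, seed = 3)
  p1 <- generate_list_pair(lex, seed = 5)
  p2 <- generate_list_pair(lex, seed = 5)
  expect_identical(p1$A$word, p2$A$word)
  expect_identical(p1$B$word, p2$B$word)
  differs <- vapply(1:20, function(k) {
    q <- generate_list_pair(lex, seed = 100 + k)
    !identical(sort(q$A$word), sort(p1$A$word))
  }, logical(1))
  expect_true(all(differs))
})

test_that("the recognition list has the canonical 44-item composition", {
  s <- fixture_session()
  C <- s$C
  expect_length(validate_recognition_list(C, s$A, s$B), 0)
  counts <- table(C$item_type)
  expect_equal(counts[["target_A"]], 16)
  expect_equal(counts[["shared_B"]] + counts[["nonshared_B"]], 8)
  expect_equal(counts[["prototype_A"]], 4)
  expect_equal(counts[["phonetic_A"]], 8)
  expect_equal(counts[["unrelated"]], 8)
  # every A word present and keyed "yes"
  expect_setequal(C$word[C$correct_answer], s$A$word)
  # shared_B: 2 per shared category
  shared <- intersect(attr(s$A, "list_categories"),
                      attr(s$B, "list_categories"))
  sb <- table(C$category[C$item_type == "shared_B"])
  expect_setequal(names(sb), shared)
  expect_true(all(sb == 2))
  # phonetic and unrelated distractors never overlap the learning lists
  distract <- C$word[C$item_type %in% c("phonetic_A", "unrelated", "prototype_A")]
  expect_length(intersect(distract, c(s$A$word, s$B$word)), 0)
  # unrelated items share no phonetic key with any A word
  lex <- s$lexicon
  a_keys <- lex$phonetic_key[match(s$A$word, lex$word)]
  un_keys <- lex$phonetic_key[match(C$word[C$item_type == "unrelated"], lex$word)]
  expect_length(intersect(un_keys, a_keys), 0)
})

test_that("deficient candidate pools raise capacity errors naming the pool", {
  lex <- synth_lexicon(10, 16, seed = 11)
  lex$prototypical <- FALSE
  pair <- generate_list_pair(lex, seed = 11)
  expect_error(build_recognition_list(pair$A, pair$B, lex, seed = 1),
               "prototype_A", class = "ll_error_capacity")
})

test_that("the category correspondence is the fixed published constant", {
  m <- cvlt_category_map()
  expect_equal(m$to[m$list == "A" & m$from == "tools"], "vehicles")
  expect_equal(m$to[m$list == "A" & m$from == "herbs"], "shops")
  expect_equal(m$to[m$list == "B" & m$from == "fishes"], "urban furniture")
  expect_equal(m$to[m$list == "B" & m$from == "cooking utensils"], "vehicles")
  rev <- cvlt_category_map("game_to_cvlt")
  expect_equal(rev$to[rev$list == "A" & rev$from == "vehicles"], "tools")
  # unmapped category: no row
  expect_length(m$to[m$list == "A" & m$from == "fishes"], 0)
  expect_error(cvlt_category_map("sideways"), class = "ll_error_argument")
})
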