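test_that("recall phases are scored by the standard counting rules", {
  s <- fixture_session()
  log <- fixture_perfect_log()
  tr <- trial_recall(log, 1)
  expect_equal(tr$correct, 16)
  expect_equal(tr$intrusions, 0)
  expect_equal(tr$perseverations, 0)
  expect_equal(tr$recall_sequence, s$A$word)

  # [a, a, x]: one correct, one perseveration, one intrusion
  a <- s$A$word[1]
  log2 <- administer(default_schedule(), s$lists,
                     scripted_responder(c(a, a, "notaword")), seed = 1)
  tr2 <- trial_recall(log2, 1)
  expect_equal(tr2$correct, 1)
  expect_equal(tr2$perseverations, 1)
  expect_equal(tr2$intrusions, 1)

  mute <- administer(default_schedule(), s$lists, mute_responder, seed = 1)
  tr3 <- trial_recall(mute, 1)
  expect_equal(unlist(tr3[c("correct", "intrusions", "perseverations")]),
               c(correct = 0, intrusions = 0, perseverations = 0))
  expect_error(trial_recall(log, which(log$schedule$phase_kind == "break")),
               class = "ll_error_argument")
})

test_that("the learning slope is the OLS slope over trials", {
  expect_equal(learning_slope(c(5, 7, 9)), 2)
  expect_equal(learning_slope(c(6, 6, 6)), 0)
  expect_equal(learning_slope(c(4, 8, 6)), 1)
})

test_that("semantic clustering matches its closed-form chance expectation", {
  cat_of <- c(w1 = "A", w2 = "A", w3 = "B", w4 = "B")
  blocked <- semantic_clustering(c("w1", "w2", "w3", "w4"), cat_of)
  expect_equal(blocked$observed, 2)
  expect_equal(blocked$expected, 1)
  expect_equal(blocked$index, 1)
  alternating <- semantic_clustering(c("w1", "w3", "w2", "w4"), cat_of)
  expect_equal(alternating$observed, 0)
  expect_equal(alternating$index, -1)
  expect_equal(semantic_clustering("w1", cat_of),
               list(observed = 0, expected = 0, index = 0))
  expect_error(semantic_clustering(c("w1", "zz"), cat_of),
               class = "ll_error_data")
})

test_that("semantic expectation equals exhaustive permutation enumeration", {
  set.seed(99)
  for (rep in 1:8) {
    r <- sample(2:6, 1)
    cats <- sample(letters[1:3], r, replace = TRUE)
    words <- paste0("w", seq_len(r))
    cat_of <- stats::setNames(cats, words)
    got <- semantic_clustering(words, cat_of)$expected
    oracle <- mean(vapply(oracle_perms(seq_len(r)), function(p) {
      cc <- cats[p]
      sum(cc[-1] == cc[-r])
    }, numeric(1)))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("serial clustering counts forward transitions against chance", {
  pos <- stats::setNames(1:4, paste0("w", 1:4))
  expect_equal(serial_clustering(paste0("w", 1:4), pos)$observed, 3)
  expect_equal(serial_clustering(paste0("w", 4:1), pos)$observed, 0)
  r3 <- serial_clustering(paste0("w", 1:3), stats::setNames(1:3, paste0("w", 1:3)))
  expect_equal(r3$expected, 4 / 6, tolerance = 1e-12)
  # exhaustive baseline agrees with an independent enumeration for r = 5
  pos5 <- stats::setNames(c(2, 5, 9, 10, 14), paste0("w", 1:5))
  got <- serial_clustering(paste0("w", 1:5), pos5)$expected
  oracle <- mean(vapply(oracle_perms(unname(pos5)), function(p) {
    sum(p[-1] == p[-5] + 1)
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-12)
  # Monte Carlo path stays within 3 standard errors of the closed form:
  # for distinct positions the expectation is (# consecutive pairs) / r
  pos9 <- stats::setNames(c(1:5, 8, 11, 12, 16), paste0("w", 1:9))
  mc <- serial_clustering(paste0("w", 1:9), pos9, seed = 4)$expected
  closed <- 5 / 9  # 5 consecutive position pairs present, r = 9
  se <- sqrt(closed / 10000)  # loose Poisson-style bound
  expect_lt(abs(mc - closed), 3 * max(se, 0.02))
})

test_that("serial-position percentages follow the 4/8/4 regions", {
  early <- primacy_recency(c(1, 2, 3, 4, 2))
  expect_equal(early$primacy_pct, 100)
  expect_equal(early$recency_pct, 0)
  spread <- primacy_recency(c(2, 8, 15))
  expect_equal(spread$primacy_pct, 100 / 3, tolerance = 1e-9)
  expect_equal(spread$middle_pct + spread$primacy_pct + spread$recency_pct, 100)
  none <- primacy_recency(integer())
  expect_true(none$degenerate)
  expect_true(is.na(none$primacy_pct))
})

test_that("interference scores are the difference forms", {
  expect_equal(interference_scores(a1 = 6, b1 = 4, a3 = 9, sdfr = 9)$proactive, -2)
  expect_equal(interference_scores(a1 = 6, b1 = 4, a3 = 9, sdfr = 9)$retroactive, 0)
  expect_equal(interference_scores(0, 0, 0, 0)$proactive, 0)
})

test_that("recognition scoring handles perfect, yea-saying and nay-saying", {
  s <- fixture_session()
  perfect <- recognition_scores(fixture_perfect_log())
  expect_equal(perfect$hits, 16)
  expect_equal(perfect$fp_total, 0)
  expect_equal(perfect$discriminability_pct, 100)

  yes_all <- function(phase, target, cues) {
    if (phase$phase_kind == "break") return(NULL)
    if (phase$phase_kind == "recognition") {
      return(tibble::tibble(word = target$word, answer = TRUE, latency = 1))
    }
    NULL
  }
  ry <- recognition_scores(administer(default_schedule(), s$lists, yes_all,
                                      seed = 1))
  expect_equal(ry$hits, 16)
  expect_equal(ry$fp_total, 28)
  expect_equal(ry$discriminability_pct, (1 - 28 / 44) * 100, tolerance = 1e-9)

  rn <- recognition_scores(administer(default_schedule(), s$lists,
                                      mute_responder, seed = 1))
  expect_equal(rn$hits, 0)
  expect_equal(rn$misses, 16)
  expect_equal(rn$discriminability_pct, (1 - 16 / 44) * 100, tolerance = 1e-9)
  # d-prime finite at floor/ceiling thanks to the log-linear correction
  expect_true(is.finite(perfect$d_prime) && is.finite(rn$d_prime))
})

test_that("the full battery composes correctly for perfect and mute subjects", {
  bat <- compute_battery(fixture_perfect_log())
  expect_equal(bat$total_A, 48)
  expect_equal(bat$discriminability_pct, 100)
  expect_equal(bat$a1 + bat$omissions_a1, 16)
  expect_equal(bat$proactive_interference, bat$b1 - bat$a1)
  expect_equal(bat$retroactive_interference, bat$sdfr - bat$a3)
  expect_equal(bat$primacy_pct + bat$middle_pct + bat$recency_pct, 100,
               tolerance = 0.01)

  mute <- administer(default_schedule(), fixture_session()$lists,
                     mute_responder, seed = 3)
  bm <- compute_battery(mute)
  expect_equal(bm$total_A, 0)
  expect_equal(bm$omissions_a1, 16)
  expect_true(bm$serial_position_degenerate)
  # identical schema across very different subjects
  expect_identical(names(bat), names(bm))
})

test_that("scoring is a pure function of the log", {
  log <- fixture_perfect_log()
  expect_identical(compute_battery(log), compute_battery(log))
  co <- fixture_pilot_cohort()
  expect_identical(compute_battery(co$logs[[1]]), compute_battery(co$logs[[1]]))
})

test_that("an added correct response never lowers the phase count", {
  s <- fixture_session()
  half <- s$A$word[seq(1, 16, by = 2)]
  base <- administer(default_schedule(), s$lists, scripted_responder(half),
                     seed = 1)
  more <- administer(default_schedule(), s$lists,
                     scripted_responder(c(half, s$A$word[2])), seed = 1)
  b0 <- compute_battery(base)
  b1 <- compute_battery(more)
  expect_gte(b1$a1, b0$a1)
  expect_equal(b1$recog_hits, b0$recog_hits)
})
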