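test_that("confusion-table metrics follow the ratio definitions", {
  m <- metrics_from_confusion(8, 2, 4, 2)
  expect_equal(m$precision, 0.8)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 4 / 6, tolerance = 1e-9)
  expect_equal(m$f1, 0.8)
  expect_false(m$degenerate)

  perfect <- metrics_from_confusion(5, 0, 7, 0)
  expect_equal(unlist(perfect[1:4]), c(precision = 1, f1 = 1,
                                       sensitivity = 1, specificity = 1))
  degen <- metrics_from_confusion(0, 0, 3, 2)
  expect_equal(degen$precision, 0)
  expect_true(degen$degenerate)
  expect_error(metrics_from_confusion(-1, 0, 0, 0),
               class = "ll_error_argument")
})

test_that("macro averaging is one-vs-rest and order-invariant", {
  truth <- c(rep("HC", 8), rep("MCI", 3), rep("AD", 5))
  ident <- macro_metrics(truth, truth)
  expect_equal(unlist(ident), c(precision = 1, f1 = 1, sensitivity = 1,
                                specificity = 1))
  majority <- macro_metrics(truth, rep("HC", 16))
  expect_equal(majority$sensitivity, 1 / 3, tolerance = 1e-9)
  perm <- sample(16)
  shuffled <- macro_metrics(truth[perm], rep("HC", 16)[perm])
  expect_equal(shuffled, majority, ignore_attr = TRUE)
  expect_error(macro_metrics(truth, c(rep("HC", 15), "XX")),
               class = "ll_error_argument")
})

test_that("feature assembly is deterministic and toggles the aux block", {
  co <- fixture_pilot_cohort()
  f1 <- build_features(co, include_aux = TRUE)
  f2 <- build_features(co, include_aux = TRUE)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 16)
  f0 <- build_features(co, include_aux = FALSE)
  expect_equal(ncol(f1) - ncol(f0), 12)
  # latent generator parameters must not leak into the features
  expect_false(any(c("p_base", "aux_ability", "recog_hit") %in% names(f1)))
  unscored <- simulate_cohort(composition = c(HC = 1, AD = 1), seed = 1)
  expect_error(build_features(unscored), class = "ll_error_state")
})

test_that("separable synthetic clusters are classified perfectly", {
  f <- synthetic_features()
  for (fam in c("linear", "forest", "svm")) {
    rep <- loocv(f, fam, seed = 1)
    expect_equal(rep$metrics$precision, 1)
    expect_equal(nrow(rep$predictions), nrow(f))
  }
  hold <- repeated_holdout(f, "linear", test_fraction = 0.2, n_reps = 5,
                           seed = 1)
  expect_equal(hold$metrics$precision, 1)
  expect_equal(hold$scheme$n_reps, 5)
})

test_that("constant features collapse predictions to one class", {
  f <- synthetic_features()
  f$f1 <- 1; f$f2 <- 1; f$f3 <- 1; f$f4 <- 1
  rep <- loocv(f, "forest", seed = 1)
  expect_equal(nrow(rep$predictions), nrow(f))
  expect_lte(length(unique(rep$predictions$predicted)), 2)
  expect_lt(rep$metrics$precision, 1)
})

test_that("label-permuted data scores at chance level", {
  f <- synthetic_features(n_per = 10)
  f$group <- withr::with_seed(33, sample(f$group))
  rep <- repeated_holdout(f, "linear", test_fraction = 0.2, n_reps = 20,
                          seed = 3)
  expect_gt(rep$metrics$sensitivity, 0.13)
  expect_lt(rep$metrics$sensitivity, 0.53)
  lo <- loocv(f, "linear", seed = 3)
  expect_lt(lo$metrics$precision, 0.6)
})

test_that("informative-variable selection finds a planted label feature", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      g <- rep(c("HC", "MCI", "AD"), each = 6)
      f <- tibble::tibble(
        subject_id = as.character(seq_along(g)), group = g,
        signal = as.numeric(factor(g)) + stats::rnorm(18, 0, 0.01),
        n1 = stats::rnorm(18), n2 = stats::rnorm(18), n3 = stats::rnorm(18),
        n4 = stats::rnorm(18), n5 = stats::rnorm(18))
      f <- structure(f, class = c("ll_features", class(tibble::tibble())))
      select_informative(f, fraction = 0.2, seed = s)[1] == "signal"
    })
  }, logical(1))
  expect_gte(sum(hits), 9)

  f <- synthetic_features()
  expect_setequal(select_informative(f, fraction = 1, seed = 1),
                  c("f1", "f2", "f3", "f4"))
  expect_identical(select_informative(f, 0.5, seed = 2),
                   select_informative(f, 0.5, seed = 2))
})

test_that("correlation matrices behave at the edges", {
  x <- tibble::tibble(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))
  r <- correlation_matrix(x)
  expect_equal(r["a", "a"], 1)
  expect_equal(r["a", "b"], -1)
  # cells below the pair minimum are flagged absent
  x2 <- tibble::tibble(a = c(1, 2, NA, NA), b = c(1, NA, 2, NA))
  r2 <- correlation_matrix(x2, min_pairs = 3)
  expect_true(is.na(r2["a", "b"]))
  # independent noise stays near zero at large n
  withr::with_seed(10, {
    big <- tibble::tibble(u = rnorm(1000), v = rnorm(1000))
    expect_lt(abs(correlation_matrix(big)["u", "v"]), 0.1)
  })
})

test_that("paired pre/post reproduces the rate-of-increase arithmetic", {
  r <- paired_pre_post(c(1, 1, 1, 2), c(3, 3, 3, 4))
  expect_equal(r$median_pre, 1)
  expect_equal(r$median_post, 3)
  expect_equal(r$rate_increase_pct, 40)
  r2 <- paired_pre_post(c(3, 3, 3, 3), c(3, 3, 4, 4))
  expect_equal(r2$median_post, 3.5)
  expect_equal(r2$rate_increase_pct, 10)
  same <- paired_pre_post(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$rate_increase_pct, 0)
  expect_equal(same$t_statistic, 0)
  expect_error(paired_pre_post(1:3, 1:4), class = "ll_error_argument")
})

test_that("reports expose tidy and glance views", {
  f <- synthetic_features()
  rep <- loocv(f, "linear", seed = 1)
  td <- tidy(rep)
  expect_equal(nrow(td), 3)
  expect_true(all(c("class", "precision") %in% names(td)))
  gl <- glance(rep)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$scheme, "loocv")
  tf <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, tf)
  parsed <- jsonlite::fromJSON(tf)
  expect_equal(parsed$model, "linear")
  expect_equal(nrow(parsed$predictions), nrow(f))
})
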