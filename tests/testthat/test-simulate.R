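test_that("subject sampling is deterministic, clipped and centred", {
  hc <- group_presets()$HC
  p1 <- sample_subject(hc, seed = 5)
  p2 <- sample_subject(hc, seed = 5)
  expect_identical(p1, p2)

  draws <- lapply(1:200, function(s) sample_subject(hc, seed = s))
  probs <- vapply(draws, function(p) {
    unlist(p[c("p_base", "retention", "recog_hit", "cluster_tendency",
               "fa_unrelated")])
  }, numeric(5))
  expect_true(all(probs >= 0 & probs <= 1))
  expect_true(all(vapply(draws, function(p) p$intrusion_rate, numeric(1)) >= 0))
  # sample mean of p_base within 3 standard errors of the preset mean
  pb <- vapply(draws, function(p) p$p_base, numeric(1))
  se <- hc$sds[["p_base"]] / sqrt(length(pb))
  expect_lt(abs(mean(pb) - hc$means[["p_base"]]), 3 * se)
  # ordinal demographics stay on the 1..5 scale
  demo <- vapply(draws, function(p) p$demographics[["ict_use"]], numeric(1))
  expect_true(all(demo >= 1 & demo <= 5))
})

test_that("default presets keep the clinically ordered false-alarm profile", {
  for (pr in group_presets()) {
    m <- pr$means
    expect_true(m[["fa_shared_B"]] >= m[["fa_prototype_A"]] &&
                  m[["fa_prototype_A"]] >= m[["fa_phonetic_A"]] &&
                  m[["fa_phonetic_A"]] >= m[["fa_unrelated"]])
  }
  # expected recall ordering of the preset means
  m <- vapply(group_presets(), function(p) p$means[["p_base"]], numeric(1))
  expect_true(m[["HC"]] > m[["MCI"]] && m[["MCI"]] > m[["AD"]])
})

test_that("saturated and floored parameters produce perfect and null recall", {
  s <- fixture_session()
  base <- sample_subject(group_presets()$HC, seed = 1)
  sat <- base
  sat$p_base <- 1; sat$learn_rate <- 0; sat$retention <- 1
  sat$cue_boost <- 0; sat$primacy_boost <- 0; sat$recency_boost <- 0
  sat$intrusion_rate <- 0; sat$persev_prob <- 0; sat$recog_hit <- 1
  sat[paste0("fa_", c("shared_B", "nonshared_B", "prototype_A", "phonetic_A",
                      "unrelated"))] <- 0
  log <- administer(default_schedule(), s$lists,
                    behavioral_responder(sat, s$lists, seed = 2), seed = 2)
  bat <- compute_battery(log)
  expect_equal(bat$total_A, 48)
  expect_equal(bat$sdfr, 16)
  expect_equal(bat$ldcr, 16)
  expect_equal(bat$discriminability_pct, 100)

  nil <- sat
  nil$p_base <- 0; nil$primacy_boost <- 0; nil$recency_boost <- 0
  nil$cue_boost <- 0
  log0 <- administer(default_schedule(), s$lists,
                     behavioral_responder(nil, s$lists, seed = 2), seed = 2)
  bat0 <- compute_battery(log0)
  expect_equal(bat0$total_A, 0)
  expect_equal(bat0$sdcr, 0)
})

test_that("clustering tendency raises the semantic clustering index", {
  s <- fixture_session()
  base <- sample_subject(group_presets()$HC, seed = 1)
  base$intrusion_rate <- 0; base$persev_prob <- 0; base$p_base <- 0.6
  idx_for <- function(kappa, seeds) {
    vapply(seeds, function(sd) {
      p <- base; p$cluster_tendency <- kappa
      log <- administer(default_schedule(), s$lists,
                        behavioral_responder(p, s$lists, seed = sd), seed = sd)
      compute_battery(log)$sem_idx_a1
    }, numeric(1))
  }
  hi <- idx_for(1, 1:40)
  lo <- idx_for(0, 1:40)
  expect_gt(mean(hi), mean(lo))
})

test_that("cohorts are reproducible and match their composition", {
  co <- fixture_pilot_cohort()
  expect_equal(nrow(co$subjects), 16)
  expect_length(co$logs, 16)
  expect_equal(as.integer(table(co$subjects$group)[c("HC", "MCI", "AD")]),
               c(8L, 3L, 5L))
  co2 <- simulate_cohort(seed = 42)
  expect_identical(co2$subjects, fixture_pilot_cohort()$subjects[names(co2$subjects)])
  expect_error(simulate_cohort(composition = c(HC = 0, MCI = 0, AD = 0)),
               class = "ll_error_argument")
})

test_that("group recall ordering and delay/cue effects hold in expectation", {
  co <- fixture_balanced_cohort()
  df <- dplyr::bind_cols(co$subjects["group"], co$batteries)
  means <- df |>
    dplyr::group_by(group) |>
    dplyr::summarise(total_A = mean(total_A),
                     disc = mean(discriminability_pct),
                     sdfr = mean(sdfr), ldfr = mean(ldfr), sdcr = mean(sdcr))
  m <- function(g, v) means[[v]][means$group == g]
  expect_true(m("HC", "total_A") > m("MCI", "total_A"))
  expect_true(m("MCI", "total_A") > m("AD", "total_A"))
  expect_gt(m("HC", "disc"), m("AD", "disc"))
  # retention < 1: long delay does not beat short delay on average
  expect_lte(mean(df$ldfr), mean(df$sdfr))
  # cue benefit: cued short-delay recall at least matches free recall
  expect_gte(mean(df$sdcr), mean(df$sdfr))
})

test_that("scored recall recovers the generating ability parameter", {
  co <- fixture_balanced_cohort()
  fit <- stats::lm(co$batteries$total_A ~ co$subjects$p_base)
  sm <- summary(fit)
  expect_gt(stats::coef(fit)[2], 0)
  expect_lt(sm$coefficients[2, 4], 0.01)
})

test_that("cohorts serialize to a manifest directory", {
  co <- fixture_pilot_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort_manifest.csv")))
  expect_true(file.exists(file.path(dir, "batteries.csv")))
  expect_length(list.files(dir, pattern = "^log_.*jsonl$"), 16)
})
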