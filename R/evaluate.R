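#' Psychometric validation pipeline
#'
#' Feature assembly from scored cohorts, diagnostic classification under
#' repeated stratified holdout and leave-one-out cross-validation with
#' three model families (regularized linear, randomized-tree ensemble,
#' maximum-margin), random-forest informative-variable selection,
#' macro-averaged quality metrics (precision, F1, sensitivity,
#' specificity), a correlation study, and paired pre/post comparison of
#' ordinal questionnaire scores.
#'
#' @name evaluate
#' @keywords internal
NULL

MODEL_FAMILIES <- c("linear", "forest", "svm")

#' Assemble the feature matrix for classification
#'
#' Flattens each subject's score battery and demographics — and, when
#' `include_aux` is on, the auxiliary break-game feature block — into one
#' row per subject with a deterministic column order. Degenerate-flagged
#' battery values are explicit `NA`s.
#'
#' @param cohort A scored `ll_cohort` (see [score_cohort()]).
#' @param include_aux Include the auxiliary feature block?
#' @return An `ll_features` tibble with `subject_id`, `group` (the label)
#'   and numeric feature columns.
#' @export
build_features <- function(cohort, include_aux = TRUE) {
  if (is.null(cohort$batteries)) {
    abort_state("Cohort is not scored; run score_cohort() first.")
  }
  demo_cols <- c("age", "education", "ict_use", "game_use", "socialization",
                 "exercise")
  aux_cols <- grep("^aux_[0-9]+$", names(cohort$subjects), value = TRUE)
  base <- dplyr::select(cohort$subjects, "subject_id", "group",
                        dplyr::all_of(demo_cols))
  if (include_aux) {
    base <- dplyr::bind_cols(base,
                             dplyr::select(cohort$subjects,
                                           dplyr::all_of(aux_cols)))
  }
  bat <- dplyr::select(cohort$batteries, -dplyr::any_of("subject_id"))
  bat <- dplyr::mutate(bat, dplyr::across(dplyr::where(is.logical), as.numeric))
  out <- dplyr::bind_cols(base, bat)
  structure(out, class = c("ll_features", class(tibble::tibble())))
}

feature_columns <- function(features) {
  setdiff(names(features), c("subject_id", "group"))
}

# Numeric model matrix with median imputation of missing (degenerate) cells
# and zero-variance guard handled by the individual fitters.
feature_matrix <- function(features, cols = feature_columns(features)) {
  x <- as.matrix(dplyr::select(tibble::as_tibble(features),
                               dplyr::all_of(cols)))
  storage.mode(x) <- "double"
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) {
      med <- stats::median(x[!nas, j])
      x[nas, j] <- if (is.na(med)) 0 else med
    }
  }
  x
}

#' Quality metrics from a binary confusion table
#'
#' The four standard ratios: precision `TP/(TP+FP)`, sensitivity (recall)
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, and F1 `2PR/(P+R)`. A zero
#' denominator yields 0 with the `degenerate` flag set — tiny-fold
#' cross-validation hits these cells routinely.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return A one-row tibble: `precision`, `f1`, `sensitivity`,
#'   `specificity`, `degenerate`.
#' @export
#' @examples
#' metrics_from_confusion(8, 2, 4, 2)
metrics_from_confusion <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0)) abort_argument("Counts must be non-negative.")
  ratio <- function(num, den) if (den == 0) c(0, TRUE) else c(num / den, FALSE)
  p <- ratio(tp, tp + fp)
  r <- ratio(tp, tp + fn)
  s <- ratio(tn, tn + fp)
  f1 <- if (p[1] + r[1] == 0) c(0, TRUE) else c(2 * p[1] * r[1] / (p[1] + r[1]), FALSE)
  degen <- any(c(p[2], r[2], s[2], f1[2]) > 0)
  tibble::tibble(precision = p[1], f1 = f1[1], sensitivity = r[1],
                 specificity = s[1], degenerate = degen)
}

#' Macro-averaged metrics over classes
#'
#' Builds a one-vs-rest confusion table per class, computes
#' [metrics_from_confusion()] for each, and averages unweighted across
#' classes.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param classes The class set (defaults to the classes present in
#'   `truth`).
#' @return A one-row tibble of macro `precision`, `f1`, `sensitivity`,
#'   `specificity` plus the per-class table in the `per_class` attribute.
#' @export
macro_metrics <- function(truth, predicted, classes = sort(unique(truth))) {
  if (length(truth) != length(predicted)) {
    abort_argument("`truth` and `predicted` must have equal length.")
  }
  if (any(!predicted %in% classes)) {
    abort_argument("`predicted` contains classes outside `classes`.")
  }
  per_class <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    tn <- sum(truth != cl & predicted != cl)
    dplyr::bind_cols(tibble::tibble(class = cl),
                     metrics_from_confusion(tp, fp, tn, fn))
  })
  out <- tibble::tibble(
    precision = mean(per_class$precision),
    f1 = mean(per_class$f1),
    sensitivity = mean(per_class$sensitivity),
    specificity = mean(per_class$specificity))
  attr(out, "per_class") <- per_class
  out
}

fit_predict <- function(family, x_train, y_train, x_test, seed = 1L) {
  y_train <- factor(y_train)
  keep <- which(apply(x_train, 2, function(col) stats::sd(col) > 0))
  if (length(keep) == 0) {
    # no informative columns: predict the training majority class
    maj <- names(which.max(table(y_train)))
    return(rep(maj, nrow(x_test)))
  }
  x_train <- x_train[, keep, drop = FALSE]
  x_test <- x_test[, keep, drop = FALSE]
  # class-balanced observation weights: at pilot scale (e.g. 8/3/5) the
  # minority class is otherwise squeezed out of the decision rule
  w <- 1 / table(y_train)[y_train]
  w <- as.numeric(w * length(w) / sum(w))
  if (family == "linear") {
    if (ncol(x_train) == 1) {
      x_train <- cbind(x_train, jitter_col = 0)
      x_test <- cbind(x_test, jitter_col = 0)
    }
    # pairwise (one-vs-one) voting over binary ridge fits: with ordered
    # diagnostic groups the middle class is not one-vs-rest separable by a
    # single linear score, while every pairwise boundary is linear
    classes <- levels(y_train)
    pairs <- utils::combn(classes, 2, simplify = FALSE)
    votes <- matrix(0, nrow(x_test), length(classes),
                    dimnames = list(NULL, classes))
    prob_sum <- votes
    for (pr in pairs) {
      in_pair <- which(y_train %in% pr)
      # glmnet needs >= 2 rows per class: represent a singleton class by a
      # duplicated row with split weight (identical ridge likelihood)
      singleton <- pr[table(factor(y_train[in_pair], levels = pr)) == 1]
      for (cl in singleton) {
        in_pair <- c(in_pair, in_pair[y_train[in_pair] == cl])
      }
      yp <- factor(as.character(y_train[in_pair]), levels = pr)
      wp <- 1 / table(yp)[yp]
      wp <- as.numeric(wp * length(wp) / sum(wp))
      # suppressed warning: glmnet flags any class below 8 observations,
      # which is the normal regime at pilot cohort sizes
      fit <- suppressWarnings(
        glmnet::glmnet(x_train[in_pair, , drop = FALSE], yp,
                       family = "binomial", alpha = 0, lambda = 0.1,
                       weights = wp))
      p2 <- drop(stats::predict(fit, newx = x_test, type = "response"))
      winner <- ifelse(p2 > 0.5, pr[2], pr[1])
      for (r in seq_len(nrow(x_test))) {
        votes[r, winner[r]] <- votes[r, winner[r]] + 1
      }
      prob_sum[, pr[1]] <- prob_sum[, pr[1]] + (1 - p2)
      prob_sum[, pr[2]] <- prob_sum[, pr[2]] + p2
    }
    vapply(seq_len(nrow(x_test)), function(r) {
      top <- which(votes[r, ] == max(votes[r, ]))
      if (length(top) > 1) top <- top[which.max(prob_sum[r, top])]
      classes[top]
    }, character(1))
  } else if (family == "forest") {
    df <- data.frame(x_train)
    df$.y <- y_train
    fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                          num.trees = 500, seed = seed)
    nd <- data.frame(x_test)
    names(nd) <- names(data.frame(x_train))
    as.character(stats::predict(fit, data = nd)$predictions)
  } else if (family == "svm") {
    cw <- length(y_train) / (nlevels(y_train) * table(y_train))
    fit <- e1071::svm(x_train, y_train, kernel = "linear", scale = TRUE,
                      class.weights = cw)
    as.character(stats::predict(fit, x_test))
  } else {
    abort_argument(paste0("Unknown model family: ", family,
                          " (use one of ", paste(MODEL_FAMILIES, collapse = ", "),
                          ")."))
  }
}

new_report <- function(scheme, model, features_used, metrics, predictions) {
  structure(list(scheme = scheme, model = model,
                 features_used = features_used, metrics = metrics,
                 predictions = predictions),
            class = "ll_report")
}

#' @export
print.ll_report <- function(x, ...) {
  cat(sprintf("<evaluation report> %s / %s (%d features)\n",
              x$scheme$type, x$model, length(x$features_used)))
  print(x$metrics)
  invisible(x)
}

#' Repeated stratified holdout evaluation
#'
#' Splits the cohort into stratified seeded train/test partitions
#' (`test_fraction` held out, at least one training subject per class —
#' splits leaving a class out of training are redrawn up to a retry
#' budget), fits the model family, and averages macro metrics over
#' repetitions.
#'
#' @param features An `ll_features` tibble.
#' @param model_family One of `"linear"`, `"forest"`, `"svm"`.
#' @param test_fraction Fraction held out per repetition.
#' @param n_reps Number of repetitions.
#' @param seed Integer seed.
#' @param feature_subset Optional character vector of feature columns.
#' @return An `ll_report`; `metrics` holds the averaged macro metrics,
#'   `predictions` the per-repetition test predictions.
#' @export
repeated_holdout <- function(features, model_family = "linear",
                             test_fraction = 0.2, n_reps = 5, seed = 1L,
                             feature_subset = NULL) {
  seed <- check_seed(seed)
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort_argument("`test_fraction` must be in (0, 1).")
  }
  cols <- feature_subset %||% feature_columns(features)
  x <- feature_matrix(features, cols)
  y <- features$group
  classes <- sort(unique(y))
  if (any(table(y) < 2)) {
    abort_argument("Need at least 2 subjects per class for holdout splits.")
  }
  reps <- list()
  preds <- list()
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      for (try in 1:50) {
        test_idx <- unlist(lapply(classes, function(cl) {
          idx <- which(y == cl)
          k <- max(0, min(length(idx) - 1, round(length(idx) * test_fraction)))
          if (k == 0) integer() else sample(idx, k)
        }))
        if (length(test_idx) > 0 &&
            all(classes %in% y[-test_idx])) break
      }
      pred <- fit_predict(model_family, x[-test_idx, , drop = FALSE],
                          y[-test_idx], x[test_idx, , drop = FALSE],
                          seed = derive_seed(seed, r))
      reps[[r]] <- macro_metrics(y[test_idx], pred, classes)
      preds[[r]] <- tibble::tibble(rep = r,
                                   subject_id = features$subject_id[test_idx],
                                   truth = y[test_idx], predicted = pred)
    }
  })
  metrics <- dplyr::summarise(dplyr::bind_rows(reps),
                              dplyr::across(dplyr::everything(), mean))
  new_report(list(type = "repeated_holdout", test_fraction = test_fraction,
                  n_reps = n_reps, seed = seed),
             model_family, cols, metrics, dplyr::bind_rows(preds))
}

#' Leave-one-out cross-validation
#'
#' One fold per subject: the model is trained on all other subjects and
#' predicts the one left out; macro metrics are computed from the pooled
#' predictions.
#'
#' @inheritParams repeated_holdout
#' @return An `ll_report` with one prediction per subject.
#' @export
loocv <- function(features, model_family = "linear", feature_subset = NULL,
                  seed = 1L) {
  seed <- check_seed(seed)
  cols <- feature_subset %||% feature_columns(features)
  x <- feature_matrix(features, cols)
  y <- features$group
  if (length(unique(y)) < 2) {
    abort_argument("Need at least 2 classes for cross-validation.")
  }
  pred <- vapply(seq_along(y), function(i) {
    fit_predict(model_family, x[-i, , drop = FALSE], y[-i],
                x[i, , drop = FALSE], seed = derive_seed(seed, i))
  }, character(1))
  metrics <- macro_metrics(y, pred, sort(unique(y)))
  new_report(list(type = "loocv", seed = seed), model_family, cols, metrics,
             tibble::tibble(subject_id = features$subject_id, truth = y,
                            predicted = pred))
}

#' Select the most informative variables
#'
#' Ranks features by impurity-based importance from a seeded
#' randomized-tree ensemble (descending, ties broken lexicographically) and
#' returns the top `ceiling(fraction * n_features)` names.
#'
#' @param features An `ll_features` tibble.
#' @param fraction Top proportion to keep, in (0, 1].
#' @param seed Integer seed.
#' @param num_trees Ensemble size.
#' @return Character vector of selected feature names, most informative
#'   first.
#' @export
select_informative <- function(features, fraction = 0.125, seed = 1L,
                               num_trees = 1000) {
  seed <- check_seed(seed)
  if (fraction <= 0 || fraction > 1) {
    abort_argument("`fraction` must be in (0, 1].")
  }
  cols <- feature_columns(features)
  x <- feature_matrix(features, cols)
  df <- data.frame(x)
  df$.y <- factor(features$group)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = num_trees, importance = "impurity",
                        seed = seed)
  imp <- fit$variable.importance
  ord <- order(-imp, names(imp))
  k <- ceiling(fraction * length(cols))
  cols[match(names(imp)[ord][seq_len(k)], make.names(cols))]
}

#' Correlation matrix between battery variables and reference scores
#'
#' Pairwise-complete correlation coefficients (Pearson by default,
#' rank-based optionally) between two sets of paired observations; cells
#' with fewer than `min_pairs` complete pairs are set to `NA`.
#'
#' @param x A data frame / matrix of variables (rows are subjects).
#' @param y Optional second set; defaults to `x`.
#' @param method `"pearson"` or `"spearman"`.
#' @param min_pairs Minimum complete pairs per cell.
#' @return A numeric matrix with `rownames` from `x` and `colnames` from
#'   `y`.
#' @export
correlation_matrix <- function(x, y = NULL, method = c("pearson", "spearman"),
                               min_pairs = 3) {
  method <- match.arg(method)
  xm <- as.matrix(x)
  ym <- if (is.null(y)) xm else as.matrix(y)
  r <- stats::cor(xm, ym, use = "pairwise.complete.obs", method = method)
  n_pairs <- crossprod(!is.na(xm), !is.na(ym))
  r[n_pairs < min_pairs] <- NA_real_
  r
}

#' Paired pre/post comparison of ordinal scores
#'
#' For 5-point ordinal questionnaire items answered by the same subjects
#' before and after: the medians, the rate of increase
#' `(median_post - median_pre) / 5 * 100` (percent of the scale), and the
#' paired t-test on per-subject differences.
#'
#' @param pre,post Equal-length numeric vectors on the 1..5 scale.
#' @return A one-row tibble: `median_pre`, `median_post`,
#'   `rate_increase_pct`, `t_statistic`, `p_value`.
#' @export
#' @examples
#' paired_pre_post(c(1, 1, 2, 1), c(3, 3, 3, 4))
paired_pre_post <- function(pre, post) {
  if (length(pre) != length(post)) {
    abort_argument("`pre` and `post` must have equal length.")
  }
  med_pre <- stats::median(pre)
  med_post <- stats::median(post)
  d <- post - pre
  if (stats::sd(d) == 0) {
    t_stat <- if (all(d == 0)) 0 else Inf
    p_val <- if (all(d == 0)) 1 else 0
  } else {
    tt <- stats::t.test(post, pre, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p_val <- tt$p.value
  }
  tibble::tibble(median_pre = med_pre, median_post = med_post,
                 rate_increase_pct = (med_post - med_pre) / 5 * 100,
                 t_statistic = t_stat, p_value = p_val)
}
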