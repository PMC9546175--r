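test_that("every base learner trains on all deleterious rows plus the configured neutral bootstrap", {
  d <- sim_labeled_dataset(sim_config(), seed = 1) # 24 deleterious / 219 neutral
  m <- mirlog(d, l2 = 0.1, ratio = 4, feature_fraction = 0.6,
    n_estimators = 40, seed = 1)
  idx_del <- which(d$label == 1)
  expect_length(m$learners, 40)
  for (l in m$learners) {
    expect_true(all(idx_del %in% l$sample_idx))
    # 24 deleterious + round(4 * 24) bootstrapped neutral rows
    expect_length(l$sample_idx, 24 + 96)
    expect_true(all(d$label[setdiff(l$sample_idx, idx_del)] == 0))
    # ceiling(0.6 * 77) derived features, drawn without replacement
    expect_length(l$feats, ceiling(0.6 * 77))
    expect_false(any(duplicated(l$feats)))
  }
})

test_that("fitting is deterministic and rejects degenerate inputs", {
  d <- sim_labeled_dataset(sim_config(), n_deleterious = 12, n_neutral = 60, seed = 2)
  m1 <- mirlog(d, n_estimators = 10, seed = 5)
  m2 <- mirlog(d, n_estimators = 10, seed = 5)
  expect_identical(
    lapply(m1$learners, `[[`, "beta"),
    lapply(m2$learners, `[[`, "beta")
  )
  expect_identical(predict(m1, d), predict(m2, d))

  expect_error(mirlog(dplyr::mutate(d, label = 0L)), "both classes")
  expect_error(mirlog(d, l2 = -1), "l2")
  expect_error(mirlog(d, ratio = 0), "ratio")
  expect_error(mirlog(d, feature_fraction = 1.5), "feature_fraction")
  d_na <- d
  d_na$cadd[1] <- NA
  expect_error(mirlog(d_na), "impute")
})

test_that("separable classes are fit perfectly and scores behave like probabilities", {
  d <- sim_labeled_dataset(sim_config(d_prime = 6), seed = 3)
  m <- mirlog(d, l2 = 0.1, n_estimators = 30, seed = 1)
  expect_equal(m$train_auc, 1.0)
  p <- predict(m, d)$.pred
  expect_true(all(p >= 0 & p <= 1))
  # a training deleterious row scores above the 0.5 threshold
  expect_true(all(p[d$label == 1] > 0.5))
  expect_error(predict(m, dplyr::mutate(d, remm = NA_real_)), "impute")
})

test_that("the ensemble mean of identical learners equals the single-learner probability", {
  d <- sim_labeled_dataset(sim_config(), n_deleterious = 12, n_neutral = 60, seed = 4)
  m <- mirlog(d, n_estimators = 1, seed = 9)
  single <- predict(m, d)$.pred
  m$learners <- rep(m$learners, 3)
  expect_equal(predict(m, d)$.pred, single, tolerance = 1e-12)
})

test_that("stratified folds spread deleterious SNVs equally", {
  y <- c(rep(1L, 24), rep(0L, 219))
  set.seed(1)
  fold <- mirlogr:::make_folds(y, 12)
  expect_equal(unname(table(fold[y == 1L])), rep(2L, 12), ignore_attr = TRUE)
  # total fold sizes balanced within 1
  sizes <- table(fold)
  expect_lte(diff(range(sizes)), 1)
})

test_that("cross-validation is leakage-free, deterministic, and errors with too few deleterious rows", {
  d <- sim_labeled_dataset(sim_config(), n_deleterious = 16, n_neutral = 80, seed = 5)
  cv1 <- mirlog_cv(d, n_estimators = 8, folds = 8, repeats = 2, seed = 11)
  cv2 <- mirlog_cv(d, n_estimators = 8, folds = 8, repeats = 2, seed = 11)
  expect_identical(cv1$per_repeat, cv2$per_repeat)
  # every row scored exactly once per repeat, out of fold
  for (r in 1:2) {
    oof_r <- cv1$oof[cv1$oof$repeat_id == r, ]
    expect_setequal(oof_r$row, seq_len(nrow(d)))
  }
  expect_error(
    mirlog_cv(d, folds = 20, repeats = 1, seed = 1),
    "fewer folds"
  )
})

test_that("AUC: ties give 0.5, the rank statistic matches brute-force pair counting", {
  expect_equal(auc_rank(rep(1, 10), c(rep(1, 3), rep(0, 7))), 0.5)
  set.seed(8)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    scores <- sample(round(rnorm(n), 1)) # rounding forces ties
    expect_equal(auc_rank(scores, labels), auc_pairs(scores, labels))
  }
})

test_that("grid search returns the best point with regularization-first tie-breaking", {
  d <- sim_labeled_dataset(sim_config(d_prime = 6), n_deleterious = 12,
    n_neutral = 60, seed = 6)
  g1 <- tibble::tibble(l2 = 0.5, ratio = 2, feature_fraction = 0.6)
  t1 <- mirlog_tune(d, g1, folds = 6, repeats = 1, n_estimators = 8, seed = 2)
  expect_equal(nrow(t1$cv_table), 1)
  expect_equal(t1$best$l2, 0.5)
  expect_gte(t1$best$mean_auc, 0.95) # separable data

  # on perfectly separable data all points tie at AUC 1; the strongest
  # regularization, then the lowest ratio, must win
  g <- tidyr::expand_grid(l2 = c(0.1, 1), ratio = c(2, 4), feature_fraction = 1)
  tn <- mirlog_tune(d, g, folds = 6, repeats = 1, n_estimators = 8, seed = 2)
  if (all(tn$cv_table$mean_auc == 1)) {
    expect_equal(tn$best$l2, 1)
    expect_equal(tn$best$ratio, 2)
  }
  expect_error(mirlog_tune(d, g[0, ]), "empty")
})

test_that("prediction is monotone in a single informative score", {
  set.seed(9)
  n <- 120
  d <- tibble::tibble(cadd = c(rnorm(n / 2, 3), rnorm(n / 2, -3)))
  for (t in setdiff(score_tools(), "cadd")) d[[t]] <- rnorm(n, sd = 0.1)
  d$autosomal <- TRUE
  d$label <- rep(c(1L, 0L), each = n / 2)
  m <- mirlog(d, l2 = 1, ratio = 4, feature_fraction = 1, n_estimators = 20, seed = 1)
  grid <- d[rep(1, 41), ]
  grid$cadd <- seq(-4, 4, by = 0.2)
  for (t in setdiff(score_tools(), "cadd")) grid[[t]] <- 0
  p <- predict(m, grid)$.pred
  expect_true(all(diff(p) >= -1e-8))
})

test_that("a saved model reproduces its scores exactly after reload", {
  d <- sim_labeled_dataset(sim_config(), n_deleterious = 12, n_neutral = 60, seed = 7)
  m <- mirlog(d, n_estimators = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  mirlog_save(m, path)
  m2 <- mirlog_load(path)
  expect_equal(predict(m2, d)$.pred, predict(m, d)$.pred, tolerance = 1e-14)
  expect_error(mirlog_load(withr::local_tempfile(fileext = ".json") |>
    (\(p) { jsonlite::write_json(list(a = 1), p); p })()), "not a mirlog model")
})

test_that("tidy and glance summarize the fitted ensemble", {
  d <- sim_labeled_dataset(sim_config(), n_deleterious = 12, n_neutral = 60, seed = 8)
  m <- mirlog(d, n_estimators = 6, feature_fraction = 0.5, seed = 2)
  td <- tidy(m)
  expect_equal(nrow(td), 77) # 11 inputs -> 11 linear + 66 quadratic terms
  expect_true(all(td$n_selected <= 6))
  gl <- glance(m)
  expect_equal(gl$n_estimators, 6)
  expect_equal(gl$n_deleterious, 12)
})

test_that("score_all keys every SNV and chunks large tables consistently", {
  h <- sim_hairpins(sim_config(n_hairpins = 4), seed = 10)
  snvs <- enumerate_allelic_snvs(h)
  feats <- fixture_scores_for(snvs, seed = 3)
  feats$autosomal <- is_auto <- !snvs$chrom %in% "chrX"
  d <- sim_labeled_dataset(sim_config(), n_deleterious = 12, n_neutral = 60, seed = 9)
  m <- mirlog(d, n_estimators = 5, seed = 4)
  st <- score_all(m, feats)
  expect_equal(nrow(st), nrow(snvs))
  expect_true(all(st$mirlog >= 0 & st$mirlog <= 1))
  st_chunked <- score_all(m, feats, chunk_size = 37)
  expect_equal(st_chunked$mirlog, st$mirlog, tolerance = 1e-14)
})
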