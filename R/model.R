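#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Degree-2 polynomial expansion: all linear terms, squares and pairwise
# products, no bias column (the intercept lives in the logistic regression).
poly_expand <- function(A) {
  n <- ncol(A)
  nms <- colnames(A)
  pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  quad <- A[, pairs[, "row"], drop = FALSE] * A[, pairs[, "col"], drop = FALSE]
  colnames(quad) <- paste0(nms[pairs[, "row"]], "*", nms[pairs[, "col"]])
  cbind(A, quad)
}

check_hyperparams <- function(l2, ratio, feature_fraction, n_estimators) {
  if (!is.numeric(l2) || l2 <= 0) stop("l2 must be a positive real", call. = FALSE)
  if (!is.numeric(ratio) || ratio <= 0) stop("ratio must be positive", call. = FALSE)
  if (!is.numeric(feature_fraction) || feature_fraction <= 0 || feature_fraction > 1) {
    stop("feature_fraction must be in (0, 1]", call. = FALSE)
  }
  if (n_estimators < 1) stop("n_estimators must be >= 1", call. = FALSE)
}

extract_label <- function(data) {
  if (!"label" %in% names(data)) stop("data needs a 'label' column", call. = FALSE)
  y <- data$label
  if (is.factor(y)) y <- as.integer(y == levels(y)[2])
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("label must be 0 (neutral) / 1 (deleterious)", call. = FALSE)
  y
}

# Shared forward transform: standardize -> PCA rotation -> append the
# autosomal flag -> quadratic polynomial expansion.
transform_features <- function(model, data) {
  X <- as.matrix(data[model$feature_names])
  if (anyNA(X)) stop("missing score values: impute before fitting/prediction", call. = FALSE)
  Xs <- sweep(sweep(X, 2, model$scaler$center), 2, model$scaler$scale, "/")
  Z <- Xs %*% model$rotation
  A <- cbind(Z, autosomal = as.numeric(data$autosomal))
  poly_expand(A)
}

#' Fit the bagged logistic meta-predictor for miRNA SNV deleteriousness
#'
#' Fits the full classification pipeline on a labeled SNV set: (1) each of the
#' ten score columns is standardized to zero mean and unit variance; (2) the
#' standardized scores are rotated onto their principal components (all
#' components kept -- the PCA removes collinearity, not dimensions); (3) the
#' autosomal flag is appended; (4) a degree-2 polynomial expansion (linear
#' terms, squares and pairwise products) produces the derived features; (5)
#' `n_estimators` L2-regularized logistic regressions are fitted, each on a
#' sample holding *all* deleterious rows plus `round(ratio * n_deleterious)`
#' neutral rows drawn with replacement, using `ceiling(feature_fraction * p)`
#' derived features drawn without replacement. Only the minority-preserving
#' neutral bootstrap is resampled, so every base learner sees every
#' deleterious SNV. Predictions are the ensemble mean of the per-learner
#' logistic probabilities.
#'
#' @param data Tibble with the ten score columns ([score_tools()]), a logical
#'   `autosomal` column and a `label` column (1 = deleterious, 0 = neutral).
#'   Scores must be complete (see [impute_scores()]).
#' @param l2 L2 regularization strength (glmnet lambda) of each base learner.
#' @param ratio Neutral-to-deleterious bootstrap ratio per base learner.
#' @param feature_fraction Fraction of derived features drawn per learner.
#' @param n_estimators Number of base learners (default 200).
#' @param seed Integer seed; (data, hyperparameters, seed) fully determine
#'   the model.
#' @return An object of class `"mirlog"`.
#' @export
mirlog <- function(data, l2 = 1, ratio = 4, feature_fraction = 0.6,
                   n_estimators = 200, seed = 1) {
  check_hyperparams(l2, ratio, feature_fraction, n_estimators)
  y <- extract_label(data)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (min(table(y)) < 2) stop("need at least 2 rows per class", call. = FALSE)

  X <- as.matrix(data[SCORE_TOOLS])
  if (anyNA(X)) stop("missing score values: impute before fitting", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  rot <- prcomp(Xs, center = FALSE, scale. = FALSE)$rotation
  colnames(rot) <- paste0("pc", seq_len(ncol(rot)))

  model <- list(
    version = "1.0",
    feature_names = SCORE_TOOLS,
    scaler = list(center = ctr, scale = scl),
    rotation = rot,
    hyperparams = list(
      l2 = l2, ratio = ratio, feature_fraction = feature_fraction,
      n_estimators = n_estimators
    ),
    seed = seed
  )
  class(model) <- "mirlog"

  P <- transform_features(model, data)
  p_feat <- ncol(P)
  idx_del <- which(y == 1L)
  idx_neu <- which(y == 0L)
  n_boot <- max(1L, round(ratio * length(idx_del)))
  n_sel <- max(2L, ceiling(feature_fraction * p_feat))

  set.seed(seed)
  learners <- vector("list", n_estimators)
  for (e in seq_len(n_estimators)) {
    neu <- sample(idx_neu, n_boot, replace = TRUE)
    feats <- sort(sample.int(p_feat, n_sel, replace = FALSE))
    rows <- c(idx_del, neu)
    fit <- glmnet::glmnet(
      P[rows, feats, drop = FALSE], y[rows],
      family = "binomial", alpha = 0, lambda = l2, standardize = FALSE
    )
    cf <- as.numeric(coef(fit))
    learners[[e]] <- list(
      intercept = cf[1], beta = cf[-1],
      feats = feats, sample_idx = rows
    )
  }
  model$learners <- learners
  model$n_train <- length(y)
  model$n_deleterious <- length(idx_del)
  model$n_neutral <- length(idx_neu)
  model$train_auc <- auc_rank(ensemble_scores(model, P), y)
  model
}

# Running-sum accumulation keeps memory at O(n) regardless of ensemble size.
ensemble_scores <- function(model, P) {
  acc <- numeric(nrow(P))
  for (l in model$learners) {
    acc <- acc + plogis(l$intercept + as.numeric(P[, l$feats, drop = FALSE] %*% l$beta))
  }
  acc / length(model$learners)
}

#' Predict deleteriousness probabilities
#'
#' Applies the fit-time standardization, rotation and polynomial expansion to
#' new rows and averages the logistic probabilities of the base learners.
#' Scores lie in `[0, 1]`; 0.5 is the conventional deleteriousness threshold.
#'
#' @param object A fitted [mirlog()] model.
#' @param new_data Tibble with the ten score columns and `autosomal`; no
#'   missing values allowed.
#' @param ... Unused.
#' @return A tibble with one column `.pred`.
#' @export
predict.mirlog <- function(object, new_data, ...) {
  P <- transform_features(object, new_data)
  tibble(.pred = ensemble_scores(object, P))
}

#' @export
print.mirlog <- function(x, ...) {
  cat(sprintf(
    "Bagged logistic meta-predictor: %d base learners (l2=%g, ratio=%g, feature_fraction=%g)\n",
    length(x$learners), x$hyperparams$l2, x$hyperparams$ratio,
    x$hyperparams$feature_fraction
  ))
  cat(sprintf(
    "Trained on %d SNVs (%d deleterious / %d neutral), training AUC %.3f\n",
    x$n_train, x$n_deleterious, x$n_neutral, x$train_auc
  ))
  invisible(x)
}

#' @rdname mirlog
#' @param x A fitted `mirlog` model (for `tidy`/`glance`).
#' @export
tidy.mirlog <- function(x, ...) {
  P <- length(x$learners[[1]]$beta) # per-learner width; terms indexed globally
  n_in <- length(x$feature_names) + 1L
  term_names <- colnames(poly_expand(
    matrix(0, 1, n_in,
      dimnames = list(NULL, c(colnames(x$rotation), "autosomal"))
    )
  ))
  acc <- lapply(seq_along(term_names), function(j) {
    est <- unlist(lapply(x$learners, function(l) {
      k <- match(j, l$feats)
      if (is.na(k)) NULL else l$beta[k]
    }))
    tibble(
      term = term_names[j], n_selected = length(est),
      estimate = if (length(est)) mean(est) else NA_real_,
      std_error = if (length(est) > 1) sd(est) else NA_real_
    )
  })
  bind_rows(acc)
}

#' @rdname mirlog
#' @export
glance.mirlog <- function(x, ...) {
  tibble(
    n_estimators = length(x$learners),
    l2 = x$hyperparams$l2,
    ratio = x$hyperparams$ratio,
    feature_fraction = x$hyperparams$feature_fraction,
    n_train = x$n_train,
    n_deleterious = x$n_deleterious,
    n_neutral = x$n_neutral,
    train_auc = x$train_auc
  )
}

#' Area under the ROC curve by the rank statistic
#'
#' Computes AUC as the normalized Mann-Whitney U statistic using midranks,
#' `(sum of positive ranks - n1(n1+1)/2) / (n1 n0)`, which equals the
#' probability that a random positive outscores a random negative (ties
#' counted half).
#'
#' @param scores Numeric predictions.
#' @param labels 0/1 labels (1 = positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined with a single class")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Points of an empirical ROC curve
#'
#' @param scores Numeric predictions.
#' @param labels 0/1 labels.
#' @return Tibble with `threshold`, `fpr`, `tpr`, sorted from (0,0) to (1,1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  fp <- tapply(1 - y, grp, sum)
  tibble(
    threshold = c(Inf, s[!duplicated(s)]),
    tpr = c(0, cumsum(tp)) / sum(y),
    fpr = c(0, cumsum(fp)) / sum(1 - y)
  )
}

# Stratified fold assignment: deleterious rows are shuffled and dealt
# round-robin so folds differ by at most one deleterious SNV; neutral rows are
# then dealt to keep total fold sizes balanced. Uses the caller's RNG state.
make_folds <- function(labels, k) {
  n <- length(labels)
  fold <- integer(n)
  del <- sample(which(labels == 1L))
  neu <- sample(which(labels == 0L))
  fold[del] <- rep(seq_len(k), length.out = length(del))
  del_counts <- tabulate(fold[del], nbins = k)
  fill_order <- order(del_counts, seq_len(k))
  fold[neu] <- rep(fill_order, length.out = length(neu))
  fold
}

#' Repeated stratified cross-validation of the meta-predictor
#'
#' Runs `repeats` independent rounds of `folds`-fold cross-validation with
#' deleterious-stratified folds (the deleterious SNVs are distributed equally
#' across folds). Inside every training fold the whole pipeline --
#' standardization, PCA, polynomial expansion, bagging -- is refitted from
#' scratch, so no information leaks into the held-out fold. Out-of-fold
#' scores are collected per repeat; the AUC is the rank statistic of
#' [auc_rank()]. Both the mean of per-repeat AUCs and the AUC of all pooled
#' out-of-fold scores are reported.
#'
#' @inheritParams mirlog
#' @param folds Number of folds (default 12).
#' @param repeats Number of repeated splits (default 4).
#' @return An object of class `"mirlog_cv"`: a list with `per_repeat`
#'   (tibble of repeat, auc), `mean_auc`, `pooled_auc`, `roc` (pooled ROC
#'   points) and `oof` (all out-of-fold scores).
#' @export
mirlog_cv <- function(data, l2 = 1, ratio = 4, feature_fraction = 0.6,
                      n_estimators = 200, folds = 12, repeats = 4, seed = 1) {
  y <- extract_label(data)
  n_del <- sum(y == 1L)
  if (n_del < folds) {
    stop(sprintf(
      "only %d deleterious rows for %d folds; use fewer folds", n_del, folds
    ), call. = FALSE)
  }
  oof_all <- list()
  per_repeat <- numeric(repeats)
  skipped <- 0L
  for (r in seq_len(repeats)) {
    set.seed(seed + 7919L * r)
    fold <- make_folds(y, folds)
    pred <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      if (length(unique(y[test])) < 2) {
        skipped <- skipped + 1L
        next
      }
      fit <- mirlog(data[train, ],
        l2 = l2, ratio = ratio,
        feature_fraction = feature_fraction,
        n_estimators = n_estimators,
        seed = seed + 7919L * r + f
      )
      pred[test] <- predict(fit, data[test, ])$.pred
    }
    keep <- !is.na(pred)
    per_repeat[r] <- auc_rank(pred[keep], y[keep])
    oof_all[[r]] <- tibble(
      repeat_id = r, row = which(keep),
      label = y[keep], .pred = pred[keep]
    )
  }
  if (skipped > 0) {
    warning(sprintf("%d fold(s) rejected for holding a single class", skipped))
  }
  oof <- bind_rows(oof_all)
  out <- list(
    per_repeat = tibble(repeat_id = seq_len(repeats), auc = per_repeat),
    mean_auc = mean(per_repeat),
    pooled_auc = auc_rank(oof$.pred, oof$label),
    roc = roc_points(oof$.pred, oof$label),
    oof = oof,
    folds = folds, repeats = repeats, seed = seed
  )
  class(out) <- "mirlog_cv"
  out
}

#' @export
print.mirlog_cv <- function(x, ...) {
  cat(sprintf(
    "%d-repeat %d-fold CV: mean AUC %.3f (per repeat: %s), pooled AUC %.3f\n",
    x$repeats, x$folds, x$mean_auc,
    paste(sprintf("%.3f", x$per_repeat$auc), collapse = ", "),
    x$pooled_auc
  ))
  invisible(x)
}

#' Grid-search hyperparameter tuning by repeated stratified CV
#'
#' Evaluates every grid point with [mirlog_cv()] (same seed, hence identical
#' fold assignments across points) and returns the point with the highest
#' mean validation AUC. Ties are broken toward stronger regularization
#' (larger `l2`), then a lower neutral ratio, then a lower feature fraction.
#'
#' @inheritParams mirlog_cv
#' @param grid Tibble of hyperparameter combinations with columns `l2`,
#'   `ratio`, `feature_fraction` (optionally `n_estimators`).
#' @return An object of class `"mirlog_tune"`: list with `best` (one-row
#'   tibble) and `cv_table` (grid plus `mean_auc`).
#' @export
mirlog_tune <- function(data, grid, folds = 12, repeats = 4,
                        n_estimators = 200, seed = 1) {
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  if (!"n_estimators" %in% names(grid)) grid$n_estimators <- n_estimators
  res <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    mirlog_cv(data,
      l2 = grid$l2[i], ratio = grid$ratio[i],
      feature_fraction = grid$feature_fraction[i],
      n_estimators = grid$n_estimators[i],
      folds = folds, repeats = repeats, seed = seed
    )$mean_auc
  })
  cv_table <- mutate(grid, mean_auc = res)
  best <- cv_table[order(-cv_table$mean_auc, -cv_table$l2, cv_table$ratio,
    cv_table$feature_fraction
  )[1], ]
  out <- list(best = best, cv_table = cv_table, folds = folds,
    repeats = repeats, seed = seed)
  class(out) <- "mirlog_tune"
  out
}

#' @export
print.mirlog_tune <- function(x, ...) {
  cat(sprintf(
    "Grid search over %d points (%d-repeat %d-fold CV)\nBest: l2=%g ratio=%g feature_fraction=%g (mean AUC %.3f)\n",
    nrow(x$cv_table), x$repeats, x$folds,
    x$best$l2, x$best$ratio, x$best$feature_fraction, x$best$mean_auc
  ))
  invisible(x)
}

#' Score a full SNV table with a fitted model
#'
#' @param model A fitted [mirlog()] model.
#' @param features Complete feature tibble keyed by `chrom, pos, ref, alt`
#'   with the ten score columns and `autosomal`.
#' @param chunk_size Rows scored per pass, bounding peak memory when scoring
#'   the full enumeration of possible SNVs.
#' @return The key columns plus a `mirlog` score column in `[0, 1]`.
#' @export
score_all <- function(model, features, chunk_size = 100000L) {
  keys <- intersect(c("chrom", "pos", "ref", "alt", "hairpin_id", "hgvs"),
    names(features))
  out <- features[keys]
  n <- nrow(features)
  scores <- numeric(n)
  starts <- seq(1L, n, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, n)
    scores[idx] <- predict(model, features[idx, ])$.pred
  }
  out$mirlog <- scores
  as_tibble(out)
}

#' Save / load a fitted model as versioned JSON
#'
#' The model file is a plain-text JSON document holding the scaler, PCA
#' loadings, polynomial specification, per-learner coefficients and feature
#' subsets, hyperparameters and seed, so a stored model reproduces its scores
#' exactly.
#'
#' @param model A fitted [mirlog()] model.
#' @param path File path.
#' @return `mirlog_save` returns `path` invisibly; `mirlog_load` returns the
#'   restored `"mirlog"` object.
#' @export
mirlog_save <- function(model, path) {
  obj <- list(
    format = "mirlog-model", version = model$version,
    feature_names = model$feature_names,
    scaler = list(
      center = as.list(model$scaler$center),
      scale = as.list(model$scaler$scale)
    ),
    rotation = list(
      rownames = rownames(model$rotation),
      colnames = colnames(model$rotation),
      values = as.numeric(model$rotation)
    ),
    hyperparams = model$hyperparams,
    seed = model$seed,
    n_train = model$n_train,
    n_deleterious = model$n_deleterious,
    n_neutral = model$n_neutral,
    train_auc = model$train_auc,
    learners = lapply(model$learners, function(l) {
      list(
        intercept = l$intercept, beta = l$beta,
        feats = l$feats, sample_idx = l$sample_idx
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mirlog_save
#' @export
mirlog_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mirlog-model")) {
    stop("not a mirlog model file: ", path, call. = FALSE)
  }
  rot <- matrix(obj$rotation$values,
    nrow = length(obj$rotation$rownames),
    dimnames = list(obj$rotation$rownames, obj$rotation$colnames)
  )
  learners <- if (is.data.frame(obj$learners)) {
    lapply(seq_len(nrow(obj$learners)), function(i) {
      list(
        intercept = obj$learners$intercept[i],
        beta = obj$learners$beta[[i]],
        feats = obj$learners$feats[[i]],
        sample_idx = obj$learners$sample_idx[[i]]
      )
    })
  } else {
    obj$learners
  }
  model <- list(
    version = obj$version,
    feature_names = obj$feature_names,
    scaler = list(
      center = unlist(obj$scaler$center),
      scale = unlist(obj$scaler$scale)
    ),
    rotation = rot,
    hyperparams = obj$hyperparams,
    seed = obj$seed,
    learners = learners,
    n_train = obj$n_train,
    n_deleterious = obj$n_deleterious,
    n_neutral = obj$n_neutral,
    train_auc = obj$train_auc
  )
  class(model) <- "mirlog"
  model
}
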