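#' Assemble the per-SNV feature matrix from the ten scoring systems
#'
#' Joins per-tool score tables onto a requested SNV list. Allele-level tools
#' are keyed by (chrom, pos, ref, alt); position-level tools (phyloP,
#' phastCons, LINSIGHT) are keyed by (chrom, pos) and their single value is
#' broadcast to all three alternative alleles at the site. Absent entries stay
#' `NA`; the per-column missingness fraction is attached as the
#' `"missingness"` attribute. An `autosomal` flag (chromosome not X/Y) is
#' appended as the eleventh feature.
#'
#' @param score_tables Named list of tibbles, one per tool in
#'   [score_tools()]; allele-level tables have columns
#'   `chrom, pos, ref, alt, score`, position-level tables `chrom, pos, score`.
#' @param snvs Tibble of requested SNVs with columns `chrom, pos, ref, alt`.
#' @return A tibble with the SNV keys, one column per tool (native scales,
#'   `NA` where missing) and a logical `autosomal` column.
#' @export
assemble_scores <- function(score_tables, snvs) {
  missing_tools <- setdiff(SCORE_TOOLS, names(score_tables))
  if (length(missing_tools) > 0) {
    stop(
      "score_tables lacks: ", paste(missing_tools, collapse = ", "),
      call. = FALSE
    )
  }
  out <- select(as_tibble(snvs), "chrom", "pos", "ref", "alt")
  for (tool in SCORE_TOOLS) {
    tab <- as_tibble(score_tables[[tool]])
    key_cols <- if (tool %in% POSITION_LEVEL_TOOLS) {
      c("chrom", "pos")
    } else {
      c("chrom", "pos", "ref", "alt")
    }
    dup <- tab[duplicated(tab[key_cols]) | duplicated(tab[key_cols], fromLast = TRUE), ]
    if (nrow(dup) > 0 && nrow(distinct(dup)) < nrow(dup)) {
      # exact duplicate rows are tolerated; conflicting values are not
      tab <- distinct(tab)
      dup <- tab[duplicated(tab[key_cols]) | duplicated(tab[key_cols], fromLast = TRUE), ]
    }
    if (anyDuplicated(tab[key_cols]) > 0) {
      stop(sprintf("tool '%s': conflicting duplicate entries for a key", tool),
        call. = FALSE
      )
    }
    tab <- tab[c(key_cols, "score")]
    names(tab)[names(tab) == "score"] <- tool
    out <- left_join(out, tab, by = key_cols)
  }
  out$autosomal <- is_autosomal_chrom(out$chrom)
  miss <- vapply(out[SCORE_TOOLS], function(x) mean(is.na(x)), numeric(1))
  attr(out, "missingness") <- miss
  out
}

# Fit an extremely-randomized-trees regressor of y on X and predict at X_new.
# replace = FALSE + sample.fraction = 1 gives the classic Extra-Trees scheme
# (no bootstrap; randomness comes from the random split points).
extratrees_predict <- function(X, y, X_new, n_trees, seed) {
  df <- as.data.frame(X)
  df$.y <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = n_trees, splitrule = "extratrees", num.random.splits = 1,
    replace = FALSE, sample.fraction = 1, seed = seed,
    num.threads = 1, verbose = FALSE
  )
  predict(fit, data = as.data.frame(X_new), num.threads = 1)$predictions
}

#' Impute missing scores with an iterative Extra-Trees imputer
#'
#' Round-robin iterative imputation: missing cells are initialized at the
#' column mean, then each incomplete column in turn (least missing first) is
#' regressed on all other score columns with an extremely-randomized-trees
#' regressor and its missing entries replaced by the predictions, for up to
#' `max_iter` rounds or until the largest change falls below `tol` times the
#' column scale. The whole procedure is run `repeats` times with distinct
#' seeds and the imputed values averaged across repeats. Observed cells are
#' never altered, and the `autosomal` flag never participates.
#'
#' @param features Feature tibble from [assemble_scores()].
#' @param n_trees Trees per Extra-Trees regressor (default 126).
#' @param repeats Independent imputer runs to average (default 10).
#' @param max_iter Maximum round-robin sweeps per run (default 10).
#' @param tol Relative convergence tolerance (default 1e-3).
#' @param seed Integer seed; the run is fully deterministic given
#'   (`seed`, `repeats`).
#' @return The feature tibble with all score columns complete; the original
#'   missingness mask is attached as attribute `"imputed_mask"`.
#' @export
impute_scores <- function(features, n_trees = 126, repeats = 10,
                          max_iter = 10, tol = 1e-3, seed = 1) {
  X <- as.matrix(features[SCORE_TOOLS])
  mask <- is.na(X)
  fully_missing <- colnames(X)[colSums(!mask) == 0]
  if (length(fully_missing) > 0) {
    stop(
      "column(s) fully missing: ", paste(fully_missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!any(mask)) {
    attr(features, "imputed_mask") <- mask
    return(features)
  }
  col_means <- colMeans(X, na.rm = TRUE)
  incomplete <- order(colSums(mask))
  incomplete <- incomplete[colSums(mask)[incomplete] > 0]
  col_scale <- apply(X, 2, function(x) {
    s <- max(abs(x), na.rm = TRUE)
    if (!is.finite(s) || s == 0) 1 else s
  })

  one_run <- function(run_seed) {
    Xi <- X
    for (j in seq_len(ncol(Xi))) Xi[mask[, j], j] <- col_means[j]
    for (iter in seq_len(max_iter)) {
      max_delta <- 0
      for (j in incomplete) {
        obs <- !mask[, j]
        pred <- extratrees_predict(
          Xi[obs, -j, drop = FALSE], Xi[obs, j],
          Xi[mask[, j], -j, drop = FALSE],
          n_trees = n_trees,
          seed = run_seed * 1000L + iter * 13L + j
        )
        max_delta <- max(max_delta, max(abs(pred - Xi[mask[, j], j]) / col_scale[j]))
        Xi[mask[, j], j] <- pred
      }
      if (max_delta < tol) break
    }
    Xi
  }

  runs <- lapply(seq_len(repeats), function(r) one_run(seed + r - 1L))
  Xavg <- Reduce(`+`, runs) / repeats
  Xavg[!mask] <- X[!mask] # observed cells bit-identical
  out <- features
  out[SCORE_TOOLS] <- as_tibble(Xavg)
  attr(out, "imputed_mask") <- mask
  attr(out, "repeat_values") <- lapply(runs, function(Xi) Xi[mask])
  out
}

#' Principal-component collinearity diagnostic
#'
#' PCA of the ten (imputed) score columns on the correlation scale, used to
#' quantify redundancy among the scoring systems: strongly collinear tools
#' concentrate the variance in few components.
#'
#' @param features Complete feature tibble (no missing score values).
#' @return A tibble with `component`, `variance_ratio` (non-negative, sorted
#'   descending, summing to 1) and `cumulative`; the loading matrix is
#'   attached as attribute `"loadings"`.
#' @export
pca_diagnostic <- function(features) {
  X <- as.matrix(features[intersect(SCORE_TOOLS, names(features))])
  if (nrow(X) < 2) stop("need at least 2 rows for PCA", call. = FALSE)
  if (anyNA(X)) stop("impute the matrix before the PCA diagnostic", call. = FALSE)
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  ratio <- p$sdev^2 / sum(p$sdev^2)
  out <- tibble(
    component = seq_along(ratio),
    variance_ratio = ratio,
    cumulative = cumsum(ratio)
  )
  attr(out, "loadings") <- p$rotation
  out
}
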