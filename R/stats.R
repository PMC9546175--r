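TS_CATEGORIES <- c("A/T>G/C", "G/C>A/T")
TV_CATEGORIES <- c("G/C>C/G", "G/C>T/A", "A/T>T/A", "A/T>C/G")

#' Classify a nucleotide substitution as transition or transversion
#'
#' Transitions exchange purine for purine or pyrimidine for pyrimidine
#' (A<->G, C<->T); all other substitutions are transversions. The category is
#' the strand-symmetric class, e.g. both `C>G` and `G>C` map to `"G/C>C/G"`.
#'
#' @param ref,alt Single bases in `{A, C, G, T}` (vectorized), `ref != alt`.
#' @return Tibble with columns `ref`, `alt`, `class`
#'   (`"transition"`/`"transversion"`) and `category`.
#' @export
#' @examples
#' classify_substitution("A", "G")
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  ok <- ref %in% DNA_BASES & alt %in% DNA_BASES & ref != alt
  if (!all(ok)) stop("invalid substitution: bases must differ and be in {A,C,G,T}", call. = FALSE)
  key <- paste0(ref, ">", alt)
  category <- c(
    "A>G" = "A/T>G/C", "T>C" = "A/T>G/C",
    "G>A" = "G/C>A/T", "C>T" = "G/C>A/T",
    "G>C" = "G/C>C/G", "C>G" = "G/C>C/G",
    "G>T" = "G/C>T/A", "C>A" = "G/C>T/A",
    "A>T" = "A/T>T/A", "T>A" = "A/T>T/A",
    "A>C" = "A/T>C/G", "T>G" = "A/T>C/G"
  )[key]
  tibble(
    ref = ref, alt = alt,
    class = ifelse(category %in% TS_CATEGORIES, "transition", "transversion"),
    category = unname(category)
  )
}

#' Transition/transversion report for a variant set
#'
#' Counts the two transition and four transversion strand-symmetric
#' categories and their fractions (summing to 1), plus the Ts/Tv ratio. An
#' empty transversion set yields an infinite ratio rather than an error.
#'
#' @param variants Tibble with `ref` and `alt` columns.
#' @return A list of class `"tstv_report"`: `categories` tibble
#'   (category, class, n, fraction), `n_ts`, `n_tv`, `ts_tv_ratio`.
#' @export
tstv_report <- function(variants) {
  cl <- classify_substitution(variants$ref, variants$alt)
  all_cats <- tibble(
    category = c(TS_CATEGORIES, TV_CATEGORIES),
    class = c(rep("transition", 2), rep("transversion", 4))
  )
  counts <- cl |>
    dplyr::count(.data$category, name = "n") |>
    left_join(x = all_cats, by = "category") |>
    mutate(
      n = ifelse(is.na(.data$n), 0L, .data$n),
      fraction = .data$n / sum(.data$n)
    )
  n_ts <- sum(counts$n[counts$class == "transition"])
  n_tv <- sum(counts$n[counts$class == "transversion"])
  out <- list(
    categories = counts, n_ts = n_ts, n_tv = n_tv,
    ts_tv_ratio = if (n_tv == 0) Inf else n_ts / n_tv
  )
  class(out) <- "tstv_report"
  out
}

#' @export
print.tstv_report <- function(x, ...) {
  cat(sprintf(
    "Ts: %d (%.1f%%)  Tv: %d (%.1f%%)  Ts/Tv = %s\n",
    x$n_ts, 100 * x$n_ts / (x$n_ts + x$n_tv),
    x$n_tv, 100 * x$n_tv / (x$n_ts + x$n_tv),
    format(round(x$ts_tv_ratio, 2))
  ))
  print(x$categories)
  invisible(x)
}

#' SNV density of a region in variants per kilobase
#'
#' Multi-allelic sites contribute one variant per alternative allele.
#'
#' @param n_snvs Number of SNVs observed in the region (or a variant tibble,
#'   in which case its row count is used).
#' @param region_length_nt Region length in nucleotides.
#' @param region Label for the report row.
#' @return Tibble with `region`, `n_snvs`, `length_nt`, `density` (SNVs/kb).
#' @export
snv_density <- function(n_snvs, region_length_nt, region = "region") {
  if (is.data.frame(n_snvs)) n_snvs <- nrow(n_snvs)
  tibble(
    region = region, n_snvs = as.integer(n_snvs),
    length_nt = as.integer(region_length_nt),
    density = n_snvs / (region_length_nt / 1000)
  )
}

#' Chi-square comparison of two SNV densities
#'
#' 2x2 test on (variant, non-variant) counts of the two regions, without
#' continuity correction. A `small_expected` flag marks tables with an
#' expected cell below 5 where the chi-square approximation is doubtful.
#'
#' @param count_a,count_b Variant counts in regions A and B.
#' @param len_a,len_b Region lengths in nucleotides.
#' @return Tibble with `statistic`, `p_value`, `small_expected`.
#' @export
compare_densities <- function(count_a, len_a, count_b, len_b) {
  tab <- matrix(c(count_a, len_a - count_a, count_b, len_b - count_b), nrow = 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(expected < 5)) {
    warning("expected cell count below 5; chi-square approximation doubtful")
  }
  tibble(
    statistic = unname(res$statistic),
    p_value = unname(res$p.value),
    small_expected = any(expected < 5)
  )
}

#' Per-site SNV density along mature miRNAs
#'
#' For each mature-local site the count of SNVs is normalized to the number
#' of mature miRNAs long enough to have that site, expressed per 1000
#' miRNAs.
#'
#' @param site Mature-local 1-based positions of the observed SNVs
#'   (1 = first mature base).
#' @param mature_lengths Integer vector of mature lengths, one per mature
#'   miRNA in the cohort.
#' @return Tibble with `site`, `n_snvs`, `n_mirnas`, `per_1000`.
#' @export
per_base_density <- function(site, mature_lengths) {
  sites <- seq_len(max(mature_lengths))
  counts <- tabulate(site, nbins = max(mature_lengths))
  denom <- vapply(sites, function(s) sum(mature_lengths >= s), integer(1))
  tibble(
    site = sites, n_snvs = counts, n_mirnas = denom,
    per_1000 = 1000 * counts / denom
  )
}

#' Allele-frequency spectrum and ultra-rare fraction
#'
#' Histograms allele frequencies over the given breaks and reports the
#' ultra-rare fraction, i.e. the proportion of variants with
#' `AF <= ultra_rare_cut` (default 0.01%).
#'
#' @param af Numeric allele frequencies in `[0, 1]`.
#' @param breaks Bin edges (default log-spaced from 0 to 1).
#' @param ultra_rare_cut Ultra-rare threshold (default `1e-4`).
#' @return A list of class `"af_spectrum"`: `bins` tibble (lower, upper, n),
#'   `ultra_rare_fraction`, `n`.
#' @export
af_spectrum <- function(af, breaks = c(0, 1e-5, 1e-4, 1e-3, 1e-2, 0.1, 0.5, 1),
                        ultra_rare_cut = 1e-4) {
  stopifnot(all(af >= 0 & af <= 1))
  cuts <- cut(af, breaks = breaks, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(cuts))
  out <- list(
    bins = tibble(
      lower = breaks[-length(breaks)], upper = breaks[-1], n = counts
    ),
    ultra_rare_fraction = mean(af <= ultra_rare_cut),
    n = length(af)
  )
  class(out) <- "af_spectrum"
  out
}

#' @export
print.af_spectrum <- function(x, ...) {
  cat(sprintf(
    "%d variants; ultra-rare fraction %.1f%%\n", x$n,
    100 * x$ultra_rare_fraction
  ))
  print(x$bins)
  invisible(x)
}

#' Coverage rule for properly covered miRNAs
#'
#' A hairpin passes when, at a sequencing depth of at least `min_depth`
#' reads, at least `base_frac` of its bases are covered in at least
#' `indiv_frac` of the individuals. All comparisons are inclusive. The input
#' is either a per-base summary with a `frac_individuals` column (fraction of
#' individuals reaching `min_depth` at that base), or per-base, per-individual
#' depths in long form (`hairpin_id`, `pos`, `individual`, `depth`) from which
#' that fraction is computed.
#'
#' @param depth_summary Tibble as described above.
#' @param min_depth Minimum read depth (default 20; only used with the long
#'   per-individual form).
#' @param base_frac Minimum fraction of bases (default 0.8).
#' @param indiv_frac Minimum fraction of individuals (default 0.8).
#' @return Tibble with one row per hairpin: `hairpin_id`, `frac_bases_covered`,
#'   `pass`.
#' @export
coverage_pass <- function(depth_summary, min_depth = 20, base_frac = 0.8,
                          indiv_frac = 0.8) {
  ds <- as_tibble(depth_summary)
  if (!"frac_individuals" %in% names(ds)) {
    stopifnot(all(c("hairpin_id", "pos", "depth") %in% names(ds)))
    ds <- ds |>
      group_by(.data$hairpin_id, .data$pos) |>
      summarise(frac_individuals = mean(.data$depth >= min_depth), .groups = "drop")
  }
  ds |>
    group_by(.data$hairpin_id) |>
    summarise(
      frac_bases_covered = mean(.data$frac_individuals >= indiv_frac),
      .groups = "drop"
    ) |>
    mutate(pass = .data$frac_bases_covered >= base_frac)
}

#' Compare two score distributions with the Mann-Whitney test
#'
#' Two-sided rank-sum test with tie correction (normal approximation), plus
#' medians and means of both samples.
#'
#' @param scores_a,scores_b Numeric score vectors.
#' @return Tibble with `u_statistic`, `p_value`, `median_a`, `median_b`,
#'   `mean_a`, `mean_b`.
#' @export
compare_score_distributions <- function(scores_a, scores_b) {
  res <- suppressWarnings(
    wilcox.test(scores_a, scores_b, exact = FALSE, correct = FALSE)
  )
  tibble(
    u_statistic = unname(res$statistic),
    p_value = unname(res$p.value),
    median_a = median(scores_a), median_b = median(scores_b),
    mean_a = mean(scores_a), mean_b = mean(scores_b)
  )
}

#' Correlation between two numeric vectors
#'
#' Spearman by default (average ranks for ties), as used for relating SNV
#' density, disease associations and mean deleteriousness scores.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble with `estimate`, `p_value`, `method`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  res <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  tibble(
    estimate = unname(res$estimate),
    p_value = unname(res$p.value),
    method = method
  )
}

#' Select scores above a quantile threshold
#'
#' The threshold is the `q` quantile of the scores (linear interpolation
#' between order statistics, R type 7); the selection keeps scores strictly
#' greater than the threshold, so a constant score vector selects nothing.
#'
#' @param scores Numeric score vector.
#' @param q Quantile in `[0, 1]` (default 0.99, the 99th percentile).
#' @return A list of class `"percentile_selection"`: `threshold`, `q`,
#'   `selected` (integer indices), `n_selected`.
#' @export
percentile_select <- function(scores, q = 0.99) {
  stopifnot(q >= 0, q <= 1)
  threshold <- unname(quantile(scores, q, type = 7))
  selected <- which(scores > threshold)
  structure(
    list(
      threshold = threshold, q = q,
      selected = selected, n_selected = length(selected)
    ),
    class = "percentile_selection"
  )
}

#' @export
print.percentile_selection <- function(x, ...) {
  cat(sprintf(
    "quantile %.3g threshold %.4g: %d score(s) strictly above\n",
    x$q, x$threshold, x$n_selected
  ))
  invisible(x)
}

#' Percentile rank of a threshold within a score distribution
#'
#' The percentage of scores less than or equal to `value`; e.g. if 27% of all
#' scores exceed the 0.5 deleteriousness threshold, the threshold sits at the
#' 73rd percentile.
#'
#' @param scores Numeric score vector.
#' @param value Threshold value.
#' @return Percentile rank in `[0, 100]`.
#' @export
percentile_rank <- function(scores, value) {
  100 * mean(scores <= value)
}
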