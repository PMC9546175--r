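#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the generators that emulate the real inputs:
#' miRBase-style hairpin annotation, per-tool score tables, labeled training
#' sets and population VCFs. The defaults reproduce the study conditions of
#' the human miRNA cohort: hairpins of 41-180 nt averaging ~80 nt, mature
#' arms of 16-28 nt, about half of hairpins carrying two annotated matures,
#' an 11% missing-score rate, an SNV density of 71.9/kb, a Ts/Tv ratio of
#' 2.03 and an allele-frequency spectrum placing 73% of the mass at
#' AF <= 0.01%.
#'
#' @param n_hairpins Number of hairpins to generate.
#' @param hairpin_length_range Min/max hairpin length (nt). Lengths are drawn
#'   from a right-skewed Beta distribution over this range with mean ~80 nt.
#' @param mature_length_range Min/max mature length (nt), uniform (mean 22).
#' @param prob_two_matures Probability that a hairpin has two mature arms.
#' @param x_chrom_fraction Fraction of hairpins placed on chromosome X.
#' @param loadings 10 x 3 latent-factor loading matrix inducing the
#'   collinearity among the ten scoring systems.
#' @param noise_sd Standard deviation of the per-tool idiosyncratic noise.
#' @param missing_rate MCAR missingness rate of the score tables.
#' @param d_prime Class separation of labeled sets, in standard deviations
#'   along the first latent factor.
#' @param density_per_kb Target SNV density of population cohorts (SNVs/kb).
#' @param ts_tv Target transition/transversion ratio.
#' @param af_spectrum_spec Tibble (`weight`, `lo`, `hi`) of allele-frequency
#'   mixture components; AF is log-uniform within each component.
#' @param pass_fraction Fraction of population variants with FILTER = PASS.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_hairpins = 100,
                       hairpin_length_range = c(41, 180),
                       mature_length_range = c(16, 28),
                       prob_two_matures = 0.5,
                       x_chrom_fraction = 0.05,
                       loadings = default_loadings(),
                       noise_sd = 0.2,
                       missing_rate = 0.11,
                       d_prime = 6,
                       density_per_kb = 71.9,
                       ts_tv = 2.03,
                       af_spectrum_spec = default_af_spectrum(),
                       pass_fraction = 1.0) {
  stopifnot(
    missing_rate >= 0, missing_rate <= 1,
    prob_two_matures >= 0, prob_two_matures <= 1,
    pass_fraction >= 0, pass_fraction <= 1,
    density_per_kb > 0, ts_tv > 0,
    nrow(loadings) == length(SCORE_TOOLS),
    abs(sum(af_spectrum_spec$weight) - 1) < 1e-8
  )
  structure(
    list(
      n_hairpins = n_hairpins,
      hairpin_length_range = hairpin_length_range,
      mature_length_range = mature_length_range,
      prob_two_matures = prob_two_matures,
      x_chrom_fraction = x_chrom_fraction,
      loadings = loadings,
      noise_sd = noise_sd,
      missing_rate = missing_rate,
      d_prime = d_prime,
      density_per_kb = density_per_kb,
      ts_tv = ts_tv,
      af_spectrum_spec = af_spectrum_spec,
      pass_fraction = pass_fraction
    ),
    class = "sim_config"
  )
}

# Three latent factors: a shared deleteriousness axis loading on every tool,
# a conservation axis on the position-level tools, and a functional-genomics
# axis on four of the allele-level tools.
default_loadings <- function() {
  W <- matrix(0, nrow = length(SCORE_TOOLS), ncol = 3,
    dimnames = list(SCORE_TOOLS, paste0("factor", 1:3)))
  W[, 1] <- 0.8
  W[POSITION_LEVEL_TOOLS, 2] <- 0.5
  W[c("cadd", "remm", "eigen_pc", "funseq"), 3] <- 0.4
  W
}

default_af_spectrum <- function() {
  tibble(
    weight = c(0.73, 0.22, 0.05),
    lo = c(1e-6, 1e-4, 0.1),
    hi = c(1e-4, 0.1, 0.5)
  )
}

sample_hairpin_length <- function(n, range) {
  lo <- range[1]
  hi <- range[2]
  # Beta(2, 5.13) over [lo, hi]: right-skewed, mean ~80 nt for the 41-180 band
  target_mean <- min(80, (lo + hi) / 2)
  m <- (target_mean - lo) / (hi - lo)
  a <- 2
  b <- a * (1 - m) / m
  as.integer(round(lo + (hi - lo) * stats::rbeta(n, a, b)))
}

#' Generate a synthetic miRNA hairpin set
#'
#' Draws hairpins with random sequences and one or two non-overlapping mature
#' arms separated by at least 2 nt, placed 10 kb apart along synthetic
#' chromosomes so the set satisfies every anatomy invariant. Fully
#' reproducible from the seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param lengths Optional integer vector of hairpin lengths overriding the
#'   length distribution (its length then fixes the number of hairpins).
#' @return A hairpin tibble (see [hairpin()]).
#' @export
sim_hairpins <- function(cfg = sim_config(), seed = 1, lengths = NULL) {
  set.seed(seed)
  n <- if (is.null(lengths)) cfg$n_hairpins else length(lengths)
  if (is.null(lengths)) {
    lengths <- sample_hairpin_length(n, cfg$hairpin_length_range)
  }
  n_x <- rbinom(1, n, cfg$x_chrom_fraction)
  chroms <- sample(c(
    rep("chrX", n_x),
    sample(paste0("chr", 1:22), n - n_x, replace = TRUE)
  ))
  mat_lo <- cfg$mature_length_range[1]
  mat_hi <- cfg$mature_length_range[2]
  pos_next <- stats::setNames(rep(10000L, 23), c(paste0("chr", 1:22), "chrX"))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    len <- lengths[i]
    two <- runif(1) < cfg$prob_two_matures
    mats <- NULL
    for (try in 1:50) {
      if (two) {
        m1 <- sample(mat_lo:mat_hi, 1)
        m2 <- sample(mat_lo:mat_hi, 1)
        slack <- len - m1 - m2
        if (slack < 2) next
        pre <- sample(0:(slack - 2), 1)
        gap <- sample(2:(slack - pre), 1)
        mats <- tibble(
          name = paste0("syn-mir-", i, c("-5p", "-3p")),
          offset = c(pre + 1L, pre + m1 + gap + 1L),
          length = c(m1, m2)
        )
      } else {
        m1 <- sample(mat_lo:mat_hi, 1)
        if (m1 > len) next
        mats <- tibble(
          name = paste0("syn-mir-", i, "-5p"),
          offset = sample(seq_len(len - m1 + 1), 1),
          length = m1
        )
      }
      break
    }
    if (is.null(mats)) {
      stop(sprintf("could not place mature arms in a %d nt hairpin", len),
        call. = FALSE)
    }
    chrom <- chroms[i]
    start <- pos_next[[chrom]]
    pos_next[[chrom]] <- start + len + 10000L
    out[[i]] <- hairpin(
      id = paste0("syn-mir-", i), chrom = chrom,
      strand = sample(c("+", "-"), 1),
      start = start, end = start + len - 1L,
      sequence = paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
        collapse = ""
      ),
      matures = mats
    )
  }
  bind_rows(out)
}

#' Generate synthetic score tables for an SNV list
#'
#' Scores are drawn from a latent-factor model: each nucleotide position gets
#' a 3-dimensional latent state and every tool reads it through its loading
#' row plus idiosyncratic noise, reproducing the strong inter-tool
#' collinearity seen among real deleteriousness scores. Position-level tools
#' share one value across the three alternative alleles of a site;
#' allele-level tools add per-allele noise. MCAR holes are punched at the
#' configured missing rate (whole sites at once for position-level tools).
#'
#' @param snvs Tibble of SNVs with columns `chrom, pos, ref, alt`.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A wide tibble (keys + 10 score columns with `NA` holes). The
#'   hole-free matrix is attached as attribute `"complete"`.
#' @export
sim_score_matrix <- function(snvs, cfg = sim_config(), seed = 1) {
  set.seed(seed)
  snvs <- as_tibble(snvs)
  pos_key <- paste(snvs$chrom, snvs$pos)
  upos <- unique(pos_key)
  pidx <- match(pos_key, upos)
  Zp <- matrix(rnorm(length(upos) * 3), ncol = 3)
  W <- cfg$loadings
  n <- nrow(snvs)

  complete <- snvs[c("chrom", "pos", "ref", "alt")]
  for (tool in SCORE_TOOLS) {
    signal <- as.numeric(Zp %*% W[tool, ])
    if (tool %in% POSITION_LEVEL_TOOLS) {
      vals <- (signal + rnorm(length(upos), sd = cfg$noise_sd))[pidx]
    } else {
      vals <- signal[pidx] + rnorm(n, sd = cfg$noise_sd)
    }
    complete[[tool]] <- vals
  }
  out <- complete
  for (tool in SCORE_TOOLS) {
    if (tool %in% POSITION_LEVEL_TOOLS) {
      hole_pos <- runif(length(upos)) < cfg$missing_rate
      out[[tool]][hole_pos[pidx]] <- NA_real_
    } else {
      out[[tool]][runif(n) < cfg$missing_rate] <- NA_real_
    }
  }
  attr(out, "complete") <- complete
  out
}

#' Generate a labeled SNV training set
#'
#' Neutral rows are drawn from the latent-factor score model; deleterious
#' rows are shifted by `cfg$d_prime` standard deviations along the first
#' latent factor, emulating the deleteriousness signal the scoring systems
#' share. Default sizes match the curated training set (24 deleterious, 219
#' neutral, 243 SNVs in total).
#'
#' @param cfg A [sim_config()].
#' @param n_deleterious,n_neutral Class sizes.
#' @param seed Integer seed.
#' @return Tibble with the ten score columns, `autosomal` and `label`.
#' @export
sim_labeled_dataset <- function(cfg = sim_config(), n_deleterious = 24,
                                n_neutral = 219, seed = 1) {
  set.seed(seed)
  n <- n_deleterious + n_neutral
  label <- c(rep(1L, n_deleterious), rep(0L, n_neutral))
  Z <- matrix(rnorm(n * 3), ncol = 3)
  Z[label == 1L, 1] <- Z[label == 1L, 1] + cfg$d_prime
  X <- Z %*% t(cfg$loadings) +
    matrix(rnorm(n * length(SCORE_TOOLS), sd = cfg$noise_sd), ncol = length(SCORE_TOOLS))
  colnames(X) <- SCORE_TOOLS
  out <- as_tibble(X)
  out$autosomal <- runif(n) >= cfg$x_chrom_fraction
  out$label <- label
  out[sample(n), ]
}

#' Generate a synthetic population variant cohort over a hairpin set
#'
#' Variants are placed by independent per-site draws at the configured
#' density over the hairpin nucleotides (and optionally their flanking
#' regions). The alternative allele is a transition with probability
#' `ts_tv / (1 + ts_tv)` and otherwise one of the two transversions, so the
#' cohort hits the target Ts/Tv in expectation; allele frequencies follow the
#' configured mixture spectrum; FILTER is `PASS` for a `pass_fraction` share
#' of records.
#'
#' @param hairpins A hairpin tibble.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param include_flanks If `TRUE`, also place variants over the six 100-nt
#'   flanking regions of each hairpin (with random reference bases), tagged in
#'   the `region_type` column.
#' @return Tibble with `chrom, pos, ref, alt, af, filter, pass_filters,
#'   region_type`.
#' @export
sim_population_vcf <- function(hairpins, cfg = sim_config(), seed = 1,
                               include_flanks = FALSE) {
  set.seed(seed)
  sites <- purrr::map_dfr(seq_len(nrow(hairpins)), function(i) {
    h <- hairpins[i, ]
    offs <- seq_len(nchar(h$sequence))
    ref <- rna_to_dna(strsplit(h$sequence, "")[[1]])
    if (h$strand == "-") ref <- complement_base(ref)
    tibble(
      chrom = h$chrom,
      pos = offset_to_genomic(h$strand, h$start, h$end, offs),
      ref = ref, region_type = "mirna"
    )
  })
  if (include_flanks) {
    fl <- flanking_regions(hairpins)
    flank_sites <- purrr::map_dfr(seq_len(nrow(fl)), function(i) {
      tibble(
        chrom = fl$chrom[i], pos = seq(fl$start[i], fl$end[i]),
        ref = sample(DNA_BASES, fl$end[i] - fl$start[i] + 1, replace = TRUE),
        region_type = paste0("flank_", fl$side[i], "_", fl$rank[i])
      )
    })
    sites <- bind_rows(sites, distinct(flank_sites, .data$chrom, .data$pos,
      .keep_all = TRUE
    ))
  }
  sites <- distinct(sites, .data$chrom, .data$pos, .keep_all = TRUE)
  hit <- runif(nrow(sites)) < cfg$density_per_kb / 1000
  v <- sites[hit, ]
  n <- nrow(v)

  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  is_ts <- runif(n) < cfg$ts_tv / (1 + cfg$ts_tv)
  alt <- character(n)
  alt[is_ts] <- transition_of[v$ref[is_ts]]
  if (any(!is_ts)) {
    alt[!is_ts] <- vapply(v$ref[!is_ts], function(r) {
      sample(setdiff(DNA_BASES, c(r, transition_of[[r]])), 1)
    }, character(1))
  }
  v$alt <- alt

  spec <- cfg$af_spectrum_spec
  comp <- sample.int(nrow(spec), n, replace = TRUE, prob = spec$weight)
  v$af <- exp(runif(n, log(spec$lo[comp]), log(spec$hi[comp])))
  v$filter <- ifelse(runif(n) < cfg$pass_fraction, "PASS", "RF")
  v$pass_filters <- v$filter == "PASS"
  select(
    v, "chrom", "pos", "ref", "alt", "af", "filter",
    "pass_filters", "region_type"
  )
}
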