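#' Write a hairpin set as miRBase-style GFF3 and FASTA
#'
#' Emits one `miRNA_primary_transcript` feature per hairpin and one `miRNA`
#' feature per mature arm (linked by `Derives_from`), plus a FASTA file with
#' the hairpin sequences in hairpin sense (RNA alphabet). The files round-trip
#' through [read_hairpins()].
#'
#' @param hairpins A hairpin tibble.
#' @param gff3_file,fasta_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_hairpins <- function(hairpins, gff3_file, fasta_file) {
  recs <- purrr::map_dfr(seq_len(nrow(hairpins)), function(i) {
    h <- hairpins[i, ]
    m <- h$matures[[1]]
    hp_row <- tibble(
      chrom = h$chrom, start = h$start, end = h$end, strand = h$strand,
      type = "miRNA_primary_transcript", ID = h$id, Name = h$id,
      Derives_from = NA_character_
    )
    if (nrow(m) == 0) {
      return(hp_row)
    }
    gstart <- if (h$strand == "+") {
      h$start + m$offset - 1L
    } else {
      h$end - (m$offset + m$length - 1L) + 1L
    }
    bind_rows(hp_row, tibble(
      chrom = h$chrom, start = gstart, end = gstart + m$length - 1L,
      strand = h$strand, type = "miRNA", ID = m$name, Name = m$name,
      Derives_from = h$id
    ))
  })
  gr <- GenomicRanges::GRanges(
    seqnames = recs$chrom,
    ranges = IRanges::IRanges(recs$start, recs$end),
    strand = recs$strand,
    type = recs$type, ID = recs$ID, Name = recs$Name,
    Derives_from = recs$Derives_from
  )
  rtracklayer::export(gr, gff3_file, format = "gff3")
  seqs <- Biostrings::BStringSet(stats::setNames(hairpins$sequence, hairpins$id))
  Biostrings::writeXStringSet(seqs, fasta_file)
  invisible(c(gff3_file, fasta_file))
}

#' Write and read per-tool score tables
#'
#' One TSV per scoring system: allele-level tools carry
#' `chrom, pos, ref, alt, score`; position-level tools (phyloP, phastCons,
#' LINSIGHT) carry `chrom, pos, score` with one row per site. Rows with
#' missing scores are not written (a hole in the table *is* the missing
#' value). Readers are gzip-tolerant.
#'
#' @param scores Wide score tibble (keys plus the ten tool columns), e.g.
#'   from [sim_score_matrix()].
#' @param dir Directory for the per-tool files (`<tool>.tsv`).
#' @return `write_score_tables` invisibly returns the file paths;
#'   `read_score_tables` returns the named list of tibbles expected by
#'   [assemble_scores()].
#' @export
write_score_tables <- function(scores, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (tool in SCORE_TOOLS) {
    path <- file.path(dir, paste0(tool, ".tsv"))
    if (tool %in% POSITION_LEVEL_TOOLS) {
      tab <- distinct(
        scores[!is.na(scores[[tool]]), c("chrom", "pos", tool)]
      )
    } else {
      tab <- scores[!is.na(scores[[tool]]), c("chrom", "pos", "ref", "alt", tool)]
    }
    names(tab)[names(tab) == tool] <- "score"
    readr::write_tsv(tab, path, progress = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_score_tables
#' @export
read_score_tables <- function(dir) {
  out <- lapply(SCORE_TOOLS, function(tool) {
    path <- file.path(dir, paste0(tool, ".tsv"))
    if (!file.exists(path) && file.exists(paste0(path, ".gz"))) {
      path <- paste0(path, ".gz")
    }
    if (!file.exists(path)) stop("missing score table: ", path, call. = FALSE)
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  })
  stats::setNames(out, SCORE_TOOLS)
}

#' Write population variants as VCF
#'
#' Minimal VCF v4.2 with the allele frequency in `INFO/AF` and the filter
#' status in `FILTER`; round-trips through [read_population_vcf()].
#'
#' @param variants Tibble with `chrom, pos, ref, alt, af, filter`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele Frequency">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      sep = "\t"
    )
  )
  v <- arrange(as_tibble(variants), .data$chrom, .data$pos, .data$alt)
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\tAF=%s",
    v$chrom, as.integer(v$pos), v$ref, v$alt,
    if ("filter" %in% names(v)) v$filter else "PASS",
    sprintf("%.17g", v$af)
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a population VCF into a variant tibble
#'
#' Extracts `chrom, pos, ref, alt`, the `INFO/AF` allele frequency and the
#' filter status (`pass_filters` is `TRUE` for `PASS` records). Multi-allelic
#' records are expanded to one row per alternative allele.
#'
#' @param path Path to a VCF (v4.x, optionally gzipped).
#' @return Tibble with `chrom, pos, ref, alt, af, filter, pass_filters`.
#' @export
read_population_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  af <- vcfR::extract.info(v, "AF")
  out <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    af = af,
    filter = ifelse(is.na(fix$FILTER), ".", fix$FILTER)
  )
  out <- tidyr::separate_rows(out, "alt", "af", sep = ",")
  out$af <- as.numeric(out$af)
  out$pass_filters <- out$filter == "PASS"
  out
}

#' Build labeled training/testing datasets from curated and population SNVs
#'
#' Applies the dataset-construction rules. Under `rule = "dataset1"`:
#' deleterious SNVs are curated variants *absent* from the population cohort;
#' neutral SNVs are high-quality population variants with
#' `AF > af_threshold` not present in the curated list. Under
#' `rule = "dataset2"`: likely deleterious SNVs are curated variants
#' *present* in the population cohort; likely benign SNVs have
#' `AF < af_threshold` and no curated record. Both inequalities are strict,
#' so a variant at exactly the threshold joins neither neutral set, and the
#' two datasets are disjoint by construction. Every excluded input row is
#' written to the audit log with its reason.
#'
#' @param curated Tibble of curated deleterious SNVs with columns
#'   `chrom, pos, ref, alt` (and optionally `source`).
#' @param population Tibble of population variants with `chrom, pos, ref,
#'   alt, af, pass_filters` (see [read_population_vcf()]).
#' @param rule `"dataset1"` or `"dataset2"`.
#' @param af_threshold Allele-frequency cutoff (default 0.10).
#' @param hairpins Optional hairpin tibble; curated entries whose reference
#'   allele mismatches the hairpin sequence are then excluded and logged.
#' @return A list with `dataset` (tibble `chrom, pos, ref, alt, label,
#'   provenance`) and `audit` (tibble of excluded rows with `origin` and
#'   `reason`); `nrow(dataset) + nrow(audit)` equals the number of input rows.
#' @export
build_datasets <- function(curated, population, rule = c("dataset1", "dataset2"),
                           af_threshold = 0.10, hairpins = NULL) {
  rule <- match.arg(rule)
  curated <- as_tibble(curated)
  population <- as_tibble(population)
  if (!"source" %in% names(curated)) curated$source <- "curated"
  ckey <- snv_key(curated$chrom, curated$pos, curated$ref, curated$alt)
  pop_hq <- population[population$pass_filters, ]
  pkey_all <- snv_key(population$chrom, population$pos, population$ref, population$alt)
  pkey <- snv_key(pop_hq$chrom, pop_hq$pos, pop_hq$ref, pop_hq$alt)

  audit <- list()
  cur_ok <- rep(TRUE, nrow(curated))
  if (!is.null(hairpins) && nrow(curated) > 0) {
    loc <- locate_variants(curated, hairpins)
    mism <- unique(snv_key(loc$chrom, loc$pos, loc$ref, loc$alt)[loc$ref_mismatch])
    bad <- ckey %in% mism
    if (any(bad)) {
      audit <- c(audit, list(mutate(curated[bad, c("chrom", "pos", "ref", "alt")],
        origin = "curated", reason = "reference_allele_mismatch"
      )))
      cur_ok <- cur_ok & !bad
    }
  }

  in_pop <- ckey %in% pkey
  if (rule == "dataset1") {
    del_keep <- cur_ok & !in_pop
    del_reason <- "present_in_population"
    neu_keep <- pop_hq$af > af_threshold & !(pkey %in% ckey)
    neu_reason <- ifelse(pkey %in% ckey, "present_in_curated",
      ifelse(pop_hq$af == af_threshold, "af_at_threshold", "af_not_above_threshold")
    )
  } else {
    del_keep <- cur_ok & in_pop
    del_reason <- "absent_from_population"
    neu_keep <- pop_hq$af < af_threshold & !(pkey %in% ckey)
    neu_reason <- ifelse(pkey %in% ckey, "present_in_curated",
      ifelse(pop_hq$af == af_threshold, "af_at_threshold", "af_not_below_threshold")
    )
  }
  if (any(cur_ok & !del_keep)) {
    audit <- c(audit, list(mutate(
      curated[cur_ok & !del_keep, c("chrom", "pos", "ref", "alt")],
      origin = "curated", reason = del_reason
    )))
  }
  if (any(!population$pass_filters)) {
    audit <- c(audit, list(mutate(
      population[!population$pass_filters, c("chrom", "pos", "ref", "alt")],
      origin = "population", reason = "failed_filters"
    )))
  }
  if (any(!neu_keep)) {
    audit <- c(audit, list(mutate(
      pop_hq[!neu_keep, c("chrom", "pos", "ref", "alt")],
      origin = "population", reason = neu_reason[!neu_keep]
    )))
  }

  dataset <- bind_rows(
    mutate(curated[del_keep, c("chrom", "pos", "ref", "alt")],
      label = 1L, provenance = "deleterious-source"
    ),
    mutate(pop_hq[neu_keep, c("chrom", "pos", "ref", "alt")],
      label = 0L, provenance = "neutral-by-frequency"
    )
  )
  list(
    dataset = dataset,
    audit = if (length(audit)) bind_rows(audit) else
      tibble(
        chrom = character(), pos = integer(), ref = character(),
        alt = character(), origin = character(), reason = character()
      )
  )
}

#' Assemble the full per-SNV annotation table
#'
#' Builds one record per possible allelic SNV of the hairpin set: anatomy
#' (hairpin, offset, subregion, HGVS name, cluster flag), the ten raw scores,
#' the meta-predictor score (when a fitted model is supplied), the population
#' allele frequency (when a cohort is supplied, high-quality records only)
#' and optional generic key-joined annotations (e.g. dbSNP identifiers).
#' Output order is deterministic, so identical inputs give byte-identical
#' exports.
#'
#' @param hairpins A hairpin tibble.
#' @param features Complete (imputed) feature tibble from [assemble_scores()]
#'   / [impute_scores()], or `NULL` to omit scores.
#' @param population Optional population variant tibble.
#' @param model Optional fitted [mirlog()] model (requires `features`).
#' @param annotations Optional named list of tibbles keyed by
#'   `chrom, pos, ref, alt` to left-join (a generic stand-in for external
#'   annotation resources).
#' @return A tibble with one row per allelic SNV.
#' @export
build_dbmir <- function(hairpins, features = NULL, population = NULL,
                        model = NULL, annotations = NULL) {
  recs <- enumerate_allelic_snvs(hairpins)
  cl <- cluster_flag(hairpins)
  recs <- left_join(recs, select(cl, hairpin_id = "id", "clustered"),
    by = "hairpin_id"
  )
  if (!is.null(features)) {
    feat_cols <- c("chrom", "pos", "ref", "alt", SCORE_TOOLS, "autosomal")
    recs <- left_join(recs, features[feat_cols],
      by = c("chrom", "pos", "ref", "alt")
    )
    orphan <- dplyr::anti_join(features, recs, by = c("chrom", "pos", "ref", "alt"))
    if (nrow(orphan) > 0) {
      warning(sprintf(
        "%d scored SNV(s) fall outside all hairpins", nrow(orphan)
      ))
    }
    if (!is.null(model)) {
      recs$mirlog <- predict(model, recs)$.pred
    }
  } else if (!is.null(model)) {
    stop("a model requires 'features'", call. = FALSE)
  }
  if (!is.null(population)) {
    pop <- population[population$pass_filters, c("chrom", "pos", "ref", "alt", "af")]
    recs <- left_join(recs, distinct(pop), by = c("chrom", "pos", "ref", "alt"))
  }
  if (!is.null(annotations)) {
    for (ann in annotations) {
      recs <- left_join(recs, as_tibble(ann), by = c("chrom", "pos", "ref", "alt"))
    }
  }
  arrange(recs, .data$hairpin_id, .data$hairpin_offset, .data$alt)
}

#' Write the annotation table as TSV
#'
#' Tab-separated, UTF-8, header row, empty string for missing values;
#' identical tables yield byte-identical files.
#'
#' @param records Tibble from [build_dbmir()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dbmir <- function(records, path) {
  readr::write_tsv(records, path, na = "", progress = FALSE)
  invisible(path)
}

#' Summary statistics bundle for a population cohort over a hairpin set
#'
#' Convenience wrapper computing, from high-quality variants only: the SNV
#' density over the hairpin nucleotides, the Ts/Tv report, the
#' allele-frequency spectrum with its ultra-rare fraction, and the observed
#' fraction of all possible allelic SNVs.
#'
#' @param hairpins A hairpin tibble.
#' @param variants Population variant tibble.
#' @return A list with `density`, `tstv`, `af`, `n_variants`,
#'   `n_possible_snvs`, `observed_fraction`.
#' @export
variability_stats <- function(hairpins, variants) {
  hq <- variants[variants$pass_filters, ]
  inside <- locate_variants(hq, hairpins)
  inside <- distinct(inside, .data$chrom, .data$pos, .data$ref, .data$alt)
  total_nt <- sum(nchar(hairpins$sequence))
  dens <- snv_density(nrow(inside), total_nt, region = "mirna")
  list(
    density = dens,
    tstv = tstv_report(hq),
    af = af_spectrum(hq$af),
    n_variants = nrow(inside),
    n_possible_snvs = 3L * total_nt,
    observed_fraction = nrow(inside) / (3 * total_nt)
  )
}

#' Write a statistics bundle as JSON
#'
#' @param stats A list from [variability_stats()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stats_json <- function(stats, path) {
  obj <- list(
    density_per_kb = stats$density$density,
    n_variants = stats$n_variants,
    n_possible_snvs = stats$n_possible_snvs,
    observed_fraction = stats$observed_fraction,
    ts_tv_ratio = stats$tstv$ts_tv_ratio,
    n_ts = stats$tstv$n_ts,
    n_tv = stats$tstv$n_tv,
    ultra_rare_fraction = stats$af$ultra_rare_fraction
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a labeled SNV dataset TSV
#'
#' @param data Labeled dataset tibble.
#' @param path File path.
#' @return The tibble (readers) or `path` invisibly (writers).
#' @export
write_labeled_dataset <- function(data, path) {
  readr::write_tsv(data, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_labeled_dataset
#' @export
read_labeled_dataset <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
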