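#' Construct a miRNA hairpin table
#'
#' A hairpin table is a tibble with one row per precursor (pre-miRNA): its
#' genomic placement (1-based inclusive coordinates), its sequence written
#' 5'->3' in the RNA alphabet, and a `matures` list-column holding 0-2 mature
#' arms as tibbles with columns `name`, `offset` (1-based start within the
#' hairpin sequence) and `length` (nt).
#'
#' @param id Hairpin identifier, e.g. `"hsa-mir-96"`.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param start,end 1-based inclusive genomic coordinates of the hairpin.
#' @param sequence Hairpin sequence 5'->3' (RNA or DNA alphabet; `T` is
#'   normalized to `U`). Its length must equal `end - start + 1`.
#' @param matures A tibble with columns `name`, `offset`, `length`, or `NULL`
#'   for a hairpin with no annotated mature arm.
#' @return A one-row hairpin tibble.
#' @export
#' @examples
#' hairpin("hp-1", "chr1", "+", 1000, 1069,
#'   paste(rep("ACGU", 18), collapse = ""),
#'   matures = tibble::tibble(name = "hp-1-5p", offset = 10, length = 22)
#' )
hairpin <- function(id, chrom, strand, start, end, sequence, matures = NULL) {
  sequence <- dna_to_rna(sequence)
  if (nchar(sequence) != end - start + 1) {
    stop(sprintf(
      "hairpin '%s': sequence length %d does not match span %d",
      id, nchar(sequence), end - start + 1
    ), call. = FALSE)
  }
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  if (is.null(matures)) {
    matures <- tibble(name = character(), offset = integer(), length = integer())
  }
  matures <- as_tibble(matures)
  if (nrow(matures) > 2) {
    stop(sprintf("hairpin '%s': more than 2 mature arms", id), call. = FALSE)
  }
  if (nrow(matures) > 0) {
    bad <- matures$offset < 1 | matures$offset + matures$length - 1 > nchar(sequence)
    if (any(bad)) {
      stop(sprintf(
        "hairpin '%s': mature arm(s) %s fall outside the hairpin",
        id, paste(matures$name[bad], collapse = ", ")
      ), call. = FALSE)
    }
    if (nrow(matures) == 2) {
      m <- matures[order(matures$offset), ]
      if (m$offset[2] <= m$offset[1] + m$length[1] - 1) {
        stop(sprintf("hairpin '%s': mature arms overlap", id), call. = FALSE)
      }
    }
  }
  tibble(
    id = id, chrom = chrom, strand = strand,
    start = as.integer(start), end = as.integer(end),
    sequence = sequence, matures = list(matures)
  )
}

#' Read miRNA hairpin definitions from GFF3 and FASTA
#'
#' Parses miRBase-style annotation: `miRNA_primary_transcript` features define
#' hairpins and `miRNA` features define mature arms (matched by
#' `Derives_from`, falling back on genomic containment). Sequences are taken
#' from the FASTA keyed by hairpin name; hairpins on the minus strand keep
#' their FASTA sequence, which is already written 5'->3' in hairpin sense, and
#' mature genomic coordinates are converted to hairpin-local offsets
#' respecting the strand.
#'
#' @param gff3_file Path to a GFF3 file (miRBase dialect).
#' @param fasta_file Path to a FASTA file with one record per hairpin.
#' @return A hairpin tibble (see [hairpin()]).
#' @export
read_hairpins <- function(gff3_file, fasta_file) {
  gr <- rtracklayer::import(gff3_file)
  meta <- as.data.frame(gr)
  get_attr <- function(col) {
    if (col %in% names(meta)) as.character(meta[[col]]) else rep(NA_character_, nrow(meta))
  }
  nm <- get_attr("Name")
  ids <- get_attr("ID")
  nm <- ifelse(is.na(nm) | nm == "", ids, nm)
  type <- as.character(meta$type)

  seqs <- Biostrings::readBStringSet(fasta_file)
  # miRBase FASTA headers carry accessions after the name; key on first token
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1)

  hp_idx <- which(type == "miRNA_primary_transcript")
  mat_idx <- which(type == "miRNA")
  if (length(hp_idx) == 0) {
    stop("GFF3 contains no miRNA_primary_transcript features", call. = FALSE)
  }

  derives <- get_attr("Derives_from")
  out <- vector("list", length(hp_idx))
  for (k in seq_along(hp_idx)) {
    i <- hp_idx[k]
    hid <- nm[i]
    if (!hid %in% names(seqs)) {
      stop(sprintf("hairpin '%s' has no FASTA record", hid), call. = FALSE)
    }
    seq_i <- dna_to_rna(as.character(seqs[[hid]]))
    span <- meta$end[i] - meta$start[i] + 1
    if (nchar(seq_i) != span) {
      stop(sprintf(
        "hairpin '%s': FASTA length %d != GFF3 span %d",
        hid, nchar(seq_i), span
      ), call. = FALSE)
    }
    if (span < 41 || span > 180) {
      warning(sprintf("hairpin '%s' length %d outside the usual 41-180 nt band", hid, span))
    }
    own <- mat_idx[!is.na(derives[mat_idx]) & derives[mat_idx] == ids[i]]
    if (length(own) == 0) {
      own <- mat_idx[meta$seqnames[mat_idx] == meta$seqnames[i] &
        meta$start[mat_idx] >= meta$start[i] &
        meta$end[mat_idx] <= meta$end[i] &
        meta$strand[mat_idx] == meta$strand[i]]
    }
    strand_i <- as.character(meta$strand[i])
    mats <- tibble(name = character(), offset = integer(), length = integer())
    if (length(own) > 0) {
      offs <- if (strand_i == "+") {
        meta$start[own] - meta$start[i] + 1L
      } else {
        meta$end[i] - meta$end[own] + 1L
      }
      mats <- tibble(
        name = nm[own],
        offset = as.integer(offs),
        length = as.integer(meta$end[own] - meta$start[own] + 1L)
      )
    }
    out[[k]] <- hairpin(
      hid, as.character(meta$seqnames[i]), strand_i,
      meta$start[i], meta$end[i], seq_i,
      matures = mats
    )
  }
  # matures that match no hairpin are rejected with a warning
  claimed <- unlist(lapply(out, function(h) h$matures[[1]]$name))
  orphan <- setdiff(nm[mat_idx], claimed)
  if (length(orphan) > 0) {
    warning(sprintf(
      "%d mature feature(s) not contained in any hairpin, dropped: %s",
      length(orphan), paste(head(orphan, 5), collapse = ", ")
    ))
  }
  bind_rows(out)
}

#' Assign each hairpin nucleotide to an anatomical subregion
#'
#' Subregions follow the mature-arm anatomy: `seed` covers mature positions
#' 1-8, `rest_of_mature` positions 9 to the mature end. For hairpins with two
#' mature arms the remaining positions split into `loop` (strictly between
#' the arms) and `out_of_loop` (outside both arms); with at most one arm all
#' non-mature positions are `rest_of_premirna`. The returned map is a
#' partition: every offset of every hairpin appears exactly once.
#'
#' @param hairpins A hairpin tibble.
#' @return A tibble with columns `hairpin_id`, `offset`, `region`.
#' @export
assign_subregions <- function(hairpins) {
  purrr::map_dfr(seq_len(nrow(hairpins)), function(i) {
    h <- hairpins[i, ]
    len <- nchar(h$sequence)
    m <- h$matures[[1]]
    region <- rep(NA_character_, len)
    if (nrow(m) > 0 && any(m$length < 8)) {
      stop(sprintf(
        "hairpin '%s': mature arm shorter than 8 nt, seed undefined", h$id
      ), call. = FALSE)
    }
    for (j in seq_len(nrow(m))) {
      o <- m$offset[j]
      region[o:(o + 7)] <- "seed"
      region[(o + 8):(o + m$length[j] - 1)] <- "rest_of_mature"
    }
    if (nrow(m) == 2) {
      ms <- m[order(m$offset), ]
      first_end <- ms$offset[1] + ms$length[1] - 1
      gap <- seq_len(len) > first_end & seq_len(len) < ms$offset[2]
      region[is.na(region) & gap] <- "loop"
      region[is.na(region)] <- "out_of_loop"
    } else {
      region[is.na(region)] <- "rest_of_premirna"
    }
    tibble(hairpin_id = h$id, offset = seq_len(len), region = region)
  })
}

# hairpin-local offset -> genomic position (1-based), respecting strand
# (plain arithmetic so scalar strand recycles over vector offsets)
offset_to_genomic <- function(strand, start, end, offset) {
  plus <- strand == "+"
  as.integer(plus * (start + offset - 1) + (!plus) * (end - offset + 1))
}

genomic_to_offset <- function(strand, start, end, pos) {
  plus <- strand == "+"
  as.integer(plus * (pos - start + 1) + (!plus) * (end - pos + 1))
}

#' Enumerate all possible allelic SNVs of a hairpin set
#'
#' Every nucleotide position admits exactly three single-nucleotide
#' substitutions, so a hairpin of L unambiguous bases yields 3L allelic SNVs.
#' Alleles are reported on the genomic plus strand (`ref`, `alt`, DNA
#' alphabet); positions whose base is ambiguous (`N`) are skipped with a
#' warning. Each SNV carries its hairpin-local offset, subregion label and
#' HGVS-style name. Overlapping hairpins each contribute their own SNVs, so a
#' shared locus is counted once per hairpin.
#'
#' @param hairpins A hairpin tibble.
#' @return A tibble with one row per allelic SNV: `hairpin_id`, `chrom`,
#'   `pos`, `hairpin_offset`, `ref`, `alt`, `region`, `hgvs`.
#' @export
enumerate_allelic_snvs <- function(hairpins) {
  regions <- assign_subregions(hairpins)
  res <- purrr::map_dfr(seq_len(nrow(hairpins)), function(i) {
    h <- hairpins[i, ]
    bases_rna <- strsplit(h$sequence, "")[[1]]
    len <- length(bases_rna)
    keep <- bases_rna %in% c("A", "C", "G", "U")
    if (any(!keep)) {
      warning(sprintf(
        "hairpin '%s': %d ambiguous base(s) skipped", h$id, sum(!keep)
      ))
    }
    offs <- which(keep)
    # genomic plus-strand reference base at each kept offset
    ref_plus <- rna_to_dna(bases_rna[offs])
    if (h$strand == "-") ref_plus <- complement_base(ref_plus)
    alt_list <- lapply(ref_plus, function(r) setdiff(DNA_BASES, r))
    tibble(
      hairpin_id = h$id,
      chrom = h$chrom,
      pos = rep(offset_to_genomic(h$strand, h$start, h$end, offs), each = 3L),
      hairpin_offset = rep(offs, each = 3L),
      ref = rep(ref_plus, each = 3L),
      alt = unlist(alt_list),
      strand = h$strand
    )
  })
  res <- left_join(res, regions,
    by = c("hairpin_id" = "hairpin_id", "hairpin_offset" = "offset")
  )
  res$hgvs <- hgvs_name(
    res$hairpin_id, res$hairpin_offset, res$ref, res$alt, res$strand
  )
  select(res, -"strand")
}

#' HGVS-style name for a noncoding-RNA substitution
#'
#' Builds names of the form `"<hairpin_id>:n.<offset><ref>><alt>"` with
#' 1-based hairpin-local offsets and RNA-sense alleles: genomic plus-strand
#' alleles are complemented for minus-strand hairpins and written with `U`
#' instead of `T`.
#'
#' @param hairpin_id Hairpin identifier(s).
#' @param offset 1-based position(s) within the hairpin sequence.
#' @param ref,alt Genomic plus-strand alleles (DNA alphabet).
#' @param strand Hairpin strand, `"+"` or `"-"`.
#' @return Character vector of HGVS-style names.
#' @export
#' @examples
#' hgvs_name("hsa-mir-x", 34, "A", "G", "+")
hgvs_name <- function(hairpin_id, offset, ref, alt, strand) {
  ref_s <- ifelse(strand == "-", complement_base(ref), toupper(ref))
  alt_s <- ifelse(strand == "-", complement_base(alt), toupper(alt))
  paste0(hairpin_id, ":n.", offset, dna_to_rna(ref_s), ">", dna_to_rna(alt_s))
}

#' Parse an HGVS-style noncoding-RNA substitution name
#'
#' Inverse of [hgvs_name()]: recovers the hairpin id, offset and RNA-sense
#' alleles from names like `"hsa-mir-x:n.34A>G"`.
#'
#' @param hgvs Character vector of names.
#' @return A tibble with columns `hairpin_id`, `offset`, `ref`, `alt`
#'   (RNA-sense alleles).
#' @export
parse_hgvs <- function(hgvs) {
  m <- stringr::str_match(hgvs, "^(.*):n\\.(\\d+)([ACGU])>([ACGU])$")
  if (any(is.na(m[, 1]))) {
    stop("malformed HGVS name(s): ",
      paste(head(hgvs[is.na(m[, 1])], 3), collapse = ", "),
      call. = FALSE
    )
  }
  tibble(
    hairpin_id = m[, 2], offset = as.integer(m[, 3]),
    ref = m[, 4], alt = m[, 5]
  )
}

#' Locate genomic variants within a hairpin set
#'
#' Annotates each (chrom, pos, ref, alt) record with every hairpin it falls
#' in (hairpins may overlap, giving several rows per variant); variants
#' outside all hairpins are dropped. A `ref_mismatch` flag marks records
#' whose stated reference allele disagrees with the hairpin sequence.
#'
#' @param variants A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param hairpins A hairpin tibble.
#' @return A tibble of located variants with `hairpin_id`, `hairpin_offset`,
#'   `region`, `hgvs` and `ref_mismatch` columns.
#' @export
locate_variants <- function(variants, hairpins) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (!all(toupper(variants$ref) %in% DNA_BASES & toupper(variants$alt) %in% DNA_BASES)) {
    stop("malformed alleles: ref/alt must be single bases in {A,C,G,T}", call. = FALSE)
  }
  regions <- assign_subregions(hairpins)
  out <- purrr::map_dfr(seq_len(nrow(hairpins)), function(i) {
    h <- hairpins[i, ]
    hit <- variants$chrom == h$chrom & variants$pos >= h$start & variants$pos <= h$end
    if (!any(hit)) {
      return(NULL)
    }
    v <- variants[hit, ]
    v$hairpin_id <- h$id
    v$hairpin_offset <- genomic_to_offset(h$strand, h$start, h$end, v$pos)
    seq_bases <- strsplit(h$sequence, "")[[1]]
    ref_plus <- rna_to_dna(seq_bases[v$hairpin_offset])
    if (h$strand == "-") ref_plus <- complement_base(ref_plus)
    v$ref_mismatch <- toupper(v$ref) != ref_plus
    v$hgvs <- hgvs_name(h$id, v$hairpin_offset, v$ref, v$alt, h$strand)
    v
  })
  if (nrow(out) == 0) {
    return(mutate(variants[0, ],
      hairpin_id = character(), hairpin_offset = integer(),
      ref_mismatch = logical(), hgvs = character(), region = character()
    ))
  }
  left_join(out, regions,
    by = c("hairpin_id" = "hairpin_id", "hairpin_offset" = "offset")
  )
}

#' Flag hairpins located in a putative miRNA cluster
#'
#' A hairpin is flagged as clustered when another hairpin on the same
#' chromosome overlaps it or lies within `window` nucleotides of its span.
#'
#' @param hairpins A hairpin tibble.
#' @param window Flanking distance in nucleotides (default 200).
#' @return The hairpin tibble with a logical `clustered` column.
#' @export
cluster_flag <- function(hairpins, window = 200) {
  n <- nrow(hairpins)
  flag <- logical(n)
  for (i in seq_len(n)) {
    same <- hairpins$chrom == hairpins$chrom[i] & seq_len(n) != i
    if (!any(same)) next
    gap <- pmax(
      0L,
      pmax(hairpins$start[same], hairpins$start[i]) -
        pmin(hairpins$end[same], hairpins$end[i]) - 1L
    )
    flag[i] <- any(gap <= window)
  }
  mutate(hairpins, clustered = flag)
}

#' Non-overlapping flanking regions around each hairpin
#'
#' Returns `count` contiguous upstream and `count` downstream genomic
#' intervals of exactly `width` nt each, adjacent to the hairpin span and
#' never overlapping it. Rank 1 is nearest to the hairpin. Intervals that
#' would extend past the chromosome start are truncated or dropped with a
#' warning.
#'
#' @param hairpins A hairpin tibble.
#' @param width Interval width in nucleotides (default 100).
#' @param count Number of intervals per side (default 3).
#' @return A tibble with `hairpin_id`, `side`, `rank`, `chrom`, `start`, `end`.
#' @export
flanking_regions <- function(hairpins, width = 100, count = 3) {
  out <- purrr::map_dfr(seq_len(nrow(hairpins)), function(i) {
    h <- hairpins[i, ]
    up <- tibble(
      hairpin_id = h$id, side = "upstream", rank = seq_len(count),
      chrom = h$chrom,
      start = h$start - width * seq_len(count),
      end = h$start - width * (seq_len(count) - 1L) - 1L
    )
    down <- tibble(
      hairpin_id = h$id, side = "downstream", rank = seq_len(count),
      chrom = h$chrom,
      start = h$end + width * (seq_len(count) - 1L) + 1L,
      end = h$end + width * seq_len(count)
    )
    bind_rows(up, down)
  })
  clipped <- out$start < 1
  if (any(clipped)) {
    warning(sprintf(
      "%d flanking region(s) truncated or dropped at chromosome start",
      sum(clipped)
    ))
    out$start[clipped] <- 1L
    out <- out[out$end >= out$start, ]
  }
  out
}
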