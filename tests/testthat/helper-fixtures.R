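# Small in-code fixtures shared across test files.

# A plus-strand hairpin: chr1:1000-1079, mature at chr1:1009-1030
# (hairpin-local offset 10, length 22).
fixture_plus_hairpin <- function() {
  hairpin(
    id = "hp-plus", chrom = "chr1", strand = "+",
    start = 1000, end = 1079,
    sequence = paste(rep("ACGU", 20), collapse = ""),
    matures = tibble::tibble(name = "hp-plus-5p", offset = 10, length = 22)
  )
}

# Two-mature hairpin of length 70 with matures at offsets 10-31 and 40-61.
fixture_two_mature_hairpin <- function() {
  hairpin(
    id = "hp-two", chrom = "chr2", strand = "+",
    start = 5000, end = 5069,
    sequence = paste(rep("GUCA", 70 / 4 + 1), collapse = "") |> substr(1, 70),
    matures = tibble::tibble(
      name = c("hp-two-5p", "hp-two-3p"),
      offset = c(10, 40), length = c(22, 22)
    )
  )
}

# Write a miRBase-style GFF3 + FASTA by hand (independent of write_hairpins)
# so read_hairpins is tested against a hand-built oracle file.
write_fixture_mirbase_files <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("mirbase-fixture-")
    dir.create(dir)
  }
  gff <- file.path(dir, "mirna.gff3")
  fa <- file.path(dir, "mirna.fa")
  seq_plus <- paste(rep("ACGU", 20), collapse = "")   # 80 nt
  seq_minus <- paste(rep("GGCU", 20), collapse = "")  # 80 nt
  writeLines(c(
    "##gff-version 3",
    paste("chr1", "test", "miRNA_primary_transcript", "1000", "1079", ".", "+",
      ".", "ID=MI001;Name=fix-mir-1",
      sep = "\t"
    ),
    paste("chr1", "test", "miRNA", "1009", "1030", ".", "+", ".",
      "ID=MIMAT001;Name=fix-miR-1-5p;Derives_from=MI001",
      sep = "\t"
    ),
    paste("chr1", "test", "miRNA_primary_transcript", "2000", "2079", ".", "-",
      ".", "ID=MI002;Name=fix-mir-2",
      sep = "\t"
    ),
    paste("chr1", "test", "miRNA", "2050", "2071", ".", "-", ".",
      "ID=MIMAT002;Name=fix-miR-2-3p;Derives_from=MI002",
      sep = "\t"
    )
  ), gff)
  writeLines(c(
    ">fix-mir-1 MI001 Homo sapiens fix-mir-1 stem-loop", seq_plus,
    ">fix-mir-2 MI002 Homo sapiens fix-mir-2 stem-loop", seq_minus
  ), fa)
  list(gff3 = gff, fasta = fa, seq_plus = seq_plus, seq_minus = seq_minus)
}

# Complete wide score tibble for a set of SNV keys, values deterministic.
fixture_scores_for <- function(snvs, seed = 1) {
  set.seed(seed)
  out <- snvs[c("chrom", "pos", "ref", "alt")]
  for (tool in score_tools()) out[[tool]] <- rnorm(nrow(out))
  for (tool in score_tools(position_level = TRUE)) {
    key <- paste(out$chrom, out$pos)
    out[[tool]] <- out[[tool]][match(key, key)]
  }
  out
}

# Brute-force AUC over all (positive, negative) pairs; ties count half.
auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
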