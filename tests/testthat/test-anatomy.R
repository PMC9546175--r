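test_that("read_hairpins converts mature coordinates to hairpin-local offsets on both strands", {
  fx <- write_fixture_mirbase_files()
  h <- read_hairpins(fx$gff3, fx$fasta)

  expect_equal(nrow(h), 2)
  plus <- h[h$id == "fix-mir-1", ]
  m <- plus$matures[[1]]
  expect_equal(m$offset, 10L) # chr1:1009 in a hairpin starting at 1000
  expect_equal(m$length, 22L)
  expect_equal(plus$sequence, fx$seq_plus)

  minus <- h[h$id == "fix-mir-2", ]
  m2 <- minus$matures[[1]]
  # minus strand: offset counts from the genomic end (2079 - 2071 + 1 = 9)
  expect_equal(m2$offset, 9L)
  expect_equal(m2$length, 22L)
})

test_that("read_hairpins rejects mismatched records and orphan matures", {
  fx <- write_fixture_mirbase_files()
  # truncate one FASTA record -> hard error naming it
  lines <- readLines(fx$fasta)
  lines[2] <- substr(lines[2], 1, 50)
  bad_fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(lines, bad_fa)
  expect_error(read_hairpins(fx$gff3, bad_fa), "fix-mir-1")

  # a mature feature outside every hairpin is dropped with a warning
  gff_lines <- readLines(fx$gff3)
  gff_lines <- c(gff_lines, paste("chr9", "test", "miRNA", "100", "121", ".",
    "+", ".", "ID=MIMAT999;Name=orphan-miR",
    sep = "\t"
  ))
  bad_gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff_lines, bad_gff)
  expect_warning(read_hairpins(bad_gff, fx$fasta), "orphan-miR")
})

test_that("subregion assignment partitions the hairpin per the anatomy rules", {
  h2 <- fixture_two_mature_hairpin()
  sr <- assign_subregions(h2)
  expect_equal(nrow(sr), 70)
  expect_equal(sr$region[10:17], rep("seed", 8))
  expect_equal(sr$region[40:47], rep("seed", 8))
  expect_equal(sr$region[18:31], rep("rest_of_mature", 14))
  expect_equal(sr$region[32:39], rep("loop", 8))
  expect_equal(sr$region[c(1:9, 62:70)], rep("out_of_loop", 18))

  # single mature, length 80, mature 5-26
  h1 <- hairpin("hp-one", "chr3", "+", 1, 80,
    paste(rep("A", 80), collapse = ""),
    matures = tibble::tibble(name = "m", offset = 5, length = 22)
  )
  sr1 <- assign_subregions(h1)
  expect_equal(sr1$region[5:12], rep("seed", 8))
  expect_equal(sr1$region[13:26], rep("rest_of_mature", 14))
  expect_true(all(sr1$region[c(1:4, 27:80)] == "rest_of_premirna"))

  # partition property: every offset exactly once, lengths sum to hairpin length
  both <- dplyr::bind_rows(h1, h2)
  sr_all <- assign_subregions(both)
  counts <- table(sr_all$hairpin_id)
  expect_equal(as.integer(counts[c("hp-one", "hp-two")]), c(80L, 70L))
  expect_false(any(duplicated(sr_all[c("hairpin_id", "offset")])))

  # a mature shorter than the 8-nt seed is rejected
  h_bad <- hairpin("hp-bad", "chr3", "+", 1, 50,
    paste(rep("A", 50), collapse = ""),
    matures = tibble::tibble(name = "m", offset = 5, length = 6)
  )
  expect_error(assign_subregions(h_bad), "seed")
})

test_that("subregion labels are strand-independent in hairpin-local coordinates", {
  seq70 <- paste(sample(c("A", "C", "G", "U"), 70, replace = TRUE), collapse = "")
  mats <- tibble::tibble(
    name = c("a", "b"), offset = c(10, 40), length = c(22, 22)
  )
  hp <- hairpin("hp-p", "chr1", "+", 100, 169, seq70, mats)
  hm <- hairpin("hp-m", "chr1", "+", 100, 169, seq70, mats)
  hm$strand <- "-"
  expect_equal(assign_subregions(hp)$region, assign_subregions(hm)$region)
})

test_that("allelic SNV enumeration yields 3 unique substitutions per unambiguous base", {
  h <- hairpin("hp5", "chr1", "+", 101, 105, "ACGUG")
  withr::local_seed(1)
  snvs <- enumerate_allelic_snvs(h)
  expect_equal(nrow(snvs), 15)
  expect_true(all(snvs$ref != snvs$alt))
  expect_false(any(duplicated(snvs[c("chrom", "pos", "alt")])))
  expect_equal(snvs$ref[snvs$pos == 101][1], "A")
  expect_setequal(snvs$alt[snvs$pos == 101], c("C", "G", "T"))

  # ambiguous base skipped, count adjusted
  hn <- hairpin("hpN", "chr1", "+", 101, 105, "ACNUG")
  expect_warning(snvs_n <- enumerate_allelic_snvs(hn), "ambiguous")
  expect_equal(nrow(snvs_n), 12)

  # minus strand: genomic plus-strand ref is the complement of the hairpin base
  hm <- hairpin("hpM", "chr1", "-", 101, 105, "ACGUG")
  sm <- enumerate_allelic_snvs(hm)
  # hairpin offset 1 ("A") sits at genomic pos 105 with plus-strand ref "T"
  expect_equal(unique(sm$ref[sm$pos == 105]), "T")

  # size property over a generated set
  hs <- sim_hairpins(sim_config(n_hairpins = 8), seed = 4)
  expect_equal(nrow(enumerate_allelic_snvs(hs)), 3 * sum(nchar(hs$sequence)))
})

test_that("HGVS naming uses RNA-sense alleles and round-trips", {
  expect_equal(hgvs_name("hsa-mir-x", 34, "A", "G", "+"), "hsa-mir-x:n.34A>G")
  # minus strand: genomic C>T reads G>A in hairpin sense
  expect_equal(hgvs_name("hsa-mir-x", 12, "C", "T", "-"), "hsa-mir-x:n.12G>A")
  # plus strand T becomes U
  expect_equal(hgvs_name("hsa-mir-x", 3, "T", "A", "+"), "hsa-mir-x:n.3U>A")

  h <- sim_hairpins(sim_config(n_hairpins = 5), seed = 2)
  snvs <- enumerate_allelic_snvs(h)
  parsed <- parse_hgvs(snvs$hgvs)
  expect_equal(parsed$hairpin_id, snvs$hairpin_id)
  expect_equal(parsed$offset, snvs$hairpin_offset)
  # parsed alleles are RNA-sense: re-derive them from the genomic alleles
  strand <- h$strand[match(snvs$hairpin_id, h$id)]
  renamed <- hgvs_name(snvs$hairpin_id, snvs$hairpin_offset, snvs$ref, snvs$alt, strand)
  expect_equal(renamed, snvs$hgvs)
  expect_error(parse_hgvs("not-a-name"), "malformed")
})

test_that("locate_variants annotates overlapping hairpins and flags ref mismatches", {
  h1 <- fixture_plus_hairpin() # chr1:1000-1079, seq ACGUACGU... (offset 10 = C)
  v <- tibble::tibble(chrom = "chr1", pos = 1009, ref = "C", alt = "G")
  loc <- locate_variants(v, h1)
  expect_equal(nrow(loc), 1)
  expect_equal(loc$hairpin_offset, 10L)
  expect_equal(loc$region, "seed")
  expect_false(loc$ref_mismatch)

  outside <- tibble::tibble(chrom = "chr1", pos = 5, ref = "A", alt = "G")
  expect_equal(nrow(locate_variants(outside, h1)), 0)

  # two hairpins sharing a locus -> two entries
  h_ov <- dplyr::bind_rows(
    h1,
    hairpin("hp-ov", "chr1", "+", 1050, 1129, paste(rep("ACGU", 20), collapse = ""))
  )
  v2 <- tibble::tibble(chrom = "chr1", pos = 1060, ref = "C", alt = "T")
  expect_equal(nrow(locate_variants(v2, h_ov)), 2)

  # hairpin base at 1009 is C on the plus strand; claiming ref A is a mismatch
  v3 <- tibble::tibble(chrom = "chr1", pos = 1009, ref = "A", alt = "T")
  expect_true(locate_variants(v3, h1)$ref_mismatch)

  bad <- tibble::tibble(chrom = "chr1", pos = 1009, ref = "AT", alt = "G")
  expect_error(locate_variants(bad, h1), "malformed")
})

test_that("cluster flag obeys the 200-nt window", {
  mk <- function(id, start, end) hairpin(id, "chr1", "+", start, end,
    paste(rep("A", end - start + 1), collapse = ""))
  near <- dplyr::bind_rows(mk("a", 1000, 1100), mk("b", 1251, 1350)) # 150 nt apart
  expect_true(all(cluster_flag(near)$clustered))
  far <- dplyr::bind_rows(mk("a", 1000, 1100), mk("b", 1351, 1450)) # 250 nt apart
  expect_false(any(cluster_flag(far)$clustered))
  ov <- dplyr::bind_rows(mk("a", 1000, 1100), mk("b", 1050, 1150))
  expect_true(all(cluster_flag(ov)$clustered))
  # window boundary is inclusive
  edge <- dplyr::bind_rows(mk("a", 1000, 1100), mk("b", 1301, 1400)) # exactly 200
  expect_true(all(cluster_flag(edge)$clustered))
})

test_that("flanking regions tile 3 x 100 nt on each side without touching the hairpin", {
  h <- hairpin("hp", "chr1", "+", 1000, 1080,
    paste(rep("A", 81), collapse = ""))
  fl <- flanking_regions(h)
  up <- fl[fl$side == "upstream", ]
  expect_equal(up$start, c(900L, 800L, 700L))
  expect_equal(up$end, c(999L, 899L, 799L))
  down <- fl[fl$side == "downstream", ]
  expect_equal(down$start, c(1081L, 1181L, 1281L))
  expect_equal(down$end, c(1180L, 1280L, 1380L))
  expect_equal(sum(fl$end - fl$start + 1), 600)
  expect_true(all(fl$end < 1000 | fl$start > 1080))

  near_start <- hairpin("hp2", "chr1", "+", 150, 230,
    paste(rep("A", 81), collapse = ""))
  expect_warning(fl2 <- flanking_regions(near_start), "truncated")
  expect_true(all(fl2$start >= 1))
})
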