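test_that("NG86 site counts match hand enumeration and sum to 3", {
  expect_equal(ng86_site_counts("TTT"), c(S = 1 / 3, N = 8 / 3))
  expect_equal(ng86_site_counts("GGG"), c(S = 1, N = 2))
  expect_equal(ng86_site_counts("ATG"), c(S = 0, N = 3))
  expect_error(ng86_site_counts("TAA"), "stop")
  expect_error(ng86_site_counts("NNN"), "invalid")

  code <- Biostrings::GENETIC_CODE
  for (cod in names(code)[code != "*"]) {
    sn <- ng86_site_counts(cod)
    expect_equal(unname(sn[["S"]] + sn[["N"]]), 3, info = cod)
  }
})

test_that("the worked NG86 + Jukes-Cantor pair reproduces the hand computation", {
  r <- ng86_pairwise("TTTAAAGGG", "TTCAAAGGG")
  expect_equal(r$S_sites, 5 / 3, tolerance = 1e-12)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$ps, 0.6, tolerance = 1e-12)
  expect_equal(r$ds, -0.75 * log(0.2), tolerance = 1e-12)
  expect_equal(r$dn, 0)
  expect_equal(r$ratio, 0)

  ident <- ng86_pairwise("TTTAAAGGG", "TTTAAAGGG")
  expect_equal(ident$Sd + ident$Nd, 0)
  expect_true(is.na(ident$ratio))
})

test_that("pathway-averaged differences match the brute-force path enumerator", {
  set.seed(21)
  for (k in 1:80) {
    c1 <- random_sense_codon(); c2 <- random_sense_codon()
    d <- g4telo:::ng86_path_diffs(c1, c2)
    oracle <- oracle_path_diffs(c1, c2)
    expect_equal(unname(d[["Sd"]]), oracle[1], info = paste(c1, c2))
    expect_equal(unname(d[["Nd"]]), oracle[2], info = paste(c1, c2))
  }
  # embedded in a longer pair so the Jukes-Cantor step stays defined
  set.seed(22)
  pad <- strrep("ATGGCT", 10)
  for (k in 1:20) {
    c1 <- random_sense_codon(); c2 <- random_sense_codon()
    oracle <- oracle_path_diffs(c1, c2)
    r <- ng86_pairwise(paste0(pad, c1), paste0(pad, c2))
    if (anyNA(oracle)) {
      expect_equal(r$n_skipped, 1L)
    } else {
      expect_equal(r$Sd, oracle[1], info = paste(c1, c2))
      expect_equal(r$Nd, oracle[2], info = paste(c1, c2))
    }
  }
})

test_that("gapped and N codon pairs are skipped, not counted", {
  r <- ng86_pairwise("TTTAAAGGG---", "TTCAAAGGGAAA")
  expect_equal(r$n_codons, 3L)
  expect_equal(r$n_skipped, 1L)
  expect_equal(r$ps, 0.6, tolerance = 1e-12)
  rn <- ng86_pairwise("TTTAAAGGGANA", "TTCAAAGGGAAA")
  expect_equal(rn$n_codons, 3L)
  expect_equal(rn$n_skipped, 1L)
})

test_that("Jukes-Cantor correction is monotone and saturates at 3/4", {
  p <- seq(0, 0.7, 0.05)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(d) > 0))
  # saturation raises an error through the pairwise interface
  long1 <- strrep("AAA", 30)
  long2 <- strrep("AAG", 30)   # every codon pair differs synonymously
  expect_error(ng86_pairwise(long1, long2), "saturation")
})

test_that("two-row alignments reduce to the single pairwise result", {
  cm <- structure(list(ids = c("a", "b"),
                       aa = c("FKG", "FKG"),
                       dna = c("TTTAAAGGG", "TTCAAAGGG")), class = "codon_msa")
  d <- dnds_alignment(cm)
  r <- ng86_pairwise("TTTAAAGGG", "TTCAAAGGG")
  expect_equal(d$mean_ds, r$ds)
  expect_equal(d$mean_dn, r$dn)
  expect_equal(d$mean_ratio, r$ratio)
  expect_equal(d$n_pairs, 1L)

  # identical rows: all-zero means, ratios excluded
  cm3 <- structure(list(ids = c("a", "b", "c"),
                        aa = rep("FKG", 3),
                        dna = rep("TTTAAAGGG", 3)), class = "codon_msa")
  d3 <- dnds_alignment(cm3)
  expect_equal(d3$mean_ds, 0)
  expect_equal(d3$mean_dn, 0)
  expect_equal(d3$n_ratio_excluded, 3L)
})

test_that("delta-GC is measured against the full synonymous family", {
  # proline family {CCT, CCC, CCA, CCG}: mean GC = 10/12
  expect_equal(synonymous_family_gc("P"), 10 / 12)
  expect_equal(delta_gc("CCG"), 1 - 10 / 12, tolerance = 1e-12)
  expect_equal(delta_gc("ATG"), 0)   # single-codon family
  expect_error(delta_gc("TGA"), "stop")

  # family mean of delta-GC is exactly zero for every amino acid
  code <- Biostrings::GENETIC_CODE
  for (aa in setdiff(unique(code), "*")) {
    fam <- names(code)[code == aa]
    expect_equal(mean(delta_gc(fam)), 0, tolerance = 1e-12, info = aa)
  }
})

test_that("codons are assigned to the PQS set by >= 1 bp overlap", {
  cds <- strrep("ATGAAACCC", 10)   # 30 codons
  part <- partition_by_pqs(cds, data.frame(start = 9L, end = 33L))
  expect_equal(part$index[part$in_pqs], 3:10)
  # PQS ending mid-codon claims that codon
  part2 <- partition_by_pqs(cds, data.frame(start = 9L, end = 31L))
  expect_equal(part2$index[part2$in_pqs], 3:10)
  # partition is exhaustive and disjoint
  expect_equal(sum(part$in_pqs) + sum(!part$in_pqs), 30L)
  part3 <- partition_by_pqs(cds, NULL)
  expect_false(any(part3$in_pqs))
})

test_that("codon position stats report C3 and amino-acid usage ratios", {
  pqs <- c("TTC", "AAC", "GGC", "CCC")          # all end in C
  non <- c("TTC", "AAC", "GGA", "CCA")          # half end in C
  st <- codon_position_stats(pqs, non)
  expect_equal(st$C3_ratio, 2.0)

  st2 <- codon_position_stats(pqs, pqs)
  expect_equal(st2$C3_ratio, 1.0)
  expect_true(all(st2$aa_freq$ratio == 1.0))

  # zero denominator -> Inf sentinel with counts intact
  st3 <- codon_position_stats(c("CCC", "AAA"), c("AAA", "AAA"))
  pro <- st3$aa_freq[st3$aa_freq$aa == "P", ]
  expect_true(is.infinite(pro$ratio))
  expect_equal(pro$n_pqs, 1L)
  expect_error(codon_position_stats(character(0), "AAA"), "non-empty")
})
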