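mk_hits <- function(start, end, strand, seqid = "chr1") {
  data.frame(seqid = seqid, start = start, end = end, strand = strand,
             type = "PQS", score = 60L, stringsAsFactors = FALSE)
}
mk_repeats <- function(start, end, strand, family, seqid = "chr1", ...) {
  data.frame(seqid = seqid, start = start, end = end, strand = strand,
             type = "repeat", family = family, ..., stringsAsFactors = FALSE)
}

test_that("relative orientation is sense iff PQS and repeat strands agree", {
  reps <- mk_repeats(0L, 5000L, "+", "HetA")
  ix <- intersect_pqs_repeats(mk_hits(100L, 130L, "+"), reps)
  expect_equal(ix$records$relative_orientation, "sense")
  expect_equal(ix$records$overlap_bp, 30L)

  reps$strand <- "-"
  ix2 <- intersect_pqs_repeats(mk_hits(100L, 130L, "+"), reps)
  expect_equal(ix2$records$relative_orientation, "antisense")
})

test_that("a PQS straddling two repeats yields two records covering its length", {
  reps <- mk_repeats(c(0L, 1000L), c(1000L, 2000L), "+", c("HetA", "TART"))
  ix <- intersect_pqs_repeats(mk_hits(985L, 1015L, "+"), reps)
  expect_equal(nrow(ix$records), 2L)
  expect_equal(sum(ix$records$overlap_bp), 30L)
  expect_equal(nrow(ix$unassigned), 0L)

  # a hit outside every repeat is unassigned
  ix3 <- intersect_pqs_repeats(mk_hits(c(100L, 5000L), c(130L, 5030L), "+"),
                               mk_repeats(0L, 1000L, "+", "HetA"))
  expect_equal(nrow(ix3$records), 1L)
  expect_equal(nrow(ix3$unassigned), 1L)
  expect_equal(ix3$unassigned$start, 5000L)
})

test_that("orientation_summary fills the strand x orientation grid", {
  reps <- mk_repeats(rep(0L, 1), 5000L, "-", "HetA")
  ix <- intersect_pqs_repeats(mk_hits(c(100L, 300L, 500L), c(130L, 330L, 530L),
                                      c("+", "+", "+")), reps)
  s <- orientation_summary(ix$records)
  expect_equal(sum(s$n), 3L)
  expect_equal(s$n[s$repeat_strand == "-" & s$orientation == "antisense"], 3L)
  expect_true(all(s$n[!(s$repeat_strand == "-" & s$orientation == "antisense")] == 0L))

  # label equivariance: flipping every strand permutes the counts
  reps2 <- reps; reps2$strand <- "+"
  ix2 <- intersect_pqs_repeats(mk_hits(c(100L, 300L, 500L), c(130L, 330L, 530L),
                                       c("-", "-", "-")), reps2)
  s2 <- orientation_summary(ix2$records)
  expect_equal(s2$n[s2$repeat_strand == "+" & s2$orientation == "antisense"], 3L)
})

test_that("density counts midpoints per 10 kbp with N bases removed", {
  region <- data.frame(seqid = "chr1", start = 0L, end = 10000L)
  h <- mk_hits(seq(1000L, 9000L, 2000L), seq(1030L, 9030L, 2000L), "+")
  expect_equal(pqs_density(h, region), 5.0)

  region2 <- data.frame(seqid = "chr1", start = 0L, end = 20000L)
  mask <- data.frame(seqid = "chr1", start = 10000L, end = 20000L, strand = ".")
  expect_equal(pqs_density(h, region2, mask), 5.0)
  expect_error(pqs_density(h, data.frame(seqid = "chr1", start = 0L, end = 10000L),
                           data.frame(seqid = "chr1", start = 0L, end = 10000L,
                                      strand = ".")),
               "undefined density")

  # translation invariance
  h_shift <- h; h_shift$start <- h$start + 5000L; h_shift$end <- h$end + 5000L
  region_shift <- data.frame(seqid = "chr1", start = 5000L, end = 15000L)
  expect_equal(pqs_density(h_shift, region_shift), pqs_density(h, region))
})

test_that("bp_proportion normalizes PQS bp by PQS-containing fragment length", {
  frags <- mk_repeats(c(0L, 2000L, 4000L), c(1000L, 3000L, 5000L), "+",
                      c("HetA", "HetA", "TART"))
  # one 30-bp PQS in fragment 1, nothing in fragment 2 (HetA), none in TART
  ix <- intersect_pqs_repeats(mk_hits(100L, 130L, "+"), frags)
  bp <- bp_proportion(ix$records, frags)
  expect_equal(bp$family, "HetA")
  expect_equal(bp$percent, 3.0)
  expect_equal(bp$n_fragments, 1L)      # the PQS-free fragment is excluded
  expect_false("TART" %in% bp$family)   # family with no PQS fragment excluded

  # two fragments, one with a 50-bp PQS: 50/1000 = 5%
  ix2 <- intersect_pqs_repeats(mk_hits(100L, 150L, "+"), frags)
  expect_equal(bp_proportion(ix2$records, frags)$percent, 5.0)
})

test_that("bp_proportion equals a direct interval-sum recomputation", {
  set.seed(77)
  frags <- mk_repeats(seq(0L, 18000L, 2000L), seq(1500L, 19500L, 2000L), "+",
                      sample(c("A", "B"), 10, replace = TRUE))
  starts <- sort(sample.int(19000L, 25L))
  hits <- mk_hits(starts, starts + 25L, "+")
  ix <- intersect_pqs_repeats(hits, frags)
  bp <- bp_proportion(ix$records, frags)
  for (fam in bp$family) {
    total_ov <- 0; total_len <- 0
    for (r in which(frags$family == fam)) {
      ov <- pmax(0, pmin(hits$end, frags$end[r]) - pmax(hits$start, frags$start[r]))
      if (sum(ov) > 0) {
        total_ov <- total_ov + sum(ov)
        total_len <- total_len + frags$end[r] - frags$start[r]
      }
    }
    expect_equal(bp$percent[bp$family == fam], 100 * total_ov / total_len)
  }
  expect_true(all(bp$percent >= 0 & bp$percent <= 100))
})

test_that("partition_summary reports repeat and PQS percentages", {
  # repeats covering half the genome, PQS uniform
  reps <- mk_repeats(0L, 5000L, "+", "R")
  starts <- seq(100L, 9900L, 200L)
  h <- mk_hits(starts, starts + 20L, "+")
  p <- partition_summary(h, reps, 10000L)
  expect_equal(p$repeat_percent, 50)
  expect_equal(p$pqs_in_repeat_percent, 50)

  p0 <- partition_summary(h, reps[0, ], 10000L)
  expect_equal(p0$repeat_percent, 0)
  expect_equal(p0$pqs_in_repeat_percent, 0)

  # overlapping repeats are merged before computing coverage
  reps2 <- mk_repeats(c(0L, 2500L), c(5000L, 7500L), "+", c("R", "R"))
  expect_equal(partition_summary(h, reps2, 10000L)$repeat_percent, 75)
})

test_that("record counts plus unassigned conserve the pairing total", {
  set.seed(8)
  frags <- mk_repeats(c(0L, 3000L), c(2000L, 6000L), c("+", "-"), c("A", "B"))
  starts <- sort(sample.int(7000L, 30L))
  hits <- mk_hits(starts, starts + 30L, sample(c("+", "-"), 30, replace = TRUE))
  ix <- intersect_pqs_repeats(hits, frags)
  n_pairs <- 0L
  assigned <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    for (r in seq_len(nrow(frags))) {
      if (min(hits$end[i], frags$end[r]) > max(hits$start[i], frags$start[r])) {
        n_pairs <- n_pairs + 1L
        assigned[i] <- TRUE
      }
    }
  }
  expect_equal(nrow(ix$records), n_pairs)
  expect_equal(nrow(ix$unassigned), sum(!assigned))
})
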