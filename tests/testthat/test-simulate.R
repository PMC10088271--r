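test_that("background generation is deterministic with controlled GC and clean", {
  s1 <- gen_background(10000L, 0.4, seed = 17)
  s2 <- gen_background(10000L, 0.4, seed = 17)
  expect_identical(s1, s2)

  # empirical GC within 3 sigma of the binomial expectation
  gc_obs <- mean(strsplit(s1, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))

  # cleaning leaves no accidental PQS at the default threshold
  expect_equal(nrow(scan(s1)), 0L)
  hot <- gen_background(20000L, 0.6, seed = 18)
  expect_equal(nrow(scan(hot)), 0L)

  expect_error(gen_background(100L, 1.2), "gc")
})

test_that("motif construction matches the scoring formula and warns below threshold", {
  m <- make_pqs_motif(3L, c(1L, 1L, 1L), loop_alphabet = "T")
  expect_equal(as.character(m), "GGGTGGGTGGGTGGG")
  expect_equal(attr(m, "score"), 60L)
  m4 <- make_pqs_motif(4L, c(3L, 3L, 3L), loop_alphabet = "A")
  expect_equal(attr(m4, "score"), 90L)
  expect_warning(m2 <- make_pqs_motif(2L, c(1L, 1L, 1L), loop_alphabet = "T"),
                 "below the default")
  expect_equal(attr(m2, "score"), 30L)
  expect_error(make_pqs_motif(3L, c(1L, 1L)), "length")
})

test_that("planted elements are recovered exactly by rescanning", {
  cfg <- sim_config(seed = 23)
  el <- gen_element(cfg)
  tp <- truth_pqs(el)
  expect_equal(nrow(tp), 4L)
  expect_equal(sum(tp$region == "gag"), 3L)
  h <- scan(el$seq)
  expect_equal(nrow(h), nrow(tp))
  expect_equal(h$start, tp$start)
  expect_equal(h$end, tp$end)
  expect_equal(h$strand, tp$strand)
  expect_equal(h$score, tp$score)
  # antisense plants sit on the minus strand of the element
  expect_true(all(tp$strand == "-"))
})

test_that("a zero-plant element scans clean", {
  cfg <- sim_config(seed = 29,
                    pqs_plan = data.frame(region = character(0),
                                          count = integer(0),
                                          orientation = character(0),
                                          n_tetrads = integer(0),
                                          loops = character(0)))
  el <- gen_element(cfg)
  expect_equal(nrow(scan(el$seq)), 0L)
})

test_that("head-to-tail arrays put every planted PQS on one genomic strand", {
  el <- gen_element(sim_config(seed = 37))
  arr <- gen_htt_array(el, n = 5)
  h <- scan(arr$seq)
  tp <- truth_pqs(arr)
  expect_equal(nrow(h), 20L)
  expect_equal(h$start, tp$start)
  expect_equal(h$strand, tp$strand)
  expect_equal(unique(h$strand), "-")

  # flipping the array flips every hit strand and mirrors coordinates
  arrm <- gen_htt_array(el, n = 5, array_strand = "-")
  hm <- scan(arrm$seq)
  expect_equal(unique(hm$strand), "+")
  L <- nchar(arr$seq[[1]])
  expect_equal(sort(L - hm$end), sort(h$start))

  # density over the array equals planted count / length, per 10 kbp
  region <- data.frame(seqid = "htt_array", start = 0L, end = L)
  expect_equal(pqs_density(h, region), 10000 * 20 / L)
})

test_that("tandem arrays follow the requested substitution rate", {
  mono <- gen_background(321L, 0.45, seed = 41, clean = FALSE)
  t0 <- gen_tandem_array(mono, 10L, 0, seed = 43)
  expect_equal(t0$seq[[1]], strrep(mono, 10))
  expect_identical(gen_tandem_array(mono, 5L, 0.1, seed = 44)$seq,
                   gen_tandem_array(mono, 5L, 0.1, seed = 44)$seq)

  # two copies each mutated at rate p agree with prob (1-p)^2 + p^2/3
  tt <- gen_tandem_array(mono, 10L, 0.1, seed = 45)
  copies <- substring(tt$seq[[1]], tt$features$start + 1L, tt$features$end)
  ids <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    ids <- c(ids, pairwise_identity(copies[i], copies[j]))
  }
  expected <- 100 * (0.9^2 + 0.1^2 / 3)
  expect_lt(abs(mean(ids) - expected), 1.5)
  expect_error(gen_tandem_array(mono, 3L, 1.1), "rate")
})

test_that("CDS families honour rate and omega limits", {
  f0 <- gen_cds_family(4, 60, subs_per_codon = 0, seed = 51)
  expect_true(all(f0$cds == f0$ancestor))
  d0 <- dnds_alignment(f0$cmsa)
  expect_equal(d0$mean_ds, 0)
  expect_equal(d0$mean_dn, 0)

  fsyn <- gen_cds_family(4, 120, subs_per_codon = 0.5,
                         regions = data.frame(name = "all", start = 0L, end = 120L),
                         omega = c(all = 0), seed = 53)
  dsyn <- dnds_alignment(fsyn$cmsa)
  expect_equal(dsyn$mean_dn, 0)
  expect_gt(dsyn$mean_ds, 0)

  # descendants contain no internal stops
  code <- Biostrings::GENETIC_CODE
  for (s in fsyn$cds) {
    idx <- seq(1L, nchar(s), 3L)
    expect_false(any(code[substring(s, idx, idx + 2L)] == "*"))
  }
  expect_error(gen_cds_family(4, 60, omega = c(all = -1),
                              regions = data.frame(name = "all", start = 0L,
                                                   end = 60L)),
               "omega")
})

test_that("generators are pure functions of their seed", {
  e1 <- gen_element(sim_config(seed = 61))
  e2 <- gen_element(sim_config(seed = 61))
  expect_identical(e1$seq, e2$seq)
  expect_identical(e1$features, e2$features)
  f1 <- gen_cds_family(5, 80, subs_per_codon = 0.3, seed = 62)
  f2 <- gen_cds_family(5, 80, subs_per_codon = 0.3, seed = 62)
  expect_identical(f1$cds, f2$cds)
})

test_that("truth annotations survive a GFF3 round-trip", {
  el <- gen_element(sim_config(seed = 67))
  f <- withr_local_tempfile(ext = ".gff3")
  feat <- el$features
  feat$score[is.na(feat$score)] <- 0
  feat$region[is.na(feat$region)] <- "NA"
  write_features(feat, f, "gff3")
  back <- read_features(f, "gff3")
  expect_equal(back$start, feat$start)
  expect_equal(back$end, feat$end)
  expect_equal(back$strand, feat$strand)
})
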