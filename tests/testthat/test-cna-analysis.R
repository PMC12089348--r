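# Copy-number analytics: altered fraction, broad events, switch
# counting, chromothripsis tiers, focal filters, two-hit calls.

test_that("altered-genome fraction measures departure from diploid", {
  expect_equal(altered_genome_fraction(make_profile(c(2, 2, 2))), 0)
  p <- cn_profile("S1", data.frame(
    chrom = "chr1", start = c(1, 50e6 + 1, 60e6 + 1),
    end = c(50e6, 60e6, 100e6),
    total_cn = c(2L, 1L, 2L), minor_cn = c(1L, 0L, 1L)))
  expect_equal(altered_genome_fraction(p), 0.10, tolerance = 1e-12)
  # sex chromosomes are excluded from the denominator
  px <- cn_profile("S1", rbind(p$segments, data.frame(
    chrom = "chrX", start = 1, end = 50e6, total_cn = 1L, minor_cn = 0L)))
  expect_equal(altered_genome_fraction(px), 0.10, tolerance = 1e-12)
  # brute-force oracle on random mixed profiles
  set.seed(11)
  for (i in 1:20) {
    rp <- random_profile()
    seg <- rp$segments
    oracle <- sum(ifelse(seg$total_cn != 2, seg$end - seg$start + 1, 0)) /
      sum(seg$end - seg$start + 1)
    expect_equal(altered_genome_fraction(rp), oracle, tolerance = 1e-12)
  }
})

test_that("broad events need at least half an arm, with loss precedence", {
  arm <- data.frame(chrom = "chr1", arm = c("chr1p", "chr1q"),
                    start = c(1, 25e6 + 1), end = c(25e6, 60e6))
  seg60 <- cn_profile("S1", data.frame(
    chrom = "chr1", start = c(1, 15e6 + 1, 25e6 + 1),
    end = c(15e6, 25e6, 60e6),
    total_cn = c(1L, 2L, 2L), minor_cn = c(0L, 1L, 1L)))
  b <- call_broad_events(seg60, arm)          # 60% of p lost
  expect_equal(b$call[b$arm == "chr1p"], "loss")
  expect_equal(b$call[b$arm == "chr1q"], "neutral")

  seg49 <- cn_profile("S1", data.frame(
    chrom = "chr1", start = c(1, 12.25e6 + 1),
    end = c(12.25e6, 60e6),
    total_cn = c(1L, 2L), minor_cn = c(0L, 1L)))
  expect_equal(call_broad_events(seg49, arm)$call[1], "neutral")  # 49%

  gain <- cn_profile("S1", data.frame(
    chrom = "chr1", start = c(1, 25e6 + 1), end = c(25e6, 60e6),
    total_cn = c(2L, 3L), minor_cn = c(1L, 1L)))
  expect_equal(call_broad_events(gain, arm)$call[2], "gain")

  tied <- cn_profile("S1", data.frame(
    chrom = "chr1", start = c(1, 12.5e6 + 1), end = c(12.5e6, 25e6),
    total_cn = c(1L, 3L), minor_cn = c(0L, 1L)))
  expect_equal(call_broad_events(tied, arm)$call[1], "loss")

  bad_arm <- arm[arm$chrom != "chr1", ]
  expect_error(call_broad_events(seg60, bad_arm), "arm table lacks")
})

test_that("switch counting matches the stated examples", {
  alternating <- make_profile(rep(c(1, 2), length.out = 11), seg_bp = 4e6)
  sw <- count_cn_switches(alternating, "chr1")
  expect_equal(sw$count, 10L)
  expect_equal(sw$n_states, 2L)
  expect_equal(count_cn_switches(make_profile(rep(2, 8)), "chr1")$count, 0L)
  expect_equal(count_cn_switches(make_profile(2), "chr1")$count, 0L)
  expect_error(count_cn_switches(make_profile(2), "chr9"), "absent")
})

test_that("switch counting equals the brute-force window oracle on random profiles", {
  set.seed(23)
  for (i in 1:200) {
    rp <- random_profile()
    got <- count_cn_switches(rp, "chr1")$count
    extra <- runif(25, 1, 60e6)
    expect_equal(got, oracle_max_switches(rp, "chr1", extra_starts = extra))
  }
})

test_that("tier thresholds scale with chromosome length as published", {
  sc <- scale_switch_thresholds(46.709)
  expect_equal(sc$scaling_factor, 46.709 / 50, tolerance = 1e-9)
  expect_equal(round(sc$scaling_factor, 3), 0.934)
  expect_equal(unname(sc$thresholds), c(9, 7, 6))
  expect_equal(unname(scale_switch_thresholds(50)$thresholds), c(10, 8, 6))
  expect_equal(unname(scale_switch_thresholds(80)$thresholds), c(10, 8, 6))
})

test_that("chromothripsis classification assigns tiers and canonicity", {
  hi <- classify_chromothripsis(10, 3, 60)
  expect_equal(hi$tier, "high")
  expect_equal(hi$canonicity, "canonical")
  expect_equal(classify_chromothripsis(10, 4, 60)$canonicity,
               "non_canonical")
  expect_equal(classify_chromothripsis(5, 2, 60)$tier, "none")
  expect_equal(classify_chromothripsis(5, 2, 60)$canonicity,
               "not_applicable")
  # 46.709 Mb chromosome: 9 switches already high-confidence
  expect_equal(classify_chromothripsis(9, 2, 46.709)$tier, "high")
  expect_equal(classify_chromothripsis(8, 2, 46.709)$tier, "intermediate")
  expect_equal(classify_chromothripsis(6, 2, 46.709)$tier, "low")
})

test_that("tier is monotone in switch count", {
  rank <- c(none = 0, low = 1, intermediate = 2, high = 3)
  for (len in c(20, 46.709, 50, 60)) {
    tiers <- vapply(0:15, function(k) {
      classify_chromothripsis(k, 2, len)$tier
    }, character(1))
    expect_true(all(diff(rank[tiers]) >= 0))
  }
})

test_that("null profiles with few segments never reach a confidence tier", {
  set.seed(31)
  for (i in 1:100) {
    rp <- random_profile(max_segs = 4L)   # at most 3 switches
    calls <- call_chromothripsis(rp, data.frame(chrom = "chr1",
                                                length = 60e6))
    expect_true(all(calls$tier == "none"))
  }
})

test_that("focal-event post-filters apply size, difficulty and concordance in order", {
  mask <- make_targets(2e6, 3e6)$granges
  events <- data.frame(
    chrom = "chr1",
    start = c(1e6, 1.99e6, 5e6, 8e6),
    end = c(1.1e6, 2.99e6, 6e6, 9e6),
    direction = c("loss", "loss", "loss", "gain"),
    concordant_fraction = c(1, 1, 0.75, 0.5),
    stringsAsFactors = FALSE)
  out <- filter_focal_events(events, difficult_mask = mask)
  expect_equal(out$status, c("removed_small", "removed_difficult",
                             "kept", "removed_discordant"))
  expect_equal(out$size_bp[1], 100000)
  expect_gt(out$difficult_overlap_fraction[2], 0.40)
  # statuses partition the input; re-filtering kept events is a no-op
  expect_false(any(is.na(out$status)))
  kept <- out[out$status == "kept", ]
  again <- filter_focal_events(kept, difficult_mask = mask)
  expect_equal(again$status, "kept")
})

test_that("focal concordance can be computed from per-sample profiles", {
  profs <- list(
    A = make_profile(c(1, 2), seg_bp = 10e6, sample_id = "A"),
    B = make_profile(c(2, 2), seg_bp = 10e6, sample_id = "B"))
  events <- data.frame(chrom = "chr1", start = 2e6, end = 8e6,
                       direction = "loss",
                       supporting_samples = "A,B",
                       stringsAsFactors = FALSE)
  out <- filter_focal_events(events, per_sample_calls = profs)
  expect_equal(out$concordant_fraction, 0.5)
  expect_equal(out$status, "removed_discordant")
})

test_that("two-hit calls need two damaging variants or one plus LOH", {
  gm <- data.frame(gene = "TSG1", chrom = "chr1", start = 1e6, end = 1.1e6)
  loh_profile <- cn_profile("S1", data.frame(
    chrom = "chr1", start = c(1, 2e6 + 1), end = c(2e6, 60e6),
    total_cn = c(1L, 2L), minor_cn = c(0L, 1L)))
  diploid <- make_profile(2, seg_bp = 60e6)

  splice <- make_variant(pos = 1.05e6, consequence = "splice_acceptor_variant")
  out <- call_two_hit(splice, loh_profile, gm)
  expect_equal(out$evidence, "variant_plus_loh")

  two_fs <- bind_variants(
    make_variant(pos = 1.01e6, ref = "AT", alt = "A",
                 consequence = "frameshift_variant"),
    make_variant(pos = 1.07e6, ref = "G", alt = "GC",
                 consequence = "frameshift_variant"))
  out2 <- call_two_hit(two_fs, diploid, gm)
  expect_equal(out2$evidence, "two_variants")

  missense <- make_variant(pos = 1.05e6, consequence = "missense_variant")
  expect_equal(nrow(call_two_hit(missense, diploid, gm)), 0L)
  # LOH covering less than half the gene is not enough
  partial <- cn_profile("S1", data.frame(
    chrom = "chr1", start = c(1, 1.04e6 + 1), end = c(1.04e6, 60e6),
    total_cn = c(1L, 2L), minor_cn = c(0L, 1L)))
  expect_equal(nrow(call_two_hit(splice, partial, gm)), 0L)
})
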