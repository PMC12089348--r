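# Refinement cascade: rule boundaries, MNV merging, proximity, rescue,
# and the pipeline contracts (idempotence, order invariance,
# monotonicity, audit uniqueness).

cfg <- refinement_config()

test_that("common-SNP exclusion uses an inclusive 0.01 boundary and spares missing AF", {
  calls <- bind_variants(
    make_variant(pos = 100, pop_af = 0.02),
    make_variant(pos = 200, pop_af = 0.01),
    make_variant(pos = 300, pop_af = 0.0099),
    make_variant(pos = 400, pop_af = NA))
  out <- exclude_common_snps(calls, cfg)
  expect_equal(out$calls$pos, c(300L, 400L))
  expect_equal(nrow(out$audit), 2L)
  expect_true(all(out$audit$rule == "common_snp"))
})

test_that("adjacent in-cis SNVs merge into one MNV with conservative support", {
  pair <- bind_variants(
    make_variant(pos = 100, ref = "A", alt = "G", t_depth = 50, t_alt = 20,
                 phase_set = "ps1"),
    make_variant(pos = 101, ref = "C", alt = "T", t_depth = 44, t_alt = 18,
                 phase_set = "ps1"))
  merged <- merge_adjacent_snvs(pair, cfg)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$vclass, "MNV")
  expect_equal(merged$ref, "AC")
  expect_equal(merged$alt, "GT")
  expect_equal(merged$t_depth, 44L)
  expect_equal(merged$t_alt, 18L)
})

test_that("runs longer than the MNV limit and out-of-phase SNVs stay unmerged", {
  run4 <- bind_variants(
    make_variant(pos = 100, phase_set = "ps1"),
    make_variant(pos = 101, ref = "C", alt = "T", phase_set = "ps1"),
    make_variant(pos = 102, ref = "G", alt = "A", phase_set = "ps1"),
    make_variant(pos = 103, ref = "T", alt = "C", phase_set = "ps1"))
  expect_equal(merge_adjacent_snvs(run4, cfg)$vclass, rep("SNV", 4L))

  diff_phase <- bind_variants(
    make_variant(pos = 100, phase_set = "ps1"),
    make_variant(pos = 101, ref = "C", alt = "T", phase_set = "ps2"))
  expect_equal(nrow(merge_adjacent_snvs(diff_phase, cfg)), 2L)

  conflicting <- bind_variants(
    make_variant(pos = 100, chrom = "chr1", phase_set = "ps1"),
    make_variant(pos = 101, chrom = "chr2", ref = "C", alt = "T",
                 phase_set = "ps1"))
  expect_error(merge_adjacent_snvs(conflicting, cfg), "chromosomes")
})

test_that("the retention cascade enforces the VAF and allele-length rule table", {
  long_ref <- strrep("A", 12)
  long_alt <- paste0("G", strrep("T", 10))   # 11 bp
  calls <- bind_variants(
    make_variant(pos = 100, ref = "AT", alt = "A", t_depth = 40, t_alt = 2),
    make_variant(pos = 200, ref = long_ref, alt = long_alt, t_depth = 40,
                 t_alt = 6, n_depth = 25),
    make_variant(pos = 300, ref = long_ref, alt = long_alt, t_depth = 40,
                 t_alt = 12, n_depth = 25),
    make_variant(pos = 400, ref = strrep("A", 30), alt = "A", t_depth = 40,
                 t_alt = 20, n_depth = 30),
    make_variant(pos = 500, t_depth = 0, t_alt = 0))
  out <- apply_refinement_cascade(calls, cfg)
  expect_equal(out$calls$pos, c(300L, 400L))
  rule_of <- function(pos) {
    out$audit$rule[grepl(paste0(":", pos, ":"), out$audit$variant_key)]
  }
  expect_equal(rule_of(100), "low_vaf")
  expect_equal(rule_of(200), "complex_fail")
  expect_equal(rule_of(500), "malformed")
  # pos 400: 30 bp ref makes the pair complex, but VAF 0.5 and depths pass
  expect_equal(nrow(out$audit), 3L)
})

test_that("overlong MNVs are always removed", {
  mnv <- make_variant(pos = 100, ref = "ACGT", alt = "TGCA", t_depth = 60,
                      t_alt = 30)
  out <- apply_refinement_cascade(mnv, cfg)
  expect_equal(nrow(out$calls), 0L)
  expect_equal(out$audit$rule, "long_mnv")
  kept <- apply_refinement_cascade(
    make_variant(pos = 100, ref = "ACG", alt = "TGC", t_depth = 60,
                 t_alt = 30), cfg)
  expect_equal(kept$calls$vclass, "MNV")
})

test_that("target proximity is inclusive at 100 bp", {
  ts <- make_targets(1000, 2000)          # 1-based 1001..2000
  calls <- bind_variants(
    make_variant(pos = 900),              # gap 100
    make_variant(pos = 899),              # gap 101
    make_variant(pos = 1500))             # inside
  out <- restrict_to_target_space(calls, ts, cfg)
  expect_equal(out$calls$pos, c(900L, 1500L))
  expect_equal(out$audit$rule, "off_target")
  expect_match(out$audit$variant_key, ":899:")
})

test_that("hotspot rescue reinstates adequately supported filtered calls only", {
  hs <- default_hotspot_sites()
  ct <- hs[hs$gene == "CTNNB1", ]
  ts <- make_targets(ct$pos - 500, ct$pos + 500, chrom = ct$chrom)
  raw <- bind_variants(
    make_variant(pos = ct$pos, chrom = ct$chrom, ref = ct$ref, alt = ct$alt,
                 t_depth = 60, t_alt = 4),          # VAF 0.067, rescuable
    make_variant(pos = ct$pos + 50, chrom = ct$chrom, t_depth = 60,
                 t_alt = 4),                        # non-hotspot, same VAF
    make_variant("S2", pos = ct$pos, chrom = ct$chrom, ref = ct$ref,
                 alt = ct$alt, t_depth = 60, t_alt = 1))  # below floor
  out <- refine_variants(raw, ts, cfg)
  expect_equal(nrow(out$calls), 1L)
  expect_equal(out$calls$sample_id, "S1")
  expect_match(out$calls$filters, "rescued:low_vaf")
  reinstated <- out$audit[out$audit$action == "reinstated", ]
  expect_equal(nrow(reinstated), 1L)
})

test_that("refinement is idempotent and order invariant", {
  co <- generate_cohort(seed = 1)
  ref1 <- refine_variants(co$variants, co$targets)
  ref2 <- refine_variants(ref1$calls, co$targets)
  expect_equal(ref2$calls, ref1$calls, ignore_attr = TRUE)

  set.seed(42)
  shuffled <- co$variants[sample.int(nrow(co$variants)), ]
  ref3 <- refine_variants(shuffled, co$targets)
  expect_equal(ref3$calls, ref1$calls, ignore_attr = TRUE)
})

test_that("raising the VAF floor never enlarges the retained set", {
  co <- generate_cohort(seed = 2)
  keys <- lapply(c(0.1, 0.2, 0.3), function(v) {
    cfg_v <- refinement_config(min_vaf = v, rescue_vaf_floor = max(v, 0.25))
    sgcohort:::variant_key(refine_variants(co$variants, co$targets,
                                           cfg_v)$calls)
  })
  expect_true(all(keys[[2]] %in% keys[[1]]))
  expect_true(all(keys[[3]] %in% keys[[2]]))
})

test_that("every removed record is audited exactly once with its first rule", {
  co <- generate_cohort(seed = 3)
  ref <- refine_variants(co$variants, co$targets)
  removed <- ref$audit[ref$audit$action == "removed", ]
  expect_false(any(duplicated(removed$variant_key)))
  all_keys <- sgcohort:::variant_key(
    merge_adjacent_snvs(co$variants, refinement_config()))
  kept_keys <- sgcohort:::variant_key(ref$calls)
  # kept (non-rescued) + removed partitions the merged raw set
  rescued <- grepl("rescued:", ref$calls$filters)
  expect_setequal(c(kept_keys[!rescued], removed$variant_key), all_keys)
})
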