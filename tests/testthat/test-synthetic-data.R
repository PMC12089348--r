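# Synthetic cohort generator: planted structure, determinism, planting
# operators.

test_that("defaults reproduce the study cohort structure", {
  co <- generate_cohort(seed = 7)
  expect_equal(nrow(co$manifest), 43L)
  expect_equal(sum(co$manifest$cohort == "benign"), 32L)
  ha <- co$truth$hotspot_assignment
  benign <- co$manifest$sample_id[co$manifest$cohort == "benign"]
  expect_equal(sum(ha[benign] == "CTNNB1_hotspot"), 25L)
  expect_equal(sum(ha[benign] == "FBXW11_hotspot"), 5L)
  # hotspot labels are mutually exclusive per sample by construction
  expect_true(all(ha %in% c("CTNNB1_hotspot", "FBXW11_hotspot", "none")))
  hs <- default_hotspot_sites()
  carriers <- function(gene) {
    s <- hs[hs$gene == gene, ]
    unique(co$variants$sample_id[co$variants$chrom == s$chrom &
                                   co$variants$pos == s$pos])
  }
  expect_length(intersect(carriers("CTNNB1"), carriers("FBXW11")), 0L)
  expect_setequal(carriers("CTNNB1"), names(ha)[ha == "CTNNB1_hotspot"])
})

test_that("a minimal cohort with no planted prevalence is background only", {
  cfg <- cohort_config(n_benign = 1L, n_malignant = 1L, n_ctnnb1 = 0L,
                       n_fbxw11 = 0L, n_malignant_fbxw11 = 0L,
                       n_low_purity_hotspot = 0L,
                       arm_loss_plants = c(chr3q = 0L, chr2q = 0L),
                       chromothripsis = NULL, plant_two_hit = FALSE)
  co <- generate_cohort(cfg, seed = 5)
  expect_equal(nrow(co$manifest), 2L)
  hs <- default_hotspot_sites()
  expect_false(any(co$variants$pos %in% hs$pos &
                     co$variants$chrom %in% hs$chrom))
  expect_true(all(co$truth$hotspot_assignment == "none"))
})

test_that("infeasible prevalences fail before anything is generated", {
  expect_error(cohort_config(n_ctnnb1 = 30L, n_fbxw11 = 5L),
               "infeasible hotspot prevalence")
  expect_error(cohort_config(n_benign = 0L), ">= 1")
  expect_error(cohort_config(arm_loss_plants = c(chr3q = 12L)),
               "arm-loss")
})

test_that("generation is deterministic and bundles are byte-identical", {
  co1 <- generate_cohort(seed = 11)
  co2 <- generate_cohort(seed = 11)
  expect_identical(co1$variants, co2$variants)
  expect_identical(co1$minimizer, co2$minimizer)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort_bundle(co1, d1)
  write_cohort_bundle(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_false(identical(co1$variants, generate_cohort(seed = 12)$variants))
})

test_that("per-sample streams are stable when the cohort grows", {
  small <- generate_cohort(cohort_config(n_benign = 4L, n_malignant = 2L,
                                         n_ctnnb1 = 2L, n_fbxw11 = 1L,
                                         n_low_purity_hotspot = 1L,
                                         arm_loss_plants = c(chr3q = 1L),
                                         plant_two_hit = FALSE,
                                         chromothripsis = NULL), seed = 3)
  big <- generate_cohort(cohort_config(n_benign = 5L, n_malignant = 2L,
                                       n_ctnnb1 = 2L, n_fbxw11 = 1L,
                                       n_low_purity_hotspot = 1L,
                                       arm_loss_plants = c(chr3q = 1L),
                                       plant_two_hit = FALSE,
                                       chromothripsis = NULL), seed = 3)
  v_small <- small$variants[small$variants$sample_id == "BCA02", ]
  v_big <- big$variants[big$variants$sample_id == "BCA02", ]
  expect_equal(v_small, v_big, ignore_attr = TRUE)
})

test_that("planted chromothripsis oscillations carry the requested switches", {
  base <- cn_profile("S1", data.frame(chrom = "chr1", start = 1, end = 60e6,
                                      total_cn = 2L, minor_cn = 1L))
  for (cs in list(c(10, 2), c(6, 4), c(7, 2), c(12, 3))) {
    planted <- plant_chromothripsis(base, "chr1", n_switches = cs[1],
                                    n_states = cs[2])
    expect_equal(oracle_max_switches(planted, "chr1"), cs[1])
    sw <- count_cn_switches(planted, "chr1")
    expect_equal(sw$count, cs[1])
    expect_equal(sw$n_states, cs[2])
    # untouched outside the region: total genome length conserved
    expect_equal(sum(planted$segments$end - planted$segments$start + 1),
                 sum(base$segments$end - base$segments$start + 1))
  }
})

test_that("planted oscillations classify at the expected tier and canonicity", {
  base <- cn_profile("S1", data.frame(chrom = "chr1", start = 1, end = 60e6,
                                      total_cn = 2L, minor_cn = 1L))
  hi <- plant_chromothripsis(base, "chr1", 10, 2)
  sw <- count_cn_switches(hi, "chr1")
  cl <- classify_chromothripsis(sw$count, sw$n_states, 60)
  expect_equal(cl$tier, "high")
  expect_equal(cl$canonicity, "canonical")
  lo <- plant_chromothripsis(base, "chr1", 6, 4)
  sw2 <- count_cn_switches(lo, "chr1")
  cl2 <- classify_chromothripsis(sw2$count, sw2$n_states, 60)
  expect_equal(cl2$tier, "low")
  expect_equal(cl2$canonicity, "non_canonical")
  expect_error(plant_chromothripsis(base, "chr1", 10, 2, region_bp = 70e6),
               "shorter than")
  expect_error(plant_chromothripsis(base, "chr9", 10, 2), "absent")
})

test_that("taxon planting scales the expected count and caps at M", {
  rec <- data.frame(sample_id = "s", taxon_id = c("A", "B"),
                    m = c(2, 3), M = c(100, 100), n = c(20, 30),
                    N = c(1000, 1000), proportion = c(0.02, 0.03),
                    p_value = NA_real_, q_value = NA_real_)
  up <- plant_taxon(rec, "A", enrichment = 10)   # expected 2 -> 20
  expect_equal(up$m[up$taxon_id == "A"], 20)
  expect_equal(up$proportion[up$taxon_id == "A"], 0.2)
  capped <- plant_taxon(rec, "A", enrichment = 100)
  expect_equal(capped$m[capped$taxon_id == "A"], 100)
  expect_error(plant_taxon(rec, "A", enrichment = 1), "> 1")
  expect_error(plant_taxon(rec, "Z", enrichment = 2), "absent")
})

test_that("background burden falls in the configured cohort bands", {
  co <- generate_cohort(seed = 13)
  ref <- refine_variants(co$variants, co$targets)
  tmb <- compute_tmb(ref$calls, co$targets,
                     sample_ids = co$manifest$sample_id)
  lab <- stats::setNames(co$manifest$cohort, co$manifest$sample_id)
  benign <- tmb$tmb[lab[tmb$sample_id] == "benign"]
  expect_true(all(benign > 0.05 & benign < 1))
  hyper <- tmb$tmb[tmb$sample_id == co$truth$hypermutator_sample]
  expect_equal(tmb$sample_id[which.max(tmb$tmb)],
               co$truth$hypermutator_sample)
  expect_gt(hyper, 5)
  # the hypermutator's spectrum is indel-rich relative to the cohort
  hcalls <- ref$calls[ref$calls$sample_id == co$truth$hypermutator_sample, ]
  ifrac_h <- mean(hcalls$vclass %in% c("INS", "DEL"))
  other <- ref$calls[ref$calls$sample_id != co$truth$hypermutator_sample, ]
  expect_gt(ifrac_h, mean(other$vclass %in% c("INS", "DEL")))
})

test_that("planted arm losses are recovered by the broad-event caller", {
  co <- generate_cohort(seed = 17)
  pl <- co$truth$planted_arm_losses
  for (i in seq_len(nrow(pl))) {
    b <- call_broad_events(co$profiles[[pl$sample[i]]], co$arm_table)
    expect_equal(b$call[b$arm == pl$arm[i]], "loss")
  }
})

test_that("planted two-hit narratives are recovered", {
  co <- generate_cohort(seed = 19)
  ref <- refine_variants(co$variants, co$targets)
  for (gene in names(co$truth$two_hit_plants)) {
    plant <- co$truth$two_hit_plants[[gene]]
    calls <- ref$calls[ref$calls$sample_id == plant$sample, ]
    th <- call_two_hit(calls, co$profiles[[plant$sample]], co$gene_models)
    expect_true(gene %in% th$gene)
    expect_equal(th$evidence[th$gene == gene], plant$evidence)
  }
})
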