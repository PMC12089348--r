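# Synthetic cohort generator.
#
# Emits a complete cohort -- somatic variant calls, allele-specific CN
# segment profiles, a taxon minimizer report and a sample manifest -- with
# planted ground truth, so every downstream stage is testable without
# controlled-access patient data.  The default configuration mirrors the
# modelled study: 32 benign and 11 malignant tumours; 25 benign samples
# carry the CTNNB1 hotspot and 5 the FBXW11 hotspot (disjoint sets), with
# one additional FBXW11 carrier among the malignant samples; one
# mismatch-repair-deficient hypermutator with an indel-rich spectrum;
# q-arm losses planted in 4/11 and 2/11 malignant samples (emulating the
# study's 16q and 5q losses on the synthetic genome); one
# chromothripsis-like chromosome; and one enriched taxon in the minimizer
# report.
#
# The genome model is synthetic: three autosomes of 60/50/47 Mb with a
# regular exon grid, so chromosome-length scaling logic is exercised
# without human reference files.  Gene anchors (CTNNB1, FBXW11, MLH1,
# CYLD, KMT2D, DICER1) are synthetic coordinates on this model, not human
# ones.

#' Default synthetic genome model
#'
#' Three autosomes of 60, 50 and 47 Mb with centromere positions; the
#' 47 Mb chromosome exercises the sub-50 Mb chromothripsis threshold
#' scaling.
#'
#' @return data frame with columns `chrom`, `length`, `centromere`.
#' @export
default_genome <- function() {
  data.frame(chrom = c("chr1", "chr2", "chr3"),
             length = c(60e6, 50e6, 47e6),
             centromere = c(25e6, 20e6, 19e6),
             stringsAsFactors = FALSE)
}

#' Chromosome arm coordinate table for a genome model
#'
#' @param genome genome model data frame (see [default_genome()]).
#' @return data frame `chrom`, `arm`, `start`, `end` (1-based inclusive);
#'   arm names are `<chrom>p` / `<chrom>q`.
#' @export
default_arm_table <- function(genome = default_genome()) {
  do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    g <- genome[i, ]
    data.frame(chrom = g$chrom,
               arm = paste0(g$chrom, c("p", "q")),
               start = c(1, g$centromere + 1),
               end = c(g$centromere, g$length),
               stringsAsFactors = FALSE)
  }))
}

# Anchor genes of the modelled narratives, on the synthetic genome.
anchor_gene_models <- function() {
  data.frame(
    gene = c("CTNNB1", "FBXW11", "MLH1", "KMT2D", "CYLD", "DICER1"),
    chrom = c("chr1", "chr2", "chr1", "chr1", "chr3", "chr3"),
    start = c(10000001, 5000001, 40000001, 45000001, 30000001, 10000001),
    end = c(10120000, 5120000, 40120000, 45120000, 30120000, 10120000),
    stringsAsFactors = FALSE)
}

#' Gene model table for the synthetic genome
#'
#' The six anchor genes of the planted narratives plus a panel of
#' `n_background` background genes tiled across the genome (120 kb each,
#' round-robin over chromosomes, skipping blocks that overlap an anchor).
#'
#' @param genome genome model data frame.
#' @param n_background number of background panel genes (default 250).
#' @return data frame `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
default_gene_models <- function(genome = default_genome(),
                                n_background = 250L) {
  anchors <- anchor_gene_models()
  span <- 120000
  step <- 200000
  cand <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    g <- genome[i, ]
    starts <- seq(500001, g$length - span, by = step)
    data.frame(chrom = g$chrom, start = starts, end = starts + span - 1,
               stringsAsFactors = FALSE)
  }))
  overlaps_anchor <- vapply(seq_len(nrow(cand)), function(i) {
    any(anchors$chrom == cand$chrom[i] &
          anchors$start <= cand$end[i] & anchors$end >= cand$start[i])
  }, logical(1))
  cand <- cand[!overlaps_anchor, , drop = FALSE]
  # round-robin over chromosomes so the panel spreads across the genome
  cand$rank <- stats::ave(seq_len(nrow(cand)), cand$chrom, FUN = seq_along)
  cand <- cand[order(cand$rank, cand$chrom), , drop = FALSE]
  if (nrow(cand) < n_background) {
    stop("genome model too small for ", n_background, " background genes",
         call. = FALSE)
  }
  bg <- cand[seq_len(n_background), c("chrom", "start", "end")]
  bg <- cbind(gene = sprintf("BG%03d", seq_len(n_background)), bg,
              stringsAsFactors = FALSE)
  out <- rbind(anchors, bg)
  rownames(out) <- NULL
  out
}

#' Hotspot site coordinates used by the synthetic cohort
#'
#' The CTNNB1 and FBXW11 hotspot coordinates on the synthetic genome;
#' these are also the default rescue sites of [refinement_config()].
#'
#' @return data frame `gene`, `chrom`, `pos`, `ref`, `alt`.
#' @export
default_hotspot_sites <- function() {
  data.frame(gene = c("CTNNB1", "FBXW11"),
             chrom = c("chr1", "chr2"),
             pos = c(10001000, 5001000),
             ref = c("A", "T"),
             alt = c("G", "C"),
             stringsAsFactors = FALSE)
}

#' Synthetic exome target intervals
#'
#' A regular exon grid: one `exon_bp` exon every `spacing_bp` along each
#' chromosome (BED convention, 0-based half-open).
#'
#' @param genome genome model data frame.
#' @param exon_bp exon length (default 2000).
#' @param spacing_bp grid period (default 10000).
#' @return data frame `chrom`, `start`, `end` suitable for
#'   [target_space()].
#' @export
synthetic_target_intervals <- function(genome = default_genome(),
                                       exon_bp = 2000L,
                                       spacing_bp = 10000L) {
  do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    g <- genome[i, ]
    starts <- seq(0, g$length - spacing_bp, by = spacing_bp)
    data.frame(chrom = g$chrom, start = starts, end = starts + exon_bp,
               stringsAsFactors = FALSE)
  }))
}

#' Synthetic cohort configuration
#'
#' Defaults are the study conditions the generator emulates; see the
#' methods vignette for the rationale behind each numeric choice.
#'
#' @param n_benign,n_malignant cohort sizes (default 32 and 11).
#' @param n_ctnnb1,n_fbxw11 benign hotspot carrier counts (default 25 and
#'   5; the sets are disjoint).
#' @param n_malignant_fbxw11 malignant FBXW11 carriers (default 1).
#' @param n_low_purity_hotspot benign CTNNB1 carriers emitted at low VAF
#'   (tumour VAF ~0.07) to exercise hotspot rescue (default 2).
#' @param benign_tmb_median,benign_tmb_sdlog lognormal background
#'   mutation-rate parameters for benign samples, mutations/Mb
#'   (default median 0.32, sdlog 0.3, giving ~0.15-0.7/Mb).
#' @param malignant_tmb_median,malignant_tmb_sdlog same for non-hypermutated
#'   malignant samples (default median 0.56, sdlog 0.5, ~0.2-2.5/Mb).
#' @param hypermutator_tmb mutation rate of the mismatch-repair-deficient
#'   hypermutator (default 7.5/Mb).
#' @param indel_frac,hypermutator_indel_frac indel share of background
#'   mutations (default 0.1, i.e. indel:SNV 1:9; hypermutator 0.25, 1:3,
#'   echoing dMMR indel signatures).
#' @param mnv_pair_rate per-sample probability of one planted adjacent
#'   in-cis SNV pair (default 0.25).
#' @param off_target_frac fraction of extra calls placed mid-gap, well
#'   beyond the 100 bp target-proximity rule (default 0.05).
#' @param common_snp_rate expected contaminating common-SNP calls as a
#'   fraction of the background count (default 0.2).
#' @param arm_loss_plants named integer vector: arm name -> number of
#'   malignant samples with a planted whole-q-arm loss (default
#'   `c(chr3q = 4, chr2q = 2)`).
#' @param chromothripsis list with `chrom`, `n_switches`, `n_states` for
#'   the planted chromothripsis-like region (default chr1, 10 switches,
#'   2 states).
#' @param plant_two_hit plant the biallelic-inactivation narratives
#'   (MLH1 splice + LOH in the hypermutator; CYLD variant + arm-loss LOH;
#'   KMT2D and DICER1 double mutants) (default TRUE).
#' @param n_taxa,taxon_N taxa in the minimizer report and total evaluated
#'   reads (default 150 taxa, 1e6 reads).
#' @param planted_taxon,taxon_enrichment,planted_taxon_M,planted_taxon_n
#'   the enriched taxon and its parameters (default TAX0042 at 10x
#'   enrichment with M = 20000 database minimizers and n = 2000 reads).
#' @param genome genome model (default [default_genome()]).
#' @param exon_bp,exon_spacing_bp target grid (default 2000 bp exons
#'   every 10 kb, ~31.4 Mb of targets).
#' @param flank_bp splice flank (default 2).
#' @param n_background_genes background gene panel size (default 250).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_benign = 32L, n_malignant = 11L,
                          n_ctnnb1 = 25L, n_fbxw11 = 5L,
                          n_malignant_fbxw11 = 1L,
                          n_low_purity_hotspot = 2L,
                          benign_tmb_median = 0.32,
                          benign_tmb_sdlog = 0.3,
                          malignant_tmb_median = 0.56,
                          malignant_tmb_sdlog = 0.5,
                          hypermutator_tmb = 7.5,
                          indel_frac = 0.1,
                          hypermutator_indel_frac = 0.25,
                          mnv_pair_rate = 0.25,
                          off_target_frac = 0.05,
                          common_snp_rate = 0.2,
                          arm_loss_plants = c(chr3q = 4L, chr2q = 2L),
                          chromothripsis = list(chrom = "chr1",
                                                n_switches = 10L,
                                                n_states = 2L),
                          plant_two_hit = TRUE,
                          n_taxa = 150L, taxon_N = 1e6,
                          planted_taxon = "TAX0042",
                          taxon_enrichment = 10,
                          planted_taxon_M = 20000L,
                          planted_taxon_n = 2000L,
                          genome = default_genome(),
                          exon_bp = 2000L, exon_spacing_bp = 10000L,
                          flank_bp = 2L,
                          n_background_genes = 250L) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  check_cohort_config(cfg)
  cfg
}

check_cohort_config <- function(cfg) {
  if (cfg$n_benign < 1L || cfg$n_malignant < 1L) {
    stop("cohort sizes must be >= 1", call. = FALSE)
  }
  if (cfg$n_ctnnb1 + cfg$n_fbxw11 > cfg$n_benign) {
    stop("infeasible hotspot prevalence: ", cfg$n_ctnnb1, " + ", cfg$n_fbxw11,
         " carriers exceed ", cfg$n_benign, " benign samples", call. = FALSE)
  }
  if (cfg$n_malignant_fbxw11 > cfg$n_malignant) {
    stop("infeasible malignant FBXW11 prevalence", call. = FALSE)
  }
  if (cfg$n_low_purity_hotspot > cfg$n_ctnnb1) {
    stop("low-purity carriers exceed CTNNB1 carriers", call. = FALSE)
  }
  if (any(cfg$arm_loss_plants > cfg$n_malignant)) {
    stop("infeasible arm-loss prevalence", call. = FALSE)
  }
  invisible(cfg)
}

sample_ids <- function(cfg) {
  list(benign = sprintf("BCA%02d", seq_len(cfg$n_benign)),
       malignant = sprintf("BCAC%02d", seq_len(cfg$n_malignant)))
}

# Per-sample RNG fork: the stream for one sample depends only on the run
# seed and the sample id, so adding samples does not perturb the data of
# existing ones.
fork_seed <- function(seed, what) {
  as.integer((as.numeric(seed) * 7919 + stable_hash(what)) %% 2147483629)
}

random_bases <- function(k) {
  paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
}

random_snv_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  list(ref = ref, alt = alt)
}

# One sample's somatic calls (background + planted extras are appended by
# the caller).  Positions land uniformly in the exon grid.
simulate_sample_variants <- function(sid, rate_per_mb, indel_frac, cfg,
                                     exons, total_mb, seed) {
  set.seed(fork_seed(seed, sid))
  n_back <- rpois(1L, rate_per_mb * total_mb)
  rows <- list()
  if (n_back > 0L) {
    exon_idx <- sample.int(nrow(exons), n_back, replace = TRUE)
    pos <- exons$start[exon_idx] + sample.int(cfg$exon_bp, n_back,
                                              replace = TRUE)
    is_indel <- runif(n_back) < indel_frac
    al <- random_snv_alleles(n_back)
    ref <- al$ref
    alt <- al$alt
    for (i in which(is_indel)) {
      len <- 1L + stats::rgeom(1L, 0.45)
      len <- min(len, 8L)
      if (runif(1) < 0.5) {           # insertion
        ref[i] <- substr(ref[i], 1L, 1L)
        alt[i] <- paste0(ref[i], random_bases(len))
      } else {                        # deletion
        alt[i] <- substr(ref[i], 1L, 1L)
        ref[i] <- paste0(alt[i], random_bases(len))
      }
    }
    t_depth <- 30L + rpois(n_back, 50L)
    vaf_true <- runif(n_back, 0.25, 0.55)
    t_alt <- rbinom(n_back, t_depth, vaf_true)
    n_depth <- 25L + rpois(n_back, 40L)
    cons <- ifelse(is_indel,
                   sample(c("frameshift_variant", "inframe_deletion"), n_back,
                          replace = TRUE, prob = c(0.8, 0.2)),
                   sample(c("missense_variant", "synonymous_variant",
                            "stop_gained", "splice_region_variant"), n_back,
                          replace = TRUE, prob = c(0.55, 0.32, 0.08, 0.05)))
    rows$background <- data.frame(
      sample_id = sid, chrom = exons$chrom[exon_idx], pos = pos,
      ref = ref, alt = alt, vclass = classify_allele(ref, alt),
      t_depth = t_depth, t_alt = t_alt, n_depth = n_depth, n_alt = 0L,
      pop_af = NA_real_, phase_set = NA_character_, gene = NA_character_,
      consequence = cons, filters = "", stringsAsFactors = FALSE)
  }
  # contaminating common germline SNPs (removed by the refinery)
  n_common <- rpois(1L, cfg$common_snp_rate * rate_per_mb * total_mb)
  if (n_common > 0L) {
    exon_idx <- sample.int(nrow(exons), n_common, replace = TRUE)
    al <- random_snv_alleles(n_common)
    dp <- 40L + rpois(n_common, 40L)
    ndp <- 30L + rpois(n_common, 40L)
    rows$common <- data.frame(
      sample_id = sid, chrom = exons$chrom[exon_idx],
      pos = exons$start[exon_idx] + sample.int(cfg$exon_bp, n_common,
                                               replace = TRUE),
      ref = al$ref, alt = al$alt, vclass = "SNV",
      t_depth = dp, t_alt = rbinom(n_common, dp, 0.5),
      n_depth = ndp, n_alt = rbinom(n_common, ndp, 0.5),
      pop_af = round(runif(n_common, 0.01, 0.5), 4),
      phase_set = NA_character_, gene = NA_character_,
      consequence = "missense_variant", filters = "",
      stringsAsFactors = FALSE)
  }
  # off-target calls, placed mid-gap (> 100 bp from any flanked exon)
  n_off <- rpois(1L, cfg$off_target_frac * rate_per_mb * total_mb)
  if (n_off > 0L) {
    exon_idx <- sample.int(nrow(exons), n_off, replace = TRUE)
    gap <- cfg$exon_spacing_bp - cfg$exon_bp
    al <- random_snv_alleles(n_off)
    dp <- 30L + rpois(n_off, 40L)
    rows$off <- data.frame(
      sample_id = sid, chrom = exons$chrom[exon_idx],
      pos = exons$start[exon_idx] + cfg$exon_bp +
        sample(500:(gap - 500), n_off, replace = TRUE),
      ref = al$ref, alt = al$alt, vclass = "SNV",
      t_depth = dp, t_alt = rbinom(n_off, dp, 0.4),
      n_depth = 30L + rpois(n_off, 40L), n_alt = 0L,
      pop_af = NA_real_, phase_set = NA_character_, gene = NA_character_,
      consequence = "missense_variant", filters = "",
      stringsAsFactors = FALSE)
  }
  # one adjacent in-cis SNV pair, sometimes, to exercise MNV merging
  if (runif(1) < cfg$mnv_pair_rate) {
    exon_idx <- sample.int(nrow(exons), 1L)
    p0 <- exons$start[exon_idx] + sample.int(cfg$exon_bp - 1L, 1L)
    al <- random_snv_alleles(2L)
    dp <- 40L + rpois(2L, 40L)
    ta <- rbinom(2L, dp, 0.4)
    rows$mnv <- data.frame(
      sample_id = sid, chrom = exons$chrom[exon_idx], pos = c(p0, p0 + 1L),
      ref = al$ref, alt = al$alt, vclass = "SNV",
      t_depth = dp, t_alt = ta, n_depth = 30L + rpois(2L, 40L), n_alt = 0L,
      pop_af = NA_real_, phase_set = paste0(sid, "_ps1"),
      gene = NA_character_, consequence = "missense_variant", filters = "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_variants()
  rownames(out) <- NULL
  out
}

planted_call <- function(sid, chrom, pos, ref, alt, consequence,
                         t_depth = 60L, t_alt = 24L, n_depth = 45L,
                         n_alt = 0L, phase_set = NA_character_) {
  data.frame(sample_id = sid, chrom = chrom, pos = pos, ref = ref, alt = alt,
             vclass = classify_allele(ref, alt), t_depth = t_depth,
             t_alt = t_alt, n_depth = n_depth, n_alt = n_alt,
             pop_af = NA_real_, phase_set = phase_set, gene = NA_character_,
             consequence = consequence, filters = "", stringsAsFactors = FALSE)
}

#' Generate the default synthetic cohort
#'
#' Produces variants, copy-number profiles, a minimizer report, the
#' sample manifest and a `truth` record describing everything that was
#' planted.  Fully deterministic given `(config, seed)`; per-sample
#' streams are forked by a stable hash of the sample id.
#'
#' @param config [cohort_config()].
#' @param seed integer run seed.
#' @return list of class `synthetic_cohort` with elements `truth`,
#'   `manifest`, `variants`, `targets`, `profiles`, `minimizer`,
#'   `gene_models`, `arm_table`, `genome`, `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  cfg <- check_cohort_config(config)
  ids <- sample_ids(cfg)
  genome <- cfg$genome
  exons <- synthetic_target_intervals(genome, cfg$exon_bp,
                                      cfg$exon_spacing_bp)
  targets <- target_space(exons, flank_bp = cfg$flank_bp)
  gene_models <- default_gene_models(genome, cfg$n_background_genes)
  hotspots <- default_hotspot_sites()

  # --- planted assignments (deterministic, not RNG-driven) --------------
  ctnnb1_carriers <- ids$benign[seq_len(cfg$n_ctnnb1)]
  fbxw11_carriers <- ids$benign[cfg$n_ctnnb1 + seq_len(cfg$n_fbxw11)]
  low_purity <- ctnnb1_carriers[seq_len(cfg$n_low_purity_hotspot)]
  hypermutator <- ids$malignant[1L]
  ct_sample <- ids$malignant[min(2L, cfg$n_malignant)]
  mal_fbxw11 <- if (cfg$n_malignant_fbxw11 > 0L) {
    ids$malignant[cfg$n_malignant - seq_len(cfg$n_malignant_fbxw11) + 1L]
  } else character(0)
  arm_losses <- list()
  arm_pool <- setdiff(ids$malignant, c(hypermutator, ct_sample))
  offset <- 0L
  for (arm in names(cfg$arm_loss_plants)) {
    k <- cfg$arm_loss_plants[[arm]]
    take <- arm_pool[((offset + seq_len(k) - 1L) %% length(arm_pool)) + 1L]
    arm_losses[[arm]] <- take
    offset <- offset + max(k - 1L, 1L)
  }

  hotspot_assignment <- c(
    stats::setNames(rep("CTNNB1_hotspot", length(ctnnb1_carriers)),
                    ctnnb1_carriers),
    stats::setNames(rep("FBXW11_hotspot", length(fbxw11_carriers)),
                    fbxw11_carriers),
    stats::setNames(rep("FBXW11_hotspot", length(mal_fbxw11)), mal_fbxw11))
  all_ids <- c(ids$benign, ids$malignant)
  hotspot_assignment <- stats::setNames(
    ifelse(all_ids %in% names(hotspot_assignment),
           hotspot_assignment[all_ids], "none"), all_ids)

  manifest <- data.frame(
    sample_id = all_ids,
    cohort = c(rep("benign", cfg$n_benign), rep("malignant", cfg$n_malignant)),
    stringsAsFactors = FALSE)

  # --- variants ---------------------------------------------------------
  set.seed(fork_seed(seed, "rates"))
  rates <- c(rlnorm(cfg$n_benign, log(cfg$benign_tmb_median),
                    cfg$benign_tmb_sdlog),
             rlnorm(cfg$n_malignant, log(cfg$malignant_tmb_median),
                    cfg$malignant_tmb_sdlog))
  names(rates) <- all_ids
  rates[hypermutator] <- cfg$hypermutator_tmb
  indel_fracs <- stats::setNames(rep(cfg$indel_frac, length(all_ids)),
                                 all_ids)
  indel_fracs[hypermutator] <- cfg$hypermutator_indel_frac

  # background mutations avoid the anchor genes, whose carriers are
  # planted explicitly, so planted prevalences stay exact
  anchors <- anchor_gene_models()
  in_anchor <- vapply(seq_len(nrow(exons)), function(i) {
    any(anchors$chrom == exons$chrom[i] &
          anchors$start <= exons$end[i] &
          anchors$end >= exons$start[i] + 1L)
  }, logical(1))
  exons_bg <- exons[!in_anchor, , drop = FALSE]
  per_sample <- lapply(all_ids, function(sid) {
    simulate_sample_variants(sid, rates[[sid]], indel_fracs[[sid]], cfg,
                             exons_bg, targets$total_mb, seed)
  })
  variants <- do.call(rbind, per_sample)

  ct_site <- hotspots[hotspots$gene == "CTNNB1", ]
  fb_site <- hotspots[hotspots$gene == "FBXW11", ]
  plants <- list()
  for (sid in ctnnb1_carriers) {
    lowp <- sid %in% low_purity
    plants[[length(plants) + 1L]] <- planted_call(
      sid, ct_site$chrom, ct_site$pos, ct_site$ref, ct_site$alt,
      "missense_variant",
      t_depth = 60L, t_alt = if (lowp) 4L else 24L)
  }
  for (sid in c(fbxw11_carriers, mal_fbxw11)) {
    plants[[length(plants) + 1L]] <- planted_call(
      sid, fb_site$chrom, fb_site$pos, fb_site$ref, fb_site$alt,
      "missense_variant")
  }
  gm <- gene_models
  anchor <- function(g) gm[gm$gene == g, ]
  two_hit_truth <- list()
  if (isTRUE(cfg$plant_two_hit)) {
    # anchor-gene starts sit on the exon grid; offsets below stay inside
    # an exon so planted calls survive the target-proximity filter
    a <- anchor("MLH1")
    plants[[length(plants) + 1L]] <- planted_call(
      hypermutator, a$chrom, a$start + 1500, "G", "A",
      "splice_acceptor_variant")
    two_hit_truth$MLH1 <- list(sample = hypermutator,
                               evidence = "variant_plus_loh")
    if (length(arm_losses$chr3q)) {
      a <- anchor("CYLD")
      cyld_sample <- arm_losses$chr3q[1L]
      plants[[length(plants) + 1L]] <- planted_call(
        cyld_sample, a$chrom, a$start + 1200, "C", "T", "stop_gained")
      two_hit_truth$CYLD <- list(sample = cyld_sample,
                                 evidence = "variant_plus_loh")
    }
    pool <- setdiff(ids$malignant,
                    c(hypermutator, unlist(arm_losses), mal_fbxw11))
    if (length(pool) >= 1L) {
      a <- anchor("KMT2D")
      plants[[length(plants) + 1L]] <- planted_call(
        pool[1L], a$chrom, a$start + 1000, "CTG", "C", "frameshift_variant")
      plants[[length(plants) + 1L]] <- planted_call(
        pool[1L], a$chrom, a$start + 11500, "T", "TAA", "frameshift_variant")
      two_hit_truth$KMT2D <- list(sample = pool[1L],
                                  evidence = "two_variants")
    }
    if (length(pool) >= 2L) {
      a <- anchor("DICER1")
      plants[[length(plants) + 1L]] <- planted_call(
        pool[2L], a$chrom, a$start + 1600, "G", "T", "stop_gained")
      plants[[length(plants) + 1L]] <- planted_call(
        pool[2L], a$chrom, a$start + 10800, "AGT", "A", "frameshift_variant")
      two_hit_truth$DICER1 <- list(sample = pool[2L],
                                   evidence = "two_variants")
    }
  }
  variants <- rbind(variants, do.call(rbind, plants))

  # gene labels from the gene model intervals
  gr_var <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, end = variants$pos))
  gr_gene <- GenomicRanges::GRanges(
    seqnames = gm$chrom,
    ranges = IRanges::IRanges(start = gm$start, end = gm$end))
  hit <- GenomicRanges::findOverlaps(gr_var, gr_gene, select = "first")
  variants$gene <- ifelse(is.na(hit), NA_character_, gm$gene[hit])
  variants <- sort_variants(variants)
  rownames(variants) <- NULL

  # --- copy-number profiles ---------------------------------------------
  arm_table <- default_arm_table(genome)
  profiles <- lapply(all_ids, function(sid) {
    make_sample_profile(sid, genome, arm_table, arm_losses, cfg, seed,
                        gene_models, hypermutator,
                        mlh1_loh = isTRUE(cfg$plant_two_hit))
  })
  names(profiles) <- all_ids
  ct_cfg <- cfg$chromothripsis
  ct_plant <- NULL
  if (!is.null(ct_cfg)) {
    profiles[[ct_sample]] <- plant_chromothripsis(
      profiles[[ct_sample]], ct_cfg$chrom,
      n_switches = ct_cfg$n_switches, n_states = ct_cfg$n_states)
    ct_plant <- list(sample = ct_sample, chrom = ct_cfg$chrom,
                     n_switches = ct_cfg$n_switches,
                     n_states = ct_cfg$n_states)
  }

  # --- minimizer report --------------------------------------------------
  minimizer <- simulate_minimizer_report(cfg, seed)
  minimizer <- plant_taxon(minimizer, cfg$planted_taxon,
                           enrichment = cfg$taxon_enrichment)

  truth <- list(
    seed = seed,
    cohort_sizes = c(benign = cfg$n_benign, malignant = cfg$n_malignant),
    hotspot_assignment = hotspot_assignment,
    low_purity_hotspot_samples = low_purity,
    hypermutator_sample = hypermutator,
    planted_arm_losses = do.call(rbind, c(
      list(data.frame(sample = character(0), arm = character(0),
                      stringsAsFactors = FALSE)),
      lapply(names(arm_losses)[lengths(arm_losses) > 0], function(a) {
        data.frame(sample = arm_losses[[a]], arm = a,
                   stringsAsFactors = FALSE)
      }))),
    chromothripsis_plant = ct_plant,
    planted_taxon = list(taxon_id = cfg$planted_taxon,
                         enrichment = cfg$taxon_enrichment),
    two_hit_plants = two_hit_truth,
    background_tmb_params = list(
      benign = c(median = cfg$benign_tmb_median, sdlog = cfg$benign_tmb_sdlog),
      malignant = c(median = cfg$malignant_tmb_median,
                    sdlog = cfg$malignant_tmb_sdlog),
      hypermutator = cfg$hypermutator_tmb))

  structure(list(truth = truth, manifest = manifest, variants = variants,
                 targets = targets, profiles = profiles,
                 minimizer = minimizer, gene_models = gene_models,
                 arm_table = arm_table, genome = genome, config = cfg),
            class = "synthetic_cohort")
}

make_sample_profile <- function(sid, genome, arm_table, arm_losses, cfg,
                                seed, gene_models, hypermutator, mlh1_loh) {
  set.seed(fork_seed(seed, paste0(sid, ":cn")))
  lost_arms <- names(arm_losses)[vapply(arm_losses, function(s) sid %in% s,
                                        logical(1))]
  segs <- list()
  for (i in seq_len(nrow(genome))) {
    g <- genome[i, ]
    qa <- paste0(g$chrom, "q")
    pa <- paste0(g$chrom, "p")
    cen <- g$centromere
    if (qa %in% lost_arms) {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = g$chrom, start = c(1, cen + 1), end = c(cen, g$length),
        total_cn = c(2L, 1L), minor_cn = c(1L, 0L), stringsAsFactors = FALSE)
    } else if (pa %in% lost_arms) {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = g$chrom, start = c(1, cen + 1), end = c(cen, g$length),
        total_cn = c(1L, 2L), minor_cn = c(0L, 1L), stringsAsFactors = FALSE)
    } else {
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = g$chrom, start = 1, end = g$length, total_cn = 2L,
        minor_cn = 1L, stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, segs)
  profile <- cn_profile(sid, segments, ploidy = 2,
                        goodness_of_fit = round(runif(1, 0.93, 0.99), 3))
  # occasional sporadic focal event (keeps altered fraction low but nonzero)
  if (runif(1) < 0.3) {
    g <- genome[sample.int(nrow(genome), 1L), ]
    size <- sample(3e6:8e6, 1L)
    start <- sample.int(g$length - size, 1L)
    cn <- sample(c(1L, 3L), 1L)
    profile <- overlay_segment(profile, g$chrom, start, start + size - 1L,
                               total_cn = cn,
                               minor_cn = if (cn == 1L) 0L else 1L)
  }
  if (mlh1_loh && sid == hypermutator) {
    a <- gene_models[gene_models$gene == "MLH1", ]
    profile <- overlay_segment(profile, a$chrom, a$start - 500000,
                               a$end + 500000, total_cn = 1L, minor_cn = 0L)
  }
  profile
}

# Replace the copy-number state over [start, end] on one chromosome,
# splitting flanking segments as needed.
overlay_segment <- function(profile, chrom, start, end, total_cn, minor_cn) {
  seg <- profile$segments
  on_chr <- seg$chrom == chrom
  chr_seg <- seg[on_chr, , drop = FALSE]
  if (nrow(chr_seg) == 0L) stop("chromosome ", chrom, " absent from profile",
                                call. = FALSE)
  keep <- list()
  for (i in seq_len(nrow(chr_seg))) {
    s <- chr_seg[i, ]
    if (s$end < start || s$start > end) {
      keep[[length(keep) + 1L]] <- s
      next
    }
    if (s$start < start) {
      left <- s; left$end <- start - 1
      keep[[length(keep) + 1L]] <- left
    }
    if (s$end > end) {
      right <- s; right$start <- end + 1
      keep[[length(keep) + 1L]] <- right
    }
  }
  keep[[length(keep) + 1L]] <- data.frame(
    chrom = chrom, start = start, end = end, total_cn = total_cn,
    minor_cn = minor_cn, stringsAsFactors = FALSE)
  new_chr <- do.call(rbind, keep)
  out <- rbind(seg[!on_chr, , drop = FALSE], new_chr)
  cn_profile(profile$sample_id, out, ploidy = profile$ploidy,
             goodness_of_fit = profile$goodness_of_fit)
}

#' Plant a chromothripsis-like oscillation into a copy-number profile
#'
#' Rewrites a region of at most 50 Mb on one chromosome into
#' `n_switches + 1` equal segments whose total copy numbers oscillate
#' among `n_states` distinct states, producing exactly `n_switches`
#' adjacent total-CN changes; outside the region the profile is
#' unchanged.  For an even switch count the oscillation starts and ends
#' at the baseline state so the region boundaries add no extra switches;
#' for an odd count the region is anchored at the chromosome end.
#'
#' @param profile [cn_profile] object.
#' @param chromosome chromosome to rewrite.
#' @param n_switches number of CN state switches (>= 1).
#' @param n_states number of distinct total-CN states (>= 2; at most
#'   `floor(n_switches/2) + 1`).
#' @param region_start 1-based start of the region (default: 2,000,001
#'   for even `n_switches`, chromosome end minus region for odd).
#' @param region_bp region length in bp (default `min(45 Mb, 90%` of the
#'   chromosome)).
#' @return A new [cn_profile].
#' @export
plant_chromothripsis <- function(profile, chromosome, n_switches,
                                 n_states = 2L, region_start = NULL,
                                 region_bp = NULL) {
  stopifnot(inherits(profile, "cn_profile"), n_switches >= 1L, n_states >= 2L)
  seg <- profile$segments
  chr_seg <- seg[seg$chrom == chromosome, , drop = FALSE]
  if (nrow(chr_seg) == 0L) {
    stop("chromosome ", chromosome, " absent from profile", call. = FALSE)
  }
  chrom_len <- max(chr_seg$end)
  if (is.null(region_bp)) region_bp <- min(45e6, floor(0.9 * chrom_len))
  if (region_bp > chrom_len) {
    stop("chromosome ", chromosome, " shorter than requested region",
         call. = FALSE)
  }
  even <- n_switches %% 2L == 0L
  max_states <- floor(n_switches / 2) + 1L
  if (n_states > max_states) {
    stop("n_states = ", n_states, " needs more than ", n_switches,
         " switches", call. = FALSE)
  }
  if (is.null(region_start)) {
    region_start <- if (even) min(2000001, chrom_len - region_bp + 1)
                    else chrom_len - region_bp + 1
  }
  region_end <- region_start + region_bp - 1
  if (region_end > chrom_len) {
    stop("region extends past chromosome end", call. = FALSE)
  }
  if (!even && region_end != chrom_len) {
    stop("odd switch counts require the region to end at the chromosome end",
         call. = FALSE)
  }
  baseline <- 2L
  others <- setdiff(c(1L, 3L, 4L, 5L, 6L, 7L), baseline)[seq_len(n_states - 1L)]
  states <- integer(n_switches + 1L)
  states[seq(1L, n_switches + 1L, by = 2L)] <- baseline
  odd_slots <- seq(2L, n_switches + 1L, by = 2L)
  states[odd_slots] <- rep(others, length.out = length(odd_slots))
  # equal integer split of the region across the oscillation segments
  k <- n_switches + 1L
  widths <- rep(floor(region_bp / k), k)
  widths[seq_len(region_bp - sum(widths))] <-
    widths[seq_len(region_bp - sum(widths))] + 1L
  starts <- region_start + cumsum(c(0, widths[-k]))
  osc <- data.frame(chrom = chromosome, start = starts,
                    end = starts + widths - 1,
                    total_cn = states,
                    minor_cn = pmin(1L, states), stringsAsFactors = FALSE)
  out <- profile
  for (i in seq_len(nrow(osc))) {
    out <- overlay_segment(out, chromosome, osc$start[i], osc$end[i],
                           osc$total_cn[i], osc$minor_cn[i])
  }
  out
}

simulate_minimizer_report <- function(cfg, seed) {
  set.seed(fork_seed(seed, "minimizer"))
  n <- cfg$n_taxa
  taxa <- sprintf("TAX%04d", seq_len(n))
  M <- pmax(100L, as.integer(round(rlnorm(n, log(4e4), 0.5))))
  reads <- pmax(10L, as.integer(round(rlnorm(n, log(1500), 0.5))))
  N <- cfg$taxon_N
  if (cfg$planted_taxon %in% taxa) {
    i <- match(cfg$planted_taxon, taxa)
    M[i] <- cfg$planted_taxon_M
    reads[i] <- cfg$planted_taxon_n
  }
  m <- rbinom(n, M, reads / N)
  rec <- data.frame(sample_id = "cohort_pool", taxon_id = taxa, m = m, M = M,
                    n = reads, N = N, stringsAsFactors = FALSE)
  rec$proportion <- rec$m / rec$M
  rec$p_value <- NA_real_
  rec$q_value <- NA_real_
  rec
}

#' Raise a taxon's minimizer count to a fixed enrichment over the null
#'
#' Sets the planted taxon's observed distinct minimizers to
#' `enrichment` times the null expectation `M * n / N`, capped at `M`.
#'
#' @param records minimizer report data frame.
#' @param taxon_id taxon to enrich (must be present).
#' @param enrichment multiplicative enrichment, strictly greater than 1.
#' @return the report with the planted row updated.
#' @export
plant_taxon <- function(records, taxon_id, enrichment) {
  if (enrichment <= 1) stop("enrichment must be > 1", call. = FALSE)
  i <- which(records$taxon_id == taxon_id)
  if (length(i) == 0L) stop("taxon ", taxon_id, " absent from report",
                            call. = FALSE)
  expected <- records$M[i] * records$n[i] / records$N[i]
  records$m[i] <- pmin(records$M[i], as.integer(round(enrichment * expected)))
  records$proportion[i] <- records$m[i] / records$M[i]
  records
}

#' Write a synthetic cohort bundle to disk
#'
#' Emits exactly the formats the I/O layer reads -- variant table,
#' segment table, minimizer report, manifest, target BED -- plus the
#' truth manifest as JSON.  Output is byte-identical for identical
#' `(config, seed)`.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_bundle <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = cohort$truth$seed)
  write_variant_table(cohort$variants, file.path(dir, "variants.tsv"), meta)
  write_segments(cohort$profiles, file.path(dir, "segments.tsv"), meta)
  write_minimizer_report(cohort$minimizer,
                         file.path(dir, "minimizer_report.tsv"), meta)
  write.table(cohort$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bed <- synthetic_target_intervals(cohort$genome, cohort$config$exon_bp,
                                    cohort$config$exon_spacing_bp)
  write.table(bed, file.path(dir, "targets.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(dir)
}
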