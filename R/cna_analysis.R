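# Copy-number analytics: altered-genome fraction, broad arm events,
# chromothripsis CN-state-switch scoring with tiered confidence and
# chromosome-length scaling, focal-event post-filters, and two-hit
# (biallelic inactivation) calling.

seg_len <- function(seg) seg$end - seg$start + 1

overlap_len <- function(seg, start, end) {
  pmax(0, pmin(seg$end, end) - pmax(seg$start, start) + 1)
}

is_autosome <- function(chrom) {
  !grepl("^(chr)?[XYxy]$", chrom)
}

#' Fraction of the autosomal genome with altered copy number
#'
#' The altered-genome fraction is the summed length of autosomal segments
#' whose total copy number departs from the baseline, divided by the
#' total autosomal segmented length.  The default baseline is the diploid
#' state (total CN = 2); `baseline = "ploidy"` instead measures departure
#' from the rounded sample ploidy.
#'
#' @param profile [cn_profile]; profiles flagged `low_fit` are refused.
#' @param baseline `"diploid"` (default) or `"ploidy"`.
#' @return fraction in `[0, 1]`.
#' @export
altered_genome_fraction <- function(profile,
                                    baseline = c("diploid", "ploidy")) {
  stopifnot(inherits(profile, "cn_profile"))
  baseline <- match.arg(baseline)
  if ("low_fit" %in% profile$flags) {
    stop("profile ", profile$sample_id,
         " is flagged low_fit; excluded from copy-number analysis",
         call. = FALSE)
  }
  seg <- profile$segments[is_autosome(profile$segments$chrom), , drop = FALSE]
  if (nrow(seg) == 0L) stop("empty profile", call. = FALSE)
  base_cn <- if (baseline == "diploid") 2L else as.integer(round(profile$ploidy))
  total <- sum(as.numeric(seg_len(seg)))
  altered <- sum(as.numeric(seg_len(seg)[seg$total_cn != base_cn]))
  altered / total
}

#' Call broad (arm-level) copy-number events
#'
#' An arm is called lost when at least half its length has total CN below
#' 2, gained when at least half has total CN above 2, and neutral
#' otherwise.  If the lost and gained lengths tie at exactly half an arm
#' each, loss takes precedence.
#'
#' @param profile [cn_profile].
#' @param arm_table data frame `chrom`, `arm`, `start`, `end`
#'   (see [default_arm_table()]).
#' @return data frame `arm`, `call` in `{loss, gain, neutral}`, with the
#'   lost/gained length fractions.
#' @export
call_broad_events <- function(profile, arm_table) {
  stopifnot(inherits(profile, "cn_profile"))
  if ("low_fit" %in% profile$flags) {
    stop("profile ", profile$sample_id, " is flagged low_fit", call. = FALSE)
  }
  seg <- profile$segments
  missing_arm <- setdiff(unique(seg$chrom), unique(arm_table$chrom))
  if (length(missing_arm)) {
    stop("arm table lacks chromosome(s): ",
         paste(missing_arm, collapse = ", "), call. = FALSE)
  }
  res <- lapply(seq_len(nrow(arm_table)), function(i) {
    a <- arm_table[i, ]
    arm_len <- a$end - a$start + 1
    on_chr <- seg[seg$chrom == a$chrom, , drop = FALSE]
    ol <- overlap_len(on_chr, a$start, a$end)
    loss_frac <- sum(as.numeric(ol[on_chr$total_cn < 2])) / arm_len
    gain_frac <- sum(as.numeric(ol[on_chr$total_cn > 2])) / arm_len
    call <- if (loss_frac >= 0.5) "loss"
            else if (gain_frac >= 0.5) "gain"
            else "neutral"
    data.frame(sample_id = profile$sample_id, arm = a$arm, call = call,
               loss_frac = loss_frac, gain_frac = gain_frac,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Maximum copy-number state switches within a sliding window
#'
#' A switch is a breakpoint between adjacent segments on one chromosome
#' with differing total copy number.  Candidate windows of `window_mb`
#' megabases are anchored at every such breakpoint; since any window can
#' slide until its left edge meets a breakpoint without losing switches,
#' the maximum over anchored windows is exact.
#'
#' @param profile [cn_profile].
#' @param chrom chromosome to scan.
#' @param window_mb window size in Mb (default 50).
#' @return list with `count` (max switches in any window), `window`
#'   (start/end of the achieving window, `NA` when there are no
#'   switches) and `n_states` (distinct total-CN values among segments
#'   overlapping the achieving window).
#' @export
count_cn_switches <- function(profile, chrom, window_mb = 50) {
  stopifnot(inherits(profile, "cn_profile"))
  seg <- profile$segments[profile$segments$chrom == chrom, , drop = FALSE]
  if (nrow(seg) == 0L) {
    stop("chromosome ", chrom, " absent from profile", call. = FALSE)
  }
  seg <- seg[order(seg$start), , drop = FALSE]
  if (nrow(seg) == 1L) {
    return(list(count = 0L, window = c(NA_real_, NA_real_), n_states = 1L))
  }
  change <- which(diff(seg$total_cn) != 0)
  if (length(change) == 0L) {
    return(list(count = 0L, window = c(NA_real_, NA_real_),
                n_states = length(unique(seg$total_cn))))
  }
  bp <- seg$end[change]           # breakpoint = end of the left segment
  w <- window_mb * 1e6
  counts <- vapply(bp, function(b) sum(bp >= b & bp <= b + w), integer(1))
  best <- which.max(counts)
  ws <- bp[best]
  we <- ws + w
  in_win <- seg$start <= we & seg$end >= ws
  list(count = counts[best], window = c(ws, we),
       n_states = length(unique(seg$total_cn[in_win])))
}

#' Scaled chromothripsis switch-count thresholds
#'
#' Tier thresholds of 10 (high), 8 (intermediate) and 6 (low) switches
#' per 50 Mb, scaled by `min(1, chrom_length_mb / window_mb)` for
#' chromosomes shorter than the window and rounded to the nearest whole
#' number (halves away from zero).  A 46.709 Mb chromosome gives the
#' scaling factor 0.934 and thresholds 9 / 7 / 6.
#'
#' @param chrom_length_mb chromosome length in Mb.
#' @param window_mb window size in Mb (default 50).
#' @return list with `scaling_factor` and integer `thresholds`
#'   (`high`, `intermediate`, `low`).
#' @export
scale_switch_thresholds <- function(chrom_length_mb, window_mb = 50) {
  stopifnot(chrom_length_mb > 0)
  scale <- min(1, chrom_length_mb / window_mb)
  th <- round_half_up(c(high = 10, intermediate = 8, low = 6) * scale)
  list(scaling_factor = scale, thresholds = th)
}

#' Classify a chromothripsis candidate by switch count and CN states
#'
#' Confidence tiers follow the switch-count definitions (10+/8-9/6-7
#' switches in 50 Mb), scaled for chromosomes shorter than the window
#' (see [scale_switch_thresholds()]).  Calls are canonical when the
#' window oscillates among 2 or 3 distinct total-CN states and
#' non-canonical above 3; canonicity is not applicable when no tier is
#' reached.
#'
#' @param switch_count maximum switch count (>= 0).
#' @param n_states distinct total-CN states in the achieving window.
#' @param chrom_length_mb chromosome length in Mb.
#' @param window_mb window size in Mb (default 50).
#' @return list with `tier` in `{high, intermediate, low, none}`,
#'   `canonicity` in `{canonical, non_canonical, not_applicable}`, and
#'   the scaled `thresholds`.
#' @export
classify_chromothripsis <- function(switch_count, n_states, chrom_length_mb,
                                    window_mb = 50) {
  stopifnot(switch_count >= 0)
  sc <- scale_switch_thresholds(chrom_length_mb, window_mb)
  th <- sc$thresholds
  tier <- if (switch_count >= th[["high"]]) "high"
          else if (switch_count >= th[["intermediate"]]) "intermediate"
          else if (switch_count >= th[["low"]]) "low"
          else "none"
  canonicity <- if (tier == "none") "not_applicable"
                else if (n_states <= 3) "canonical"
                else "non_canonical"
  list(tier = tier, canonicity = canonicity, thresholds = th,
       scaling_factor = sc$scaling_factor)
}

#' Score every chromosome of a profile for chromothripsis
#'
#' @param profile [cn_profile].
#' @param genome genome model data frame (`chrom`, `length`).
#' @param window_mb window size in Mb (default 50).
#' @return data frame: one row per chromosome with `switch_count`,
#'   `window_start`, `window_end`, `n_states`, `tier`, `canonicity`.
#' @export
call_chromothripsis <- function(profile, genome = default_genome(),
                                window_mb = 50) {
  stopifnot(inherits(profile, "cn_profile"))
  if ("low_fit" %in% profile$flags) {
    stop("profile ", profile$sample_id, " is flagged low_fit", call. = FALSE)
  }
  chroms <- intersect(genome$chrom, unique(profile$segments$chrom))
  rows <- lapply(chroms, function(chr) {
    sw <- count_cn_switches(profile, chr, window_mb)
    cl <- classify_chromothripsis(sw$count, sw$n_states,
                                  genome$length[genome$chrom == chr] / 1e6,
                                  window_mb)
    data.frame(sample_id = profile$sample_id, chrom = chr,
               switch_count = sw$count, window_start = sw$window[1L],
               window_end = sw$window[2L], n_states = sw$n_states,
               tier = cl$tier, canonicity = cl$canonicity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Post-filter focal copy-number events
#'
#' Applies, in order, the three artefact filters for focal events:
#' `removed_small` for events of at most 100 kb; `removed_difficult` for
#' events whose overlap with difficult (hard-to-sequence/map) regions
#' exceeds 40%; `removed_discordant` for events supported by fewer than
#' 75% concordant samples.  Statuses partition the input and re-running
#' on the kept subset changes nothing.
#'
#' @param events data frame `chrom`, `start`, `end`, `direction`
#'   (`gain`/`loss`), plus either a `concordant_fraction` column or a
#'   `supporting_samples` column (comma-separated sample ids) together
#'   with `per_sample_calls`.
#' @param difficult_mask merged [GenomicRanges::GRanges] of difficult
#'   regions, or `NULL` for none.
#' @param per_sample_calls named list of [cn_profile] used to compute
#'   each supporting sample's own segment state at the event locus; a
#'   sample concurs when at least half the event length carries copy
#'   number in the event direction.
#' @param max_small_bp,max_difficult_overlap,min_concordance thresholds
#'   (defaults 100 kb, 0.40, 0.75).
#' @return `events` with `size_bp`, `difficult_overlap_fraction`,
#'   `concordant_fraction` and `status` columns.
#' @export
filter_focal_events <- function(events, difficult_mask = NULL,
                                per_sample_calls = NULL,
                                max_small_bp = 100000,
                                max_difficult_overlap = 0.40,
                                min_concordance = 0.75) {
  if (nrow(events) == 0L) {
    events$status <- character(0)
    return(events)
  }
  events$size_bp <- events$end - events$start
  gr <- GenomicRanges::GRanges(
    seqnames = events$chrom,
    ranges = IRanges::IRanges(start = events$start + 1L, end = events$end))
  if (is.null(difficult_mask) || length(difficult_mask) == 0L) {
    events$difficult_overlap_fraction <- 0
  } else {
    ov_bp <- vapply(seq_along(gr), function(i) {
      sum(as.numeric(IRanges::width(
        suppressWarnings(GenomicRanges::intersect(gr[i], difficult_mask)))))
    }, numeric(1))
    events$difficult_overlap_fraction <- ov_bp / events$size_bp
  }
  if (!"concordant_fraction" %in% names(events)) {
    if (is.null(per_sample_calls) || !"supporting_samples" %in% names(events)) {
      stop("supply either concordant_fraction or supporting_samples with ",
           "per_sample_calls", call. = FALSE)
    }
    events$concordant_fraction <- vapply(seq_len(nrow(events)), function(i) {
      ev <- events[i, ]
      sids <- strsplit(ev$supporting_samples, ",", fixed = TRUE)[[1L]]
      sids <- trimws(sids[nzchar(sids)])
      if (length(sids) == 0L) return(0)
      concur <- vapply(sids, function(sid) {
        p <- per_sample_calls[[sid]]
        if (is.null(p)) return(FALSE)
        seg <- p$segments[p$segments$chrom == ev$chrom, , drop = FALSE]
        ol <- overlap_len(seg, ev$start + 1, ev$end)
        matched <- if (ev$direction == "loss") seg$total_cn < 2
                   else seg$total_cn > 2
        sum(as.numeric(ol[matched])) >= 0.5 * ev$size_bp
      }, logical(1))
      mean(concur)
    }, numeric(1))
  }
  events$status <- ifelse(events$size_bp <= max_small_bp, "removed_small",
                   ifelse(events$difficult_overlap_fraction >
                            max_difficult_overlap, "removed_difficult",
                   ifelse(events$concordant_fraction < min_concordance,
                          "removed_discordant", "kept")))
  events
}

default_damaging_classes <- function() {
  c("stop_gained", "frameshift_variant", "splice_acceptor_variant",
    "splice_donor_variant", "start_lost", "stop_lost")
}

#' Call two-hit (biallelic) inactivation for one sample
#'
#' A gene is called biallelically inactivated either through two distinct
#' damaging variants (`two_variants`) or through one damaging variant
#' combined with loss of heterozygosity -- minor copy number of zero over
#' at least half the gene interval (`variant_plus_loh`).
#'
#' @param calls refined variant data frame for one sample.
#' @param profile the sample's [cn_profile] (may be `NULL`: LOH evidence
#'   is then unavailable).
#' @param gene_models data frame `gene`, `chrom`, `start`, `end`.
#' @param damaging_classes consequence strings treated as damaging
#'   (default: truncating and splice-disrupting classes).
#' @return data frame `sample_id`, `gene`, `evidence`, `details`; zero
#'   rows when no gene qualifies.
#' @export
call_two_hit <- function(calls, profile, gene_models,
                         damaging_classes = default_damaging_classes()) {
  sid <- unique(calls$sample_id)
  if (length(sid) > 1L) {
    stop("call_two_hit expects calls from a single sample", call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    in_gene <- calls$chrom == g$chrom & calls$pos >= g$start &
      calls$pos <= g$end & !is.na(calls$consequence) &
      calls$consequence %in% damaging_classes
    dmg <- calls[in_gene, , drop = FALSE]
    keys <- unique(variant_key(dmg))
    loh <- FALSE
    if (!is.null(profile)) {
      seg <- profile$segments[profile$segments$chrom == g$chrom, ,
                              drop = FALSE]
      ol <- overlap_len(seg, g$start, g$end)
      loh_len <- sum(as.numeric(ol[seg$minor_cn == 0]))
      loh <- loh_len >= 0.5 * (g$end - g$start + 1)
    }
    if (length(keys) >= 2L) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, gene = g$gene, evidence = "two_variants",
        details = paste(keys, collapse = ";"), stringsAsFactors = FALSE)
    } else if (length(keys) == 1L && loh) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, gene = g$gene, evidence = "variant_plus_loh",
        details = paste0(keys, ";LOH"), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(sample_id = character(), gene = character(),
                      evidence = character(), details = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
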