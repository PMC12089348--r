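# Post-calling somatic variant refinement: common-SNP exclusion, in-cis
# SNV -> MNV merging, the allele-length/VAF retention cascade, restriction
# to the neighbourhood of the exome target space, and hotspot rescue.
#
# Every removal is recorded once in an audit log (variant key, rule,
# action) with the first rule that removed the record.

#' Refinement configuration
#'
#' Thresholds of the somatic refinement cascade.  Defaults follow the
#' study design this package models: common germline SNPs are excluded at
#' population MAF >= 0.01; calls need tumour VAF >= 0.1; multinucleotide
#' variants longer than 3 bp are dropped; "complex" long alleles (not both
#' alleles <= 25 bp, or both > 10 bp) are retained only at VAF > 0.25 with
#' >= 20x depth in tumour and matched normal; and calls farther than
#' 100 bp from any flanked target interval are discarded.  Hotspot rescue
#' reinstates filtered calls at configured recurrent sites when tumour
#' evidence is adequate and the matched normal is clean, replacing the
#' study's manual alignment inspection with explicit thresholds.
#'
#' @param common_af_threshold population MAF at or above which a call is
#'   treated as a common germline SNP (default 0.01).
#' @param min_vaf minimum tumour VAF (default 0.1).
#' @param rescue_vaf_floor VAF floor for complex long alleles
#'   (default 0.25; strict `>`).
#' @param min_depth depth needed in tumour and normal for complex alleles
#'   (default 20).
#' @param max_allele_len simple alleles are at most this long (default 25).
#' @param both_long_len alleles are "both long" above this length
#'   (default 10).
#' @param max_mnv_len longest MNV retained/merged (default 3).
#' @param target_proximity_bp maximum gap to a flanked target interval
#'   (default 100, inclusive).
#' @param hotspot_sites data frame `chrom`, `pos`, `ref`, `alt` of
#'   recurrent sites eligible for rescue (defaults to the synthetic
#'   cohort's CTNNB1 and FBXW11 hotspot coordinates).
#' @param rescue_min_t_alt minimum tumour alt reads to rescue (default 3).
#' @param rescue_max_n_vaf maximum normal VAF to rescue (default 0.01).
#' @return A list of class `refinement_config`.
#' @export
refinement_config <- function(common_af_threshold = 0.01,
                              min_vaf = 0.1,
                              rescue_vaf_floor = 0.25,
                              min_depth = 20L,
                              max_allele_len = 25L,
                              both_long_len = 10L,
                              max_mnv_len = 3L,
                              target_proximity_bp = 100L,
                              hotspot_sites = default_hotspot_sites(),
                              rescue_min_t_alt = 3L,
                              rescue_max_n_vaf = 0.01) {
  if (min_vaf > rescue_vaf_floor) {
    stop("min_vaf must not exceed rescue_vaf_floor", call. = FALSE)
  }
  if (any(c(common_af_threshold, min_vaf, rescue_vaf_floor, min_depth,
            max_allele_len, both_long_len, max_mnv_len, target_proximity_bp,
            rescue_min_t_alt, rescue_max_n_vaf) < 0)) {
    stop("refinement thresholds must be non-negative", call. = FALSE)
  }
  structure(
    list(common_af_threshold = common_af_threshold, min_vaf = min_vaf,
         rescue_vaf_floor = rescue_vaf_floor, min_depth = min_depth,
         max_allele_len = max_allele_len, both_long_len = both_long_len,
         max_mnv_len = max_mnv_len,
         target_proximity_bp = target_proximity_bp,
         hotspot_sites = hotspot_sites,
         rescue_min_t_alt = rescue_min_t_alt,
         rescue_max_n_vaf = rescue_max_n_vaf),
    class = "refinement_config")
}

# Tumour VAF; defined as 0 when depth is 0 (such records are later
# removed as malformed rather than dividing by zero).
tumour_vaf <- function(calls) {
  ifelse(calls$t_depth > 0, calls$t_alt / calls$t_depth, 0)
}

normal_vaf <- function(calls) {
  ifelse(calls$n_depth > 0, calls$n_alt / calls$n_depth, 0)
}

audit_entry <- function(calls, rule, action) {
  data.frame(variant_key = variant_key(calls),
             rule = rep(rule, nrow(calls)),
             action = rep(action, nrow(calls)),
             stringsAsFactors = FALSE)
}

empty_audit <- function() {
  data.frame(variant_key = character(), rule = character(),
             action = character(), stringsAsFactors = FALSE)
}

#' Exclude common germline SNPs
#'
#' A call is removed if and only if its population allele frequency is at
#' or above `common_af_threshold` in the configured population source.  A
#' missing `pop_af` never removes a call.
#'
#' @param calls variant data frame.
#' @param cfg [refinement_config()].
#' @return list with `calls` (retained) and `audit` (removal log).
#' @export
exclude_common_snps <- function(calls, cfg = refinement_config()) {
  common <- !is.na(calls$pop_af) & calls$pop_af >= cfg$common_af_threshold
  list(calls = calls[!common, , drop = FALSE],
       audit = audit_entry(calls[common, , drop = FALSE],
                           "common_snp", "removed"))
}

#' Merge adjacent in-cis SNVs into MNVs
#'
#' Maximal runs of SNVs at consecutive positions that share sample,
#' chromosome and phase set (i.e. are in cis) are replaced by one MNV.
#' Runs longer than `max_mnv_len` are left unmerged as their constituent
#' SNVs.  The merged record's tumour/normal support is the minimum over
#' constituents (the conservative read support for the joint event).
#'
#' @param calls variant data frame; `phase_set` identifies in-cis groups.
#' @param cfg [refinement_config()].
#' @return variant data frame with qualifying runs replaced by MNVs.
#' @export
merge_adjacent_snvs <- function(calls, cfg = refinement_config()) {
  if (nrow(calls) == 0L) return(calls)
  phased_snv <- calls$vclass == "SNV" & !is.na(calls$phase_set) &
    nzchar(calls$phase_set)
  keep <- calls[!phased_snv, , drop = FALSE]
  cand <- calls[phased_snv, , drop = FALSE]
  if (nrow(cand) == 0L) return(sort_variants(calls))
  groups <- split(cand, list(cand$sample_id, cand$phase_set), drop = TRUE)
  merged <- lapply(groups, function(g) {
    if (length(unique(g$chrom)) > 1L) {
      stop("phase_set ", g$phase_set[1L], " of sample ", g$sample_id[1L],
           " spans multiple chromosomes", call. = FALSE)
    }
    g <- g[order(g$pos), , drop = FALSE]
    run_id <- cumsum(c(1L, diff(g$pos) != 1L))
    do.call(rbind, lapply(split(g, run_id), function(run) {
      if (nrow(run) < 2L || nrow(run) > cfg$max_mnv_len) return(run)
      mnv <- run[1L, , drop = FALSE]
      mnv$ref <- paste(run$ref, collapse = "")
      mnv$alt <- paste(run$alt, collapse = "")
      mnv$vclass <- "MNV"
      mnv$t_depth <- min(run$t_depth)
      mnv$t_alt <- min(run$t_alt)
      mnv$n_depth <- min(run$n_depth)
      mnv$n_alt <- min(run$n_alt)
      mnv$pop_af <- suppressWarnings(max(run$pop_af, na.rm = TRUE))
      if (!is.finite(mnv$pop_af)) mnv$pop_af <- NA_real_
      mnv
    }))
  })
  out <- rbind(keep, do.call(rbind, merged))
  rownames(out) <- NULL
  sort_variants(out)
}

# The one predicate encoding the adopted reading of the allele-length
# retention rule: an allele pair is "simple" when both alleles are at
# most max_allele_len long AND they are not both longer than
# both_long_len.  Everything else is "complex" and must clear the higher
# VAF/depth bar.  Alternative readings are a one-line change here.
is_simple_allele <- function(ref, alt, cfg) {
  lr <- nchar(ref)
  la <- nchar(alt)
  (pmax(lr, la) <= cfg$max_allele_len) & !(lr > cfg$both_long_len &
                                             la > cfg$both_long_len)
}

#' Apply the allele-length / VAF retention cascade
#'
#' Retention rules, applied in order, each removal logged once with the
#' first rule that fired:
#' \enumerate{
#'   \item records with zero tumour depth are removed (`malformed`);
#'   \item MNVs longer than `max_mnv_len` are removed (`long_mnv`);
#'   \item tumour VAF below `min_vaf` removes the record (`low_vaf`);
#'   \item simple allele pairs (see Details) are retained;
#'   \item complex allele pairs are retained only with VAF above
#'     `rescue_vaf_floor` and at least `min_depth` in both tumour and
#'     normal (`complex_fail` otherwise).
#' }
#'
#' @details A pair of alleles is simple when both are at most
#' `max_allele_len` (25 bp) long and they are not both longer than
#' `both_long_len` (10 bp); this is the package's documented reading of
#' an ambiguous published rule and is isolated in a single predicate.
#'
#' @param calls variant data frame.
#' @param cfg [refinement_config()].
#' @return list with `calls` (retained, `filters` annotated) and `audit`.
#' @export
apply_refinement_cascade <- function(calls, cfg = refinement_config()) {
  if (nrow(calls) == 0L) return(list(calls = calls, audit = empty_audit()))
  vaf <- tumour_vaf(calls)
  malformed <- calls$t_depth == 0
  long_mnv <- !malformed & calls$vclass == "MNV" &
    nchar(calls$ref) > cfg$max_mnv_len
  low_vaf <- !malformed & !long_mnv & vaf < cfg$min_vaf
  simple <- is_simple_allele(calls$ref, calls$alt, cfg)
  complex_fail <- !malformed & !long_mnv & !low_vaf & !simple &
    !(vaf > cfg$rescue_vaf_floor & calls$t_depth >= cfg$min_depth &
        calls$n_depth >= cfg$min_depth)
  removed <- malformed | long_mnv | low_vaf | complex_fail
  audit <- rbind(
    audit_entry(calls[malformed, , drop = FALSE], "malformed", "removed"),
    audit_entry(calls[long_mnv, , drop = FALSE], "long_mnv", "removed"),
    audit_entry(calls[low_vaf, , drop = FALSE], "low_vaf", "removed"),
    audit_entry(calls[complex_fail, , drop = FALSE], "complex_fail",
                "removed"))
  kept <- calls[!removed, , drop = FALSE]
  rownames(kept) <- NULL
  list(calls = kept, audit = audit)
}

#' Restrict calls to the neighbourhood of the target space
#'
#' A call is retained if and only if its reference span lies within
#' `target_proximity_bp` of a flanked target interval; a gap of exactly
#' the threshold still counts as within (inclusive boundary).
#'
#' @param calls variant data frame.
#' @param targets [target_space] object (already flanked and merged).
#' @param cfg [refinement_config()].
#' @return list with `calls` and `audit`.
#' @export
restrict_to_target_space <- function(calls, targets,
                                     cfg = refinement_config()) {
  stopifnot(inherits(targets, "target_space"))
  if (length(targets$granges) == 0L) stop("empty target space", call. = FALSE)
  if (nrow(calls) == 0L) return(list(calls = calls, audit = empty_audit()))
  span_end <- calls$pos + pmax(nchar(calls$ref) - 1L, 0L)
  gr <- GenomicRanges::GRanges(
    seqnames = calls$chrom,
    ranges = IRanges::IRanges(start = calls$pos, end = span_end))
  # gap in bases between span and nearest target interval (0 = overlap or
  # adjacency); chromosomes absent from the target space give NA.
  d <- suppressWarnings(GenomicRanges::distanceToNearest(gr, targets$granges))
  gap <- rep(NA_integer_, nrow(calls))
  gap[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
  within <- !is.na(gap) & gap <= cfg$target_proximity_bp
  list(calls = calls[within, , drop = FALSE],
       audit = audit_entry(calls[!within, , drop = FALSE],
                           "off_target", "removed"))
}

#' Rescue filtered calls at configured hotspot sites
#'
#' Recurrently mutated sites (e.g. the CTNNB1 and FBXW11 hotspots) can be
#' lost to VAF or depth filters when tumour purity is low or the matched
#' normal carries contaminating tumour cells.  A raw call at a configured
#' hotspot site that was removed by any filter is reinstated when it has
#' at least `rescue_min_t_alt` tumour alt reads and a normal VAF of at
#' most `rescue_max_n_vaf`.  Reinstated records carry the flag
#' `rescued:<rule>` naming the overridden filter.
#'
#' @param raw_calls all calls before refinement (post MNV merge).
#' @param retained_calls calls surviving the filters.
#' @param audit audit log of removals (used to name the overridden rule).
#' @param cfg [refinement_config()].
#' @return list with `calls` (retained plus rescued) and `audit` (rescue
#'   entries appended).
#' @export
rescue_hotspots <- function(raw_calls, retained_calls, audit,
                            cfg = refinement_config()) {
  hs <- cfg$hotspot_sites
  if (is.null(hs) || nrow(hs) == 0L) {
    return(list(calls = retained_calls, audit = audit))
  }
  site_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt,
                                                   sep = ":")
  hs_keys <- site_key(hs$chrom, hs$pos, hs$ref, hs$alt)
  raw_site <- site_key(raw_calls$chrom, raw_calls$pos, raw_calls$ref,
                       raw_calls$alt)
  at_hotspot <- raw_site %in% hs_keys
  if (!any(at_hotspot)) {
    message("no raw calls at configured hotspot sites; nothing to rescue")
    return(list(calls = retained_calls, audit = audit))
  }
  removed <- !(variant_key(raw_calls) %in% variant_key(retained_calls))
  eligible <- at_hotspot & removed &
    raw_calls$t_alt >= cfg$rescue_min_t_alt &
    normal_vaf(raw_calls) <= cfg$rescue_max_n_vaf
  if (!any(eligible)) return(list(calls = retained_calls, audit = audit))
  rescued <- raw_calls[eligible, , drop = FALSE]
  overridden <- vapply(variant_key(rescued), function(k) {
    hit <- audit$rule[audit$variant_key == k & audit$action == "removed"]
    if (length(hit)) hit[1L] else "unknown"
  }, character(1))
  already <- grepl("rescued:", rescued$filters, fixed = TRUE)
  rescued$filters <- ifelse(already, rescued$filters,
                     ifelse(nzchar(rescued$filters),
                            paste0(rescued$filters, ";rescued:", overridden),
                            paste0("rescued:", overridden)))
  out <- sort_variants(rbind(retained_calls, rescued))
  rownames(out) <- NULL
  list(calls = out,
       audit = rbind(audit, audit_entry(rescued, paste0("rescued:", overridden),
                                        "reinstated")))
}

#' Run the full somatic refinement pipeline
#'
#' Applies, in order: common-SNP exclusion, in-cis SNV to MNV merging,
#' the allele-length/VAF cascade, target-proximity restriction, and
#' hotspot rescue.  The pipeline is idempotent and its result does not
#' depend on input record order.
#'
#' @param calls raw variant data frame.
#' @param targets [target_space] object.
#' @param cfg [refinement_config()].
#' @return list with `calls` (refined) and `audit` (one row per removal
#'   or reinstatement, first rule wins).
#' @export
refine_variants <- function(calls, targets, cfg = refinement_config()) {
  validate_variants(calls)
  s1 <- exclude_common_snps(calls, cfg)
  merged <- merge_adjacent_snvs(s1$calls, cfg)
  s2 <- apply_refinement_cascade(merged, cfg)
  s3 <- restrict_to_target_space(s2$calls, targets, cfg)
  audit <- rbind(s1$audit, s2$audit, s3$audit)
  s4 <- rescue_hotspots(merged, s3$calls, audit, cfg)
  list(calls = s4$calls, audit = s4$audit)
}

#' Write a refinement audit log
#'
#' @param audit audit data frame (`variant_key`, `rule`, `action`).
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(audit, path) {
  write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
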