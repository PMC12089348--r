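# I/O layer: every external format the pipeline touches.
#
# Coordinate conventions (conversions happen here and nowhere else):
#   * variants: 1-based position of the first reference base (VCF);
#   * interval files (targets, difficult-region masks): BED, 0-based
#     half-open; internally intervals are held as 1-based GRanges;
#   * copy-number segments: 1-based inclusive start/end.

VARIANT_COLUMNS <- c("sample_id", "chrom", "pos", "ref", "alt", "vclass",
                     "t_depth", "t_alt", "n_depth", "n_alt", "pop_af",
                     "phase_set", "gene", "consequence", "filters")

# ---------------------------------------------------------------------------
# Target space

#' Construct a flanked, merged target space
#'
#' The assayable coding territory is the set of exome target intervals,
#' each extended by `flank_bp` on both sides (to take in splice sites) and
#' then merged so overlapping bases are counted once.  Its total size in
#' megabases is the denominator of every mutation-burden calculation.
#'
#' @param intervals data frame with columns `chrom`, `start`, `end` in BED
#'   convention (0-based half-open).
#' @param flank_bp non-negative integer flank added to both sides of every
#'   interval before merging (default 2, splice flank).
#' @return An object of class `target_space`: a list with elements
#'   `granges` (merged 1-based [GenomicRanges::GRanges]), `flank_bp` and
#'   `total_mb` (megabases of merged flanked territory).
#' @examples
#' ts <- target_space(data.frame(chrom = "chr1", start = 100, end = 200),
#'                    flank_bp = 2)
#' ts$total_mb  # 104 bp
#' @export
target_space <- function(intervals, flank_bp = 2L) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (flank_bp < 0) stop("flank_bp must be non-negative", call. = FALSE)
  if (nrow(intervals) == 0L) stop("target space is empty", call. = FALSE)
  bad <- which(intervals$end <= intervals$start)
  if (length(bad)) {
    stop("interval with end <= start at input row ", bad[1L], call. = FALSE)
  }
  check_chrom_style(intervals$chrom)
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
  gr <- gr + flank_bp
  IRanges::start(gr) <- pmax(IRanges::start(gr), 1L)
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  structure(
    list(granges = gr,
         flank_bp = as.integer(flank_bp),
         total_mb = sum(as.numeric(IRanges::width(gr))) / 1e6),
    class = "target_space")
}

#' @export
print.target_space <- function(x, ...) {
  cat(sprintf("<target_space> %d merged intervals, flank %d bp, %.6f Mb\n",
              length(x$granges), x$flank_bp, x$total_mb))
  invisible(x)
}

#' Read exome target intervals (BED) into a target space
#'
#' @param path BED3 file, 0-based half-open, tab-separated, no header.
#'   Unsorted input is accepted and sorted.
#' @param flank_bp flank in bp added to both sides before merging.
#' @return A [target_space] object.
#' @export
read_targets <- function(path, flank_bp = 2L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bed <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns", call. = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  target_space(bed[, 1:3], flank_bp = flank_bp)
}

#' Read a BED interval mask (e.g. difficult regions) as merged GRanges
#'
#' @param path BED3 file, 0-based half-open.
#' @return Merged, sorted [GenomicRanges::GRanges] (1-based).
#' @export
read_interval_mask <- function(path) {
  read_targets(path, flank_bp = 0L)$granges
}

# ---------------------------------------------------------------------------
# Variants

#' Validate a somatic variant table
#'
#' Enforces the per-record invariants: alt-supporting reads never exceed
#' depth, ref differs from alt, and the variant class is consistent with
#' the allele lengths (an SNV has single-base ref and alt).
#'
#' @param calls data frame of variant calls.
#' @param line_offset added to row indices in error messages (e.g. 1 for a
#'   file with a header line).
#' @return `calls`, invisibly, if valid; otherwise an error naming the
#'   offending line.
#' @export
validate_variants <- function(calls, line_offset = 0L) {
  missing_cols <- setdiff(VARIANT_COLUMNS, names(calls))
  if (length(missing_cols)) {
    stop("variant table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(calls) == 0L) return(invisible(calls))
  check_chrom_style(calls$chrom)
  fail <- function(i, msg) {
    stop(sprintf("invalid variant record at line %d: %s", i + line_offset, msg),
         call. = FALSE)
  }
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    if (is.na(r$t_depth) || is.na(r$t_alt) || r$t_alt > r$t_depth) {
      fail(i, "t_alt > t_depth (or missing depth)")
    }
    if (is.na(r$n_depth) || is.na(r$n_alt) || r$n_alt > r$n_depth) {
      fail(i, "n_alt > n_depth (or missing depth)")
    }
    if (r$t_depth < 0 || r$t_alt < 0 || r$n_depth < 0 || r$n_alt < 0) {
      fail(i, "negative read counts")
    }
    if (identical(r$ref, r$alt)) fail(i, "ref equals alt")
    if (!is.na(r$pop_af) && (r$pop_af < 0 || r$pop_af > 1)) {
      fail(i, "pop_af outside [0,1]")
    }
    if (r$vclass == "SNV" && (nchar(r$ref) != 1L || nchar(r$alt) != 1L)) {
      fail(i, "vclass SNV but alleles are not single bases")
    }
  }
  invisible(calls)
}

sort_variants <- function(calls) {
  calls[order(calls$sample_id, calls$chrom, calls$pos, calls$ref, calls$alt), ,
        drop = FALSE]
}

empty_variants <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), vclass = character(),
             t_depth = integer(), t_alt = integer(), n_depth = integer(),
             n_alt = integer(), pop_af = numeric(), phase_set = character(),
             gene = character(), consequence = character(),
             filters = character(), stringsAsFactors = FALSE)
}

#' Read a somatic variant table
#'
#' Two dialects are supported.  `"tsv"` is the package's own tab-separated
#' shape with one row per call and the full column set (see
#' [validate_variants()]); it exists so that analyses and tests never need
#' a full VCF stack.  `"vcf_minimal"` reads CHROM/POS/REF/ALT plus per
#' sample allelic depths (`AD`) from a conventional tumour/normal VCF via
#' \pkg{VariantAnnotation}; symbolic alternate alleles (e.g. `<DEL>`) are
#' skipped with a warning.  Positions are 1-based in both dialects.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf_minimal"`.
#' @param tumour_sample,normal_sample genotype column names used by the VCF
#'   dialect.
#' @param sample_id sample identifier assigned to records read from VCF
#'   (defaults to `tumour_sample`).
#' @param pop_af_info INFO key holding the population allele frequency
#'   (VCF dialect; absent key leaves `pop_af` missing).
#' @return data frame of validated variant calls sorted by
#'   (sample, chrom, pos).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf_minimal"),
                               tumour_sample = "TUMOUR",
                               normal_sample = "NORMAL",
                               sample_id = tumour_sample,
                               pop_af_info = "POP_AF") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    calls <- read.delim(path, stringsAsFactors = FALSE,
                        colClasses = list(sample_id = "character",
                                          chrom = "character",
                                          ref = "character",
                                          alt = "character",
                                          phase_set = "character",
                                          gene = "character",
                                          consequence = "character",
                                          filters = "character"),
                        na.strings = c("NA", "."))
    if (nrow(calls) == 0L) return(empty_variants())
    calls$filters[is.na(calls$filters)] <- ""
    validate_variants(calls, line_offset = 1L)
    return(sort_variants(calls))
  }
  read_vcf_minimal(path, tumour_sample, normal_sample, sample_id, pop_af_info)
}

read_vcf_minimal <- function(path, tumour_sample, normal_sample, sample_id,
                             pop_af_info) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  if (nrow(vcf) == 0L) return(empty_variants())
  for (s in c(tumour_sample, normal_sample)) {
    if (!s %in% colnames(vcf)) {
      stop("VCF lacks genotype column '", s, "'", call. = FALSE)
    }
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  # symbolic / breakend / ambiguous alleles are anything that is not a
  # plain base string
  symbolic <- !grepl("^[ACGTNacgtn]+$", alt)
  if (any(symbolic)) {
    warning(sum(symbolic), " record(s) with symbolic alternate alleles skipped")
  }
  keep <- which(!symbolic)
  if (length(keep) == 0L) return(empty_variants())
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF lacks the AD genotype field", call. = FALSE)
  ad_counts <- function(column, allele_index) {
    if (is.array(ad) && length(dim(ad)) == 3L) {
      return(as.integer(ad[, column, allele_index]))
    }
    vapply(ad[, column], function(v) {
      v <- suppressWarnings(as.integer(v))
      if (length(v) < allele_index || anyNA(v)) NA_integer_ else v[allele_index]
    }, integer(1))
  }
  t_ref <- ad_counts(tumour_sample, 1L)
  t_alt <- ad_counts(tumour_sample, 2L)
  n_ref <- ad_counts(normal_sample, 1L)
  n_alt <- ad_counts(normal_sample, 2L)
  info <- VariantAnnotation::info(vcf)
  pop_af <- rep(NA_real_, nrow(vcf))
  if (pop_af_info %in% names(info)) {
    pop_af <- suppressWarnings(as.numeric(unlist(info[[pop_af_info]])))
  }
  phase_set <- rep(NA_character_, nrow(vcf))
  if ("PS" %in% names(info)) phase_set <- as.character(unlist(info[["PS"]]))
  calls <- data.frame(
    sample_id = sample_id,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = ref, alt = alt,
    vclass = classify_allele(ref, alt),
    t_depth = t_ref + t_alt, t_alt = t_alt,
    n_depth = n_ref + n_alt, n_alt = n_alt,
    pop_af = pop_af, phase_set = phase_set,
    gene = NA_character_, consequence = NA_character_,
    filters = "", stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(calls) <- NULL
  validate_variants(calls)
  sort_variants(calls)
}

#' Write a somatic variant table (tsv dialect) with a JSON sidecar
#'
#' @param calls variant data frame.
#' @param path output path; a `<path>.meta.json` run-metadata sidecar is
#'   written next to it.
#' @param metadata named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path, metadata = list()) {
  validate_variants(calls)
  out <- calls[, VARIANT_COLUMNS, drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  write_run_sidecar(path, "variant_table", nrow(out), metadata)
  invisible(path)
}

write_run_sidecar <- function(path, kind, n_records, metadata) {
  side <- c(list(format = kind,
                 n_records = n_records,
                 package = "sgcohort",
                 version = as.character(utils::packageVersion("sgcohort"))),
            metadata)
  jsonlite::write_json(side, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# ---------------------------------------------------------------------------
# Copy-number segment profiles

#' Construct a per-sample allele-specific copy-number profile
#'
#' @param sample_id sample identifier.
#' @param segments data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `total_cn`, `minor_cn`.
#' @param ploidy positive real.
#' @param goodness_of_fit fit quality in `[0,1]`; profiles below
#'   `low_fit_threshold` carry the `low_fit` flag and are excluded from
#'   downstream copy-number stages.
#' @param low_fit_threshold default 0.9.
#' @return An object of class `cn_profile`.
#' @export
cn_profile <- function(sample_id, segments, ploidy = 2,
                       goodness_of_fit = 1, low_fit_threshold = 0.9) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end", "total_cn", "minor_cn") %in%
                  names(segments)))
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  if (any(segments$end < segments$start)) {
    stop("segment with end < start in sample ", sample_id, call. = FALSE)
  }
  if (any(segments$total_cn < 0) || any(segments$minor_cn < 0)) {
    stop("negative copy number in sample ", sample_id, call. = FALSE)
  }
  if (any(segments$minor_cn > segments$total_cn)) {
    stop("minor_cn > total_cn in sample ", sample_id, call. = FALSE)
  }
  for (chr in unique(segments$chrom)) {
    seg <- segments[segments$chrom == chr, , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$start[-1L] <= seg$end[-nrow(seg)])) {
      stop("overlapping segments on ", chr, " in sample ", sample_id,
           call. = FALSE)
    }
  }
  if (is.na(goodness_of_fit) || goodness_of_fit < 0 || goodness_of_fit > 1) {
    stop("goodness_of_fit outside [0,1] in sample ", sample_id, call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, segments = segments, ploidy = ploidy,
         goodness_of_fit = goodness_of_fit,
         flags = if (goodness_of_fit < low_fit_threshold) "low_fit"
                 else character(0)),
    class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("<cn_profile> %s: %d segments, ploidy %.2f, fit %.3f%s\n",
              x$sample_id, nrow(x$segments), x$ploidy, x$goodness_of_fit,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Read allele-specific copy-number segment profiles
#'
#' Consumes the tabular shape emitted by allele-specific copy-number
#' callers: one row per segment with per-sample ploidy and goodness of
#' fit.  Profiles whose goodness of fit is below 0.9 are flagged
#' `low_fit` (noisy solutions) and must be excluded from downstream
#' copy-number stages.
#'
#' @param path tab-separated file with columns `sample`, `chrom`, `start`,
#'   `end`, `total_cn`, `minor_cn`, `ploidy`, `goodness_of_fit`
#'   (1-based inclusive coordinates).
#' @param low_fit_threshold flag threshold, default 0.9.
#' @return Named list of [cn_profile] objects, one per sample.
#' @export
read_segments <- function(path, low_fit_threshold = 0.9) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(sample = "character",
                                      chrom = "character"))
  required <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn",
                "ploidy", "goodness_of_fit")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("segment table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_chrom_style(tab$chrom)
  profiles <- lapply(split(tab, tab$sample), function(seg) {
    cn_profile(sample_id = seg$sample[1L],
               segments = seg[, c("chrom", "start", "end", "total_cn",
                                  "minor_cn")],
               ploidy = seg$ploidy[1L],
               goodness_of_fit = seg$goodness_of_fit[1L],
               low_fit_threshold = low_fit_threshold)
  })
  profiles[order(names(profiles))]
}

#' Write copy-number profiles as a segment table with a JSON sidecar
#'
#' @param profiles list of [cn_profile] objects.
#' @param path output path.
#' @param metadata named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profiles, path, metadata = list()) {
  rows <- lapply(profiles, function(p) {
    cbind(data.frame(sample = p$sample_id, stringsAsFactors = FALSE),
          p$segments,
          data.frame(ploidy = p$ploidy, goodness_of_fit = p$goodness_of_fit))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_sidecar(path, "segment_table", nrow(tab), metadata)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimizer reports

#' Read a classifier-report-style taxon minimizer table
#'
#' One row per taxon (optionally per sample): `m` distinct clade-level
#' minimizers observed out of `M` available in the database, from `n`
#' reads assigned to the taxon of `N` reads evaluated in the sample.  The
#' minimizer proportion `m/M` is computed here; p- and q-values are left
#' unset for [flag_significant()].
#'
#' @param path tab-separated file with columns `taxon_id`, `m`, `M`, `n`,
#'   `N` and optionally `sample_id`.
#' @return data frame with `proportion` added and `p_value`/`q_value`
#'   columns set to `NA`.
#' @export
read_minimizer_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(taxon_id = "character"))
  missing_cols <- setdiff(c("taxon_id", "m", "M", "n", "N"), names(tab))
  if (length(missing_cols)) {
    stop("minimizer report is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"sample_id" %in% names(tab)) tab$sample_id <- "sample1"
  validate_minimizer_records(tab)
  tab$proportion <- tab$m / tab$M
  tab$p_value <- NA_real_
  tab$q_value <- NA_real_
  tab[, c("sample_id", "taxon_id", "m", "M", "n", "N", "proportion",
          "p_value", "q_value")]
}

validate_minimizer_records <- function(tab) {
  bad <- which(tab$m > tab$M)
  if (length(bad)) {
    stop("m > M for taxon ", tab$taxon_id[bad[1L]], call. = FALSE)
  }
  bad <- which(tab$n > tab$N)
  if (length(bad)) {
    stop("n > N for taxon ", tab$taxon_id[bad[1L]], call. = FALSE)
  }
  if (any(tab$m < 0 | tab$n < 0 | tab$M <= 0 | tab$N <= 0)) {
    stop("minimizer counts must satisfy m,n >= 0 and M,N > 0", call. = FALSE)
  }
  invisible(tab)
}

#' Write a taxon minimizer report with a JSON sidecar
#'
#' @param records minimizer report data frame.
#' @param path output path.
#' @param metadata named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_minimizer_report <- function(records, path, metadata = list()) {
  validate_minimizer_records(records)
  cols <- intersect(c("sample_id", "taxon_id", "m", "M", "n", "N",
                      "proportion", "p_value", "q_value"), names(records))
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  write_run_sidecar(path, "minimizer_report", nrow(records), metadata)
  invisible(path)
}
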