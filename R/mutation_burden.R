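# Tumour mutation burden over the flanked coding target space, and the
# rank-sum comparison between cohorts.

#' Per-sample tumour mutation burden
#'
#' TMB counts refined SNVs, MNVs and indels whose reference span overlaps
#' the flanked target territory (a variant touching only the 2 bp splice
#' flank is in a splice site and counts), divided by the territory size
#' in megabases.  An MNV counts as one mutation.
#'
#' @param calls refined variant data frame.
#' @param targets [target_space]; `total_mb` is the denominator.
#' @param sample_ids optional character vector forcing the output to
#'   cover these samples (zero counts for samples without calls).
#' @return data frame with one row per sample: `sample_id`, `n_snv`,
#'   `n_mnv`, `n_indel`, `tmb` (mutations/Mb) and `low_burden_flag`
#'   (`tmb < 1`).
#' @export
compute_tmb <- function(calls, targets, sample_ids = NULL) {
  stopifnot(inherits(targets, "target_space"))
  if (targets$total_mb <= 0) stop("target space has zero size", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- sort(unique(calls$sample_id))
  if (nrow(calls) > 0L) {
    span_end <- calls$pos + pmax(nchar(calls$ref) - 1L, 0L)
    gr <- GenomicRanges::GRanges(
      seqnames = calls$chrom,
      ranges = IRanges::IRanges(start = calls$pos, end = span_end))
    hit <- suppressWarnings(
      GenomicRanges::countOverlaps(gr, targets$granges)) > 0
    calls <- calls[hit, , drop = FALSE]
  }
  rows <- lapply(sample_ids, function(sid) {
    cc <- calls[calls$sample_id == sid, , drop = FALSE]
    n_snv <- sum(cc$vclass == "SNV")
    n_mnv <- sum(cc$vclass == "MNV")
    n_indel <- sum(cc$vclass %in% c("INS", "DEL", "COMPLEX"))
    tmb <- (n_snv + n_mnv + n_indel) / targets$total_mb
    data.frame(sample_id = sid, n_snv = n_snv, n_mnv = n_mnv,
               n_indel = n_indel, tmb = tmb, low_burden_flag = tmb < 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unpaired Wilcoxon rank-sum test (normal approximation)
#'
#' Two-sided rank-sum test using mid-ranks for ties, the tie-corrected
#' variance, and a 0.5 continuity correction toward the mean, matching
#' the normal-approximation convention of standard statistical software.
#' With small groups the approximate p agrees with exact permutation
#' enumeration to within about 0.02.
#'
#' @param x,y numeric vectors (each non-empty).
#' @return list with `statistic` (Mann-Whitney U for `x`), `z`, and
#'   two-sided `p_value` in `(0, 1]`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0L, length(y) > 0L,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nties <- table(r)
  n <- n1 + n2
  sigma2 <- (n1 * n2 / 12) *
    ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    warning("all values identical across both groups; p = 1")
    return(list(statistic = u, z = 0, p_value = 1))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = u, z = z, p_value = p)
}

#' Summarize mutation burden by cohort
#'
#' Per-cohort median and range of TMB plus the two-sided rank-sum
#' comparison between the two cohorts.
#'
#' @param records output of [compute_tmb()].
#' @param labels named character vector or manifest data frame
#'   (`sample_id`, `cohort`) labelling every sample.
#' @param cohorts the two cohort labels to compare (default: the sorted
#'   unique labels).
#' @return list with `by_cohort` (data frame of n, median, min, max) and
#'   `test` (rank-sum result between `cohorts[1]` and `cohorts[2]`).
#' @export
summarize_cohort_burden <- function(records, labels, cohorts = NULL) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$cohort, labels$sample_id)
  }
  unlabelled <- setdiff(records$sample_id, names(labels))
  if (length(unlabelled)) {
    stop("unlabelled sample(s): ", paste(unlabelled, collapse = ", "),
         call. = FALSE)
  }
  records$cohort <- unname(labels[records$sample_id])
  if (is.null(cohorts)) cohorts <- sort(unique(records$cohort))
  by_cohort <- do.call(rbind, lapply(cohorts, function(cc) {
    v <- records$tmb[records$cohort == cc]
    if (length(v) == 0L) stop("cohort ", cc, " has zero samples",
                              call. = FALSE)
    data.frame(cohort = cc, n = length(v), median_tmb = median(v),
               min_tmb = min(v), max_tmb = max(v), stringsAsFactors = FALSE)
  }))
  test <- wilcoxon_rank_sum(records$tmb[records$cohort == cohorts[1L]],
                            records$tmb[records$cohort == cohorts[2L]])
  list(by_cohort = by_cohort, test = test)
}
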