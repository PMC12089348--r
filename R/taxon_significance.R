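# Minimizer-proportion significance test for taxon presence.
#
# For a taxon with M clade-level minimizers in the classifier database,
# of which m distinct minimizers were observed in a sample that assigned
# n of its N evaluated reads to the taxon, the null model is
# m ~ Binomial(M, p0) with p0 = n/N: under background (reads carrying no
# genuine signal for the taxon) a taxon's chance of revealing any one of
# its database minimizers is taken proportional to its share of the
# sample's reads.  The test is one-sided for enrichment (presence), with
# a continuity-corrected normal approximation to the binomial upper tail
# and an exact-tail fallback where the approximation is invalid.

#' Taxon test configuration
#'
#' @param alpha significance level on the adjusted p-value (default
#'   0.05; strict `<`).
#' @param approx_validity_min minimum `M * p0 * (1 - p0)` for the normal
#'   approximation; below it the exact binomial tail is used.  The
#'   default of 25 keeps the continuity-corrected normal tail within
#'   0.01 absolute of the exact tail everywhere it is used (the
#'   worst-case gap only drops below 0.01 around a variance of 25, and
#'   the exact tail is cheap at small expected counts anyway).
#' @param continuity_correction apply the 0.5 continuity correction in
#'   the normal approximation (default TRUE).
#' @return list of class `taxon_test_config`.
#' @export
taxon_test_config <- function(alpha = 0.05, approx_validity_min = 25,
                              continuity_correction = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(alpha = alpha,
                 approx_validity_min = approx_validity_min,
                 continuity_correction = continuity_correction),
            class = "taxon_test_config")
}

#' One-sided upper-tail p-value for minimizer enrichment
#'
#' Computes `P(X >= m)` under `X ~ Binomial(M, p0)` with `p0 = n/N`.
#' When `M * p0 * (1 - p0)` is at least `approx_validity_min` the
#' continuity-corrected normal approximation
#' `z = (m - M p0 - 0.5) / sqrt(M p0 (1 - p0))` is used; otherwise the
#' exact binomial tail.  Vectorized over records.
#'
#' @param m,M,n,N minimizer and read counts (vectors recycle).
#' @param cfg [taxon_test_config()].
#' @return p-values in `[0, 1]`.
#' @export
taxon_pvalue <- function(m, M, n, N, cfg = taxon_test_config()) {
  stopifnot(all(M > 0), all(N > 0), all(m >= 0), all(n >= 0), all(m <= M),
            all(n <= N))
  p0 <- n / N
  if (any(p0 >= 1)) stop("degenerate null: p0 = n/N must be < 1",
                         call. = FALSE)
  out <- numeric(length(m))
  degenerate <- p0 == 0
  if (any(degenerate & m > 0)) {
    warning("p0 = 0 with m > 0: degenerate null, p set to 0")
  }
  out[degenerate] <- ifelse(m[degenerate] > 0, 0, 1)
  var0 <- M * p0 * (1 - p0)
  use_normal <- !degenerate & var0 >= cfg$approx_validity_min
  if (any(use_normal)) {
    cc <- if (isTRUE(cfg$continuity_correction)) 0.5 else 0
    z <- (m[use_normal] - M[use_normal] * p0[use_normal] - cc) /
      sqrt(var0[use_normal])
    out[use_normal] <- pnorm(z, lower.tail = FALSE)
  }
  use_exact <- !degenerate & !use_normal
  if (any(use_exact)) {
    out[use_exact] <- pbinom(m[use_exact] - 1, M[use_exact], p0[use_exact],
                             lower.tail = FALSE)
  }
  pmin(1, pmax(0, out))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement; the output order matches the input order.
#'
#' @param p_values p-values in `[0, 1]`.
#' @return q-values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Flag significantly present taxa in a minimizer report
#'
#' Computes the per-taxon enrichment p-value, applies Benjamini-Hochberg
#' within each sample (taxa screened in one sample form one family), and
#' flags taxa with adjusted p strictly below `alpha`.
#'
#' @param records minimizer report data frame (see
#'   [read_minimizer_report()]).
#' @param cfg [taxon_test_config()].
#' @return the report with `p_value`, `q_value` and `significant`
#'   columns filled in, original order preserved.
#' @export
flag_significant <- function(records, cfg = taxon_test_config()) {
  if (nrow(records) == 0L) {
    records$significant <- logical(0)
    return(records)
  }
  if (!"sample_id" %in% names(records)) records$sample_id <- "sample1"
  records$p_value <- taxon_pvalue(records$m, records$M, records$n,
                                  records$N, cfg)
  records$q_value <- stats::ave(records$p_value, records$sample_id,
                                FUN = bh_adjust)
  records$significant <- records$q_value < cfg$alpha
  records
}
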