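# Cohort-level integration: the binary alteration matrix, hotspot
# frequency reporting, the margin-preserving mutual-exclusivity screen,
# the two-proportion comparison, and report assembly.

SILENT_CONSEQUENCES <- c("synonymous_variant", "silent",
                         "stop_retained_variant", "intron_variant")

#' Build the samples-by-genes binary alteration matrix
#'
#' A cell is 1 when the sample carries at least one non-silent call in
#' the gene.  Genes altered in fewer than `min_recurrence` samples are
#' dropped (recurrence filter); every labelled sample keeps a row even
#' when unaltered.
#'
#' @param calls refined variant data frame with `gene` and `consequence`.
#' @param labels manifest data frame (`sample_id`, `cohort`) or named
#'   character vector of cohort labels.
#' @param min_recurrence minimum samples altered for a gene to enter
#'   (default 2).
#' @return object of class `alteration_matrix`: list with `matrix`
#'   (binary, samples x genes) and `labels`.
#' @export
build_alteration_matrix <- function(calls, labels, min_recurrence = 2L) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$cohort, labels$sample_id)
  }
  samples <- names(labels)
  eligible <- !is.na(calls$gene) & !is.na(calls$consequence) &
    !(calls$consequence %in% SILENT_CONSEQUENCES) &
    calls$sample_id %in% samples
  cc <- calls[eligible, , drop = FALSE]
  genes <- sort(unique(cc$gene))
  mat <- matrix(0L, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
  if (nrow(cc)) {
    idx <- cbind(match(cc$sample_id, samples), match(cc$gene, genes))
    mat[idx] <- 1L
  }
  keep <- colSums(mat) >= min_recurrence
  if (!any(keep)) {
    warning("no gene reaches the recurrence threshold; matrix is empty")
  }
  mat <- mat[, keep, drop = FALSE]
  structure(list(matrix = mat, labels = labels),
            class = "alteration_matrix")
}

#' Restrict an alteration matrix to one cohort
#'
#' Keeps the cohort's samples and re-applies the recurrence filter
#' within the cohort, matching a per-subtype screen ("genes mutated in
#' 2 or more samples within the cohort").
#'
#' @param matrix an `alteration_matrix`.
#' @param cohort cohort label to keep.
#' @param min_recurrence recurrence threshold re-applied within the
#'   cohort (default 2).
#' @return an `alteration_matrix` over the cohort's samples.
#' @export
subset_alteration_matrix <- function(matrix, cohort, min_recurrence = 2L) {
  stopifnot(inherits(matrix, "alteration_matrix"))
  keep <- names(matrix$labels)[matrix$labels == cohort]
  if (length(keep) == 0L) stop("cohort ", cohort, " is empty", call. = FALSE)
  mat <- matrix$matrix[keep, , drop = FALSE]
  mat <- mat[, colSums(mat) >= min_recurrence, drop = FALSE]
  structure(list(matrix = mat, labels = matrix$labels[keep]),
            class = "alteration_matrix")
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat(sprintf("<alteration_matrix> %d samples x %d genes (%d altered cells)\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$matrix)))
  invisible(x)
}

#' Per-gene alteration frequencies within a cohort
#'
#' Reports, for each gene in the matrix, the number of altered samples
#' in the cohort and the corresponding percentage, both rounded to the
#' nearest integer and at one decimal.
#'
#' @param matrix an `alteration_matrix`.
#' @param cohort cohort label to summarize.
#' @param display one-decimal display convention: `"round"` (default,
#'   93.75 -> 93.8) or `"truncate"` (93.75 -> 93.7).
#' @return data frame `gene`, `count`, `cohort_size`, `percent_int`,
#'   `percent_1dp`.
#' @export
hotspot_frequencies <- function(matrix, cohort,
                                display = c("round", "truncate")) {
  stopifnot(inherits(matrix, "alteration_matrix"))
  display <- match.arg(display)
  in_cohort <- names(matrix$labels)[matrix$labels == cohort]
  if (length(in_cohort) == 0L) stop("cohort ", cohort, " is empty",
                                    call. = FALSE)
  sub <- matrix$matrix[in_cohort, , drop = FALSE]
  counts <- colSums(sub)
  pct <- 100 * counts / length(in_cohort)
  one_dp <- if (display == "round") round_half_up(pct, 1)
            else floor(pct * 10) / 10
  data.frame(gene = colnames(sub), count = as.integer(counts),
             cohort_size = length(in_cohort),
             percent_int = round_half_up(pct),
             percent_1dp = one_dp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Margin-preserving permutation test for mutual exclusivity
#'
#' For every gene pair, compares the observed co-occurrence count (the
#' number of samples altered in both genes) with its distribution over
#' null matrices generated by checkerboard swaps that conserve every row
#' and column sum.  The exclusivity p-value is
#' `(1 + #\{null co-occurrence <= observed\}) / (n_permutations + 1)`;
#' a co-occurrence p-value uses the opposite tail.  Benjamini-Hochberg
#' is applied across pairs.  Deterministic given `seed`.
#'
#' @param matrix an `alteration_matrix` (at least 2 genes and 2
#'   samples after excluding degenerate all-zero/all-one columns).
#' @param n_permutations number of null matrices (must be >= 1).
#' @param seed RNG seed.
#' @param swaps_per_ones swap attempts per permutation, as a multiple of
#'   the number of 1-cells (default 10); a burn-in of the same length
#'   precedes sampling.
#' @param fdr_threshold FDR used for the `exclusive` flag (default 0.1).
#' @param check_margins assert row/column sum conservation after every
#'   permutation (test mode; default FALSE).
#' @return data frame: one row per gene pair with `co_occurrence`,
#'   `p_exclusivity`, `p_exclusivity_strict` (point mass at the observed
#'   count excluded, for discreteness-aware calibration checks),
#'   `p_cooccurrence`, `q_exclusivity`, `exclusive`.
#' @export
mutual_exclusivity_test <- function(matrix, n_permutations = 2000L,
                                    seed = 1L, swaps_per_ones = 10L,
                                    fdr_threshold = 0.1,
                                    check_margins = FALSE) {
  stopifnot(inherits(matrix, "alteration_matrix"))
  if (n_permutations < 1L) {
    stop("n_permutations must be at least 1", call. = FALSE)
  }
  mat <- matrix$matrix
  degenerate <- colSums(mat) == 0L | colSums(mat) == nrow(mat)
  if (any(degenerate)) {
    warning("excluding degenerate gene column(s): ",
            paste(colnames(mat)[degenerate], collapse = ", "))
    mat <- mat[, !degenerate, drop = FALSE]
  }
  if (ncol(mat) < 2L || nrow(mat) < 2L) {
    stop("matrix is degenerate (need >= 2 genes and >= 2 samples)",
         call. = FALSE)
  }
  ones <- sum(mat)
  nswaps <- swaps_per_ones * ones
  observed <- crossprod(mat)
  pairs <- which(upper.tri(observed), arr.ind = TRUE)
  obs <- observed[pairs]
  le <- integer(length(obs))   # null co-occurrence <= observed
  lt <- integer(length(obs))   # null co-occurrence <  observed
  ge <- integer(length(obs))   # null co-occurrence >= observed
  set.seed(seed)
  cur <- checkerboard_swaps(mat, nswaps)   # burn-in
  for (b in seq_len(n_permutations)) {
    cur <- checkerboard_swaps(cur, nswaps)
    if (check_margins) {
      stopifnot(identical(rowSums(cur), rowSums(mat)),
                identical(colSums(cur), colSums(mat)))
    }
    nullco <- crossprod(cur)[pairs]
    le <- le + (nullco <= obs)
    lt <- lt + (nullco < obs)
    ge <- ge + (nullco >= obs)
  }
  p_excl <- (1 + le) / (n_permutations + 1)
  p_cooc <- (1 + ge) / (n_permutations + 1)
  out <- data.frame(gene_a = colnames(mat)[pairs[, 1L]],
                    gene_b = colnames(mat)[pairs[, 2L]],
                    co_occurrence = obs,
                    p_exclusivity = p_excl,
                    # strict-tail variant: with the point mass at the
                    # observed count excluded; p_lt <= p_exclusivity, and
                    # randomizing between the two gives the standard
                    # uniform p for a discrete statistic
                    p_exclusivity_strict = (1 + lt) / (n_permutations + 1),
                    p_cooccurrence = p_cooc,
                    stringsAsFactors = FALSE)
  out$q_exclusivity <- bh_adjust(out$p_exclusivity)
  out$exclusive <- out$q_exclusivity < fdr_threshold
  out
}

#' Two-proportion chi-square comparison
#'
#' Pearson chi-square on the 2x2 table of carriers/non-carriers in two
#' groups, with optional Yates continuity correction (each cell's
#' `|O - E|` is reduced by 0.5, clamped at zero).
#'
#' @param k1,n1 carriers and size of group 1.
#' @param k2,n2 carriers and size of group 2.
#' @param yates apply the continuity correction (default FALSE).
#' @return list with `statistic`, `df` (1) and `p_value`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2, yates = FALSE) {
  stopifnot(k1 >= 0, k2 >= 0, n1 >= 1, n2 >= 1, k1 <= n1, k2 <= n2)
  obs <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expected == 0)) {
    stop("expected cell count of zero; use an exact test", call. = FALSE)
  }
  dev <- abs(obs - expected)
  if (yates) dev <- pmax(0, dev - 0.5)
  statistic <- sum(dev^2 / expected)
  list(statistic = statistic, df = 1L,
       p_value = stats::pchisq(statistic, df = 1L, lower.tail = FALSE))
}

#' Assemble the cohort report
#'
#' Gathers the stage outputs into one report: alteration matrix, hotspot
#' frequencies (including the fraction of benign samples carrying either
#' defining hotspot), burden summary, exclusivity screen, taxon flags,
#' chromothripsis and two-hit calls.  Missing stages leave explicit gaps
#' rather than failing.  Regeneration from the same inputs is
#' deterministic; when `dir` is given, the matrix and pairwise test
#' tables are written as TSV and the summary as JSON.
#'
#' @param matrix an `alteration_matrix` (required).
#' @param burden output of [summarize_cohort_burden()] or `NULL`.
#' @param exclusivity output of [mutual_exclusivity_test()] or `NULL`.
#' @param taxa output of [flag_significant()] or `NULL`.
#' @param chromothripsis data frame of [call_chromothripsis()] rows or
#'   `NULL`.
#' @param two_hit data frame of [call_two_hit()] rows or `NULL`.
#' @param hotspot_genes the cohort-defining hotspot genes (default
#'   CTNNB1 and FBXW11).
#' @param cohort cohort whose hotspot frequencies are reported (default
#'   `"benign"`).
#' @param display percent display convention, see
#'   [hotspot_frequencies()].
#' @param dir optional output directory.
#' @return list of class `cohort_report`.
#' @export
assemble_report <- function(matrix, burden = NULL, exclusivity = NULL,
                            taxa = NULL, chromothripsis = NULL,
                            two_hit = NULL,
                            hotspot_genes = c("CTNNB1", "FBXW11"),
                            cohort = "benign",
                            display = c("round", "truncate"),
                            dir = NULL) {
  stopifnot(inherits(matrix, "alteration_matrix"))
  display <- match.arg(display)
  if (nrow(matrix$matrix) == 0L) stop("empty cohort input", call. = FALSE)
  in_cohort <- names(matrix$labels)[matrix$labels == cohort]
  if (length(in_cohort) == 0L) stop("empty cohort input", call. = FALSE)
  freq <- hotspot_frequencies(matrix, cohort, display = display)
  present <- intersect(hotspot_genes, colnames(matrix$matrix))
  either_count <- if (length(present)) {
    sum(rowSums(matrix$matrix[in_cohort, present, drop = FALSE]) > 0)
  } else 0L
  either_pct <- 100 * either_count / length(in_cohort)
  gaps <- c("burden", "exclusivity", "taxa", "chromothripsis",
            "two_hit")[c(is.null(burden), is.null(exclusivity),
                         is.null(taxa), is.null(chromothripsis),
                         is.null(two_hit))]
  report <- structure(
    list(hotspot_frequencies = freq,
         either_hotspot = list(
           count = either_count, cohort_size = length(in_cohort),
           percent_int = round_half_up(either_pct),
           percent_1dp = if (display == "round") round_half_up(either_pct, 1)
                         else floor(either_pct * 10) / 10),
         burden = burden, exclusivity = exclusivity, taxa = taxa,
         chromothripsis = chromothripsis, two_hit = two_hit,
         gaps = gaps),
    class = "cohort_report")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.table(cbind(sample_id = rownames(matrix$matrix),
                      as.data.frame(matrix$matrix)),
                file.path(dir, "alteration_matrix.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(exclusivity)) {
      write.table(exclusivity, file.path(dir, "pairwise_tests.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      report[c("hotspot_frequencies", "either_hotspot", "gaps")],
      file.path(dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA, force = TRUE)
  }
  report
}
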