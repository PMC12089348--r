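# Fixture builders shared across test files.  Everything is generated in
# code; no binary data.

make_variant <- function(sample_id = "S1", chrom = "chr1", pos = 1000L,
                         ref = "A", alt = "G", t_depth = 50L, t_alt = 20L,
                         n_depth = 40L, n_alt = 0L, pop_af = NA_real_,
                         phase_set = NA_character_, gene = NA_character_,
                         consequence = "missense_variant", filters = "") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt,
             vclass = sgcohort:::classify_allele(ref, alt),
             t_depth = as.integer(t_depth), t_alt = as.integer(t_alt),
             n_depth = as.integer(n_depth), n_alt = as.integer(n_alt),
             pop_af = pop_af, phase_set = phase_set, gene = gene,
             consequence = consequence, filters = filters,
             stringsAsFactors = FALSE)
}

bind_variants <- function(...) {
  out <- do.call(rbind, list(...))
  rownames(out) <- NULL
  out
}

# target space from (start, end) BED pairs on one chromosome
make_targets <- function(starts, ends, chrom = "chr1", flank_bp = 0L) {
  target_space(data.frame(chrom = chrom, start = starts, end = ends),
               flank_bp = flank_bp)
}

# profile with one segment per copy-number state, each seg_bp long,
# laid end-to-end from position 1
make_profile <- function(cn, seg_bp = 5e6, chrom = "chr1",
                         sample_id = "S1", minor = NULL,
                         goodness_of_fit = 0.95) {
  k <- length(cn)
  start <- seq(1, by = seg_bp, length.out = k)
  if (is.null(minor)) minor <- pmin(1L, cn)
  cn_profile(sample_id,
             data.frame(chrom = chrom, start = start,
                        end = start + seg_bp - 1,
                        total_cn = as.integer(cn),
                        minor_cn = as.integer(minor),
                        stringsAsFactors = FALSE),
             ploidy = 2, goodness_of_fit = goodness_of_fit)
}

# random segmentation of one chromosome for oracle comparisons
random_profile <- function(chrom_len = 60e6, max_segs = 12L,
                           chrom = "chr1", sample_id = "R1") {
  k <- sample.int(max_segs, 1L)
  cuts <- sort(sample.int(chrom_len - 1L, k - 1L))
  start <- c(1, cuts + 1)
  end <- c(cuts, chrom_len)
  cn_profile(sample_id,
             data.frame(chrom = chrom, start = start, end = end,
                        total_cn = sample(0:4, k, replace = TRUE),
                        minor_cn = 0L, stringsAsFactors = FALSE),
             ploidy = 2, goodness_of_fit = 0.95)
}

# independent-path window oracle: enumerate candidate windows anchored at
# every switch breakpoint (plus extra probes), recounting switches by an
# explicit scan over adjacent segment pairs
oracle_max_switches <- function(profile, chrom, window_bp = 50e6,
                                extra_starts = numeric(0)) {
  seg <- profile$segments[profile$segments$chrom == chrom, , drop = FALSE]
  seg <- seg[order(seg$start), , drop = FALSE]
  if (nrow(seg) < 2L) return(0L)
  bps <- c()
  for (i in seq_len(nrow(seg) - 1L)) {
    if (seg$total_cn[i] != seg$total_cn[i + 1L]) bps <- c(bps, seg$end[i])
  }
  if (length(bps) == 0L) return(0L)
  best <- 0L
  for (ws in c(bps, extra_starts)) {
    cnt <- 0L
    for (b in bps) if (b >= ws && b <= ws + window_bp) cnt <- cnt + 1L
    best <- max(best, cnt)
  }
  best
}

# exact two-sided rank-sum p by enumeration of all group assignments
exact_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  mu <- n1 * length(y) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

write_minimal_vcf <- function(path, rows,
                              samples = c("TUMOUR", "NORMAL")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr3,length=50000000>",
    "##INFO=<ID=POP_AF,Number=1,Type=Float,Description=\"Population AF\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}
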