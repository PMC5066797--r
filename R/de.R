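# Differential expression for digital tag counts: RPKM normalization, the
# Audic-Claverie exact test, BH FDR control, the conjunction significance
# thresholds for genes and miRNAs, and Z-score profiles for heatmaps.

#' Default pipeline thresholds
#'
#' Gene significance is the conjunction p < `gene_p`, FDR <= `gene_fdr`
#' and |log2 ratio| >= `gene_lfc`; miRNAs use the looser `mirna_p` with a
#' stricter total-abundance gate `mirna_abundance`; the coexpression
#' soft-threshold power and the target-score and correlation cutoffs sit
#' alongside so one object configures the whole pipeline.
#'
#' @param gene_p,gene_fdr,gene_lfc gene DE thresholds.
#' @param mirna_p,mirna_abundance miRNA DE thresholds (abundance is total
#'   raw reads across libraries).
#' @param network_power soft-threshold power.
#' @param score_cutoff degradome alignment-score cutoff.
#' @param corr_negative negative-correlation threshold for pair calling.
#' @return a named list of thresholds.
#' @export
de_thresholds <- function(gene_p = 0.005, gene_fdr = 0.001, gene_lfc = 1,
                          mirna_p = 0.05, mirna_abundance = 10,
                          network_power = 6, score_cutoff = 4,
                          corr_negative = -0.5) {
  stopifnot(gene_p > 0, gene_fdr > 0, gene_lfc > 0, mirna_p > 0,
            mirna_abundance > 0, network_power > 0, score_cutoff > 0,
            corr_negative < 0)
  list(gene_p = gene_p, gene_fdr = gene_fdr, gene_lfc = gene_lfc,
       mirna_p = mirna_p, mirna_abundance = mirna_abundance,
       network_power = network_power, score_cutoff = score_cutoff,
       corr_negative = corr_negative)
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / (length/1000) / (library_size/1e6)`.
#'
#' @param counts matrix, features x samples.
#' @param lengths feature lengths in nt (> 0), recycled along rows.
#' @param library_sizes per-sample totals (> 0); defaults to column sums.
#' @return numeric matrix of RPKM values.
#' @export
rpkm <- function(counts, lengths, library_sizes = colSums(counts)) {
  stopifnot(all(lengths > 0))
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  t(t(counts / (rep_len(lengths, nrow(counts)) / 1000)) /
      (library_sizes / 1e6))
}

#' Audic-Claverie exact test for two tag counts
#'
#' The exact test for digital expression: given `x` reads in a library of
#' `N1` and `y` in a library of `N2`, the conditional law of y is
#' negative binomial, P(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1)).
#' The two-sided p doubles the smaller of the tails P(Y <= y) and
#' P(Y > y) and caps at 1 -- the convention under which the test is
#' exactly exchange-symmetric, p(x,y,N1,N2) = p(y,x,N2,N1), and x = y with
#' equal library sizes gives p = 1. Computed through the negative-binomial
#' CDF (log-space internally), so it is overflow-safe for large counts.
#'
#' @param x,y tag counts (vectorized).
#' @param n1,n2 library sizes (> 0).
#' @return two-sided p-values.
#' @export
ac_test <- function(x, y, n1, n2) {
  stopifnot(all(x >= 0), all(y >= 0), all(n1 > 0), all(n2 > 0))
  pr <- n1 / (n1 + n2)
  lower <- stats::pnbinom(y, size = x + 1, prob = pr)
  upper <- stats::pnbinom(y, size = x + 1, prob = pr, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved.
#'
#' @param p p-values in [0, 1].
#' @return adjusted values in the same order.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes against a control sample
#'
#' Each non-control sample is tested against the control with the exact
#' test on raw counts (library sizes = column totals); FDR is adjusted
#' per comparison across features; log2 ratios are taken on RPKM with a
#' 0.01 pseudocount. A feature is significant in a comparison iff
#' p < `gene_p` AND fdr <= `gene_fdr` AND |log2 ratio| >= `gene_lfc`.
#'
#' @param counts raw count matrix, features x samples.
#' @param lengths feature lengths (named or positional); features with a
#'   missing/invalid length are excluded with a message.
#' @param control control sample id (default "S1").
#' @param thresholds see [de_thresholds()].
#' @return data.frame: `feature`, `comparison`, `count_control`,
#'   `count_treatment`, `p`, `fdr`, `log2_ratio`, `significant`.
#' @export
call_deg <- function(counts, lengths, control = "S1",
                     thresholds = de_thresholds()) {
  if (!control %in% colnames(counts)) {
    stop("control sample '", control, "' not found")
  }
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  ok <- !is.na(lengths) & lengths > 0
  if (any(!ok)) {
    message(sum(!ok), " feature(s) without a valid length excluded")
    counts <- counts[ok, , drop = FALSE]
    lengths <- lengths[ok]
  }
  libsz <- colSums(counts)
  rpk <- rpkm(counts, lengths, libsz)
  eps <- 0.01
  out <- list()
  for (s in setdiff(colnames(counts), control)) {
    p <- ac_test(counts[, control], counts[, s], libsz[control], libsz[s])
    fdr <- bh_fdr(p)
    lfc <- log2((rpk[, s] + eps) / (rpk[, control] + eps))
    out[[s]] <- data.frame(
      feature = rownames(counts),
      comparison = paste0(s, "_vs_", control),
      count_control = counts[, control], count_treatment = counts[, s],
      p = p, fdr = fdr, log2_ratio = lfc,
      significant = p < thresholds$gene_p & fdr <= thresholds$gene_fdr &
        abs(lfc) >= thresholds$gene_lfc,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call differentially expressed miRNAs
#'
#' Per-library counts are tested pairwise against the control with the
#' exact test. The loose set flags any comparison at p < `mirna_p`; the
#' strict set additionally requires total abundance across libraries
#' above `mirna_abundance` raw reads. Per-comparison up/down tallies (by
#' CPM ratio among loose-significant comparisons) are returned alongside.
#'
#' @param counts miRNA count matrix, features x libraries.
#' @param control control library id.
#' @param thresholds see [de_thresholds()].
#' @return list: `mirnas` (per-miRNA table with `total`, `min_p`,
#'   `loose`, `strict`), `tests` (per-comparison long table), `updown`
#'   (comparison, up, down).
#' @export
call_de_mirna <- function(counts, control = "S1",
                          thresholds = de_thresholds()) {
  if (!control %in% colnames(counts)) {
    stop("control sample '", control, "' not found")
  }
  libsz <- colSums(counts)
  cpm <- t(t(counts) / (libsz / 1e6))
  tests <- list()
  for (s in setdiff(colnames(counts), control)) {
    p <- ac_test(counts[, control], counts[, s], libsz[control], libsz[s])
    tests[[s]] <- data.frame(
      feature = rownames(counts), comparison = paste0(s, "_vs_", control),
      p = p, fdr = bh_fdr(p),
      direction = ifelse(cpm[, s] >= cpm[, control], "up", "down"),
      significant = p < thresholds$mirna_p,
      stringsAsFactors = FALSE)
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  total <- rowSums(counts)
  min_p <- tapply(tests$p, tests$feature, min)[rownames(counts)]
  loose <- tapply(tests$significant, tests$feature, any)[rownames(counts)]
  mirnas <- data.frame(
    feature = rownames(counts), total = total, min_p = as.numeric(min_p),
    loose = as.logical(loose),
    strict = as.logical(loose) & total > thresholds$mirna_abundance,
    stringsAsFactors = FALSE)
  rownames(mirnas) <- NULL
  sig <- tests[tests$significant, , drop = FALSE]
  comps <- unique(tests$comparison)
  updown <- data.frame(
    comparison = comps,
    up = vapply(comps, function(cc) {
      sum(sig$comparison == cc & sig$direction == "up")
    }, integer(1)),
    down = vapply(comps, function(cc) {
      sum(sig$comparison == cc & sig$direction == "down")
    }, integer(1)))
  rownames(updown) <- NULL
  list(mirnas = mirnas, tests = tests, updown = updown)
}

#' Z-score normalization of expression profiles
#'
#' Per-feature (row) standardization, the display normalization of
#' expression heatmaps; constant profiles map to all zeros.
#'
#' @param m matrix, features x samples (k >= 2).
#' @return matrix of the same shape with row mean 0 and sd 1 (or 0).
#' @export
zscore <- function(m) {
  stopifnot(ncol(m) >= 2)
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  z
}
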