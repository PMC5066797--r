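# Integration: join differentially expressed miRNAs with their
# degradome-validated differentially expressed targets, classify the
# correlation direction of each pair over the time course, and run generic
# term enrichment on target sets.

#' Pair differentially expressed miRNAs with their DE degradome targets
#'
#' A pair (m, t) is emitted iff m is in the strict DE-miRNA set, the hit
#' (m, t) is in the degradome target table, and t passes the gene DE
#' thresholds in at least one comparison. Pairs are deduplicated on
#' (miRNA, target), keeping the best-scoring hit.
#'
#' @param mirna_de the `mirnas` table from [call_de_mirna()] (or a
#'   character vector of strict-DE miRNA ids).
#' @param target_hits table from [call_targets()].
#' @param gene_de table from [call_deg()] (or a character vector of DE
#'   feature ids).
#' @return data.frame of pairs with the hit columns carried along.
#' @export
pair_de <- function(mirna_de, target_hits, gene_de) {
  de_mirnas <- if (is.character(mirna_de)) mirna_de else {
    mirna_de$feature[mirna_de$strict]
  }
  de_genes <- if (is.character(gene_de)) gene_de else {
    unique(gene_de$feature[gene_de$significant])
  }
  keep <- target_hits$mirna_id %in% de_mirnas &
    target_hits$transcript_id %in% de_genes
  out <- target_hits[keep, , drop = FALSE]
  out <- out[order(out$mirna_id, out$transcript_id, out$score), ,
             drop = FALSE]
  out <- out[!duplicated(out[, c("mirna_id", "transcript_id")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate miRNA and target expression profiles
#'
#' Pearson correlation of the Z-scored eight-point profiles (Z-scoring
#' leaves Pearson's r unchanged; it is kept to mirror the heatmap
#' presentation). Direction is `negative` at r <= `negative_threshold`,
#' `positive` at r >= |threshold|, `uncorrelated` between; a constant
#' profile is defined as r = 0, uncorrelated.
#'
#' @param pairs data.frame with `mirna_id`, `transcript_id` (e.g. from
#'   [pair_de()]).
#' @param mirna_profiles,gene_profiles matrices (features x samples) with
#'   identical sample order (checked by column name).
#' @param negative_threshold default -0.5.
#' @return `pairs` with added columns `r` and `direction`.
#' @export
correlate_pairs <- function(pairs, mirna_profiles, gene_profiles,
                            negative_threshold = -0.5) {
  stopifnot(negative_threshold < 0)
  if (!identical(colnames(mirna_profiles), colnames(gene_profiles))) {
    stop("sample order differs between miRNA and gene profiles")
  }
  zm <- zscore(mirna_profiles)
  zg <- zscore(gene_profiles)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    x <- zm[pairs$mirna_id[i], ]
    y <- zg[pairs$transcript_id[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) 0
    else stats::cor(x, y)
  }, numeric(1))
  pairs$r <- r
  pairs$direction <- ifelse(r <= negative_threshold, "negative",
                     ifelse(r >= abs(negative_threshold), "positive",
                            "uncorrelated"))
  pairs
}

#' Term enrichment of a gene selection
#'
#' One-sided hypergeometric upper-tail p per term (equivalent to one-sided
#' Fisher's exact), flagged at p < 0.05 on the raw p-value; a BH column is
#' reported but does not gate.
#'
#' @param selected character vector of selected genes (must be a subset
#'   of `background`).
#' @param background character vector of background genes (defaults to
#'   every annotated gene in `gene2term`).
#' @param gene2term data.frame with columns `gene`, `term`.
#' @return data.frame per term: `term`, `overlap`, `selected_size`,
#'   `term_size`, `background_size`, `p`, `fdr`, `significant`.
#' @export
term_enrichment <- function(selected, background = NULL, gene2term) {
  stopifnot(all(c("gene", "term") %in% names(gene2term)))
  if (is.null(background)) background <- unique(gene2term$gene)
  selected <- unique(selected)
  background <- unique(background)
  if (!all(selected %in% background)) {
    stop("selected genes must be a subset of the background")
  }
  g2t <- unique(gene2term[gene2term$gene %in% background,
                          c("gene", "term")])
  terms <- sort(unique(g2t$term))
  N <- length(background)
  n <- length(selected)
  res <- do.call(rbind, lapply(terms, function(tm) {
    genes <- g2t$gene[g2t$term == tm]
    K <- length(genes)
    k <- sum(selected %in% genes)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, selected_size = n, term_size = K,
               background_size = N, p = p, stringsAsFactors = FALSE)
  }))
  res$fdr <- bh_fdr(res$p)
  res$significant <- res$p < 0.05
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
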