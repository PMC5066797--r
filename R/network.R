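# Weighted coexpression network: zero-count filtering and log2 transform,
# soft-threshold (power-beta) adjacency, topological overlap, module
# detection by average-linkage clustering of the TOM dissimilarity,
# module eigengenes and hub-centred subnetwork export.

#' Filter lowly expressed genes and log2-transform
#'
#' Genes with more than `max_zeros` zero values across the samples are
#' removed; survivors are transformed as log2(x + 1).
#'
#' @param m count matrix, genes x samples (>= 2 samples).
#' @param max_zeros maximum tolerated zeros per gene (default 4).
#' @param transform apply log2(x + 1) (default TRUE).
#' @return the filtered (transformed) matrix; errors if nothing survives.
#' @export
filter_genes <- function(m, max_zeros = 4, transform = TRUE) {
  stopifnot(ncol(m) >= 2)
  keep <- rowSums(m == 0) <= max_zeros
  if (!any(keep)) stop("no genes survive the zero filter")
  out <- m[keep, , drop = FALSE]
  if (transform) out <- log2(out + 1)
  out
}

#' Soft-threshold adjacency matrix
#'
#' Unsigned: `a_ij = |cor(x_i, x_j)|^power` (signed option available:
#' `((1 + cor)/2)^power`). The diagonal is 1; genes with zero variance get
#' correlation 0 to every other gene, with a warning.
#'
#' @param m expression matrix, genes x samples (>= 3 samples for a
#'   meaningful correlation).
#' @param power soft-threshold power (default 6, the conventional default
#'   for unsigned networks).
#' @param signed use the signed transformation.
#' @return symmetric adjacency matrix in [0, 1] with unit diagonal.
#' @export
adjacency_matrix <- function(m, power = 6, signed = FALSE) {
  stopifnot(ncol(m) >= 3)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance gene(s): correlation set to 0")
  }
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[is.na(cc)] <- 0
  a <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `k_i = sum_{j != i} a_ij` and `TOM_ii = 1`: similarity of two
#' genes combining their direct adjacency with their shared neighbourhood.
#'
#' @param a adjacency matrix (symmetric, unit diagonal).
#' @return TOM similarity matrix in [0, 1].
#' @export
tom_similarity <- function(a) {
  stopifnot(isSymmetric(unname(a)))
  k <- rowSums(a) - 1
  shared <- a %*% a - 2 * a  # subtracts the u = i and u = j terms (diag 1)
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect coexpression modules
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM
#' with a static tree cut at `cut_height`; clusters below `min_size` are
#' merged into the unassigned module "grey". Labels are assigned by size
#' rank, largest first ("M1", "M2", ...), so the labelling is
#' deterministic.
#'
#' @param tom TOM similarity matrix.
#' @param min_size minimum module size (default 30).
#' @param cut_height static cut height on 1 - TOM (default 0.95).
#' @return named character vector of module labels.
#' @export
detect_modules <- function(tom, min_size = 30, cut_height = 0.95) {
  n <- nrow(tom)
  ids <- rownames(tom) %||% as.character(seq_len(n))
  if (n < min_size) {
    return(stats::setNames(rep("grey", n), ids))
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(h, h = cut_height)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_size]
  # size rank, ties broken by original cluster index
  big <- big[order(-sizes[big], as.integer(big))]
  lab <- stats::setNames(rep("grey", n), ids)
  for (i in seq_along(big)) {
    lab[raw == as.integer(big[i])] <- paste0("M", i)
  }
  lab
}

#' Module eigengene
#'
#' First principal component of the standardized module submatrix with
#' samples as observations, sign-oriented to correlate positively with
#' the module's mean profile; the variance explained is reported. A
#' degenerate (zero-variance) module falls back to its standardized mean
#' profile with a message.
#'
#' @param m expression submatrix of one module, genes x samples
#'   (>= 2 genes).
#' @return list: `eigengene` (one value per sample, unit norm),
#'   `var_explained`.
#' @export
eigengene <- function(m) {
  if (nrow(m) < 2) stop("module must contain at least 2 genes")
  z <- zscore(m)
  mean_profile <- colMeans(z)
  if (all(z == 0)) {
    message("degenerate module: eigengene set to standardized mean profile")
    return(list(eigengene = stats::setNames(rep(0, ncol(m)), colnames(m)),
                var_explained = NA_real_))
  }
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  e <- pc$x[, 1]
  if (sqrt(sum(e^2)) > 0) e <- e / sqrt(sum(e^2))
  if (stats::sd(mean_profile) > 0 && stats::sd(e) > 0 &&
        stats::cor(e, mean_profile) < 0) {
    e <- -e
  }
  list(eigengene = stats::setNames(e, colnames(m)),
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Per-gene connectivity
#'
#' `k_i = sum_{j != i} a_ij`; with `labels`, the sum is restricted to the
#' gene's own module (within-module connectivity).
#'
#' @param a adjacency matrix.
#' @param labels optional module labels (named as the matrix).
#' @return named numeric vector.
#' @export
connectivity <- function(a, labels = NULL) {
  if (is.null(labels)) return(rowSums(a) - 1)
  stopifnot(all(rownames(a) %in% names(labels)))
  k <- stats::setNames(numeric(nrow(a)), rownames(a))
  for (mod in unique(labels)) {
    genes <- intersect(rownames(a), names(labels)[labels == mod])
    if (length(genes) < 2) next
    sub <- a[genes, genes, drop = FALSE]
    k[genes] <- rowSums(sub) - 1
  }
  k
}

#' Hub-centred subnetwork export
#'
#' Edges (hub, gene, weight) with adjacency at or above `edge_threshold`,
#' undirected and deduplicated; the neighbour set shared by all hubs
#' (coregulated genes) is reported alongside.
#'
#' @param a adjacency matrix.
#' @param hub_ids hub gene ids (must be in the network).
#' @param edge_threshold minimum adjacency for an exported edge
#'   (default 0.1).
#' @return list: `edges` (data.frame gene1, gene2, weight), `shared`
#'   (character vector of common neighbours), `degree` (edges per hub).
#' @export
hub_subnetwork <- function(a, hub_ids, edge_threshold = 0.1) {
  unknown <- setdiff(hub_ids, rownames(a))
  if (length(unknown) > 0) {
    stop("unknown hub id(s): ", paste(unknown, collapse = ", "),
         "; known ids include: ",
         paste(utils::head(rownames(a), 5), collapse = ", "))
  }
  rows <- list()
  nb <- list()
  for (h in hub_ids) {
    wts <- a[h, ]
    sel <- names(wts)[wts >= edge_threshold & names(wts) != h]
    nb[[h]] <- sel
    if (length(sel) > 0) {
      rows[[h]] <- data.frame(gene1 = h, gene2 = sel,
                              weight = unname(wts[sel]),
                              stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene1 = character(0), gene2 = character(0),
               weight = numeric(0))
  }
  if (nrow(edges) > 0) {
    key <- apply(edges[, c("gene1", "gene2")], 1,
                 function(v) paste(sort(v), collapse = "\r"))
    edges <- edges[!duplicated(key), , drop = FALSE]
    rownames(edges) <- NULL
  }
  shared <- if (length(nb) == 0) character(0) else Reduce(intersect, nb)
  list(edges = edges, shared = shared,
       degree = vapply(nb, length, integer(1)))
}

#' Build the full coexpression network
#'
#' Convenience wrapper: zero filter + log2 -> adjacency -> TOM -> modules
#' -> eigengenes -> connectivity; the pipeline's `network` stage.
#'
#' @param counts gene count matrix (genes x samples).
#' @param power,signed,max_zeros,min_size,cut_height see the individual
#'   steps.
#' @param pre_filtered set TRUE when `counts` is already on a log/
#'   Gaussian scale (skips the zero filter and transform).
#' @return list: `expr`, `adjacency`, `tom`, `labels`, `eigengenes`
#'   (modules x samples), `var_explained`, `connectivity` (within-module).
#' @export
build_network <- function(counts, power = 6, signed = FALSE, max_zeros = 4,
                          min_size = 30, cut_height = 0.95,
                          pre_filtered = FALSE) {
  expr <- if (pre_filtered) counts else filter_genes(counts, max_zeros)
  a <- adjacency_matrix(expr, power = power, signed = signed)
  tom <- tom_similarity(a)
  labels <- detect_modules(tom, min_size = min_size,
                           cut_height = cut_height)
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(as.integer(sub("^M", "", mods)))]
  eg <- lapply(mods, function(mod) {
    eigengene(expr[names(labels)[labels == mod], , drop = FALSE])
  })
  eigengenes <- if (length(eg)) {
    em <- do.call(rbind, lapply(eg, `[[`, "eigengene"))
    rownames(em) <- mods
    em
  } else matrix(numeric(0), 0, ncol(expr))
  list(expr = expr, adjacency = a, tom = tom, labels = labels,
       eigengenes = eigengenes,
       var_explained = stats::setNames(
         vapply(eg, `[[`, numeric(1), "var_explained"), mods),
       connectivity = connectivity(a, labels))
}
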