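#' Hierarchical clustering of expression profiles
#'
#' Transforms FPKM to log2(FPKM + 1), z-scores each gene across samples
#' (constant genes get all-zero profiles), clusters genes by average-linkage
#' hierarchical agglomeration on Euclidean distances, and cuts the dendrogram
#' into \code{k} clusters. Genes are processed in id order, so ties break
#' deterministically (lowest gene id first), and cluster labels are assigned
#' in order of first appearance.
#'
#' @param expr an \linkS4class{FpkmExperiment}.
#' @param k number of clusters.
#' @param heatmapFile optional file path for a heat-map export (pheatmap).
#' @return list(clusters = named character vector gene -> "C1".."Ck",
#'   hclust = the dendrogram, transformed = the z-scored matrix).
#' @export
clusterExpression <- function(expr, k = 3, heatmapFile = NULL) {
  stopifnot(is(expr, "FpkmExperiment"), k >= 1)
  x <- fpkm(expr)
  if (k > nrow(x)) stop("k exceeds the number of genes")
  x <- x[order(rownames(x)), , drop = FALSE]
  lx <- log2(x + 1)
  mu <- rowMeans(lx)
  sd_ <- apply(lx, 1, stats::sd)
  z <- (lx - mu) / ifelse(sd_ > 0, sd_, 1)
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "average")
  raw <- stats::cutree(hc, k = k)
  relabel <- match(raw, unique(raw))
  clusters <- stats::setNames(sprintf("C%d", relabel), rownames(z))
  if (!is.null(heatmapFile))
    pheatmap::pheatmap(z, clustering_method = "average",
                       cluster_cols = ncol(z) > 1, show_rownames = nrow(z) <= 80,
                       filename = heatmapFile, silent = TRUE)
  list(clusters = clusters, hclust = hc, transformed = z)
}

#' Thresholded gene co-expression network
#'
#' Pearson correlation of every gene pair across samples; an edge is kept iff
#' |r| >= rMin AND p < pMax (strict, two-sided t-transform p). Note that with
#' few samples this conjunction is more stringent than the |r| cutoff alone
#' (at n = 6, r = 0.95 has p ~ 0.0037 > 0.001). Hubs are nodes ranked by
#' degree.
#'
#' @param expr an \linkS4class{FpkmExperiment}.
#' @param rMin minimum |r|.
#' @param pMax strict upper bound on the p-value.
#' @param topHubs number of hub genes to report.
#' @return list(edges, hubs).
#' @export
coexpressionNetwork <- function(expr, rMin = 0.95, pMax = 0.001, topHubs = 10) {
  stopifnot(is(expr, "FpkmExperiment"))
  if (ncol(expr) < 4) stop("need >= 4 samples for correlation p-values")
  all_edges <- .cor_edges(t(fpkm(expr)), minN = 4)
  edges <- all_edges[abs(all_edges$r) >= rMin & all_edges$p < pMax, , drop = FALSE]
  rownames(edges) <- NULL
  deg <- sort(table(c(edges$node_a, edges$node_b)), decreasing = TRUE)
  hubs <- data.frame(gene = names(deg), degree = as.integer(deg),
                     stringsAsFactors = FALSE)
  hubs <- utils::head(hubs, topHubs)
  list(edges = edges, hubs = hubs)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(target gene) - Ct(reference gene); ddCt subtracts the
#' calibrator sample's dCt; fold change = 2^-ddCt. The calibrator's own fold
#' change is 1 by construction, and shifting every Ct by a constant leaves
#' fold changes unchanged.
#'
#' @param ctTarget named numeric vector of target-gene Ct values per sample.
#' @param ctReference named numeric vector of reference-gene Ct values.
#' @param calibrator calibrator sample id.
#' @param samples samples to report (default: all in \code{ctTarget}).
#' @return Named numeric vector of fold changes.
#' @examples
#' ddctFoldChange(c(s = 20, cal = 22), c(s = 15, cal = 15), calibrator = "cal")
#' @export
ddctFoldChange <- function(ctTarget, ctReference, calibrator,
                           samples = names(ctTarget)) {
  if (!calibrator %in% names(ctTarget)) stop("calibrator sample not present")
  miss <- setdiff(samples, names(ctReference))
  if (length(miss))
    stop("missing reference Ct for sample(s): ", paste(miss, collapse = ", "))
  ct_t <- ctTarget[samples]
  ct_r <- ctReference[samples]
  if (any(!is.finite(c(ct_t, ct_r, ctTarget[calibrator], ctReference[calibrator]))))
    stop("Ct values must be finite")
  dct <- ct_t - ct_r
  dct_cal <- ctTarget[calibrator] - ctReference[calibrator]
  ddct <- dct - dct_cal
  stats::setNames(2^(-ddct), samples)
}
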