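#' Hierarchical clustering of samples on signature genes
#'
#' Signature-gene expression is z-scored gene-wise across samples (so
#' high-magnitude genes do not dominate), pairwise sample distance is
#' 1 - Pearson correlation (or Euclidean), and samples are merged by
#' agglomerative average linkage (or Ward) with the tree cut at `k`
#' clusters.  Genes constant across samples carry no distance information
#' and are dropped with a warning; if every gene is constant the call is
#' an error.
#'
#' @param expr An [expression_matrix()].
#' @param signature Signature genes to cluster on.
#' @param k Number of clusters (default 2: e.g. tumor-like vs normal-like).
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default) or `"ward"` (Ward.D2).
#' @return List of class `ClusterAssignment`: `assignment` (named integer
#'   vector sample -> cluster), `merge`, `height` (the linkage record),
#'   `hclust` (the underlying tree).
#' @export
hierarchical_cluster <- function(expr, signature, k = 2,
                                 distance = c("correlation", "euclidean"),
                                 linkage = c("average", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  sig <- signature_genes(signature)
  miss <- setdiff(sig, rownames(expr))
  if (length(miss))
    stop("signature gene(s) missing from matrix: ",
         paste(head(miss, 10), collapse = ", "))
  if (ncol(expr) < 2) stop("need >= 2 samples")
  v <- unclass(expr)[sig, , drop = FALSE]
  sds <- apply(v, 1, sd)
  if (all(sds == 0)) stop("all signature genes are constant across samples")
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before clustering")
    v <- v[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (v - rowMeans(v)) / sds
  d <- if (distance == "correlation") {
    if (nrow(z) < 2)
      stop("correlation distance needs >= 2 non-constant genes")
    as.dist(1 - cor(z))
  } else {
    dist(t(z))
  }
  hc <- hclust(d, method = if (linkage == "average") "average"
                           else "ward.D2")
  assignment <- cutree(hc, k = k)
  structure(list(assignment = assignment, merge = hc$merge,
                 height = hc$height, hclust = hc),
            class = "ClusterAssignment")
}

#' Association between clusters and tissue class
#'
#' Builds the 2x2 cluster-by-class contingency table and applies the exact
#' conditional test, two-sided by default since segregation claims carry
#' no direction.
#'
#' @param assignment A [hierarchical_cluster()] result (or a named vector
#'   sample -> cluster with two levels).
#' @param tissue_classes Named character vector sample -> class, exactly
#'   two distinct classes among the clustered samples.
#' @param sided Passed to [fisher_exact_2x2()]; default `"two"`.
#' @return List with `table` (2x2 matrix) and `p_value`.
#' @export
cluster_class_association <- function(assignment, tissue_classes,
                                      sided = "two") {
  if (inherits(assignment, "ClusterAssignment"))
    assignment <- assignment$assignment
  samples <- names(assignment)
  miss <- setdiff(samples, names(tissue_classes))
  if (length(miss))
    stop("missing tissue class for sample(s): ",
         paste(head(miss, 5), collapse = ", "))
  classes <- tissue_classes[samples]
  if (length(unique(classes)) > 2)
    stop("more than two tissue classes")
  if (length(unique(classes)) < 2 || length(unique(assignment)) < 2)
    stop("degenerate contingency table: a margin has a single level")
  tab <- table(cluster = assignment, class = classes)
  list(table = unclass(tab),
       p_value = fisher_exact_2x2(matrix(as.integer(tab), 2, 2),
                                  sided = sided))
}
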