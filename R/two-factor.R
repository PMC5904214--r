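#' Gene signatures
#'
#' A `GeneSignature` is an ordered, duplicate-free gene list plus free-form
#' provenance (the cutoff used, per-filter drop counts, source experiment).
#'
#' @param gene_ids Character vector, non-empty, no duplicates.
#' @param provenance Named list of metadata.
#' @return An object of class `GeneSignature`.
#' @export
gene_signature <- function(gene_ids, provenance = list()) {
  gene_ids <- as.character(gene_ids)
  if (!length(gene_ids)) stop("a gene signature must be non-empty")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s) in signature: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  structure(list(gene_ids = gene_ids, provenance = provenance),
            class = "GeneSignature")
}

#' @rdname gene_signature
#' @param x A `GeneSignature` or plain character vector.
#' @export
signature_genes <- function(x) {
  if (inherits(x, "GeneSignature")) x$gene_ids else as.character(x)
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature with %d genes\n", length(x$gene_ids)))
  cat("  ", paste(head(x$gene_ids, 8), collapse = ", "),
      if (length(x$gene_ids) > 8) ", ..." else "", "\n", sep = "")
  if (length(x$provenance)) {
    keep <- vapply(x$provenance, function(v)
      is.atomic(v) && length(v) == 1, logical(1))
    for (nm in names(x$provenance)[keep])
      cat(sprintf("  %s: %s\n", nm, format(x$provenance[[nm]])))
  }
  invisible(x)
}

#' Fit the additive two-factor model gene by gene
#'
#' Ordinary least squares of log2 expression on intercept + p52 + lps
#' (additive, no interaction) across the eight samples, vectorized over
#' genes through a single QR decomposition of the shared design matrix.
#' The p52 coefficient is its estimated log2 fold change; its two-sided
#' p-value comes from the t distribution on the residual degrees of freedom.
#'
#' An optional pooled-variance moderation is available: with
#' `shrink_prior_df = d0 > 0`, each gene's residual variance is shrunk
#' toward the mean gene variance with prior weight `d0`
#' (`s2* = (d0 * mean(s2) + df * s2) / (d0 + df)`, t on `df + d0` df).
#' Selection downstream is by logFC, which is identical either way.
#'
#' Degenerate genes: a gene constant across all samples gets both
#' coefficients 0 and p = 1; a gene with zero residual variance but a
#' nonzero coefficient gets p floored at the smallest positive double.
#'
#' @param expr A log2 [expression_matrix()].
#' @param annotation Data frame with columns `sample_id`, `p52`, `lps`
#'   (0/1 levels) covering every sample in `expr`.
#' @param shrink_prior_df Prior df for variance moderation (0 = plain OLS).
#' @return Data frame with columns `gene_id`, `coef_p52`, `coef_lps`,
#'   `t_p52`, `p_value_p52`, `rank`.  Ranks order genes by descending
#'   `coef_p52`, ties broken by ascending p then gene id.
#' @export
fit_two_factor_model <- function(expr, annotation, shrink_prior_df = 0) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr_scale(expr) != "log2")
    stop("two-factor model expects a log2-scale matrix")
  miss <- setdiff(colnames(expr), annotation$sample_id)
  if (length(miss))
    stop("annotation missing sample(s): ", paste(miss, collapse = ", "))
  ann <- annotation[match(colnames(expr), annotation$sample_id), ]
  if (!all(ann$p52 %in% c(0, 1)) || !all(ann$lps %in% c(0, 1)))
    stop("factor levels must be 0/1")
  X <- cbind(intercept = 1, p52 = ann$p52, lps = ann$lps)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    confounded <- all(ann$p52 == ann$lps) || all(ann$p52 == 1 - ann$lps)
    conf <- c("p52", "lps")[c(length(unique(ann$p52)) < 2 || confounded,
                              length(unique(ann$lps)) < 2 || confounded)]
    stop("rank-deficient design; confounded or constant factor(s): ",
         paste(unique(conf), collapse = ", "))
  }
  Y <- t(unclass(expr))                      # samples x genes
  coefs <- qr.coef(qr_x, Y)                  # 3 x genes
  fitted <- X %*% coefs
  res <- Y - fitted
  df <- nrow(X) - ncol(X)
  s2 <- colSums(res^2) / df
  if (shrink_prior_df > 0) {
    s2 <- (shrink_prior_df * mean(s2) + df * s2) / (shrink_prior_df + df)
    df_t <- df + shrink_prior_df
  } else df_t <- df
  xtx_inv <- chol2inv(qr.R(qr_x))            # (X'X)^-1
  se_p52 <- sqrt(s2 * xtx_inv[2, 2])
  t_p52 <- coefs["p52", ] / se_p52
  p <- 2 * pt(-abs(t_p52), df_t)
  zero_var <- s2 <= .Machine$double.eps * 100
  zero_coef <- abs(coefs["p52", ]) <= sqrt(.Machine$double.eps)
  t_p52[zero_var & zero_coef] <- 0
  p[zero_var & zero_coef] <- 1
  if (any(zero_var & !zero_coef)) {
    log_msg("fit_two_factor", sum(zero_var & !zero_coef),
            " zero-variance gene(s); p floored at smallest double")
    p[zero_var & !zero_coef] <- .Machine$double.xmin
  }
  res_df <- data.frame(gene_id = colnames(Y),
                       coef_p52 = coefs["p52", ],
                       coef_lps = coefs["lps", ],
                       t_p52 = t_p52,
                       p_value_p52 = p,
                       stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-res_df$coef_p52, res_df$p_value_p52, res_df$gene_id)
  res_df$rank <- integer(nrow(res_df))
  res_df$rank[ord] <- seq_len(nrow(res_df))
  res_df
}

#' Select the p52-associated gene signature
#'
#' Applies the selection cascade to two-factor results: keep genes with a
#' positive p52 coefficient at or above `logfc_cutoff` (inclusive: a gene at
#' exactly the cutoff is kept), map them through the ortholog table, then
#' intersect with the human expression universe, preserving rank order
#' throughout.  Provenance records the cutoff, the implied linear fold
#' change `2^cutoff`, and how many genes each filter dropped, so the final
#' count always reconciles with the inputs.
#'
#' @param results Output of [fit_two_factor_model()].
#' @param logfc_cutoff Positive log2 fold-change cutoff (default 0.41,
#'   i.e. a ~1.33x linear increase).
#' @param mapping Optional ortholog mapping (data frame `source`/`target`,
#'   see [read_gene_mapping()]).  Genes with no mapping are dropped with
#'   reason `no_homolog`.
#' @param universe Optional character vector of ids present in the human
#'   cohort; mapped genes outside it are dropped with reason
#'   `not_in_universe`.
#' @return A [gene_signature()].
#' @export
select_signature <- function(results, logfc_cutoff = 0.41, mapping = NULL,
                             universe = NULL) {
  if (logfc_cutoff <= 0) stop("`logfc_cutoff` must be > 0")
  res <- results[order(results$rank), ]
  pos <- res[res$coef_p52 > 0, ]
  pass <- pos[pos$coef_p52 >= logfc_cutoff, ]
  dropped <- data.frame(gene_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  genes <- pass$gene_id
  n_pass <- length(genes)
  n_no_homolog <- 0L
  if (!is.null(mapping)) {
    per_gene <- lapply(genes, function(g)
      unique(mapping$target[mapping$source == g]))
    unmapped <- genes[lengths(per_gene) == 0]
    n_no_homolog <- length(unmapped)
    if (n_no_homolog)
      dropped <- rbind(dropped, data.frame(gene_id = unmapped,
                                           reason = "no_homolog"))
    genes <- unique(unlist(per_gene, use.names = FALSE))
  }
  n_not_in_universe <- 0L
  if (!is.null(universe)) {
    if (!length(universe)) stop("`universe` must be non-empty")
    out <- setdiff(genes, universe)
    n_not_in_universe <- length(out)
    if (n_not_in_universe)
      dropped <- rbind(dropped, data.frame(gene_id = out,
                                           reason = "not_in_universe"))
    genes <- genes[genes %in% universe]
  }
  if (!length(genes))
    stop("no genes pass the selection cascade; consider relaxing ",
         "`logfc_cutoff` (currently ", logfc_cutoff, ")")
  gene_signature(genes, provenance = list(
    cutoff = logfc_cutoff,
    linear_fold_change = 2^logfc_cutoff,
    n_input = nrow(res),
    n_positive = nrow(pos),
    n_pass_cutoff = n_pass,
    n_dropped_no_homolog = n_no_homolog,
    n_dropped_not_in_universe = n_not_in_universe,
    n_selected = length(genes),
    dropped = dropped))
}
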