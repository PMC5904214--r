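#' Convert RSEM transcript fractions to TPM
#'
#' TPM is obtained by multiplying RSEM fractional estimates by 10^6; the
#' scale tag is updated accordingly.  Anything not tagged `rsem_fraction`
#' is refused.
#'
#' @param expr An [expression_matrix()] with scale `rsem_fraction`.
#' @return The same matrix on the `tpm` scale.
#' @examples
#' m <- matrix(c(2e-6, 1e-6, 3e-6, 4e-6), 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' rsem_to_tpm(expression_matrix(m, "rsem_fraction"))
#' @export
rsem_to_tpm <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr_scale(expr) != "rsem_fraction")
    stop("rsem_to_tpm() expects scale 'rsem_fraction', got '",
         expr_scale(expr), "'")
  expression_matrix(unclass(expr) * 1e6, "tpm")
}

#' Paired tumor/normal differential expression
#'
#' For each gene, per-pair differences `d_i = log2(tumor_i + c) -
#' log2(normal_i + c)` are formed (pseudocount `c` guards zeros on the TPM
#' scale) and a paired t-test is applied: `t = mean(d) / (sd(d) / sqrt(n))`,
#' two-sided p from the t distribution on `n - 1` df, `logfc = mean(d)`.
#' p-values are Benjamini-Hochberg adjusted across all genes.
#'
#' Zero-variance guards: all differences zero gives `t = 0`, `p = 1`;
#' identical nonzero differences give p floored at the smallest positive
#' double (logged) rather than an exact zero.
#'
#' @param expr A `tpm` [expression_matrix()] containing both members of
#'   every pair.
#' @param annotation Data frame with `sample_id`, `tissue_class`
#'   (`tumor`/`normal`) and `pair_id`; each pair must have exactly one
#'   tumor and one normal sample present in `expr`.
#' @param pseudocount Positive pseudocount added before log2 (default 1).
#' @return Data frame of per-gene records: `gene_id`, `logfc`, `t_stat`,
#'   `p_value`, `fdr`.
#' @export
paired_differential <- function(expr, annotation, pseudocount = 1) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (expr_scale(expr) != "tpm")
    stop("paired_differential() expects scale 'tpm'; apply rsem_to_tpm() ",
         "or exponentiate first")
  if (pseudocount <= 0) stop("`pseudocount` must be > 0")
  ann <- annotation[!is.na(annotation$pair_id) &
                      annotation$tissue_class %in% c("tumor", "normal"), ]
  pairs <- unique(ann$pair_id)
  if (length(pairs) < 2) stop("need >= 2 complete pairs")
  t_ids <- n_ids <- character(length(pairs))
  for (i in seq_along(pairs)) {
    rows <- ann[ann$pair_id == pairs[i], ]
    tu <- rows$sample_id[rows$tissue_class == "tumor"]
    no <- rows$sample_id[rows$tissue_class == "normal"]
    if (length(tu) != 1 || length(no) != 1 ||
        !all(c(tu, no) %in% colnames(expr)))
      stop("pair '", pairs[i],
           "' lacks exactly one tumor and one normal sample in the matrix")
    t_ids[i] <- tu; n_ids[i] <- no
  }
  v <- unclass(expr)
  D <- log2(v[, t_ids, drop = FALSE] + pseudocount) -
    log2(v[, n_ids, drop = FALSE] + pseudocount)
  k <- ncol(D)
  m <- rowMeans(D)
  s <- sqrt(rowSums((D - m)^2) / (k - 1))
  t_stat <- m / (s / sqrt(k))
  p <- 2 * pt(-abs(t_stat), k - 1)
  zero_s <- s <= .Machine$double.eps * 100
  t_stat[zero_s & abs(m) <= sqrt(.Machine$double.eps)] <- 0
  p[zero_s & abs(m) <= sqrt(.Machine$double.eps)] <- 1
  hard <- zero_s & abs(m) > sqrt(.Machine$double.eps)
  if (any(hard)) {
    log_msg("paired_differential", sum(hard),
            " zero-variance gene(s); p floored at smallest double")
    t_stat[hard] <- sign(m[hard]) * Inf
    p[hard] <- .Machine$double.xmin
  }
  data.frame(gene_id = rownames(v), logfc = m, t_stat = t_stat,
             p_value = p, fdr = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`: sorted
#' p-values are scaled by `m / i`, made monotone by a cumulative minimum
#' from the largest rank, capped at 1 and mapped back to input order; tied
#' p-values share the identical adjusted value.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return FDR values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Call up-regulated genes
#'
#' Up-regulation requires both `logfc > logfc_threshold` and
#' `fdr < fdr_threshold`, with strict inequalities (a gene at exactly the
#' logFC threshold is excluded).
#'
#' @param records Data frame from [paired_differential()].
#' @param logfc_threshold Positive log2 fold-change threshold (default 1;
#'   use 1.3 for the stricter microarray-cohort preset).
#' @param fdr_threshold Positive FDR threshold (default 0.01).
#' @return Character vector of up-regulated gene ids.
#' @export
call_upregulated <- function(records, logfc_threshold = 1,
                             fdr_threshold = 0.01) {
  if (logfc_threshold <= 0 || fdr_threshold <= 0)
    stop("thresholds must be positive")
  records$gene_id[records$logfc > logfc_threshold &
                    records$fdr < fdr_threshold]
}

#' Signature/up-regulation overlap report
#'
#' The reporting layer behind overlap statements of the form "1,274 of
#' 20,501 genes (6.2%) were up-regulated; 35 of the 71 signature genes
#' (49.3%)": percentages are rounded half-up to one decimal, and the
#' hypergeometric upper-tail and Fisher (greater) p-values for the
#' over-representation of signature genes among the up-regulated set are
#' attached.
#'
#' @param universe_n Genes tested.
#' @param up_n Up-regulated genes.
#' @param signature_n Signature genes (all within the universe).
#' @param signature_up_n Up-regulated signature genes.
#' @return List with `pct_up_global`, `pct_up_signature`, the four input
#'   counts, `hypergeom_p` and `fisher_p`.
#' @export
signature_overlap_report <- function(universe_n, up_n, signature_n,
                                     signature_up_n) {
  if (signature_up_n > min(up_n, signature_n) || up_n > universe_n ||
      signature_n > universe_n)
    stop("inconsistent overlap counts")
  tab <- matrix(c(signature_up_n, signature_n - signature_up_n,
                  up_n - signature_up_n,
                  universe_n - signature_n - (up_n - signature_up_n)),
                2, 2, byrow = TRUE)
  list(universe_n = universe_n, up_n = up_n, signature_n = signature_n,
       signature_up_n = signature_up_n,
       pct_up_global = round_half_up(100 * up_n / universe_n, 1),
       pct_up_signature = round_half_up(100 * signature_up_n / signature_n, 1),
       hypergeom_p = hypergeom_overrep(universe_n, up_n, signature_n,
                                       signature_up_n),
       fisher_p = fisher_exact_2x2(tab, sided = "greater"))
}
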