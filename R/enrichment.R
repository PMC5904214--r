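# Log-space helpers: hypergeometric point mass and log-sum-exp.  Everything
# over-representation related runs through these so p-values remain accurate
# down to ~1e-300 without underflow.

log_hyper_pmf <- function(i, N, K, n) {
  lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
}

logsumexp <- function(lx) {
  lx <- lx[is.finite(lx) | lx == -Inf]
  m <- max(lx)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lx - m)))
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= x)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance of drawing at least `x` successes in a sample of `n` from a
#' universe of `N` containing `K` successes.  Computed by log-gamma
#' summation over the support.
#'
#' @param universe_n Universe size `N`.
#' @param universe_success_k Successes in the universe `K`.
#' @param sample_n Sample size `n`.
#' @param sample_success_x Observed successes `x`.
#' @return The p-value.
#' @examples
#' hypergeom_overrep(10, 5, 4, 4)  # 5 / 210
#' @export
hypergeom_overrep <- function(universe_n, universe_success_k, sample_n,
                              sample_success_x) {
  N <- universe_n; K <- universe_success_k
  n <- sample_n; x <- sample_success_x
  if (any(c(N, K, n, x) < 0) || K > N || n > N || x > min(K, n))
    stop("inconsistent hypergeometric counts")
  if (x <= max(0, n + K - N)) return(1)
  hi <- min(K, n)
  p <- exp(logsumexp(log_hyper_pmf(x:hi, N, K, n)))
  min(p, 1)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test with fixed margins, enumerated over the whole
#' support in log space.  `sided = "greater"` sums hypergeometric
#' probabilities of tables whose top-left cell is at least the observed
#' one (the enrichment direction); `sided = "two"` sums all tables whose
#' probability does not exceed the observed table's (with a 1 + 1e-7
#' relative tolerance, the conventional tie guard).
#'
#' @param table 2x2 integer matrix (or length-4 vector `a, b, c, d` filled
#'   by row); rows index signature membership, columns up-regulation.
#' @param sided `"greater"` (default) or `"two"`.
#' @return The p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2, byrow = TRUE), "two")  # 0.1
#' @export
fisher_exact_2x2 <- function(table, sided = c("greater", "two")) {
  sided <- match.arg(sided)
  if (is.vector(table) && length(table) == 4)
    table <- matrix(table, 2, 2, byrow = TRUE)
  if (!all(dim(table) == c(2, 2)))
    stop("`table` must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("cell counts must be non-negative integers")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  N <- a + b + c + d
  if (N == 0) stop("table total is zero")
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) return(1)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  support <- lo:hi
  lp <- log_hyper_pmf(support, N, c1, r1)
  if (sided == "greater") {
    keep <- support >= a
  } else {
    lp_obs <- lp[support == a]
    keep <- lp <= lp_obs + log(1 + 1e-7)
  }
  min(exp(logsumexp(lp[keep])), 1)
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric upper-tail test of a query gene list against each set in
#' a collection, relative to a stated universe.  Each set is intersected
#' with the universe before testing; the expected count is
#' `|query| * |set n universe| / |universe|`.  p-values are BH-adjusted
#' across all tested sets and records are flagged significant below
#' `fdr_threshold` (default 0.001, a stringent level suited to screening
#' thousands of ontology terms).
#'
#' @param query Character vector of query genes, a subset of `universe`.
#' @param universe Character vector, the reference gene universe.
#' @param gene_sets Named list of character vectors (see
#'   [read_gene_sets()]).
#' @param fdr_threshold Significance threshold on the FDR.
#' @return Data frame sorted by ascending p (ties by term id):
#'   `term_id`, `reference_set_size`, `expected_count`, `observed_count`,
#'   `p_value`, `fdr`, `significant`.
#' @export
gene_set_enrichment <- function(query, universe, gene_sets,
                                fdr_threshold = 0.001) {
  universe <- unique(universe)
  if (!length(universe)) stop("`universe` must be non-empty")
  query <- unique(query)
  out <- setdiff(query, universe)
  if (length(out))
    stop("query gene(s) outside the universe: ",
         paste(head(out, 5), collapse = ", "))
  recs <- lapply(names(gene_sets), function(nm) {
    ref <- intersect(gene_sets[[nm]], universe)
    obs <- length(intersect(ref, query))
    data.frame(term_id = nm,
               reference_set_size = length(ref),
               expected_count = length(query) * length(ref) /
                 length(universe),
               observed_count = obs,
               p_value = hypergeom_overrep(length(universe), length(ref),
                                           length(query), obs),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, recs)
  res$fdr <- bh_adjust(res$p_value)
  res$significant <- res$fdr < fdr_threshold
  res[order(res$p_value, res$term_id), , drop = FALSE]
}

# Transitive ancestor sets for a child -> parent DAG, with cycle detection.
dag_ancestors <- function(term_dag) {
  stopifnot(all(c("child", "parent") %in% names(term_dag)))
  nodes <- unique(c(term_dag$child, term_dag$parent))
  parents <- split(term_dag$parent, term_dag$child)
  anc <- setNames(vector("list", length(nodes)), nodes)
  state <- setNames(integer(length(nodes)), nodes)  # 0 new, 1 open, 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) stop("cycle detected in term DAG at '", v, "'")
    if (state[[v]] == 2L) return(anc[[v]])
    state[[v]] <<- 1L
    ps <- parents[[v]]
    acc <- character()
    for (p in ps) acc <- c(acc, p, visit(p))
    anc[[v]] <<- unique(acc)
    state[[v]] <<- 2L
    anc[[v]]
  }
  for (v in nodes) visit(v)
  anc
}

#' Prune enrichment results to most-specific significant terms
#'
#' Given a child-to-parent term DAG (e.g. the Biological Process topology),
#' removes any significant term that is an ancestor of another significant
#' term, so only the most specific representative of each significant
#' lineage survives.  Non-significant records and record order are
#' untouched.
#'
#' @param records Output of [gene_set_enrichment()].
#' @param term_dag Data frame with columns `child`, `parent` (edges point
#'   child to parent); must be acyclic.
#' @return `records` with ancestor-significant rows removed.
#' @export
prune_to_specific <- function(records, term_dag) {
  anc <- dag_ancestors(term_dag)
  sig <- records$term_id[records$significant]
  anc_of_sig <- unique(unlist(anc[intersect(sig, names(anc))],
                              use.names = FALSE))
  drop <- records$significant & records$term_id %in% anc_of_sig
  records[!drop, , drop = FALSE]
}
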