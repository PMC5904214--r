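#' Signature scores per sample
#'
#' `sum_score()` sums expression of the signature genes in each sample
#' (optionally on the log2(TPM + 1) scale); `vote_score()` counts, per
#' sample, the signature genes whose expression is at or above that gene's
#' median across samples (inclusive, so a gene constant across samples
#' votes for every sample).  The vote statistic prevents a sample with a
#' few extremely expressed genes from dominating the ranking.
#'
#' @param expr An [expression_matrix()] containing all signature genes.
#' @param signature Character vector or [gene_signature()].
#' @param log_transform For `sum_score()`: sum `log2(x + 1)` instead of
#'   raw values (default `FALSE`, i.e. the linear TPM scale as stored).
#' @return Named numeric (sum) or integer (vote) vector over samples.
#' @export
sum_score <- function(expr, signature, log_transform = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  sig <- signature_genes(signature)
  miss <- setdiff(sig, rownames(expr))
  if (length(miss))
    stop("signature gene(s) missing from matrix: ",
         paste(head(miss, 10), collapse = ", "))
  v <- unclass(expr)[sig, , drop = FALSE]
  if (log_transform) v <- log2(v + 1)
  colSums(v)
}

#' @rdname sum_score
#' @export
vote_score <- function(expr, signature) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  sig <- signature_genes(signature)
  miss <- setdiff(sig, rownames(expr))
  if (length(miss))
    stop("signature gene(s) missing from matrix: ",
         paste(head(miss, 10), collapse = ", "))
  v <- unclass(expr)[sig, , drop = FALSE]
  med <- apply(v, 1, median)
  colSums(v >= med)
}

#' Split a cohort into high- and low-score halves
#'
#' Patients are sorted by descending score with ties broken by ascending
#' patient id (deterministic across platforms); the top `floor(n/2)` form
#' the high-expression group, so with an odd cohort the median patient goes
#' to the low group.
#'
#' @param scores Named numeric vector (patient id -> score), length >= 2.
#' @return Data frame `patient_id`, `score`, `group` (`high`/`low`), in
#'   the sorted order.
#' @export
split_by_score <- function(scores) {
  if (length(scores) < 2) stop("need >= 2 patients to split")
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("`scores` must be named by patient id")
  ord <- order(-scores, names(scores))
  n_high <- floor(length(scores) / 2)
  data.frame(patient_id = names(scores)[ord],
             score = unname(scores[ord]),
             group = rep(c("high", "low"),
                         c(n_high, length(scores) - n_high)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Truncate follow-up to a horizon
#'
#' Converts follow-up beyond `limit_days` to censoring at `limit_days`
#' (default 1825 days = 5 years, reflecting 5-year survival).  A record at
#' exactly the limit is unchanged; truncation never adds events.
#'
#' @param records Clinical data frame (see [validate_clinical()]).
#' @param limit_days Positive horizon in days.
#' @return The truncated records.
#' @export
truncate_survival <- function(records, limit_days = 1825) {
  if (limit_days <= 0) stop("`limit_days` must be > 0")
  records <- validate_clinical(records)
  over <- records$time_days > limit_days
  records$event[over] <- 0L
  records$time_days[over] <- limit_days
  records
}

#' Kaplan-Meier product-limit estimate
#'
#' At each distinct event time `t_j` with `d_j` events among `n_j` at risk,
#' the survival estimate multiplies by `1 - d_j / n_j`; censored times only
#' shrink the risk set, and censoring at an event time is processed after
#' the event (the usual convention).  `S(0) = 1` implicitly.
#'
#' @param records Clinical data frame.
#' @return Data frame of class `SurvivalCurve` with one row per distinct
#'   observed time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(records) {
  records <- validate_clinical(records)
  if (!nrow(records)) stop("no records")
  tt <- sort(unique(records$time_days))
  n_event <- vapply(tt, function(t)
    sum(records$time_days == t & records$event == 1L), numeric(1))
  n_censor <- vapply(tt, function(t)
    sum(records$time_days == t & records$event == 0L), numeric(1))
  n_risk <- vapply(tt, function(t) sum(records$time_days >= t), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv,
                       row.names = NULL),
            class = c("SurvivalCurve", "data.frame"))
}

# Fast log-rank core on bare vectors; shared by logrank_test() and the
# calibration/power simulations, so a 10^4-replicate null run stays cheap.
logrank_core <- function(time, event, grp) {
  # grp: logical, TRUE = group 1.  Single sort + tabulate, O(n log n).
  o <- order(time)
  time <- time[o]; event <- event[o]; grp <- grp[o]
  ut <- unique(time)                     # ascending
  idx <- match(time, ut)
  nt <- length(ut)
  d <- tabulate(idx[event == 1L], nbins = nt)
  d1 <- tabulate(idx[event == 1L & grp], nbins = nt)
  leave <- tabulate(idx, nbins = nt)     # everyone leaving at each time
  leave1 <- tabulate(idx[grp], nbins = nt)
  n <- length(time) - c(0, cumsum(leave))[seq_len(nt)]
  n1 <- sum(grp) - c(0, cumsum(leave1))[seq_len(nt)]
  keep <- d > 0
  if (!any(keep)) return(c(chi_square = 0, p_value = 1))
  d <- d[keep]; d1 <- d1[keep]; n <- n[keep]; n1 <- n1[keep]
  e1 <- d * n1 / n
  v1 <- ifelse(n > 1, d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1), 0)
  V <- sum(v1)
  if (V <= 0) return(c(chi_square = 0, p_value = 1))
  chi <- (sum(d1) - sum(e1))^2 / V
  c(chi_square = chi, p_value = pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of events in one group
#' is compared with its expectation under the margin-fixed hypergeometric
#' null; the accumulated `(sum O - sum E)^2 / sum V` is referred to a
#' chi-square distribution on 1 df.  No continuity correction is applied.
#'
#' @param records Clinical data frame.
#' @param groups Named character vector or factor (patient id -> group
#'   label) with exactly two levels, or a data frame with `patient_id` and
#'   `group` columns (e.g. from [split_by_score()]).
#' @return List with `chi_square` and `p_value`.
#' @export
logrank_test <- function(records, groups) {
  records <- validate_clinical(records)
  if (is.data.frame(groups))
    groups <- setNames(groups$group, groups$patient_id)
  groups <- groups[records$patient_id]
  if (anyNA(groups))
    stop("missing group label for patient(s): ",
         paste(head(records$patient_id[is.na(groups)], 5), collapse = ", "))
  lev <- sort(unique(as.character(groups)))
  if (length(lev) != 2) stop("exactly two groups required, got ",
                             length(lev))
  res <- logrank_core(records$time_days, records$event,
                      as.character(groups) == lev[1])
  list(chi_square = unname(res["chi_square"]),
       p_value = unname(res["p_value"]))
}

#' Score-stratified survival analysis
#'
#' Composes the full stratification chain: score each patient's tumor by
#' the signature (`sum` or `vote` method), split the cohort at the median
#' score, truncate follow-up to `limit_days`, estimate a Kaplan-Meier
#' curve per group, and compare groups by the log-rank test.  An optional
#' stage filter restricts the cohort first (e.g. `stage_filter = "I"` for
#' early-stage-only analyses).
#'
#' @param expr `tpm` [expression_matrix()], one column per patient tumor.
#' @param signature Signature to score by.
#' @param clinical Clinical data frame covering the scored patients.
#' @param method `"sum"` or `"vote"`.
#' @param limit_days Truncation horizon (default 1825).
#' @param stage_filter Optional stage label to keep.
#' @param log_transform Passed to [sum_score()].
#' @return List of class `SurvivalReport`: `cohort` (the split), `curves`
#'   (`high`/`low` [km_estimate()] curves), `n_high`, `n_low`,
#'   `chi_square`, `p_value`, `method`, `limit_days`.
#' @export
stratified_survival_report <- function(expr, signature, clinical,
                                       method = c("sum", "vote"),
                                       limit_days = 1825,
                                       stage_filter = NULL,
                                       log_transform = FALSE) {
  method <- match.arg(method)
  clinical <- validate_clinical(clinical)
  if (!is.null(stage_filter)) {
    clinical <- clinical[!is.na(clinical$stage) &
                           clinical$stage %in% stage_filter, ]
    if (!nrow(clinical)) stop("no patients left after stage filter")
  }
  unmatched <- setdiff(clinical$patient_id, colnames(expr))
  if (length(unmatched))
    stop("patient id(s) missing from expression matrix: ",
         paste(head(unmatched, 10), collapse = ", "))
  sub <- expr[, clinical$patient_id, drop = FALSE]
  scores <- if (method == "sum") sum_score(sub, signature, log_transform)
            else vote_score(sub, signature)
  cohort <- split_by_score(scores)
  clinical <- truncate_survival(clinical, limit_days)
  rec <- clinical[match(cohort$patient_id, clinical$patient_id), ]
  high <- rec[cohort$group == "high", ]
  low <- rec[cohort$group == "low", ]
  if (!nrow(high) || !nrow(low))
    stop("a group is empty after stratification")
  lr <- logrank_test(rec, setNames(cohort$group, cohort$patient_id))
  structure(list(cohort = cohort,
                 curves = list(high = km_estimate(high),
                               low = km_estimate(low)),
                 n_high = nrow(high), n_low = nrow(low),
                 chi_square = lr$chi_square, p_value = lr$p_value,
                 method = method, limit_days = limit_days),
            class = "SurvivalReport")
}

#' @export
print.SurvivalReport <- function(x, ...) {
  cat(sprintf("Stratified survival report (%s score, truncated %d d)\n",
              x$method, x$limit_days))
  cat(sprintf("  n_high = %d, n_low = %d\n", x$n_high, x$n_low))
  cat(sprintf("  log-rank chi-square = %.3f, p = %.4g\n",
              x$chi_square, x$p_value))
  invisible(x)
}
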