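#' Expression matrix with an explicit scale tag
#'
#' An `ExpressionMatrix` is a numeric genes x samples matrix carrying a scale
#' tag stating what its values mean: `"log2"` (log2 intensities or log2
#' abundances), `"tpm"` (transcripts per million, linear scale), or
#' `"rsem_fraction"` (RSEM transcript fractions, so each sample column sums to
#' at most 1).  Downstream operations check the tag instead of guessing, e.g.
#' [rsem_to_tpm()] refuses anything that is not tagged `rsem_fraction` and
#' [paired_differential()] requires `tpm`.
#'
#' @param values Numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids).  All values must be finite;
#'   missing values are a hard error because no downstream stage defines
#'   missing-data handling.
#' @param scale One of `"log2"`, `"tpm"`, `"rsem_fraction"`.
#' @return A numeric matrix of class `ExpressionMatrix` with a `scale`
#'   attribute.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expression_matrix(m, "log2")
#' @export
expression_matrix <- function(values,
                              scale = c("log2", "tpm", "rsem_fraction")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`values` must have rownames (gene ids) and colnames (sample ids)")
  gene_ids <- trimws(gene_ids)
  sample_ids <- trimws(sample_ids)
  if (any(gene_ids == "")) stop("empty gene id at row ",
                                which(gene_ids == "")[1])
  if (any(sample_ids == "")) stop("empty sample id at column ",
                                  which(sample_ids == "")[1])
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(head(dup_g, 5), collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(head(dup_s, 5), collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1]], sample_ids[bad[2]]))
  }
  if (scale == "tpm" && any(values < 0))
    stop("tpm-scale values must be non-negative")
  if (scale == "rsem_fraction") {
    if (any(values < 0)) stop("rsem_fraction values must be non-negative")
    cs <- colSums(values)
    if (any(cs > 1 + 1e-6))
      stop("rsem_fraction column sums exceed 1: sample '",
           sample_ids[which(cs > 1 + 1e-6)[1]], "'")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, scale = scale, class = c("ExpressionMatrix", "matrix"))
}

#' @export
`[.ExpressionMatrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod("[")
  if (is.matrix(out))
    out <- structure(out, scale = attr(x, "scale"),
                     class = c("ExpressionMatrix", "matrix"))
  out
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
expr_scale <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  attr(x, "scale")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  n <- min(nrow(x), 5L); m <- min(ncol(x), 5L)
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' Read / write a tab-separated expression matrix
#'
#' The on-disk layout is a TSV whose first column holds gene ids and whose
#' header row holds sample ids.  Files with samples as rows are handled by
#' `orientation = "samples"`, which transposes on load.  Lines starting with
#' `#` are treated as comments (generators use them to echo the seed).
#'
#' @param path File path.
#' @param scale Scale tag to attach, see [expression_matrix()].
#' @param orientation `"genes"` (default, genes as rows on disk) or
#'   `"samples"` (samples as rows on disk; transposed on load).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   scale = c("log2", "tpm", "rsem_fraction"),
                                   orientation = c("genes", "samples")) {
  scale <- match.arg(scale)
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2)
    stop("malformed header in '", path, "': need an id column plus >= 1 ",
         "data column")
  ids <- trimws(as.character(df[[1]]))
  num <- df[-1]
  for (cn in names(num)) {
    v <- suppressWarnings(as.numeric(num[[cn]]))
    bad <- which(is.na(v) & !is.na(num[[cn]]))
    if (length(bad))
      stop(sprintf("non-numeric cell in '%s': row id '%s', column '%s'",
                   path, ids[bad[1]], cn))
    if (anyNA(v))
      stop(sprintf("missing value in '%s': row id '%s', column '%s'",
                   path, ids[which(is.na(v))[1]], cn))
    num[[cn]] <- v
  }
  mat <- as.matrix(num)
  rownames(mat) <- ids
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate row id(s) in '", path, "': ",
         paste(head(dup, 5), collapse = ", "))
  if (orientation == "samples") mat <- t(mat)
  expression_matrix(mat, scale)
}

#' @rdname read_expression_matrix
#' @param x An `ExpressionMatrix` to write.
#' @param comment Optional character vector of comment lines (written with a
#'   leading `#`), used for seed provenance.
#' @export
write_expression_matrix <- function(x, path, comment = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- cbind(rownames(x),
                apply(unclass(x), 2, format, digits = 17, trim = TRUE))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
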