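#' Read and write GMT gene-set collections
#'
#' One set per line: `name TAB description TAB gene TAB gene ...`.  Genes are
#' deduplicated within a set preserving first-seen order; duplicate set names
#' across lines are an error.
#'
#' @param path File path.
#' @return A named list of character vectors, with a `descriptions`
#'   attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (length(f) < 3)
      stop(sprintf("GMT parse error at line %d of '%s': %d field(s), need >= 3",
                   i, path, length(f)))
    name <- f[1]
    if (name %in% names(sets))
      stop(sprintf("duplicate gene-set name '%s' at line %d of '%s'",
                   name, i, path))
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    sets[[name]] <- unique(genes)
    desc[name] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' @rdname read_gene_sets
#' @param sets Named list of character vectors.
#' @param descriptions Optional named character vector of descriptions.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction network (SIF or two-column edge list)
#'
#' Produces an undirected simple [igraph][igraph::graph_from_edgelist] graph.
#' Reciprocal duplicate edges are collapsed and self-loops dropped; counts of
#' both are reported via a message so no discarded line goes unlogged.
#'
#' @param path File path.
#' @param dialect `"edgelist"` (two tab-separated columns) or `"sif"`
#'   (`node relation node`, whitespace-separated).
#' @return An undirected simple `igraph` graph.
#' @export
read_network <- function(path, dialect = c("edgelist", "sif")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  pairs <- lapply(seq_along(lines), function(i) {
    f <- if (dialect == "sif") strsplit(trimws(lines[[i]]), "\\s+")[[1]]
         else trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (dialect == "sif") {
      if (length(f) < 3)
        stop(sprintf("SIF parse error at line %d of '%s'", i, path))
      f <- f[c(1, 3)]
    } else {
      if (length(f) < 2)
        stop(sprintf("edge-list parse error at line %d of '%s'", i, path))
      f <- f[1:2]
    }
    if (any(!nzchar(f)))
      stop(sprintf("blank node name at line %d of '%s'", i, path))
    f
  })
  el <- do.call(rbind, pairs)
  if (is.null(el)) stop("no edges in '", path, "'")
  loops <- el[, 1] == el[, 2]
  if (any(loops))
    log_msg("read_network", sum(loops), " self-loop(s) dropped")
  el <- el[!loops, , drop = FALSE]
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    log_msg("read_network", sum(dup), " duplicate edge(s) collapsed")
  el <- el[!dup, , drop = FALSE]
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  # nodes appearing only in dropped self-loops survive as isolated vertices
  seen <- unique(unlist(pairs, use.names = FALSE))
  g + igraph::vertices(setdiff(seen, igraph::V(g)$name))
}

#' @rdname read_network
#' @param graph An undirected `igraph` graph.
#' @param relation Relation label used for the SIF dialect (default `"pp"`).
#' @export
write_network <- function(graph, path, dialect = c("edgelist", "sif"),
                          relation = "pp") {
  dialect <- match.arg(dialect)
  el <- igraph::as_edgelist(graph)
  lines <- if (dialect == "sif")
    paste(el[, 1], relation, el[, 2], sep = "\t")
  else paste(el[, 1], el[, 2], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Clinical survival tables
#'
#' A clinical table is a data frame with columns `patient_id`, `time_days`
#' (non-negative), `event` (1 = death observed, 0 = censored) and an optional
#' `stage` label.  `validate_clinical()` enforces the invariants and is
#' called by every consumer.
#'
#' @param records Data frame to validate.
#' @return The validated data frame (invisibly for the writer).
#' @export
validate_clinical <- function(records) {
  need <- c("patient_id", "time_days", "event")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  records$patient_id <- as.character(records$patient_id)
  dup <- unique(records$patient_id[duplicated(records$patient_id)])
  if (length(dup))
    stop("duplicate patient id(s): ", paste(head(dup, 5), collapse = ", "))
  bad_t <- which(!is.finite(records$time_days) | records$time_days < 0)
  if (length(bad_t))
    stop("negative or missing time_days for patient '",
         records$patient_id[bad_t[1]], "'")
  bad_e <- which(!records$event %in% c(0, 1))
  if (length(bad_e))
    stop("event must be 0 or 1; offending patient '",
         records$patient_id[bad_e[1]], "'")
  records$time_days <- as.numeric(records$time_days)
  records$event <- as.integer(records$event)
  if (!"stage" %in% names(records))
    records$stage <- rep(NA_character_, nrow(records))
  records
}

#' @rdname validate_clinical
#' @param path File path of a TSV with columns `patient_id`, `time_days`,
#'   `event`, optional `stage`.
#' @export
read_clinical_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, comment.char = "#")
  validate_clinical(df)
}

#' @rdname validate_clinical
#' @export
write_clinical_table <- function(records, path) {
  records <- validate_clinical(records)
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ortholog / identifier mapping
#'
#' `read_gene_mapping()` loads a two-column TSV (`source_id TAB target_id`,
#' optional header detected by the literal names `source`/`target`); the
#' relation may be many-to-many.  `map_genes()` applies it: output order
#' follows input order, one-to-many mappings are expanded (with a warning),
#' duplicate targets are collapsed keeping the first occurrence, and inputs
#' with no mapping are reported separately rather than failing.
#'
#' @param path File path.
#' @return For `read_gene_mapping()`, a data frame with columns `source`,
#'   `target`.
#' @export
read_gene_mapping <- function(path) {
  df <- read.delim(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("mapping file '", path, "' needs two columns")
  df <- df[, 1:2]
  names(df) <- c("source", "target")
  if (identical(tolower(trimws(df$source[1])), "source"))
    df <- df[-1, , drop = FALSE]
  df$source <- trimws(df$source); df$target <- trimws(df$target)
  if (any(!nzchar(df$source)) || any(!nzchar(df$target)))
    stop("empty identifier in mapping file '", path, "'")
  df
}

#' @rdname read_gene_mapping
#' @param gene_ids Character vector of ids to map.
#' @param mapping Data frame with columns `source`, `target` (see
#'   `read_gene_mapping()`).
#' @return For `map_genes()`, a list with `mapped` (unique targets, input
#'   order preserved), `unmapped` (inputs with no target) and `n_expanded`
#'   (count of one-to-many inputs).
#' @export
map_genes <- function(gene_ids, mapping) {
  stopifnot(all(c("source", "target") %in% names(mapping)))
  gene_ids <- trimws(gene_ids)
  hits <- lapply(gene_ids, function(g) mapping$target[mapping$source == g])
  n_hit <- lengths(hits)
  if (any(n_hit > 1))
    warning(sum(n_hit > 1), " gene(s) with one-to-many mappings expanded")
  mapped <- as.character(unlist(hits[n_hit > 0], use.names = FALSE))
  if (anyDuplicated(mapped))
    log_msg("map_genes", sum(duplicated(mapped)),
            " duplicate target id(s) collapsed")
  list(mapped = unique(mapped),
       unmapped = gene_ids[n_hit == 0],
       n_expanded = sum(n_hit > 1))
}

#' @rdname read_gene_mapping
#' @param mapping_df Data frame with columns `source`, `target`.
#' @export
write_gene_mapping <- function(mapping_df, path) {
  write.table(mapping_df[, c("source", "target")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
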