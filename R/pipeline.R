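#' Pipeline configuration
#'
#' Collects every tunable the end-to-end run uses.  The defaults are the
#' analysis constants of the embodied study design: signature cutoff 0.41
#' log2 units, up-regulation thresholds logFC > 1 with FDR < 0.01 (with a
#' stricter logFC > 1.3 preset for microarray validation cohorts),
#' enrichment FDR 0.001, and survival truncation at 1825 days.  Simulation
#' parameters come from [simulation_spec()]; any field can be overridden.
#'
#' @param seed Global seed; every stage derives its own seed from it.
#' @param out_dir Output directory for stage files and the manifest.
#' @param signature_cutoff Log2 cutoff for signature selection.
#' @param de_logfc,de_fdr Up-regulation thresholds for the paired cohort.
#' @param enrich_fdr Significance threshold for gene-set enrichment.
#' @param truncate_days Survival truncation horizon.
#' @param strat_method `"sum"` or `"vote"`.
#' @param steiner_mode `"auto"`, `"exact"`, or `"heuristic"`.
#' @param map_fraction Fraction of simulated genes given a human ortholog.
#' @param universe_fraction Fraction of mapped ids present in the human
#'   expression universe.
#' @param sim Named list of overrides for [simulation_spec()].
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = tempfile("p52signet_run_"),
                            signature_cutoff = 0.41,
                            de_logfc = 1,
                            de_fdr = 0.01,
                            enrich_fdr = 0.001,
                            truncate_days = 1825,
                            strat_method = "sum",
                            steiner_mode = "auto",
                            map_fraction = 0.95,
                            universe_fraction = 0.97,
                            sim = list()) {
  for (v in c(signature_cutoff, de_logfc, de_fdr, enrich_fdr,
              truncate_days))
    if (v <= 0) stop("thresholds must be positive")
  spec <- do.call(simulation_spec, c(list(seed = seed), sim))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 signature_cutoff = signature_cutoff,
                 de_logfc = de_logfc, de_fdr = de_fdr,
                 enrich_fdr = enrich_fdr, truncate_days = truncate_days,
                 strat_method = strat_method, steiner_mode = steiner_mode,
                 map_fraction = map_fraction,
                 universe_fraction = universe_fraction,
                 spec = spec),
            class = "PipelineConfig")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys override [pipeline_config()] arguments
#'   (simulation overrides under a `sim:` block).
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

run_stage <- function(name, fn) {
  tryCatch(fn(), error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes every stage end to end on generated data: simulate the
#' two-factor experiment, derive the p52 signature (through an ortholog
#' map and a human universe), simulate the matched tumor/normal cohort,
#' convert RSEM fractions to TPM, run paired differential expression, call
#' up-regulated genes and compute the over-representation report, run
#' gene-set enrichment against generated sets, extract the Steiner
#' subnetwork of up-regulated signature genes from a simulated interactome
#' with its imputed mediators, stratify a simulated survival cohort by the
#' signature (and by the imputed genes alone), and cluster the cohort on
#' the signature.  All stage outputs are written as TSV/GMT/JSON files in
#' `config$out_dir`; a JSON manifest records the seed, thresholds, and
#' per-stage counts, and is returned invisibly.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  spec <- config$spec
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(package = "p52signet",
                   version = as.character(packageVersion("p52signet")),
                   seed = config$seed,
                   thresholds = config[c("signature_cutoff", "de_logfc",
                                         "de_fdr", "enrich_fdr",
                                         "truncate_days")])

  # -- stage 1: two-factor experiment and signature derivation
  sig <- NULL; mapping <- NULL; universe <- NULL; planted_mouse <- NULL
  run_stage("signature", function() {
    tf <- simulate_two_factor_experiment(spec)
    planted_mouse <<- tf$planted
    write_expression_matrix(tf$expr, out("two_factor_expr.tsv"),
                            comment = paste("seed", spec$seed))
    write.table(tf$annotation, out("two_factor_annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    fit <- fit_two_factor_model(tf$expr, tf$annotation)
    write.table(fit, out("two_factor_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    genes <- rownames(tf$expr)
    mapping <<- withr::with_seed(spec$seed + 606L, {
      src <- sort(sample(genes, round(config$map_fraction * length(genes))))
      data.frame(source = src, target = toupper(src),
                 stringsAsFactors = FALSE)
    })
    universe <<- withr::with_seed(spec$seed + 707L,
      sort(sample(mapping$target,
                  round(config$universe_fraction * nrow(mapping)))))
    write_gene_mapping(mapping, out("ortholog_map.tsv"))
    sig <<- select_signature(fit, config$signature_cutoff, mapping,
                             universe)
    writeLines(sig$gene_ids, out("signature_genes.txt"))
    manifest$signature <<- c(
      sig$provenance[c("cutoff", "linear_fold_change", "n_input",
                       "n_positive", "n_pass_cutoff",
                       "n_dropped_no_homolog",
                       "n_dropped_not_in_universe", "n_selected")],
      list(n_planted = length(planted_mouse)))
  })

  # -- stage 2: paired cohort, differential expression, over-representation
  up <- NULL; de <- NULL; cohort <- NULL; tpm <- NULL
  run_stage("diffexp", function() {
    cohort <<- simulate_paired_cohort(spec, sig, universe = universe,
                                      scale = "rsem_fraction")
    tpm <<- rsem_to_tpm(cohort$expr)
    de <<- paired_differential(tpm, cohort$annotation)
    write.table(de, out("paired_differential.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    up <<- call_upregulated(de, config$de_logfc, config$de_fdr)
    writeLines(up, out("upregulated_genes.txt"))
    rep <- signature_overlap_report(nrow(tpm), length(up),
                                    length(sig$gene_ids),
                                    length(intersect(up, sig$gene_ids)))
    manifest$diffexp <<- rep
  })

  # -- stage 3: gene-set enrichment on generated sets
  run_stage("enrichment", function() {
    sets <- withr::with_seed(spec$seed + 808L, {
      filler <- lapply(1:19, function(i)
        sample(universe, sample(50:400, 1)))
      names(filler) <- sprintf("RANDOM_SET_%02d", 1:19)
      c(list(CELL_CYCLE_LIKE = unique(c(
          sample(sig$gene_ids, ceiling(length(sig$gene_ids) * 0.6)),
          sample(universe, 60)))),
        filler)
    })
    write_gene_sets(sets, out("gene_sets.gmt"))
    enr <- gene_set_enrichment(sig$gene_ids, universe, sets,
                               config$enrich_fdr)
    write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$enrichment <<- list(n_sets = length(sets),
                                 n_significant = sum(enr$significant),
                                 top_term = enr$term_id[1])
  })

  # -- stage 4: Steiner subnetwork of up-regulated signature genes
  imputed <- NULL
  run_stage("steiner", function() {
    terminals <- intersect(sig$gene_ids, up)
    if (length(terminals) < 2)
      stop("fewer than two up-regulated signature genes to connect")
    net <- simulate_interactome(spec, terminals = terminals)
    write_network(net, out("interactome.sif"), dialect = "sif")
    sol <- steiner_tree(net, terminals, mode = config$steiner_mode)
    write_network(igraph::graph_from_edgelist(sol$tree_edges,
                                              directed = FALSE),
                  out("steiner_tree.sif"), dialect = "sif")
    imputed <<- extract_imputed(sol)
    node_tab <- data.frame(node = sol$tree_nodes,
                           is_terminal = sol$tree_nodes %in% sol$terminals,
                           is_imputed = sol$tree_nodes %in% imputed)
    write.table(node_tab, out("steiner_nodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$steiner <<- list(n_terminals = length(sol$terminals),
                              n_imputed = length(imputed),
                              cost = sol$cost, method = sol$method,
                              n_dropped = length(sol$dropped_terminals))
  })

  # -- stage 5: survival stratification (signature and imputed mediators)
  run_stage("survival", function() {
    surv_genes <- unique(c(universe, imputed))
    sexpr <- simulate_cohort_expression(spec, surv_genes)
    clinical <- simulate_survival_cohort(sexpr, sig, spec)
    write_clinical_table(clinical, out("clinical.tsv"))
    rep_sig <- stratified_survival_report(sexpr, sig, clinical,
                                          method = config$strat_method,
                                          limit_days = config$truncate_days)
    rep_vote <- stratified_survival_report(sexpr, sig, clinical,
                                           method = "vote",
                                           limit_days = config$truncate_days)
    rep_stage1 <- stratified_survival_report(sexpr, sig, clinical,
                                             method = config$strat_method,
                                             limit_days = config$truncate_days,
                                             stage_filter = "I")
    man <- list(n = nrow(clinical), n_events = sum(clinical$event),
                chi_square = rep_sig$chi_square, p_value = rep_sig$p_value,
                p_value_vote = rep_vote$p_value,
                p_value_stage1 = rep_stage1$p_value)
    if (length(imputed) >= 1) {
      rep_imp <- stratified_survival_report(sexpr, imputed, clinical,
                                            method = config$strat_method,
                                            limit_days = config$truncate_days)
      man$p_value_imputed <- rep_imp$p_value
    }
    for (nm in c("high", "low")) {
      cv <- rep_sig$curves[[nm]]
      write.table(cv, out(sprintf("km_curve_%s.tsv", nm)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    write.table(rep_sig$cohort, out("stratification.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$survival <<- man
  })

  # -- stage 6: clustering of the paired cohort on the signature
  run_stage("clustering", function() {
    cl <- hierarchical_cluster(tpm, sig)
    classes <- setNames(cohort$annotation$tissue_class,
                        cohort$annotation$sample_id)
    assoc <- cluster_class_association(cl, classes)
    write.table(data.frame(sample_id = names(cl$assignment),
                           cluster = cl$assignment,
                           tissue_class = classes[names(cl$assignment)]),
                out("clusters.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest$clustering <<- list(
      n_samples = length(cl$assignment),
      table = as.vector(table(cl$assignment,
                              classes[names(cl$assignment)])),
      p_value = assoc$p_value)
  })

  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("pipeline", "complete; outputs in ", config$out_dir)
  invisible(manifest)
}
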