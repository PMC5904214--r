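#' Simulation specification
#'
#' Bundles every parameter the synthetic-data generators use, with defaults
#' fixed to the conditions of the study design this package emulates: an
#' eight-sample 2x2 (p52 x LPS) factorial with two replicates per cell,
#' a 54-pair matched tumor/normal cohort, a 437-patient survival cohort
#' truncated at five years, and a connected scale-free interactome of
#' 9,218 nodes with ~36.9k edges (preferential attachment, m = 4).
#'
#' All generators are pure functions of `(spec, seed)`: per-stage seeds are
#' derived from `spec$seed` by fixed offsets (two-factor +101, paired cohort
#' +202, survival +303, interactome +404, cohort expression +505), echoed in
#' the log, so reruns are bit-identical and stages are independent.
#'
#' @param seed Integer global seed.
#' @param n_genes Number of genes in the simulated universe.
#' @param n_planted Number of genes given a p52 (or tumor) effect.
#' @param planted_logfc Planted effect size, log2 units.
#' @param noise_sd Residual standard deviation, log2 units.
#' @param baseline_mean,baseline_sd Gene baseline log2 abundance distribution.
#' @param n_pairs Number of matched tumor/normal pairs.
#' @param signature_fraction Fraction of signature genes planted up-regulated
#'   in tumors (default 0.5, the order of the 35/71 observed in lung
#'   adenocarcinoma).
#' @param background_fraction Fraction of non-signature genes planted
#'   up-regulated (default 0.062, a typical global up-regulation rate).
#' @param pair_sd SD of the per-pair Gaussian random intercept (log2 units);
#'   this is what makes the paired t-test genuinely more powerful than an
#'   unpaired one.
#' @param hazard_log_hr Log hazard ratio per unit standardized signature
#'   score.
#' @param baseline_hazard Baseline hazard, events/day.
#' @param censor_time_max Administrative censoring horizon, days; censoring
#'   times are Uniform(0, `censor_time_max`).
#' @param n_survival Patients in the survival cohort.
#' @param network_nodes,edges_per_new_node Interactome size and preferential
#'   attachment parameter m (m = 1 yields a tree).
#' @return A validated list of class `SimulationSpec`.
#' @export
simulation_spec <- function(seed = 1L,
                            n_genes = 2000L,
                            n_planted = 100L,
                            planted_logfc = 1.5,
                            noise_sd = 0.5,
                            baseline_mean = 6,
                            baseline_sd = 1.5,
                            n_pairs = 54L,
                            signature_fraction = 0.5,
                            background_fraction = 0.062,
                            pair_sd = 0.5,
                            hazard_log_hr = 0.7,
                            baseline_hazard = 1 / 1500,
                            censor_time_max = 3650,
                            n_survival = 437L,
                            network_nodes = 9218L,
                            edges_per_new_node = 4L) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_planted = as.integer(n_planted),
               planted_logfc = planted_logfc, noise_sd = noise_sd,
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               n_pairs = as.integer(n_pairs),
               signature_fraction = signature_fraction,
               background_fraction = background_fraction, pair_sd = pair_sd,
               hazard_log_hr = hazard_log_hr,
               baseline_hazard = baseline_hazard,
               censor_time_max = censor_time_max,
               n_survival = as.integer(n_survival),
               network_nodes = as.integer(network_nodes),
               edges_per_new_node = as.integer(edges_per_new_node))
  counts <- c("n_genes", "n_planted", "n_pairs", "n_survival",
              "network_nodes", "edges_per_new_node")
  for (f in counts)
    if (spec[[f]] <= 0) stop("`", f, "` must be positive")
  if (spec$noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (spec$n_planted > spec$n_genes)
    stop("`n_planted` exceeds `n_genes`")
  if (spec$censor_time_max < 0) stop("`censor_time_max` must be >= 0")
  if (spec$signature_fraction < 0 || spec$signature_fraction > 1 ||
      spec$background_fraction < 0 || spec$background_fraction > 1)
    stop("planted fractions must lie in [0, 1]")
  structure(spec, class = "SimulationSpec")
}

mouse_gene_ids <- function(n) sprintf("mgene%05d", seq_len(n))
human_gene_ids <- function(n) sprintf("HGENE%05d", seq_len(n))

#' Simulate the two-factor (p52 x LPS) expression experiment
#'
#' Eight samples in a 2x2 design with two replicates per cell, Gaussian on
#' the log2 scale (the microarray/RMA input boundary).  Each gene follows
#' `baseline + beta_p52 * p52 + beta_lps * lps + N(0, noise_sd)`.  Planted
#' genes get `beta_p52 = planted_logfc`; a disjoint random subset of equal
#' size gets a nonzero `beta_lps`, so the two factors are separable.
#'
#' @param spec A [simulation_spec()].
#' @return List with `expr` (log2 [expression_matrix()]), `annotation`
#'   (data frame: `sample_id`, `p52`, `lps`), and `planted` (gene ids with
#'   the p52 effect).
#' @export
simulate_two_factor_experiment <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (spec$n_planted * 2 > spec$n_genes)
    stop("need n_genes >= 2 * n_planted for disjoint p52/LPS gene subsets")
  genes <- mouse_gene_ids(spec$n_genes)
  ann <- data.frame(
    sample_id = c("WT_dox_1", "WT_dox_2", "WT_lps_1", "WT_lps_2",
                  "p52_dox_1", "p52_dox_2", "p52_lps_1", "p52_lps_2"),
    p52 = c(0, 0, 0, 0, 1, 1, 1, 1),
    lps = c(0, 0, 1, 1, 0, 0, 1, 1),
    stringsAsFactors = FALSE)
  withr::with_seed(spec$seed + 101L, {
    planted <- sort(sample(genes, spec$n_planted))
    lps_genes <- sort(sample(setdiff(genes, planted), spec$n_planted))
    baseline <- rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
    b_p52 <- ifelse(genes %in% planted, spec$planted_logfc, 0)
    b_lps <- ifelse(genes %in% lps_genes, spec$planted_logfc, 0)
    mu <- outer(baseline, rep(1, 8)) +
      outer(b_p52, ann$p52) + outer(b_lps, ann$lps)
    vals <- mu + matrix(rnorm(length(mu), 0, spec$noise_sd), nrow(mu))
  })
  dimnames(vals) <- list(genes, ann$sample_id)
  log_msg("simulate_two_factor", "seed=", spec$seed + 101L,
          " genes=", spec$n_genes, " planted=", spec$n_planted)
  list(expr = expression_matrix(vals, "log2"), annotation = ann,
       planted = planted)
}

#' Simulate a matched tumor/normal cohort
#'
#' Log2 expression is Gaussian per gene with a per-pair random intercept
#' (paired structure); a configurable fraction of signature genes and a
#' background fraction of other genes receive a tumor log2 fold change of
#' `planted_logfc`.  Values are exponentiated to a TPM-like linear scale;
#' with `scale = "rsem_fraction"` each column is further normalized to sum
#' to 1 (compositional, so realized fold changes shrink slightly).
#'
#' @param spec A [simulation_spec()].
#' @param signature Character vector of signature gene ids (or a
#'   `GeneSignature`).
#' @param universe Optional gene universe; defaults to the signature plus
#'   generated filler ids up to `spec$n_genes`.  Signature genes absent from
#'   a supplied universe are an error.
#' @param scale `"tpm"` (default) or `"rsem_fraction"`.
#' @return List with `expr`, `annotation` (columns `sample_id`,
#'   `tissue_class`, `pair_id`) and `planted` (gene ids given the tumor
#'   effect).
#' @export
simulate_paired_cohort <- function(spec, signature, universe = NULL,
                                   scale = c("tpm", "rsem_fraction")) {
  stopifnot(inherits(spec, "SimulationSpec"))
  scale <- match.arg(scale)
  sig <- signature_genes(signature)
  if (is.null(universe)) {
    n_fill <- spec$n_genes - length(sig)
    if (n_fill < 0) stop("signature larger than `n_genes`")
    universe <- c(sig, setdiff(human_gene_ids(spec$n_genes), sig)[seq_len(n_fill)])
  } else if (!all(sig %in% universe)) {
    stop("signature gene(s) absent from universe: ",
         paste(head(setdiff(sig, universe), 5), collapse = ", "))
  }
  genes <- universe
  n <- spec$n_pairs
  withr::with_seed(spec$seed + 202L, {
    n_sig_up <- round(spec$signature_fraction * length(sig))
    sig_up <- sort(sample(sig, n_sig_up))
    others <- setdiff(genes, sig)
    bg_up <- sort(sample(others, round(spec$background_fraction *
                                         length(others))))
    planted <- sort(c(sig_up, bg_up))
    baseline <- rnorm(length(genes), spec$baseline_mean, spec$baseline_sd)
    pair_int <- matrix(rnorm(length(genes) * n, 0, spec$pair_sd),
                       length(genes), n)
    eff <- ifelse(genes %in% planted, spec$planted_logfc, 0)
    normal <- baseline + pair_int +
      matrix(rnorm(length(genes) * n, 0, spec$noise_sd), length(genes), n)
    tumor <- baseline + pair_int + eff +
      matrix(rnorm(length(genes) * n, 0, spec$noise_sd), length(genes), n)
  })
  pair_ids <- sprintf("PT%03d", seq_len(n))
  vals <- cbind(2^tumor, 2^normal)
  dimnames(vals) <- list(genes, c(paste0(pair_ids, "_T"),
                                  paste0(pair_ids, "_N")))
  if (scale == "rsem_fraction")
    vals <- sweep(vals, 2, colSums(vals), "/")
  ann <- data.frame(
    sample_id = colnames(vals),
    tissue_class = rep(c("tumor", "normal"), each = n),
    pair_id = rep(pair_ids, 2),
    stringsAsFactors = FALSE)
  log_msg("simulate_paired_cohort", "seed=", spec$seed + 202L,
          " pairs=", n, " planted=", length(planted))
  list(expr = expression_matrix(vals, scale), annotation = ann,
       planted = planted)
}

#' Simulate tumor-cohort expression (no paired structure)
#'
#' Convenience generator for survival analyses: log2 expression
#' `baseline + N(0, noise_sd)` per gene and patient, exponentiated to TPM.
#'
#' @param spec A [simulation_spec()].
#' @param gene_ids Genes to simulate (e.g. a signature plus filler).
#' @param n_samples Number of patients (default `spec$n_survival`).
#' @return A `tpm` [expression_matrix()] with patient ids `S0001`, ...
#' @export
simulate_cohort_expression <- function(spec, gene_ids,
                                       n_samples = spec$n_survival) {
  stopifnot(inherits(spec, "SimulationSpec"))
  gene_ids <- unique(gene_ids)
  withr::with_seed(spec$seed + 505L, {
    baseline <- rnorm(length(gene_ids), spec$baseline_mean, spec$baseline_sd)
    vals <- baseline + matrix(rnorm(length(gene_ids) * n_samples, 0,
                                    spec$noise_sd),
                              length(gene_ids), n_samples)
  })
  vals <- 2^vals
  dimnames(vals) <- list(gene_ids, sprintf("S%04d", seq_len(n_samples)))
  expression_matrix(vals, "tpm")
}

#' Simulate a survival cohort whose hazard tracks a signature score
#'
#' Each patient's signature sum-score is standardized to `z`; the event time
#' is Exponential with rate `baseline_hazard * exp(hazard_log_hr * z)`
#' (an exponential proportional-hazards model), censoring is
#' Uniform(0, `censor_time_max`), and the recorded time is the minimum with
#' `event = 1` when death comes first.  Stage labels are drawn with
#' probabilities (0.69, 0.155, 0.155) for I/II/III, the early-stage-heavy
#' mix typical of resected lung adenocarcinoma series.
#'
#' @param expr `tpm` [expression_matrix()] of tumor samples (one per
#'   patient).
#' @param signature Signature used for the score (character vector or
#'   `GeneSignature`); all its genes must be present in `expr`.
#' @param spec A [simulation_spec()].
#' @return A clinical data frame (`patient_id`, `time_days`, `event`,
#'   `stage`), see [validate_clinical()].
#' @export
simulate_survival_cohort <- function(expr, signature, spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  if (spec$baseline_hazard <= 0) stop("`baseline_hazard` must be positive")
  score <- sum_score(expr, signature)
  z <- as.numeric(scale(score))
  if (any(!is.finite(z))) z <- rep(0, length(score))  # constant scores
  rate <- spec$baseline_hazard * exp(spec$hazard_log_hr * z)
  withr::with_seed(spec$seed + 303L, {
    t_event <- rexp(length(rate), rate)
    t_cens <- runif(length(rate), 0, spec$censor_time_max)
    stage <- sample(c("I", "II", "III"), length(rate), replace = TRUE,
                    prob = c(0.69, 0.155, 0.155))
  })
  time <- pmin(t_event, t_cens)
  rec <- data.frame(patient_id = colnames(expr),
                    time_days = round(time),
                    event = as.integer(t_event <= t_cens),
                    stage = stage,
                    stringsAsFactors = FALSE)
  log_msg("simulate_survival", "seed=", spec$seed + 303L,
          " n=", nrow(rec), " events=", sum(rec$event))
  validate_clinical(rec)
}

#' Simulate a connected scale-free interactome
#'
#' Grows a preferential-attachment (Barabasi-Albert) graph: each new node
#' attaches to `edges_per_new_node` existing nodes with probability
#' proportional to degree, which guarantees connectivity and yields the
#' heavy-tailed degree distribution characteristic of protein-interaction
#' networks.  Requested terminal labels are assigned to nodes drawn at
#' random; remaining nodes get generic `st#####` labels.
#'
#' @param spec A [simulation_spec()].
#' @param terminals Optional character vector of node labels to embed.
#' @return An undirected simple connected `igraph` graph.
#' @export
simulate_interactome <- function(spec, terminals = NULL) {
  stopifnot(inherits(spec, "SimulationSpec"))
  n <- spec$network_nodes
  if (!is.null(terminals) && n < length(terminals) + 2)
    stop("`network_nodes` must be >= length(terminals) + 2")
  withr::with_seed(spec$seed + 404L, {
    g <- igraph::sample_pa(n, m = spec$edges_per_new_node, directed = FALSE)
    labels <- sprintf("st%05d", seq_len(n))
    if (!is.null(terminals)) {
      slots <- sample(n, length(terminals))
      labels[slots] <- terminals
    }
  })
  g <- igraph::simplify(g)
  igraph::V(g)$name <- labels
  stopifnot(igraph::is_connected(g))
  log_msg("simulate_interactome", "seed=", spec$seed + 404L, " nodes=", n,
          " edges=", igraph::ecount(g))
  g
}
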