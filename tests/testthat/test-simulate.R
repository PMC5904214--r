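test_that("simulation specs validate their parameters", {
  expect_error(simulation_spec(n_planted = 0), "positive")
  expect_error(simulation_spec(n_planted = 50, n_genes = 40), "exceeds")
  expect_error(simulation_spec(noise_sd = 0), "noise_sd")
  expect_error(simulation_spec(signature_fraction = 1.5), "fractions")
})

test_that("generators are pure functions of (spec, seed)", {
  spec <- simulation_spec(seed = 4, n_genes = 200, n_planted = 20,
                          n_pairs = 10, n_survival = 50,
                          network_nodes = 60, edges_per_new_node = 2)
  a <- simulate_two_factor_experiment(spec)
  b <- simulate_two_factor_experiment(spec)
  expect_identical(a, b)
  pa <- simulate_paired_cohort(spec, a$planted[1:10])
  pb <- simulate_paired_cohort(spec, a$planted[1:10])
  expect_identical(pa, pb)
  ga <- simulate_interactome(spec)
  gb <- simulate_interactome(spec)
  expect_identical(igraph::as_edgelist(ga), igraph::as_edgelist(gb))
  ex <- simulate_cohort_expression(spec, sprintf("G%02d", 1:30), 50)
  ca <- simulate_survival_cohort(ex, sprintf("G%02d", 1:5), spec)
  cb <- simulate_survival_cohort(ex, sprintf("G%02d", 1:5), spec)
  expect_identical(ca, cb)
  # a different seed changes the data
  spec2 <- simulation_spec(seed = 5, n_genes = 200, n_planted = 20)
  expect_false(identical(unclass(simulate_two_factor_experiment(spec2)$expr),
                         unclass(a$expr)))
})

test_that("two-factor generator plants the requested p52 effect", {
  # zero-noise limit: planted genes differ by exactly planted_logfc
  spec0 <- simulation_spec(seed = 2, n_genes = 60, n_planted = 10,
                           planted_logfc = 1, noise_sd = 1e-12)
  tf0 <- simulate_two_factor_experiment(spec0)
  v <- unclass(tf0$expr)
  p52_cols <- tf0$annotation$sample_id[tf0$annotation$p52 == 1]
  wt_cols <- tf0$annotation$sample_id[tf0$annotation$p52 == 0]
  gap <- rowMeans(v[, p52_cols]) - rowMeans(v[, wt_cols])
  expect_equal(unname(gap[tf0$planted]), rep(1, 10), tolerance = 1e-9)
  un_planted <- setdiff(rownames(v), tf0$planted)
  expect_equal(max(abs(gap[un_planted])), 0, tolerance = 1e-9)

  # Monte-Carlo: mean estimated p52 coefficient over planted genes
  spec <- simulation_spec(seed = 1, n_genes = 2000, n_planted = 100,
                          planted_logfc = 1.5, noise_sd = 0.5)
  tf <- simulate_two_factor_experiment(spec)
  fit <- fit_two_factor_model(tf$expr, tf$annotation)
  mean_coef <- mean(fit$coef_p52[fit$gene_id %in% tf$planted])
  expect_lt(abs(mean_coef - 1.5), 0.05)
})

test_that("paired-cohort generator is calibrated under the null", {
  spec <- simulation_spec(seed = 7, n_genes = 2000, n_pairs = 20,
                          signature_fraction = 0, background_fraction = 0)
  pc <- simulate_paired_cohort(spec, sprintf("HGENE%05d", 1:50))
  expect_identical(pc$planted, character(0))
  de <- paired_differential(pc$expr, pc$annotation)
  alpha <- 0.05
  frac <- mean(de$p_value < alpha)
  band <- 3 * sqrt(alpha * (1 - alpha) / nrow(de))
  expect_lt(abs(frac - alpha), band)
})

test_that("paired-cohort generator saturates and respects its universe", {
  sig <- sprintf("HGENE%05d", 1:30)
  spec <- simulation_spec(seed = 3, n_genes = 300, n_pairs = 10,
                          signature_fraction = 1, background_fraction = 0,
                          planted_logfc = 6, noise_sd = 0.05,
                          pair_sd = 0.05)
  pc <- simulate_paired_cohort(spec, sig)
  de <- paired_differential(pc$expr, pc$annotation)
  up <- call_upregulated(de, 1, 0.01)
  expect_true(all(sig %in% up))
  expect_error(simulate_paired_cohort(spec, sig, universe = c("A", "B")),
               "absent from universe")
})

test_that("survival generator has the stated degenerate and null limits", {
  spec <- simulation_spec(seed = 11, censor_time_max = 1e-9,
                          n_survival = 30)
  ex <- simulate_cohort_expression(spec, sprintf("G%02d", 1:10), 30)
  rec <- simulate_survival_cohort(ex, sprintf("G%02d", 1:10), spec)
  expect_true(all(rec$event == 0L))
  expect_true(all(rec$time_days == 0))

  expect_error(
    simulate_survival_cohort(ex, sprintf("G%02d", 1:10),
                             simulation_spec(baseline_hazard = 0)),
    "baseline_hazard")

  # null: log-rank on an arbitrary fixed split rejects at ~ the nominal rate
  null_spec <- function(s)
    simulation_spec(seed = s, hazard_log_hr = 0, n_survival = 60,
                    censor_time_max = 3650)
  reps <- 400
  grp <- rep(c("a", "b"), each = 30)
  ex2 <- simulate_cohort_expression(null_spec(1), sprintf("G%02d", 1:10), 60)
  rej <- vapply(seq_len(reps), function(i) {
    rec <- simulate_survival_cohort(ex2, sprintf("G%02d", 1:10),
                                    null_spec(1000 + i))
    logrank_test(rec, setNames(grp, rec$patient_id))$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("interactome generator yields connected scale-free graphs", {
  spec1 <- simulation_spec(seed = 6, network_nodes = 80,
                           edges_per_new_node = 1)
  g1 <- simulate_interactome(spec1)
  expect_equal(igraph::ecount(g1), 79)           # m = 1 gives a tree
  expect_true(igraph::is_connected(g1))

  spec4 <- simulation_spec(seed = 3, network_nodes = 1000,
                           edges_per_new_node = 4)
  g4 <- simulate_interactome(spec4)
  expect_true(igraph::is_connected(g4))
  deg <- igraph::degree(g4)
  expect_gt(max(deg), 10 * median(deg))          # heavy tail

  terms <- sprintf("TERM%02d", 1:5)
  gt <- simulate_interactome(spec4, terminals = terms)
  expect_true(all(terms %in% igraph::V(gt)$name))
  expect_error(simulate_interactome(
    simulation_spec(network_nodes = 4), terminals = sprintf("T%d", 1:3)),
    "network_nodes")
})
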