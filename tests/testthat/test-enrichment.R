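test_that("hypergeometric upper tail matches enumeration and phyper", {
  expect_equal(hypergeom_overrep(10, 5, 4, 0), 1)
  expect_equal(hypergeom_overrep(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  withr::with_seed(31, {
    for (i in 1:50) {
      N <- sample(5:200, 1)
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      x <- sample(max(0, n + K - N):min(K, n), 1)
      mine <- hypergeom_overrep(N, K, n, x)
      expect_equal(mine, enum_hyper_upper(N, K, n, x), tolerance = 1e-10)
      expect_equal(mine,
                   phyper(x - 1, K, N - K, n, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  })
  expect_error(hypergeom_overrep(10, 12, 4, 1), "inconsistent")
})

test_that("hypergeometric pmf sums to one and tails stay exact at 1e-300", {
  withr::with_seed(7, {
    for (i in 1:20) {
      N <- sample(10:300, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
      lo <- max(0, n + K - N)
      expect_equal(hypergeom_overrep(N, K, n, lo), 1, tolerance = 1e-12)
      xs <- lo:min(K, n)
      total <- sum(exp(p52signet:::log_hyper_pmf(xs, N, K, n)))
      expect_equal(total, 1, tolerance = 1e-12)
    }
  })
  # deep tail without underflow (log-gamma route)
  p <- hypergeom_overrep(40000, 20000, 600, 590)
  expect_gt(p, 0)
  expect_lt(p, 1e-100)
})

test_that("Fisher exact matches enumeration and stats::fisher.test", {
  expect_equal(fisher_exact_2x2(c(1, 1, 1, 1), "two"), 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2, byrow = TRUE),
                                "two"), 0.1, tolerance = 1e-12)
  withr::with_seed(41, {
    for (i in 1:40) {
      tab <- matrix(rpois(4, 8), 2)
      mine_g <- fisher_exact_2x2(tab, "greater")
      mine_t <- fisher_exact_2x2(tab, "two")
      expect_equal(mine_g, enum_fisher(tab[1, 1], tab[1, 2], tab[2, 1],
                                       tab[2, 2], "greater"),
                   tolerance = 1e-10)
      if (sum(tab) > 0 && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        expect_equal(mine_g,
                     fisher.test(tab, alternative = "greater")$p.value,
                     tolerance = 1e-8)
        expect_equal(mine_t, fisher.test(tab)$p.value, tolerance = 1e-8)
      }
    }
  })
  expect_error(fisher_exact_2x2(c(0, 0, 0, 0)), "zero")
})

test_that("exact tests on the printed cohort counts agree with the stats
           oracles (documented discrepancy with the printed values)", {
  # 20,501 genes / 1,274 up / 71 signature / 35 up among them
  p_tcga <- hypergeom_overrep(20501, 1274, 71, 35)
  expect_equal(p_tcga, phyper(34, 1274, 20501 - 1274, 71,
                              lower.tail = FALSE), tolerance = 1e-10)
  # 22,216 / 9,832 / 71 / 54
  tab <- matrix(c(54, 17, 9832 - 54, 22216 - 71 - (9832 - 54)), 2,
                byrow = TRUE)
  p_battle <- fisher_exact_2x2(tab, "greater")
  expect_equal(p_battle,
               fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-8)
  # recomputed values (frozen from the stats oracles), which differ from
  # the published prints of 6.0e-25 and 0.0034 respectively
  expect_equal(p_tcga, 9.40289e-24, tolerance = 1e-5)
  expect_equal(p_battle, 4.811908e-08, tolerance = 1e-5)
})

test_that("gene-set enrichment computes expected counts and orderings", {
  universe <- sprintf("G%04d", 1:1000)
  sets <- list(big = universe[1:50], tiny = universe[900:905])
  query <- universe[1:20]
  enr <- gene_set_enrichment(query, universe, sets, fdr_threshold = 0.001)
  big <- enr[enr$term_id == "big", ]
  expect_equal(big$expected_count, 20 * 50 / 1000)  # = 1.0
  expect_equal(big$observed_count, 20)
  expect_identical(enr$term_id[1], "big")           # sorted by p

  # the expected-count convention back-solves a realistic genome universe
  expect_equal(71 * 230 / 16663, 0.98, tolerance = 1e-3)

  # query equal to a set attains that set's minimal possible p
  q2 <- sets$tiny
  enr2 <- gene_set_enrichment(q2, universe, sets)
  tiny <- enr2[enr2$term_id == "tiny", ]
  expect_equal(tiny$observed_count, 6)
  expect_equal(tiny$p_value,
               enum_hyper_upper(1000, 6, 6, 6), tolerance = 1e-12)
  expect_error(gene_set_enrichment(c(query, "ZZZ"), universe, sets),
               "outside the universe")
  expect_error(gene_set_enrichment(query, character(), sets), "non-empty")
})

test_that("DAG pruning keeps only most-specific significant terms", {
  rec <- data.frame(term_id = c("A", "B", "C"),
                    reference_set_size = 10, expected_count = 1,
                    observed_count = 5, p_value = c(1e-5, 1e-4, 0.5),
                    fdr = c(1e-4, 1e-3, 0.5),
                    significant = c(TRUE, TRUE, FALSE))
  dag <- data.frame(child = "A", parent = "B")   # B is an ancestor of A
  pruned <- prune_to_specific(rec, dag)
  expect_identical(pruned$term_id, c("A", "C"))

  # unrelated significant terms are all kept
  dag2 <- data.frame(child = "X", parent = "Y")
  expect_identical(prune_to_specific(rec, dag2)$term_id, rec$term_id)

  # cycles are refused
  dag3 <- data.frame(child = c("A", "B"), parent = c("B", "A"))
  expect_error(prune_to_specific(rec, dag3), "cycle")
})

test_that("DAG pruning agrees with a brute-force reachability oracle", {
  withr::with_seed(19, {
    for (rep in 1:5) {
      n <- 30
      terms <- sprintf("T%02d", 1:n)
      # random DAG respecting index order (child -> higher-index parent)
      edges <- do.call(rbind, lapply(1:n, function(i) {
        ps <- which(seq_len(n) > i)
        if (!length(ps)) return(NULL)
        k <- sample(0:min(3, length(ps)), 1)
        if (k == 0) return(NULL)
        data.frame(child = terms[i],
                   parent = terms[ps[sample.int(length(ps), k)]])
      }))
      sig <- sample(c(TRUE, FALSE), n, replace = TRUE)
      rec <- data.frame(term_id = terms, reference_set_size = 5,
                        expected_count = 1, observed_count = 2,
                        p_value = runif(n), fdr = runif(n),
                        significant = sig)
      pruned <- prune_to_specific(rec, edges)
      # oracle: transitive reachability by repeated edge joins
      reach <- unique(edges[c("child", "parent")])
      repeat {
        joined <- merge(reach, edges, by.x = "parent", by.y = "child")
        new <- unique(rbind(reach,
                            data.frame(child = joined$child,
                                       parent = joined$parent.y)))
        if (nrow(new) == nrow(reach)) break
        reach <- new
      }
      anc_of_sig <- unique(reach$parent[reach$child %in% terms[sig]])
      keep <- !(sig & terms %in% anc_of_sig)
      expect_identical(pruned$term_id, terms[keep])
    }
  })
})
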