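test_that("sum and vote scores follow their definitions", {
  v <- matrix(c(3, 4, 0, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("sA", "sB")))
  ex <- expression_matrix(v, "tpm")
  expect_equal(sum_score(ex, c("g1", "g2")), c(sA = 7, sB = 0))
  expect_equal(sum_score(ex, c("g1", "g2"), log_transform = TRUE),
               c(sA = log2(4) + log2(5), sB = 0))
  expect_error(sum_score(ex, c("g1", "gX")), "gX")

  # median votes: even count uses the mean of central order statistics
  v2 <- matrix(1:4, 1, 4, dimnames = list("g", sprintf("s%d", 1:4)))
  ex2 <- expression_matrix(v2, "tpm")
  expect_equal(unname(vote_score(ex2, "g")), c(0, 0, 1, 1))  # median 2.5
  # constant gene votes for every sample (inclusive >=)
  v3 <- matrix(5, 1, 4, dimnames = list("g", sprintf("s%d", 1:4)))
  expect_equal(unname(vote_score(expression_matrix(v3, "tpm"), "g")),
               rep(1, 4))
  # two genes with opposite orderings: every sample scores exactly 1
  v4 <- rbind(g1 = 1:4, g2 = 4:1)
  colnames(v4) <- sprintf("s%d", 1:4)
  expect_equal(unname(vote_score(expression_matrix(v4, "tpm"),
                                 c("g1", "g2"))), rep(1, 4))

  # sum oracle on random data
  ex5 <- rand_expr(20, 7, seed = 3, scale = "tpm")
  expect_equal(sum_score(ex5, rownames(ex5)[1:9]),
               colSums(unclass(ex5)[1:9, ]))
})

test_that("median split is deterministic with the odd patient going low", {
  s <- c(A = 1, B = 2, C = 3, D = 4)
  sp <- split_by_score(s)
  expect_identical(sp$patient_id[sp$group == "high"], c("D", "C"))
  expect_identical(sp$patient_id[sp$group == "low"], c("B", "A"))

  s3 <- c(A = 1, B = 2, C = 3)
  sp3 <- split_by_score(s3)
  expect_identical(sp3$patient_id[sp3$group == "high"], "C")
  expect_setequal(sp3$patient_id[sp3$group == "low"], c("A", "B"))

  # all-equal scores: ordering purely by id, sizes differ by <= 1
  s5 <- setNames(rep(2, 5), c("e", "c", "a", "d", "b"))
  sp5 <- split_by_score(s5)
  expect_identical(sp5$patient_id, c("a", "b", "c", "d", "e"))
  expect_equal(abs(sum(sp5$group == "high") - sum(sp5$group == "low")), 1)
  expect_error(split_by_score(c(A = 1)), ">= 2")
})

test_that("truncation converts late follow-up to censoring at the limit", {
  rec <- data.frame(patient_id = c("a", "b", "c"),
                    time_days = c(2000, 1825, 100),
                    event = c(1L, 1L, 0L))
  tr <- truncate_survival(rec, 1825)
  expect_equal(tr$time_days, c(1825, 1825, 100))
  expect_equal(tr$event, c(0L, 1L, 0L))     # boundary record untouched
  # truncation never increases the number of events
  withr::with_seed(23, {
    for (i in 1:10) {
      r <- data.frame(patient_id = sprintf("p%02d", 1:40),
                      time_days = sample(0:4000, 40),
                      event = sample(0:1, 40, TRUE))
      expect_lte(sum(truncate_survival(r, 1825)$event), sum(r$event))
    }
  })
})

test_that("Kaplan-Meier estimate matches the hand product-limit example", {
  rec <- data.frame(patient_id = sprintf("p%d", 1:5),
                    time_days = c(1, 2, 3, 3, 4),
                    event = c(0L, 1L, 1L, 1L, 0L))
  km <- km_estimate(rec)
  expect_equal(km$survival[km$time == 2], 3 / 4)
  expect_equal(km$survival[km$time == 3], 1 / 4)
  expect_true(all(diff(km$survival) <= 0))
  expect_true(all(km$survival >= 0 & km$survival <= 1))
  expect_error(km_estimate(rec[0, ]), "no records")
})

test_that("KM with no censoring equals the empirical survival function", {
  withr::with_seed(29, {
    for (i in 1:10) {
      n <- sample(3:25, 1)
      t <- sample(1:40, n, replace = TRUE)
      rec <- data.frame(patient_id = sprintf("p%02d", 1:n),
                        time_days = t, event = 1L)
      km <- km_estimate(rec)
      emp <- vapply(km$time, function(tt) mean(t > tt), numeric(1))
      expect_equal(km$survival, emp, tolerance = 1e-12)
    }
  })
})

test_that("KM and log-rank agree with the survival package on random data", {
  withr::with_seed(37, {
    for (i in 1:8) {
      n <- sample(10:60, 1)
      rec <- data.frame(patient_id = sprintf("p%03d", 1:n),
                        time_days = sample(1:500, n, replace = TRUE),
                        event = sample(0:1, n, replace = TRUE))
      grp <- setNames(sample(c("x", "y"), n, replace = TRUE),
                      rec$patient_id)
      if (length(unique(grp)) < 2 || sum(rec$event) == 0) next
      sf <- survival::survfit(survival::Surv(time_days, event) ~ 1,
                              data = rec)
      km <- km_estimate(rec)
      expect_equal(km$survival[km$n_event > 0],
                   sf$surv[sf$n.event > 0], tolerance = 1e-10)
      sd_ref <- survival::survdiff(
        survival::Surv(time_days, event) ~ g,
        data = cbind(rec, g = grp[rec$patient_id]))
      lr <- logrank_test(rec, grp)
      expect_equal(lr$chi_square, sd_ref$chisq, tolerance = 1e-8)
      # label swap invariance
      swapped <- setNames(ifelse(grp == "x", "y", "x"), names(grp))
      expect_equal(logrank_test(rec, swapped)$chi_square, lr$chi_square,
                   tolerance = 1e-12)
    }
  })
})

test_that("log-rank on two identical groups is exactly null", {
  rec <- data.frame(patient_id = sprintf("p%d", 1:6),
                    time_days = rep(c(10, 20, 30), 2),
                    event = rep(1L, 6))
  grp <- setNames(rep(c("a", "b"), 3), rec$patient_id)
  lr <- logrank_test(rec, grp)
  expect_equal(lr$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(rec, setNames(rep("a", 6), rec$patient_id)),
               "two groups")
})

test_that("six-patient worked log-rank example matches hand O/E/V tables", {
  # group A: events at 1, 2; censored 3.  group B: events at 2, 4; cens 5.
  rec <- data.frame(patient_id = sprintf("p%d", 1:6),
                    time_days = c(1, 2, 3, 2, 4, 5),
                    event = c(1L, 1L, 0L, 1L, 1L, 0L))
  grp <- setNames(rep(c("A", "B"), each = 3), rec$patient_id)
  # t=1: n=6, nA=3, d=1, dA=1 -> E=0.5, V=1*(3/6)(3/6)(5/5)=0.25
  # t=2: n=5, nA=2, d=2, dA=1 -> E=0.8, V=2*(2/5)(3/5)(3/4)=0.36
  # t=4: n=2, nA=0, d=1, dA=0 -> E=0,   V=0
  O <- 2; E <- 1.3; V <- 0.61
  chi_hand <- (O - E)^2 / V
  lr <- logrank_test(rec, grp)
  expect_equal(lr$chi_square, chi_hand, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(chi_hand, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("stratified report separates a hazard-linked synthetic cohort", {
  spec <- simulation_spec(seed = 13, hazard_log_hr = 0.7, n_survival = 200)
  genes <- sprintf("G%03d", 1:100)
  sig <- genes[1:30]
  ex <- simulate_cohort_expression(spec, genes, 200)
  clinical <- simulate_survival_cohort(ex, sig, spec)
  rep <- stratified_survival_report(ex, sig, clinical, method = "sum")
  expect_equal(rep$n_high + rep$n_low, 200)
  expect_lt(rep$p_value, 0.05)
  # high-score curve lies at or below the low-score curve at shared times
  common <- intersect(rep$curves$high$time, rep$curves$low$time)
  sh <- approxfun(rep$curves$high$time, rep$curves$high$survival,
                  method = "constant", yleft = 1, rule = 2)
  sl <- approxfun(rep$curves$low$time, rep$curves$low$survival,
                  method = "constant", yleft = 1, rule = 2)
  ts <- sort(unique(c(rep$curves$high$time, rep$curves$low$time)))
  expect_true(mean(sh(ts) <= sl(ts) + 1e-12) > 0.95)
  expect_lt(sh(max(ts)), sl(max(ts)))

  # stage filter restricts the cohort
  rep1 <- stratified_survival_report(ex, sig, clinical, method = "sum",
                                     stage_filter = "I")
  expect_equal(rep1$n_high + rep1$n_low, sum(clinical$stage == "I"))
  # id mismatch errors name the missing patients
  expect_error(
    stratified_survival_report(ex[, 1:50], sig, clinical),
    "missing from expression")
})

test_that("comonotone scores give identical sum and vote splits", {
  # strictly increasing values per gene across samples => vote count and
  # sum rank samples identically
  v <- rbind(g1 = c(1, 2, 3, 4) * 10, g2 = c(2, 4, 6, 8))
  colnames(v) <- c("s1", "s2", "s3", "s4")
  ex <- expression_matrix(v, "tpm")
  sig <- c("g1", "g2")
  sp_sum <- split_by_score(sum_score(ex, sig))
  sp_vote <- split_by_score(vote_score(ex, sig))
  expect_setequal(sp_sum$patient_id[sp_sum$group == "high"],
                  sp_vote$patient_id[sp_vote$group == "high"])
})
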