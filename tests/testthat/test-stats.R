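test_that("performance index hits its boundary values", {
  expect_equal(performance_index(10, 0, 0), 1)
  expect_equal(performance_index(0, 0, 10), 0)
  expect_equal(performance_index(0, 10, 0), 0.5)
  # mixed counts follow the printed formula
  expect_equal(performance_index(20, 20, 10),
               0.5 * (20 + 20 + 10 + 20 - 10) / 50)
})

test_that("performance index is scale invariant and guarded", {
  set.seed(71)
  for (i in 1:20) {
    cnt <- rmultinom(1, 50, c(0.3, 0.4, 0.3))
    base <- performance_index(cnt[1], cnt[2], cnt[3])
    for (k in c(2L, 5L, 13L)) {
      expect_equal(performance_index(k * cnt[1], k * cnt[2], k * cnt[3]),
                   base)
    }
    expect_gte(base, 0)
    expect_lte(base, 1)
  }
  expect_error(performance_index(0, 0, 0), "undefined")
  expect_error(performance_index(-1, 2, 3), ">= 0")
})

test_that("Kaplan-Meier matches the hand product-limit estimate", {
  # deaths at days 2 and 5, n = 2
  rec <- data.frame(day = c(2, 5), censored = c(FALSE, FALSE))
  km <- kaplan_meier(rec)
  expect_equal(km$time, c(2, 5))
  expect_equal(km$surv, c(0.5, 0))
  expect_equal(km_at(km, c(1, 2, 4.9, 5, 10)), c(1, 0.5, 0.5, 0, 0))

  # all censored: S(t) = 1 everywhere
  rec <- data.frame(day = c(3, 6, 9), censored = TRUE)
  km <- kaplan_meier(rec)
  expect_true(all(km$surv == 1))
  expect_equal(km_at(km, c(0, 5, 100)), c(1, 1, 1))

  # duplicating every record leaves the curve unchanged
  rec <- data.frame(day = c(1, 2, 2, 4, 7), censored = c(0, 0, 1, 0, 0))
  expect_equal(kaplan_meier(rec)$surv,
               kaplan_meier(rbind(rec, rec))$surv)

  expect_error(kaplan_meier(data.frame(day = c(0, 2), censored = FALSE)),
               "positive")
})

test_that("Kaplan-Meier curves are non-increasing from S(0) = 1", {
  set.seed(72)
  rec <- simulate_survival(survival_sim_params(n_per_group = 40,
                                               censor_day = 80, seed = 72))
  km <- kaplan_meier(rec)
  expect_true(all(diff(c(1, km$surv)) <= 0))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
})

test_that("log-rank statistic equals the hand O/E/V tabulation", {
  # 6-fly toy dataset, including a tie and a censored fly
  a <- data.frame(day = c(2, 4, 6), censored = c(FALSE, FALSE, TRUE))
  b <- data.frame(day = c(4, 5, 9), censored = c(FALSE, FALSE, FALSE))
  lr <- logrank_test(a, b)
  expect_equal(lr$chi_square, oracle_logrank_chisq(a, b), tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value,
               stats::pchisq(lr$chi_square, 1, lower.tail = FALSE))

  # identical groups: O = E at every time
  g <- data.frame(day = c(1, 3, 5), censored = FALSE)
  lr0 <- logrank_test(g, g)
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p_value, 1)
})

test_that("log-rank agrees with survdiff and is symmetric in group order", {
  set.seed(73)
  for (i in 1:10) {
    rec <- simulate_survival(survival_sim_params(
      n_per_group = 30, induction_hr = sample(c(1, 1.5, 2.5), 1),
      censor_day = if (i %% 2) 90 else NULL, seed = 7300 + i))
    a <- rec[rec$induction == "RU0", ]
    b <- rec[rec$induction == "RU200", ]
    lr <- logrank_test(a, b)
    lr_rev <- logrank_test(b, a)
    expect_equal(lr$chi_square, lr_rev$chi_square, tolerance = 1e-12)
    sd <- survival::survdiff(
      survival::Surv(day, !censored) ~ induction, data = rec)
    expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-8)
    expect_equal(oracle_logrank_chisq(a, b), sd$chisq, tolerance = 1e-8)
  }
  expect_error(
    logrank_test(data.frame(day = c(1, 2), censored = TRUE),
                 data.frame(day = c(1, 2), censored = FALSE)),
    "degenerate")
})

test_that("one-way ANOVA matches the sum-of-squares oracle", {
  groups <- list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(3, 4, 5))
  res <- one_way_anova(groups)
  orc <- oracle_anova_f(groups)
  expect_equal(res$f_stat, orc$f, tolerance = 1e-10)
  expect_equal(res$df_between, orc$df_between)
  expect_equal(res$df_within, orc$df_within)

  # identical constant groups: no between-group variance
  flat <- one_way_anova(list(a = c(5, 5, 5), b = c(5, 5, 5)))
  expect_equal(flat$f_stat, 0)
  expect_equal(flat$p_value, 1)

  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(one_way_anova(list(a = c(1, 2))), "2 groups")
})

test_that("ANOVA has the F(3, 14) shape for 4 groups of sizes 5,5,4,4", {
  set.seed(74)
  groups <- list(a = rnorm(5), b = rnorm(5), c = rnorm(4), d = rnorm(4))
  res <- one_way_anova(groups)
  expect_equal(res$df_between, 3L)
  expect_equal(res$df_within, 14L)
  expect_equal(nrow(res$tukey), choose(4, 2))
})

test_that("two-group ANOVA reduces to the squared t statistic", {
  set.seed(75)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1), mean = runif(1, -1, 1))
    res <- one_way_anova(list(a = a, b = b))
    tt <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(res$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
    # with two groups the single Tukey comparison equals the ANOVA p
    # (up to ptukey's own numerical accuracy)
    expect_equal(res$tukey$p_adj, res$p_value, tolerance = 1e-6)
  }
})

test_that("Tukey adjusted p-values follow the studentized range", {
  set.seed(76)
  groups <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 2))
  res <- one_way_anova(groups)
  # hand-computed studentized range p for one pair
  n <- 6L
  k <- 3L
  df <- 3L * n - k
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0))
  msw <- ssw / df
  dmean <- abs(mean(groups$b) - mean(groups$a))
  q <- dmean / sqrt(msw / n)
  p_hand <- stats::ptukey(q, k, df, lower.tail = FALSE)
  row <- res$tukey[res$tukey$pair == "b-a", ]
  expect_equal(row$p_adj, p_hand, tolerance = 1e-8)
})

test_that("permutation interaction test is deterministic and never zero", {
  rec <- simulate_survival(survival_sim_params(n_per_group = 25,
                                               interaction_hr = 3,
                                               seed = 77))
  r1 <- permutation_interaction_test(rec, n_perm = 300, seed = 5)
  r2 <- permutation_interaction_test(rec, n_perm = 300, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$null_stats, r2$null_stats)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)

  r3 <- permutation_interaction_test(rec, n_perm = 300, seed = 6)
  expect_false(identical(r1$null_stats, r3$null_stats))

  expect_warning(permutation_interaction_test(rec, n_perm = 99, seed = 1),
                 "coarse")
  bad <- rec[!(rec$genotype == rec$genotype[1] &
                 rec$induction == rec$induction[1]), ]
  expect_error(permutation_interaction_test(bad, n_perm = 100, seed = 1),
               "cell")
  expect_error(permutation_interaction_test(rec, n_perm = 100), "seed")
})

test_that("interaction test agrees with a Cox model on a strong effect", {
  rec <- simulate_survival(survival_sim_params(n_per_group = 120,
                                               induction_hr = 2,
                                               interaction_hr = 2.5,
                                               seed = 78))
  perm <- permutation_interaction_test(rec, n_perm = 500, seed = 9)
  cox <- survival::coxph(
    survival::Surv(day, !censored) ~ genotype * induction, data = rec)
  p_cox <- summary(cox)$coefficients[3, "Pr(>|z|)"]
  expect_lt(perm$p_value, 0.05)
  expect_lt(p_cox, 0.05)
})

test_that("PI permutation test detects a genotype gap and calibrates", {
  set.seed(79)
  tp <- rep(c(7, 14, 21), each = 4)
  pi_null <- data.frame(genotype = rep(c("a", "b"), 6), timepoint = tp,
                        pi = runif(12, 0.4, 0.6))
  r <- permutation_pi_test(pi_null, n_perm = 400, seed = 2)
  expect_gt(r$p_value, 0.01)

  pi_gap <- pi_null
  pi_gap$pi[pi_gap$genotype == "a"] <- pi_gap$pi[pi_gap$genotype == "a"] + 0.3
  r2 <- permutation_pi_test(pi_gap, n_perm = 400, seed = 2)
  expect_lt(r2$p_value, 0.05)
})
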