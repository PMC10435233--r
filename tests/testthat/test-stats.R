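test_that("per-larva averaging honors exclusions", {
  trials <- data.frame(
    larva_id = c(1, 1, 1, 2),
    trial = c(1, 2, 3, 1),
    rate = c(0, 100, 100, 50),
    excluded = c(FALSE, FALSE, FALSE, FALSE)
  )
  avg <- per_larva_average(trials, metrics = "rate")
  expect_equal(avg$rate, c(200 / 3, 50))
  # excluded trial leaves the denominator
  trials$excluded[1] <- TRUE
  avg2 <- per_larva_average(trials, metrics = "rate")
  expect_equal(avg2$rate[1], 100)
  # single trial: average equals that trial
  expect_equal(avg2$rate[2], 50)
})

test_that("group summaries report mean and sd/sqrt(n)", {
  g <- group_summary(c(2, 4, 6, 8), "demo")
  expect_equal(g$mean, 5)
  expect_equal(g$sem, stats::sd(c(2, 4, 6, 8)) / 2)
  expect_error(group_summary(numeric(0)), "at least one")
})

test_that("sem scales as 1/sqrt(n) on replicated cohorts", {
  withr::with_seed(50, {
    sems <- vapply(c(10, 40, 160), function(n) {
      mean(replicate(40, group_summary(stats::rnorm(n))$sem))
    }, numeric(1))
  })
  expect_equal(sems[1] / sems[2], 2, tolerance = 0.15)
  expect_equal(sems[2] / sems[3], 2, tolerance = 0.15)
})

test_that("exact rank-sum p matches full enumeration on the reference case", {
  res <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, enumerate_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
})

test_that("rank-sum matches enumeration across all small group sizes", {
  withr::with_seed(60, {
    for (na in 1:9) {
      for (nb in 1:(10 - na)) {
        x <- sample(seq_len(50), na + nb) + stats::runif(na + nb, 0, 0.1)
        a <- x[seq_len(na)]
        b <- x[-seq_len(na)]
        expect_equal(
          rank_sum_test(a, b)$p_value,
          enumerate_ranksum_p(a, b),
          tolerance = 1e-12,
          info = sprintf("na=%d nb=%d", na, nb)
        )
      }
    }
  })
})

test_that("rank-sum is symmetric and sane on identical groups", {
  a <- c(1.2, 3.4, 2.2)
  b <- c(0.5, 5.5, 2.9)
  expect_equal(rank_sum_test(a, b)$p_value, rank_sum_test(b, a)$p_value)
  same <- rank_sum_test(c(1, 2, 3, 4), c(1.01, 2.01, 3.01, 4.01))
  expect_gt(same$p_value, 0.5)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("two-group Tukey reduces to the equal-variance t comparison", {
  withr::with_seed(70, {
    a <- stats::rnorm(8, 0, 1)
    b <- stats::rnorm(9, 0.8, 1)
  })
  res <- anova_tukey(list(a = a, b = b))
  p_tukey <- res$p_value[res$test == "tukey_hsd"]
  p_t <- stats::t.test(a, b, var.equal = TRUE)$p.value
  expect_equal(p_tukey, p_t, tolerance = 1e-9)
  # omnibus F p equals the t-test p with two groups as well
  expect_equal(res$p_value[res$test == "one_way_anova"], p_t,
    tolerance = 1e-9
  )
})

test_that("anova statistics are shift invariant and p-values stay in [0,1]", {
  withr::with_seed(71, {
    g <- list(
      a = stats::rnorm(6), b = stats::rnorm(6, 1), c = stats::rnorm(6, 2)
    )
  })
  r1 <- anova_tukey(g)
  r2 <- anova_tukey(lapply(g, function(x) x + 42))
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
  expect_true(all(r1$p_value >= 0 & r1$p_value <= 1))
  # equal-mean groups with variance: large p
  withr::with_seed(72, g0 <- list(a = stats::rnorm(10), b = stats::rnorm(10)))
  expect_gt(anova_tukey(g0)$p_value[1], 0.01)
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "at least two")
})

test_that("trial 1 vs 6 comparison pairs larvae correctly", {
  trials <- data.frame(
    larva_id = rep(1:4, each = 6),
    trial = rep(1:6, 4),
    rate = rep(100, 24)
  )
  te <- trial_effect_table(trials, "rate")
  expect_equal(nrow(te$pairs), 4)
  expect_true(all(te$pairs$difference == 0))
  expect_true(is.na(te$test$p_value)) # degenerate all-zero case

  # planted attenuation in the final trial
  trials$rate[trials$trial == 6] <- 60
  te2 <- trial_effect_table(trials, "rate")
  expect_lt(stats::median(te2$pairs$difference), 0)

  # single pair
  one <- trials[trials$larva_id == 1, ]
  expect_equal(nrow(trial_effect_table(one, "rate")$pairs), 1)
  expect_error(
    trial_effect_table(trials[trials$trial == 1, ], "rate"),
    "no complete"
  )
})
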