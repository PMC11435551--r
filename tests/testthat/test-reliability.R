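test_that("SEM is the root mean of per-trial variances", {
  expect_equal(sem(c(9, 9, 9)), 3)
  expect_equal(sem(c(4, 16, 25)), sqrt(15))
  expect_equal(sem(c(0, 0, 0)), 0)
  expect_equal(sem(sample(c(4, 16, 25))), sem(c(4, 16, 25)))  # order-free
  expect_error(sem(numeric(0)), "at least one")
  expect_error(sem(c(-1, 2)), "non-negative")
})

test_that("SEM percent scales by the parameter mean", {
  expect_equal(sem_percent(0.31, 8.13), 3.81, tolerance = 0.01)
  expect_equal(sem_percent(6.77, 408.3), 1.66, tolerance = 0.005)
  expect_equal(sem_percent(0, 5), 0)
  expect_error(sem_percent(1, 0), "zero mean")
})

test_that("MDD95 is 1.96 * sqrt(2) * SEM at machine precision", {
  sems <- c(0.31, 47.82, 1e-8, 123.4)
  expect_equal(mdd95(sems) / sems, rep(1.96 * sqrt(2), length(sems)),
               tolerance = 1e-12)
  expect_equal(mdd95(0), 0)
  expect_error(mdd95(-1), ">= 0")
})

test_that("curve SEM averages the pointwise SEM over the stance grid", {
  grid <- 101
  flat <- matrix(5, 40, grid)
  expect_equal(curve_sem(list(flat, flat, flat)), 0)
  # constant + i.i.d. noise of sd s at every point recovers s
  s <- 0.3
  set.seed(99)
  trials <- lapply(1:3, function(i)
    matrix(5 + rnorm(1000 * grid, 0, s), 1000, grid))
  expect_equal(curve_sem(trials), s, tolerance = 0.05)
  # permutation of cycles within trials changes nothing
  perm <- lapply(trials, function(m) m[sample(nrow(m)), ])
  expect_equal(curve_sem(perm), curve_sem(trials), tolerance = 1e-12)
  expect_error(curve_sem(list(flat)), "at least 2 trials")
  expect_error(curve_sem(list(flat, flat[1, , drop = FALSE])),
               "fewer than 2 cycles")
})

test_that("effect size is the signed standardized mean difference", {
  expect_equal(effect_size(583.8, 706.9, 11.5), -10.70, tolerance = 0.005)
  expect_equal(effect_size(420.7, 408.3, 10.4), 1.19, tolerance = 0.005)
  expect_equal(effect_size(5, 5, 2), 0)
  # antisymmetry in the means
  expect_equal(effect_size(3, 7, 1.3), -effect_size(7, 3, 1.3))
  expect_error(effect_size(1, 2, 0), "positive")
})

test_that("ICC(3,k) matches hand cases and an independent ANOVA oracle", {
  expect_equal(icc_3k(matrix(rep(c(1, 5, 9, 2), 3), 4, 3)), 1)
  # columns differing by constants: perfect consistency
  expect_equal(icc_3k(matrix(1:12, 4, 3, byrow = TRUE)), 1)
  set.seed(123)
  for (i in 1:200) {
    m <- matrix(rnorm(15, sd = runif(1, 0.5, 3)) +
                  rep(rnorm(5, sd = runif(1, 0, 3)), 3), 5, 3)
    expect_equal(icc_3k(m), icc_oracle_aov(m), tolerance = 1e-10)
  }
  expect_error(icc_3k(matrix(1, 4, 1)), "2 trials")
})

test_that("ICC(3,k) handles missing rows by listwise deletion up to a cap", {
  set.seed(8)
  m <- matrix(rnorm(30), 10, 3)
  m2 <- m; m2[c(1, 5), 2] <- NA
  expect_equal(icc_3k(m2), icc_3k(m[-c(1, 5), ]))
  m3 <- m; m3[1:4, 1] <- NA
  expect_error(icc_3k(m3), "missing cells")
})

test_that("ICC and SEM estimates recover the generating model", {
  y <- simulate_parameter_table(2, 2, 500, 3, seed = 42)
  expect_equal(icc_3k(y), attr(y, "population_icc_3k"), tolerance = 0.05)
  y2 <- simulate_parameter_table(0, 5, 200, 3, seed = 11)
  expect_equal(sem(apply(y2, 2, var)), 5, tolerance = 0.10)
})

test_that("ICC and effect-size bins label values with upper-bin boundaries", {
  expect_equal(classify_icc(c(0.85, 0.7, 0.5, 0.1)),
               c("very good", "good", "moderate", "poor"))
  expect_equal(classify_icc(c(0.40, 0.60, 0.80)),
               c("moderate", "good", "very good"))
  expect_equal(classify_es(c(0.1, -0.3, 0.6, -1.0, 2.5)),
               c("very small", "small", "moderate", "large", "very large"))
  expect_equal(classify_es(c(0.2, 0.5, 0.8, 1.2, -1.2)),
               c("small", "moderate", "large", "very large", "very large"))
})

test_that("aggregation applies the max-across-feet and pooled-asymmetry SEM rules", {
  res <- full_run_60s()
  s <- res$report$summary
  mdd <- res$report$mdd
  for (param in gait_parameter_names()) {
    # O and T groups: the SEM behind the MDD row is the worst foot
    for (g in c("O", "T")) {
      cond <- if (g == "O") "TDM6-SYM-GROUND" else "TDM6-SYM-MGAIT"
      expect_equal(mdd$sem_used[mdd$group == g & mdd$parameter == param],
                   max(s$sem[s$condition == cond & s$parameter == param]))
    }
    # TA: the worst SEM across all six asymmetric conditions and both feet
    asym <- grepl("ASYM", s$condition)
    expect_equal(mdd$sem_used[mdd$group == "TA" & mdd$parameter == param],
                 max(s$sem[asym & s$parameter == param]))
  }
  expect_equal(mdd$mdd95, 1.96 * sqrt(2) * mdd$sem_used, tolerance = 1e-12)
  # effect sizes exist for both pairs, all asym conditions, feet, durations
  es <- res$report$effect_sizes
  expect_equal(nrow(es), 2 * 6 * 2 * 4)
  expect_equal(sort(unique(es$pair)), c("O-TA", "T-TA"))
  # census percentages sum to 100 per pair
  for (p in unique(res$report$es_census$pair))
    expect_equal(sum(res$report$es_census$percent[
      res$report$es_census$pair == p]), 100)
})

test_that("a single-condition single-foot report degenerates to min = max", {
  res <- full_run_60s()
  one <- res$datasets["TDM6-SYM-MGAIT"]
  rep1 <- aggregate_report(one)
  s <- rep1$summary
  for (param in gait_parameter_names()) {
    cell <- s[s$parameter == param, ]
    expect_equal(rep1$mdd$sem_used[rep1$mdd$parameter == param],
                 max(cell$sem))
  }
  expect_equal(nrow(rep1$effect_sizes), 0L)  # no asymmetric pair present
})
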