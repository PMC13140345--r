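test_that("error summary reproduces the random-level manikin campaign numbers", {
  t2 <- validation_table("manikin_random")
  res <- error_summary(t2, measured_pct, target_col = target_pct)
  expect_equal(round(res$mean_error, 1), 0.8)
  expect_equal(round(res$min_error, 1), -1.0)
  expect_equal(round(res$max_error, 1), 4.0)
})

test_that("error summary degenerates cleanly", {
  d <- tibble::tibble(loading = rep(16.5, 5))
  res <- error_summary(d, loading, target_pct = 16.5)
  expect_equal(res$mean_error, 0)
  expect_equal(res$sd_error, 0)
  expect_error(error_summary(tibble::tibble(loading = NA_real_), loading,
                             target_pct = 16.5), "non-missing")
  expect_error(error_summary(d, loading), "target")
})

test_that("Bland-Altman matches a direct hand computation", {
  x <- c(17.6, 20.8, 19.3, 22.8, 14.4)
  y <- c(18.7, 19.1, 26.0, 17.6, 20.9)
  ba <- bland_altman(tibble::tibble(x = x, y = y), x, y)
  d <- x - y
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  tq <- qt(0.975, 4)
  expect_equal(ba$ci_bias, mean(d) + c(-1, 1) * tq * sd(d) / sqrt(5))
  expect_equal(ba$ci_loa_upper,
               mean(d) + 1.96 * sd(d) + c(-1, 1) * tq * sd(d) * sqrt(3 / 5))
  expect_true(ba$loa_lower <= ba$bias && ba$bias <= ba$loa_upper)
})

test_that("Bland-Altman is antisymmetric and collapses on self-comparison", {
  d <- tibble::tibble(a = c(17.6, 20.8, 19.3, 22.8), b = c(18.7, 19.1, 26.0, 17.6))
  expect_equal(bland_altman(d, a, b)$bias, -bland_altman(d, b, a)$bias)
  expect_warning(self <- bland_altman(d, a, a), "zero variance")
  expect_equal(self$bias, 0)
  expect_equal(self$loa_upper, 0)
  expect_error(bland_altman(d[1:2, ], a, b), "at least 3")
})

test_that("Bland-Altman drops incomplete pairs and tidies", {
  d <- tibble::tibble(a = c(1, 2, NA, 4, 5), b = c(1.5, NA, 3, 4.7, 5.1))
  ba <- bland_altman(d, a, b)
  expect_equal(ba$n, 3)
  td <- tidy(ba)
  expect_identical(td$term, c("bias", "loa_lower", "loa_upper"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(ba)
  expect_equal(gl$n, 3)
})

test_that("ICC is 1 for identical occasions and ~0 for independent noise", {
  x <- rnorm(10) + 18
  d1 <- tibble::tibble(participant = rep(1:10, 2),
                       visit = rep(c("v1", "v2"), each = 10),
                       loading = rep(x, 2))
  fit <- icc_agreement(d1, participant, visit, loading)
  expect_equal(fit$icc, 1, tolerance = 1e-9)
  expect_identical(fit$label, "excellent")
  d0 <- withr::with_seed(7, tibble::tibble(
    participant = rep(1:200, 3),
    visit = rep(c("v1", "v2", "v3"), each = 200),
    loading = rnorm(600)))
  fit0 <- icc_agreement(d0, participant, visit, loading)
  expect_lt(abs(fit0$icc), 0.1)  # MC error at n = 200
  expect_identical(fit0$label, "poor")
})

test_that("ICC recovers a known variance ratio on seeded two-way data", {
  d <- sim_loading_table(n_participants = 200, n_visits = 3,
                         sd_between = 2, sd_within = 1, seed = 11)
  expect_equal(attr(d, "true_icc"), 0.8)
  fit <- icc_agreement(d, participant, visit, loading_pct)
  expect_equal(fit$icc, 0.8, tolerance = 0.05 / 0.8)
  expect_true(fit$ci[1] <= fit$icc && fit$icc <= fit$ci[2])
  expect_lt(fit$p_value, 1e-6)
})

test_that("absolute agreement penalises an occasion offset but not a common shift", {
  d <- sim_loading_table(n_participants = 30, n_visits = 3,
                         sd_between = 2, sd_within = 1, seed = 5)
  base <- icc_agreement(d, participant, visit, loading_pct)$icc
  shifted <- dplyr::mutate(d, loading_pct = loading_pct + 10)
  expect_equal(icc_agreement(shifted, participant, visit, loading_pct)$icc,
               base, tolerance = 1e-9)
  biased <- dplyr::mutate(d, loading_pct = loading_pct +
                            ifelse(visit == "v2", 5, 0))
  expect_lt(icc_agreement(biased, participant, visit, loading_pct)$icc, base)
})

test_that("ICC point estimate matches lme4 variance components on balanced data", {
  skip_if_not_installed("lme4")
  d <- sim_loading_table(n_participants = 60, n_visits = 3,
                         sd_between = 2, sd_within = 1, seed = 21)
  fit <- icc_agreement(d, participant, visit, loading_pct)
  m <- lme4::lmer(loading_pct ~ 1 + (1 | participant) + (1 | visit), data = d)
  vc <- as.data.frame(lme4::VarCorr(m))
  v <- setNames(vc$vcov, vc$grp)
  icc_reml <- v[["participant"]] /
    (v[["participant"]] + v[["visit"]] + v[["Residual"]])
  # ANOVA-moment and REML estimators agree closely on balanced data
  expect_equal(fit$icc, icc_reml, tolerance = 0.02)
})

test_that("ICC demands a complete two-way layout", {
  d <- sim_loading_table(n_participants = 10, seed = 2)
  expect_error(icc_agreement(d[-1, ], participant, visit, loading_pct),
               "complete")
  d2 <- d
  d2$loading_pct[4] <- NA
  expect_error(icc_agreement(d2, participant, visit, loading_pct), "missing")
  expect_error(icc_agreement(d[d$participant < 3, ], participant, visit,
                             loading_pct), "3 subjects")
})

test_that("mean ICC estimate is nearly unbiased over repeated simulations", {
  true_icc <- 2^2 / (2^2 + 1)  # 0.8
  est <- vapply(seq_len(500), function(i) {
    d <- sim_loading_table(n_participants = 50, n_visits = 3,
                           sd_between = 2, sd_within = 1, seed = 1000 + i)
    icc_agreement(d, participant, visit, loading_pct)$icc
  }, numeric(1))
  expect_equal(mean(est), true_icc, tolerance = 0.02 / true_icc)
})
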