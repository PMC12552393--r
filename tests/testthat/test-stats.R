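test_that("Welch test matches the closed-form statistic and df", {
  x <- c(1, 2, 3)
  y <- c(1, 2, 3, 4, 5, 6)
  out <- welch_t_test(x, y)
  # brute-force Welch formulas
  se2 <- var(x) / 3 + var(y) / 6
  t_exp <- (mean(x) - mean(y)) / sqrt(se2)
  df_exp <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 6)^2 / 5)
  expect_equal(out$statistic, t_exp, tolerance = 1e-12)
  expect_equal(out$df, df_exp, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * pt(-abs(t_exp), df_exp), tolerance = 1e-12)

  ident <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)

  # equal variances and sizes collapse to df = 2n - 2
  expect_equal(welch_t_test(c(1, 2, 3), c(4, 5, 6))$df, 4)

  expect_error(welch_t_test(c(1, 1, 1), c(1, 2, 3)), "positive variance")
  expect_error(welch_t_test(1, c(1, 2, 3)), "positive variance")
})

test_that("OLS fits reproduce a normal-equations hand solution", {
  d <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 4, 5, 4, 5))
  fit <- fit_linear_model(d, y ~ x)
  X <- cbind(1, d$x)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)[, 1]
  expect_equal(unname(coef(fit$lm)), unname(beta), tolerance = 1e-12)

  exact <- data.frame(x = 1:6, y = 3 * (1:6) - 1)
  efit <- suppressWarnings(fit_linear_model(exact, y ~ x))
  expect_equal(efit$r_squared, 1)
  expect_true(all(abs(residuals(efit$lm)) < 1e-10))

  # residuals orthogonal to the design, adjusted R2 <= R2
  set.seed(3)
  d2 <- data.frame(x = rnorm(40), z = rnorm(40))
  d2$y <- 1 + d2$x + rnorm(40)
  f2 <- fit_linear_model(d2, y ~ x + z)
  X2 <- model.matrix(f2$lm)
  expect_true(all(abs(t(X2) %*% residuals(f2$lm)) < 1e-8))
  expect_lte(f2$adj_r_squared, f2$r_squared)

  d3 <- d2
  d3$x2 <- d3$x * 2  # aliased
  expect_error(fit_linear_model(d3, y ~ x + x2), "rank-deficient")

  d4 <- d2
  d4$y[1:3] <- NA
  expect_message(f4 <- fit_linear_model(d4, y ~ x), "3 row")
  expect_equal(f4$n, 37)
})

test_that("noiseless telomere simulation recovers the generating slope", {
  cfg <- small_config(resid_sd_kb = 1e-6)
  tel <- telomere_pairs(simulate_telomeres(simulate_metadata(cfg), cfg))
  fit <- fit_linear_model(tel, gonad_kb ~ fin_kb + sex)
  est <- tidy(fit)
  expect_equal(est$estimate[est$term == "fin_kb"], cfg$slope_b,
               tolerance = 1e-4)
  expect_equal(est$estimate[est$term == "sexM"], cfg$male_offset_kb,
               tolerance = 1e-4)
})

test_that("AICc applies the small-sample correction on top of AIC", {
  set.seed(4)
  d <- data.frame(x = rnorm(10))
  d$y <- d$x + rnorm(10)
  fit <- fit_linear_model(d, y ~ x)
  k <- fit$k
  expect_equal(aicc(fit), AIC(fit$lm) + 2 * k * (k + 1) / (10 - k - 1),
               tolerance = 1e-12)

  # worked example: k = 2, n = 10, logLik = -12.5 -> 29 + 12/7
  expect_equal(-2 * (-12.5) + 2 * 2 + 2 * 2 * 3 / (10 - 2 - 1), 29 + 12 / 7)

  # undefined when n <= k + 1
  d5 <- data.frame(x = rnorm(4), z = rnorm(4), w = rnorm(4))
  d5$y <- rnorm(4)
  fit5 <- fit_linear_model(d5, y ~ x + z)   # k = 4, n = 4
  expect_error(aicc(fit5), "undefined")
})

test_that("AICc converges to AIC as n grows at fixed k", {
  gaps <- sapply(c(20, 100, 1000), function(n) {
    set.seed(n)
    d <- data.frame(x = rnorm(n))
    d$y <- 2 * d$x + rnorm(n)
    fit <- fit_linear_model(d, y ~ x)
    aicc(fit) - AIC(fit$lm)
  })
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.05)
})

test_that("AICc selection prefers the generating structure", {
  set.seed(10)
  d <- data.frame(x = rnorm(32))
  d$y <- 5 * d$x + rnorm(32)
  rank <- select_model(d, list(empty = y ~ 1, slope = y ~ x))
  expect_equal(rank$model[1], "slope")
  expect_equal(rank$delta_aicc[1], 0)
  expect_equal(sum(rank$weight), 1)

  # intercept-only data: the empty model wins in most seeds
  wins <- sapply(1:10, function(s) {
    set.seed(s)
    d0 <- data.frame(x = rnorm(32), y = rnorm(32))
    select_model(d0, list(empty = y ~ 1, slope = y ~ x))$model[1]
  })
  expect_gte(sum(wins == "empty"), 6)

  single <- select_model(d, list(only = y ~ x))
  expect_equal(nrow(single), 1)
  expect_s3_class(best_model(single), "epirad_fit")
})

test_that("estimated means reproduce OLS cell means with t-based CIs", {
  set.seed(11)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 8))
  d$y <- rnorm(24, mean = c(a = 1, b = 3, c = 5)[d$g])
  fit <- fit_linear_model(d, y ~ g)
  em <- estimated_means(fit)
  obs <- tapply(d$y, d$g, mean)
  expect_equal(em$estimate, as.numeric(obs[as.character(em$g)]),
               tolerance = 1e-10)
  expect_true(all(em$conf_low < em$estimate & em$estimate < em$conf_high))

  # intercept-only: every estimate is the grand mean
  f0 <- fit_linear_model(d, y ~ 1)
  expect_equal(estimated_means(f0)$estimate, mean(d$y))

  expect_error(estimated_means(fit, grid = data.frame(g = "z")),
               "outside the design")

  # CI width shrinks like 1 / sqrt(n)
  widths <- sapply(c(20, 80), function(n) {
    set.seed(12)
    dd <- data.frame(g = rep(c("a", "b"), each = n / 2))
    dd$y <- rnorm(n, ifelse(dd$g == "a", 0, 1))
    emn <- estimated_means(fit_linear_model(dd, y ~ g))
    mean(emn$conf_high - emn$conf_low)
  })
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.3)
})

test_that("Type II term F tests respect marginality and match car::Anova", {
  set.seed(13)
  d <- data.frame(
    age_group = rep(c("AGE1", "AGE2", "AGE3"), length.out = 32),
    sex = rep(c("F", "M"), length.out = 32)
  )
  d$y <- ifelse(d$age_group == "AGE3", 1.5, 0) +
    ifelse(d$sex == "M", 0.8, 0) + rnorm(32)

  fit <- fit_linear_model(d, y ~ age_group + sex)
  ft <- term_f_tests(fit)
  expect_equal(ft$df1[ft$term == "age_group"], 2)
  expect_equal(ft$df2, c(28, 28))

  aov2 <- car::Anova(fit$lm, type = 2)
  expect_equal(ft$statistic,
               aov2[c("age_group", "sex"), "F value"], tolerance = 1e-10)
  expect_equal(ft$p_value,
               aov2[c("age_group", "sex"), "Pr(>F)"], tolerance = 1e-10)

  # with the interaction present, main effects are tested without it
  fit_int <- fit_linear_model(d, y ~ age_group * sex)
  expect_message(ft_int <- term_f_tests(fit_int), "marginality")
  aov2i <- car::Anova(fit_int$lm, type = 2)
  expect_equal(ft_int$statistic[ft_int$term == "age_group"],
               aov2i["age_group", "F value"], tolerance = 1e-10)

  # one-factor two-level model: F equals t squared
  d2 <- d[, c("sex", "y")]
  f1 <- fit_linear_model(d2, y ~ sex)
  tstat <- tidy(f1)$statistic[2]
  expect_equal(term_f_tests(f1)$statistic, unname(tstat^2), tolerance = 1e-10)
})

test_that("Q-Q tables expose residual normality and its violations", {
  set.seed(14)
  d <- data.frame(x = rnorm(500))
  d$y <- d$x + rnorm(500)
  qq <- qq_normality_check(fit_linear_model(d, y ~ x))
  slope <- coef(lm(sample ~ theoretical, data = qq))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)

  # heavy-tailed residuals stray further from the reference line
  d_t <- data.frame(x = rnorm(500))
  d_t$y <- d_t$x + rt(500, df = 2)
  qq_t <- qq_normality_check(fit_linear_model(d_t, y ~ x))
  expect_gt(max(abs(qq_t$sample - qq_t$theoretical)),
            max(abs(qq$sample - qq$theoretical)))

  one <- fit_linear_model(data.frame(x = 1, y = 2), y ~ 1)
  qq1 <- qq_normality_check(one)
  expect_equal(nrow(qq1), 1)
  expect_equal(qq1$theoretical, 0)
  expect_equal(qq1$sample, 0)
})
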