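# Per-metabolite model fitting: coefficients, variance components,
# conditional residuals, adjusted means

test_that("a constant response in a single usable group fits exactly", {
  # second group entirely missing: model degenerates to an intercept
  df <- data.frame(Sample = sprintf("s%d", 1:6),
                   Group = rep(c("A", "B"), each = 3),
                   Met1 = c(32, 32, 32, NA, NA, NA))
  tab <- metabolite_table(df, model_spec("Group"))
  fit <- fit_metabolite_model(log2(df$Met1), tab)
  expect_equal(fit$mu, 5)
  expect_equal(fit$residuals, rep(0, 3))
  expect_equal(unname(fit$group_means["A"]), 5)
  expect_true(is.na(fit$group_means["B"]))
  expect_equal(fit$n_used, 3L)
})

test_that("least-squares slopes match the normal-equations oracle", {
  set.seed(101)
  n <- 40
  q <- runif(n, 20, 80)
  y <- 10 + 2 * q + rnorm(n, 0, 0.01)
  df <- data.frame(Sample = sprintf("s%d", 1:n),
                   Group = rep(c("A", "B"), each = n / 2),
                   Quantity = q, Met1 = 2^pmin(y, 300))
  tab <- metabolite_table(df, model_spec("Group", fixed_continuous = "Quantity"))
  fit <- fit_metabolite_model(y, tab)
  expect_lt(abs(fit$betas[["Quantity"]] - 2), 0.01)
  # oracle: direct normal-equations solve on the same design
  X <- cbind(1, as.numeric(df$Group == "B"), q)
  beta_hat <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fit$betas[["Quantity"]]), beta_hat[3], tolerance = 1e-10)
  expect_equal(unname(fit$mu), beta_hat[1], tolerance = 1e-10)
})

test_that("REML variance components match a profile-likelihood grid oracle", {
  set.seed(11)
  n_day <- 20
  day <- rep(c("d1", "d2"), each = n_day)
  offs <- c(d1 = 1, d2 = -1)   # true day offsets +/-1
  y <- 12 + offs[day] + rnorm(2 * n_day, 0, 0.5)
  df <- data.frame(Sample = sprintf("s%d", seq_along(y)),
                   Group = rep(c("A", "B"), n_day), Day = day,
                   Met1 = 2^y)
  tab <- metabolite_table(df, model_spec("Group", random_factors = "Day"))
  fit <- fit_metabolite_model(y, tab)
  X <- stats::model.matrix(~ factor(rep(c("A", "B"), n_day)))
  oracle <- reml_profile_oracle(y, X, factor(day))
  expect_equal(unname(fit$random_variances[["Day"]]),
               unname(oracle["sigma_b2"]), tolerance = 0.02)
  expect_equal(unname(fit$sigma2_e), unname(oracle["sigma_e2"]),
               tolerance = 0.01)
  # with true between-day variance 1, the estimate stays in a wide band
  expect_gte(fit$random_variances[["Day"]], 0.5)
  expect_lte(fit$random_variances[["Day"]], 2.0)
  # conditional residuals subtract the BLUPs
  expect_equal(length(fit$blups$Day), 2L)
})

test_that("adjusted means reduce to cell means in balanced one-way designs", {
  set.seed(3)
  df <- data.frame(Sample = sprintf("s%d", 1:12),
                   Group = rep(c("A", "B", "C"), each = 4),
                   Met1 = 2^rnorm(12, 15, 1))
  tab <- metabolite_table(df, model_spec("Group"))
  y <- log2(df$Met1)
  fit <- fit_metabolite_model(y, tab)
  expect_equal(fit$group_means,
               c(tapply(y, df$Group, mean)), tolerance = 1e-12)
})

test_that("adjusted means equalize groups differing only in a covariate", {
  # y = 2 * Quantity exactly; groups get different Quantity distributions,
  # so raw means differ but predictions at the common covariate mean agree
  q <- c(1, 2, 3, 4, 11, 12, 13, 14)
  y <- 2 * q
  df <- data.frame(Sample = sprintf("s%d", 1:8),
                   Group = rep(c("A", "B"), each = 4),
                   Quantity = q, Met1 = 2^(y / 10))
  tab <- metabolite_table(df, model_spec("Group", fixed_continuous = "Quantity"))
  fit <- fit_metabolite_model(y, tab)
  expect_equal(unname(fit$group_means["A"]), unname(fit$group_means["B"]),
               tolerance = 1e-8)
  expect_equal(unname(fit$group_means["A"]), 2 * mean(q), tolerance = 1e-8)
})

test_that("fixed and mixed paths agree when the block variance is zero", {
  # balanced day allocation, no day effect: GLS reduces to OLS
  sim <- simulate_dataset(simulation_spec(
    n_per_group = 6, groups = c("A", "B", "C"), n_metabolites = 3,
    log2_group_effects = c(0, 0.5, 1),
    covariate_slopes = numeric(), covariate_distributions = list(),
    block_factors = list(Day = list(levels = 3, sd = 0)),
    residual_sd = 0.3, missing_rate = 0, seed = 21))
  tab <- sim$table
  spec_mixed <- tab$spec
  spec_fixed <- model_spec("Group", transform = "log2")
  tab_fixed <- metabolite_table(tab$data[setdiff(names(tab$data), "Day")],
                                spec_fixed)
  for (m in tab$metabolites) {
    y <- log2(tab$data[[m]])
    f_mix <- fit_metabolite_model(y, tab, spec_mixed)
    f_fix <- fit_metabolite_model(y, tab_fixed, spec_fixed)
    expect_lt(max(abs(f_mix$coefficients - f_fix$coefficients)), 1e-6)
    expect_lt(max(abs(f_mix$group_means - f_fix$group_means)), 1e-6)
  }
})

test_that("estimates are invariant to row permutation", {
  sim <- simulate_dataset(simulation_spec(
    n_per_group = 8, groups = c("A", "B"), n_metabolites = 1,
    log2_group_effects = c(0, 1), residual_sd = 0.3, missing_rate = 0,
    seed = 5))
  tab <- sim$table
  y <- log2(tab$data[[tab$metabolites]])
  set.seed(99)
  perm <- sample(nrow(tab$data))
  tab_p <- metabolite_table(tab$data[perm, ], tab$spec)
  f1 <- fit_metabolite_model(y, tab, tab$spec)
  f2 <- fit_metabolite_model(y[perm], tab_p, tab$spec)
  expect_equal(f1$group_means, f2$group_means, tolerance = 1e-6)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)

  # fixed-only path is exactly permutation invariant
  spec_f <- model_spec("Group", fixed_continuous = "Quantity")
  tab_f <- metabolite_table(tab$data[setdiff(names(tab$data), "Day")], spec_f)
  tab_fp <- metabolite_table(tab_f$data[perm, ], spec_f)
  g1 <- fit_metabolite_model(y, tab_f, spec_f)
  g2 <- fit_metabolite_model(y[perm], tab_fp, spec_f)
  expect_lt(max(abs(g1$group_means - g2$group_means)), 1e-10)
})

test_that("slope estimates are unbiased on data simulated from the model", {
  beta_true <- 0.8
  est <- se <- numeric(200)
  for (r in 1:200) {
    set.seed(4000 + r)
    n <- 24
    q <- rnorm(n, 50, 10)
    y <- 15 + 0.5 * (rep(c(0, 1), each = n / 2)) + beta_true * 0.01 * q +
      rnorm(n, 0, 0.3)
    df <- data.frame(Sample = sprintf("s%d", 1:n),
                     Group = rep(c("A", "B"), each = n / 2),
                     Quantity = q, Met1 = 2^y)
    tab <- metabolite_table(df, model_spec("Group",
                                           fixed_continuous = "Quantity"))
    fit <- fit_metabolite_model(y, tab)
    est[r] <- fit$betas[["Quantity"]]
    se[r] <- sqrt(fit$sigma2_e / sum((q - mean(q))^2))
  }
  mc_se <- sd(est) / sqrt(200)
  expect_lt(abs(mean(est) - beta_true * 0.01), 3 * mc_se)
})

test_that("degenerate fits raise named errors", {
  df <- data.frame(Sample = c("s1", "s2", "s3", "s4"),
                   Group = c("A", "A", "B", "B"), Met1 = c(2, 4, 8, 16))
  tab <- metabolite_table(df, model_spec("Group"))
  # a single usable observation in one group
  expect_error(fit_metabolite_model(c(1, 2, 3, NA), tab),
               "single usable observation")
  # residual df < 1: four fixed parameters for four observations
  spec_q <- model_spec("Group", fixed_continuous = c("Quantity", "IS"))
  df$Quantity <- c(1, 2, 3, 4)
  df$IS <- c(2, 1, 5, 3)
  tab_q <- metabolite_table(df, spec_q)
  expect_error(fit_metabolite_model(c(1, 2, 3, 4), tab_q),
               "residual degrees of freedom")
})
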