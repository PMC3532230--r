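# Pairwise inference: Tukey HSD, Storey q-values, fold-changes, compact
# letter display, screening

test_that("Tukey HSD handles the null difference and degenerate input", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("A", "B"), each = 3)
  tk <- tukey_hsd(v, g)
  expect_equal(tk$diff, 0)
  expect_equal(tk$p, 1)
  expect_equal(tk$comparison, "B-A")
  expect_error(tukey_hsd(rep(1, 6), g), "zero within-group variance")
  expect_error(tukey_hsd(v, rep("A", 6)), "at least 2 groups")
})

test_that("Tukey p-values match the Studentized-range quadrature oracle", {
  set.seed(19)
  cases <- list(
    list(k = 2, n = 6), list(k = 3, n = 5), list(k = 4, n = 4))
  for (cs in cases) {
    g <- rep(LETTERS[seq_len(cs$k)], each = cs$n)
    v <- rnorm(length(g)) + 0.8 * (g == "B")
    tk <- tukey_hsd(v, g)
    nu <- attr(tk, "df")
    mse <- attr(tk, "MSE")
    for (i in seq_len(nrow(tk))) {
      q_obs <- abs(tk$diff[i]) / tk$se[i]
      expect_lt(abs(tk$p[i] - (1 - ptukey_oracle(q_obs, cs$k, nu))), 1e-4)
    }
  }
})

test_that("Tukey with two groups reduces to the pooled-variance t-test", {
  set.seed(27)
  v <- c(rnorm(8, 0), rnorm(10, 0.7))      # unbalanced on purpose
  g <- rep(c("A", "B"), c(8, 10))
  tk <- tukey_hsd(v, g)
  tt <- stats::t.test(v ~ g, var.equal = TRUE)
  expect_lt(abs(tk$p - tt$p.value), 1e-6)
})

test_that("Tukey-Kramer standard errors respect unbalanced group sizes", {
  set.seed(33)
  v <- rnorm(15)
  g <- rep(c("A", "B", "C"), c(3, 5, 7))
  tk <- tukey_hsd(v, g)
  mse <- attr(tk, "MSE")
  n <- attr(tk, "n")
  ab <- tk[tk$comparison == "B-A", ]
  expect_equal(ab$se, sqrt((mse / 2) * (1 / n[["A"]] + 1 / n[["B"]])),
               tolerance = 1e-12)
  # TukeyHSD from a one-way aov is the same procedure: cross-check p-values
  hsd <- stats::TukeyHSD(stats::aov(v ~ factor(g)))[[1]]
  expect_equal(sort(tk$p), sort(unname(hsd[, "p adj"])), tolerance = 1e-8)
})

test_that("Storey q-values reduce to BH at pi0 = 1 and cap at 1", {
  set.seed(41)
  p <- runif(50)^2
  q <- storey_qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), stats::p.adjust(p, "BH"), tolerance = 1e-12)

  q1 <- storey_qvalues(rep(1, 50))
  expect_true(all(q1 == 1))

  # fewer than 100 p-values: automatic BH fallback
  expect_equal(attr(storey_qvalues(p), "pi0"), 1)

  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(storey_qvalues(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("pi0 estimation behaves under a uniform null", {
  set.seed(47)
  p <- runif(1000)
  q <- storey_qvalues(p)
  pi0 <- attr(q, "pi0")
  expect_gte(pi0, 0.85)
  expect_lte(pi0, 1.0)
  # oracle: direct evaluation of the lambda formula feeding the spline
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (1000 * (1 - l)), 0)
  sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
  expect_equal(pi0, min(stats::predict(sp, 0.95)$y, 1), tolerance = 1e-10)
  # the spline smooths rather than interpolates: bounded fit residuals
  expect_lt(max(abs(stats::predict(sp, lambda)$y - pi0_l)), 0.2)
})

test_that("q-values are monotone in p and invariant to input order", {
  set.seed(53)
  p <- runif(300)
  q <- as.numeric(storey_qvalues(p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  perm <- sample(300)
  q_perm <- as.numeric(storey_qvalues(p[perm]))
  expect_equal(q_perm, q[perm], tolerance = 1e-12)
  # NA p-values pass through as NA without disturbing the rest
  p_na <- c(p[1:5], NA, p[6:10])
  q_na <- storey_qvalues(p_na, pi0 = 1)
  expect_true(is.na(q_na[6]))
})

test_that("fold-changes back-transform adjusted mean differences", {
  m <- c(A = 10, B = 11, C = 10)
  fc <- fold_change_matrix(m, "log2")
  expect_equal(fc["B", "A"], 2)            # one log2 unit -> 2-fold
  expect_equal(fc["C", "A"], 1)            # equal means -> 1
  expect_equal(fc["A", "B"] * fc["B", "A"], 1, tolerance = 1e-10)
  expect_true(all(diag(fc) == 1))

  fc_none <- fold_change_matrix(c(A = 4, B = 2, Z = 0), "none")
  expect_equal(fc_none["A", "B"], 2)
  expect_true(is.na(fc_none["A", "Z"]))    # zero denominator undefined
  m_na <- c(A = 10, B = NA, C = 12)
  expect_true(all(is.na(fold_change_matrix(m_na, "log2")["B", c("A", "C")])))
})

test_that("compact letter display matches brute force on all k <= 4 patterns", {
  for (k in 2:4) {
    n_pairs <- choose(k, 2)
    idx <- which(upper.tri(matrix(0, k, k)))
    for (mask in 0:(2^n_pairs - 1)) {
      sig <- matrix(FALSE, k, k,
                    dimnames = list(LETTERS[1:k], LETTERS[1:k]))
      bits <- as.logical(bitwAnd(mask, 2^(seq_len(n_pairs) - 1)))
      sig[idx] <- bits
      sig <- sig | t(sig)
      got <- compact_letter_display(sig)
      expect_identical(got, cld_oracle(sig),
                       label = sprintf("k=%d mask=%d", k, mask))
      # groups share a letter iff not significantly different
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        share <- length(intersect(strsplit(got[i], "")[[1]],
                                  strsplit(got[j], "")[[1]])) > 0
        expect_identical(share, !sig[i, j])
      }
    }
  }
})

test_that("compact letter display reproduces the canonical examples", {
  lev <- c("Control", "Fast", "InsNeut")
  none <- matrix(FALSE, 3, 3, dimnames = list(lev, lev))
  expect_identical(unname(compact_letter_display(none)), rep("a", 3))

  all_sig <- !diag(3)
  dimnames(all_sig) <- list(lev, lev)
  expect_identical(unname(compact_letter_display(all_sig)),
                   c("a", "b", "c"))

  # only Fast <-> InsNeut differ: Control shares a letter with both
  fi <- none
  fi["Fast", "InsNeut"] <- fi["InsNeut", "Fast"] <- TRUE
  expect_identical(compact_letter_display(fi),
                   c(Control = "ab", Fast = "a", InsNeut = "b"))
})

test_that("screening criteria combine p, q and fold-change correctly", {
  res <- data.frame(
    metabolite = c("M1", "M1", "M2", "M2"),
    comparison = rep(c("B-A", "C-A"), 2),
    fold_change = c(2.0, 1.1, 0.4, 1.0),
    tukey_p = c(0.01, 0.20, 0.03, 0.90),
    q_value = c(0.04, 0.30, 0.08, 0.95))
  sp <- screen_metabolites(res, screen_config("p", alpha = 0.05))
  expect_setequal(sp$significant_metabolites, c("M1", "M2"))
  sq <- screen_metabolites(res, screen_config("q", alpha = 0.05))
  expect_setequal(sq$significant_metabolites, "M1")
  # fc criterion is two-sided: 0.4 -> 2.5-fold
  sf <- screen_metabolites(res, screen_config("fc", fc_threshold = 1.5))
  expect_setequal(sf$significant_metabolites, c("M1", "M2"))
  spf <- screen_metabolites(res, screen_config("p_and_fc", alpha = 0.05,
                                               fc_threshold = 2.2))
  expect_setequal(spf$significant_metabolites, "M2")
  # fc threshold 1 passes every tested pair
  s1 <- screen_metabolites(res, screen_config("fc", fc_threshold = 1))
  expect_true(all(s1$results$significant))
  # a vanishing alpha silences everything
  s0 <- screen_metabolites(res, screen_config("p", alpha = 1e-12))
  expect_length(s0$significant_metabolites, 0)
})

test_that("compare_groups assembles consistent results across metabolites", {
  sim <- simulate_dataset(simulation_spec(
    n_per_group = 8, groups = c("Control", "Fast", "InsNeut"),
    n_metabolites = 6,
    log2_group_effects = matrix(c(0, 0, 0,
                                  0, -1.5, 1,
                                  0, 0, 0,
                                  0, 0, 1.2,
                                  0, 0, 0,
                                  0, 0, 0), 6, 3, byrow = TRUE),
    residual_sd = 0.25, missing_rate = 0, seed = 61))
  fit <- metabnorm(sim$table)
  cmp <- compare_groups(fit)
  expect_equal(nrow(cmp$results), 6 * 3)
  expect_setequal(cmp$pairs,
                  c("Fast-Control", "InsNeut-Control", "InsNeut-Fast"))
  expect_true(all(cmp$results$fold_change > 0))
  expect_true(all(cmp$results$tukey_p >= 0 & cmp$results$tukey_p <= 1))
  expect_true(all(cmp$results$q_value >= 0 & cmp$results$q_value <= 1))
  # metabolites with injected effects are detected
  expect_true(all(c("Met02", "Met04") %in% cmp$significant_metabolites))
  # letters agree with pairwise significance at alpha
  for (m in names(cmp$letters)) {
    tk <- cmp$anova[[m]]
    lt <- cmp$letters[[m]]
    for (i in seq_len(nrow(tk))) {
      share <- length(intersect(strsplit(lt[[tk$group1[i]]], "")[[1]],
                                strsplit(lt[[tk$group2[i]]], "")[[1]])) > 0
      expect_identical(share, tk$p[i] >= 0.05)
    }
  }
})
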