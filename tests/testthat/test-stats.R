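test_that("contingency tables carry counts and row percentages", {
  lab <- expand_counts(table2_counts())
  tab <- build_contingency(lab$cluster, lab$epoch)
  expect_equal(unname(tab$counts),
               unname(table2_counts()[, colnames(tab$counts)]))
  expect_equal(unname(rowSums(tab$row_pct)), rep(100, 3))

  expect_error(build_contingency(character(0), character(0)), "positive length")
  one <- build_contingency("1", "ictal_active")
  expect_equal(sum(one$counts), 1)
  expect_error(build_contingency(c("1", "2"), c("ictal_active", "unassigned")),
               "unassigned|unknown")
})

test_that("the chi-square statistic equals the brute-force formula", {
  # hand-checkable 2x2: all expected counts 15
  m <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  r <- chi_square_test(m)
  expect_equal(r$statistic, 4 * 25 / 15)
  expect_equal(r$df, 1)

  # identical rows: exact independence
  expect_equal(chi_square_test(matrix(c(5, 10, 5, 10), 2, byrow = TRUE))$statistic, 0)

  # oracle equivalence on random tables
  set.seed(20)
  for (i in 1:100) {
    tt <- matrix(rpois(9, 15) + 1, 3, 3)
    e <- outer(rowSums(tt), colSums(tt)) / sum(tt)
    expect_equal(chi_square_test(tt)$statistic, sum((tt - e)^2 / e),
                 tolerance = 1e-10)
  }

  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2)), "degenerate")
})

test_that("multinomial fits are saturated: ORs equal cross-product ratios", {
  lab <- expand_counts(table2_counts())
  fit <- multinomial_logit(lab$epoch, lab$cluster)
  cf <- fit$coefficients
  m <- table2_counts()
  # OR for cluster 3 / ictal-active vs reference = (21/2)/(29/23)
  or33 <- cf$or[cf$outcome == "ictal_active" & cf$term == "clcluster3"]
  expect_equal(or33, (21 / 2) / (29 / 23), tolerance = 1e-4)
  or22 <- cf$or[cf$outcome == "interictal_active" & cf$term == "clcluster2"]
  expect_equal(or22, (53 / 10) / (13 / 23), tolerance = 1e-4)

  # fitted cell probabilities equal empirical proportions
  emp <- m / rowSums(m)
  expect_equal(unname(fit$fitted_probs[, colnames(m)]), unname(emp),
               tolerance = 1e-6)

  # independence: all ORs 1 (rows proportional)
  ind <- matrix(c(10, 20, 30, 20, 40, 60, 5, 10, 15), 3, byrow = TRUE,
                dimnames = dimnames(m))
  labi <- expand_counts(ind)
  fiti <- multinomial_logit(labi$epoch, labi$cluster)
  expect_equal(fiti$coefficients$or, rep(1, 4), tolerance = 1e-4)

  # Wald CIs bracket the OR
  expect_true(all(cf$ci_lo < cf$or & cf$or < cf$ci_hi))
})

test_that("Tukey-Kramer agrees with hand computation and with TukeyHSD", {
  # balanced textbook layout: groups (1,2,3), (2,3,4), (5,6,7)
  v <- c(1, 2, 3, 2, 3, 4, 5, 6, 7)
  g <- rep(c("a", "b", "c"), each = 3)
  h <- tukey_kramer_hsd(v, g)
  # MSE = 1, se = sqrt(1/2*(1/3+1/3)) = sqrt(1/3)
  expect_equal(h$q[h$group_a == "a" & h$group_b == "b"], 1 / sqrt(1 / 3))
  expect_equal(h$q[h$group_a == "a" & h$group_b == "c"], 4 / sqrt(1 / 3))

  # equal group sizes: identical adjusted p to stats::TukeyHSD
  o <- TukeyHSD(aov(v ~ factor(g)))[[1]]
  expect_equal(sort(h$p_adj), sort(unname(o[, "p adj"])), tolerance = 1e-8)

  # unbalanced sizes: still matches TukeyHSD (Tukey-Kramer form)
  set.seed(21)
  v2 <- c(rnorm(5, 0), rnorm(9, 1), rnorm(14, 3))
  g2 <- rep(c("a", "b", "c"), c(5, 9, 14))
  h2 <- tukey_kramer_hsd(v2, g2)
  o2 <- TukeyHSD(aov(v2 ~ factor(g2)))[[1]]
  expect_equal(sort(h2$p_adj), sort(unname(o2[, "p adj"])), tolerance = 1e-8)

  # identical group means: all adjusted p near 1
  v3 <- rep(c(1, 2, 3), times = 3)
  g3 <- rep(c("a", "b", "c"), each = 3)
  expect_true(all(tukey_kramer_hsd(v3, g3)$p_adj > 0.999))

  # extreme separation
  v4 <- c(rnorm(30, 0, 1), rnorm(30, 20, 1))
  g4 <- rep(c("a", "b"), each = 30)
  expect_lt(tukey_kramer_hsd(v4, g4)$p_adj, 1e-6)

  expect_error(tukey_kramer_hsd(c(1, 2, 3), c("a", "a", "b")), "2 observations")
})

test_that("epoch regression recovers group means, is location invariant and standardizes correctly", {
  ep <- rep(c("interictal_seizure_free", "interictal_active", "ictal_active"),
            c(35, 71, 57))
  means <- c(interictal_seizure_free = 138.8, interictal_active = 122.6,
             ictal_active = 153.2)
  y_exact <- means[ep]
  # a zero-residual fit makes summary.lm warn about perfect fits
  f <- suppressWarnings(ols_regression(y_exact, ep))
  expect_equal(f$beta[f$term == "interictal_active"],
               unname(means["interictal_active"] - means["interictal_seizure_free"]),
               tolerance = 1e-9)
  expect_equal(f$beta[f$term == "ictal_active"],
               unname(means["ictal_active"] - means["interictal_seizure_free"]),
               tolerance = 1e-9)

  # adding a constant to the response leaves the dummy coefficients unchanged
  set.seed(22)
  y <- y_exact + rnorm(163, 0, 15)
  f1 <- ols_regression(y, ep)
  f2 <- ols_regression(y + 100, ep)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-9)

  # standardized beta identity: beta * SD(x) / SD(y)
  X <- stats::model.matrix(~ stats::relevel(factor(ep), "interictal_seizure_free"))
  expect_equal(f1$std_beta[1], f1$beta[1] * sd(X[, 2]) / sd(y), tolerance = 1e-9)

  # simulation recovery at the printed crude effect for average frequency
  set.seed(23)
  gen <- c(interictal_seizure_free = 138.8,
           interictal_active = 138.8 - 16.19,
           ictal_active = 138.8 + 14.43)
  ysim <- gen[ep] + rnorm(163, 0, 16)
  fs <- ols_regression(ysim, ep)
  se <- (fs$ci_hi - fs$ci_lo) / (2 * qt(0.975, df = 160))
  expect_lt(abs(fs$beta[fs$term == "interictal_active"] - (-16.19)),
            2 * se[fs$term == "interictal_active"])
  expect_lt(abs(fs$beta[fs$term == "ictal_active"] - 14.43),
            2 * se[fs$term == "ictal_active"])

  # age adjustment: age column enters, rank-deficiency is caught
  age <- runif(163, 6, 17)
  fa <- ols_regression(ysim, ep, age = age)
  expect_true("age" %in% fa$term)
  expect_error(ols_regression(ysim, ep, age = rep(1, 163)) , "rank")
})

test_that("report files reproduce the printed layout and are byte-stable", {
  lab <- expand_counts(table2_counts())
  tab <- build_contingency(lab$cluster, lab$epoch)
  chi <- chi_square_test(tab)
  mfit <- multinomial_logit(lab$epoch, lab$cluster)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- make_reports(tab, chi, mfit, dir = d1)
  t2 <- read.csv(f1[["table2"]], check.names = FALSE)
  r2 <- t2[t2$cluster == "cluster2", ]
  expect_equal(r2$interictal_seizure_free_n, 10)
  expect_equal(r2$interictal_active_n, 53)
  expect_equal(r2$ictal_active_n, 7)
  expect_equal(r2$interictal_seizure_free_pct, 14.3)
  expect_equal(r2$interictal_active_pct, 75.7)
  expect_equal(r2$ictal_active_pct, 10.0)

  f2 <- make_reports(tab, chi, mfit, dir = d2)
  expect_identical(readLines(f1[["table2"]]), readLines(f2[["table2"]]))
  expect_identical(readLines(f1[["stats"]]), readLines(f2[["stats"]]))

  # empty cluster row: emitted with zeros and a warning
  counts0 <- table2_counts(); counts0["cluster3", ] <- 0
  lab0 <- expand_counts(counts0)
  tab0 <- build_contingency(lab0$cluster, lab0$epoch)
  tab0$counts <- rbind(tab0$counts, cluster3 = c(0, 0, 0))
  tab0$row_pct <- 100 * tab0$counts / pmax(rowSums(tab0$counts), 1)
  expect_warning(make_reports(tab0, chi, NULL, dir = tempfile()), "empty cluster")
})
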