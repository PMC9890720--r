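test_that("contingency tables validate counts and margins", {
  expect_error(contingency_table(matrix(c(1, -1, 2, 3), 2)), "non-negative")
  expect_error(contingency_table(matrix(0, 2, 2)), "total")
  expect_error(pearson_chi_square(matrix(c(5, 0, 7, 0), 2)), "degenerate")
  expect_error(pearson_chi_square(matrix(c(1, 2), 1)), "2 x 2")
})

test_that("Pearson chi-square matches the textbook statistic and conventions", {
  # identical row proportions -> statistic 0, p = 1
  r <- suppressWarnings(pearson_chi_square(matrix(c(10, 20, 30, 60), 2,
                                                  byrow = TRUE)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 1)

  # hand-computed statistic on a 2x2 (no continuity correction)
  tab <- matrix(c(38, 27, 15, 26), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  r2 <- pearson_chi_square(tab)
  expect_equal(r2$statistic, sum((tab - E)^2 / E))
  expect_equal(r2$p_value, pchisq(r2$statistic, 1, lower.tail = FALSE))

  # df matches the table shape for r x c
  r3 <- suppressWarnings(pearson_chi_square(matrix(1:12, 3, 4)))
  expect_equal(r3$df, 6)

  # small expected counts warn but still test
  expect_warning(pearson_chi_square(matrix(c(13, 4, 32, 1), 2, byrow = TRUE)),
                 "expected")
})

test_that("chi-square p agrees with the enumeration oracle where it is valid", {
  # fixed-margin enumeration oracle (mid-p, the continuity-matched version
  # of a discrete null) on tables with all expected counts >= 10
  for (tab in list(matrix(c(110, 90, 90, 110), 2, byrow = TRUE),
                   matrix(c(60, 40, 45, 55), 2, byrow = TRUE),
                   matrix(c(30, 20, 18, 32), 2, byrow = TRUE))) {
    p_pkg <- pearson_chi_square(tab)$p_value
    expect_lt(abs(p_pkg - exact_cond_chisq_p(tab, midp = TRUE)), 0.01)
  }
})

test_that("Fisher's exact test matches direct hypergeometric enumeration", {
  tab <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  # oracle: hypergeometric enumeration, summing probabilities <= observed
  probs <- dhyper(0:10, 10, 14, 12)
  p_oracle <- sum(probs[probs <= dhyper(1, 10, 14, 12) + 1e-12])
  r <- fisher_exact(tab)
  expect_equal(r$p_value, p_oracle, tolerance = 1e-10)
  expect_equal(round(r$p_value, 5), 0.00276)

  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
  expect_error(fisher_exact(matrix(c(800, 700, 600, 900), 2, byrow = TRUE)),
               "guard")
})

test_that("Spearman rho equals the midrank brute-force computation", {
  expect_equal(spearman(1:10, 1:10)$rho, 1)
  expect_equal(spearman(1:10, 10:1)$rho, -1)
  set.seed(10)
  x <- rnorm(30); y <- x + rnorm(30)
  x[3] <- x[7]  # inject ties
  r <- spearman(x, y)
  # oracle: Pearson correlation of average ranks, t-approximation p
  rho_bf <- cor(rank(x), rank(y))
  expect_equal(r$rho, rho_bf, tolerance = 1e-12)
  tstat <- rho_bf * sqrt(28 / (1 - rho_bf^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), 28), tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("Mann-Whitney matches exact enumeration on small samples", {
  r <- mann_whitney(1:3, 4:6)
  expect_equal(r$statistic, 0)  # all first-group ranks below
  # oracle: full enumeration of the 20 label assignments
  sums <- apply(combn(6, 3), 2, function(i) sum(rank(1:6)[i]))
  u <- sums - 6
  p_exact <- mean(abs(u - 4.5) >= abs(0 - 4.5))
  expect_equal(r$p_value, p_exact)

  # identical groups: U at its mean, two-sided p = 1
  expect_equal(mann_whitney(c(1, 1, 1), c(1, 1, 1))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Kruskal-Wallis and Dunn post hoc behave on null and shifted groups", {
  expect_lt(kruskal_wallis(list(1:5, 1:5, 1:5))$statistic, 1e-9)
  set.seed(11)
  g <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15) + 3)
  kw <- kruskal_wallis(g)
  expect_equal(kw$df, 2)
  expect_lt(kw$p_value, 0.01)
  # agreement with base R
  expect_equal(kw$statistic,
               unname(kruskal.test(unlist(g),
                                   rep(1:3, each = 15))$statistic))
  d <- dunn_posthoc(g)
  expect_equal(nrow(d), 3)
  # only the pairs involving the shifted group are significant
  ab <- d$p_adjusted[d$group1 == "a" & d$group2 == "b"]
  expect_gt(ab, 0.05)
  expect_lt(d$p_adjusted[d$group1 == "a" & d$group2 == "c"], 0.05)
  # Holm never decreases p
  expect_true(all(d$p_adjusted >= d$p_value - 1e-12))
  # two-group Dunn z agrees with the tie-corrected normal MW z in p
  g2 <- list(x = rep(1:10, 2), y = rep(3:12, 2))  # ties force the
  # normal-approximation path in both tests
  d2 <- dunn_posthoc(g2, adjustment = "none")
  expect_equal(d2$p_value, mann_whitney(g2$x, g2$y)$p_value, tolerance = 1e-9)
  expect_error(dunn_posthoc(list(1:3)), "two")
})

test_that("Kaplan-Meier product-limit estimates match hand calculations", {
  # times {1,2,3}, all events: S(2) = 1/3
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$curve$survival, c(2/3, 1/3, 0))
  # no censoring: KM equals the empirical survival function
  set.seed(12)
  tms <- rexp(40, 0.1)
  km2 <- km_estimate(tms, rep(TRUE, 40))
  emp <- vapply(km2$curve$time, function(t) mean(tms > t), 0)
  expect_equal(km2$curve$survival, emp, tolerance = 1e-12)
  # all censored: survival stays 1, restricted mean = tau
  km3 <- km_estimate(c(5, 8, 12), c(FALSE, FALSE, FALSE), tau = 12)
  expect_true(all(km3$curve$survival == 1))
  expect_equal(km3$rmean, 12)
  # restricted mean equals the area under the step function
  rm2 <- restricted_mean(km, tau = 3)
  expect_equal(rm2[["mean"]], 1 * 1 + 2/3 * 1 + 1/3 * 1)
})

test_that("log-rank agrees with a label-permutation oracle", {
  set.seed(13)
  tm <- c(rexp(10, 0.08), rexp(10, 0.04))
  ev <- rbinom(20, 1, 0.8) == 1
  gr <- rep(c("a", "b"), each = 10)
  r <- logrank(tm, ev, gr)
  perm <- replicate(2000, {
    g <- sample(gr)
    survival::survdiff(survival::Surv(tm, ev) ~ g)$chisq
  })
  p_perm <- mean(perm >= r$statistic - 1e-12)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 2000)
  expect_lt(abs(r$p_value - p_perm), 0.02 + 3 * mc_se)
  expect_error(logrank(tm, rep(FALSE, 20), gr), "no events")
  expect_error(logrank(tm, ev, rep("a", 20)), "two groups")
})
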