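test_that("Stuart-Maxwell: symmetric tables give zero, matrix oracle agrees", {
  sym <- matrix(c(10, 5, 0, 0, 10, 5, 5, 0, 10), 3, byrow = TRUE)
  # this table has equal margins, so the marginal differences vanish
  r <- stuart_maxwell(sym)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  expect_equal(r$df, 2)
  # asymmetric table: compare against an independently coded quadratic form
  tab <- matrix(c(20, 10, 2, 4, 30, 9, 1, 6, 12), 3, byrow = TRUE)
  r2 <- stuart_maxwell(tab)
  d <- (rowSums(tab) - colSums(tab))[1:2]
  S <- matrix(0, 2, 2)
  S[1, 1] <- sum(tab[1, ]) + sum(tab[, 1]) - 2 * tab[1, 1]
  S[2, 2] <- sum(tab[2, ]) + sum(tab[, 2]) - 2 * tab[2, 2]
  S[1, 2] <- S[2, 1] <- -(tab[1, 2] + tab[2, 1])
  oracle <- drop(t(d) %*% solve(S) %*% d)
  expect_equal(r2$statistic, oracle, tolerance = 1e-12)
  expect_equal(r2$p.value, pchisq(oracle, 2, lower.tail = FALSE))
  expect_equal(r2$n, sum(tab))
})

test_that("Stuart-Maxwell reduces to McNemar for 2 x 2 tables", {
  tab <- matrix(c(15, 9, 3, 20), 2, byrow = TRUE)
  r <- stuart_maxwell(tab)
  b <- tab[1, 2]; c0 <- tab[2, 1]
  expect_equal(r$statistic, (b - c0)^2 / (b + c0))
  expect_equal(r$df, 1)
  mc <- mcnemar.test(tab, correct = FALSE)
  expect_equal(r$statistic, unname(mc$statistic))
  expect_equal(r$p.value, mc$p.value)
})

test_that("Stuart-Maxwell is invariant under category relabelling", {
  tab <- matrix(c(20, 10, 2, 4, 30, 9, 1, 6, 12), 3, byrow = TRUE)
  base <- stuart_maxwell(tab)$statistic
  perms <- list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1), c(3, 2, 1))
  for (p in perms) {
    expect_equal(stuart_maxwell(tab[p, p])$statistic, base,
                 tolerance = 1e-10)
  }
})

test_that("Stuart-Maxwell drops empty categories and validates input", {
  tab <- matrix(0, 4, 4)
  tab[1:3, 1:3] <- matrix(c(20, 10, 2, 4, 30, 9, 1, 6, 12), 3, byrow = TRUE)
  r <- stuart_maxwell(tab)
  expect_equal(r$df, 2) # fourth category carries no observations
  expect_equal(r$statistic,
               stuart_maxwell(tab[1:3, 1:3])$statistic)
  expect_error(stuart_maxwell(matrix(1, 2, 3)), "square")
  expect_error(stuart_maxwell(matrix(-1, 2, 2)), "non-negative")
})

test_that("Wilcoxon signed rank: degenerate patterns and V statistic", {
  # all positive: V is the full rank sum n(n+1)/2
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 15)
  # antisymmetric differences: V = n(n+1)/4 and Z = 0
  r2 <- wilcoxon_signed_rank(c(-1, 1, -2, 2, -3, 3))
  expect_equal(r2$statistic, 6 * 7 / 4)
  expect_equal(r2$Z, 0)
  # zeros are dropped
  r3 <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3))
  expect_equal(r3$n, 3)
  expect_equal(r3$statistic, 6)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "all differences are zero")
})

test_that("Wilcoxon agrees with stats::wilcox.test on V and p", {
  set.seed(23)
  for (i in 1:10) {
    x <- rnorm(25); y <- rnorm(25, 0.3)
    ours <- wilcoxon_signed_rank(x, y, exact = FALSE)
    ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                        correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Wilcoxon exact p matches full sign enumeration at n = 8", {
  set.seed(29)
  for (i in 1:5) {
    d <- round(rnorm(8, 0.5, 1.2), 3) # continuous-ish, no ties
    if (any(d == 0) || any(duplicated(abs(d)))) next
    ours <- wilcoxon_signed_rank(d)
    expect_true(ours$exact)
    expect_equal(ours$p.value, enumerate_signed_rank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("rm ANOVA: null patterns give F = 0", {
  # constant values per participant: no condition variance anywhere
  Y <- matrix(rep(rnorm(8), 6), nrow = 8)
  r <- rm_anova_2x3(Y)
  expect_equal(r$F, c(0, 0, 0))
  expect_equal(r$p, c(1, 1, 1))
  expect_equal(r$pes, c(0, 0, 0))
})

test_that("rm ANOVA matches the aov Error-stratum oracle on random tables", {
  set.seed(37)
  for (i in 1:5) {
    Y <- matrix(rnorm(60, sd = 2), 10, 6) + rnorm(10, sd = 3)
    ours <- rm_anova_2x3(Y)
    orc <- aov_oracle(Y)
    expect_equal(ours$F, c(orc$A$F, orc$B$F, orc$AB$F), tolerance = 1e-8)
    expect_equal(ours$p_uncorrected, c(orc$A$p, orc$B$p, orc$AB$p),
                 tolerance = 1e-8)
    # partial eta squared from the oracle's sums of squares
    pes_orc <- c(orc$A$ss / (orc$A$ss + orc$A$ss_err),
                 orc$B$ss / (orc$B$ss + orc$B$ss_err),
                 orc$AB$ss / (orc$AB$ss + orc$AB$ss_err))
    expect_equal(ours$pes, pes_orc, tolerance = 1e-8)
  }
})

test_that("Greenhouse-Geisser epsilon matches Box's covariance formula", {
  set.seed(41)
  for (i in 1:5) {
    Y <- matrix(rnorm(72), 12, 6)
    Y[, 2] <- Y[, 2] * 2 + 0.8 * Y[, 1] # induce non-sphericity
    ours <- rm_anova_2x3(Y)
    # context main effect: epsilon from the covariance of the three
    # context scores (averaged over preference), Box's element formula
    ctx <- sapply(1:3, function(k) rowMeans(Y[, c(k, k + 3)]))
    eps_box <- box_epsilon(cov(ctx))
    expect_equal(ours$epsilon[ours$effect == "context"], eps_box,
                 tolerance = 1e-10)
    expect_equal(ours$epsilon[ours$effect == "preference"], 1)
    # GG-corrected p uses the shrunk degrees of freedom
    row <- ours[ours$effect == "context", ]
    expect_equal(row$p,
                 pf(row$F, 2 * row$epsilon, 22 * row$epsilon,
                    lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("rm ANOVA is location and scale equivariant", {
  set.seed(43)
  Y <- matrix(rnorm(60), 10, 6)
  base <- rm_anova_2x3(Y)
  shifted <- rm_anova_2x3(Y + 100)
  scaled <- rm_anova_2x3(Y * 3.7)
  expect_equal(shifted$F, base$F, tolerance = 1e-9)
  expect_equal(scaled$F, base$F, tolerance = 1e-9)
  expect_equal(scaled$pes, base$pes, tolerance = 1e-9)
  expect_equal(scaled$epsilon, base$epsilon, tolerance = 1e-9)
})

test_that("rm ANOVA input validation", {
  expect_error(rm_anova_2x3(matrix(rnorm(6), 1, 6)), "at least 2")
  expect_error(rm_anova_2x3(matrix(rnorm(50), 10, 5)), "expected 6")
  Y <- matrix(rnorm(60), 10, 6); Y[3, 4] <- NA
  expect_error(rm_anova_2x3(Y), "missing cells")
})

test_that("Bonferroni post-hocs multiply and cap raw p-values", {
  set.seed(47)
  Y <- matrix(rnorm(60), 10, 6)
  ph <- bonferroni_posthoc(Y, "B")
  expect_equal(nrow(ph), 3)
  # oracle: paired t-test on context scores, p times 3
  ctx <- sapply(1:3, function(k) rowMeans(Y[, c(k, k + 3)]))
  for (r in 1:3) {
    ij <- combn(3, 2)[, r]
    ref <- t.test(ctx[, ij[1]], ctx[, ij[2]], paired = TRUE)
    expect_equal(ph$p_raw[r], ref$p.value, tolerance = 1e-10)
    expect_equal(ph$p_adj[r], min(1, ref$p.value * 3), tolerance = 1e-10)
  }
  # identical conditions: adjusted p exactly 1
  Yid <- cbind(Y[, 1], Y[, 1], Y[, 1], Y[, 1], Y[, 1], Y[, 1])
  ph_id <- bonferroni_posthoc(Yid, "A")
  expect_equal(ph_id$p_adj, 1)
  expect_equal(ph_id$estimate, 0)
})
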