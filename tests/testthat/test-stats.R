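test_that("exact Wilcoxon p-values match the classical distribution", {
  # identical multisets: symmetric null, two-sided p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2))$comparisons$p_adjusted, 1)
  # fully separated samples: most extreme of the C(6,3) = 20 assignments
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$comparisons$p_adjusted, 1 / 20)
  # tie-free configurations up to n = 10 against pwilcox
  set.seed(5)
  for (nx in c(2, 3, 4, 5)) {
    for (ny in c(2, 4, 10 - nx)) {
      if (ny < 1) next
      x <- rnorm(nx)
      y <- rnorm(ny)
      mine <- wilcoxon_rank_sum(x, y)$comparisons
      u <- mine$statistic
      p_oracle <- min(1, 2 * min(pwilcox(u, nx, ny),
                                 1 - pwilcox(u - 1, nx, ny)))
      expect_equal(mine$p_adjusted, p_oracle, tolerance = 1e-12)
    }
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")
})

test_that("the normal approximation tracks the exact Wilcoxon p", {
  set.seed(8)
  for (rep in 1:10) {
    x <- rnorm(10)
    y <- rnorm(10, 0.5)
    p_apx <- wilcoxon_rank_sum(x, y, exact = FALSE)$comparisons$p_adjusted
    p_exa <- wilcoxon_rank_sum(x, y, exact = TRUE)$comparisons$p_adjusted
    expect_lt(abs(p_apx - p_exa), 0.01)
    # and both agree with the standard implementation
    expect_equal(p_apx, wilcox.test(x, y, exact = FALSE)$p.value,
                 tolerance = 1e-9)
  }
  # tied data: midranks + tie correction, still matching wilcox.test
  x <- c(1, 2, 2, 3, 5, 5, 6, 8, 8, 9, 10, 11)
  y <- c(2, 3, 3, 5, 7, 7, 9, 9, 12, 13, 14, 15)
  expect_equal(
    wilcoxon_rank_sum(x, y, exact = FALSE)$comparisons$p_adjusted,
    suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value),
    tolerance = 1e-9
  )
})

test_that("Dunnett reduces to the pooled t-test with two groups", {
  set.seed(2)
  for (rep in 1:3) {
    x <- rnorm(7)
    y <- rnorm(9, 0.7)
    d <- dunnett(list(ctrl = x, trt = y), reps = 2e5, seed = rep)
    tt <- t.test(y, x, var.equal = TRUE)$p.value
    expect_lt(abs(d$comparisons$p_adjusted - tt), 0.005)
  }
})

test_that("Dunnett agrees with the multivariate-t reference implementation", {
  skip_if_not_installed("multcomp")
  set.seed(14)
  g <- data.frame(
    group = factor(rep(c("ctrl", "a", "b", "c"), times = c(8, 6, 9, 7)),
                   levels = c("ctrl", "a", "b", "c")),
    value = c(rnorm(8), rnorm(6, 1), rnorm(9, 0.3), rnorm(7, -0.5))
  )
  mine <- dunnett(split(g$value, g$group), control = "ctrl",
                  reps = 2e5, seed = 4)
  fit <- multcomp::glht(stats::aov(value ~ group, data = g),
                        linfct = multcomp::mcp(group = "Dunnett"))
  ref <- summary(fit)$test$pvalues
  expect_equal(unname(mine$comparisons$p_adjusted), as.numeric(ref),
               tolerance = 0.01)
})

test_that("Tukey-Kramer matches the t-test at k = 2 and TukeyHSD generally", {
  set.seed(3)
  x <- rnorm(6)
  y <- rnorm(8, 1)
  tk <- tukey_kramer(list(a = x, b = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(tk$comparisons$statistic, sqrt(2) * abs(tt$statistic),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tk$comparisons$p_adjusted, tt$p.value, tolerance = 1e-9)
  # two identical groups: q = 0, p = 1 (variance within groups only)
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  tk0 <- tukey_kramer(same)
  expect_equal(tk0$comparisons$statistic, 0)
  expect_equal(tk0$comparisons$p_adjusted, 1)
  # all-pairs agreement with TukeyHSD on unbalanced data
  g <- data.frame(
    group = factor(rep(c("a", "b", "c"), times = c(5, 7, 6))),
    value = c(rnorm(5), rnorm(7, 1), rnorm(6, 0.2))
  )
  mine <- tukey_kramer(split(g$value, g$group))
  ref <- TukeyHSD(stats::aov(value ~ group, data = g))$group[, "p adj"]
  expect_equal(sort(unname(mine$comparisons$p_adjusted)),
               sort(unname(ref)), tolerance = 1e-6)
})

test_that("Steel reduces to the pairwise Wilcoxon with two groups", {
  set.seed(6)
  x <- rnorm(9)
  y <- rnorm(9, 0.8)
  s <- steel(list(ctrl = x, trt = y), reps = 4e4, seed = 2)
  w <- wilcoxon_rank_sum(y, x, exact = TRUE)
  expect_lt(abs(s$comparisons$p_adjusted - w$comparisons$p_adjusted), 0.01)
  # identical constant groups: nothing to detect
  s0 <- steel(list(ctrl = rep(1, 5), a = rep(1, 5), b = rep(1, 5)),
              reps = 500, seed = 1)
  expect_true(all(s0$comparisons$p_adjusted == 1))
})

test_that("many-one adjusted p-values dominate their pairwise counterparts", {
  set.seed(9)
  g <- list(ctrl = rnorm(8), a = rnorm(8, 0.9), b = rnorm(8, 0.4),
            c = rnorm(8, -0.6))
  d <- dunnett(g, reps = 1e5, seed = 3)
  s <- steel(g, reps = 2e4, seed = 3)
  for (trt in c("a", "b", "c")) {
    p_t <- t.test(g[[trt]], g$ctrl, var.equal = TRUE)$p.value
    p_w <- wilcoxon_rank_sum(g[[trt]], g$ctrl)$comparisons$p_adjusted
    cmp <- paste(trt, "vs ctrl")
    expect_gt(d$comparisons$p_adjusted[d$comparisons$comparison == cmp],
              p_t - 0.005)
    expect_gt(s$comparisons$p_adjusted[s$comparisons$comparison == cmp],
              p_w - 0.005)
  }
})

test_that("relabelling groups permutes comparisons but not p-values", {
  set.seed(11)
  g <- list(ctrl = rnorm(6), a = rnorm(5, 1), b = rnorm(7, 0.5))
  perm <- g[c("ctrl", "b", "a")]
  for (fn in list(function(x) dunnett(x, "ctrl", reps = 1e4, seed = 5),
                  function(x) steel(x, "ctrl", reps = 5e3, seed = 5),
                  function(x) tukey_kramer(x))) {
    r1 <- fn(g)$comparisons
    r2 <- fn(perm)$comparisons
    m <- merge(r1, r2, by = "comparison")
    expect_identical(m$p_adjusted.x, m$p_adjusted.y)
  }
})

test_that("Monte Carlo and permutation procedures are seed-deterministic", {
  g <- list(ctrl = c(1.2, 0.8, 1.5, 0.3), a = c(2.0, 1.7, 2.4, 1.1))
  expect_identical(dunnett(g, reps = 1e4, seed = 7)$comparisons,
                   dunnett(g, reps = 1e4, seed = 7)$comparisons)
  expect_identical(steel(g, reps = 2e3, seed = 7)$comparisons,
                   steel(g, reps = 2e3, seed = 7)$comparisons)
  expect_error(dunnett(list(a = c(1, 1, 1), b = c(1, 1, 1))), "variance")
})
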