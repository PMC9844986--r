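test_that("Shapiro-Wilk wrapper validates input and returns W in (0, 1]", {
  expect_error(shapiro_wilk(c(1, 2)), class = "crestscope_validation")
  expect_error(shapiro_wilk(rep(3, 10)), class = "crestscope_validation")
  set.seed(1)
  res <- shapiro_wilk(rnorm(50))
  expect_gt(res$statistic, 0)
  expect_lte(res$statistic, 1)
  expect_gte(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("Shapiro-Wilk p-values are uniform under the null (calibration)", {
  set.seed(10)
  pvals <- replicate(200, shapiro_wilk(rnorm(40))$p_value)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Shapiro-Wilk detects strong skew (power)", {
  set.seed(11)
  rej <- mean(replicate(100, shapiro_wilk(rexp(50))$p_value < 0.05))
  expect_gte(rej, 0.95)
})

test_that("unpaired t matches the pooled-variance closed form", {
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4, 5, 6)
  res <- t_unpaired(a, b)
  expect_equal(res$statistic, student_t_oracle(a, b), tolerance = 1e-12)
  expect_equal(res$df, length(a) + length(b) - 2)
  # identical groups: t = 0, p = 1
  same <- t_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(t_unpaired(1, c(1, 2)), class = "crestscope_validation")
  # Welch flag changes the df
  set.seed(3)
  x <- rnorm(10); y <- rnorm(20, sd = 4)
  expect_false(isTRUE(all.equal(t_unpaired(x, y, welch = TRUE)$df, 28)))
})

test_that("two-group one-way ANOVA F equals t squared (exact identity)", {
  set.seed(4)
  x <- rnorm(12, 5); y <- rnorm(15, 6)
  tt <- t_unpaired(x, y)
  av <- anova_tukey(c(x, y), rep(c("A", "B"), c(12, 15)))
  expect_equal(av$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(av$p_value, tt$p_value, tolerance = 1e-10)
})

test_that("three identical groups give F ~ 0 and Tukey p ~ 1", {
  vals <- rep(c(1, 2, 3, 4), times = 3)
  fac <- rep(c("A", "B", "C"), each = 4)
  av <- anova_tukey(vals, fac)
  expect_lt(av$statistic, 1e-20)
  expect_true(all(av$pairwise$p_adj > 0.999))
})

test_that("a 2-SD shifted group is detected by Tukey in most replicates", {
  set.seed(12)
  hits <- mean(replicate(60, {
    vals <- c(rnorm(15), rnorm(15), rnorm(15, mean = 2))
    fac <- rep(c("A", "B", "C"), each = 15)
    pw <- anova_tukey(vals, fac)$pairwise
    involved <- grepl("C", pw$comparison)
    all(pw$p_adj[involved] < 0.05)
  }))
  expect_gte(hits, 0.9)
})

test_that("two-way ANOVA reports both effects and Tukey over cell means", {
  set.seed(13)
  d <- expand.grid(rep = 1:6, A = c("P20", "P60"), B = c("WT", "KO"))
  d$y <- rnorm(nrow(d)) + 2 * (d$A == "P60") + 1 * (d$B == "KO")
  av <- anova_tukey(d$y, d$A, d$B)
  expect_setequal(av$effects$effect, c("A", "B", "A:B"))
  expect_lt(av$effects$p[av$effects$effect == "A"], 0.001)
  expect_equal(nrow(av$pairwise), choose(4, 2))
  expect_equal(av$pairwise_over, "A:B cell means")
  # empty cell -> validation error
  keep <- !(d$A == "P60" & d$B == "KO")
  expect_error(anova_tukey(d$y[keep], d$A[keep], d$B[keep]),
               class = "crestscope_validation")
})

test_that("Fisher exact matches enumeration and its symmetries", {
  expect_equal(fisher_exact(matrix(c(3, 0, 0, 3), 2))$p_value, 0.1,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  set.seed(14)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 4), 2)
    p <- fisher_exact(tab)$p_value
    expect_equal(p, fisher_oracle(tab), tolerance = 1e-9)
    # invariant under swapping both rows and both columns
    expect_equal(fisher_exact(tab[2:1, 2:1])$p_value, p, tolerance = 1e-12)
  }
  expect_error(fisher_exact(matrix(c(1, 2, 3, -1), 2)),
               class = "crestscope_validation")
  expect_error(fisher_exact(matrix(c(1, 2, 3, 1.5), 2)),
               class = "crestscope_validation")
})

test_that("log-rank: identical groups give statistic 0; oracle agreement", {
  tm <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  gr <- rep(c("A", "B"), each = 5)
  res <- logrank_test(tm, rep(TRUE, 10), gr)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  # complete separation, no censoring: compare to the hand-built
  # 2x2-per-event-time chi-square
  tm2 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  res2 <- logrank_test(tm2, rep(TRUE, 10), gr)
  expect_equal(res2$statistic,
               logrank_oracle(tm2, rep(TRUE, 10), gr), tolerance = 1e-9)
  # and on censored random data
  set.seed(15)
  tm3 <- rexp(30); ev3 <- runif(30) < 0.7
  gr3 <- rep(c("A", "B"), 15)
  res3 <- logrank_test(tm3, ev3, gr3)
  expect_equal(res3$statistic, logrank_oracle(tm3, ev3, gr3),
               tolerance = 1e-9)
  expect_error(logrank_test(tm, rep(TRUE, 10), rep("A", 10)),
               class = "crestscope_validation")
  expect_error(logrank_test(c(-1, tm[-1]), rep(TRUE, 10), gr),
               class = "crestscope_validation")
})

test_that("Kaplan-Meier curves start at 1, never rise, drop only at events", {
  set.seed(16)
  tm <- rexp(40); ev <- runif(40) < 0.6
  gr <- rep(c("A", "B"), 20)
  km <- logrank_test(tm, ev, gr)$km
  for (g in c("A", "B")) {
    d <- km[km$group == g, ]
    expect_true(all(diff(d$survival) <= 1e-12))
    expect_lte(max(d$survival), 1)
    drops <- d$survival < c(1, head(d$survival, -1)) - 1e-12
    expect_true(all(d$n_event[drops] > 0))
  }
})

test_that("test results are deterministic and print cleanly", {
  a <- c(1.2, 2.3, 3.1, 4.5); b <- c(2.2, 3.3, 4.1, 5.5)
  expect_identical(t_unpaired(a, b), t_unpaired(a, b))
  expect_output(print(t_unpaired(a, b)), "t_unpaired")
  expect_output(print(anova_tukey(c(a, b), rep(c("x", "y"), each = 4))),
                "pairwise")
})
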