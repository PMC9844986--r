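#' @name group_tests
#' @title Statistical battery for group comparisons
#'
#' @description
#' The test suite conventionally applied to T-tubule metrics and crest
#' morphometry: Shapiro-Wilk normality screening, unpaired two-group
#' Student t (equal variance by default, Welch optional), one- and two-way
#' ANOVA with Tukey HSD post hoc comparisons, the two-sided Fisher exact
#' test for 2 x 2 classifications, and the log-rank test with Kaplan-Meier
#' curves for survival. All tests are two-sided and deterministic (no RNG).
#' Each function returns a `crest_test` record with `method`, `statistic`,
#' `p_value` and method-specific detail.
NULL

new_crest_test <- function(method, statistic, p_value, ...) {
  structure(
    c(list(method = method, statistic = unname(statistic),
           p_value = unname(p_value)), list(...)),
    class = "crest_test"
  )
}

#' @export
print.crest_test <- function(x, ...) {
  cat(sprintf("<crest_test> %s: statistic = %.6g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    cat("  Tukey-adjusted pairwise comparisons:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric vector, at least 3 finite values, not all equal.
#' @return a `crest_test` with the W statistic and p-value.
#' @rdname group_tests
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) {
    stop_validation("Shapiro-Wilk needs at least 3 finite values")
  }
  if (sd(values) == 0) {
    stop_validation("Shapiro-Wilk is undefined for a constant sample ",
                    "(zero variance)")
  }
  res <- shapiro.test(values)
  new_crest_test("shapiro_wilk", res$statistic, res$p.value,
                 n = length(values))
}

#' Unpaired two-group t test
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @param welch use the Welch unequal-variance form instead of the pooled
#'   Student form.
#' @return a `crest_test` with t, df, p and the group means.
#' @rdname group_tests
#' @export
t_unpaired <- function(group_a, group_b, welch = FALSE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_validation("each group needs at least 2 finite values")
  }
  res <- t.test(group_a, group_b, var.equal = !welch)
  new_crest_test(if (welch) "t_welch" else "t_unpaired",
                 res$statistic, res$p.value,
                 df = unname(res$parameter),
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 n_a = length(group_a), n_b = length(group_b))
}

#' One- or two-way ANOVA with Tukey HSD
#'
#' One-way when only `factor_a` is given; two-way with interaction
#' (`value ~ A * B`) when `factor_b` is supplied. Tukey HSD adjusted
#' pairwise comparisons run over the levels of `factor_a` (one-way) or
#' over the A:B cell means (two-way); the `pairwise_over` field records
#' which.
#'
#' @param values numeric response.
#' @param factor_a,factor_b grouping factors (>= 2 levels each; two-way
#'   designs must have no empty cell and >= 2 observations per cell).
#' @return a `crest_test`; `statistic`/`p_value` refer to the first
#'   factor's F; `effects` holds the full ANOVA table, `pairwise` the
#'   Tukey comparisons.
#' @rdname group_tests
#' @export
anova_tukey <- function(values, factor_a, factor_b = NULL) {
  factor_a <- factor(factor_a)
  if (length(values) != length(factor_a)) {
    stop_validation("values and factor_a lengths differ")
  }
  if (nlevels(factor_a) < 2L) {
    stop_validation("factor_a needs at least 2 levels")
  }
  if (is.null(factor_b)) {
    d <- data.frame(y = values, A = factor_a)
    fit <- aov(y ~ A, data = d)
    tk <- TukeyHSD(fit)$A
    pairwise_over <- "A"
  } else {
    factor_b <- factor(factor_b)
    if (length(values) != length(factor_b)) {
      stop_validation("values and factor_b lengths differ")
    }
    if (nlevels(factor_b) < 2L) {
      stop_validation("factor_b needs at least 2 levels")
    }
    cell_n <- table(factor_a, factor_b)
    if (any(cell_n == 0)) {
      stop_validation("two-way design has empty cells")
    }
    if (any(cell_n < 2)) {
      stop_validation("two-way design needs >= 2 observations per cell")
    }
    d <- data.frame(y = values, A = factor_a, B = factor_b)
    fit <- aov(y ~ A * B, data = d)
    tk <- TukeyHSD(fit)$`A:B`
    pairwise_over <- "A:B cell means"
  }
  tab <- summary(fit)[[1]]
  eff <- data.frame(
    effect = trimws(rownames(tab)),
    df = tab$Df, F = tab$`F value`, p = tab$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  eff <- eff[eff$effect != "Residuals", ]
  pw <- data.frame(
    comparison = rownames(tk), diff = tk[, "diff"],
    p_adj = tk[, "p adj"], stringsAsFactors = FALSE
  )
  rownames(pw) <- NULL
  new_crest_test(
    if (is.null(factor_b)) "anova1_tukey" else "anova2_tukey",
    eff$F[1], eff$p[1],
    effects = eff, pairwise = pw, pairwise_over = pairwise_over
  )
}

#' Two-sided Fisher exact test on a 2 x 2 table
#'
#' Exact p-value obtained by summing the hypergeometric probabilities of
#' all tables with the observed margins that are no more likely than the
#' observed one.
#'
#' @param table2x2 2 x 2 matrix of nonnegative integer counts.
#' @return a `crest_test`; `statistic` is the conditional odds ratio
#'   estimate.
#' @rdname group_tests
#' @export
fisher_exact <- function(table2x2) {
  if (!is.matrix(table2x2) || !all(dim(table2x2) == 2L)) {
    stop_validation("table2x2 must be a 2 x 2 matrix")
  }
  if (any(!is.finite(table2x2)) || any(table2x2 < 0) ||
      any(abs(table2x2 - round(table2x2)) > 1e-8)) {
    stop_validation("table cells must be nonnegative integers")
  }
  res <- fisher.test(round(table2x2))
  new_crest_test("fisher_exact", unname(res$estimate), res$p.value,
                 table = round(table2x2))
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' Chi-square statistic (1 df) comparing observed vs. expected event
#' counts over the pooled event times, plus the per-group Kaplan-Meier
#' step functions.
#'
#' @param times positive follow-up times.
#' @param events event indicator (TRUE/1 = event, FALSE/0 = censored).
#' @param groups two-level grouping.
#' @return a `crest_test` with `statistic` (chi-square), `p_value`, `df`,
#'   `observed`/`expected` per group, and `km` — a data.frame of the
#'   Kaplan-Meier curves (`group`, `time`, `n_risk`, `n_event`,
#'   `survival`).
#' @rdname group_tests
#' @export
logrank_test <- function(times, events, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) {
    stop_validation("log-rank comparison needs exactly 2 groups")
  }
  if (any(table(groups) == 0)) {
    stop_validation("each group needs at least one subject")
  }
  if (!is.numeric(times) || any(!is.finite(times)) || any(times <= 0)) {
    stop_validation("times must be finite and > 0")
  }
  events <- as.logical(events)
  if (anyNA(events)) stop_validation("events must be TRUE/FALSE")
  d <- data.frame(time = times, event = as.integer(events), group = groups)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  km_fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  km <- data.frame(
    group = rep(sub("^group=", "", names(km_fit$strata)),
                times = km_fit$strata),
    time = km_fit$time, n_risk = km_fit$n.risk, n_event = km_fit$n.event,
    survival = km_fit$surv, stringsAsFactors = FALSE
  )
  new_crest_test("logrank", sd_fit$chisq, p, df = 1,
                 observed = sd_fit$obs, expected = sd_fit$exp, km = km)
}

#' Plot Kaplan-Meier curves from a log-rank result
#'
#' @param x a `crest_test` from [logrank_test()].
#' @param ... passed to [plot()].
#' @export
plot.crest_test <- function(x, ...) {
  if (x$method != "logrank" || is.null(x$km)) {
    stop_validation("plot method is available for logrank results only")
  }
  groups <- unique(x$km$group)
  plot(NA, xlim = c(0, max(x$km$time)), ylim = c(0, 1),
       xlab = "time", ylab = "survival", ...)
  for (i in seq_along(groups)) {
    d <- x$km[x$km$group == groups[i], ]
    lines(c(0, rep(d$time, each = 2)),
          c(1, 1, rep(d$survival, each = 2)[-(2 * nrow(d))]),
          col = i)
  }
  legend("bottomleft", legend = groups, col = seq_along(groups), lty = 1)
  invisible(x)
}
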