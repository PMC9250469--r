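new_test_result <- function(statistic, df, p_value, estimate, method) {
  structure(
    list(statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), estimate = unname(estimate),
         method = method),
    class = "ects_test")
}

#' @export
print.ects_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4f, df = %.4g, p = %.4g, estimate = %.4f\n",
              x$statistic, x$df, x$p_value, x$estimate))
  invisible(x)
}

#' Summarise a numeric vector as n / mean / SD
#'
#' Convenience for feeding raw data into the summary-statistic t-test.
#'
#' @param x numeric vector.
#' @return list with elements `n`, `mean`, `sd`.
#' @export
group_summary <- function(x) {
  x <- x[is.finite(x)]
  list(n = length(x), mean = mean(x), sd = stats::sd(x))
}

as_group_summary <- function(g, arg) {
  if (is.numeric(g)) {
    g <- if (length(g) == 3 && setequal(names(g), c("n", "mean", "sd")))
      as.list(g) else group_summary(g)
  }
  if (!all(c("n", "mean", "sd") %in% names(g)))
    stop(sprintf("'%s' must be a numeric vector or a list with n, mean, sd", arg))
  if (g$n < 2) stop(sprintf("'%s': need n >= 2 per group", arg))
  if (!is.finite(g$sd) || g$sd <= 0)
    stop(sprintf("'%s': degenerate input, SD must be positive", arg))
  g
}

#' Two-sample t-test from raw data or summary statistics
#'
#' Accepts either raw numeric vectors or `list(n=, mean=, sd=)` summaries per
#' group, so printed table statistics (group n, mean, SD) can be re-tested
#' directly. The pooled-variance Student form is the default; Welch
#' (Satterthwaite df) is available via `variant`.
#'
#' @param a,b raw numeric vectors, or lists/named vectors with `n`, `mean`, `sd`.
#' @param variant `"pooled"` (df = n1+n2-2) or `"welch"`.
#' @return an `ects_test` with the t statistic, df, two-sided p, and the mean
#'   difference (a minus b) as the estimate.
#' @export
t_test_two_sample <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as_group_summary(a, "a"); b <- as_group_summary(b, "b")
  d <- a$mean - b$mean
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  tt <- d / se
  new_test_result(tt, df, 2 * stats::pt(-abs(tt), df), d,
                  sprintf("Two-sample t-test (%s)", variant))
}

#' One-sample t-test
#'
#' Used for edge screening: does an edge's Fisher-z FC differ from zero?
#'
#' @param values numeric vector, n >= 2.
#' @param mu0 null value (0 for FC screening).
#' @return an `ects_test`; estimate is `mean(values) - mu0`.
#' @export
t_test_one_sample <- function(values, mu0 = 0) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need n >= 2")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("degenerate input: zero variance")
  tt <- (mean(values) - mu0) / (s / sqrt(n))
  new_test_result(tt, n - 1, 2 * stats::pt(-abs(tt), n - 1), mean(values) - mu0,
                  "One-sample t-test")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Continuity correction is off by default, matching standard software output
#' for group-by-category clinical tables.
#'
#' @param table 2x2 matrix of counts.
#' @param correction apply Yates continuity correction.
#' @return an `ects_test`; estimate is the chi-square statistic.
#' @export
chi_square_2x2 <- function(table, correction = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in table")
  expd <- outer(rs, cs) / n
  dev <- abs(table - expd)
  if (correction) dev <- pmax(dev - 0.5, 0)
  x2 <- sum(dev^2 / expd)
  new_test_result(x2, 1, stats::pchisq(x2, 1, lower.tail = FALSE), x2,
                  if (correction) "Pearson chi-square (Yates)" else "Pearson chi-square")
}

#' Pearson correlation with two-sided p-value
#'
#' p is obtained from t = r * sqrt((n-2)/(1-r^2)) on n-2 df.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-constant.
#' @return an `ects_test`; estimate is r.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0; tt <- sign(r) * Inf
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  new_test_result(tt, n - 2, p, r, "Pearson correlation")
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up q-values plus rejection flags at level `alpha`. The rejection set is
#' invariant to the order of the input vector.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param alpha FDR level for the rejection flags.
#' @return data.frame with columns `p`, `q`, `reject`, in input order.
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, q = q, reject = q < alpha)
}

partial_p <- function(fit) {
  # two-sided p for each non-intercept coefficient (partial F = t^2 on 1 df)
  cf <- stats::summary.lm(fit)$coefficients
  keep <- rownames(cf) != "(Intercept)"
  stats::setNames(cf[keep, "Pr(>|t|)"], rownames(cf)[keep])
}

#' Stepwise multivariate linear regression on partial-F p-values
#'
#' Forward entry / backward removal: at each step the candidate with the
#' smallest entry p-value <= `entry_p` is added (ties broken by p then
#' alphabetical name), then any selected predictor whose p-value in the joint
#' model exceeds `removal_p` is dropped (largest first). Iterates to a fixed
#' point. Candidates nearly collinear with the current model are skipped with
#' a warning. This is the p-value procedure of classical clinical-statistics
#' packages, not AIC-based selection.
#'
#' @param outcome numeric response vector.
#' @param candidates data.frame (or matrix) of numeric candidate predictors.
#' @param entry_p,removal_p entry and removal thresholds.
#' @return list of class `stepwise_model`: `selected_predictors` (ordered by
#'   entry), `coefficients` (final lm coefficients incl. intercept),
#'   `r_squared`, `entry_p`, `removal_p`, and the final `fit`.
#' @export
stepwise_regression <- function(outcome, candidates, entry_p = 0.05,
                                removal_p = 0.10) {
  candidates <- as.data.frame(candidates)
  stopifnot(nrow(candidates) == length(outcome))
  if (length(outcome) <= ncol(candidates) + 1)
    stop("need n > number of candidates + 1")
  dat <- cbind(.y = outcome, candidates)
  selected <- character(0)
  warned <- character(0)
  repeat {
    changed <- FALSE
    # forward entry
    pool <- setdiff(sort(names(candidates)), selected)
    entry <- vapply(pool, function(v) {
      if (length(selected)) {
        r2 <- suppressWarnings(  # perfect-fit warnings are the point here
          summary(stats::lm(stats::reformulate(selected, v), dat))$r.squared)
        if (r2 > 1 - 1e-10) return(NA_real_)  # collinear with current model
      } else if (stats::sd(dat[[v]]) == 0) return(NA_real_)
      fit <- stats::lm(stats::reformulate(c(selected, v), ".y"), dat)
      unname(partial_p(fit)[v])
    }, numeric(1))
    for (v in setdiff(pool[is.na(entry)], warned)) {
      warning(sprintf("candidate '%s' is collinear with the selected set; skipped", v))
      warned <- c(warned, v)
    }
    entry <- entry[!is.na(entry)]
    if (length(entry) && min(entry) <= entry_p) {
      best <- names(entry)[order(entry, names(entry))][1]
      selected <- c(selected, best)
      changed <- TRUE
    }
    # backward removal
    repeat {
      if (!length(selected)) break
      fit <- stats::lm(stats::reformulate(selected, ".y"), dat)
      pp <- partial_p(fit)[selected]
      if (max(pp) > removal_p) {
        worst <- names(pp)[order(-pp, names(pp))][1]
        selected <- setdiff(selected, worst)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- if (length(selected)) stats::lm(stats::reformulate(selected, ".y"), dat)
         else stats::lm(.y ~ 1, dat)
  structure(list(
    selected_predictors = selected,
    coefficients = stats::coef(fit),
    r_squared = if (length(selected)) summary(fit)$r.squared else 0,
    entry_p = entry_p, removal_p = removal_p, fit = fit),
    class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("Stepwise linear model (entry p <=", x$entry_p,
      ", removal p >", x$removal_p, ")\n")
  if (!length(x$selected_predictors)) cat("  (empty model)\n")
  else {
    cat("  selected:", paste(x$selected_predictors, collapse = ", "), "\n")
    cat("  R-squared:", round(x$r_squared, 4), "\n")
  }
  invisible(x)
}
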