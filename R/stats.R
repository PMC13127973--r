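# Association layer: Pearson correlations with Fisher-z intervals, Welch
# t-tests with Cohen's d, the correlation matrix, and moderated regressions.

#' Pearson correlation with Fisher-z confidence interval
#'
#' Pairwise-complete deletion, Pearson r, a 95% CI from the Fisher z
#' transform (`atanh(r) +/- z_{.975}/sqrt(n-3)`), and a two-sided p-value
#' from the t distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors.
#' @param conf Confidence level (default 0.95).
#' @return A `correlation_result`: `r`, `n`, `ci_low`, `ci_high`, `p`.
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("pearson_ci requires at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_ci: zero variance in x or y")
  }
  r <- stats::cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(r = r, n = n, ci_low = tanh(z - q * se),
                 ci_high = tanh(z + q * se), p = p, conf = conf),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r(%d) = %.3f, [%.3f, %.3f], p = %.4g\n",
              x$n - 2L, x$r, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Welch two-sample t-test with Cohen's d
#'
#' Welch statistic with Satterthwaite (fractional) degrees of freedom and a
#' two-sided p-value, plus Cohen's d in its pooled-SD form — the conventional
#' pairing in psychological reporting even alongside the Welch test.
#'
#' @param x,y Numeric vectors (each n >= 2); `NA`s dropped.
#' @return A `ttest_result`: `t`, `df`, `p`, `d`, group sizes and means.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("welch_t requires at least 2 observations per group")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("welch_t: both groups have zero variance")
  }
  res <- stats::t.test(x, y, var.equal = FALSE)
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  structure(list(t = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value, d = (mean(x) - mean(y)) / sp,
                 n_x = nx, n_y = ny,
                 mean_x = mean(x), mean_y = mean(y)),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t(%.2f) = %.3f, p = %.4g, d = %.3f\n", x$df, x$t, x$p, x$d))
  invisible(x)
}

sig_stars <- function(p) {
  ifelse(p < .001, "***", ifelse(p < .01, "**", ifelse(p < .05, "*", "")))
}

#' Correlation matrix with significance markers
#'
#' Pairwise Pearson correlations over the supplied variables, with
#' per-cell sample sizes (pairwise-complete deletion, so n can vary across
#' cells) and significance stars at p < .05 / .01 / .001. Cells involving a
#' constant variable are marked unavailable.
#'
#' @param data Data frame holding the variables.
#' @param variables Ordered character vector of column names (>= 2).
#' @param adjust `"none"` (default, exploratory reporting) or `"holm"` for a
#'   Holm correction across the lower-triangle p-values.
#' @return A `correlation_matrix`: square matrices `r`, `n`, `p`, `stars`.
#' @export
correlation_matrix <- function(data, variables,
                               adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(length(variables) >= 2L, all(variables %in% names(data)))
  k <- length(variables)
  r <- n <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      res <- tryCatch(pearson_ci(data[[variables[i]]], data[[variables[j]]]),
                      error = function(e) NULL)
      if (!is.null(res)) {
        r[i, j] <- res$r; n[i, j] <- res$n; p[i, j] <- res$p
      }
    }
  }
  if (adjust == "holm") {
    low <- lower.tri(p)
    p[low] <- stats::p.adjust(p[low], method = "holm")
    p[upper.tri(p)] <- t(p)[upper.tri(p)]
  }
  stars <- matrix("", k, k, dimnames = dimnames(p))
  stars[!is.na(p)] <- sig_stars(p[!is.na(p)])
  structure(list(r = r, n = n, p = p, stars = stars, variables = variables,
                 adjust = adjust),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  k <- length(x$variables)
  out <- matrix("", k, k, dimnames = list(
    sprintf("%d. %s", seq_len(k), x$variables), sprintf("%d.", seq_len(k))))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i > j && !is.na(x$r[i, j])) {
      out[i, j] <- paste0(formatC(x$r[i, j], digits = digits, format = "f"),
                          x$stars[i, j])
    }
  }
  print(as.data.frame(out[, -k, drop = FALSE]), right = TRUE)
  invisible(x)
}

#' Write a correlation matrix as delimited text
#' @param x A `correlation_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(x, path) {
  k <- length(x$variables)
  rows <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i <= j || is.na(x$r[i, j])) next
    rows[[length(rows) + 1L]] <- data.frame(
      var1 = x$variables[i], var2 = x$variables[j],
      r = x$r[i, j], n = x$n[i, j], p = x$p[i, j],
      stars = x$stars[i, j], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("# correlation matrix (pairwise complete, adjust=%s)",
                     x$adjust), con, useBytes = TRUE)
  write_tsv_con(df, con)
  invisible(path)
}

#' Moderated regression with standardized coefficients
#'
#' Z-standardises the outcome, predictor and moderator on complete cases,
#' forms the product term after standardisation, and fits the OLS model
#' `y ~ x + m + x:m`. The interaction coefficient tests whether the
#' predictor-outcome association depends on the moderator.
#'
#' @param y,x,m Numeric vectors: outcome, predictor, moderator.
#' @param labels Optional names for the three variables (used in the
#'   coefficient table).
#' @return A `moderation_fit`: coefficient data frame (`beta`, `se`, `t`,
#'   `p`, `ci_low`, `ci_high` for x, m and x:m), `n`, `r_squared`.
#' @export
moderated_regression <- function(y, x, m, labels = c("x", "m")) {
  ok <- stats::complete.cases(y, x, m)
  y <- y[ok]; x <- x[ok]; m <- m[ok]
  n <- length(y)
  if (n <= 4L) stop("moderated_regression requires n > 4 complete cases")
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("moderated_regression: zero-variance variable")
    (v - mean(v)) / s
  }
  zy <- zs(y); zx <- zs(x); zm <- zs(m)
  fit <- stats::lm(zy ~ zx + zm + zx:zm)
  if (fit$rank < 4L) stop("moderated_regression: rank-deficient design")
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  terms <- c("zx", "zm", "zx:zm")
  coefs <- data.frame(
    term = c(labels[1], labels[2], paste0(labels[1], ":", labels[2])),
    beta = cf[terms, 1], se = cf[terms, 2], t = cf[terms, 3],
    p = cf[terms, 4], ci_low = ci[terms, 1], ci_high = ci[terms, 2],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, n = n,
                 r_squared = summary(fit)$r.squared),
            class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf("<moderation_fit: n = %d, R^2 = %.3f>\n", x$n, x$r_squared))
  print(x$coefficients, digits = 3)
  invisible(x)
}

# deterministic TSV writer onto an open connection
write_tsv_con <- function(df, con) {
  num <- vapply(df, is.numeric, TRUE)
  for (nm in names(df)[num]) df[[nm]] <- sprintf("%.6g", df[[nm]])
  writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con,
               useBytes = TRUE)
  }
  invisible(con)
}
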