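#' Regression fits used in the storage analysis
#'
#' Thin, df-explicit wrappers around base [lm()] that return a uniform fit
#' record: model kind, coefficients `B0`/`B1`/`B2` as applicable, `R2`, the
#' slope (or overall) F statistic with its numerator/denominator degrees of
#' freedom, and the p value.  Conventions:
#' * through-origin fits report R^2 on the uncorrected total sum of squares
#'   (the standard for no-intercept models) and test the slope with
#'   `df = (1, n - 1)`;
#' * ordinary linear fits test the slope with `df = (1, n - 2)`;
#' * quadratic fits report the coefficients and R^2; with only one residual
#'   degree of freedom the overall F is reported as is, and an exact
#'   interpolation (zero residual df) is flagged.
#'
#' @name regression_fits
NULL

new_pc_fit <- function(kind, coefs, R2, F_stat, dfn, dfd, p, n,
                       flag = NULL) {
  structure(list(kind = kind, coefficients = coefs, R2 = R2,
                 F = F_stat, dfn = dfn, dfd = dfd, p = p, n = n,
                 flag = flag),
            class = "pc_fit")
}

#' @export
print.pc_fit <- function(x, ...) {
  co <- paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
              collapse = ", ")
  pstr <- if (is.na(x$p)) "NA" else if (x$p < 1e-15) "<1e-15" else
    sprintf("%.4g", x$p)
  cat(sprintf("<pc_fit %s> %s\n  R2 = %.4f  F(%d, %d) = %.4g  p = %s\n",
              x$kind, co, x$R2, x$dfn, x$dfd, x$F, pstr))
  if (!is.null(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}

check_xy <- function(x, y, min_n) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < min_n)
    stop(sprintf("need at least %d points", min_n), call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA in regression inputs", call. = FALSE)
}

#' Least-squares line through the origin
#'
#' `Y = B1 X`; slope `sum(xy)/sum(x^2)`, R^2 on uncorrected sums of
#' squares, slope F test with df (1, n - 1).
#'
#' @param x predictor
#' @param y response
#' @return `pc_fit`
#' @export
fit_linear_origin <- function(x, y) {
  check_xy(x, y, 2)
  if (all(x == 0)) stop("degenerate predictor (all zero)", call. = FALSE)
  fit <- lm(y ~ x + 0)
  n <- length(x)
  slope <- unname(coef(fit)[["x"]])
  rss <- sum(fit$residuals^2)
  uss <- sum(y^2)                        # uncorrected total SS
  eps <- 1e-25 * (uss + 1)
  R2 <- if (uss > 0) 1 - rss / uss else 1
  F_stat <- if (rss > eps) slope^2 * sum(x^2) / (rss / (n - 1)) else Inf
  p <- pf(F_stat, 1, n - 1, lower.tail = FALSE)
  new_pc_fit("origin-linear", c(B1 = slope),
             R2, F_stat, 1L, as.integer(n - 1), p, n)
}

#' Ordinary least-squares line with intercept
#'
#' `Y = B0 + B1 X`; slope F test with df (1, n - 2).
#'
#' @inheritParams fit_linear_origin
#' @return `pc_fit`
#' @export
fit_linear <- function(x, y) {
  check_xy(x, y, 3)
  if (stats::sd(x) == 0) stop("degenerate predictor (constant)",
                              call. = FALSE)
  fit <- lm(y ~ x)
  n <- length(x)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  eps <- 1e-25 * (tss + sum(y^2)) + 1e-300
  R2 <- if (tss > 0) 1 - rss / tss else 0
  F_stat <- if (rss > eps) (tss - rss) / (rss / (n - 2))
    else if (tss - rss > eps) Inf else 0
  p <- pf(F_stat, 1, n - 2, lower.tail = FALSE)
  new_pc_fit("linear",
             c(B0 = unname(coef(fit)[1]), B1 = unname(coef(fit)[2])),
             R2, F_stat, 1L, as.integer(n - 2), p, n)
}

#' Least-squares quadratic
#'
#' `Y = B0 + B1 X + B2 X^2`.  With exactly three distinct x values this is
#' an exact interpolation (zero residual df), which is flagged.
#'
#' @inheritParams fit_linear_origin
#' @return `pc_fit`
#' @export
fit_quadratic <- function(x, y) {
  check_xy(x, y, 3)
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct x values", call. = FALSE)
  fit <- lm(y ~ x + I(x^2))
  n <- length(x)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  dfd <- n - 3L
  R2 <- if (tss > 0) 1 - rss / tss else 1
  if (dfd > 0) {
    F_stat <- ((tss - rss) / 2) / (rss / dfd)
    p <- pf(F_stat, 2, dfd, lower.tail = FALSE)
    flag <- NULL
  } else {
    F_stat <- NA_real_; p <- NA_real_
    flag <- "exact interpolation: zero residual df"
    R2 <- 1
  }
  co <- coef(fit)
  new_pc_fit("quadratic",
             c(B0 = unname(co[1]), B1 = unname(co[2]), B2 = unname(co[3])),
             R2, F_stat, 2L, as.integer(max(dfd, 0)), p, n, flag)
}

#' Common-slope intercept-difference test between two groups
#'
#' Compares the common-slope/common-intercept model against the
#' common-slope/two-intercept model by an extra-sum-of-squares F test with
#' df (1, n_total - 3).  A perfect constant offset between groups drives F
#' to infinity; it is reported as `Inf` with p = 0 in that limit.
#'
#' @param x shared predictor (one copy; both groups observed at these x)
#' @param y_a,y_b responses of groups a and b at `x`
#' @return list with `F`, `dfn`, `dfd`, `p`
#' @export
intercept_difference_test <- function(x, y_a, y_b) {
  stopifnot(length(y_a) == length(x), length(y_b) == length(x))
  if (length(x) < 2) stop("need >= 2 points per group", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate predictor", call. = FALSE)
  xx <- c(x, x)
  yy <- c(y_a, y_b)
  grp <- factor(rep(c("a", "b"), each = length(x)))
  full <- lm(yy ~ xx + grp)
  reduced <- lm(yy ~ xx)
  rss_f <- sum(full$residuals^2)
  rss_r <- sum(reduced$residuals^2)
  n <- length(yy)
  dfd <- n - 3L
  ss_diff <- max(rss_r - rss_f, 0)
  eps <- 1e-25 * (sum(yy^2) + 1) # numerically-zero RSS threshold
  F_stat <- if (rss_f > eps) ss_diff / (rss_f / dfd)
    else if (ss_diff > eps) Inf else 0
  p <- if (is.finite(F_stat)) pf(F_stat, 1, dfd, lower.tail = FALSE) else 0
  list(F = F_stat, dfn = 1L, dfd = as.integer(dfd), p = p)
}

#' Pearson product-moment correlation
#'
#' Standard r with the two-sided p value from the t transform.
#'
#' @param x,y numeric vectors (n >= 3, both with nonzero variance)
#' @return list with `r` and `p`
#' @export
pearson <- function(x, y) {
  check_xy(x, y, 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in correlation input", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Format a p value the way the analysis reports it
#'
#' Values below 1e-15 print as "<1e-15".
#' @param p numeric p value
#' @return character
#' @export
format_p <- function(p) {
  ifelse(is.na(p), "NA", ifelse(p < 1e-15, "<1e-15", sprintf("%.4g", p)))
}
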