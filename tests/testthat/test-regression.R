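test_that("through-origin fit matches trivial cases and the oracle", {
  x <- c(20, 40, 60)
  f <- fit_linear_origin(x, 2 * x)
  expect_equal(f$coefficients[["B1"]], 2)
  expect_equal(f$R2, 1)
  expect_identical(c(f$dfn, f$dfd), c(1L, 2L))
  set.seed(3)
  for (k in 1:5) {
    xx <- rnorm(6, 10, 3); yy <- 0.5 * xx + rnorm(6)
    f <- fit_linear_origin(xx, yy)
    o <- oracle_origin_fit(xx, yy)
    expect_equal(f$coefficients[["B1"]], o$slope, tolerance = 1e-12)
    expect_equal(f$R2, o$R2, tolerance = 1e-12)
    expect_equal(f$F, o$F, tolerance = 1e-8)
  }
  expect_error(fit_linear_origin(c(0, 0), c(1, 2)), "degenerate")
})

test_that("ordinary linear fit follows OLS with df (1, n-2)", {
  x <- 1:4
  flat <- fit_linear(x, rep(2, 4))
  expect_equal(flat$coefficients[["B1"]], 0, tolerance = 1e-14)
  expect_lt(flat$F, 1e-20)
  exact <- fit_linear(x, 3 + 2 * x)
  expect_equal(exact$R2, 1)
  expect_lt(exact$p, 0.01)
  expect_identical(c(exact$dfn, exact$dfd), c(1L, 2L))
  # textbook set vs the normal-equations oracle
  xx <- c(1, 2, 3, 5); yy <- c(2.1, 3.9, 6.2, 9.8)
  f <- fit_linear(xx, yy)
  co <- oracle_lm(cbind(1, xx), yy)
  expect_equal(unname(f$coefficients), unname(co), tolerance = 1e-12)
})

test_that("quadratic fit recovers coefficients and flags zero df", {
  x <- c(0, 20, 40, 60)
  f <- fit_quadratic(x, x^2)
  expect_equal(f$coefficients[["B2"]], 1, tolerance = 1e-10)
  expect_equal(f$coefficients[["B0"]], 0, tolerance = 1e-8)
  expect_equal(f$coefficients[["B1"]], 0, tolerance = 1e-9)
  set.seed(5)
  xx <- runif(6, 0, 10); yy <- 1 + 0.5 * xx - 0.2 * xx^2 + rnorm(6, 0, 0.1)
  f2 <- fit_quadratic(xx, yy)
  expect_equal(unname(f2$coefficients), unname(oracle_quadratic_fit(xx, yy)),
               tolerance = 1e-10)
  f3 <- fit_quadratic(c(1, 2, 3), c(2, 5, 10))
  expect_equal(f3$R2, 1)
  expect_identical(f3$dfd, 0L)
  expect_match(f3$flag, "zero residual df")
  expect_error(fit_quadratic(c(1, 1, 2), 1:3), "distinct")
})

test_that("intercept-difference test isolates a constant offset", {
  x <- c(0, 20, 40, 60)
  same <- intercept_difference_test(x, 1 + 0.1 * x, 1 + 0.1 * x)
  expect_lt(same$F, 1e-16)
  offset <- intercept_difference_test(x, 1 + 0.1 * x, 3 + 0.1 * x)
  expect_identical(offset$F, Inf)
  expect_identical(offset$p, 0)
  expect_identical(c(offset$dfn, offset$dfd), c(1L, 5L))
  set.seed(9)
  ya <- 1 + 0.1 * x + rnorm(4, 0, 0.05)
  yb <- 2 + 0.1 * x + rnorm(4, 0, 0.05)
  got <- intercept_difference_test(x, ya, yb)
  expect_equal(got$F, oracle_intercept_F(x, ya, yb), tolerance = 1e-8)
})

test_that("Pearson correlation handles the exact and degenerate cases", {
  x <- seq(1, 10)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_error(pearson(x, rep(1, 10)), "variance")
  set.seed(13)
  a <- rnorm(50); b <- a + rnorm(50, 0, 0.3)
  got <- pearson(a, b)
  expect_equal(got$r, cor(a, b), tolerance = 1e-12)
  expect_gt(got$r, 0.9)
})

test_that("fits are order-invariant and affine-equivariant", {
  set.seed(21)
  x <- c(0, 20, 40, 60); y <- 1 + 0.05 * x + rnorm(4, 0, 0.2)
  perm <- c(3, 1, 4, 2)
  f1 <- fit_linear(x, y); f2 <- fit_linear(x[perm], y[perm])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  expect_equal(f1$F, f2$F, tolerance = 1e-10)
  fshift <- fit_linear(x, y + 7)
  expect_equal(fshift$coefficients[["B1"]], f1$coefficients[["B1"]],
               tolerance = 1e-12)
  expect_equal(fshift$coefficients[["B0"]], f1$coefficients[["B0"]] + 7,
               tolerance = 1e-12)
  q1 <- fit_quadratic(x, y); q2 <- fit_quadratic(x[perm], y[perm])
  expect_equal(q1$coefficients, q2$coefficients, tolerance = 1e-10)
})

test_that("df bookkeeping reproduces the reported design patterns", {
  # 3 agitated rpm values through the origin -> (1, 2)
  f1 <- fit_linear_origin(c(20, 40, 60), c(0.03, 0.07, 0.09))
  expect_identical(c(f1$dfn, f1$dfd), c(1L, 2L))
  # 4 rpm values with intercept -> (1, 2)
  f2 <- fit_linear(c(0, 20, 40, 60), c(1, 2, 2.5, 2.4))
  expect_identical(c(f2$dfn, f2$dfd), c(1L, 2L))
  # 3 rpm values with intercept -> (1, 1)
  f3 <- fit_linear(c(20, 40, 60), c(1, 2, 2.5))
  expect_identical(c(f3$dfn, f3$dfd), c(1L, 1L))
  # two groups over 4 shared x -> (1, 5)
  f4 <- intercept_difference_test(c(0, 20, 40, 60),
                                  c(1, 1.1, 1.2, 1.15),
                                  c(2, 2.1, 2.2, 2.18))
  expect_identical(c(f4$dfn, f4$dfd), c(1L, 5L))
})

test_that("p values format with the underflow convention", {
  expect_identical(format_p(1e-20), "<1e-15")
  expect_identical(format_p(0.049), "0.049")
  expect_identical(format_p(NA_real_), "NA")
})
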