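test_that("OLS recovers exact linear data and matches the normal equations", {
  # exact data: y = 2 x1 - x2 + 3
  tab <- rand_table(12, 2, seed = 21)
  y <- 2 * tab[, 1] - tab[, 2] + 3
  m <- fit_ols(tab, setNames(y, rownames(tab)))
  expect_equal(unname(m$coefficients), c(2, -1), tolerance = 1e-10)
  expect_equal(m$intercept, 3, tolerance = 1e-10)

  # random 20 x 3 problem against the explicit (X'X)^-1 X'y oracle
  tab <- rand_table(20, 3, seed = 22)
  y <- setNames(rnorm(20, 4.6, 0.4), rownames(tab))
  m <- fit_ols(tab, y)
  beta <- oracle_ols(unclass(tab), unname(y[rownames(tab)]))
  expect_equal(c(m$intercept, unname(m$coefficients)), unname(beta),
               tolerance = 1e-8)

  # residuals orthogonal to every regressor
  res <- y - predict(m, tab)
  expect_equal(max(abs(crossprod(cbind(1, unclass(tab)), res))), 0,
               tolerance = 1e-8)
})

test_that("degenerate and collinear designs fail loudly", {
  tab <- rand_table(4, 3, seed = 1)  # n = p + 1
  expect_error(fit_ols(tab, setNames(rnorm(4), rownames(tab))),
               "n > p \\+ 1")
  m <- unclass(rand_table(15, 2, seed = 2))
  m <- cbind(m, dup = m[, 1] + m[, 2])
  expect_error(fit_ols(descriptor_table(m),
                       setNames(rnorm(15), rownames(m))),
               "rank deficient.*dup")
})

test_that("prediction is name-matched and linear in each descriptor", {
  m <- hct116_model()
  zero <- descriptor_table(matrix(0, 1, 5,
                                  dimnames = list("z", m$descriptors)))
  expect_equal(unname(predict(m, zero)), 6.319854761)
  bump <- unclass(zero)
  bump[1, "nS"] <- 1
  expect_equal(unname(predict(m, descriptor_table(bump))) -
                 unname(predict(m, zero)), -0.124851343)
  # shuffled column order gives identical predictions
  tab <- rand_table(6, 5, seed = 30)
  colnames(tab) <- m$descriptors
  shuffled <- descriptor_table(unclass(tab)[, c(3, 1, 5, 2, 4)])
  expect_equal(predict(m, tab), predict(m, shuffled))
  expect_error(predict(m, rand_table(3, 2, seed = 1)), "missing")
})

test_that("ANOVA assembly reproduces mean squares, F and the identity", {
  # from published regression statistics of the bundled model
  tab <- anova_from_ss(2.349644479, 5, 0.8268128, 19)
  expect_equal(tab$ms[2], 0.043516463, tolerance = 1e-8)
  expect_equal(tab$f[1], 10.79888, tolerance = 1e-3)
  expect_equal(tab$ss[3], 3.176457278, tolerance = 1e-9)
  expect_lt(tab$p_value[1], 5.1e-5)

  # identity SS_tot = SS_reg + SS_res on random fitted problems
  for (seed in 1:5) {
    tabX <- rand_table(18, 3, seed = seed)
    y <- setNames(rnorm(18, 4.5, 0.5), rownames(tabX))
    m <- fit_ols(tabX, y)
    a <- anova_table(m, tabX, y)
    ss_reg_direct <- sum((predict(m, tabX) - mean(y))^2)
    expect_equal(a$ss[1], ss_reg_direct, tolerance = 1e-9 * a$ss[3])
    expect_equal(a$ss[1] + a$ss[2], a$ss[3], tolerance = 1e-9 * a$ss[3])
    expect_equal(a$df[1] + a$df[2], a$df[3])
    expect_equal(a$f[1], a$ms[1] / a$ms[2])
    # R2 from SS equals squared correlation of fitted vs observed
    r2 <- 1 - a$ss[2] / a$ss[3]
    expect_equal(r2, cor(predict(m, tabX), y)^2, tolerance = 1e-9)
  }

  # a perfect fit has zero residual SS and collapses the F test
  tabX <- rand_table(10, 2, seed = 99)
  y <- setNames(1.5 * tabX[, 1] + 4.8, rownames(tabX))
  m <- fit_ols(tabX, y)
  a <- anova_table(m, tabX, y)
  expect_equal(a$ss[2], 0, tolerance = 1e-18)
  expect_gt(a$f[1], 1e10)           # only rounding noise left
  expect_lt(a$p_value[1], 1e-15)
  # an exactly zero residual SS collapses the F test outright
  a0 <- anova_from_ss(3, 5, 0, 19)
  expect_identical(a0$f[1], Inf)
  expect_identical(a0$p_value[1], 0)
})

test_that("adjusted R2 follows the size-penalized formula", {
  expect_equal(r2_adjusted(0.7397, 25, 5), 0.6712, tolerance = 1e-4)
  expect_equal(r2_adjusted(1, 20, 3), 1)
  expect_equal(r2_adjusted(0.5, 11, 4), 1 - 0.5 * 10 / 6,
               tolerance = 1e-12)
  expect_error(r2_adjusted(0.9, 6, 5), "n > p \\+ 1")
})

test_that("standardized residuals use the RMS residual scale", {
  tab <- rand_table(10, 2, seed = 44)
  y <- setNames(rnorm(10, 4.5, 0.3), rownames(tab))
  m <- fit_ols(tab, y)
  sr <- standardized_residuals(m, tab, y)
  res <- y - predict(m, tab)
  s <- sqrt(sum(res^2) / (10 - 2 - 1))
  expect_equal(sr, res / s, tolerance = 1e-12)
  expect_equal(sign(sr), sign(res))
  expect_equal(mean(sr), 0, tolerance = 1e-10)

  # perfect fit: all zeros
  y2 <- setNames(2 * tab[, 1] + 1, rownames(tab))
  m2 <- fit_ols(tab, y2)
  expect_equal(unname(standardized_residuals(m2, tab, y2)), rep(0, 10))
})

test_that("predict after fit reproduces the fitted values exactly", {
  tab <- rand_table(16, 4, seed = 50)
  y <- setNames(rnorm(16, 4.5, 0.4), rownames(tab))
  m <- fit_ols(tab, y)
  fs <- fit_summary(m, tab, y)
  expect_identical(fs$fitted, predict(m, tab))
  expect_lte(fs$r2_adj, fs$r2)
})
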