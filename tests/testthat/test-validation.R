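test_that("leave-one-out Q2 matches the explicit refit oracle", {
  tab <- rand_table(15, 3, seed = 61)
  y <- setNames(rnorm(15, 4.6, 0.4), rownames(tab))
  expect_equal(q2_loo(tab, y),
               oracle_q2_loo(unclass(tab), unname(y[rownames(tab)])),
               tolerance = 1e-9)

  # noise-free linear data predicts perfectly out of the fold
  y2 <- setNames(0.5 * tab[, 1] - tab[, 2] + 4.5, rownames(tab))
  expect_equal(q2_loo(tab, y2), 1, tolerance = 1e-9)

  expect_error(q2_loo(tab, setNames(rep(4.5, 15), rownames(tab))),
               "constant activity")
  small <- rand_table(5, 3, seed = 1)  # n = p + 2 exactly
  expect_error(q2_loo(small, setNames(rnorm(5), rownames(small))),
               "n > p \\+ 2")
})

test_that("Q2 never exceeds R2 on the same training data", {
  for (seed in 1:8) {
    tab <- rand_table(15, 3, seed = seed)
    y <- setNames(rnorm(15, 4.6, 0.4) + 0.3 * tab[, 1], rownames(tab))
    m <- fit_ols(tab, y)
    fs <- fit_summary(m, tab, y)
    expect_lte(q2_loo(tab, y), fs$r2)
  }
})

test_that("external R2 measures predictivity against the training mean", {
  expect_equal(r2_external(c(5, 4.5, 4), c(5, 4.5, 4), 4.4), 1)
  expect_equal(r2_external(c(5, 4.5, 4), rep(4.4, 3), 4.4), 0)
  # 3-point toy: numerator 0.03, denominator 0.36 + 0.01 + 0.16 = 0.53
  expect_equal(r2_external(c(5.0, 4.5, 4.0), c(4.9, 4.6, 4.1), 4.4),
               1 - 0.03 / 0.53, tolerance = 1e-12)
  expect_error(r2_external(numeric(0), numeric(0), 4.4), "empty")
  expect_error(r2_external(c(4.4, 4.4), c(4, 4), 4.4), "undefined")
  expect_error(r2_external(c(5, 4), 4.5, 4.4), "length")
})

test_that("VIF is the diagonal of the inverse correlation matrix", {
  # exactly orthogonal columns
  u <- c(1, 1, -1, -1)
  v <- c(1, -1, 1, -1)
  orth <- descriptor_table(cbind(u = u, v = v),
                           compound_ids = letters[1:4])
  expect_equal(unname(vif(orth)), c(1, 1), tolerance = 1e-12)

  # two columns at r = 0.7 exactly: closed form 1 / (1 - 0.49)
  set.seed(123)
  a <- scale(rnorm(50))[, 1]
  b <- scale(residuals(lm(rnorm(50) ~ a)))[, 1]
  x2 <- 0.7 * a + sqrt(1 - 0.49) * b  # cor(a, x2) == 0.7 by construction
  tab <- descriptor_table(cbind(a = a, x2 = x2),
                          compound_ids = sprintf("c%02d", 1:50))
  expect_equal(unname(vif(tab)), rep(1 / (1 - 0.49), 2),
               tolerance = 1e-9)

  # random 20 x 4: equals the auxiliary-regression oracle
  tab4 <- rand_table(20, 4, seed = 71)
  expect_equal(unname(vif(tab4)), oracle_vif(unclass(tab4)),
               tolerance = 1e-9)
  expect_true(all(vif(tab4) >= 1))

  # affine rescaling of a column leaves VIF unchanged
  m <- unclass(tab4)
  m[, 2] <- 100 * m[, 2] - 7
  expect_equal(unname(vif(descriptor_table(m))), unname(vif(tab4)),
               tolerance = 1e-9)

  dup <- cbind(unclass(tab4), d5 = unclass(tab4)[, 1])
  expect_error(vif(descriptor_table(dup)), "singular|collinear")
  expect_error(vif(rand_table(10, 1, seed = 1)), "at least 2")
})

test_that("mean effects are beta-weighted column-sum fractions summing to 1", {
  # single descriptor: trivially 1
  m1 <- linear_model("a", 2, 0)
  tab1 <- descriptor_table(cbind(a = c(1, 2, 3)),
                           compound_ids = c("x", "y", "z"))
  expect_equal(unname(mean_effect(m1, tab1)), 1)

  # hand toy: beta = (1, 2, -1), column sums (4, 1, 2)
  tab3 <- descriptor_table(rbind(c(4, 1, 2), c(0, 0, 0)),
                           compound_ids = c("r1", "r2"),
                           descriptor_names = c("a", "b", "c"))
  m3 <- linear_model(c("a", "b", "c"), c(1, 2, -1), 0)
  expect_equal(unname(mean_effect(m3, tab3)), c(4, 2, -2) / 4,
               tolerance = 1e-12)

  # symmetry: equal betas, equal column sums
  tabs <- descriptor_table(cbind(a = c(1, 3), b = c(3, 1)),
                           compound_ids = c("x", "y"))
  ms <- linear_model(c("a", "b"), c(1.5, 1.5), 0)
  expect_equal(unname(mean_effect(ms, tabs)), c(0.5, 0.5))

  # sums to 1 on every fitted model
  for (seed in 1:5) {
    tab <- rand_table(14, 3, seed = seed)
    y <- setNames(rnorm(14, 4.5, 0.4), rownames(tab))
    m <- fit_ols(tab, y)
    expect_equal(sum(mean_effect(m, tab)), 1, tolerance = 1e-9)
  }
})

test_that("the benchmark gate applies the standard inclusive thresholds", {
  v <- benchmark_gate(0.7397, 0.6712, 0.5547, 0.7202)
  expect_true(attr(v, "overall"))
  expect_true(all(v$pass))

  v2 <- benchmark_gate(0.5, 0.5, 0.5, 0.5)
  expect_false(v2$pass[v2$criterion == "r2"])
  expect_false(attr(v2, "overall"))

  v3 <- benchmark_gate(0.6, 0.6, 0.5, 0.6)  # boundary: >= is inclusive
  expect_true(attr(v3, "overall"))
  expect_error(benchmark_gate(NA, 0.6, 0.5, 0.6), "finite")
})

test_that("descriptor diagnostics agree with a reference lm fit", {
  tab <- rand_table(20, 3, seed = 81)
  y <- setNames(rnorm(20, 4.5, 0.3) + 0.4 * tab[, 2], rownames(tab))
  m <- fit_ols(tab, y)
  d <- descriptor_diagnostics(m, tab, y)
  ref <- summary(lm(y ~ ., data = as.data.frame(unclass(tab))))$coefficients
  expect_equal(d$coefficient, unname(ref[-1, "Estimate"]),
               tolerance = 1e-9)
  expect_equal(d$t_stat, unname(ref[-1, "t value"]), tolerance = 1e-9)
  expect_equal(d$p_value, unname(ref[-1, "Pr(>|t|)"]), tolerance = 1e-9)
  expect_equal(d$std_error, unname(ref[-1, "Std. Error"]),
               tolerance = 1e-9)
  expect_equal(sum(d$mean_effect), 1, tolerance = 1e-9)
  expect_true(all(d$vif >= 1))
})

test_that("a full validation report assembles consistently", {
  gen <- generate_qsar_data(synthetic_spec(seed = 10))
  ds <- apply_split(
    qsar_dataset(pretreat(gen$dataset$table)$table, gen$dataset$pic50),
    ks_split(pretreat(gen$dataset$table)$table, 0.7))
  train <- subset_membership(ds, "train")
  test <- subset_membership(ds, "test")
  m <- fit_ols(train$table, train$pic50, gen$ground_truth$informative)
  rep <- validation_report(m, train, test)
  expect_equal(rep$r2, 1 - rep$anova$ss[2] / rep$anova$ss[3],
               tolerance = 1e-12)
  expect_equal(rep$r2_adj, r2_adjusted(rep$r2, 25, 5), tolerance = 1e-12)
  expect_equal(rep$q2_cv,
               q2_loo(train$table, train$pic50, m$descriptors),
               tolerance = 1e-12)
  expect_identical(attr(rep$verdict, "overall"), all(rep$verdict$pass))
})
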