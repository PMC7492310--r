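test_that("constant filter drops exactly the low-variance columns", {
  set.seed(42)
  n <- 30
  vals <- cbind(k0 = rep(2, n),
                k1 = 2 + rnorm(n, sd = sqrt(1e-9) / 2),
                k2 = rnorm(n, sd = sqrt(0.5)),
                k3 = rnorm(n, sd = sqrt(2)),
                k4 = rnorm(n, sd = sqrt(3)))
  # rescale columns to the exact target variances {0, 1e-9, 0.5, 2, 3}
  target <- c(0, 1e-9, 0.5, 2, 3)
  for (j in 2:5) {
    vals[, j] <- (vals[, j] - mean(vals[, j])) /
      sd(vals[, j]) * sqrt(target[j])
  }
  tab <- descriptor_table(vals, compound_ids = sprintf("c%02d", 1:n))
  out <- remove_constant(tab, variance_tol = 1e-8)
  expect_equal(out$report$survivors, c("k2", "k3", "k4"))
  expect_equal(out$report$dropped_constant, c("k0", "k1"))
  expect_equal(ncol(out$table), 3L)

  # strictly increasing column survives at tol 0
  inc <- descriptor_table(cbind(a = 1:10, b = rep(1, 10)),
                          compound_ids = letters[1:10])
  expect_equal(remove_constant(inc, 0)$report$survivors, "a")
  expect_warning(remove_constant(descriptor_table(
    cbind(z = rep(1, 5)), compound_ids = letters[1:5])), "constant")
})

test_that("correlation filter keeps first-seen columns and honors cutoff", {
  set.seed(7)
  x <- rnorm(40)
  tab <- descriptor_table(cbind(a = x, b = x, c = rnorm(40)),
                          compound_ids = sprintf("c%02d", 1:40))
  out <- correlation_filter(tab, 0.7)
  expect_equal(out$report$survivors, c("a", "c"))  # duplicate 'b' dropped
  expect_equal(out$report$dropped_correlated$dropped, "b")
  expect_equal(out$report$dropped_correlated$kept, "a")
  expect_equal(out$report$dropped_correlated$abs_r, 1)

  # exactly orthogonal pair both kept
  u <- c(1, 1, -1, -1)
  v <- c(1, -1, 1, -1)
  orth <- descriptor_table(cbind(u = u, v = v),
                           compound_ids = letters[1:4])
  expect_equal(correlation_filter(orth, 0.7)$report$survivors, c("u", "v"))

  expect_error(correlation_filter(tab, 0), "\\(0, 1\\]")
  expect_error(correlation_filter(tab, 1.2), "\\(0, 1\\]")
})

test_that("greedy scan result matches a brute-force pairwise audit", {
  # 4-column toy with hand-computable correlation structure
  set.seed(11)
  z <- rnorm(60)
  tab <- descriptor_table(
    cbind(p = z,
          q = 0.9 * z + sqrt(1 - 0.81) * rnorm(60),  # r(p,q) ~ 0.9
          r = rnorm(60),
          s = 0.2 * z + rnorm(60)),
    compound_ids = sprintf("c%02d", 1:60))
  out <- correlation_filter(tab, 0.7)
  m <- unclass(out$table)
  cm <- abs(cor(m))
  diag(cm) <- 0
  expect_lte(max(cm), 0.7)  # no surviving pair above the cutoff
  # every dropped column does exceed the cutoff with its recorded keeper
  rep <- out$report$dropped_correlated
  for (i in seq_len(nrow(rep))) {
    expect_gt(abs(cor(unclass(tab)[, rep$dropped[i]],
                      unclass(tab)[, rep$kept[i]])), 0.7)
  }
})

test_that("pretreatment is idempotent, order-preserving, and partitions", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 25
    base <- matrix(rnorm(n * 4), n, 4)
    vals <- cbind(base,
                  base + matrix(rnorm(n * 4, sd = 0.3), n, 4),
                  rep(1, n))
    colnames(vals) <- sprintf("v%02d", 1:9)
    tab <- descriptor_table(vals, compound_ids = sprintf("c%02d", 1:n))
    out <- pretreat(tab, cutoff = 0.7)
    # survivors ∪ dropped = original, disjoint
    all_names <- c(out$report$survivors, out$report$dropped_constant,
                   out$report$dropped_correlated$dropped)
    expect_setequal(all_names, colnames(vals))
    expect_equal(anyDuplicated(all_names), 0L)
    # survivor order preserves input order
    expect_equal(out$report$survivors,
                 colnames(vals)[colnames(vals) %in% out$report$survivors])
    # idempotence
    again <- pretreat(out$table, cutoff = 0.7)
    expect_equal(again$report$survivors, out$report$survivors)
    expect_equal(nrow(again$report$dropped_correlated), 0L)
    # post-condition audit
    cm <- abs(cor(unclass(out$table)))
    diag(cm) <- 0
    expect_lte(max(cm), 0.7)
  }
})

test_that("correlation filter refuses constant columns", {
  tab <- descriptor_table(cbind(a = 1:5, b = rep(2, 5)),
                          compound_ids = letters[1:5])
  expect_error(correlation_filter(tab), "remove_constant")
})
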