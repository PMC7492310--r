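# Independent brute-force oracles used to check the package's linear
# algebra and search code. Deliberately naive implementations.

# random descriptor table
rand_table <- function(n, p, seed) {
  set.seed(seed)
  descriptor_table(matrix(rnorm(n * p), n, p,
                          dimnames = list(sprintf("c%02d", seq_len(n)),
                                          sprintf("x%02d", seq_len(p)))))
}

# explicit normal-equations OLS: (A'A)^-1 A'y with intercept column
oracle_ols <- function(X, y) {
  A <- cbind(1, as.matrix(X))
  drop(solve(t(A) %*% A) %*% t(A) %*% y)
}

# explicit hat-matrix diagonal / cross-leverages
oracle_leverage <- function(Xt, Xq = Xt) {
  A <- cbind(1, as.matrix(Xt))
  B <- cbind(1, as.matrix(Xq))
  diag(B %*% solve(t(A) %*% A) %*% t(B))
}

# leave-one-out Q2 by n explicit refits
oracle_q2_loo <- function(X, y) {
  X <- as.matrix(X)
  press <- 0
  for (i in seq_along(y)) {
    A <- cbind(1, X[-i, , drop = FALSE])
    beta <- solve(t(A) %*% A) %*% t(A) %*% y[-i]
    pred <- drop(c(1, X[i, ]) %*% beta)
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# VIF_j as 1 / (1 - R2_j) from regressing column j on the others
oracle_vif <- function(X) {
  X <- as.matrix(X)
  vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    1 / (1 - summary(fit)$r.squared)
  }, numeric(1))
}

# brute-force Kennard-Stone maxmin selection (row indices, pick order)
oracle_ks_order <- function(m, k) {
  z <- scale(as.matrix(m))
  d <- as.matrix(dist(z))
  n <- nrow(d)
  best <- c(Inf, NA, NA)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d[i, j] > -best[1]) best <- c(-d[i, j], i, j)
  }
  picked <- c(best[2], best[3])
  while (length(picked) < k) {
    rest <- setdiff(seq_len(n), picked)
    mind <- vapply(rest, function(r) min(d[r, picked]), numeric(1))
    picked <- c(picked, rest[which.max(mind)])
  }
  picked
}

# exhaustive best-LOF subset of a fixed size
oracle_best_subset <- function(X, y, L, d = 0.5) {
  X <- as.matrix(X)
  n <- nrow(X)
  combos <- utils::combn(ncol(X), L)
  lofs <- apply(combos, 2, function(idx) {
    A <- cbind(1, X[, idx, drop = FALSE])
    res <- y - A %*% solve(t(A) %*% A) %*% t(A) %*% y
    friedman_lof(sum(res^2), n, L + 1, d, L)
  })
  list(idx = combos[, which.min(lofs)], lof = min(lofs))
}
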