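test_that("the lack-of-fit score follows the size-penalized formula", {
  expect_equal(friedman_lof(0, 25, 6, 0.5, 5), 0)
  # hand arithmetic: (1/25) / (1 - 8.5/25)^2
  expect_equal(friedman_lof(1, 25, 6, 0.5, 5), 0.04 / 0.4356,
               tolerance = 1e-12)
  # monotone in the residual SS at fixed sizes
  lofs <- vapply(seq(0.1, 2, by = 0.1),
                 function(ss) friedman_lof(ss, 25, 6, 0.5, 5), numeric(1))
  expect_true(all(diff(lofs) > 0))
  # overfit configurations are rejected
  expect_error(friedman_lof(1, 10, 8, 0.5, 7), "denominator")
  expect_error(friedman_lof(1, 25, 6, -1, 5), "smoothness")
  expect_error(friedman_lof(-1, 25, 6, 0.5, 5), "ss_res")
})

test_that("the GFA search is seeded, deterministic and well-formed", {
  tab <- rand_table(20, 12, seed = 120)
  y <- setNames(4.5 + 0.5 * tab[, 3] - 0.4 * tab[, 7] +
                  rnorm(20, 0, 0.1), rownames(tab))
  cfg <- gfa_config(equation_length = 3, population_size = 20,
                    generations = 15, seed = 5)
  r1 <- gfa_search(tab, y, cfg)
  r2 <- gfa_search(tab, y, cfg)
  expect_identical(r1$ranking, r2$ranking)
  expect_identical(r1$best, r2$best)

  # every ranked subset has exactly equation_length distinct descriptors
  subsets <- strsplit(r1$ranking$subset, ",")
  expect_true(all(vapply(subsets, length, integer(1)) == 3))
  expect_true(all(vapply(subsets,
                         function(s) anyDuplicated(s) == 0, logical(1))))
  # ranking is sorted ascending by LOF, no duplicate subsets
  expect_true(!is.unsorted(r1$ranking$lof))
  expect_equal(anyDuplicated(r1$ranking$subset), 0L)
  # elitism: the best LOF never worsens across generations
  expect_true(all(diff(r1$generation_log) <= 1e-12))
})

test_that("GFA converges to the exhaustive optimum on small pools", {
  hits <- 0
  n_seeds <- 100
  tab <- rand_table(20, 10, seed = 121)
  X <- unclass(tab)
  set.seed(200)
  y <- setNames(4.5 + 0.4 * X[, 2] - 0.3 * X[, 8] + rnorm(20, 0, 0.3),
                rownames(X))
  best <- oracle_best_subset(X, unname(y), 2)
  for (seed in seq_len(n_seeds)) {
    cfg <- gfa_config(equation_length = 2, population_size = 30,
                      generations = 20, seed = seed)
    r <- gfa_search(tab, y, cfg)
    if (abs(r$ranking$lof[1] - best$lof) <= 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("GFA recovers planted descriptors from a pretreated pool", {
  hits <- 0
  n_runs <- 50
  for (seed in seq_len(n_runs)) {
    gen <- generate_qsar_data(synthetic_spec(n_descriptors = 50,
                                             seed = seed))
    pre <- pretreat(gen$dataset$table)
    split <- ks_split(pre$table, 0.7)
    ds <- apply_split(qsar_dataset(pre$table, gen$dataset$pic50), split)
    train <- subset_membership(ds, "train")
    r <- gfa_search(train$table, train$pic50,
                    gfa_config(seed = seed))
    found <- length(intersect(r$best, gen$ground_truth$informative))
    if (found >= 4) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.9)
})

test_that("the selected model dominates single-descriptor fits on toy data", {
  tab <- rand_table(22, 8, seed = 130)
  X <- unclass(tab)
  set.seed(131)
  y <- setNames(4.5 + 0.5 * X[, 1] + 0.5 * X[, 5] + rnorm(22, 0, 0.05),
                rownames(X))
  r <- gfa_search(tab, y, gfa_config(equation_length = 2,
                                     population_size = 30,
                                     generations = 20, seed = 1))
  best_r2 <- r$ranking$r2[1]
  single <- vapply(seq_len(8), function(j) {
    summary(lm(y ~ X[, j]))$r.squared
  }, numeric(1))
  expect_gte(best_r2, max(single))
})

test_that("GFA validates its inputs", {
  tab <- rand_table(10, 4, seed = 1)
  y <- setNames(rnorm(10), rownames(tab))
  expect_error(gfa_search(tab, y, gfa_config(equation_length = 5)),
               "pool")
  tall <- rand_table(10, 8, seed = 2)
  y10 <- setNames(rnorm(10), rownames(tall))
  expect_error(gfa_search(tall, y10, gfa_config(equation_length = 8,
                                                population_size = 10)),
               "n_train - 2|too large")
  expect_error(gfa_config(crossover_prob = 1.5), "probabilities")
  expect_error(gfa_config(equation_length = 0), ">= 1")
})
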