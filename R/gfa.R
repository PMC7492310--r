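#' Friedman lack-of-fit score
#'
#' The size-penalized residual score used as the genetic-function-algorithm
#' fitness: `LOF = (SS_res / n) / (1 - (c + d * p) / n)^2`, where c is the
#' number of model terms (descriptors plus intercept), p the number of
#' descriptors, and d a smoothness factor that sharpens the penalty for
#' larger models. Smaller is better; overfit configurations where the
#' penalty denominator vanishes are rejected.
#'
#' @param ss_res residual sum of squares (activity units squared).
#' @param n number of training compounds.
#' @param n_terms number of model terms c (descriptors + intercept).
#' @param d smoothness factor, > 0; default 0.5.
#' @param p_total number of descriptors p in the model.
#' @return the lack-of-fit score.
#' @export
friedman_lof <- function(ss_res, n, n_terms, d = 0.5, p_total) {
  if (d <= 0) stop("smoothness factor `d` must be > 0", call. = FALSE)
  if (ss_res < 0) stop("`ss_res` must be >= 0", call. = FALSE)
  pen <- 1 - (n_terms + d * p_total) / n
  if (pen <= 0) {
    stop("model too large for n = ", n,
         " compounds: lack-of-fit penalty denominator <= 0", call. = FALSE)
  }
  (ss_res / n) / pen^2
}

#' Genetic-function-algorithm configuration
#'
#' @param equation_length number of descriptors per candidate model;
#'   default 5, the size of the bundled published model.
#' @param population_size,generations GA size parameters; defaults 100/100.
#' @param crossover_prob,mutation_prob per-pair crossover and per-gene
#'   mutation probabilities; defaults 0.85/0.05.
#' @param lof_smoothness the Friedman LOF `d` factor; default 0.5.
#' @param seed integer seed; the search is fully reproducible for a fixed
#'   seed.
#' @return a `gfa_config` list.
#' @export
gfa_config <- function(equation_length = 5, population_size = 100,
                       generations = 100, crossover_prob = 0.85,
                       mutation_prob = 0.05, lof_smoothness = 0.5,
                       seed = 1) {
  if (crossover_prob < 0 || crossover_prob > 1 ||
      mutation_prob < 0 || mutation_prob > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (equation_length < 1) stop("`equation_length` must be >= 1",
                                call. = FALSE)
  if (lof_smoothness <= 0) stop("`lof_smoothness` must be > 0",
                                call. = FALSE)
  structure(list(equation_length = as.integer(equation_length),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 lof_smoothness = lof_smoothness,
                 seed = as.integer(seed)),
            class = "gfa_config")
}

#' Genetic-function-algorithm descriptor-subset search
#'
#' Evolves a population of fixed-length descriptor subsets under the
#' Friedman lack-of-fit fitness: uniform-random initialization, size-2
#' tournament selection, single-point crossover on sorted index lists with
#' repair of duplicate genes, per-gene mutation to a random unused
#' descriptor, and elitism of the best individual (so the best LOF is
#' non-increasing across generations). Each subset is scored by an OLS fit
#' of activity on its descriptors.
#'
#' @param table pretreated training [descriptor_table()].
#' @param pic50 training activity, named or in row order.
#' @param config a [gfa_config()].
#' @return a `gfa_result`: list with `ranking` (data.frame of the
#'   deduplicated final population, best LOF first, with columns `subset`
#'   (comma-joined names), `lof`, `r2`), `best` (character vector of the
#'   best subset's descriptor names), and `generation_log` (best LOF per
#'   generation).
#' @export
gfa_search <- function(table, pic50, config = gfa_config()) {
  stopifnot(inherits(config, "gfa_config"))
  X <- design_matrix(table)
  y <- align_activity(X, pic50)
  n <- nrow(X)
  p_pool <- ncol(X)
  L <- config$equation_length
  if (p_pool < L) {
    stop("descriptor pool (", p_pool, ") smaller than equation length (",
         L, ")", call. = FALSE)
  }
  if (L >= n - 2L) {
    stop("`equation_length` must be < n_train - 2", call. = FALSE)
  }
  pen <- (1 - (L + 1 + config$lof_smoothness * L) / n)
  if (pen <= 0) {
    stop("equation length too large for ", n, " training compounds",
         call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)

  cache <- new.env(hash = TRUE, parent = emptyenv())
  score <- function(idx) {
    key <- paste(idx, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fit <- stats::.lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
    ss_res <- sum(fit$residuals^2)
    out <- c(lof = friedman_lof(ss_res, n, L + 1L, config$lof_smoothness,
                                L),
             r2 = 1 - ss_res / ss_tot)
    cache[[key]] <- out
    out
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  npop <- config$population_size
  pop <- lapply(seq_len(npop), function(i) sort(sample.int(p_pool, L)))
  fitness <- vapply(pop, function(g) score(g)[["lof"]], numeric(1))
  log_best <- numeric(config$generations)

  mutate <- function(g) {
    flip <- stats::runif(L) < config$mutation_prob
    if (any(flip)) {
      free <- setdiff(seq_len(p_pool), g)
      for (k in which(flip)) {
        if (length(free) == 0) break
        pick <- free[sample.int(length(free), 1L)]
        free <- c(setdiff(free, pick), g[k])
        g[k] <- pick
      }
      g <- sort(g)
    }
    g
  }
  repair <- function(child) {
    child <- unique(child)
    if (length(child) < L) {
      free <- setdiff(seq_len(p_pool), child)
      child <- c(child, free[sample.int(length(free), L - length(child))])
    }
    sort(child)
  }
  tournament <- function() {
    pair <- sample.int(npop, 2L)
    if (fitness[pair[1]] <= fitness[pair[2]]) pair[1] else pair[2]
  }

  for (gen in seq_len(config$generations)) {
    elite <- which.min(fitness)
    newpop <- vector("list", npop)
    newpop[[1]] <- pop[[elite]]
    i <- 2L
    while (i <= npop) {
      pa <- pop[[tournament()]]
      pb <- pop[[tournament()]]
      if (stats::runif(1) < config$crossover_prob && L > 1L) {
        cut <- sample.int(L - 1L, 1L)
        ca <- repair(c(pa[seq_len(cut)], pb[(cut + 1L):L]))
        cb <- repair(c(pb[seq_len(cut)], pa[(cut + 1L):L]))
      } else {
        ca <- pa
        cb <- pb
      }
      newpop[[i]] <- mutate(ca)
      if (i + 1L <= npop) newpop[[i + 1L]] <- mutate(cb)
      i <- i + 2L
    }
    pop <- newpop
    fitness <- vapply(pop, function(g) score(g)[["lof"]], numeric(1))
    log_best[gen] <- min(fitness)
  }

  keys <- vapply(pop, paste, character(1), collapse = ",")
  uniq <- !duplicated(keys)
  pop <- pop[uniq]
  fitness <- fitness[uniq]
  ord <- order(fitness)
  ranking <- data.frame(
    subset = vapply(pop[ord], function(g)
      paste(colnames(X)[g], collapse = ","), character(1)),
    lof = fitness[ord],
    r2 = vapply(pop[ord], function(g) score(g)[["r2"]], numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(ranking = ranking,
                 best = colnames(X)[pop[[ord[1]]]],
                 generation_log = log_best,
                 config = config),
            class = "gfa_result")
}

#' @export
print.gfa_result <- function(x, ...) {
  cat(sprintf("<gfa_result> best LOF = %.6g (R2 = %.4f): %s\n",
              x$ranking$lof[1], x$ranking$r2[1], x$ranking$subset[1]))
  invisible(x)
}
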