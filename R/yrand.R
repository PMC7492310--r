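#' Y-randomization robustness coefficient
#'
#' `cRp2 = R * sqrt(R^2 - Rr_bar^2)` where R and R^2 belong to the original
#' model and `Rr_bar` is the arithmetic mean of the correlation
#' coefficients of the randomized models. A value above 0.5 indicates the
#' original fit is not explicable by chance correlation.
#'
#' @param r_original correlation coefficient of the original model.
#' @param r2_original coefficient of determination of the original model.
#' @param random_rs numeric vector of R values from the randomized refits.
#' @return cRp2, or `NA` (with a warning) when the radicand is negative —
#'   the chance models beat the original, i.e. the model is not robust.
#' @export
c_rp2 <- function(r_original, r2_original, random_rs) {
  if (length(random_rs) < 1) {
    stop("need at least one randomized-model R value", call. = FALSE)
  }
  rbar <- mean(random_rs)
  rad <- r2_original - rbar^2
  if (rad < 0) {
    warning("mean randomized R exceeds the original model's fit; ",
            "cRp2 undefined (model not robust)", call. = FALSE)
    return(NA_real_)
  }
  r_original * sqrt(rad)
}

# internal: (R, R2, Q2) of an OLS fit of y on X
fit_stats <- function(X, y) {
  model <- fit_ols(X, y)
  fitted <- predict(model, X)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - sum((y - fitted)^2) / ss_tot
  r <- sign(stats::cor(fitted, y)) * sqrt(max(r2, 0))
  c(R = r, R2 = r2, Q2 = q2_loo(X, y))
}

#' Y-randomization test
#'
#' Refits the fixed descriptor set against row-permuted activity to build
#' a chance baseline. Scrambling the response against the descriptor rows
#' is the same disruption as shuffling the descriptor rows against a fixed
#' response, and gives identical OLS statistics. For each permutation the
#' correlation coefficient R (signed by the fitted-vs-observed
#' correlation), R-squared and leave-one-out Q2 are recorded; the summary
#' reports their means and the cRp2 robustness coefficient.
#'
#' @param table descriptor table restricted to the model's columns (or use
#'   `descriptors`).
#' @param pic50 activity vector.
#' @param n_permutations number of randomized refits; default 10.
#' @param seed integer seed for the permutation stream (required: the test
#'   is only meaningful if reproducible).
#' @param descriptors optional column restriction.
#' @return a `yrand_result`: list with `original` (named R/R2/Q2),
#'   `randoms` (data.frame, one row per permutation), `avg_r`, `avg_r2`,
#'   `avg_q2` and `c_rp2`.
#' @export
y_randomize <- function(table, pic50, n_permutations = 10, seed,
                        descriptors = NULL) {
  if (missing(seed)) {
    stop("`seed` is required for a reproducible Y-randomization test",
         call. = FALSE)
  }
  if (n_permutations < 1) {
    stop("`n_permutations` must be >= 1", call. = FALSE)
  }
  X <- design_matrix(table, descriptors)
  y <- align_activity(X, pic50)
  original <- fit_stats(X, y)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))
  randoms <- t(vapply(seq_len(n_permutations), function(k) {
    fit_stats(X, stats::setNames(sample(y), names(y)))
  }, numeric(3)))
  randoms <- as.data.frame(randoms)
  structure(list(original = original,
                 randoms = randoms,
                 avg_r = mean(randoms$R),
                 avg_r2 = mean(randoms$R2),
                 avg_q2 = mean(randoms$Q2),
                 c_rp2 = c_rp2(original[["R"]], original[["R2"]],
                               randoms$R),
                 seed = as.integer(seed)),
            class = "yrand_result")
}

#' @export
print.yrand_result <- function(x, ...) {
  cat(sprintf("<yrand_result> original R2 = %.4f, Q2 = %.4f\n",
              x$original[["R2"]], x$original[["Q2"]]))
  cat(sprintf("  %d permutations: mean R = %.4f, mean R2 = %.4f, cRp2 = %s\n",
              nrow(x$randoms), x$avg_r, x$avg_r2,
              if (is.na(x$c_rp2)) "undefined" else sprintf("%.4f", x$c_rp2)))
  invisible(x)
}

#' Write a Y-randomization result as CSV
#'
#' Emits the original model row, one row per randomized model, and the
#' summary rows (average R, average R2, average Q2, cRp2).
#'
#' @param result a `yrand_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_yrand_csv <- function(result, path) {
  rows <- data.frame(
    Model = c("Original", paste("Random", seq_len(nrow(result$randoms))),
              "Average R", "Average R2", "Average Q2", "cRp2"),
    R = c(result$original[["R"]], result$randoms$R, result$avg_r,
          NA, NA, NA),
    R2 = c(result$original[["R2"]], result$randoms$R2, NA, result$avg_r2,
           NA, NA),
    Q2 = c(result$original[["Q2"]], result$randoms$Q2, NA, NA,
           result$avg_q2, NA),
    cRp2 = c(rep(NA, 1 + nrow(result$randoms) + 3), result$c_rp2),
    stringsAsFactors = FALSE)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Published Y-randomization reference table
#'
#' The Y-randomization record of the bundled HCT116 imidazol-5-one model:
#' the original model's (R, R2, Q2) and the ten randomized-model rows, as
#' published. Useful for checking the cRp2 arithmetic against a known
#' result.
#'
#' @return data.frame with columns `Model`, `R`, `R2`, `Q2`.
#' @export
yrand_reference <- function() {
  utils::read.csv(system.file("extdata", "yrand_reference.csv",
                              package = "qsarpipe", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
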