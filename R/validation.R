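#' Leave-one-out cross-validated R-squared (Q2)
#'
#' `Q2 = 1 - PRESS / SS_tot`, where PRESS is the sum of squared
#' leave-one-out prediction errors. The LOO errors are obtained through the
#' hat-matrix identity `e_i / (1 - h_ii)`, which is algebraically equal to
#' refitting the model n times without each compound.
#'
#' @param table descriptor table holding the model columns.
#' @param pic50 activity vector, named or in row order.
#' @param descriptors optional column restriction, as in [fit_ols()].
#' @return Q2 (dimensionless, at most 1; can be negative).
#' @export
q2_loo <- function(table, pic50, descriptors = NULL) {
  X <- design_matrix(table, descriptors)
  y <- align_activity(X, pic50)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 2L) {
    stop("leave-one-out validation needs n > p + 2", call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("constant activity: Q2 undefined", call. = FALSE)
  }
  model <- fit_ols(X, y)
  h <- leverages(X)
  near_one <- which(1 - h < 1e-10)
  if (length(near_one) > 0) {
    stop("leave-one-out fit is rank deficient when omitting compound '",
         rownames(X)[near_one[1]], "' (leverage ~ 1)", call. = FALSE)
  }
  e <- y - predict(model, X)
  press <- sum((e / (1 - h))^2)
  1 - press / ss_tot
}

#' External coefficient of determination
#'
#' Test-set predictivity measured against the training-mean baseline:
#' `R2_ext = 1 - sum((y_exp - y_pred)^2) / sum((y_exp - ybar_train)^2)`.
#' A model that merely predicts the training mean for every test compound
#' scores 0; perfect predictions score 1.
#'
#' @param y_exp_test observed test-set pIC50.
#' @param y_pred_test predicted test-set pIC50 (same order).
#' @param ybar_train mean of the training-set experimental pIC50.
#' @return external R-squared.
#' @export
r2_external <- function(y_exp_test, y_pred_test, ybar_train) {
  if (length(y_exp_test) == 0) {
    stop("test set is empty", call. = FALSE)
  }
  if (length(y_exp_test) != length(y_pred_test)) {
    stop("observed and predicted test vectors differ in length",
         call. = FALSE)
  }
  denom <- sum((y_exp_test - ybar_train)^2)
  if (denom == 0) {
    stop("test activities all equal the training mean: R2_ext undefined",
         call. = FALSE)
  }
  1 - sum((y_exp_test - y_pred_test)^2) / denom
}

#' Variance inflation factors
#'
#' Collinearity diagnostic: the leading diagonal of the inverse of the
#' Pearson correlation matrix of the model's descriptor columns.
#' Equivalently `1 / (1 - R2_j)` where `R2_j` regresses descriptor j on the
#' others. Orthogonal descriptors give VIF = 1; values above ~4-5 signal a
#' descriptor that is largely explained by the rest.
#'
#' @param table descriptor table (>= 2 non-constant columns).
#' @param descriptors optional column restriction.
#' @return named numeric vector of VIF values, each >= 1.
#' @export
vif <- function(table, descriptors = NULL) {
  X <- design_matrix(table, descriptors)
  if (ncol(X) < 2L) {
    stop("VIF needs at least 2 descriptors", call. = FALSE)
  }
  if (any(apply(X, 2, stats::var) == 0)) {
    stop("constant descriptor column: correlation undefined", call. = FALSE)
  }
  C <- stats::cor(X)
  inv <- tryCatch(solve(C), error = function(e) {
    stop("correlation matrix is singular: descriptors are exactly ",
         "collinear", call. = FALSE)
  })
  stats::setNames(diag(inv), colnames(X))
}

#' Mean effect of each descriptor
#'
#' Signed fractional contribution of descriptor j to the predicted
#' activity over the training set:
#' `ME_j = beta_j * sum_i(x_ij) / sum_k(beta_k * sum_i(x_ik))`.
#' Mean effects sum to 1; a descriptor with |ME| near 0 contributes little
#' to the predictions even if its coefficient is large.
#'
#' @param model a [linear_model()].
#' @param table training descriptor table.
#' @return named numeric vector of mean effects summing to 1.
#' @export
mean_effect <- function(model, table) {
  X <- design_matrix(table, model$descriptors)
  contrib <- model$coefficients * colSums(X)
  denom <- sum(contrib)
  if (denom == 0) {
    stop("total descriptor contribution is zero: mean effects undefined",
         call. = FALSE)
  }
  contrib / denom
}

#' Per-descriptor diagnostics table
#'
#' For each descriptor in the model: coefficient, mean effect, VIF, and the
#' OLS coefficient t statistic, two-sided p-value and standard error from
#' refitting on the supplied training data.
#'
#' @param model a [linear_model()].
#' @param table training descriptor table.
#' @param pic50 training activity.
#' @return data.frame with columns `descriptor`, `coefficient`,
#'   `mean_effect`, `vif`, `t_stat`, `p_value`, `std_error`.
#' @export
descriptor_diagnostics <- function(model, table, pic50) {
  X <- design_matrix(table, model$descriptors)
  y <- align_activity(X, pic50)
  fit <- stats::lm(y ~ ., data = as.data.frame(X))
  coefs <- summary(fit)$coefficients[-1, , drop = FALSE]
  data.frame(descriptor = model$descriptors,
             coefficient = unname(model$coefficients),
             mean_effect = unname(mean_effect(model, X)),
             vif = unname(vif(X)),
             t_stat = unname(coefs[, "t value"]),
             p_value = unname(coefs[, "Pr(>|t|)"]),
             std_error = unname(coefs[, "Std. Error"]),
             stringsAsFactors = FALSE)
}

#' Benchmark gate for model acceptability
#'
#' Checks the four standard QSAR validation metrics against the
#' conventional acceptance thresholds: R2 >= 0.6, adjusted R2 >= 0.6,
#' leave-one-out Q2 >= 0.5 and external R2 >= 0.6 (all inclusive).
#'
#' @param r2,r2_adj,q2_cv,r2_ext the four metrics.
#' @return a `benchmark_verdict`: data.frame of (criterion, value,
#'   threshold, pass) with an `overall` attribute that is TRUE iff every
#'   criterion passes.
#' @export
benchmark_gate <- function(r2, r2_adj, q2_cv, r2_ext) {
  vals <- c(r2 = r2, r2_adj = r2_adj, q2_cv = q2_cv, r2_ext = r2_ext)
  if (any(!is.finite(vals))) {
    stop("all four metrics must be finite", call. = FALSE)
  }
  thresholds <- c(r2 = 0.6, r2_adj = 0.6, q2_cv = 0.5, r2_ext = 0.6)
  out <- data.frame(criterion = names(vals),
                    value = unname(vals),
                    threshold = unname(thresholds),
                    pass = unname(vals >= thresholds),
                    stringsAsFactors = FALSE)
  attr(out, "overall") <- all(out$pass)
  class(out) <- c("benchmark_verdict", "data.frame")
  out
}

#' @export
print.benchmark_verdict <- function(x, ...) {
  print.data.frame(x)
  cat("overall:", if (attr(x, "overall")) "PASS" else "FAIL", "\n")
  invisible(x)
}

#' Full validation report for a train/test division
#'
#' Convenience wrapper producing the complete validation picture of a
#' fitted model: ANOVA, fit summary, Q2, external R2, per-descriptor
#' diagnostics and the benchmark verdict.
#'
#' @param model a [linear_model()] fitted on the training rows.
#' @param train,test [qsar_dataset()]s for the two membership classes.
#' @return a `validation_report` list.
#' @export
validation_report <- function(model, train, test) {
  stopifnot(inherits(train, "qsar_dataset"), inherits(test, "qsar_dataset"))
  fs <- fit_summary(model, train$table, train$pic50)
  q2 <- q2_loo(train$table, train$pic50, model$descriptors)
  r2e <- r2_external(test$pic50, predict(model, test$table),
                     mean(train$pic50))
  structure(list(anova = fs$anova,
                 r2 = fs$r2,
                 r2_adj = fs$r2_adj,
                 q2_cv = q2,
                 r2_ext = r2e,
                 diagnostics = descriptor_diagnostics(model, train$table,
                                                      train$pic50),
                 standardized_residuals = fs$standardized_residuals,
                 verdict = benchmark_gate(fs$r2, fs$r2_adj, q2, r2e)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> R2 = %.4f, R2adj = %.4f, Q2 = %.4f, ",
              x$r2, x$r2_adj, x$q2_cv))
  cat(sprintf("R2ext = %.4f -> %s\n", x$r2_ext,
              if (attr(x$verdict, "overall")) "PASS" else "FAIL"))
  invisible(x)
}
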