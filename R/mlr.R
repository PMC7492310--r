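# internal: model matrix for a set of descriptor columns, with checks
design_matrix <- function(table, descriptors = NULL) {
  m <- if (inherits(table, "descriptor_table")) desc_matrix(table)
       else as.matrix(table)
  if (!is.null(descriptors)) {
    missing <- setdiff(descriptors, colnames(m))
    if (length(missing) > 0) {
      stop("descriptor(s) missing from table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    m <- m[, descriptors, drop = FALSE]
  }
  m
}

# internal: align an activity vector to a descriptor matrix by id
align_activity <- function(m, y) {
  if (!is.null(names(y)) && !is.null(rownames(m))) {
    if (!setequal(names(y), rownames(m)) || length(y) != nrow(m)) {
      stop("activity ids do not match descriptor table ids", call. = FALSE)
    }
    y <- y[rownames(m)]
  } else if (length(y) != nrow(m)) {
    stop("activity length does not match number of compounds",
         call. = FALSE)
  }
  y
}

#' Fit an ordinary least-squares multilinear regression
#'
#' Fits `pIC50 ~ descriptors` by OLS with an intercept (always included:
#' QSAR regression equations carry one). The design matrix is checked for
#' rank deficiency and ill-conditioning before fitting — a condition number
#' above `1e10` on the column-scaled design is treated as singular and the
#' dependent columns are named, rather than silently pseudo-inverting.
#'
#' @param table a [descriptor_table()] (or numeric matrix) holding the
#'   model's descriptor columns.
#' @param pic50 numeric activity vector, named by compound id or in row
#'   order.
#' @param descriptors optional character vector restricting (and ordering)
#'   the columns used; default: all columns of `table`.
#' @return a [linear_model()] with fitting provenance in `metadata`.
#' @export
fit_ols <- function(table, pic50, descriptors = NULL) {
  X <- design_matrix(table, descriptors)
  y <- align_activity(X, pic50)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1L) {
    stop("need n > p + 1 observations to fit and test ", p,
         " descriptors; got n = ", n, call. = FALSE)
  }
  A <- cbind(`(Intercept)` = 1, X)
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A)) {
    dep <- colnames(A)[qr_A$pivot[(qr_A$rank + 1L):ncol(A)]]
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  As <- A
  As[, -1] <- scale(A[, -1, drop = FALSE])
  if (any(!is.finite(As))) {
    stop("design matrix is rank deficient; dependent column(s): ",
         paste(colnames(X)[apply(X, 2, stats::var) == 0], collapse = ", "),
         call. = FALSE)
  }
  sv <- svd(As, nu = 0, nv = 0)$d
  if (max(sv) / min(sv) > 1e10) {
    stop("design matrix is numerically singular ",
         "(condition number > 1e10)", call. = FALSE)
  }
  fit <- stats::lm.fit(A, y)
  beta <- fit$coefficients
  linear_model(colnames(X), beta[-1], beta[1],
               metadata = list(n_train = n,
                               fitted_on = paste(rownames(X),
                                                 collapse = ",")))
}

#' One-way ANOVA decomposition of a fitted model
#'
#' Decomposes the total sum of squares of the observed activity (about its
#' mean) into the regression and residual components, with the F statistic
#' and its upper-tail p-value.
#'
#' @param model a [linear_model()] fitted on this data.
#' @param table descriptor table covering the model's descriptors.
#' @param pic50 observed activity, named or in row order.
#' @return an `anova_table`: data.frame rows Regression/Residual/Total with
#'   columns `df`, `ss`, `ms`, `f`, `p_value`.
#' @export
anova_table <- function(model, table, pic50) {
  X <- design_matrix(table, model$descriptors)
  y <- align_activity(X, pic50)
  fitted <- predict(model, X)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_reg <- ss_tot - ss_res
  anova_from_ss(ss_reg, length(model$descriptors), ss_res,
                length(y) - length(model$descriptors) - 1L)
}

#' Assemble an ANOVA table from sums of squares
#'
#' Useful for checking published regression statistics: given the printed
#' regression/residual sums of squares and degrees of freedom, rebuilds the
#' mean squares, F statistic and p-value.
#'
#' @param ss_regression,ss_residual sums of squares (activity units
#'   squared).
#' @param df_regression,df_residual degrees of freedom.
#' @return an `anova_table` data.frame; a zero residual SS yields
#'   `f = Inf`, `p_value = 0`.
#' @export
anova_from_ss <- function(ss_regression, df_regression, ss_residual,
                          df_residual) {
  if (df_residual <= 0) {
    stop("residual degrees of freedom must be positive", call. = FALSE)
  }
  ms_reg <- ss_regression / df_regression
  ms_res <- ss_residual / df_residual
  if (ss_residual <= 0) {
    f <- Inf
    p <- 0
  } else {
    f <- ms_reg / ms_res
    p <- stats::pf(f, df_regression, df_residual, lower.tail = FALSE)
  }
  out <- data.frame(
    source = c("Regression", "Residual", "Total"),
    df = c(df_regression, df_residual, df_regression + df_residual),
    ss = c(ss_regression, ss_residual, ss_regression + ss_residual),
    ms = c(ms_reg, ms_res, NA_real_),
    f = c(f, NA_real_, NA_real_),
    p_value = c(p, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)`, penalizing R-squared for model
#' size.
#'
#' @param r2 coefficient of determination.
#' @param n number of training compounds.
#' @param p number of descriptors in the model.
#' @return adjusted R-squared.
#' @export
r2_adjusted <- function(r2, n, p) {
  if (n <= p + 1) {
    stop("adjusted R2 requires n > p + 1", call. = FALSE)
  }
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Standardized residuals of a fitted model
#'
#' Raw residual divided by the root mean square residual error
#' `s = sqrt(SS_res / df_residual)`. Used for the systematic-error scatter
#' plot and the Williams applicability-domain plot.
#'
#' @inheritParams anova_table
#' @return named numeric vector, one value per compound.
#' @export
standardized_residuals <- function(model, table, pic50) {
  X <- design_matrix(table, model$descriptors)
  y <- align_activity(X, pic50)
  res <- y - predict(model, X)
  df_res <- length(y) - length(model$descriptors) - 1L
  if (df_res <= 0) {
    stop("no residual degrees of freedom", call. = FALSE)
  }
  s <- sqrt(sum(res^2) / df_res)
  # an exact fit leaves only rounding noise: report zeros, not noise/noise
  if (s <= 1e-10 * max(1, mean(abs(y)))) {
    return(stats::setNames(rep(0, length(res)), names(res)))
  }
  res / s
}

#' Training-fit summary
#'
#' R-squared (from the ANOVA decomposition), adjusted R-squared, fitted
#' values and standardized residuals of a model on its training data.
#'
#' @inheritParams anova_table
#' @return a `fit_summary` list: `r2`, `r2_adj`, `fitted`,
#'   `standardized_residuals`, `anova`.
#' @export
fit_summary <- function(model, table, pic50) {
  X <- design_matrix(table, model$descriptors)
  y <- align_activity(X, pic50)
  tab <- anova_table(model, X, y)
  ss_res <- tab$ss[2]
  ss_tot <- tab$ss[3]
  if (ss_tot == 0) {
    stop("constant activity: total sum of squares is zero", call. = FALSE)
  }
  r2 <- 1 - ss_res / ss_tot
  structure(list(r2 = r2,
                 r2_adj = r2_adjusted(r2, length(y),
                                      length(model$descriptors)),
                 fitted = predict(model, X),
                 standardized_residuals =
                   standardized_residuals(model, X, y),
                 anova = tab),
            class = "fit_summary")
}

#' @export
print.fit_summary <- function(x, ...) {
  cat(sprintf("<fit_summary> R2 = %.4f, R2adj = %.4f, F = %.4f (p = %.3g)\n",
              x$r2, x$r2_adj, x$anova$f[1], x$anova$p_value[1]))
  invisible(x)
}
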