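#' Leverage of compounds with respect to a training design
#'
#' The leverage of a descriptor row x is `h = x' (X'X)^-1 x` with
#' intercept-augmented rows, where X is the intercept-augmented training
#' design. Training self-leverages are the hat-matrix diagonal and sum to
#' p + 1; query leverages can exceed 1 for points far outside the training
#' space.
#'
#' @param train training descriptor table (full rank with intercept).
#' @param query optional table of rows to evaluate; default: the training
#'   rows themselves. Must contain the same descriptor columns (matched by
#'   name).
#' @return named numeric vector of leverages.
#' @export
leverages <- function(train, query = NULL) {
  Xt <- design_matrix(train)
  miss_names <- is.null(colnames(Xt))
  Xq <- if (is.null(query)) Xt else {
    q <- if (inherits(query, "descriptor_table")) desc_matrix(query)
         else as.matrix(query)
    if (!miss_names) {
      missing <- setdiff(colnames(Xt), colnames(q))
      if (length(missing) > 0) {
        stop("query is missing training descriptor column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      q <- q[, colnames(Xt), drop = FALSE]
    }
    q
  }
  A <- cbind(1, Xt)
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A)) {
    stop("training design matrix is rank deficient", call. = FALSE)
  }
  M <- chol2inv(qr.R(qr_A))
  B <- cbind(1, Xq)
  h <- rowSums((B %*% M) * B)
  stats::setNames(as.numeric(h), rownames(Xq))
}

#' Warning leverage
#'
#' The conventional Williams-plot threshold `h* = 3 (p + 1) / n`, where p
#' is the number of descriptors and n the number of training compounds.
#'
#' @param p number of descriptors in the model.
#' @param n number of training compounds.
#' @return the warning leverage.
#' @export
warning_leverage <- function(p, n) {
  if (n <= 0 || p < 0) stop("need n > 0 and p >= 0", call. = FALSE)
  3 * (p + 1) / n
}

#' Williams applicability-domain analysis
#'
#' Pairs every compound's leverage with its standardized residual and
#' flags whether it falls inside the model's applicability domain:
#' `h <= h*` and `|standardized residual| <= residual_band`. Query
#' (test or designed) compounds are standardized on the training residual
#' scale; compounds with no observed activity (e.g. designed candidates)
#' get `NA` residuals and are judged on leverage alone.
#'
#' @param model a [linear_model()] fitted on `train`.
#' @param train training [qsar_dataset()].
#' @param query optional [qsar_dataset()] (or [descriptor_table()]) of
#'   additional compounds to place on the plot.
#' @param residual_band half-width of the acceptable standardized-residual
#'   band, in standard units; default 3, the usual Williams-plot
#'   convention.
#' @return an `ad_result`: data.frame (id, membership, leverage,
#'   std_residual, inside_domain) with attributes `h_star` and
#'   `residual_band`.
#' @export
williams <- function(model, train, query = NULL, residual_band = 3) {
  stopifnot(inherits(train, "qsar_dataset"))
  Xt <- design_matrix(train$table, model$descriptors)
  y <- train$pic50
  res <- y - predict(model, Xt)
  df_res <- length(y) - length(model$descriptors) - 1L
  if (df_res <= 0) stop("no residual degrees of freedom", call. = FALSE)
  s <- sqrt(sum(res^2) / df_res)
  if (s <= 1e-10 * max(1, mean(abs(y)))) s <- 0  # exact fit
  h_star <- warning_leverage(length(model$descriptors), nrow(Xt))

  rows <- data.frame(id = rownames(Xt), membership = "train",
                     leverage = unname(leverages(Xt)),
                     std_residual = if (s > 0) unname(res) / s else
                       rep(0, length(res)),
                     stringsAsFactors = FALSE)
  if (!is.null(query)) {
    if (inherits(query, "qsar_dataset")) {
      Xq <- design_matrix(query$table, model$descriptors)
      qres <- query$pic50 - predict(model, Xq)
      qstd <- if (s > 0) unname(qres) / s else rep(0, length(qres))
      qmem <- unname(query$membership)
    } else {
      Xq <- design_matrix(query, model$descriptors)
      qstd <- rep(NA_real_, nrow(Xq))
      qmem <- rep("query", nrow(Xq))
    }
    rows <- rbind(rows,
                  data.frame(id = rownames(Xq), membership = qmem,
                             leverage = unname(leverages(Xt, Xq)),
                             std_residual = qstd,
                             stringsAsFactors = FALSE))
  }
  rows$inside_domain <- rows$leverage <= h_star &
    (is.na(rows$std_residual) | abs(rows$std_residual) <= residual_band)
  attr(rows, "h_star") <- h_star
  attr(rows, "residual_band") <- residual_band
  class(rows) <- c("ad_result", "data.frame")
  rows
}

#' @export
print.ad_result <- function(x, ...) {
  cat(sprintf("<ad_result> h* = %.4f, band = +/-%g; %d/%d inside domain\n",
              attr(x, "h_star"), attr(x, "residual_band"),
              sum(x$inside_domain), nrow(x)))
  invisible(x)
}
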