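#' Pair a descriptor table with an activity series
#'
#' Joins a [descriptor_table()] with a named pIC50 vector by compound id
#' (order-insensitive: CSV row order is not contractually stable). The two
#' must cover identical id sets. An optional membership label records the
#' train/test division.
#'
#' @param table a [descriptor_table()].
#' @param pic50 named numeric vector of pIC50 values covering the same ids.
#' @param membership optional character vector (named by id or in table row
#'   order) with values `"train"`, `"test"` or `"unassigned"`.
#' @return an object of class `qsar_dataset`: a list with elements `table`,
#'   `pic50` (reordered to the table's rows) and `membership`.
#' @export
qsar_dataset <- function(table, pic50, membership = NULL) {
  stopifnot(inherits(table, "descriptor_table"))
  ids <- rownames(table)
  if (is.null(names(pic50)) || !setequal(names(pic50), ids) ||
      length(pic50) != length(ids)) {
    stop("activity ids must match the descriptor table's compound ids ",
         "exactly", call. = FALSE)
  }
  if (any(!is.finite(pic50))) {
    stop("pIC50 values must be finite", call. = FALSE)
  }
  pic50 <- pic50[ids]
  if (is.null(membership)) {
    membership <- rep("unassigned", length(ids))
  } else {
    if (!is.null(names(membership))) membership <- membership[ids]
    membership <- as.character(membership)
    if (length(membership) != length(ids) ||
        !all(membership %in% c("train", "test", "unassigned"))) {
      stop("membership must label every compound as 'train', 'test' or ",
           "'unassigned'", call. = FALSE)
    }
  }
  names(membership) <- ids
  structure(list(table = table, pic50 = pic50, membership = membership),
            class = "qsar_dataset")
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat("<qsar_dataset> ", nrow(x$table), " compounds, ", ncol(x$table),
      " descriptors; pIC50 range [",
      sprintf("%.3f", min(x$pic50)), ", ",
      sprintf("%.3f", max(x$pic50)), "]\n", sep = "")
  cat("membership:", paste(sprintf("%s=%d", names(table(x$membership)),
                                   table(x$membership)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Restrict a dataset to one membership class
#'
#' @param dataset a [qsar_dataset()].
#' @param role `"train"`, `"test"` or `"unassigned"`.
#' @return a [qsar_dataset()] containing only the requested compounds.
#' @export
subset_membership <- function(dataset, role = c("train", "test",
                                                "unassigned")) {
  role <- match.arg(role)
  keep <- names(dataset$membership)[dataset$membership == role]
  if (length(keep) == 0) {
    stop("no compounds labelled '", role, "'", call. = FALSE)
  }
  tab <- descriptor_table(desc_matrix(dataset$table)[keep, , drop = FALSE])
  qsar_dataset(tab, dataset$pic50[keep], dataset$membership[keep])
}
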