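#' Kennard-Stone train/test division
#'
#' Deterministic maxmin-distance selection of a representative training
#' set. The first two picks are the pair of compounds at maximal Euclidean
#' distance; every subsequent pick is the compound whose minimum distance
#' to the already-picked set is largest. The remaining compounds form the
#' test set.
#'
#' Distances are computed on autoscaled (zero-mean, unit-variance)
#' descriptors so that large-magnitude descriptors do not dominate the
#' metric — the common Kennard-Stone convention. The training size is
#' `floor(train_fraction * n)` with a minimum of 2; ties in distance are
#' broken by the lower row index, so identical input always yields an
#' identical split.
#'
#' @param table a [descriptor_table()] with at least 3 rows and no constant
#'   columns.
#' @param train_fraction fraction of compounds assigned to training, in
#'   (0, 1); default 0.7.
#' @return a `ks_split` object: list with `train_ids`, `test_ids` (disjoint,
#'   covering all ids) and `selection_order` (training ids in pick order).
#' @export
ks_split <- function(table, train_fraction = 0.7) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("`train_fraction` must lie in (0, 1)", call. = FALSE)
  }
  m <- desc_matrix(table)
  n <- nrow(m)
  if (n < 3L) {
    stop("Kennard-Stone division needs at least 3 compounds, got ", n,
         call. = FALSE)
  }
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    stop("constant column(s) present (",
         paste(colnames(m)[v == 0], collapse = ", "),
         "); apply remove_constant() first", call. = FALSE)
  }
  n_train <- max(2L, as.integer(floor(train_fraction * n)))
  z <- scale(m)
  d <- as.matrix(stats::dist(z))

  # farthest pair, lowest indices on ties
  far <- which(d == max(d), arr.ind = TRUE)
  far <- far[order(far[, 1], far[, 2]), , drop = FALSE]
  picked <- sort(c(far[1, 1], far[1, 2]))

  # min distance of every point to the picked set
  mind <- pmin(d[, picked[1]], d[, picked[2]])
  mind[picked] <- -Inf
  while (length(picked) < n_train) {
    nxt <- which.max(mind)  # which.max returns the first (lowest) index
    picked <- c(picked, nxt)
    mind <- pmin(mind, d[, nxt])
    mind[nxt] <- -Inf
  }
  ids <- rownames(m)
  structure(list(train_ids = ids[sort(picked)],
                 test_ids = ids[setdiff(seq_len(n), picked)],
                 selection_order = ids[picked]),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat("<ks_split> ", length(x$train_ids), " train / ", length(x$test_ids),
      " test\n", sep = "")
  invisible(x)
}

#' Apply a split to a dataset as membership labels
#'
#' @param dataset a [qsar_dataset()].
#' @param split a `ks_split` from [ks_split()].
#' @return the dataset with membership set to `"train"`/`"test"`.
#' @export
apply_split <- function(dataset, split) {
  stopifnot(inherits(dataset, "qsar_dataset"), inherits(split, "ks_split"))
  membership <- stats::setNames(rep("test", nrow(dataset$table)),
                                rownames(dataset$table))
  membership[split$train_ids] <- "train"
  qsar_dataset(dataset$table, dataset$pic50, membership)
}
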