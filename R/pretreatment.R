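#' Drop (near-)constant descriptors
#'
#' A descriptor whose sample variance does not exceed `variance_tol`
#' carries no information about activity differences and breaks
#' correlation-based steps downstream, so it is removed before anything
#' else.
#'
#' @param table a [descriptor_table()].
#' @param variance_tol non-negative variance threshold; columns with sample
#'   variance `<= variance_tol` are dropped. Default `1e-8`.
#' @return list with `table` (the filtered [descriptor_table()]) and
#'   `report` (a `pretreat_report`).
#' @export
remove_constant <- function(table, variance_tol = 1e-8) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!is.numeric(variance_tol) || variance_tol < 0) {
    stop("`variance_tol` must be >= 0", call. = FALSE)
  }
  m <- desc_matrix(table)
  v <- apply(m, 2, stats::var)
  keep <- v > variance_tol
  if (!any(keep)) {
    warning("all descriptors are constant at this tolerance; ",
            "returning an empty table", call. = FALSE)
  }
  out <- m[, keep, drop = FALSE]
  report <- structure(
    list(dropped_constant = colnames(m)[!keep],
         dropped_correlated = data.frame(dropped = character(),
                                         kept = character(),
                                         abs_r = numeric(),
                                         stringsAsFactors = FALSE),
         survivors = colnames(m)[keep]),
    class = "pretreat_report")
  tab <- if (ncol(out) > 0) descriptor_table(out) else
    structure(out, class = c("descriptor_table", class(matrix())))
  list(table = tab, report = report)
}

#' Remove inter-correlated descriptors
#'
#' Greedy left-to-right scan in input column order: a descriptor is kept
#' iff its absolute Pearson correlation with every already-kept descriptor
#' is `<= cutoff` (a pair exactly at the cutoff survives). First-seen-wins
#' makes the result deterministic and order-documented. Each drop records
#' which kept descriptor triggered it and the offending |r|.
#'
#' @param table a [descriptor_table()] with no constant columns (run
#'   [remove_constant()] first).
#' @param cutoff absolute-correlation cutoff in (0, 1]; default 0.7, the
#'   conventional QSAR pretreatment value.
#' @return list with `table` and `report` as in [remove_constant()].
#' @export
correlation_filter <- function(table, cutoff = 0.7) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff > 1) {
    stop("`cutoff` must lie in (0, 1]", call. = FALSE)
  }
  m <- desc_matrix(table)
  v <- apply(m, 2, stats::var)
  if (any(v == 0)) {
    stop("constant column(s) present (",
         paste(colnames(m)[v == 0], collapse = ", "),
         "); apply remove_constant() first", call. = FALSE)
  }
  p <- ncol(m)
  kept <- integer(0)
  dropped <- character(0)
  trigger <- character(0)
  trig_r <- numeric(0)
  for (j in seq_len(p)) {
    r <- if (length(kept) > 0)
      abs(stats::cor(m[, j], m[, kept, drop = FALSE])) else numeric(0)
    hit <- which(r > cutoff)
    if (length(hit) > 0) {
      dropped <- c(dropped, colnames(m)[j])
      trigger <- c(trigger, colnames(m)[kept[hit[1]]])
      trig_r <- c(trig_r, r[hit[1]])
    } else {
      kept <- c(kept, j)
    }
  }
  report <- structure(
    list(dropped_constant = character(0),
         dropped_correlated = data.frame(dropped = dropped, kept = trigger,
                                         abs_r = trig_r,
                                         stringsAsFactors = FALSE),
         survivors = colnames(m)[kept]),
    class = "pretreat_report")
  list(table = descriptor_table(m[, kept, drop = FALSE]), report = report)
}

#' Full descriptor pretreatment
#'
#' [remove_constant()] followed by [correlation_filter()], the standard
#' preparation of a raw descriptor pool before data division. The combined
#' report partitions the original descriptor names into survivors, constant
#' drops and correlation drops.
#'
#' @inheritParams remove_constant
#' @inheritParams correlation_filter
#' @return list with `table` and a combined `report`.
#' @export
pretreat <- function(table, cutoff = 0.7, variance_tol = 1e-8) {
  step1 <- remove_constant(table, variance_tol)
  step2 <- correlation_filter(step1$table, cutoff)
  report <- structure(
    list(dropped_constant = step1$report$dropped_constant,
         dropped_correlated = step2$report$dropped_correlated,
         survivors = step2$report$survivors),
    class = "pretreat_report")
  list(table = step2$table, report = report)
}

#' @export
print.pretreat_report <- function(x, ...) {
  cat("<pretreat_report> ", length(x$survivors), " survivors; ",
      length(x$dropped_constant), " constant drops; ",
      nrow(x$dropped_correlated), " correlation drops\n", sep = "")
  invisible(x)
}

#' Write a pretreatment audit log as CSV
#'
#' One row per original descriptor, with its fate (`kept`, `constant` or
#' `correlated`) and, for correlation drops, the kept descriptor that
#' triggered the drop and the offending |r|.
#'
#' @param report a `pretreat_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pretreat_report <- function(report, path) {
  fate_rows <- function(desc, fate, trigger = rep("", length(desc)),
                        abs_r = rep(NA_real_, length(desc))) {
    data.frame(descriptor = desc, fate = rep(fate, length(desc)),
               trigger = trigger, abs_r = abs_r, stringsAsFactors = FALSE)
  }
  rows <- rbind(
    fate_rows(report$survivors, "kept"),
    fate_rows(report$dropped_constant, "constant"),
    fate_rows(report$dropped_correlated$dropped, "correlated",
              report$dropped_correlated$kept,
              report$dropped_correlated$abs_r))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
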