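#' Construct a descriptor table
#'
#' A descriptor table is a numeric matrix of molecular descriptor values
#' with compounds in rows and named descriptors in columns. Compound ids
#' (rownames) and descriptor names (colnames) must be unique, and every cell
#' must be finite: descriptor software emits a number for every compound, so
#' a missing value indicates an upstream failure and is rejected rather
#' than imputed.
#'
#' @param values numeric matrix (or object coercible to one) with rownames
#'   giving compound ids and colnames giving descriptor names, unless
#'   supplied separately.
#' @param compound_ids optional character vector of row labels.
#' @param descriptor_names optional character vector of column labels.
#' @return a numeric matrix of class `descriptor_table`.
#' @export
descriptor_table <- function(values, compound_ids = NULL,
                             descriptor_names = NULL) {
  values <- as.matrix(values)
  if (!is.null(compound_ids)) rownames(values) <- compound_ids
  if (!is.null(descriptor_names)) colnames(values) <- descriptor_names
  if (!is.numeric(values)) {
    stop("descriptor values must be numeric", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("descriptor table needs compound ids (rownames) and descriptor ",
         "names (colnames)", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate compound id: ",
         rownames(values)[duplicated(rownames(values))][1], call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate descriptor name: ",
         colnames(values)[duplicated(colnames(values))][1], call. = FALSE)
  }
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-finite descriptor value for compound '",
         rownames(values)[bad[1, 1]], "', descriptor '",
         colnames(values)[bad[1, 2]], "'", call. = FALSE)
  }
  structure(values, class = c("descriptor_table", class(matrix())))
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> ", nrow(x), " compounds x ", ncol(x),
      " descriptors\n", sep = "")
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]))
  invisible(x)
}

# internal: plain numeric matrix view
desc_matrix <- function(table) {
  m <- unclass(table)
  attr(m, "class") <- NULL
  m
}

#' Read a descriptor table from CSV
#'
#' Expects PaDEL-style output: a header row whose first column is `Name`
#' (compound id) followed by one numeric column per descriptor. Non-numeric
#' cells, missing values, duplicate ids and duplicate descriptor names are
#' load errors; column order is preserved.
#'
#' @param path path to a comma-delimited descriptor file.
#' @return a [descriptor_table()].
#' @export
read_descriptor_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) {
    stop("descriptor CSV needs an id column plus at least one descriptor",
         call. = FALSE)
  }
  ids <- df[[1]]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df) - 1L,
                 dimnames = list(ids, names(df)[-1]))
  for (j in seq_len(ncol(df) - 1L)) {
    cell <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad) > 0) {
      stop("non-numeric cell '", cell[bad[1]], "' at row '", ids[bad[1]],
           "', column '", names(df)[j + 1L], "'", call. = FALSE)
    }
    vals[, j] <- num
  }
  descriptor_table(vals)
}

#' Write a descriptor table to CSV
#'
#' Values are written with 15 significant digits so that any decimal input
#' of up to 12 significant digits round-trips bit-exactly through
#' [read_descriptor_csv()].
#'
#' @param table a [descriptor_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(table, path) {
  m <- desc_matrix(table)
  chr <- matrix(formatC(m, digits = 15, format = "g"), nrow = nrow(m))
  df <- data.frame(Name = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("Name", colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an activity series to CSV
#'
#' @param pic50 named numeric vector of pIC50 values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(pic50, path) {
  df <- data.frame(Name = names(pic50),
                   pIC50 = formatC(unname(pic50), digits = 15, format = "g"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
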