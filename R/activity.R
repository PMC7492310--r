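#' Convert an IC50 in micromolar to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50. Because this
#' package exchanges IC50 values in micromolar (the unit cytotoxicity assays
#' report), the conversion is `pIC50 = 6 - log10(IC50_uM)`.
#'
#' @param ic50_uM numeric vector of IC50 values in micromolar; must be
#'   positive and finite.
#' @return numeric vector of pIC50 values in -log10(molar) units.
#' @examples
#' pic50_from_ic50_uM(1)    # 6: 1 uM == 1e-6 M
#' pic50_from_ic50_uM(4.87) # ~5.31, a potent compound
#' @seealso [ic50_uM_from_pic50()] for the inverse transform.
#' @export
pic50_from_ic50_uM <- function(ic50_uM) {
  if (!is.numeric(ic50_uM)) {
    stop("`ic50_uM` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(ic50_uM)) || any(ic50_uM <= 0)) {
    stop("IC50 values must be finite and strictly positive", call. = FALSE)
  }
  6 - log10(ic50_uM)
}

#' Convert a pIC50 back to an IC50 in micromolar
#'
#' Exact inverse of [pic50_from_ic50_uM()]: `IC50_uM = 10^(6 - pIC50)`.
#'
#' @param pic50 numeric vector of pIC50 values in -log10(molar) units; must
#'   be finite.
#' @return numeric vector of IC50 values in micromolar.
#' @export
ic50_uM_from_pic50 <- function(pic50) {
  if (!is.numeric(pic50)) {
    stop("`pic50` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(pic50))) {
    stop("pIC50 values must be finite", call. = FALSE)
  }
  10^(6 - pic50)
}

#' Read an activity table from CSV
#'
#' Expects a header of either `Name,IC50_uM` or `Name,pIC50`. IC50 input is
#' converted to pIC50 on load so all downstream code works on a single
#' activity scale.
#'
#' @param path path to a comma-delimited activity file.
#' @return named numeric vector of pIC50 values; names are compound ids.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 2L || names(df)[1] != "Name") {
    stop("activity CSV must have exactly the columns 'Name' and one of ",
         "'IC50_uM' or 'pIC50'", call. = FALSE)
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate compound id in activity CSV: ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  vals <- df[[2]]
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("activity column contains non-numeric or missing values",
         call. = FALSE)
  }
  pic50 <- switch(names(df)[2],
    IC50_uM = pic50_from_ic50_uM(vals),
    pIC50   = vals,
    stop("activity column must be named 'IC50_uM' or 'pIC50', got '",
         names(df)[2], "'", call. = FALSE)
  )
  stats::setNames(pic50, ids)
}
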