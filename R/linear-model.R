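#' Construct a linear QSAR model
#'
#' A linear model is an ordered set of descriptor names, one regression
#' coefficient per descriptor, and an intercept. Predictions are
#' `intercept + sum(beta_j * x_j)` with descriptors matched by name.
#'
#' @param descriptors character vector of descriptor names.
#' @param coefficients numeric vector, one coefficient per descriptor.
#' @param intercept numeric scalar.
#' @param metadata optional named list of free-form provenance fields.
#' @return an object of class `linear_model`.
#' @export
linear_model <- function(descriptors, coefficients, intercept,
                         metadata = list()) {
  descriptors <- as.character(descriptors)
  coefficients <- as.numeric(coefficients)
  if (length(descriptors) != length(coefficients)) {
    stop("need exactly one coefficient per descriptor (",
         length(descriptors), " names, ", length(coefficients),
         " coefficients)", call. = FALSE)
  }
  if (anyDuplicated(descriptors)) {
    stop("duplicate descriptor name in model", call. = FALSE)
  }
  if (length(intercept) != 1L || !is.finite(intercept)) {
    stop("intercept must be a single finite number", call. = FALSE)
  }
  if (any(!is.finite(coefficients))) {
    stop("coefficients must be finite", call. = FALSE)
  }
  structure(list(descriptors = descriptors,
                 coefficients = stats::setNames(coefficients, descriptors),
                 intercept = as.numeric(intercept),
                 metadata = metadata),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat("<linear_model> pIC50 =\n")
  for (d in x$descriptors) {
    cat(sprintf("  %+.9g * %s\n", x$coefficients[[d]], d))
  }
  cat(sprintf("  %+.9g\n", x$intercept))
  invisible(x)
}

#' Predict activity for descriptor rows
#'
#' @param object a [linear_model()].
#' @param table a [descriptor_table()] (or numeric matrix with descriptor
#'   colnames) containing every model descriptor; extra columns and any
#'   column order are fine, matching is by name.
#' @param ... unused.
#' @return named numeric vector of predicted pIC50, one per row of `table`.
#' @export
predict.linear_model <- function(object, table, ...) {
  m <- if (inherits(table, "descriptor_table")) desc_matrix(table)
       else as.matrix(table)
  missing <- setdiff(object$descriptors, colnames(m))
  if (length(missing) > 0) {
    stop("descriptor(s) missing from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  preds <- drop(m[, object$descriptors, drop = FALSE] %*%
                  object$coefficients) + object$intercept
  stats::setNames(as.numeric(preds), rownames(m))
}

#' Read / write a linear model as JSON
#'
#' The on-disk form is a JSON object with fields `descriptors`,
#' `coefficients`, `intercept` and `metadata`. Numbers are written at full
#' precision so a save/load round trip is bit-exact.
#'
#' @param path path to a model JSON file.
#' @return [read_model_json()] returns a [linear_model()];
#'   [write_model_json()] returns `path` invisibly.
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("descriptors", "coefficients", "intercept")) {
    if (is.null(doc[[field]])) {
      stop("model document missing required field '", field, "'",
           call. = FALSE)
    }
  }
  linear_model(doc$descriptors, doc$coefficients, doc$intercept,
               metadata = if (is.null(doc$metadata)) list() else
                 as.list(doc$metadata))
}

#' @rdname read_model_json
#' @param model a [linear_model()].
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "linear_model"))
  doc <- list(descriptors = model$descriptors,
              coefficients = unname(model$coefficients),
              intercept = model$intercept,
              metadata = model$metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' The bundled published cytotoxicity model
#'
#' Loads the five-descriptor multilinear regression model of imidazol-5-one
#' cytotoxicity (pIC50) against the HCT116 colorectal cancer cell line that
#' ships with the package. Its descriptors are nS (sulfur atom count),
#' GATS5s (Geary autocorrelation, lag 5, intrinsic-state weighted), VR1_Dze
#' (Randic-like Barysz-matrix eigenvector index, electronegativity
#' weighted), ETA_dBetaP (relative unsaturation content) and L3i (3rd WHIM
#' size component, ionization-potential weighted).
#'
#' @return a [linear_model()].
#' @export
hct116_model <- function() {
  read_model_json(system.file("extdata", "hct116_imidazolone_model.json",
                              package = "qsarpipe", mustWork = TRUE))
}
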