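#' Assemble a candidate set from predicted activities
#'
#' Builds the screening table for a set of designed candidates: predicted
#' pIC50, the equivalent IC50 in micromolar, and a flag marking candidates
#' strictly more potent than the design template. Rows are ranked by
#' descending predicted pIC50 (equivalently ascending IC50).
#'
#' @param ids candidate identifiers.
#' @param pic50 predicted pIC50 per candidate.
#' @param template_pic50 the template compound's pIC50; a candidate is
#'   flagged `better_than_template` only if its pIC50 strictly exceeds it.
#' @param annotation optional free-text substituent annotation per
#'   candidate (e.g. "R1=-F, R2=-H, R3=-F").
#' @param inside_domain optional logical applicability-domain flag.
#' @return a `candidate_set` data.frame with columns `id`, `annotation`,
#'   `pic50`, `ic50_uM`, `better_than_template`, `inside_domain`.
#' @export
candidate_set <- function(ids, pic50, template_pic50, annotation = NULL,
                          inside_domain = NULL) {
  ids <- as.character(ids)
  if (length(pic50) != length(ids)) {
    stop("`pic50` must have one value per candidate", call. = FALSE)
  }
  out <- data.frame(
    id = ids,
    annotation = if (is.null(annotation)) rep("", length(ids)) else
      as.character(annotation),
    pic50 = as.numeric(pic50),
    ic50_uM = if (length(ids) > 0) ic50_uM_from_pic50(as.numeric(pic50))
              else numeric(0),
    better_than_template = as.numeric(pic50) > template_pic50,
    inside_domain = if (is.null(inside_domain)) rep(NA, length(ids)) else
      as.logical(inside_domain),
    stringsAsFactors = FALSE)
  out <- out[order(-out$pic50), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "template_pic50") <- template_pic50
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Screen candidate descriptor rows with a model
#'
#' Predicts the activity of each candidate's descriptor row with the model
#' and assembles the ranked [candidate_set()]. This is the ligand-based
#' design step: descriptor values of proposed derivatives are inserted into
#' the regression equation and compared against the template compound.
#'
#' @param model a [linear_model()].
#' @param candidates a [descriptor_table()] of candidate descriptor rows
#'   covering every model descriptor.
#' @param template_pic50 the template compound's pIC50.
#' @param annotation optional substituent annotations, named by candidate
#'   id or in row order.
#' @return a `candidate_set`, ranked by descending predicted pIC50.
#' @export
screen <- function(model, candidates, template_pic50, annotation = NULL) {
  preds <- predict(model, candidates)
  if (!is.null(annotation) && !is.null(names(annotation))) {
    annotation <- annotation[names(preds)]
  }
  candidate_set(names(preds), unname(preds), template_pic50, annotation)
}

#' Filter a candidate set by an IC50 potency threshold
#'
#' Retains candidates with predicted IC50 strictly below `ic50_max`.
#'
#' @param candidates a `candidate_set`.
#' @param ic50_max potency threshold in micromolar; must be >= 0.
#' @return the filtered `candidate_set`.
#' @export
activity_threshold_filter <- function(candidates, ic50_max) {
  stopifnot(inherits(candidates, "candidate_set"))
  if (!is.numeric(ic50_max) || length(ic50_max) != 1L || ic50_max < 0) {
    stop("`ic50_max` must be a single non-negative number", call. = FALSE)
  }
  out <- candidates[candidates$ic50_uM < ic50_max, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "template_pic50") <- attr(candidates, "template_pic50")
  class(out) <- class(candidates)
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d candidates vs template pIC50 = %.4g; %d better\n",
              nrow(x), attr(x, "template_pic50"),
              sum(x$better_than_template)))
  print.data.frame(x)
  invisible(x)
}

#' Published designed-compound activities
#'
#' The twelve imidazol-5-one derivatives designed around the template
#' compound (an R1=-Br parent, pIC50 5.257) with the activities predicted
#' by the bundled HCT116 model, plus the template row. Substituent columns
#' give the R1/R2/R3 groups of each derivative. These are published
#' predictions shipped as a fixture — the descriptor rows behind them are
#' not distributed, so they cannot be regenerated here.
#'
#' @return data.frame with columns `Name`, `R1`, `R2`, `R3`, `pIC50`,
#'   `IC50_uM`.
#' @export
designed_compounds <- function() {
  utils::read.csv(system.file("extdata", "designed_compounds.csv",
                              package = "qsarpipe", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
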