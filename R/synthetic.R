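#' Specification of a synthetic QSAR dataset
#'
#' Describes a dataset with the statistical structure the pipeline assumes:
#' a small compound panel, a wide descriptor pool organized into
#' equicorrelated blocks (emulating the redundancy of a raw descriptor
#' pool), and a planted linear signal carried by a few informative
#' descriptors, with activity rescaled into a realistic pIC50 window.
#'
#' Defaults mirror the modelled study conditions: 36 compounds, a
#' 200-descriptor pool (a reduced-width stand-in for the ~1900-descriptor
#' pools descriptor software emits), 5 informative descriptors,
#' within-block correlation 0.85 in blocks of 5, activity spanning pIC50
#' 4.0-5.3, and Gaussian noise of 0.2 pIC50 units.
#'
#' @param n_compounds number of compounds; default 36.
#' @param n_descriptors width of the descriptor pool; default 200.
#' @param n_informative number of descriptors carrying the signal (one per
#'   block, placed first in its block); default 5. Must be at most the
#'   number of blocks.
#' @param block_size descriptors per correlated block; default 5.
#' @param rho within-block pairwise correlation, in `[0, 1)`; default 0.85.
#' @param true_coefficients raw coefficients of the informative
#'   descriptors before range rescaling; default alternating +/-1.
#' @param noise_sd Gaussian noise standard deviation in pIC50 units;
#'   default 0.2.
#' @param activity_range target span of the noise-free activity; default
#'   `c(4.0, 5.3)`.
#' @param seed integer seed; generation is reproducible for a fixed seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_compounds = 36, n_descriptors = 200,
                           n_informative = 5, block_size = 5, rho = 0.85,
                           true_coefficients = NULL, noise_sd = 0.2,
                           activity_range = c(4.0, 5.3), seed = 1) {
  if (n_informative > n_descriptors) {
    stop("`n_informative` cannot exceed `n_descriptors`", call. = FALSE)
  }
  n_blocks <- ceiling(n_descriptors / block_size)
  if (n_informative > n_blocks) {
    stop("`n_informative` cannot exceed the number of blocks (",
         n_blocks, ")", call. = FALSE)
  }
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (length(activity_range) != 2L ||
      activity_range[2] <= activity_range[1]) {
    stop("`activity_range` must be an increasing pair", call. = FALSE)
  }
  if (is.null(true_coefficients)) {
    true_coefficients <- (-1)^(seq_len(n_informative) - 1)
  }
  if (length(true_coefficients) != n_informative) {
    stop("`true_coefficients` must have one value per informative ",
         "descriptor", call. = FALSE)
  }
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 n_informative = as.integer(n_informative),
                 block_size = as.integer(block_size),
                 rho = rho,
                 true_coefficients = as.numeric(true_coefficients),
                 noise_sd = noise_sd,
                 activity_range = as.numeric(activity_range),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic QSAR dataset
#'
#' Descriptor columns are drawn with equicorrelation `rho` inside each
#' block via a shared latent factor (`x = sqrt(rho) * g_block +
#' sqrt(1 - rho) * z`), independent across blocks, so pairwise
#' within-block correlation is `rho` in expectation and the pretreatment
#' cutoff can be exercised exactly. The informative descriptors are the
#' first member of each of the first `n_informative` blocks. The noise-free
#' activity `X_inf %*% beta` is affinely rescaled to span
#' `activity_range`, and Gaussian noise of `noise_sd` is added on top.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a [qsar_dataset()]) and `ground_truth`
#'   (list: `informative` descriptor names, effective `coefficients` and
#'   `intercept` on the rescaled activity scale, and `noise_sd`).
#' @export
generate_qsar_data <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_compounds
  p <- spec$n_descriptors
  block_of <- ((seq_len(p) - 1L) %/% spec$block_size) + 1L
  n_blocks <- max(block_of)
  G <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- sqrt(spec$rho) * G[, block_of, drop = FALSE] +
    sqrt(1 - spec$rho) * Z
  dimnames(X) <- list(sprintf("C%02d", seq_len(n)),
                      sprintf("D%03d", seq_len(p)))

  inf_cols <- (seq_len(spec$n_informative) - 1L) * spec$block_size + 1L
  inf_names <- colnames(X)[inf_cols]
  raw <- drop(X[, inf_cols, drop = FALSE] %*% spec$true_coefficients)
  span <- max(raw) - min(raw)
  if (span == 0) stop("degenerate signal: zero span", call. = FALSE)
  a <- (spec$activity_range[2] - spec$activity_range[1]) / span
  b <- spec$activity_range[1] - a * min(raw)
  noise_free <- a * raw + b
  y <- noise_free + stats::rnorm(n, 0, spec$noise_sd)
  names(y) <- rownames(X)

  list(dataset = qsar_dataset(descriptor_table(X), y),
       ground_truth = list(informative = inf_names,
                           coefficients = stats::setNames(
                             a * spec$true_coefficients, inf_names),
                           intercept = b,
                           noise_sd = spec$noise_sd))
}
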