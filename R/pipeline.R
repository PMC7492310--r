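#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the full modelling pipeline
#' (simulate -> pretreat -> split -> select -> fit -> validate ->
#' Y-randomize -> applicability domain -> screen). Every stage parameter
#' is validated by its owning constructor before any stage runs. The
#' global `seed` drives the synthetic generator and the GFA search, and
#' `seed + 1` the Y-randomization stream, so a rerun with the same config
#' is bit-reproducible.
#'
#' @param synthetic a [synthetic_spec()] used when no dataset is supplied
#'   to [run_qsar_pipeline()].
#' @param cutoff,variance_tol pretreatment parameters (see [pretreat()]).
#' @param train_fraction Kennard-Stone training fraction.
#' @param gfa a [gfa_config()]; its seed is overridden by the global seed.
#' @param n_permutations Y-randomization permutation count; default 10.
#' @param residual_band applicability-domain residual band; default 3.
#' @param seed global integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_spec(), cutoff = 0.7,
                            variance_tol = 1e-8, train_fraction = 0.7,
                            gfa = gfa_config(), n_permutations = 10,
                            residual_band = 3, seed = 1) {
  stopifnot(inherits(synthetic, "synthetic_spec"),
            inherits(gfa, "gfa_config"))
  if (cutoff <= 0 || cutoff > 1) stop("`cutoff` must lie in (0, 1]",
                                      call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (n_permutations < 1) stop("`n_permutations` must be >= 1",
                               call. = FALSE)
  seed <- as.integer(seed)
  synthetic$seed <- seed
  gfa$seed <- seed
  structure(list(synthetic = synthetic, cutoff = cutoff,
                 variance_tol = variance_tol,
                 train_fraction = train_fraction, gfa = gfa,
                 n_permutations = as.integer(n_permutations),
                 residual_band = residual_band, seed = seed),
            class = "pipeline_config")
}

# internal: stable hash of a config for provenance blocks
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

# internal: run one stage, naming it on failure
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full QSAR modelling pipeline
#'
#' Chains every stage on a synthetic (or supplied) dataset: descriptor
#' pretreatment, Kennard-Stone division, GFA descriptor selection, OLS
#' fitting, the validation suite with benchmark gate, Y-randomization,
#' the leverage applicability domain, and screening of the test compounds
#' against the most potent training compound as template. Each stage
#' consumes the previous stage's outputs; a stage failure halts the chain
#' with the failing stage named. All tabular outputs are CSV; the model
#' and verdict are JSON carrying a provenance block (package version,
#' seed, config hash).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param dataset optional [qsar_dataset()]; default: generated from
#'   `config$synthetic`.
#' @return invisibly, a manifest list: `files` (named vector of paths) and
#'   `summary` (model descriptors, validation metrics, benchmark verdict,
#'   cRp2, screening counts).
#' @export
run_qsar_pipeline <- function(config = pipeline_config(), out_dir,
                              dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  provenance <- list(package = "qsarpipe",
                     version = as.character(utils::packageVersion("qsarpipe")),
                     seed = config$seed,
                     config_md5 = config_hash(config))
  files <- character(0)

  if (is.null(dataset)) {
    gen <- run_stage("simulate", generate_qsar_data(config$synthetic))
    dataset <- gen$dataset
    jsonlite::write_json(c(gen$ground_truth, list(provenance = provenance)),
                         path("ground_truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files["ground_truth"] <- path("ground_truth.json")
  }
  write_descriptor_csv(dataset$table, path("descriptors.csv"))
  write_activity_csv(dataset$pic50, path("activity.csv"))
  files["descriptors"] <- path("descriptors.csv")
  files["activity"] <- path("activity.csv")

  pre <- run_stage("pretreat",
                   pretreat(dataset$table, config$cutoff,
                            config$variance_tol))
  write_pretreat_report(pre$report, path("pretreat_report.csv"))
  files["pretreat_report"] <- path("pretreat_report.csv")

  split <- run_stage("split", ks_split(pre$table, config$train_fraction))
  pretreated <- qsar_dataset(pre$table, dataset$pic50)
  pretreated <- apply_split(pretreated, split)
  utils::write.csv(data.frame(Name = names(pretreated$membership),
                              membership = unname(pretreated$membership)),
                   path("membership.csv"), row.names = FALSE)
  files["membership"] <- path("membership.csv")

  train <- subset_membership(pretreated, "train")
  test <- subset_membership(pretreated, "test")

  gfa <- run_stage("gfa", gfa_search(train$table, train$pic50, config$gfa))
  utils::write.csv(gfa$ranking, path("gfa_ranking.csv"), row.names = FALSE)
  files["gfa_ranking"] <- path("gfa_ranking.csv")

  model <- run_stage("fit",
                     fit_ols(train$table, train$pic50, gfa$best))
  model$metadata <- c(model$metadata, list(provenance = provenance))
  write_model_json(model, path("model.json"))
  files["model"] <- path("model.json")

  report <- run_stage("validate", validation_report(model, train, test))
  utils::write.csv(report$anova, path("anova.csv"), row.names = FALSE)
  utils::write.csv(report$diagnostics, path("diagnostics.csv"),
                   row.names = FALSE)
  verdict <- list(metrics = list(r2 = report$r2, r2_adj = report$r2_adj,
                                 q2_cv = report$q2_cv,
                                 r2_ext = report$r2_ext),
                  criteria = report$verdict,
                  overall_pass = attr(report$verdict, "overall"),
                  provenance = provenance)
  jsonlite::write_json(verdict, path("verdict.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files["anova"] <- path("anova.csv")
  files["diagnostics"] <- path("diagnostics.csv")
  files["verdict"] <- path("verdict.json")

  yr <- run_stage("yrand",
                  y_randomize(train$table, train$pic50,
                              config$n_permutations,
                              seed = config$seed + 1L,
                              descriptors = model$descriptors))
  write_yrand_csv(yr, path("yrand.csv"))
  files["yrand"] <- path("yrand.csv")

  ad <- run_stage("ad", williams(model, train, test,
                                 config$residual_band))
  con <- file(path("williams.csv"), "w")
  writeLines(sprintf("# h_star = %.10g, residual_band = %g",
                     attr(ad, "h_star"), attr(ad, "residual_band")), con)
  utils::write.csv(as.data.frame(ad), con, row.names = FALSE)
  close(con)
  files["williams"] <- path("williams.csv")

  template <- max(train$pic50)
  screened <- run_stage("screen",
                        screen(model, test$table, template))
  utils::write.csv(as.data.frame(screened), path("screen.csv"),
                   row.names = FALSE)
  files["screen"] <- path("screen.csv")

  manifest <- list(
    files = files,
    summary = list(descriptors = model$descriptors,
                   r2 = report$r2, r2_adj = report$r2_adj,
                   q2_cv = report$q2_cv, r2_ext = report$r2_ext,
                   benchmark_pass = attr(report$verdict, "overall"),
                   c_rp2 = yr$c_rp2,
                   n_inside_domain = sum(ad$inside_domain),
                   n_better_than_template =
                     sum(screened$better_than_template),
                   provenance = provenance))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
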