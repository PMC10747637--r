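# Run configuration and end-to-end pipeline orchestration.

#' Run configuration
#'
#' Bundles the cohort configuration and every operator parameter into one
#' validated object that round-trips losslessly through YAML.  Unknown keys
#' are rejected.
#'
#' @param cohort A [cohort_config()] or a list of its arguments.
#' @param approaches Feature approaches to run.
#' @param techniques Classifier techniques to evaluate (subset of the grid).
#' @param seed Master seed for the evaluation stage.
#' @param out_dir Output directory for [run_pipeline()].
#' @param energy_window Gabor mean-energy window.
#' @param canny_sigma,canny_low,canny_high Canny parameters for SEGL.
#' @param segl_variant SEGL chain ordering (see [features_segl()]).
#' @param nn_hidden NN hidden-layer width.
#' @param anova_unit Unit of analysis for [anova_table()].
#' @param run_ensemble,run_importance Whether to run the majority-vote and
#'   importance stages.
#' @param save_images Whether to write the cohort frames as PNGs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       approaches = c("bmode", "lbp", "gabor", "segl"),
                       techniques = c("kNN", "DT", "RF", "LR", "NB", "SVM", "NN"),
                       seed = 1L,
                       out_dir = "mtrptex_run",
                       energy_window = 5L,
                       canny_sigma = 1.0, canny_low = 0.1, canny_high = 0.2,
                       segl_variant = "glcm_edges",
                       nn_hidden = 512L,
                       anova_unit = "image",
                       run_ensemble = TRUE,
                       run_importance = FALSE,
                       save_images = FALSE) {
  if (!inherits(cohort, "cohort_config")) cohort <- do.call(cohort_config, cohort)
  stopifnot(all(approaches %in% c("bmode", "lbp", "gabor", "segl")),
            all(techniques %in% unique(classifier_grid()$technique)))
  structure(list(cohort = cohort, approaches = approaches,
                 techniques = techniques, seed = as.integer(seed),
                 out_dir = out_dir, energy_window = as.integer(energy_window),
                 canny_sigma = canny_sigma, canny_low = canny_low,
                 canny_high = canny_high, segl_variant = segl_variant,
                 nn_hidden = as.integer(nn_hidden), anova_unit = anova_unit,
                 run_ensemble = isTRUE(run_ensemble),
                 run_importance = isTRUE(run_importance),
                 save_images = isTRUE(save_images)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `read_run_config` returns the validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  ck <- setdiff(names(x$cohort), names(formals(cohort_config)))
  if (length(ck))
    stop("unknown cohort keys: ", paste(ck, collapse = ", "))
  do.call(run_config, x)
}

#' @keywords internal
compute_tables <- function(cohort, config) {
  tables <- list()
  bank <- if ("gabor" %in% config$approaches) gabor_bank() else NULL
  for (ap in config$approaches) {
    tables[[ap]] <- switch(ap,
      bmode = feature_table(cohort, "bmode"),
      lbp = feature_table(cohort, "lbp"),
      gabor = feature_table(cohort, "gabor", bank = bank,
                            energy_window = config$energy_window),
      segl = feature_table(cohort, "segl", sigma = config$canny_sigma,
                           low_frac = config$canny_low,
                           high_frac = config$canny_high,
                           variant = config$segl_variant))
  }
  tables
}

#' Run the full pipeline
#'
#' Executes generate -> features -> LOSO grid evaluation -> optional
#' ensemble / importance -> ANOVA, writing the cohort manifest, per-approach
#' feature CSVs, results JSON, metric tables, and a provenance file into
#' `config$out_dir`.  Re-running with the same configuration is
#' bit-identical.  On failure, partial outputs are moved under `failed/`.
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly; the collected results as the
#'   attribute `"results"`.
#' @export
run_pipeline <- function(config = run_config()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit({
    if (!ok) {
      fdir <- file.path(dirname(out), "failed")
      dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
      qdir <- file.path(fdir, basename(out))
      unlink(qdir, recursive = TRUE)
      file.rename(out, qdir)
      message("pipeline failed; partial outputs quarantined under ", qdir)
    }
  })

  cohort <- generate_cohort(config$cohort)
  if (config$save_images) {
    write_cohort(cohort, file.path(out, "cohort"))
  } else {
    # manifest + config only
    tmp <- cohort
    for (i in seq_along(tmp)) { tmp[[i]]$frames <- list()
                                tmp[[i]]$frame_indices <- integer(0) }
    attr(tmp, "config") <- attr(cohort, "config")
    write_cohort(tmp, file.path(out, "cohort"))
  }

  tables <- compute_tables(cohort, config)
  for (ap in names(tables))
    utils::write.csv(tables[[ap]], file.path(out, paste0("features_", ap, ".csv")),
                     row.names = FALSE)

  grid <- classifier_grid()
  grid <- grid[grid$technique %in% config$techniques, , drop = FALSE]
  ev <- evaluate_grid(tables, grid, seed = config$seed,
                      hidden = config$nn_hidden)
  utils::write.csv(ev$metrics, file.path(out, "metrics_grid.csv"),
                   row.names = FALSE)
  for (ap in names(ev$results))
    for (nm in names(ev$results[[ap]]))
      utils::write.csv(ev$results[[ap]][[nm]]$confusion,
                       file.path(out, sprintf("confusion_%s_%s.csv", ap,
                                              gsub("[^A-Za-z0-9._-]", "_", nm))),
                       row.names = TRUE)

  selected <- grid_select(ev$metrics, grid)
  utils::write.csv(selected, file.path(out, "selected_classifiers.csv"),
                   row.names = FALSE)

  results <- list(metrics = ev$metrics, selected = selected)

  if (config$run_ensemble && nrow(selected) >= 3L) {
    vote_rows <- list()
    for (ap in names(tables)) {
      v <- ensemble_vote(tables[[ap]], selected, seed = config$seed,
                         hidden = config$nn_hidden)
      vote_rows[[ap]] <- data.frame(approach = ap, as.data.frame(v$metrics),
                                    n_ties = v$n_ties)
    }
    results$ensemble <- do.call(rbind, vote_rows)
    utils::write.csv(results$ensemble, file.path(out, "metrics_ensemble.csv"),
                     row.names = FALSE)
  }

  if (config$run_importance && length(tables) == 4L) {
    best <- selected[which.max(selected$mean_accuracy), ]
    srows <- list(); arows <- list()
    for (f in STAT_NAMES) {
      rs <- evaluate_loso(single_feature_table(tables, f), best$technique,
                          best$param, seed = config$seed,
                          hidden = config$nn_hidden)
      srows[[f]] <- data.frame(feature = f, as.data.frame(rs$metrics))
      ra <- evaluate_loso(ablation_table(tables, f), best$technique,
                          best$param, seed = config$seed,
                          hidden = config$nn_hidden)
      arows[[f]] <- data.frame(feature = f, as.data.frame(ra$metrics))
    }
    results$importance <- importance_report(do.call(rbind, srows),
                                            do.call(rbind, arows))
    utils::write.csv(results$importance, file.path(out, "metrics_importance.csv"),
                     row.names = FALSE)
  }

  results$anova <- anova_table(tables, unit = config$anova_unit)
  utils::write.csv(results$anova, file.path(out, "anova_table.csv"),
                   row.names = FALSE)

  jsonlite::write_json(
    list(metrics = ev$metrics, selected = selected,
         ensemble = results$ensemble, anova = results$anova),
    file.path(out, "results.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  jsonlite::write_json(
    list(schema_version = 1L,
         package_version = as.character(utils::packageVersion("mtrptex")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = config$seed,
         config = {cf <- unclass(config); cf$cohort <- unclass(cf$cohort); cf}),
    file.path(out, "provenance.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  ok <- TRUE
  invisible(structure(out, results = results))
}
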