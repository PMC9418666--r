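#' Pipeline configuration
#'
#' Resolves a configuration for [run_pipeline()]: input paths, rule-table
#' overrides, filter criteria, frequency threshold, split settings, model
#' specifications for the filtered (random forest) and full (boosted trees)
#' arms, CV settings, Shapley settings and the global seed. Every run writes
#' the resolved configuration next to its outputs so it can be re-run
#' verbatim.
#'
#' @param receptor,poses,labels input file paths (PDB, SDF, CSV).
#' @param out_dir output directory.
#' @param rules named list of [geometry_rules()] overrides.
#' @param criteria a [filter_criteria()] object (default anchors).
#' @param frequency_threshold minimum feature frequency, default 0.10.
#' @param holdout_fraction,grouping hold-out split settings.
#' @param cv_k,cv_repeats cross-validation settings.
#' @param filtered_model,full_model [model_spec()]s for the two arms.
#' @param shap_max_samples cap on the number of poses explained.
#' @param seed global integer seed.
#' @return object of class `aifp_config`.
#' @export
pipeline_config <- function(receptor, poses, labels, out_dir,
                            rules = list(),
                            criteria = filter_criteria(),
                            frequency_threshold = 0.10,
                            holdout_fraction = 0.20,
                            grouping = "ligand",
                            cv_k = 5, cv_repeats = 2,
                            filtered_model = model_spec("random_forest"),
                            full_model = model_spec("gradient_boosted_trees"),
                            shap_max_samples = 200,
                            seed = 1) {
  structure(
    list(receptor = receptor, poses = poses, labels = labels,
         out_dir = out_dir, rules = rules, criteria = criteria,
         frequency_threshold = frequency_threshold,
         holdout_fraction = holdout_fraction, grouping = grouping,
         cv_k = cv_k, cv_repeats = cv_repeats,
         filtered_model = filtered_model, full_model = full_model,
         shap_max_samples = shap_max_samples, seed = as.integer(seed)),
    class = "aifp_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly; `rules` is a mapping of rule-table
#' overrides; `criteria` may override any [filter_criteria()] argument;
#' `filtered_model` / `full_model` take a `family` plus hyperparameter
#' overrides.
#'
#' @param path YAML file.
#' @return an `aifp_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("receptor", "poses", "labels", "out_dir",
                        "frequency_threshold", "holdout_fraction",
                        "grouping", "cv_k", "cv_repeats",
                        "shap_max_samples", "seed"))]
  if (!is.null(y$rules)) args$rules <- y$rules
  if (!is.null(y$criteria)) {
    cr <- y$criteria
    if (all(c("anchor_1", "anchor_2") %in% names(cr))) {
      # resolved-config form: two anchor blocks
      args$criteria <- filter_criteria(
        anchor1_residue = cr$anchor_1$residue,
        anchor1_atoms = unlist(cr$anchor_1$atoms),
        anchor1_elements = unlist(cr$anchor_1$elements),
        anchor1_types = unlist(cr$anchor_1$types),
        anchor2_residue = cr$anchor_2$residue,
        anchor2_atoms = unlist(cr$anchor_2$atoms),
        anchor2_elements = unlist(cr$anchor_2$elements),
        anchor2_types = unlist(cr$anchor_2$types)
      )
    } else {
      args$criteria <- do.call(filter_criteria, cr)
    }
  }
  for (arm in c("filtered_model", "full_model")) {
    if (!is.null(y[[arm]])) {
      args[[arm]] <- do.call(model_spec, y[[arm]])
    }
  }
  do.call(pipeline_config, args)
}

.write_resolved_config <- function(config, path) {
  y <- list(
    receptor = config$receptor, poses = config$poses, labels = config$labels,
    out_dir = config$out_dir, rules = config$rules,
    criteria = lapply(unclass(config$criteria), unclass),
    frequency_threshold = config$frequency_threshold,
    holdout_fraction = config$holdout_fraction, grouping = config$grouping,
    cv_k = config$cv_k, cv_repeats = config$cv_repeats,
    filtered_model = c(list(family = config$filtered_model$family),
                       config$filtered_model$params),
    full_model = c(list(family = config$full_model$family),
                   config$full_model$params),
    shap_max_samples = config$shap_max_samples, seed = config$seed
  )
  yaml::write_yaml(y, path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full fingerprint-to-pharmacology pipeline
#'
#' Stages, in order: read receptor/poses/labels, assign roles, compute all
#' fingerprints, apply the anchor filter, build the full and filtered
#' binary matrices, apply the frequency filter, compute correlation reports
#' and threshold classifiers, make the stratified hold-out split, train the
#' filtered-arm (random forest) and full-arm (boosted trees) models,
#' cross-validate, evaluate on the hold-out, and compute Shapley global
#' importances. Both arms mirror the study design: the anchor-filtered
#' dataset and the unfiltered full dataset are analysed side by side.
#'
#' Artifacts written to `out_dir`: `aifs.csv`, `filter_report.json`,
#' `matrix_full.csv`, `matrix_filtered.csv`, `correlation_full.csv`,
#' `correlation_filtered.csv`, `eval.json`, `shap_full.csv`,
#' `shap_filtered.csv`, `config_resolved.yaml`.
#'
#' @param config an [pipeline_config()] (or path to a YAML file).
#' @return named list of results (matrices, reports, evaluations, Shapley
#'   summaries and artifact paths), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "aifp_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rules <- do.call(geometry_rules, config$rules)
  receptor <- .stage("ingest", {
    assign_atom_roles(read_receptor(config$receptor))
  })
  poses <- .stage("ingest", {
    lapply(read_poses(config$poses), assign_atom_roles)
  })
  labels <- .stage("ingest", read_labels(config$labels))
  aifs <- .stage("fingerprint", {
    lapply(poses, function(p) compute_aif(receptor, p, rules))
  })
  flt <- .stage("filter", filter_dataset(aifs, config$criteria))
  matrix_full <- .stage("matrix", {
    frequency_filter(build_matrix(aifs, labels), config$frequency_threshold)
  })
  matrix_filtered <- .stage("matrix", {
    frequency_filter(build_matrix(flt$retained, labels),
                     config$frequency_threshold)
  })
  arms <- list(
    full = list(matrix = matrix_full, spec = config$full_model),
    filtered = list(matrix = matrix_filtered, spec = config$filtered_model)
  )
  results <- list()
  for (arm in names(arms)) {
    m <- arms[[arm]]$matrix
    spl <- .stage("split", {
      split_holdout(m, config$holdout_fraction, seed = config$seed,
                    grouping = config$grouping)
    })
    corr <- .stage("correlate", pointwise_correlation(spl$cv))
    thr <- .stage("correlate", fit_threshold_classifier(spl$cv, corr))
    thr_hold <- predict(thr, spl$holdout)
    thr_cm <- confusion_counts(spl$holdout$label, thr_hold)
    model <- .stage("train", train_model(spl$cv, arms[[arm]]$spec,
                                         seed = config$seed))
    cv_eval <- .stage("train", {
      repeated_stratified_kfold(spl$cv, arms[[arm]]$spec, k = config$cv_k,
                                repeats = config$cv_repeats,
                                seed = config$seed,
                                grouping = config$grouping)
    })
    pred_hold <- predict_model(model, spl$holdout, type = "class")
    cm <- confusion_counts(spl$holdout$label, pred_hold)
    shap <- .stage("explain", {
      n <- min(config$shap_max_samples, nrow(spl$cv$values))
      idx <- with_seed(config$seed,
                       sample.int(nrow(spl$cv$values), n))
      bg_idx <- with_seed(config$seed + 1,
                          sample.int(nrow(spl$cv$values), min(20, n)))
      tree_shapley(model, matrix_rows(spl$cv, idx),
                   matrix_rows(spl$cv, bg_idx))
    })
    results[[arm]] <- list(
      matrix = m, split = spl, correlation = corr,
      threshold_classifier = thr,
      threshold_holdout_mcc = mcc_from_confusion(thr_cm),
      model = model, cv = cv_eval,
      holdout_mcc = mcc_from_confusion(cm),
      holdout_accuracy = unname((cm["tp"] + cm["tn"]) / sum(cm)),
      shap_global = global_importance(shap)
    )
  }
  # artifacts
  paths <- list(
    aifs = file.path(config$out_dir, "aifs.csv"),
    filter_report = file.path(config$out_dir, "filter_report.json"),
    matrix_full = file.path(config$out_dir, "matrix_full.csv"),
    matrix_filtered = file.path(config$out_dir, "matrix_filtered.csv"),
    correlation_full = file.path(config$out_dir, "correlation_full.csv"),
    correlation_filtered = file.path(config$out_dir,
                                     "correlation_filtered.csv"),
    eval = file.path(config$out_dir, "eval.json"),
    shap_full = file.path(config$out_dir, "shap_full.csv"),
    shap_filtered = file.path(config$out_dir, "shap_filtered.csv"),
    config = file.path(config$out_dir, "config_resolved.yaml")
  )
  write.csv(aifs_to_table(aifs), paths$aifs, row.names = FALSE)
  write_filter_report(flt$report, paths$filter_report)
  write_matrix_csv(matrix_full, paths$matrix_full)
  write_matrix_csv(matrix_filtered, paths$matrix_filtered)
  write_corr_report(results$full$correlation, paths$correlation_full)
  write_corr_report(results$filtered$correlation, paths$correlation_filtered)
  evl <- lapply(results, function(r) {
    list(cv = r$cv$summary,
         holdout_mcc = r$holdout_mcc,
         holdout_accuracy = r$holdout_accuracy,
         threshold_holdout_mcc = r$threshold_holdout_mcc)
  })
  jsonlite::write_json(c(evl, list(seed = config$seed)), paths$eval,
                       auto_unbox = TRUE, digits = NA)
  write.csv(results$full$shap_global, paths$shap_full, row.names = FALSE)
  write.csv(results$filtered$shap_global, paths$shap_filtered,
            row.names = FALSE)
  .write_resolved_config(config, paths$config)
  invisible(c(results, list(filter_report = flt$report, paths = paths)))
}
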