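# End-to-end pipeline driver: simulate (or ingest) -> detect -> extract ->
# stability-select -> rank -> nested CV -> explain, with every artifact
# written to a run directory and all randomness flowing from one master
# seed.

#' Pipeline configuration
#'
#' @param n_amd,n_negative synthetic class counts (ignored when
#'   `input_manifest` is given).
#' @param scale linear scale of the synthetic images (default 1/5 desk
#'   scale).
#' @param seed master seed; every stage derives its own seed from it.
#' @param out_dir run directory for artifacts.
#' @param input_manifest optional CSV (path, label, center_x, center_y,
#'   radius) to ingest real/previously simulated images instead.
#' @param icc_threshold stability retention threshold.
#' @param augmentation an [augmentation_spec()] (scale-adjusted).
#' @param outer_k,inner_k nested-CV fold counts.
#' @param kinds model kinds to evaluate.
#' @param ensemble an [ensemble_config()].
#' @param n_bins discretisation bins.
#' @param accept_threshold detector acceptance threshold.
#' @param top_k predictors reported per case explanation.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_amd = 62, n_negative = 83, scale = 1 / 5,
                            seed = 1L, out_dir = tempfile("retinomics_run_"),
                            input_manifest = NULL, icc_threshold = 0.80,
                            augmentation = augmentation_spec(scale = scale),
                            outer_k = 10, inner_k = 10,
                            kinds = c("svm", "rf"),
                            ensemble = ensemble_config(), n_bins = 64,
                            accept_threshold = 0.5, top_k = 10) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_amd >= 0, cfg$n_negative >= 0, cfg$scale > 0,
            cfg$icc_threshold >= -1, cfg$outer_k >= 2, cfg$inner_k >= 2,
            cfg$n_bins >= 2, cfg$top_k >= 1)
  if (!is.null(cfg$input_manifest) && !file.exists(cfg$input_manifest)) {
    stop("input manifest not found: ", cfg$input_manifest)
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (!is.null(y$augmentation)) {
    y$augmentation <- do.call(augmentation_spec, y$augmentation)
  }
  if (!is.null(y$ensemble)) y$ensemble <- do.call(ensemble_config, y$ensemble)
  do.call(pipeline_config, y)
}

pipeline_log <- function(stage, t0) {
  message(sprintf("[retinomics] %-10s %6.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full screening pipeline
#'
#' Executes simulate/ingest, macula detection (with mean-position fallback),
#' feature extraction, ICC stability selection under augmentation,
#' univariate predictor ranking, nested cross-validation of the ensemble
#' models, and per-case explanations for the internally mispredicted cases.
#' All artifacts (CSV/JSON) land in `config$out_dir`; identical config +
#' seed reruns give identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with every stage result and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  # --- simulate / ingest ---------------------------------------------------
  if (is.null(config$input_manifest)) {
    scfg <- synth_config(scale = config$scale, seed = seed)
    records <- generate_dataset(config$n_amd, config$n_negative, scfg,
                                derive_seed(seed, 1))
    radius <- scfg$radius
  } else {
    man <- utils::read.csv(config$input_manifest)
    records <- lapply(seq_len(nrow(man)), function(i) {
      img <- read_image(man$path[i])
      list(image = img,
           truth = list(label = man$label[i],
                        macula_center = c(x = man$center_x[i], y = man$center_y[i]),
                        macula_radius = man$radius[i], lesions = list()))
    })
    radius <- man$radius[1]
  }
  labels <- vapply(records, function(r) r$truth$label, character(1))
  ids <- sprintf("case_%03d", seq_along(records))
  pipeline_log("simulate", t0)

  # --- detect --------------------------------------------------------------
  ext <- image_extent(records[[1]]$image)
  truth_rois <- lapply(records, function(r) {
    roi_from_center(r$truth$macula_center, r$truth$macula_radius, ext)
  })
  names(truth_rois) <- ids
  fb <- fallback_center(truth_rois)
  g <- window_geometry(crop_window(), ext)
  detector <- matched_filter_detector(radius)
  outcomes <- lapply(records, function(r) {
    detect_macula(r$image, detector, fb, radius,
                  accept_threshold = config$accept_threshold)
  })
  names(outcomes) <- ids
  dsc <- dsc_study(outcomes, truth_rois)
  utils::write.csv(dsc$per_case, file.path(config$out_dir, "dsc.csv"),
                   row.names = FALSE)
  pipeline_log("detect", t0)

  # --- extract -------------------------------------------------------------
  cat_df <- default_catalogue()
  feat_records <- lapply(seq_along(records), function(i) {
    list(image = records[[i]]$image, roi = outcomes[[i]]$roi,
         case_id = ids[i], label = labels[i])
  })
  features <- extract_feature_table(feat_records, cat_df,
                                    n_bins = config$n_bins)
  utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)
  pipeline_log("extract", t0)

  # --- stability selection -------------------------------------------------
  spec <- config$augmentation
  variant_tables <- lapply(seq_len(spec$n_variants), function(v) NULL)
  per_case_variants <- lapply(seq_along(records), function(i) {
    vs <- augment_case(records[[i]]$image, outcomes[[i]]$roi, spec,
                       case_seed_offset = i)
    lapply(vs, function(p) extract_features(p$image, p$roi, cat_df,
                                            n_bins = config$n_bins))
  })
  variant_tables <- lapply(seq_len(spec$n_variants), function(v) {
    tab <- as.data.frame(do.call(rbind, lapply(per_case_variants,
                                               function(pcv) pcv[[v]])))
    cbind(data.frame(case_id = ids), tab)
  })
  stability <- select_stable(variant_tables, config$icc_threshold)
  utils::write.csv(stability, file.path(config$out_dir, "stability.csv"),
                   row.names = FALSE)
  kept <- stability$feature[stability$retained]
  if (length(kept) < 2) stop("stability selection retained fewer than 2 features")
  pipeline_log("select", t0)

  # --- univariate ranking --------------------------------------------------
  # relevance key: how often the SVM ensemble's Fisher screen selects each
  # feature when trained on the full internal set
  sig_model <- train_model(features[, kept, drop = FALSE], labels, "svm",
                           config$ensemble, seed = derive_seed(seed, 5))
  freqs <- selection_frequencies(sig_model)
  ranking <- rank_predictors(features[, c("case_id", "label", kept)], labels,
                             frequencies = freqs,
                             ci_seed = derive_seed(seed, 3))
  utils::write.csv(ranking, file.path(config$out_dir, "ranking.csv"),
                   row.names = FALSE)
  pipeline_log("rank", t0)

  # --- nested cross-validation --------------------------------------------
  cv <- nested_cv(features[, kept, drop = FALSE], labels,
                  outer_k = config$outer_k, inner_k = config$inner_k,
                  kinds = config$kinds, config = config$ensemble,
                  seed = derive_seed(seed, 4))
  for (k in names(cv$per_kind)) {
    utils::write.csv(cv$per_kind[[k]]$report,
                     file.path(config$out_dir, paste0("performance_", k, ".csv")),
                     row.names = FALSE)
  }
  pipeline_log("crossval", t0)

  # --- explanations for mispredicted internal-test cases -------------------
  ref <- fit_reference(features[, kept, drop = FALSE], labels)
  top <- utils::head(ranking$feature, config$top_k)
  best <- cv$per_kind[[cv$winner]]
  # every mispredicted internal-test case, plus one correct exemplar per
  # class so the report set covers all outcome types
  wrong <- which(best$test_predictions != labels)
  right <- which(best$test_predictions == labels)
  exemplars <- unlist(lapply(c("AMD", "Negative"), function(cl) {
    utils::head(right[labels[right] == cl], 1)
  }))
  reports <- lapply(sort(unique(c(wrong, exemplars))), function(i) {
    explain_case(features[i, kept, drop = FALSE], best$test_predictions[i],
                 ref, top, case_id = ids[i],
                 vote_fraction = best$test_scores[i])
  })
  jsonlite::write_json(
    lapply(reports, function(r) {
      list(case_id = r$case_id, predicted = r$predicted,
           vote_fraction = r$vote_fraction, predictors = r$predictors)
    }),
    file.path(config$out_dir, "explanations.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  utils::write.csv(export_distribution_summaries(ref, top),
                   file.path(config$out_dir, "distribution_summaries.csv"),
                   row.names = FALSE)

  # --- reproducibility record ---------------------------------------------
  jsonlite::write_json(
    list(seed = seed, n_amd = config$n_amd, n_negative = config$n_negative,
         scale = config$scale, icc_threshold = config$icc_threshold,
         n_features_total = nrow(cat_df), n_features_retained = length(kept),
         winner = cv$winner,
         detector_failure_percent = dsc$failure_percent,
         mean_dsc = mean(dsc$per_case$dsc),
         test_auc = as.list(cv$test_auc),
         r_version = as.character(getRversion())),
    file.path(config$out_dir, "run_record.json"),
    auto_unbox = TRUE, digits = NA)
  pipeline_log("done", t0)

  invisible(list(records = records, outcomes = outcomes, dsc = dsc,
                 features = features, stability = stability,
                 ranking = ranking, cv = cv, reference = ref,
                 explanations = reports, out_dir = config$out_dir))
}
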