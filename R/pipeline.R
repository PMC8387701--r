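## End-to-end orchestration: curate -> label -> split -> prune/scale ->
## rank -> (sweep) -> rebalance/train -> evaluate -> domain/consensus,
## driven by a single config and a single master seed. Every stage that
## fits anything (pruning thresholds, scaling statistics, rankings, models)
## sees training-set rows only; test rows are transformed with training
## statistics and touched only at prediction time.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every default filled in.
#' Fields can be overridden by the `...` arguments or by a YAML file via
#' [read_config()]. When `descriptors`/`labels` are `NULL` the pipeline
#' generates the synthetic preset internally.
#'
#' @param ... Named overrides of the defaults.
#' @return A config list of class `aurqsar_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    descriptors = NULL,          # CSV path; NULL = synthetic preset
    labels = NULL,               # CSV path (id,label); NULL = synthetic
    activity = NULL,             # CSV path with log IC20 columns
    smiles = NULL,               # structure file for curation
    scheme = "hse-vs-ina",
    test_fraction = 0.2,
    sd_min = 0.01,
    corr_max = 0.95,
    ranking = list(method = "gini", ntree = 250, n_repeats = 10),
    subset_sizes = NULL,         # NULL = skip the sweep, use all features
    algorithms = c("brf", "knn"),
    grids = list(),              # per-algorithm overrides of default_grid()
    resample = list(method = "smote", k = 5, target_ratio = 1),
    nfolds = 10,
    ad_thresholds = seq(0.5, 1, by = 0.05),
    domain_threshold = 0.65,
    synth = list())              # synth_config() overrides
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "aurqsar_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [default_config()] values.
#' @return A config list of class `aurqsar_config`.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(default_config, over)
}

#' Run the full modelling pipeline
#'
#' Executes every stage in order and writes all artefacts into `out_dir`:
#' `curation_report.csv` (when structures are supplied), `labels.csv`
#' (`id,category,sel,label,split`), `removal_log.csv`, `ranking.csv`,
#' `sweep.csv` (when a subset sweep is configured), one
#' `predictions_<algorithm>.csv` per model, `evaluation.json` and
#' `manifest.json` (the resolved config plus MD5 hashes of every output,
#' so reruns with an identical config can be verified byte-for-byte).
#' The run is deterministic given `config$seed`. A failing stage aborts
#' with an error naming the stage.
#'
#' @param config A config list from [default_config()] or [read_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fitted models and the evaluation
#'   report.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  stopifnot(inherits(config, "aurqsar_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- curation (optional) --------------------------------------------------
  if (!is.null(config$smiles)) {
    stage("curate", {
      rec <- read_structures(config$smiles)
      rep <- curate_structures(rec)
      write_curation_report(rep, file.path(out_dir, "curation_report.csv"))
    })
  }

  # -- labels ---------------------------------------------------------------
  lab <- stage("label", {
    if (!is.null(config$activity)) {
      at <- utils::read.csv(config$activity, stringsAsFactors = FALSE)
      act <- !is.na(at$logic20_tpo)
      sel <- rep(NA_real_, nrow(at))
      sel[act] <- selectivity_score(at$logic20_tpo[act],
                                    at$logic20_luc[act],
                                    at$logic20_cyto[act])
      data.frame(id = as.character(at$id), sel = sel,
                 category = classify_selectivity(sel),
                 stringsAsFactors = FALSE)
    } else if (!is.null(config$labels)) {
      lt <- utils::read.csv(config$labels, stringsAsFactors = FALSE)
      data.frame(id = as.character(lt$id), sel = NA_real_,
                 category = ifelse(as_activity(lt$label) == "active",
                                   "HSE", "INA"),
                 stringsAsFactors = FALSE)
    } else {
      sc <- do.call(synth_config, c(config$synth, list(seed = seed)))
      ft <- synth_feature_table(sc)
      data.frame(id = rownames(ft$x), sel = NA_real_,
                 category = ifelse(ft$y == "active", "HSE", "INA"),
                 stringsAsFactors = FALSE)
    }
  })
  part <- stage("label", apply_partition_scheme(lab$category, config$scheme))
  lab$label <- part$label

  # -- descriptors ----------------------------------------------------------
  x_all <- stage("descriptors", {
    if (!is.null(config$descriptors)) {
      read_descriptors(config$descriptors)
    } else {
      sc <- do.call(synth_config, c(config$synth, list(seed = seed)))
      synth_feature_table(sc)$x
    }
  })
  usable <- !is.na(lab$label) & lab$id %in% rownames(x_all)
  ids <- lab$id[usable]
  y <- lab$label[usable]
  x_all <- x_all[ids, , drop = FALSE]

  # -- split ----------------------------------------------------------------
  spl <- stage("split", stratified_split(y, config$test_fraction, seed))
  lab$split <- NA_character_
  lab$split[usable] <- as.character(spl$split)
  utils::write.csv(lab[, c("id", "category", "sel", "label", "split")],
                   file.path(out_dir, "labels.csv"), row.names = FALSE,
                   na = "")
  tr <- spl$split == "TrS"

  # -- prune + scale (training rows only) -----------------------------------
  pruned <- stage("prune", prune_descriptors(x_all[tr, , drop = FALSE],
                                             config$sd_min, config$corr_max))
  utils::write.csv(pruned$removed, file.path(out_dir, "removal_log.csv"),
                   row.names = FALSE)
  zs <- stage("scale", zscore_fit(pruned$x))
  xs <- stage("scale", zscore_apply(x_all[, colnames(pruned$x),
                                          drop = FALSE], zs))

  # -- feature ranking (+ optional sweep) -----------------------------------
  ranking <- stage("rank", rank_features(
    xs[tr, , drop = FALSE], y[tr], method = config$ranking$method,
    ntree = config$ranking$ntree %||% 250,
    n_repeats = config$ranking$n_repeats %||% 10,
    balanced = "brf" %in% config$algorithms, seed = seed))
  utils::write.csv(as.data.frame(ranking),
                   file.path(out_dir, "ranking.csv"), row.names = FALSE)
  features <- ranking$name
  if (!is.null(config$subset_sizes)) {
    sweep <- stage("sweep", sweep_subsets(
      ranking, xs[tr, , drop = FALSE], y[tr], sizes = config$subset_sizes,
      nfolds = config$nfolds, seed = seed))
    utils::write.csv(as.data.frame(sweep), file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    features <- ranking$name[seq_len(attr(sweep, "best_size"))]
  }

  # -- train + evaluate -----------------------------------------------------
  models <- list()
  reports <- list()
  preds <- list()
  for (alg in config$algorithms) {
    models[[alg]] <- stage(paste0("train_", alg), qsar_train(
      xs[tr, , drop = FALSE], y[tr], algorithm = alg,
      grid = config$grids[[alg]], features = features,
      resample = if (alg == "brf") "none" else config$resample$method,
      smote_k = config$resample$k %||% 5,
      target_ratio = config$resample$target_ratio %||% 1,
      nfolds = config$nfolds,
      seed = substream_seed(seed, paste0("train_", alg))))
    tab <- stage(paste0("predict_", alg), qsar_predict_table(
      models[[alg]], xs[!tr, , drop = FALSE], ids = ids[!tr],
      domain_threshold = config$domain_threshold))
    utils::write.csv(tab, file.path(out_dir,
                                    sprintf("predictions_%s.csv", alg)),
                     row.names = FALSE)
    preds[[alg]] <- tab
    rep <- classification_report(y[!tr], tab$label)
    dc <- domain_curve(tab$probability_predicted_class, y[!tr], tab$label,
                       config$ad_thresholds)
    reports[[alg]] <- list(
      tuned_parameters = models[[alg]]$params,
      n_features = length(features),
      cv_ba = mean(models[[alg]]$cv_report$ba),
      test = list(confusion = unclass(rep$confusion), sen = rep$sen,
                  spe = rep$spe, ba = rep$ba, mcc = rep$mcc, n = rep$n),
      domain_curve = as.data.frame(dc))
  }
  if (length(config$algorithms) >= 2L) {
    a <- config$algorithms[1L]
    b <- config$algorithms[2L]
    cons <- consensus(preds[[a]]$label, preds[[b]]$label, y_true = y[!tr],
                      ids = ids[!tr])
    reports$consensus <- list(
      models = c(a, b), coverage = cons$coverage,
      n = cons$n, n_concordant = round(cons$coverage * cons$n),
      metrics = if (!is.null(cons$metrics)) list(
        confusion = unclass(cons$metrics$confusion),
        sen = cons$metrics$sen, spe = cons$metrics$spe,
        ba = cons$metrics$ba, mcc = cons$metrics$mcc,
        n = cons$metrics$n))
  }
  jsonlite::write_json(reports, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- manifest -------------------------------------------------------------
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("aurqsar")),
    config = unclass(config),
    seed = seed,
    outputs = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$outputs) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(models = models, reports = reports, labels = lab))
}
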