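#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> diversity -> microbial age ->
#' stage classifier -> MiSCH, writing deterministic TSV/JSON artifacts to
#' an output directory. Every artifact derives from the master seed and
#' the configuration alone, so two runs with the same config are
#' byte-identical (wall-clock timings go to a separate run log that is
#' not part of the deterministic artifact set).
#'
#' @param config a run configuration: either a list or a path to a YAML
#'   file. Fields: exactly one of `simulate` (list of
#'   [default_config()] overrides, possibly empty) or `inputs` (list with
#'   `bacteria`, `fungi`, `metadata` TSV paths); optional `stages`
#'   (subset of diversity, age, classify, misch; default all);
#'   `seed` (master seed, default 1); module options `diversity`
#'   (`permutations`), `age` (`iterations`, `subsample`, `folds`),
#'   `classify` (`repeats`, `train_fraction`), `misch` (`repeats`,
#'   `train_fraction`).
#' @param output_dir directory for artifacts (created if missing).
#' @return run report (list of artifact paths and stage summaries),
#'   invisibly; also written as `run_report.json`.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    stop("config must contain exactly one of 'simulate' or 'inputs'")
  }
  stages <- config$stages %||% c("diversity", "age", "classify", "misch")
  bad <- setdiff(stages, c("diversity", "age", "classify", "misch"))
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if ("misch" %in% stages && !has_sim && is.null(config$inputs$metadata)) {
    stop("misch stage requires cohort metadata inputs")
  }
  seed <- config$seed %||% 1L
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_path <- file.path(output_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))

  t0 <- proc.time()[["elapsed"]]
  log_path <- file.path(output_dir, "run_log.jsonl")
  unlink(log_path)
  log_line <- function(stage, ...) {
    rec <- c(list(stage = stage,
                  elapsed_s = round(proc.time()[["elapsed"]] - t0, 2)),
             list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", sep = "",
        file = log_path, append = TRUE)
  }

  artifacts <- character()
  emit <- function(name) {
    artifacts <<- c(artifacts, name)
    file.path(output_dir, name)
  }
  report <- list(package_version = as.character(
                   utils::packageVersion("mischkit")),
                 seed = seed, config_hash = config_hash, stages = list())

  if (has_sim) {
    sim_over <- config$simulate %||% list()
    # YAML parses named vectors as lists; flatten the numeric overrides
    for (nm in c("n_subjects", "age_range")) {
      if (!is.null(sim_over[[nm]])) sim_over[[nm]] <- unlist(sim_over[[nm]])
    }
    sim_cfg <- do.call(default_config, sim_over)
    cohort <- simulate_cohort(sim_cfg, seed = seed_stream(seed, "sim"))
    log_line("simulate", n_samples = nrow(cohort$metadata))
  } else {
    cohort <- list(
      bacteria = read_abundance_table(config$inputs$bacteria, "bacteria"),
      fungi = read_abundance_table(config$inputs$fungi, "fungi"),
      metadata = read_cohort_metadata(config$inputs$metadata))
    sim_cfg <- NULL
    log_line("load", n_samples = nrow(cohort$metadata))
  }
  violations <- validate_cohort(cohort$bacteria, cohort$metadata)
  if (nrow(violations) > 0L) {
    stop("cohort validation failed:\n",
         paste(violations$code, violations$id, sep = ": ",
               collapse = "\n"))
  }
  write_abundance_table(cohort$bacteria, emit("bacteria_genus.tsv"))
  write_abundance_table(cohort$fungi, emit("fungi_genus.tsv"))
  write_cohort_metadata(cohort$metadata, emit("metadata.tsv"))
  merged <- merge_kingdoms(cohort$bacteria, cohort$fungi)
  meta <- cohort$metadata

  if ("diversity" %in% stages) {
    nperm <- config$diversity$permutations %||% 999
    alpha <- data.frame(
      sample_id = sample_ids(merged),
      shannon_bacteria = alpha_diversity(cohort$bacteria, "shannon"),
      shannon_fungi = alpha_diversity(cohort$fungi, "shannon"),
      simpson_bacteria = alpha_diversity(cohort$bacteria, "simpson"),
      simpson_fungi = alpha_diversity(cohort$fungi, "simpson"))
    utils::write.table(format(alpha, digits = 10, trim = TRUE),
                       emit("alpha_diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    dm <- jsd_matrix(merged)
    utils::write.table(
      format(data.frame(sample_id = rownames(dm), dm,
                        check.names = FALSE), digits = 10, trim = TRUE),
      emit("jsd_distance.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    ord <- pcoa(dm, k = 2)
    utils::write.table(
      format(data.frame(sample_id = rownames(ord$coordinates),
                        ord$coordinates), digits = 10, trim = TRUE),
      emit("pcoa_coordinates.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    effects <- factor_effect_sizes(dm, meta,
                                   c("stage", "region", "age_bin"),
                                   n_permutations = nperm,
                                   seed = seed_stream(seed, "effects"))
    jsonlite::write_json(
      lapply(effects, function(e) e[c("factor_name", "pseudo_F",
                                      "r_squared", "p_value")]),
      emit("effect_sizes.json"), auto_unbox = TRUE, digits = NA)
    report$stages$diversity <- list(
      top_factor = effects[[1]]$factor_name,
      top_pseudo_F = effects[[1]]$pseudo_F)
    log_line("diversity", top_factor = effects[[1]]$factor_name)
  }

  if ("age" %in% stages) {
    healthy <- meta[meta$stage == "Healthy", ]
    if (nrow(healthy) >= 10L) {
      acfg <- config$age %||% list()
      ages <- stats::setNames(healthy$age, healthy$sample_id)
      merged_healthy <- subset_samples(merged, healthy$sample_id)
      ranking <- rank_age_features(
        merged_healthy, ages,
        n_iterations = acfg$iterations %||% 10,
        subsample = acfg$subsample %||% 0.9,
        seed = seed_stream(seed, "age_rank"))
      model <- forward_select_age_features(
        ranking, merged_healthy, ages, metadata = healthy,
        folds = acfg$folds %||% 10,
        seed = seed_stream(seed, "age_select"))
      pred <- predict_microbial_age(model, merged)
      curve <- age_curve(pred, meta)
      utils::write.table(
        format(data.frame(taxon_id = ranking$taxon_ids,
                          importance = unname(ranking$importance)),
               digits = 10, trim = TRUE),
        emit("age_feature_ranking.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      jsonlite::write_json(list(selected = model$selected,
                                cv_curve = model$cv_curve),
                           emit("age_model.json"), auto_unbox = TRUE,
                           digits = NA)
      utils::write.table(
        format(data.frame(sample_id = names(pred),
                          predicted_age = unname(pred)),
               digits = 10, trim = TRUE),
        emit("age_predictions.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(format(curve, digits = 10, trim = TRUE),
                         emit("age_curve.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      report$stages$age <- list(n_selected = length(model$selected))
      log_line("age", n_selected = length(model$selected))
    } else {
      warning("fewer than 10 healthy samples; skipping the age stage")
    }
  }

  if ("classify" %in% stages) {
    ccfg <- config$classify %||% list()
    evaluation <- repeated_evaluation(
      merged, meta, n_repeats = ccfg$repeats %||% 10,
      train_fraction = ccfg$train_fraction %||% 0.7,
      seed = seed_stream(seed, "classify"))
    jsonlite::write_json(
      list(per_repeat = evaluation$per_repeat,
           mean_auc = evaluation$mean_auc,
           mean_accuracy = evaluation$mean_accuracy,
           mean_kappa = evaluation$mean_kappa),
      emit("classifier_evaluation.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "columns")
    report$stages$classify <- list(mean_auc = evaluation$mean_auc,
                                   mean_kappa = evaluation$mean_kappa)
    log_line("classify", mean_auc = evaluation$mean_auc)
  }

  if ("misch" %in% stages) {
    mcfg <- config$misch %||% list()
    misch <- compute_misch(
      cohort$bacteria, cohort$fungi, meta,
      n_repeats = mcfg$repeats %||% 20,
      train_fraction = mcfg$train_fraction %||% 0.7,
      seed = seed_stream(seed, "misch"))
    utils::write.table(format(misch$samples, digits = 10, trim = TRUE),
                       emit("misch_samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    utils::write.table(format(misch$subjects, digits = 10, trim = TRUE),
                       emit("misch_subjects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(distances = as.list(misch$weights$distances),
           weights = as.list(misch$weights$weights),
           anova_F = misch$anova$F, anova_p = misch$anova$p),
      emit("misch_weights.json"), auto_unbox = TRUE, digits = NA)
    report$stages$misch <- list(anova_F = misch$anova$F,
                                n_high_risk = sum(misch$samples$high_risk))
    log_line("misch", anova_F = misch$anova$F)
  }

  report$artifacts <- artifacts
  jsonlite::write_json(report, file.path(output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_line("done")
  invisible(report)
}
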