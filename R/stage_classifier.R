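#' Subject-exclusive stratified train/test split
#'
#' Splits at the subject level, stratified by clinical stage, so both
#' scalp-region samples of a subject land on the same side. The number of
#' training subjects per stage is `ceiling(train_fraction * n_stage)`
#' (rounding toward train).
#'
#' @param metadata cohort metadata.
#' @param train_fraction fraction of subjects per stage assigned to
#'   training (default 0.7).
#' @param seed integer seed.
#' @return list with `train` and `test` sample-id vectors and
#'   `train_subjects` / `test_subjects`.
#' @export
subject_split <- function(metadata, train_fraction = 0.7, seed = 1L) {
  subj <- unique(metadata[, c("subject_id", "stage")])
  counts <- table(subj$stage)
  counts <- counts[counts > 0]
  if (any(counts < 2L)) {
    stop("stage(s) with fewer than 2 subjects: ",
         paste(names(counts)[counts < 2L], collapse = ", "))
  }
  set.seed(seed_stream(seed, "subject_split"))
  train_subjects <- character()
  for (st in names(counts)) {
    ids <- subj$subject_id[as.character(subj$stage) == st]
    n_train <- ceiling(train_fraction * length(ids))
    train_subjects <- c(train_subjects, sample(ids, n_train))
  }
  test_subjects <- setdiff(subj$subject_id, train_subjects)
  list(
    train = metadata$sample_id[metadata$subject_id %in% train_subjects],
    test = metadata$sample_id[metadata$subject_id %in% test_subjects],
    train_subjects = train_subjects,
    test_subjects = test_subjects
  )
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the marginal products of the confusion matrix.
#'
#' @param truth,predicted label vectors of equal length.
#' @return numeric kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  lev <- union(truth, predicted)
  tab <- table(factor(truth, lev), factor(predicted, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(ifelse(po >= 1, 1, 0))
  (po - pe) / (1 - pe)
}

#' Macro one-vs-rest AUC
#'
#' Per-class ROC AUC (class vs rest) averaged arithmetically over the
#' classes present in the truth labels. Classes absent from the test
#' labels have undefined AUC and are dropped with a warning.
#'
#' @param truth label vector.
#' @param probabilities matrix of class probabilities with class names as
#'   columns.
#' @return macro-averaged AUC in `[0, 1]`.
#' @export
macro_ovr_auc <- function(truth, probabilities) {
  truth <- as.character(truth)
  classes <- colnames(probabilities)
  aucs <- vapply(classes, function(cl) {
    y <- truth == cl
    if (!any(y) || all(y)) return(NA_real_)
    as.numeric(pROC::auc(
      response = factor(y, c(FALSE, TRUE)),
      predictor = probabilities[, cl],
      levels = c("FALSE", "TRUE"), direction = "<", quiet = TRUE))
  }, numeric(1))
  if (anyNA(aucs)) {
    warning("class(es) absent from truth; macro AUC over defined classes: ",
            paste(classes[is.na(aucs)], collapse = ", "))
  }
  mean(aucs, na.rm = TRUE)
}

default_classifier_params <- function() {
  list(num.trees = 300, mtry = NULL, min.node.size = 1,
       max.depth = 0, class.weights = NULL)
}

#' Fit the multi-class AGA-stage classifier
#'
#' Probability random forest over taxon abundances. The class order of
#' the probability output is fixed to (Healthy, AGA3, AGA5, AGA7)
#' regardless of input label order.
#'
#' @param table an `AbundanceTable` of training samples.
#' @param labels clinical stages aligned with the table's samples (or
#'   named by sample id).
#' @param params list of forest parameters (`num.trees`, `mtry`,
#'   `min.node.size`, `max.depth`, `class.weights`); `NULL` entries fall
#'   back to defaults.
#' @param seed integer seed.
#' @return object of class `stage_classifier`.
#' @export
fit_stage_classifier <- function(table, labels, params = NULL, seed = 1L) {
  if (!is.null(names(labels))) labels <- labels[sample_ids(table)]
  y <- stage_factor(labels)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  p <- utils::modifyList(default_classifier_params(),
                         params %||% list())
  cw <- p$class.weights
  if (identical(cw, "balanced")) {
    tab <- table(y)
    cw <- as.numeric(length(y) / (nlevels(y) * tab))
  }
  df <- as.data.frame(table$values)
  df$.stage <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".stage", data = df, probability = TRUE,
    num.trees = p$num.trees, mtry = p$mtry,
    min.node.size = p$min.node.size, max.depth = p$max.depth,
    class.weights = cw, seed = seed, num.threads = 1)
  structure(list(
    model = fit,
    taxa = taxon_ids(table),
    classes = levels(y),
    params = p,
    seed = seed
  ), class = "stage_classifier")
}

#' Predict stage probabilities
#'
#' @param object a `stage_classifier`.
#' @param table an `AbundanceTable` containing the model's taxa.
#' @param ... unused.
#' @return matrix of probabilities (samples x stages), columns in the
#'   canonical stage order restricted to the classes seen in training;
#'   rows sum to 1.
#' @export
predict.stage_classifier <- function(object, table, ...) {
  missing <- setdiff(object$taxa, taxon_ids(table))
  if (length(missing) > 0L) {
    stop("table is missing taxon(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(table$values[, object$taxa, drop = FALSE])
  pred <- stats::predict(object$model, data = df)$predictions
  ord <- intersect(STAGE_LEVELS, colnames(pred))
  pred <- pred[, ord, drop = FALSE]
  rownames(pred) <- sample_ids(table)
  pred
}

# stratified subject-grouped fold assignment: per stage, subjects are
# shuffled and dealt round-robin into folds
make_grouped_folds <- function(metadata, folds, seed) {
  set.seed(seed)
  subj <- unique(metadata[, c("subject_id", "stage")])
  fold_of_subject <- character(0)
  assign <- stats::setNames(integer(nrow(subj)), subj$subject_id)
  offset <- 0L
  for (st in levels(factor(subj$stage))) {
    ids <- sample(subj$subject_id[as.character(subj$stage) == st])
    assign[ids] <- ((seq_along(ids) - 1L + offset) %% folds) + 1L
    offset <- offset + length(ids)
  }
  unname(assign[metadata$subject_id])
}

# pooled CV kappa of a forest on one table, grouped stratified folds
cv_kappa <- function(table, labels, metadata, folds, seed, params = NULL) {
  fold_id <- make_grouped_folds(metadata, folds,
                                seed_stream(seed, "cv_kappa_folds"))
  y <- stage_factor(labels)
  pred <- rep(NA_character_, length(y))
  for (f in sort(unique(fold_id))) {
    tr_ids <- metadata$sample_id[fold_id != f]
    te_ids <- metadata$sample_id[fold_id == f]
    if (length(unique(y[fold_id != f])) < 2L) next
    fit <- fit_stage_classifier(
      subset_samples(table, tr_ids),
      stats::setNames(as.character(y), metadata$sample_id)[tr_ids],
      params = params, seed = seed_stream(seed, "cv_kappa_fit", f))
    prob <- predict(fit, subset_samples(table, te_ids))
    pred[fold_id == f] <- colnames(prob)[max.col(prob, "first")]
  }
  ok <- !is.na(pred)
  cohen_kappa(as.character(y)[ok], pred[ok])
}

#' Classifier performance grid over taxonomic levels and kingdoms
#'
#' Cross-validated Cohen's kappa of a default-parameter forest for every
#' combination of taxonomic level and feature set (bacteria, fungi,
#' combined), using subject-grouped stratified folds. Identifies which
#' annotation level and kingdom combination carries the most stage
#' signal.
#'
#' @param tables nested list: `tables[[level]][[kingdom]]` with kingdom in
#'   `bacteria`, `fungi`, `combined`; all tables must share one sample
#'   set.
#' @param metadata cohort metadata (provides labels and subject grouping).
#' @param folds CV folds (default 10).
#' @param seed integer seed.
#' @return object of class `level_kingdom_grid`: kappa matrix
#'   (levels x kingdoms) plus attributes.
#' @export
level_kingdom_grid <- function(tables, metadata, folds = 10, seed = 1L) {
  levels_ <- names(tables)
  kingdom_sets <- names(tables[[1]])
  ref_ids <- sort(sample_ids(tables[[1]][[1]]))
  labels <- stats::setNames(as.character(metadata$stage),
                            metadata$sample_id)
  kap <- matrix(NA_real_, length(levels_), length(kingdom_sets),
                dimnames = list(levels_, kingdom_sets))
  for (lv in levels_) {
    for (ks in kingdom_sets) {
      tab <- tables[[lv]][[ks]]
      if (!identical(sort(sample_ids(tab)), ref_ids)) {
        stop("table ", lv, "/", ks, " has a mismatched sample set")
      }
      tab <- subset_samples(tab, metadata$sample_id)
      kap[lv, ks] <- cv_kappa(tab, labels[metadata$sample_id], metadata,
                              folds, seed_stream(seed, paste0("grid_", lv, "_", ks)))
    }
  }
  structure(list(kappa = kap, folds = folds, seed = seed),
            class = "level_kingdom_grid")
}

#' Build the level-by-kingdom table grid from genus tables
#'
#' Aggregates bacterial and fungal genus tables to each requested level
#' with a lineage table and builds the three feature sets (bacteria,
#' fungi, combined) per level.
#'
#' @param bacteria,fungi genus-level `AbundanceTable`s.
#' @param lineage lineage `data.frame`.
#' @param levels taxonomic levels to include (default phylum..genus).
#' @return nested list suitable for [level_kingdom_grid()].
#' @export
build_level_tables <- function(bacteria, fungi, lineage,
                               levels = c("phylum", "class", "order",
                                          "family", "genus")) {
  out <- list()
  for (lv in levels) {
    b <- aggregate_to_level(bacteria, lineage, lv)
    f <- aggregate_to_level(fungi, lineage, lv)
    out[[lv]] <- list(bacteria = b, fungi = f,
                      combined = merge_kingdoms(b, f))
  }
  out
}

#' Importance-ranked feature-count selection curve
#'
#' Ranks taxa by impurity importance from a full-data forest fit, then
#' evaluates ranking prefixes of increasing size by subject-grouped
#' stratified CV kappa. `k_star` is the first prefix size attaining the
#' curve maximum (within 1e-9); the corresponding taxa are the selected
#' biomarker panel.
#'
#' @param table combined-kingdom `AbundanceTable` (genus level by
#'   default).
#' @param metadata cohort metadata.
#' @param k_max largest prefix evaluated (clipped to the taxon count with
#'   a warning).
#' @param folds CV folds (default 10).
#' @param seed integer seed.
#' @return object of class `feature_selection_curve`: list with `curve`
#'   (`data.frame` of k and kappa), `k_star`, `ranked`, `selected`.
#' @export
select_top_features <- function(table, metadata, k_max = 40, folds = 10,
                                seed = 1L) {
  if (k_max > ncol(table$values)) {
    warning("k_max exceeds taxon count; clipping to ", ncol(table$values))
    k_max <- ncol(table$values)
  }
  table <- subset_samples(table, metadata$sample_id)
  labels <- stats::setNames(as.character(metadata$stage),
                            metadata$sample_id)
  full <- fit_stage_classifier_importance(table, labels,
                                          seed_stream(seed, "select_rank"))
  ranked <- names(sort(full, decreasing = TRUE))
  kappa <- vapply(seq_len(k_max), function(k) {
    sub <- abundance_table(
      table$values[, ranked[seq_len(k)], drop = FALSE],
      table$kingdom[ranked[seq_len(k)]], table$level, normalize = FALSE)
    cv_kappa(sub, labels, metadata, folds,
             seed_stream(seed, "select_cv", k))
  }, numeric(1))
  k_star <- which(kappa >= max(kappa) - 1e-9)[1]
  structure(list(
    curve = data.frame(k = seq_len(k_max), kappa = kappa),
    k_star = k_star,
    ranked = ranked[seq_len(k_max)],
    selected = ranked[seq_len(k_star)]
  ), class = "feature_selection_curve")
}

# impurity importances from one probability-forest fit
fit_stage_classifier_importance <- function(table, labels, seed) {
  y <- droplevels(stage_factor(labels[sample_ids(table)]))
  df <- as.data.frame(table$values)
  df$.stage <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".stage", data = df, probability = TRUE,
    num.trees = 500, importance = "impurity", seed = seed,
    num.threads = 1)
  fit$variable.importance
}

# the hyperparameter space: a stand-in grid of the usual forest knobs
hyperparameter_space <- function() {
  list(
    num.trees = c(200, 500, 1000),
    max.depth = c(0, 10, 20),
    min.node.size = c(2, 5, 10),
    mtry_fraction = c(NA, -1, 0.3),   # NA = sqrt(p), -1 = log2(p)
    class.weights = c("none", "balanced")
  )
}

resolve_params <- function(combo, p_taxa) {
  mtry <- if (is.na(combo$mtry_fraction)) {
    max(1L, floor(sqrt(p_taxa)))
  } else if (combo$mtry_fraction < 0) {
    max(1L, floor(log2(p_taxa)))
  } else {
    max(1L, floor(combo$mtry_fraction * p_taxa))
  }
  list(num.trees = combo$num.trees, max.depth = combo$max.depth,
       min.node.size = combo$min.node.size, mtry = mtry,
       class.weights = if (combo$class.weights == "balanced")
         "balanced" else NULL)
}

#' Two-phase hyperparameter search for the stage classifier
#'
#' A broad random search over the full parameter space followed by an
#' exhaustive enumeration of the +/-1-neighbor grid around the incumbent,
#' both scored by subject-grouped CV kappa on the training cohort only.
#'
#' @param table training `AbundanceTable`.
#' @param metadata metadata restricted to the training samples.
#' @param broad_budget random-search draws (default 200).
#' @param folds CV folds for scoring (default 5).
#' @param seed integer seed.
#' @return list with `best_params` (resolved ranger parameters),
#'   `best_kappa`, and `log` (`data.frame`, one row per evaluated
#'   configuration with phase labels).
#' @export
tune_hyperparameters <- function(table, metadata, broad_budget = 200,
                                 folds = 5, seed = 1L) {
  if (broad_budget < 1) stop("broad_budget must be >= 1")
  table <- subset_samples(table, metadata$sample_id)
  labels <- stats::setNames(as.character(metadata$stage),
                            metadata$sample_id)
  space <- hyperparameter_space()
  set.seed(seed_stream(seed, "tune_broad"))
  draws <- lapply(seq_len(broad_budget), function(i) {
    lapply(space, function(vals) vals[sample.int(length(vals), 1)])
  })
  score_combo <- function(combo, i, phase) {
    params <- resolve_params(combo, ncol(table$values))
    kap <- cv_kappa(table, labels, metadata, folds,
                    seed_stream(seed, "tune_score"), params = params)
    data.frame(phase = phase, index = i,
               num.trees = combo$num.trees, max.depth = combo$max.depth,
               min.node.size = combo$min.node.size,
               mtry_fraction = combo$mtry_fraction,
               class.weights = combo$class.weights,
               kappa = kap, stringsAsFactors = FALSE)
  }
  log_rows <- lapply(seq_along(draws), function(i)
    score_combo(draws[[i]], i, "broad"))
  log_df <- do.call(rbind, log_rows)
  incumbent <- draws[[which.max(log_df$kappa)]]
  # neighbor grid: for each dimension keep the incumbent value and its
  # immediate neighbors in the ordered candidate list
  neighbor_values <- lapply(names(space), function(nm) {
    vals <- space[[nm]]
    pos <- which(vapply(vals, identical, logical(1), incumbent[[nm]]))
    vals[max(1, pos - 1):min(length(vals), pos + 1)]
  })
  names(neighbor_values) <- names(space)
  fine_grid <- expand.grid(lapply(neighbor_values, seq_along))
  fine_rows <- lapply(seq_len(nrow(fine_grid)), function(i) {
    combo <- lapply(names(space), function(nm)
      neighbor_values[[nm]][fine_grid[i, nm]])
    names(combo) <- names(space)
    score_combo(combo, i, "fine")
  })
  log_df <- rbind(log_df, do.call(rbind, fine_rows))
  best_row <- which.max(log_df$kappa)
  best_combo <- list(
    num.trees = log_df$num.trees[best_row],
    max.depth = log_df$max.depth[best_row],
    min.node.size = log_df$min.node.size[best_row],
    mtry_fraction = log_df$mtry_fraction[best_row],
    class.weights = log_df$class.weights[best_row])
  list(best_params = resolve_params(best_combo, ncol(table$values)),
       best_kappa = log_df$kappa[best_row],
       log = log_df)
}

#' Repeated subject-exclusive evaluation of the stage classifier
#'
#' For each repeat: a fresh stratified subject-exclusive 70/30 split, a
#' forest fit on the training side, and macro one-vs-rest AUC, accuracy,
#' and Cohen's kappa on the held-out side. Reports per-repeat values and
#' their arithmetic means.
#'
#' @param table an `AbundanceTable`.
#' @param metadata cohort metadata.
#' @param n_repeats number of repeats (default 10).
#' @param train_fraction training fraction per stage (default 0.7).
#' @param seed integer seed.
#' @param params optional classifier parameters (see
#'   [fit_stage_classifier()]).
#' @return object of class `evaluation_report`: list with `per_repeat`
#'   (`data.frame`), `mean_auc`, `mean_accuracy`, `mean_kappa`,
#'   `n_repeats`, `train_fraction`.
#' @export
repeated_evaluation <- function(table, metadata, n_repeats = 10,
                                train_fraction = 0.7, seed = 1L,
                                params = NULL) {
  table <- subset_samples(table, metadata$sample_id)
  labels <- stats::setNames(as.character(metadata$stage),
                            metadata$sample_id)
  rows <- lapply(seq_len(n_repeats), function(r) {
    split <- subject_split(metadata, train_fraction,
                           seed_stream(seed, "repeat_split", r))
    stopifnot(length(intersect(split$train_subjects,
                               split$test_subjects)) == 0L)
    fit <- fit_stage_classifier(
      subset_samples(table, split$train), labels[split$train],
      params = params, seed = seed_stream(seed, "repeat_fit", r))
    prob <- predict(fit, subset_samples(table, split$test))
    truth <- labels[split$test]
    pred <- colnames(prob)[max.col(prob, "first")]
    data.frame(
      repeat_id = r,
      auc = macro_ovr_auc(truth, prob),
      accuracy = mean(pred == truth),
      kappa = cohen_kappa(truth, pred))
  })
  per_repeat <- do.call(rbind, rows)
  structure(list(
    per_repeat = per_repeat,
    mean_auc = mean(per_repeat$auc),
    mean_accuracy = mean(per_repeat$accuracy),
    mean_kappa = mean(per_repeat$kappa),
    n_repeats = n_repeats,
    train_fraction = train_fraction
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "Stage-classifier evaluation over %d subject-exclusive splits:\n  macro OvR AUC = %.3f, accuracy = %.3f, Cohen's kappa = %.3f\n",
    x$n_repeats, x$mean_auc, x$mean_accuracy, x$mean_kappa))
  invisible(x)
}
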