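#' Subsampled importance ranking of taxa for age regression
#'
#' Repeatedly fits a random-forest regressor of host age on taxon
#' abundances, each time on a random subsample of the cohort, and records
#' impurity (Gini) importances. Taxa are ranked by the mean importance
#' across iterations, which is more stable than a single fit.
#'
#' @param table an `AbundanceTable`.
#' @param ages numeric ages aligned with the table's samples (or named by
#'   sample id).
#' @param n_iterations number of subsampled fits (default 10).
#' @param subsample fraction of samples used per iteration (default 0.9).
#' @param seed integer master seed; each iteration uses a derived stream
#'   so earlier iterations are unchanged when `n_iterations` grows.
#' @param num_trees trees per forest (default 500).
#' @return object of class `feature_ranking`: list with `taxon_ids`
#'   (ranked, non-increasing mean importance), `importance`,
#'   `n_iterations`, `subsample`.
#' @export
rank_age_features <- function(table, ages, n_iterations = 10,
                              subsample = 0.9, seed = 1L,
                              num_trees = 500) {
  if (!is.null(names(ages))) ages <- ages[sample_ids(table)]
  n <- nrow(table$values)
  if (n < 10L) stop("need at least 10 samples to rank features")
  m <- max(2L, floor(subsample * n))
  if (m < 2L || m > n) stop("invalid subsample fraction")
  imp <- matrix(0, n_iterations, ncol(table$values),
                dimnames = list(NULL, taxon_ids(table)))
  for (it in seq_len(n_iterations)) {
    it_seed <- seed_stream(seed, "rank_age_features", it)
    set.seed(it_seed)
    idx <- sample(n, m)
    df <- as.data.frame(table$values[idx, , drop = FALSE])
    df$.age <- ages[idx]
    fit <- ranger::ranger(
      dependent.variable.name = ".age", data = df,
      num.trees = num_trees, importance = "impurity",
      seed = it_seed, num.threads = 1)
    imp[it, names(fit$variable.importance)] <- fit$variable.importance
  }
  mean_imp <- colMeans(imp)
  ord <- order(-mean_imp)
  structure(list(
    taxon_ids = taxon_ids(table)[ord],
    importance = mean_imp[ord],
    n_iterations = n_iterations,
    subsample = subsample
  ), class = "feature_ranking")
}

# assign subjects (or samples when subjects is NULL) to k folds;
# both samples of a subject always share a fold
make_regression_folds <- function(n, subjects, folds, seed) {
  set.seed(seed)
  if (is.null(subjects)) {
    return(sample(rep_len(seq_len(folds), n)))
  }
  uniq <- sample(unique(subjects))
  fold_of_subject <- stats::setNames(rep_len(seq_len(folds), length(uniq)),
                                     uniq)
  unname(fold_of_subject[subjects])
}

#' Forward feature selection for the microbial-age model
#'
#' Evaluates prefixes of an importance ranking by k-fold cross-validated
#' mean absolute error (folds grouped by subject when metadata is given,
#' so the two scalp regions of a subject never straddle a fold), selects
#' the smallest prefix within one standard error of the best, and refits
#' on all samples. The model is intended to be trained on healthy
#' subjects only; mixed-stage input is rejected unless
#' `allow_mixed = TRUE`.
#'
#' @param ranking a `feature_ranking` from [rank_age_features()].
#' @param table an `AbundanceTable`.
#' @param ages numeric ages aligned with the table's samples.
#' @param metadata optional cohort metadata (enables the healthy-only
#'   guard and subject-grouped folds).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed.
#' @param max_features largest prefix evaluated (default
#'   `min(30, n taxa)`).
#' @param allow_mixed allow non-Healthy stages in the training data.
#' @param num_trees trees for the CV fits and the final refit.
#' @return object of class `age_model`: list with `selected`, `model`
#'   (fitted ranger), `cv_curve` (`data.frame` of k, MAE, SE), `seed`.
#' @export
forward_select_age_features <- function(ranking, table, ages,
                                        metadata = NULL, folds = 10,
                                        seed = 1L, max_features = NULL,
                                        allow_mixed = FALSE,
                                        num_trees = 300) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (!all(ranking$taxon_ids %in% taxon_ids(table))) {
    stop("ranking refers to taxa absent from the table")
  }
  if (!is.null(names(ages))) ages <- ages[sample_ids(table)]
  n <- nrow(table$values)
  if (folds > n) stop("more folds than samples")
  subjects <- NULL
  if (!is.null(metadata)) {
    meta <- metadata[match(sample_ids(table), metadata$sample_id), ]
    if (!allow_mixed && any(as.character(meta$stage) != "Healthy")) {
      stop("training table contains non-Healthy samples; the microbial",
           " age model is defined on healthy subjects",
           " (set allow_mixed = TRUE to override)")
    }
    subjects <- meta$subject_id
  }
  max_features <- max_features %||% min(30L, length(ranking$taxon_ids))
  max_features <- min(max_features, length(ranking$taxon_ids))
  fold_id <- make_regression_folds(n, subjects, folds,
                                   seed_stream(seed, "age_cv_folds"))
  ks <- seq_len(max_features)
  cv <- data.frame(k = ks, mae = NA_real_, se = NA_real_)
  for (k in ks) {
    feats <- ranking$taxon_ids[seq_len(k)]
    abs_err <- numeric(n)
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f
      df_tr <- as.data.frame(table$values[tr, feats, drop = FALSE])
      df_tr$.age <- ages[tr]
      fit <- ranger::ranger(
        dependent.variable.name = ".age", data = df_tr,
        num.trees = num_trees,
        seed = seed_stream(seed, "age_cv_fit", k * 100 + f),
        num.threads = 1)
      pred <- stats::predict(
        fit, data = as.data.frame(table$values[!tr, feats, drop = FALSE])
      )$predictions
      abs_err[!tr] <- abs(pred - ages[!tr])
    }
    cv$mae[k] <- mean(abs_err)
    cv$se[k] <- stats::sd(abs_err) / sqrt(n)
  }
  best <- which.min(cv$mae)
  threshold <- cv$mae[best] + cv$se[best]
  k_sel <- ks[which(cv$mae <= threshold)[1]]
  selected <- ranking$taxon_ids[seq_len(k_sel)]
  df_all <- as.data.frame(table$values[, selected, drop = FALSE])
  df_all$.age <- ages
  final <- ranger::ranger(
    dependent.variable.name = ".age", data = df_all, num.trees = 500,
    seed = seed_stream(seed, "age_final_fit"), num.threads = 1)
  structure(list(
    selected = selected,
    model = final,
    cv_curve = cv,
    seed = seed
  ), class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf(
    "Microbial age model: %d selected taxa (CV MAE at selection: %.3f years)\n",
    length(x$selected), x$cv_curve$mae[length(x$selected)]))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Predict microbial age for new samples
#'
#' @param model an `age_model`.
#' @param table an `AbundanceTable` containing the model's selected taxa
#'   (column order is irrelevant).
#' @return named numeric vector of predicted ages (years).
#' @export
predict_microbial_age <- function(model, table) {
  missing <- setdiff(model$selected, taxon_ids(table))
  if (length(missing) > 0L) {
    stop("table is missing selected taxon(s): ",
         paste(missing, collapse = ", "))
  }
  df <- as.data.frame(table$values[, model$selected, drop = FALSE])
  pred <- stats::predict(model$model, data = df)$predictions
  stats::setNames(pred, sample_ids(table))
}

#' Microbial-age curve by chronological age bin
#'
#' Mean and dispersion of predicted microbial age per chronological age
#' bin, separately for the healthy group and the AGA group (all stages
#' pooled). Empty bins are omitted.
#'
#' @param predictions named numeric vector of predicted ages.
#' @param metadata cohort metadata covering the predicted samples.
#' @param bin_width age-bin width in years (default 5).
#' @return `data.frame` with `group`, `age_bin`, `bin_mid`, `mean_pred`,
#'   `sd_pred`, `n`.
#' @export
age_curve <- function(predictions, metadata, bin_width = 5) {
  meta <- metadata[match(names(predictions), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop("metadata does not cover all predicted samples")
  }
  grp <- ifelse(as.character(meta$stage) == "Healthy", "Healthy", "AGA")
  bins <- age_bin(meta$age, width = bin_width)
  lo <- as.numeric(sub("^\\[(\\d+),.*$", "\\1", bins))
  key <- paste(grp, bins, sep = "|")
  out <- lapply(unique(key), function(k) {
    sel <- key == k
    data.frame(
      group = grp[sel][1],
      age_bin = bins[sel][1],
      bin_mid = lo[sel][1] + bin_width / 2,
      mean_pred = mean(predictions[sel]),
      sd_pred = stats::sd(predictions[sel]),
      n = sum(sel),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$group, out$bin_mid), ]
}

#' Slope of a microbial-age curve
#'
#' Least-squares slope of bin-mean predicted age on bin midpoint for one
#' group; a healthy cohort with real age structure gives a positive
#' slope, while a dysbiotic cohort whose microbiome is decoupled from age
#' plateaus (slope near zero).
#'
#' @param curve output of [age_curve()].
#' @param group `"Healthy"` or `"AGA"`.
#' @return numeric slope (predicted years per chronological year).
#' @export
age_curve_slope <- function(curve, group) {
  sub <- curve[curve$group == group, ]
  if (nrow(sub) < 2L) stop("need at least two bins to estimate a slope")
  unname(stats::coef(stats::lm(mean_pred ~ bin_mid, data = sub))[2])
}
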