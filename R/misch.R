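#' Stage-distance weights from the healthy microbiome
#'
#' For each AGA stage, the mean Jensen-Shannon divergence over all
#' (healthy sample, stage sample) pairs in the merged multi-kingdom table
#' measures how far that stage's microbiome lies from the healthy one.
#' The healthy distance is 0 by convention; weights are the distances
#' normalized by their maximum, so the most dysbiotic stage has weight 1.
#'
#' @param merged a multi-kingdom `AbundanceTable` (see
#'   [merge_kingdoms()]).
#' @param metadata cohort metadata covering the table's samples.
#' @param isotonic force weights to be non-decreasing with stage severity
#'   (pool-adjacent-violators); by default non-monotone empirical
#'   distances are used as-is with a warning.
#' @return object of class `stage_weights`: list with `distances` and
#'   `weights`, both named by stage in canonical order.
#' @export
stage_distance_weights <- function(merged, metadata, isotonic = FALSE) {
  meta <- metadata[match(sample_ids(merged), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop("metadata does not cover all samples in the merged table")
  }
  stage <- as.character(meta$stage)
  aga_stages <- setdiff(STAGE_LEVELS, "Healthy")
  empty <- c(if (!any(stage == "Healthy")) "Healthy",
             aga_stages[!aga_stages %in% stage])
  if (length(empty) > 0L) {
    stop("empty stage group(s): ", paste(empty, collapse = ", "))
  }
  dm <- jsd_matrix(merged)
  healthy_ids <- sample_ids(merged)[stage == "Healthy"]
  d <- stats::setNames(numeric(length(STAGE_LEVELS)), STAGE_LEVELS)
  for (st in aga_stages) {
    st_ids <- sample_ids(merged)[stage == st]
    d[st] <- mean(dm[healthy_ids, st_ids])
  }
  if (max(d) <= 0) {
    stop("all stage groups coincide with the healthy group; ",
         "distance weights are degenerate")
  }
  if (isotonic) {
    iso <- stats::isoreg(seq_along(d), d)
    d <- stats::setNames(iso$yf, names(d))
  } else if (is.unsorted(d)) {
    warning("empirical stage distances are not monotone in severity; ",
            "using them as-is (set isotonic = TRUE to enforce order)")
  }
  structure(list(distances = d, weights = d / max(d)),
            class = "stage_weights")
}

#' @export
print.stage_weights <- function(x, ...) {
  cat("Stage distances from the healthy microbiome (mean pairwise JSD):\n")
  print(round(x$distances, 4))
  cat("Normalized weights:\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Repeat-averaged held-out stage probabilities
#'
#' Repeatedly splits the cohort into subject-exclusive 70/30 train/test
#' sets, trains the stage classifier on the training side, and records
#' class probabilities for the held-out samples. Each sample's final
#' probability vector is the mean over the repeats in which it was held
#' out, so every probability is an out-of-sample prediction.
#'
#' @param table an `AbundanceTable` (typically the merged genus table).
#' @param metadata cohort metadata.
#' @param n_repeats number of split/train/predict repeats (default 20).
#' @param train_fraction training fraction per stage (default 0.7).
#' @param seed integer seed.
#' @param params optional classifier parameters.
#' @return matrix of averaged probabilities (samples x stages), rows
#'   summing to 1, with attribute `n_heldout` (repeats per sample).
#' @export
averaged_probabilities <- function(table, metadata, n_repeats = 20,
                                   train_fraction = 0.7, seed = 1L,
                                   params = NULL) {
  table <- subset_samples(table, metadata$sample_id)
  labels <- stats::setNames(as.character(metadata$stage),
                            metadata$sample_id)
  ids <- metadata$sample_id
  acc <- matrix(0, length(ids), length(STAGE_LEVELS),
                dimnames = list(ids, STAGE_LEVELS))
  cnt <- stats::setNames(integer(length(ids)), ids)
  for (r in seq_len(n_repeats)) {
    split <- subject_split(metadata, train_fraction,
                           seed_stream(seed, "avgprob_split", r))
    fit <- fit_stage_classifier(
      subset_samples(table, split$train), labels[split$train],
      params = params, seed = seed_stream(seed, "avgprob_fit", r))
    prob <- predict(fit, subset_samples(table, split$test))
    acc[split$test, colnames(prob)] <-
      acc[split$test, colnames(prob)] + prob
    cnt[split$test] <- cnt[split$test] + 1L
  }
  never <- ids[cnt == 0L]
  if (length(never) > 0L) {
    stop("sample(s) never assigned to a test side over ", n_repeats,
         " repeats: ", paste(never, collapse = ", "),
         "; increase n_repeats")
  }
  out <- acc / cnt
  attr(out, "n_heldout") <- cnt
  out
}

#' The MiSCH score
#'
#' Combines stage probabilities with stage-distance weights into the
#' Microbial Index of Scalp Health:
#' `score = 100 * (1 - sum_c p_c * w_c)`, where `w_Healthy = 0` and the
#' most dysbiotic stage has `w = 1`. A microbiome classified as purely
#' healthy scores 100; one classified as purely maximal-stage scores 0;
#' moving probability mass toward a higher-weight stage strictly lowers
#' the score.
#'
#' @param p probability vector over the four stages (canonical order), or
#'   a matrix with one row per sample; rows must sum to 1.
#' @param w a `stage_weights` object (or a numeric weight vector in
#'   canonical stage order).
#' @return numeric score(s) in `[0, 100]`.
#' @export
misch_score <- function(p, w) {
  if (inherits(w, "stage_weights")) w <- w$weights
  if (is.null(dim(p))) p <- matrix(p, 1, dimnames = list(NULL, names(p)))
  if (!is.null(colnames(p))) {
    if (!setequal(colnames(p), STAGE_LEVELS)) {
      stop("probability columns must be the four clinical stages")
    }
    p <- p[, STAGE_LEVELS, drop = FALSE]
  }
  if (any(p < -1e-12) || any(abs(rowSums(p) - 1) > 1e-9)) {
    stop("probabilities must be non-negative and sum to 1 per sample")
  }
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  score <- 100 * (1 - as.vector(p %*% w))
  pmin(pmax(score, 0), 100)
}

#' Severity category of a MiSCH score
#'
#' Upper-closed intervals: healthy `(75, 100]`, mild `(25, 75]`,
#' moderate `(15, 25]`, severe `[0, 15]`.
#'
#' @param score numeric score(s) in `[0, 100]`.
#' @return factor with levels healthy, mild, moderate, severe.
#' @export
categorize <- function(score) {
  if (any(score < 0 | score > 100)) {
    stop("MiSCH scores must lie in [0, 100]")
  }
  cut(score, breaks = c(0, 15, 25, 75, 100),
      labels = c("severe", "moderate", "mild", "healthy"),
      include.lowest = TRUE, right = TRUE)
}

#' Subject-level MiSCH score
#'
#' The lower of the two region scores: a lower score reflects more severe
#' dysbiosis and is the more conservative assessment of the subject.
#'
#' @param score_T,score_H region scores in `[0, 100]`; one may be `NA`
#'   (returned with a warning).
#' @return numeric subject score.
#' @export
subject_score <- function(score_T, score_H) {
  if (is.na(score_T) || is.na(score_H)) {
    warning("missing region score; using the available region only")
    return(ifelse(is.na(score_T), score_H, score_T))
  }
  min(score_T, score_H)
}

CATEGORY_TO_STAGE <- c(healthy = "Healthy", mild = "AGA3",
                       moderate = "AGA5", severe = "AGA7")

#' Discordance flag between clinical stage and MiSCH category
#'
#' Maps the MiSCH category to its stage (healthy to Healthy, mild to
#' AGA3, moderate to AGA5, severe to AGA7) and compares with the clinical
#' stage. A discordant sample gets a flag label
#' `"<clinical>-<mapped>"` in short notation (e.g. `"H-A3"`, `"A5-A7"`,
#' with an en dash); samples whose microbiome looks more severe than
#' their clinical stage are the high-risk cases.
#'
#' @param stage clinical stage(s).
#' @param category MiSCH categor(ies) from [categorize()].
#' @return `data.frame` with `stage`, `category`, `mapped_stage`, `flag`
#'   (`NA` when concordant), `direction` (more-severe / less-severe /
#'   concordant), and logical `high_risk`.
#' @export
flag_high_risk <- function(stage, category) {
  stage <- as.character(stage)
  category <- as.character(category)
  mapped <- unname(CATEGORY_TO_STAGE[category])
  delta <- stage_rank(mapped) - stage_rank(stage)
  direction <- ifelse(delta > 0, "more-severe",
                      ifelse(delta < 0, "less-severe", "concordant"))
  flag <- ifelse(delta == 0, NA_character_,
                 paste0(STAGE_SHORT[stage], "\u2013", STAGE_SHORT[mapped]))
  data.frame(stage = stage, category = category, mapped_stage = mapped,
             flag = flag, direction = direction,
             high_risk = delta > 0, stringsAsFactors = FALSE)
}

#' PERMANOVA comparison of a flagged group against reference stages
#'
#' Tests how separable the flagged (high-risk) samples are from each
#' reference stage group on the same distance matrix: a smaller pseudo-F
#' against a stage means the flagged microbiomes are more similar to that
#' stage.
#'
#' @param dm distance matrix over (at least) the flagged and reference
#'   samples.
#' @param flagged_ids sample ids of the flagged group.
#' @param reference_groups named list of sample-id vectors, one per
#'   reference stage.
#' @param n_permutations,seed passed to [permanova()].
#' @return named list of `permanova_result`, one per reference group.
#' @export
compare_flagged_group <- function(dm, flagged_ids, reference_groups,
                                  n_permutations = 999, seed = 1L) {
  if (length(flagged_ids) == 0L) stop("flagged group is empty")
  res <- list()
  for (nm in names(reference_groups)) {
    ref <- setdiff(reference_groups[[nm]], flagged_ids)
    if (length(ref) < 2L) {
      stop("reference group ", nm, " has fewer than 2 samples")
    }
    ids <- c(flagged_ids, ref)
    grouping <- stats::setNames(
      c(rep("flagged", length(flagged_ids)), rep(nm, length(ref))), ids)
    res[[nm]] <- permanova(dm[ids, ids], grouping,
                           n_permutations = n_permutations,
                           seed = seed_stream(seed, "flagged_vs", match(nm, names(reference_groups))),
                           factor_name = paste0("flagged_vs_", nm))
  }
  res
}

#' ANOVA of MiSCH scores by clinical stage
#'
#' One-way ANOVA quantifying how well the index separates clinical
#' severity levels.
#'
#' @param scores numeric MiSCH scores.
#' @param stages clinical stages aligned with `scores`.
#' @return list with `F` and `p`.
#' @export
score_association_anova <- function(scores, stages) {
  g <- factor(as.character(stages))
  if (nlevels(g) < 2L) stop("need at least 2 stages")
  oneway_anova(scores, g)
}

misch_default_params <- function() {
  # final-model forest settings: more trees than the screening default,
  # ranger's probability-forest node size, and balanced class weights to
  # offset the healthy-dominated cohort design
  list(num.trees = 500, min.node.size = 10, class.weights = "balanced")
}

#' Full MiSCH computation for a cohort
#'
#' Convenience wrapper reproducing the full index protocol: merges the
#' kingdom tables, derives stage-distance weights from the complete
#' multi-kingdom profile, selects the optimal discriminative genus panel
#' (cross-validated kappa curve), computes repeat-averaged held-out
#' probabilities from a classifier on that panel, scores every sample,
#' assigns severity categories and discordance flags, and applies the
#' lower-of-two-regions rule per subject.
#'
#' @param bacteria,fungi genus-level `AbundanceTable`s.
#' @param metadata cohort metadata.
#' @param n_repeats probability-averaging repeats (default 20).
#' @param train_fraction training fraction per repeat (default 0.7).
#' @param seed integer seed.
#' @param params classifier parameters for the probability model
#'   (defaults: 500 trees, node size 10, balanced class weights).
#' @param features taxon panel for the probability model; `NULL` (the
#'   default) selects it with [select_top_features()]; `"all"` uses every
#'   taxon.
#' @param k_max,folds passed to [select_top_features()] when the panel is
#'   selected here.
#' @return object of class `misch_result`: list with `weights`
#'   (`stage_weights`), `features`, `probabilities`, `samples`
#'   (per-sample `data.frame`: score, category, flag), `subjects`
#'   (per-subject min-rule scores), and `anova` (score-by-stage F and p).
#' @export
compute_misch <- function(bacteria, fungi, metadata, n_repeats = 20,
                          train_fraction = 0.7, seed = 1L, params = NULL,
                          features = NULL, k_max = 30, folds = 10) {
  merged <- merge_kingdoms(bacteria, fungi)
  merged <- subset_samples(merged, metadata$sample_id)
  weights <- stage_distance_weights(merged, metadata)
  params <- utils::modifyList(misch_default_params(), params %||% list())
  if (is.null(features)) {
    sel <- select_top_features(merged, metadata,
                               k_max = min(k_max, ncol(merged$values)),
                               folds = folds,
                               seed = seed_stream(seed, "misch_select"))
    features <- sel$selected
  } else if (identical(features, "all")) {
    features <- taxon_ids(merged)
  } else {
    missing <- setdiff(features, taxon_ids(merged))
    if (length(missing) > 0L) {
      stop("feature panel not in the merged table: ",
           paste(missing, collapse = ", "))
    }
  }
  panel <- abundance_table(merged$values[, features, drop = FALSE],
                           merged$kingdom[features], merged$level,
                           normalize = FALSE)
  prob <- averaged_probabilities(panel, metadata, n_repeats,
                                 train_fraction, seed, params)
  score <- misch_score(prob, weights)
  category <- categorize(score)
  flags <- flag_high_risk(metadata$stage, category)
  samples <- data.frame(
    sample_id = metadata$sample_id,
    subject_id = metadata$subject_id,
    region = metadata$region,
    stage = as.character(metadata$stage),
    score = score,
    category = as.character(category),
    flag = flags$flag,
    direction = flags$direction,
    high_risk = flags$high_risk,
    stringsAsFactors = FALSE)
  subj_rows <- lapply(unique(samples$subject_id), function(s) {
    rows <- samples[samples$subject_id == s, ]
    sT <- rows$score[rows$region == "T"]
    sH <- rows$score[rows$region == "H"]
    sc <- if (length(sT) == 1L && length(sH) == 1L) {
      min(sT, sH)
    } else {
      rows$score[1]
    }
    data.frame(subject_id = s, stage = rows$stage[1], score = sc,
               category = as.character(categorize(sc)),
               stringsAsFactors = FALSE)
  })
  anova_res <- score_association_anova(samples$score, samples$stage)
  structure(list(
    weights = weights,
    features = features,
    probabilities = prob,
    samples = samples,
    subjects = do.call(rbind, subj_rows),
    anova = anova_res,
    n_repeats = n_repeats,
    seed = seed
  ), class = "misch_result")
}

#' @export
print.misch_result <- function(x, ...) {
  cat(sprintf(
    "MiSCH over %d samples (%d probability repeats)\n",
    nrow(x$samples), x$n_repeats))
  print(x$weights)
  cat("Category counts:\n")
  print(table(x$samples$category))
  cat(sprintf("Score ~ clinical stage: F = %.2f, p = %.3g\n",
              x$anova$F, x$anova$p))
  invisible(x)
}

#' Score discordance flags against a known truth labeling
#'
#' Given ground-truth ids of samples whose microbiome genuinely belongs
#' to a more severe stage (e.g. from [inject_high_risk()]), computes
#' recall, precision, specificity, and the weighted F1 over the
#' flagged/not-flagged labeling.
#'
#' @param samples the `samples` table of a `misch_result`.
#' @param truth_ids sample ids that are genuinely high-risk.
#' @param flag restrict to one flag label (e.g. `"A5-A7"`); by
#'   default any high-risk flag counts.
#' @return list with `recall`, `precision`, `specificity`, `f1_weighted`,
#'   and the 2x2 confusion counts.
#' @export
evaluate_flags <- function(samples, truth_ids, flag = NULL) {
  flagged <- if (is.null(flag)) {
    samples$high_risk
  } else {
    !is.na(samples$flag) & samples$flag == flag
  }
  truth <- samples$sample_id %in% truth_ids
  tp <- sum(flagged & truth)
  fp <- sum(flagged & !truth)
  fn <- sum(!flagged & truth)
  tn <- sum(!flagged & !truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1_pos <- if (is.na(prec) || is.na(rec) || prec + rec == 0) 0 else
    2 * prec * rec / (prec + rec)
  prec_neg <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  rec_neg <- spec
  f1_neg <- if (is.na(prec_neg) || is.na(rec_neg) ||
                prec_neg + rec_neg == 0) 0 else
    2 * prec_neg * rec_neg / (prec_neg + rec_neg)
  n_pos <- tp + fn
  n_neg <- tn + fp
  list(recall = rec, precision = prec, specificity = spec,
       f1_weighted = (f1_pos * n_pos + f1_neg * n_neg) / (n_pos + n_neg),
       tp = tp, fp = fp, fn = fn, tn = tn)
}
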