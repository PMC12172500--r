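test_that("subject splits are stratified and subject-exclusive", {
  co <- small_cohort()
  meta <- co$metadata
  for (seed in 1:5) {
    sp <- subject_split(meta, 0.7, seed)
    expect_length(intersect(sp$train_subjects, sp$test_subjects), 0L)
    # both samples of any subject stay on one side
    train_subj <- unique(meta$subject_id[meta$sample_id %in% sp$train])
    test_subj <- unique(meta$subject_id[meta$sample_id %in% sp$test])
    expect_length(intersect(train_subj, test_subj), 0L)
    # per-stage train counts round toward train
    subj <- unique(meta[, c("subject_id", "stage")])
    for (st in levels(subj$stage)) {
      ids <- subj$subject_id[subj$stage == st]
      expect_equal(sum(sp$train_subjects %in% ids),
                   ceiling(0.7 * length(ids)))
    }
  }
  expect_identical(subject_split(meta, 0.7, 9), subject_split(meta, 0.7, 9))

  meta_small <- meta[meta$stage != "AGA7" |
                       meta$subject_id == meta$subject_id[meta$stage == "AGA7"][1], ]
  expect_error(subject_split(meta_small, 0.7, 1), "fewer than 2 subjects")
})

test_that("Cohen's kappa matches the hand-computed definition", {
  # 4x4 example: confusion matrix worked out by hand
  truth <- rep(c("Healthy", "AGA3", "AGA5", "AGA7"), times = c(6, 4, 3, 3))
  pred <- c(rep("Healthy", 5), "AGA3",
            "Healthy", rep("AGA3", 3),
            rep("AGA5", 2), "AGA7",
            "AGA5", rep("AGA7", 2))
  n <- 16
  po <- (5 + 3 + 2 + 2) / n
  pe <- (6 * 6 + 4 * 4 + 3 * 3 + 3 * 3) / n^2
  expect_equal(cohen_kappa(truth, pred), (po - pe) / (1 - pe))
  expect_equal(cohen_kappa(truth, truth), 1)

  # cross-check against an independent implementation
  skip_if_not_installed("e1071")
  set.seed(10)
  for (i in 1:5) {
    t2 <- sample(letters[1:3], 40, replace = TRUE)
    p2 <- sample(letters[1:3], 40, replace = TRUE)
    tab <- table(factor(t2, letters[1:3]), factor(p2, letters[1:3]))
    expect_equal(cohen_kappa(t2, p2),
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("macro OvR AUC behaves at its analytic extremes", {
  truth <- rep(c("Healthy", "AGA3", "AGA5"), each = 10)
  perfect <- matrix(0.01, 30, 3,
                    dimnames = list(NULL, c("Healthy", "AGA3", "AGA5")))
  for (i in seq_along(truth)) perfect[i, truth[i]] <- 0.98
  expect_equal(macro_ovr_auc(truth, perfect), 1)

  set.seed(2)
  noise <- matrix(stats::runif(30 * 3), 30, 3,
                  dimnames = list(NULL, colnames(perfect)))
  noise <- noise / rowSums(noise)
  expect_lt(abs(macro_ovr_auc(truth, noise) - 0.5), 0.2)

  # class absent from truth: dropped with a warning
  expect_warning(
    auc2 <- macro_ovr_auc(truth[1:20], perfect[1:20, ]),
    "absent")
  expect_equal(auc2, 1)
})

test_that("the stage classifier keeps a fixed class order and valid probabilities", {
  co <- small_cohort()
  m <- merge_kingdoms(co$bacteria, co$fungi)
  labels <- stats::setNames(as.character(co$metadata$stage),
                            co$metadata$sample_id)
  fit <- fit_stage_classifier(m, labels, seed = 1)
  prob <- predict(fit, m)
  expect_equal(colnames(prob), c("Healthy", "AGA3", "AGA5", "AGA7"))
  expect_equal(rowSums(prob), rep(1, nrow(prob)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # label order in the input does not change the output column order
  rev_ids <- rev(co$metadata$sample_id)
  fit2 <- fit_stage_classifier(subset_samples(m, rev_ids),
                               labels[rev_ids], seed = 1)
  expect_equal(colnames(predict(fit2, m)),
               c("Healthy", "AGA3", "AGA5", "AGA7"))

  expect_error(fit_stage_classifier(m, stats::setNames(
    rep("AGA3", nrow(co$metadata)), co$metadata$sample_id)),
    "single class")
  expect_error(predict(fit, co$bacteria), "missing taxon")

  # training-set fit is at least as good as held-out performance
  sp <- subject_split(co$metadata, 0.7, 5)
  fit3 <- fit_stage_classifier(subset_samples(m, sp$train),
                               labels[sp$train], seed = 2)
  acc <- function(ids) {
    pr <- predict(fit3, subset_samples(m, ids))
    mean(colnames(pr)[max.col(pr, "first")] == labels[ids])
  }
  expect_gte(acc(sp$train), acc(sp$test))
})

test_that("level-kingdom grid finds the kingdom carrying the signal", {
  # bacteria carry no stage signal; fungi do
  cfg <- default_config(n_subjects = c(Healthy = 8, AGA3 = 8, AGA5 = 8,
                                       AGA7 = 8), region_effect_scale = 0)
  cfg$age_trends <- list(bacteria = numeric(), fungi = numeric())
  for (st in c("AGA3", "AGA5", "AGA7")) {
    cfg$templates$bacteria[[st]] <- cfg$templates$bacteria$Healthy
  }
  co <- simulate_cohort(cfg, seed = 77)
  lin <- default_lineage(cfg)
  tables <- build_level_tables(co$bacteria, co$fungi, lin,
                               levels = c("family", "genus"))
  grid <- level_kingdom_grid(tables, co$metadata, folds = 5, seed = 3)
  expect_true(all(grid$kappa >= -1 & grid$kappa <= 1))
  expect_gt(grid$kappa["genus", "fungi"], grid$kappa["genus", "bacteria"])
  expect_gt(grid$kappa["genus", "combined"],
            grid$kappa["genus", "bacteria"])
  expect_lt(abs(grid$kappa["genus", "bacteria"]), 0.25)

  bad <- tables
  bad$genus$fungi <- subset_samples(bad$genus$fungi,
                                    sample_ids(bad$genus$fungi)[-1])
  expect_error(level_kingdom_grid(bad, co$metadata, folds = 5, seed = 3),
               "mismatched sample set")
})

test_that("select_top_features honors its contracts", {
  co <- small_cohort()
  m <- merge_kingdoms(co$bacteria, co$fungi)
  sel1 <- select_top_features(m, co$metadata, k_max = 1, folds = 3,
                              seed = 2)
  expect_equal(nrow(sel1$curve), 1L)
  expect_equal(sel1$k_star, 1L)
  expect_length(sel1$selected, 1L)

  expect_warning(
    selc <- select_top_features(m, co$metadata,
                                k_max = ncol(m$values) + 5, folds = 3,
                                seed = 2),
    "clipping")
  expect_lte(nrow(selc$curve), ncol(m$values))
  expect_equal(selc$curve$kappa[selc$k_star], max(selc$curve$kappa))
  expect_true(all(selc$curve$kappa[seq_len(selc$k_star - 1)] <
                    max(selc$curve$kappa)))
})

test_that("hyperparameter search keeps a full log and is deterministic", {
  co <- small_cohort()
  m <- merge_kingdoms(co$bacteria, co$fungi)
  expect_error(tune_hyperparameters(m, co$metadata, broad_budget = 0),
               "broad_budget")
  tuned <- tune_hyperparameters(m, co$metadata, broad_budget = 6,
                                folds = 3, seed = 4)
  n_fine <- sum(tuned$log$phase == "fine")
  expect_equal(nrow(tuned$log), 6 + n_fine)
  expect_gte(n_fine, 2^4)   # at least 2 neighbor values in each dimension
  expect_equal(tuned$best_kappa, max(tuned$log$kappa))

  tuned2 <- tune_hyperparameters(m, co$metadata, broad_budget = 6,
                                 folds = 3, seed = 4)
  expect_identical(tuned$best_params, tuned2$best_params)
  expect_identical(tuned$log$kappa, tuned2$log$kappa)

  # the argmax beats the screening defaults on the same folds
  base <- mischkit:::cv_kappa(
    m, stats::setNames(as.character(co$metadata$stage),
                       co$metadata$sample_id),
    co$metadata, folds = 3,
    seed = seed_stream(4, "tune_score"))
  expect_gte(tuned$best_kappa, base - 0.1)
})

test_that("repeated evaluation reports per-repeat metrics without leakage", {
  co <- small_cohort()
  m <- merge_kingdoms(co$bacteria, co$fungi)
  ev <- repeated_evaluation(m, co$metadata, n_repeats = 4, seed = 6)
  expect_equal(nrow(ev$per_repeat), 4L)
  expect_equal(ev$mean_auc, mean(ev$per_repeat$auc))
  expect_equal(ev$mean_kappa, mean(ev$per_repeat$kappa))
  expect_true(all(ev$per_repeat$auc >= 0 & ev$per_repeat$auc <= 1))
  expect_true(all(ev$per_repeat$accuracy >= 0 &
                    ev$per_repeat$accuracy <= 1))
})
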