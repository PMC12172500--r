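test_that("stage distances match a pairwise enumeration oracle", {
  # hand-constructed two-taxon compositions, one sample per AGA stage
  v <- rbind(
    h1 = c(0.9, 0.1), h2 = c(0.8, 0.2),
    a3 = c(0.6, 0.4), a5 = c(0.4, 0.6), a7 = c(0.1, 0.9))
  colnames(v) <- c("tA", "tB")
  tab <- abundance_table(v, "bacteria")
  meta <- cohort_metadata(
    sample_id = rownames(v),
    subject_id = c("s1", "s2", "s3", "s4", "s5"),
    region = "T", age = rep(30, 5),
    stage = c("Healthy", "Healthy", "AGA3", "AGA5", "AGA7"))
  w <- stage_distance_weights(tab, meta)
  d_oracle <- function(q) mean(c(jsd_oracle(v["h1", ], q),
                                 jsd_oracle(v["h2", ], q)))
  expect_equal(unname(w$distances),
               c(0, d_oracle(v["a3", ]), d_oracle(v["a5", ]),
                 d_oracle(v["a7", ])), tolerance = 1e-12)
  expect_equal(unname(w$weights[4]), 1)
  expect_equal(unname(w$weights), unname(w$distances / max(w$distances)))

  # identical groups are degenerate
  v_same <- v; v_same[] <- rep(c(0.5, 0.5), each = 5)
  expect_error(stage_distance_weights(abundance_table(v_same, "bacteria"),
                                      meta),
               "degenerate")
  expect_error(
    stage_distance_weights(subset_samples(tab, rownames(v)[-3]),
                           meta[-3, ]),
    "empty stage")

  # non-monotone distances warn unless isotonic correction is requested
  v_swap <- v; v_swap["a5", ] <- c(0.05, 0.95)
  tab_swap <- abundance_table(v_swap, "bacteria")
  expect_warning(w2 <- stage_distance_weights(tab_swap, meta),
                 "not monotone")
  w3 <- stage_distance_weights(tab_swap, meta, isotonic = TRUE)
  expect_true(!is.unsorted(w3$weights))
})

test_that("the default cohort's stage distances increase with severity", {
  co <- default_cohort()
  m <- merge_kingdoms(co$bacteria, co$fungi)
  w <- stage_distance_weights(m, co$metadata)
  d <- w$distances
  expect_true(d["AGA3"] < d["AGA5"] && d["AGA5"] < d["AGA7"])
})

test_that("misch_score implements the weighted-complement combiner", {
  w <- c(Healthy = 0, AGA3 = 0.4, AGA5 = 0.7, AGA7 = 1.0)
  expect_equal(misch_score(c(Healthy = 1, AGA3 = 0, AGA5 = 0, AGA7 = 0),
                           w), 100)
  expect_equal(misch_score(c(Healthy = 0, AGA3 = 0, AGA5 = 0, AGA7 = 1),
                           w), 0)
  expect_equal(misch_score(rep(0.25, 4), w), 100 * (1 - 0.525))

  expect_error(misch_score(c(0.5, 0.2, 0.2, 0.2), w), "sum to 1")
  expect_error(misch_score(c(Healthy = 0.5, AGA3 = 0.5, AGA5 = 0,
                             AGA7 = 0), w * 2), "\\[0, 1\\]")

  # strict monotonicity: moving mass eps toward a higher-weight stage
  # lowers the score by exactly 100 * eps * (w_j - w_i)
  p <- c(Healthy = 0.4, AGA3 = 0.3, AGA5 = 0.2, AGA7 = 0.1)
  eps <- 0.05
  for (ij in list(c(1, 2), c(2, 4), c(1, 4), c(3, 4))) {
    q <- p
    q[ij[1]] <- q[ij[1]] - eps
    q[ij[2]] <- q[ij[2]] + eps
    expect_equal(misch_score(p, w) - misch_score(q, w),
                 100 * eps * (w[ij[2]] - w[ij[1]]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("category boundaries follow the printed upper-closed intervals", {
  expect_equal(as.character(categorize(c(80, 100, 75.0001))),
               rep("healthy", 3))
  expect_equal(as.character(categorize(c(75, 30, 25.0001))),
               rep("mild", 3))
  expect_equal(as.character(categorize(c(25, 20, 15.0001))),
               rep("moderate", 3))
  expect_equal(as.character(categorize(c(15, 5, 0))), rep("severe", 3))
  expect_error(categorize(101), "\\[0, 100\\]")
  expect_error(categorize(-0.1), "\\[0, 100\\]")
})

test_that("subject score takes the lower of the two regions", {
  expect_equal(subject_score(80, 40), 40)
  expect_equal(subject_score(33, 33), 33)
  expect_equal(subject_score(40, 80), subject_score(80, 40))
  expect_warning(s <- subject_score(NA, 70), "missing region")
  expect_equal(s, 70)
})

test_that("discordance flags map categories to stages", {
  f1 <- flag_high_risk("Healthy", "mild")
  expect_equal(f1$flag, "H\u2013A3")
  expect_true(f1$high_risk)
  f2 <- flag_high_risk("AGA5", "severe")
  expect_equal(f2$flag, "A5\u2013A7")
  expect_equal(f2$direction, "more-severe")
  f3 <- flag_high_risk("AGA3", "mild")
  expect_true(is.na(f3$flag))
  expect_false(f3$high_risk)
  f4 <- flag_high_risk("AGA7", "moderate")
  expect_equal(f4$direction, "less-severe")
  expect_false(f4$high_risk)

  # round trip: the category matching a stage is always concordant
  cat_of <- c(Healthy = "healthy", AGA3 = "mild", AGA5 = "moderate",
              AGA7 = "severe")
  for (st in names(cat_of)) {
    expect_equal(flag_high_risk(st, cat_of[[st]])$direction, "concordant")
  }
})

test_that("flag evaluation computes the confusion summary", {
  samples <- data.frame(
    sample_id = paste0("s", 1:10),
    flag = c(rep("A5\u2013A7", 4), NA, NA, "A5\u2013A3", NA, NA, NA),
    high_risk = c(rep(TRUE, 4), rep(FALSE, 6)),
    stringsAsFactors = FALSE)
  truth <- paste0("s", c(1, 2, 3, 5))
  ev <- evaluate_flags(samples, truth, flag = "A5\u2013A7")
  expect_equal(ev$tp, 3)
  expect_equal(ev$fp, 1)
  expect_equal(ev$fn, 1)
  expect_equal(ev$tn, 5)
  expect_equal(ev$recall, 0.75)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$specificity, 5 / 6)
  f1_pos <- 0.75
  f1_neg <- 2 * (5 / 6) * (5 / 6) / (5 / 6 + 5 / 6)
  expect_equal(ev$f1_weighted, (f1_pos * 4 + f1_neg * 6) / 10)
})

test_that("averaged probabilities are held-out, normalized, reproducible", {
  co <- small_cohort()
  m <- merge_kingdoms(co$bacteria, co$fungi)
  p1 <- averaged_probabilities(m, co$metadata, n_repeats = 20, seed = 4,
                               params = list(num.trees = 100))
  p2 <- averaged_probabilities(m, co$metadata, n_repeats = 20, seed = 4,
                               params = list(num.trees = 100))
  expect_equal(p1, p2)
  expect_equal(rowSums(p1), rep(1, nrow(p1)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(colnames(p1), c("Healthy", "AGA3", "AGA5", "AGA7"))

  expect_error(
    averaged_probabilities(m, co$metadata, n_repeats = 1, seed = 3,
                           params = list(num.trees = 50)),
    "increase n_repeats")
})

test_that("score ANOVA separates planted monotone scores", {
  stages <- rep(c("Healthy", "AGA3", "AGA5", "AGA7"), each = 10)
  set.seed(8)
  scores <- c(rnorm(10, 85, 5), rnorm(10, 60, 5), rnorm(10, 30, 5),
              rnorm(10, 10, 5))
  res <- score_association_anova(scores, stages)
  expect_lt(res$p, 0.01)

  res0 <- score_association_anova(rep(50, 40), stages)
  expect_equal(res0$F, 0)

  two <- score_association_anova(c(1, 2, 3, 4, 5, 6),
                                 rep(c("Healthy", "AGA3"), each = 3))
  expect_equal(two$F, 13.5)
  expect_error(score_association_anova(1:5, rep("AGA3", 5)),
               "at least 2 stages")
})

test_that("compare_flagged_group contrasts a flagged set with references", {
  # iid samples: a flagged subset of the same population shows no
  # separation, while a shifted population does
  set.seed(61)
  base <- matrix(stats::rgamma(20 * 8, 2), 20, 8)
  shifted <- matrix(stats::rgamma(10 * 8, 2), 10, 8)
  shifted[, 1] <- shifted[, 1] + 6
  v <- rbind(base, shifted)
  dimnames(v) <- list(sprintf("s%02d", 1:30), paste0("t", 1:8))
  dm <- jsd_matrix(abundance_table(v, "bacteria"))
  same_pop <- sprintf("s%02d", 6:20)
  far_pop <- sprintf("s%02d", 21:30)
  flagged <- sprintf("s%02d", 1:5)
  res <- compare_flagged_group(dm, flagged,
                               list(same = same_pop, far = far_pop),
                               n_permutations = 199, seed = 5)
  expect_gt(res$same$p_value, 0.1)
  expect_lt(res$same$pseudo_F, res$far$pseudo_F)
  expect_lte(res$far$p_value, 0.05)
  res2 <- compare_flagged_group(dm, flagged,
                                list(same = same_pop, far = far_pop),
                                n_permutations = 199, seed = 5)
  expect_identical(res$same$p_value, res2$same$p_value)
  expect_error(compare_flagged_group(dm, character(), list(s = same_pop)),
               "empty")
})

test_that("misch score bounds hold over random simplex and weight draws", {
  set.seed(123)
  for (i in 1:300) {
    p <- rdirichlet1(stats::runif(4, 0.2, 3))
    names(p) <- c("Healthy", "AGA3", "AGA5", "AGA7")
    w <- c(0, sort(stats::runif(2)), 1)
    s <- misch_score(p, w)
    expect_gte(s, 0)
    expect_lte(s, 100)
  }
})
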