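test_that("alpha diversity matches analytic values", {
  uni4 <- abundance_table(
    matrix(0.25, 1, 4, dimnames = list("s1", paste0("t", 1:4))),
    "bacteria")
  expect_equal(unname(alpha_diversity(uni4, "shannon")), log(4))
  single <- abundance_table(
    matrix(c(1, 0), 1, 2, dimnames = list("s1", c("a", "b"))), "bacteria")
  expect_equal(unname(alpha_diversity(single, "shannon")), 0)
  expect_equal(unname(alpha_diversity(single, "simpson")), 0)
  uni2 <- abundance_table(
    matrix(0.5, 1, 2, dimnames = list("s1", c("a", "b"))), "bacteria")
  expect_equal(unname(alpha_diversity(uni2, "simpson")), 0.5)

  counts <- matrix(c(5, 2, 1, 1), 1,
                   dimnames = list("s1", paste0("t", 1:4)))
  expect_equal(unname(alpha_diversity(NULL, "chao1", counts = counts)),
               4.5)
  expect_error(alpha_diversity(NULL, "chao1", counts = counts / 2),
               "integer")

  # Shannon is maximal at uniformity for fixed richness
  tab <- random_table(10, 6, seed = 4)
  expect_true(all(alpha_diversity(tab, "shannon") <= log(6) + 1e-12))
})

test_that("jsd_matrix equals the term-by-term divergence oracle", {
  p_q <- abundance_table(
    matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE,
           dimnames = list(c("p", "q"), c("a", "b"))), "bacteria")
  dm <- jsd_matrix(p_q)
  expect_equal(dm["p", "q"], jsd_oracle(c(1, 0), c(0.5, 0.5)),
               tolerance = 1e-12)
  expect_equal(dm["p", "p"], 0)

  disjoint <- abundance_table(
    matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
           dimnames = list(c("p", "q"), c("a", "b"))), "bacteria")
  expect_equal(jsd_matrix(disjoint)["p", "q"], 1)

  tab <- random_table(8, 10, seed = 6)
  dm2 <- jsd_matrix(tab)
  expect_equal(dm2, t(dm2))
  expect_true(all(dm2 >= 0 & dm2 <= 1))
  expect_equal(unname(diag(dm2)), rep(0, 8))
  for (pair in list(c(1, 2), c(3, 7))) {
    expect_equal(dm2[pair[1], pair[2]],
                 jsd_oracle(tab$values[pair[1], ], tab$values[pair[2], ]),
                 tolerance = 1e-12)
  }

  bad <- tab
  bad$values[1, ] <- bad$values[1, ] * 2
  expect_error(jsd_matrix(bad), "normalized")
})

test_that("pcoa performs classical scaling", {
  # three equidistant samples: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord3 <- pcoa(d3, k = 2)
  eig_pos <- ord3$eigenvalues[ord3$eigenvalues > 1e-8]
  expect_length(eig_pos, 2L)
  expect_equal(eig_pos[1], eig_pos[2], tolerance = 1e-8)

  # collinear points: one dominant axis
  x <- c(0, 1, 2.5, 4, 7)
  dl <- as.matrix(stats::dist(x))
  dimnames(dl) <- list(paste0("s", 1:5), paste0("s", 1:5))
  ordl <- suppressWarnings(pcoa(dl, k = 2))
  expect_gte(ordl$proportion_explained[1], 0.99)

  # Euclidean-embeddable input is reproduced by the embedding
  set.seed(9)
  pts <- matrix(rnorm(18), 6, 3)
  de <- as.matrix(stats::dist(pts))
  dimnames(de) <- list(paste0("s", 1:6), paste0("s", 1:6))
  orde <- pcoa(de, k = 3)
  expect_equal(as.matrix(stats::dist(orde$coordinates)), de,
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_warning(pcoa(dl, k = 4), "truncating")
})

test_that("permanova matches the exhaustive brute-force oracle on n = 6", {
  tab <- random_table(6, 5, seed = 12)
  dm <- jsd_matrix(tab)
  g <- rep(c("A", "B"), each = 3)
  perm_all <- rbind(1:6, permute::allPerms(6))
  f_all <- apply(perm_all, 1, function(p) brute_pseudo_F(dm, g[p]))
  f_obs <- brute_pseudo_F(dm, g)
  p_brute <- mean(f_all >= f_obs - 1e-12)

  res <- permanova(dm, g, n_permutations = permute::allPerms(6))
  expect_equal(res$pseudo_F, f_obs, tolerance = 1e-10)
  expect_equal(res$p_value, p_brute, tolerance = 1e-12)
  expect_equal(res$r_squared,
               1 - 1 / (1 + res$pseudo_F * (2 - 1) / (6 - 2)),
               tolerance = 1e-8)
})

test_that("permanova saturates at the permutation floor for separated groups", {
  set.seed(31)
  v <- rbind(matrix(rep(c(40, 1, 1, 1), each = 8), 8) + rnorm(32, 0, .2),
             matrix(rep(c(1, 40, 1, 1), each = 8), 8) + rnorm(32, 0, .2))
  v <- abs(v)
  dimnames(v) <- list(sprintf("s%02d", 1:16), paste0("t", 1:4))
  dm <- jsd_matrix(abundance_table(v, "bacteria"))
  res <- permanova(dm, rep(c("A", "B"), each = 8),
                   n_permutations = 199, seed = 3)
  expect_equal(res$p_value, 1 / 200)

  expect_error(permanova(dm, c("A", rep("B", 15))), "singleton")
  expect_error(permanova(dm, rep("A", 16)), "at least 2 levels")
  r1 <- permanova(dm, rep(c("A", "B"), each = 8), 99, seed = 5)
  r2 <- permanova(dm, rep(c("A", "B"), each = 8), 99, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("factor effect sizes recover a planted stage-only effect", {
  co <- small_cohort()
  m <- merge_kingdoms(co$bacteria, co$fungi)
  dm <- jsd_matrix(m)
  res <- factor_effect_sizes(dm, co$metadata,
                             c("stage", "region", "age"),
                             n_permutations = 99, seed = 2)
  expect_equal(res[[1]]$factor_name, "stage")
  expect_true(all(vapply(res, function(r) r$r_squared, 1) >= 0))
  expect_true(all(diff(vapply(res, function(r) r$pseudo_F, 1)) <= 0))
  expect_error(factor_effect_sizes(dm, co$metadata, "nope"),
               "unknown factor")
})

test_that("alpha-factor ANOVA matches the textbook oracle", {
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     grp = rep(c("A", "B"), each = 3))
  alpha <- stats::setNames(c(1, 2, 3, 4, 5, 6), meta$sample_id)
  res <- alpha_factor_anova(alpha, meta, "grp")
  expect_equal(res$F, 13.5)
  expect_equal(res$p, 1 - stats::pf(13.5, 1, 4))

  flat <- stats::setNames(rep(2, 6), meta$sample_id)
  res0 <- alpha_factor_anova(flat, meta, "grp")
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  meta$one <- "x"
  expect_error(alpha_factor_anova(alpha, meta, "one"), "fewer than 2")
})

test_that("planted stage effect dominates the Shannon ANOVA", {
  co <- small_cohort()
  alpha <- alpha_diversity(co$fungi, "shannon")
  res <- alpha_factor_anova(alpha, co$metadata,
                            c("stage", "region", "age"))
  expect_equal(res$factor[which.min(res$p)], "stage")
})

test_that("rank-based utilities wrap the standard tests", {
  set.seed(3)
  x <- stats::setNames(c(rnorm(8), rnorm(8, 2)), paste0("s", 1:16))
  g <- rep(c("A", "B"), each = 8)
  res <- group_wilcoxon(x, g)
  ref <- stats::wilcox.test(x ~ factor(g), exact = FALSE)
  expect_equal(res$p_value, ref$p.value)
  expect_error(group_wilcoxon(x, rep("A", 16)), "exactly 2 levels")

  tab <- random_table(30, 5, seed = 44)
  ages <- seq(20, 58, length.out = 30)
  v <- tab$values
  v[, 1] <- v[, 1] + (ages - 20) / 80   # plant a monotone age signal
  tab2 <- abundance_table(v, "bacteria")
  cors <- taxon_age_correlation(tab2, ages)
  expect_equal(cors$taxon_id[1], taxon_ids(tab)[1])
  expect_true(all(cors$p_adjusted >= cors$p - 1e-12))
})
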