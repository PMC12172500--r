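#' Per-sample alpha diversity
#'
#' Shannon index (natural log by default; `-sum p log p`), Gini-Simpson
#' index (`1 - sum p^2`), or the bias-corrected Chao1 richness estimator
#' (`S_obs + F1 (F1 - 1) / (2 (F2 + 1))`). Shannon and Simpson operate on
#' the normalized relative abundances; Chao1 requires integer counts.
#'
#' @param table an `AbundanceTable` (shannon/simpson).
#' @param metric one of `"shannon"`, `"simpson"`, `"chao1"`.
#' @param counts integer count matrix (samples x taxa), required for
#'   chao1.
#' @param base logarithm base for Shannon (default natural log).
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, metric = c("shannon", "simpson", "chao1"),
                            counts = NULL, base = exp(1)) {
  metric <- match.arg(metric)
  if (metric == "chao1") {
    if (is.null(counts)) stop("chao1 requires an integer count matrix")
    counts <- as.matrix(counts)
    if (any(counts != round(counts))) {
      stop("chao1 requires integer counts")
    }
    est <- vegan::estimateR(counts)
    return(stats::setNames(est["S.chao1", ], rownames(counts)))
  }
  v <- table$values
  if (metric == "shannon") {
    return(vegan::diversity(v, index = "shannon", base = base))
  }
  vegan::diversity(v, index = "simpson")
}

# base-2 entropy with 0 log 0 := 0
entropy2 <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Pairwise Jensen-Shannon divergence matrix
#'
#' `JSD(p, q) = H(m) - (H(p) + H(q)) / 2` with `m = (p + q) / 2` and
#' base-2 entropies, so divergences lie in `[0, 1]`. Rows must be
#' normalized to sum to one.
#'
#' @param table an `AbundanceTable` with normalized rows.
#' @param sqrt_metric return the square-root (metric) form instead of the
#'   divergence (default `FALSE`).
#' @return symmetric matrix with zero diagonal, dimnames = sample ids.
#' @export
jsd_matrix <- function(table, sqrt_metric = FALSE) {
  v <- table$values
  rs <- rowSums(v)
  if (any(abs(rs - 1) > 1e-6)) {
    stop("rows must be normalized to sum to 1 before computing JSD")
  }
  n <- nrow(v)
  h <- apply(v, 1, entropy2)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      m <- (v[i, ] + v[j, ]) / 2
      val <- entropy2(m) - (h[i] + h[j]) / 2
      d[i, j] <- d[j, i] <- max(val, 0)  # clip tiny negative round-off
    }
  }
  if (sqrt_metric) d <- sqrt(d)
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Eigendecomposition of the double-centered `-D^2 / 2` matrix via
#' `stats::cmdscale`. Axes are restricted to positive eigenvalues;
#' negative eigenvalues are reported. Proportions explained are computed
#' over the positive eigenvalues.
#'
#' @param dm symmetric distance matrix.
#' @param k number of axes requested.
#' @return list with `coordinates` (samples x axes), `eigenvalues`, and
#'   `proportion_explained` (per returned axis).
#' @export
pcoa <- function(dm, k = 2) {
  stopifnot(k >= 1)
  d <- stats::as.dist(dm)
  n <- attr(d, "Size")
  fit <- suppressWarnings(
    stats::cmdscale(d, k = min(k, n - 1), eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (k > n_pos) {
    warning("requested ", k, " axes but only ", n_pos,
            " positive eigenvalues; truncating")
  }
  keep <- seq_len(min(k, n_pos, ncol(fit$points)))
  coords <- fit$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("PCo", keep)
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = eig[keep] / sum(eig[eig > 0]))
}

#' Single-factor PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Adonis): the pseudo-F
#' statistic from between/within sums of squares on the distance matrix,
#' with the permutation p-value `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#' Delegates the decomposition to `vegan::adonis2`; deterministic under a
#' fixed seed.
#'
#' @param dm symmetric distance matrix with sample ids as dimnames.
#' @param grouping factor (or coercible) of group labels aligned with the
#'   rows of `dm`, or a named vector matched by sample id.
#' @param n_permutations number of permutations, or a permutation matrix
#'   (one permutation per row) for exhaustive tests.
#' @param seed integer seed.
#' @param factor_name label recorded in the result.
#' @return object of class `permanova_result`: list with `factor_name`,
#'   `pseudo_F`, `r_squared`, `p_value`, `n_permutations`.
#' @export
permanova <- function(dm, grouping, n_permutations = 999, seed = 1L,
                      factor_name = "grouping") {
  ids <- rownames(dm)
  if (!is.null(names(grouping))) {
    missing <- setdiff(ids, names(grouping))
    if (length(missing) > 0L) {
      stop("grouping is missing sample(s): ",
           paste(missing, collapse = ", "))
    }
    grouping <- grouping[ids]
  }
  g <- factor(as.character(grouping))
  if (nlevels(g) < 2L) stop("grouping must have at least 2 levels")
  if (any(table(g) < 2L)) {
    stop("singleton group(s): ",
         paste(names(table(g))[table(g) < 2L], collapse = ", "))
  }
  set.seed(seed_stream(seed, "permanova"))
  df <- data.frame(g = g)
  fit <- vegan::adonis2(stats::as.dist(dm) ~ g, data = df,
                        permutations = n_permutations)
  n_perm <- if (is.matrix(n_permutations)) nrow(n_permutations) else
    n_permutations
  structure(list(
    factor_name = factor_name,
    pseudo_F = fit$F[1],
    r_squared = fit$R2[1],
    p_value = fit$`Pr(>F)`[1],
    n_permutations = n_perm
  ), class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA [%s]: pseudo-F = %.4g, R2 = %.4g, p = %.4g (%d permutations)\n",
              x$factor_name, x$pseudo_F, x$r_squared, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Per-factor PERMANOVA effect sizes
#'
#' One single-factor PERMANOVA per metadata factor on the same distance
#' matrix, ordered by decreasing pseudo-F. `age` is tested through its
#' 5-year bin (`age_bin`).
#'
#' @param dm symmetric distance matrix.
#' @param metadata cohort metadata.
#' @param factors character vector of metadata column names.
#' @param n_permutations,seed passed to [permanova()].
#' @return list of `permanova_result`, ordered by decreasing pseudo-F.
#' @export
factor_effect_sizes <- function(dm, metadata, factors,
                                n_permutations = 999, seed = 1L) {
  factors[factors == "age"] <- "age_bin"
  unknown <- setdiff(factors, names(metadata))
  if (length(unknown) > 0L) {
    stop("unknown factor(s): ", paste(unknown, collapse = ", "))
  }
  res <- lapply(seq_along(factors), function(i) {
    f <- factors[i]
    permanova(dm,
              stats::setNames(as.character(metadata[[f]]),
                              metadata$sample_id),
              n_permutations = n_permutations,
              seed = seed_stream(seed, "factor_effect", i),
              factor_name = f)
  })
  res[order(-vapply(res, function(r) r$pseudo_F, numeric(1)))]
}

#' One-way ANOVA of an alpha-diversity vector by categorical factors
#'
#' @param alpha named numeric vector of per-sample alpha diversity.
#' @param metadata cohort metadata.
#' @param factors metadata columns to test (each must have >= 2 levels).
#' @return `data.frame` with columns `factor`, `F`, `p`.
#' @export
alpha_factor_anova <- function(alpha, metadata, factors) {
  factors[factors == "age"] <- "age_bin"
  unknown <- setdiff(factors, names(metadata))
  if (length(unknown) > 0L) {
    stop("unknown factor(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(names(alpha))) {
    alpha <- alpha[metadata$sample_id]
  }
  rows <- lapply(factors, function(f) {
    g <- factor(as.character(metadata[[f]]))
    if (nlevels(g) < 2L) stop("factor ", f, " has fewer than 2 levels")
    res <- oneway_anova(alpha, g)
    data.frame(factor = f, F = res$F, p = res$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# one-way ANOVA with the convention F = 0 when the response carries no
# between-group variation (avoids 0/0 noise ratios on constant data)
oneway_anova <- function(y, g) {
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-20 * max(1, mean(y)^2)) {
    return(list(F = 0, p = 1))
  }
  fit <- stats::anova(stats::lm(y ~ g))
  ssb <- fit$`Sum Sq`[1]
  F_val <- fit$`F value`[1]
  p <- fit$`Pr(>F)`[1]
  if (!is.finite(F_val) || ssb / sst < 1e-12) {
    F_val <- 0
    p <- 1
  }
  list(F = F_val, p = p)
}

#' Wilcoxon rank-sum comparison of a per-sample statistic between groups
#'
#' Thin wrapper over `stats::wilcox.test` (normal approximation when ties
#' are present) for two-group comparisons of alpha diversity or single
#' taxa.
#'
#' @param values named numeric vector.
#' @param groups two-level factor aligned with `values`.
#' @return list with `statistic` (W) and `p_value`.
#' @export
group_wilcoxon <- function(values, groups) {
  g <- factor(as.character(groups))
  if (nlevels(g) != 2L) stop("groups must have exactly 2 levels")
  ht <- suppressWarnings(stats::wilcox.test(values ~ g, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Per-taxon Spearman correlation with host age
#'
#' Spearman correlation of each taxon's relative abundance with age,
#' with Benjamini-Hochberg FDR correction across taxa.
#'
#' @param table an `AbundanceTable`.
#' @param ages numeric vector aligned with the table's samples (or named
#'   by sample id).
#' @return `data.frame` with columns `taxon_id`, `rho`, `p`, `p_adjusted`,
#'   ordered by `p`.
#' @export
taxon_age_correlation <- function(table, ages) {
  if (!is.null(names(ages))) ages <- ages[sample_ids(table)]
  if (length(ages) != nrow(table$values)) {
    stop("ages must align with the table's samples")
  }
  res <- lapply(taxon_ids(table), function(tx) {
    ht <- suppressWarnings(
      stats::cor.test(table$values[, tx], ages, method = "spearman"))
    data.frame(taxon_id = tx, rho = unname(ht$estimate), p = ht$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}
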