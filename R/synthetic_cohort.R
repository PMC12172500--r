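#' @name synthetic_cohort
#' @title Synthetic multi-kingdom scalp cohort generator
#'
#' @description
#' Generates cohorts with the statistical structure the downstream
#' analyses assume: stage-dependent genus templates (Dirichlet means),
#' age-correlated taxa in healthy subjects, within-subject correlation
#' between the frontal (T) and occipital (H) scalp regions, and
#' multinomial sequencing noise. The default configuration mirrors the
#' reference cohort design: 89 subjects (51 Healthy, 18 AGA3, 10 AGA5,
#' 10 AGA7), two regions each (178 samples), ages 20-60.
NULL

# deterministic broken-stick expected proportions for n background taxa
broken_stick <- function(n) {
  p <- rev(cumsum(1 / rev(seq_len(n))))
  p / sum(p)
}

bacterial_panel <- function() {
  focal <- c("Propionibacterium", "Corynebacterium", "Staphylococcus",
             "Macrococcus", "Paracoccus", "Micrococcus", "Rothia",
             "Acinetobacter")
  background <- c(
    "Streptococcus", "Lactobacillus", "Pseudomonas", "Enhydrobacter",
    "Brevibacterium", "Kocuria", "Dermacoccus", "Deinococcus",
    "Sphingomonas", "Methylobacterium", "Anaerococcus", "Finegoldia",
    "Peptoniphilus", "Prevotella", "Porphyromonas", "Neisseria",
    "Haemophilus", "Moraxella", "Chryseobacterium", "Flavobacterium",
    "Janthinobacterium", "Massilia", "Ralstonia", "Burkholderia",
    "Bacillus", "Paenibacillus", "Exiguobacterium", "Brachybacterium",
    "Microbacterium", "Agrococcus", "Nesterenkonia", "Veillonella")
  list(focal = focal, background = background)
}

fungal_panel <- function() {
  focal <- c("Malassezia", "Alternaria", "Aspergillus", "Cladosporium")
  background <- c(
    "Candida", "Penicillium", "Fusarium", "Wallemia", "Rhodotorula",
    "Trichosporon", "Naganishia", "Filobasidium", "Epicoccum",
    "Cutaneotrichosporon", "Saccharomyces")
  list(focal = focal, background = background)
}

# mean composition for one stage: focal genus means set explicitly,
# remaining mass spread over background genera by a broken-stick profile
stage_mean <- function(focal_means, background) {
  rest <- 1 - sum(focal_means)
  stopifnot(rest > 0)
  c(focal_means, stats::setNames(rest * broken_stick(length(background)),
                                 background))
}

# Focal-genus means per stage. The focal genera carry all of the
# stage-dependent signal and their total mass is held constant (0.80)
# across stages, so the background genera are stage-neutral: without
# this, compositional closure would leak stage information into every
# background genus.
default_bacterial_templates <- function() {
  bg <- bacterial_panel()$background
  mk <- function(prop, cory, staph, macro, trend_each) {
    stage_mean(c(
      Propionibacterium = prop, Corynebacterium = cory,
      Staphylococcus = staph, Macrococcus = macro,
      Paracoccus = trend_each, Micrococcus = trend_each,
      Rothia = trend_each, Acinetobacter = trend_each), bg)
  }
  list(
    Healthy = mk(0.30, 0.26, 0.060, 0.020, 0.0400),
    AGA3    = mk(0.40, 0.18, 0.070, 0.060, 0.0225),
    AGA5    = mk(0.50, 0.1080, 0.080, 0.0840, 0.0070),
    AGA7    = mk(0.55, 0.07, 0.080, 0.090, 0.0025)
  )
}

default_fungal_templates <- function() {
  bg <- fungal_panel()$background
  mk <- function(mala, alt, asp, clado) {
    stage_mean(c(Malassezia = mala, Alternaria = alt,
                 Aspergillus = asp, Cladosporium = clado), bg)
  }
  list(
    Healthy = mk(0.55, 0.05, 0.10, 0.100),
    AGA3    = mk(0.44, 0.12, 0.16, 0.080),
    AGA5    = mk(0.20, 0.36, 0.20, 0.040),
    AGA7    = mk(0.12, 0.56, 0.09, 0.030)
  )
}

#' Default synthetic-cohort configuration
#'
#' Encodes the qualitative taxon dynamics the generator is built to
#' emulate: Propionibacterium enrichment increasing with AGA severity,
#' Corynebacterium strictly decreasing, Alternaria low in Healthy/AGA3 and
#' above 50% mean abundance in AGA7, Malassezia decreasing, Aspergillus
#' peaking at AGA5; in healthy subjects six genera (Paracoccus,
#' Micrococcus, Rothia, Propionibacterium, Acinetobacter and the fungus
#' Cladosporium) drift with host age on the logit scale. AGA stage
#' templates are identical between scalp regions; healthy templates are
#' mildly region-distinct.
#'
#' @param n_subjects named integer vector of subjects per stage.
#' @param age_range integer length-2 age range in years.
#' @param concentration Dirichlet precision (larger = less overdispersion).
#' @param rho within-subject region correlation in `[0, 1]`.
#' @param depth sequencing depth (multinomial counts per sample).
#' @param region_effect_scale multiplier on the healthy-region template
#'   perturbation (0 removes region structure).
#' @return a `SyntheticConfig` list.
#' @export
default_config <- function(n_subjects = c(Healthy = 51, AGA3 = 18,
                                          AGA5 = 10, AGA7 = 10),
                           age_range = c(20L, 60L),
                           concentration = 80,
                           rho = 0.7,
                           depth = 20000L,
                           region_effect_scale = 1) {
  stopifnot(all(n_subjects >= 1), rho >= 0, rho <= 1, depth >= 1,
            concentration > 0)
  config <- list(
    n_subjects = n_subjects,
    age_range = as.integer(age_range),
    concentration = concentration,
    rho = rho,
    depth = as.integer(depth),
    templates = list(bacteria = default_bacterial_templates(),
                     fungi = default_fungal_templates()),
    # logit-scale change per year, healthy subjects only
    age_trends = list(
      bacteria = c(Paracoccus = 0.06, Micrococcus = 0.05, Rothia = -0.05,
                   Propionibacterium = 0.02, Acinetobacter = -0.06),
      fungi = c(Cladosporium = 0.06)
    ),
    # logit-scale offsets applied to the occipital (H) region template of
    # healthy subjects only; AGA templates are region-identical
    healthy_region_shift = list(
      bacteria = c(Staphylococcus = 0.5, Micrococcus = 0.4,
                   Kocuria = 0.4, Anaerococcus = -0.4),
      fungi = c(Malassezia = 0.3, Cladosporium = -0.3)
    ) ,
    region_effect_scale = region_effect_scale
  )
  class(config) <- "SyntheticConfig"
  validate_config(config)
  config
}

validate_config <- function(config) {
  for (k in names(config$templates)) {
    for (st in names(config$templates[[k]])) {
      tpl <- config$templates[[k]][[st]]
      if (any(tpl < 0) || sum(tpl) <= 0) {
        stop("degenerate template for ", k, "/", st)
      }
      if (abs(sum(tpl) - 1) > 1e-8) {
        stop("template for ", k, "/", st, " does not sum to 1")
      }
    }
    trend <- config$age_trends[[k]]
    unknown <- setdiff(names(trend), names(config$templates[[k]][[1]]))
    if (length(unknown) > 0L) {
      stop("age-trend taxa missing from templates: ",
           paste(unknown, collapse = ", "))
    }
  }
  invisible(config)
}

# shift a composition on the logit scale and renormalize
logit_shift <- function(p, shift) {
  if (length(shift) == 0L || all(shift == 0)) return(p)
  q <- p
  taxa <- names(shift)
  q[taxa] <- stats::plogis(stats::qlogis(pmin(pmax(p[taxa], 1e-12),
                                              1 - 1e-12)) + shift)
  q / sum(q)
}

# per-stage, per-region, per-age template for one kingdom
effective_template <- function(config, kingdom, stage, region, age) {
  tpl <- config$templates[[kingdom]][[stage]]
  if (stage == "Healthy") {
    trend <- config$age_trends[[kingdom]]
    if (length(trend) > 0L) {
      mid <- mean(config$age_range)
      tpl <- logit_shift(tpl, trend * (age - mid))
    }
    if (region == "H" && config$region_effect_scale != 0) {
      tpl <- logit_shift(tpl, config$healthy_region_shift[[kingdom]] *
                           config$region_effect_scale)
    }
  }
  tpl
}

#' Simulate a two-region multi-kingdom cohort
#'
#' Per subject: an age is drawn uniformly over the configured range; the
#' stage template (age-shifted for Healthy subjects) defines the Dirichlet
#' mean; a subject-level composition is drawn from
#' `Dirichlet(concentration x template)`; each region composition is the
#' mixture `rho * subject + (1 - rho) * fresh draw` from the
#' region-specific template; counts are sampled multinomially at the
#' configured depth and renormalized. Deterministic for a fixed seed.
#'
#' @param config a `SyntheticConfig` (see [default_config()]).
#' @param seed integer seed.
#' @return list with elements `bacteria`, `fungi` (both `AbundanceTable`),
#'   and `metadata`.
#' @export
simulate_cohort <- function(config = default_config(), seed = 1L) {
  validate_config(config)
  set.seed(seed_stream(seed, "simulate_cohort"))
  stages <- rep(names(config$n_subjects), config$n_subjects)
  n_subj <- length(stages)
  ages <- sample(seq(config$age_range[1], config$age_range[2]), n_subj,
                 replace = TRUE)
  subject_id <- sprintf("subj%03d", seq_len(n_subj))
  regions <- c("T", "H")
  rows <- list(bacteria = list(), fungi = list())
  meta <- list()
  for (i in seq_len(n_subj)) {
    for (kingdom in KINGDOMS) {
      tpl_T <- effective_template(config, kingdom, stages[i], "T", ages[i])
      tpl_H <- effective_template(config, kingdom, stages[i], "H", ages[i])
      tpl_subject <- (tpl_T + tpl_H) / 2
      subj_comp <- rdirichlet1(config$concentration * tpl_subject)
      for (r in regions) {
        tpl_r <- if (r == "T") tpl_T else tpl_H
        fresh <- rdirichlet1(config$concentration * tpl_r)
        comp <- config$rho * subj_comp + (1 - config$rho) * fresh
        counts <- stats::rmultinom(1, size = config$depth, prob = comp)[, 1]
        rows[[kingdom]][[paste0(subject_id[i], "_", r)]] <-
          counts / sum(counts)
      }
    }
    for (r in regions) {
      meta[[paste0(subject_id[i], "_", r)]] <- data.frame(
        sample_id = paste0(subject_id[i], "_", r),
        subject_id = subject_id[i], region = r, age = ages[i],
        stage = stages[i], stringsAsFactors = FALSE)
    }
  }
  metadata <- do.call(rbind, unname(meta))
  metadata <- cohort_metadata(metadata$sample_id, metadata$subject_id,
                              metadata$region, metadata$age, metadata$stage)
  tabs <- lapply(KINGDOMS, function(k) {
    abundance_table(do.call(rbind, rows[[k]]), kingdom = k, level = "genus")
  })
  names(tabs) <- KINGDOMS
  list(bacteria = tabs$bacteria, fungi = tabs$fungi, metadata = metadata)
}

#' Inject high-risk samples into a cohort
#'
#' Adds `n` new single-region samples generated from the `to_stage`
#' templates but labeled `from_stage` in the metadata — samples whose
#' microbiome already resembles a more advanced disease stage than their
#' clinical label. Returns the ground-truth ids for benchmarking
#' discordance detection.
#'
#' @param cohort list as returned by [simulate_cohort()].
#' @param config the `SyntheticConfig` used to build the cohort.
#' @param n number of samples to inject.
#' @param from_stage clinical label assigned to the injected samples.
#' @param to_stage stage whose templates generate their composition
#'   (must be more severe than `from_stage`).
#' @param seed integer seed.
#' @return list with updated `bacteria`, `fungi`, `metadata`, and `truth`
#'   (character vector of injected sample ids).
#' @export
inject_high_risk <- function(cohort, config, n, from_stage = "AGA5",
                             to_stage = "AGA7", seed = 1L) {
  from_stage <- match.arg(from_stage, STAGE_LEVELS)
  to_stage <- match.arg(to_stage, STAGE_LEVELS)
  if (stage_rank(from_stage) >= stage_rank(to_stage)) {
    stop("from_stage must be less severe than to_stage")
  }
  if (n == 0L) return(c(cohort, list(truth = character())))
  set.seed(seed_stream(seed, "inject_high_risk"))
  ages <- sample(seq(config$age_range[1], config$age_range[2]), n,
                 replace = TRUE)
  ids <- sprintf("risk%03d_T", seq_len(n))
  new_rows <- list()
  for (kingdom in KINGDOMS) {
    mat <- matrix(0, n, length(config$templates[[kingdom]][[to_stage]]),
                  dimnames = list(ids,
                                  names(config$templates[[kingdom]][[to_stage]])))
    for (i in seq_len(n)) {
      tpl <- effective_template(config, kingdom, to_stage, "T", ages[i])
      comp <- config$rho * rdirichlet1(config$concentration * tpl) +
        (1 - config$rho) * rdirichlet1(config$concentration * tpl)
      counts <- stats::rmultinom(1, size = config$depth, prob = comp)[, 1]
      mat[i, ] <- counts / sum(counts)
    }
    new_rows[[kingdom]] <- mat
  }
  meta_new <- cohort_metadata(
    sample_id = ids, subject_id = sub("_T$", "", ids),
    region = "T", age = ages, stage = rep(from_stage, n))
  list(
    bacteria = abundance_table(rbind(cohort$bacteria$values,
                                     new_rows$bacteria),
                               "bacteria", cohort$bacteria$level),
    fungi = abundance_table(rbind(cohort$fungi$values, new_rows$fungi),
                            "fungi", cohort$fungi$level),
    metadata = rbind(cohort$metadata, meta_new),
    truth = ids
  )
}

#' Synthetic lineage for the default genus panel
#'
#' Deterministic lineage table assigning every genus in a configuration's
#' templates to synthetic coarser ranks (family through phylum), so that
#' [aggregate_to_level()] and the level-by-kingdom classifier grid can be
#' exercised without a reference taxonomy. Genera are grouped into
#' families of ~2, orders of ~4, classes of ~8 and phyla of ~16 in panel
#' order.
#'
#' @param config a `SyntheticConfig`.
#' @return lineage `data.frame` (see [read_lineage()]).
#' @export
default_lineage <- function(config = default_config()) {
  out <- list()
  for (kingdom in KINGDOMS) {
    genera <- names(config$templates[[kingdom]][[1]])
    i <- seq_along(genera)
    kname <- if (kingdom == "bacteria") "Bacteria" else "Fungi"
    pre <- substr(kingdom, 1, 1)
    out[[kingdom]] <- data.frame(
      taxon_id = genera,
      kingdom = kname,
      phylum = sprintf("%s_phy%02d", pre, (i - 1) %/% 16 + 1),
      class = sprintf("%s_cls%02d", pre, (i - 1) %/% 8 + 1),
      order = sprintf("%s_ord%02d", pre, (i - 1) %/% 4 + 1),
      family = sprintf("%s_fam%02d", pre, (i - 1) %/% 2 + 1),
      genus = genera,
      species = NA_character_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
}

#' Configuration with planted discriminative genera
#'
#' Builds a cohort configuration in which a chosen number of bacterial and
#' fungal genera carry stage-dependent abundance shifts while all other
#' genera are stage-independent background. Used to benchmark feature
#' selection: the informative genera are the ground truth a selector
#' should recover.
#'
#' @param n_bacteria,n_fungi panel sizes per kingdom.
#' @param informative_bacteria,informative_fungi number of informative
#'   genera per kingdom.
#' @param effect logit-scale bump applied to an informative genus in its
#'   marked stage.
#' @param seed seed controlling which panel positions are informative and
#'   their stage/sign assignment.
#' @param ... passed to [default_config()] overrides (`concentration`,
#'   `rho`, `depth`, `n_subjects`, `age_range`).
#' @return list with `config` (a `SyntheticConfig` without age trends or
#'   region effects) and `informative` (character vector of planted taxa).
#' @details Each informative genus is a single-stage marker: its
#'   abundance is bumped (up or down, chosen at random) in one randomly
#'   assigned stage only. Markers are therefore complementary rather
#'   than redundant, so a feature selector needs most of the panel to
#'   reach peak accuracy. Informative genera are drawn from the
#'   mid-abundance range of the broken-stick background so every planted
#'   signal is detectable at realistic sequencing depth.
#' @export
planted_feature_config <- function(n_bacteria = 70, n_fungi = 30,
                                   informative_bacteria = 22,
                                   informative_fungi = 5,
                                   effect = 0.8, seed = 1L, ...) {
  over <- list(...)
  if (is.null(over$n_subjects)) {
    # benchmark cohorts are stage-balanced at the reference total size so
    # every stage contributes equally to marker detectability
    over$n_subjects <- c(Healthy = 23, AGA3 = 22, AGA5 = 22, AGA7 = 22)
  }
  config <- do.call(default_config, over)
  config$age_trends <- list(bacteria = numeric(), fungi = numeric())
  config$region_effect_scale <- 0
  set.seed(seed_stream(seed, "planted_feature_config"))
  informative <- character()
  sizes <- c(bacteria = n_bacteria, fungi = n_fungi)
  n_inf <- c(bacteria = informative_bacteria, fungi = informative_fungi)
  for (kingdom in KINGDOMS) {
    pre <- if (kingdom == "bacteria") "Bact" else "Fung"
    genera <- sprintf("%s_g%03d", pre, seq_len(sizes[[kingdom]]))
    base <- broken_stick(sizes[[kingdom]])
    # informative genera sit in the mid-abundance range (ranks 3..60%)
    lo <- 3L
    hi <- max(lo + n_inf[[kingdom]], round(0.6 * sizes[[kingdom]]))
    pick <- sort(sample(seq(lo, hi), n_inf[[kingdom]]))
    marker_stage <- sample(seq_along(STAGE_LEVELS), n_inf[[kingdom]],
                           replace = TRUE)
    marker_sign <- sample(c(-1, 1), n_inf[[kingdom]], replace = TRUE)
    tpls <- list()
    for (s in seq_along(STAGE_LEVELS)) {
      shift <- stats::setNames(rep(0, sizes[[kingdom]]), genera)
      shift[pick] <- ifelse(marker_stage == s, marker_sign * effect, 0)
      tpls[[STAGE_LEVELS[s]]] <-
        logit_shift(stats::setNames(base, genera), shift)
    }
    config$templates[[kingdom]] <- tpls
    informative <- c(informative, genera[pick])
  }
  validate_config(config)
  list(config = config, informative = informative)
}
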