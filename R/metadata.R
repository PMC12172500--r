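#' Assign 5-year age-bin labels
#'
#' Bins are closed-open `[20,25), [25,30), ...` except the final bin,
#' which is closed at the right edge: `[55,60]`.
#'
#' @param age integer ages in years.
#' @param range numeric length-2 cohort age range (default `c(20, 60)`).
#' @param width bin width in years (default 5).
#' @return character vector of bin labels.
#' @export
age_bin <- function(age, range = c(20, 60), width = 5) {
  if (any(age < range[1] | age > range[2])) {
    stop("age outside cohort range [", range[1], ", ", range[2], "]")
  }
  lo <- range[1] + width * floor((age - range[1]) / width)
  lo <- pmin(lo, range[2] - width)  # fold the right edge into the last bin
  hi <- lo + width
  ifelse(hi == range[2],
         sprintf("[%d,%d]", lo, hi),
         sprintf("[%d,%d)", lo, hi))
}

#' Build a cohort metadata table
#'
#' @param sample_id,subject_id,region,age,stage per-sample vectors; region
#'   is `"T"` (frontal) or `"H"` (occipital), stage one of Healthy, AGA3,
#'   AGA5, AGA7.
#' @return a `data.frame` with an additional `age_bin` column; `stage` is
#'   a factor with the canonical level order.
#' @export
cohort_metadata <- function(sample_id, subject_id, region, age, stage) {
  region <- as.character(region)
  if (!all(region %in% c("T", "H"))) {
    stop("region must be 'T' (frontal) or 'H' (occipital)")
  }
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in metadata")
  data.frame(
    sample_id = as.character(sample_id),
    subject_id = as.character(subject_id),
    region = region,
    age = as.integer(age),
    stage = stage_factor(stage),
    age_bin = age_bin(as.integer(age)),
    stringsAsFactors = FALSE
  )
}

#' Read cohort metadata from TSV
#'
#' Expects columns `sample_id, subject_id, region, age, stage`.
#'
#' @param path file path.
#' @return metadata `data.frame` (see [cohort_metadata()]).
#' @export
read_cohort_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "region", "age", "stage")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  cohort_metadata(df$sample_id, df$subject_id, df$region, df$age, df$stage)
}

#' Write cohort metadata as TSV
#' @param metadata metadata `data.frame`.
#' @param path output file path.
#' @export
write_cohort_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Cross-check an abundance table against cohort metadata
#'
#' Report-only validation: sample-set agreement, per-subject pairing (at
#' most two samples, one per region), and within-subject consistency of
#' age and stage. Returns a machine-readable violation table; an empty
#' table means the cohort is consistent.
#'
#' @param table an `AbundanceTable` (or `NULL` to check metadata alone).
#' @param metadata metadata `data.frame`.
#' @return `data.frame` with columns `code`, `id`, `message`.
#' @export
validate_cohort <- function(table, metadata) {
  v <- list()
  add <- function(code, id, message) {
    v[[length(v) + 1L]] <<- data.frame(code = code, id = id,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }
  if (!is.null(table)) {
    only_t <- setdiff(sample_ids(table), metadata$sample_id)
    only_m <- setdiff(metadata$sample_id, sample_ids(table))
    for (s in only_t) add("sample_not_in_metadata", s,
                          "sample in abundance table but not in metadata")
    for (s in only_m) add("sample_not_in_table", s,
                          "sample in metadata but not in abundance table")
    rs <- rowSums(table$values)
    off <- sample_ids(table)[abs(rs - 1) > 1e-9]
    for (s in off) add("row_not_normalized", s,
                       "abundance row does not sum to 1")
  }
  for (subj in unique(metadata$subject_id)) {
    rows <- metadata[metadata$subject_id == subj, , drop = FALSE]
    if (nrow(rows) > 2L) {
      add("too_many_samples", subj, "subject has more than two samples")
    }
    if (anyDuplicated(rows$region)) {
      add("duplicate_region", subj,
          paste0("subject has multiple samples from region ",
                 paste(unique(rows$region[duplicated(rows$region)]),
                       collapse = ",")))
    }
    if (length(unique(rows$age)) > 1L) {
      add("inconsistent_age", subj, "subject samples disagree on age")
    }
    if (length(unique(as.character(rows$stage))) > 1L) {
      add("inconsistent_stage", subj, "subject samples disagree on stage")
    }
  }
  bad_bin <- metadata$sample_id[metadata$age_bin != age_bin(metadata$age)]
  for (s in bad_bin) add("age_bin_mismatch", s,
                         "age_bin is not the deterministic bin of age")
  if (length(v) == 0L) {
    return(data.frame(code = character(), id = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}
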