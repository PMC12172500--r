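#' Construct an abundance table
#'
#' The central data container: a samples x taxa matrix of non-negative
#' relative abundances, with a kingdom tag per taxon and a taxonomic level
#' for the whole table. Rows are renormalized to sum to one.
#'
#' @param values numeric matrix, samples in rows, taxa in columns; rownames
#'   are sample ids, colnames taxon ids.
#' @param kingdom either a single kingdom (`"bacteria"` or `"fungi"`)
#'   applied to all taxa, or a named character vector with one entry per
#'   taxon.
#' @param level taxonomic level of the columns (one of kingdom, phylum,
#'   class, order, family, genus, species).
#' @param normalize renormalize rows to sum to one (default `TRUE`).
#' @return an object of class `AbundanceTable`.
#' @export
abundance_table <- function(values, kingdom, level = "genus",
                            normalize = TRUE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have sample ids as rownames and taxon ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate taxon ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop("abundance values must be numeric and non-missing")
  }
  if (any(values < 0)) {
    stop("abundance values must be non-negative")
  }
  level <- match.arg(level, TAXONOMIC_LEVELS)
  if (length(kingdom) == 1L && is.null(names(kingdom))) {
    kingdom <- stats::setNames(rep(kingdom, ncol(values)), colnames(values))
  }
  if (!setequal(names(kingdom), colnames(values))) {
    stop("kingdom tags must be named by taxon id and cover all taxa")
  }
  kingdom <- kingdom[colnames(values)]
  if (!all(kingdom %in% KINGDOMS)) {
    stop("kingdom tags must be one of: ", paste(KINGDOMS, collapse = ", "))
  }
  if (normalize) {
    rs <- rowSums(values)
    zero <- rownames(values)[rs <= 0]
    if (length(zero) > 0L) {
      stop("zero-sum sample(s): ", paste(zero, collapse = ", "))
    }
    values <- values / rs
  }
  structure(
    list(values = values, kingdom = kingdom, level = level),
    class = "AbundanceTable"
  )
}

#' @export
print.AbundanceTable <- function(x, ...) {
  cat(sprintf(
    "AbundanceTable: %d samples x %d taxa (level: %s; %s)\n",
    nrow(x$values), ncol(x$values), x$level,
    paste(sprintf("%s: %d", names(table(x$kingdom)), table(x$kingdom)),
          collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.AbundanceTable <- function(x) dim(x$values)

#' Sample ids of an abundance table
#' @param table an `AbundanceTable`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(table) rownames(table$values)

#' Taxon ids of an abundance table
#' @param table an `AbundanceTable`.
#' @return character vector of taxon ids.
#' @export
taxon_ids <- function(table) colnames(table$values)

#' Subset an abundance table by sample ids
#'
#' @param table an `AbundanceTable`.
#' @param ids sample ids to keep, in the requested order.
#' @param renormalize renormalize rows after subsetting (rows are already
#'   normalized, so this is a no-op kept for symmetry with taxon subsets).
#' @return an `AbundanceTable`.
#' @export
subset_samples <- function(table, ids, renormalize = FALSE) {
  missing <- setdiff(ids, sample_ids(table))
  if (length(missing) > 0L) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  }
  abundance_table(table$values[ids, , drop = FALSE], table$kingdom,
                  table$level, normalize = renormalize)
}

#' Read an abundance table from delimited text
#'
#' Expects a TSV with a header row of taxon ids and a first column
#' `sample_id` (samples in rows). Tables stored taxa-in-rows are read with
#' `taxa_as_rows = TRUE`; the orientation is never guessed.
#'
#' @param path file path.
#' @param kingdom kingdom tag for all taxa in the file.
#' @param level taxonomic level of the taxa.
#' @param taxa_as_rows set `TRUE` if the file stores taxa in rows and
#'   samples in columns.
#' @param sep field separator (default tab).
#' @return an `AbundanceTable` with rows renormalized to sum to one.
#' @export
read_abundance_table <- function(path, kingdom, level = "genus",
                                 taxa_as_rows = FALSE, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("abundance table needs at least one taxon column")
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric abundance values in ", path)
  rownames(mat) <- ids
  if (taxa_as_rows) mat <- t(mat)
  abundance_table(mat, kingdom = kingdom, level = level)
}

#' Write an abundance table as TSV
#'
#' Taxa columns are emitted in lexicographic order so outputs are
#' byte-stable and diffable.
#'
#' @param table an `AbundanceTable`.
#' @param path output file path.
#' @export
write_abundance_table <- function(table, path) {
  ord <- order(colnames(table$values), method = "radix")
  mat <- table$values[, ord, drop = FALSE]
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge bacterial and fungal tables into one multi-kingdom table
#'
#' Each input is row-normalized per kingdom; the merged rows are
#' renormalized so bacteria and fungi carry equal mass per sample
#' (each kingdom contributes 0.5). Set `renormalize = FALSE` to keep the
#' concatenation at row sum 2.
#'
#' @param bacterial,fungal `AbundanceTable`s over the same sample set.
#' @param renormalize renormalize merged rows to sum one (default `TRUE`).
#' @return an `AbundanceTable` with taxa of both kingdoms.
#' @export
merge_kingdoms <- function(bacterial, fungal, renormalize = TRUE) {
  sb <- sample_ids(bacterial)
  sf <- sample_ids(fungal)
  if (!setequal(sb, sf)) {
    only_b <- setdiff(sb, sf)
    only_f <- setdiff(sf, sb)
    stop("sample sets differ between kingdoms; only bacterial: {",
         paste(only_b, collapse = ", "), "}; only fungal: {",
         paste(only_f, collapse = ", "), "}")
  }
  if (bacterial$level != fungal$level) {
    stop("cannot merge tables at different taxonomic levels")
  }
  vb <- bacterial$values
  vf <- fungal$values[sb, , drop = FALSE]
  shared <- intersect(colnames(vb), colnames(vf))
  if (length(shared) > 0L) {
    colnames(vb)[colnames(vb) %in% shared] <-
      paste0("b__", colnames(vb)[colnames(vb) %in% shared])
    colnames(vf)[colnames(vf) %in% shared] <-
      paste0("f__", colnames(vf)[colnames(vf) %in% shared])
  }
  values <- cbind(vb, vf)
  kingdom <- stats::setNames(
    c(rep("bacteria", ncol(vb)), rep("fungi", ncol(vf))), colnames(values))
  abundance_table(values, kingdom, bacterial$level,
                  normalize = renormalize)
}
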