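#' Read a taxon lineage table
#'
#' TSV with columns `taxon_id, kingdom, phylum, class, order, family,
#' genus, species`. Rank-prefix notation (`g__Genus`, `s__species`) is
#' tolerated and stripped; empty strings and `NA` mark unknown ranks.
#'
#' @param path file path.
#' @return `data.frame` keyed by `taxon_id` with one column per rank.
#' @export
read_lineage <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("taxon_id", TAXONOMIC_LEVELS)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("lineage file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (rank in TAXONOMIC_LEVELS) {
    df[[rank]] <- sub("^[a-z]__", "", as.character(df[[rank]]))
    df[[rank]][df[[rank]] == ""] <- NA_character_
  }
  if (anyDuplicated(df$taxon_id)) stop("duplicate taxon ids in lineage")
  df[, need]
}

#' Write a taxon lineage table as TSV
#' @param lineage lineage `data.frame` (see [read_lineage()]).
#' @param path output file path.
#' @export
write_lineage <- function(lineage, path) {
  utils::write.table(lineage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Aggregate an abundance table to a coarser taxonomic level
#'
#' Abundances of taxa sharing the same name at the target rank are summed
#' within each kingdom. Taxa with no name at that rank are pooled into an
#' `unclassified_<kingdom>` bin. Aggregating a table to its own level is
#' the identity (up to column order), and total abundance is conserved.
#'
#' @param table an `AbundanceTable`.
#' @param lineage lineage `data.frame` covering every taxon in `table`.
#' @param level target taxonomic level (must be the table's level or
#'   coarser).
#' @return an `AbundanceTable` at `level`.
#' @export
aggregate_to_level <- function(table, lineage, level) {
  level <- match.arg(level, TAXONOMIC_LEVELS)
  from <- match(table$level, TAXONOMIC_LEVELS)
  to <- match(level, TAXONOMIC_LEVELS)
  if (to > from) {
    stop("cannot aggregate from ", table$level, " down to ", level)
  }
  if (to == from) return(table)
  missing <- setdiff(taxon_ids(table), lineage$taxon_id)
  if (length(missing) > 0L) {
    stop("no lineage entry for taxon(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(taxon_ids(table), lineage$taxon_id)
  name_at <- lineage[[level]][idx]
  kingdom <- unname(table$kingdom[taxon_ids(table)])
  group <- ifelse(is.na(name_at),
                  paste0("unclassified_", kingdom),
                  name_at)
  # keep kingdoms separate even if rank names collide across kingdoms
  key <- paste(kingdom, group, sep = "\r")
  agg <- t(rowsum(t(table$values), group = key))
  keys <- colnames(agg)
  king_of <- sub("\r.*$", "", keys)
  name_of <- sub("^.*\r", "", keys)
  # disambiguate cross-kingdom name collisions in the merged id space
  dup <- name_of %in% name_of[duplicated(name_of)]
  ids <- ifelse(dup, paste0(substr(king_of, 1, 1), "__", name_of), name_of)
  colnames(agg) <- ids
  abundance_table(agg, stats::setNames(king_of, ids), level,
                  normalize = FALSE)
}
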