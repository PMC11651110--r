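# Plain-text table I/O: ASV count tables (TSV, taxa in rows), sample
# metadata (CSV), SINTAX-style taxonomy (TSV), cohort summaries (JSON).

#' Read an ASV/OTU count table
#'
#' Tab-separated, first column taxon identifiers, header row of sample ids,
#' integer counts. Duplicated taxon ids, empty cells, negative or
#' non-integer values are rejected with the offending coordinates.
#'
#' @param path TSV path.
#' @return integer taxa-by-samples matrix with taxon and sample dimnames.
#' @export
readAsvTable <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, header = TRUE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("count table needs a taxon column plus samples")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicated taxon ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  bad <- which(is.na(cells) | cells == "" |
                 !grepl("^[0-9]+$", cells), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or empty count at taxon '", ids[bad[1, 1]],
         "', sample '", colnames(cells)[bad[1, 2]], "'")
  counts <- matrix(as.integer(cells), nrow = nrow(cells),
                   dimnames = list(ids, colnames(cells)))
  counts
}

#' Write an ASV/OTU count table
#'
#' Inverse of [readAsvTable()]; round-trips exactly.
#'
#' @param counts taxa-by-samples integer matrix.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeAsvTable <- function(counts, path) {
  counts <- .checkCountMatrix(counts)
  df <- data.frame(taxon = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' CSV with required columns `sample_id`, `age_years`, `sex`, `ethnic`,
#' `geography`, `height_m`, `weight_kg`; `bmiaz` is optional (compute it with
#' [growthZscore()] when absent).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age_years", "sex", "ethnic", "geography",
            "height_m", "weight_kg")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicated sample ids in metadata")
  md
}

#' Read a taxonomy lineage table
#'
#' TSV mapping `taxon` to a SINTAX-style `lineage` string
#' (`"d:...,p:...,c:...,o:...,f:...,g:..."`).
#'
#' @param path TSV path.
#' @return data.frame with columns `taxon`, `lineage`.
#' @export
readTaxonomyTable <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  tx <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "lineage") %in% names(tx)))
    stop("taxonomy table must have columns 'taxon' and 'lineage'")
  tx
}
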