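#' Read a fragment-by-library count matrix
#'
#' Reads a tab-delimited count table whose first column holds fragment
#' identifiers and whose header row names the libraries. Cells must be
#' non-negative integers; duplicated fragment identifiers are rejected so a
#' matrix row always means one fragment.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix with fragment ids as rownames and library ids as
#'   colnames, in file order.
#' @export
read_counts <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("count file must have a fragment-id column and at least one library column")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate fragment id in count file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  libs <- colnames(tab)[-1L]
  mat <- matrix(0L, nrow = nrow(tab), ncol = length(libs),
                dimnames = list(ids, libs))
  for (j in seq_along(libs)) {
    cell <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | num < 0 | num != round(num))
    if (length(bad))
      stop(sprintf("malformed count at row '%s', column '%s': '%s'",
                   ids[bad[1L]], libs[j], cell[bad[1L]]))
    mat[, j] <- as.integer(round(num))
  }
  validate_counts(mat)
  mat
}

#' Write a count matrix as TSV
#'
#' @param counts Integer count matrix (fragments x libraries).
#' @param path Output file path.
#' @param id_col Name for the fragment-id column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, id_col = "fragment_id") {
  validate_counts(counts)
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry fragment ids (rownames) and library ids (colnames)")
  if (anyDuplicated(rownames(counts))) stop("duplicate fragment ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate library ids")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite non-negative integers")
  invisible(counts)
}

#' Read and validate a library metadata table
#'
#' Expects columns `library_id`, `individual_id`, `genotype` and `treatment`.
#' Genotype and treatment tokens are matched case-insensitively and stored
#' canonically as `wild`/`ins` and `ambient`/`elevated`. The table is checked
#' against the study-design invariants: unique library ids, at most one
#' library per individual per treatment, and a constant genotype within each
#' individual.
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame of class `library_meta`.
#' @export
read_metadata <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  as_library_meta(tab)
}

#' Coerce and validate library metadata
#'
#' @param tab data.frame with columns library_id, individual_id, genotype,
#'   treatment.
#' @return data.frame of class `library_meta` with canonical enum values.
#' @export
as_library_meta <- function(tab) {
  need <- c("library_id", "individual_id", "genotype", "treatment")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  meta <- as.data.frame(tab[need], stringsAsFactors = FALSE)
  meta$genotype <- canonical_enum(meta$genotype, GENOTYPE_LEVELS, "genotype")
  meta$treatment <- canonical_enum(meta$treatment, TREATMENT_LEVELS, "treatment")
  if (anyDuplicated(meta$library_id))
    stop("duplicate library_id in metadata")
  key <- paste(meta$individual_id, meta$treatment, sep = "\r")
  if (anyDuplicated(key)) {
    off <- meta$individual_id[duplicated(key)][1L]
    stop("individual '", off, "' has more than one library in one treatment")
  }
  geno_per_ind <- tapply(meta$genotype, meta$individual_id,
                         function(g) length(unique(g)))
  if (any(geno_per_ind > 1L))
    stop("genotype differs within individual: ",
         paste(names(geno_per_ind)[geno_per_ind > 1L], collapse = ", "))
  class(meta) <- c("library_meta", "data.frame")
  meta
}

canonical_enum <- function(x, levels, what) {
  idx <- match(tolower(trimws(x)), levels)
  if (anyNA(idx))
    stop("unknown ", what, " token: '", x[which(is.na(idx))[1L]], "'")
  levels[idx]
}

#' Write library metadata as TSV
#' @param meta `library_meta` data.frame.
#' @param path Output path.
#' @export
write_metadata <- function(meta, path) {
  write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a transcript feature map
#'
#' Columns `transcript_id`, `gene_id`, `homology_id` (optionally
#' `cluster_id`); an empty `homology_id` marks an unannotated transcript.
#'
#' @param path Path to a TSV file.
#' @return data.frame with one row per transcript.
#' @export
read_feature_map <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  as_feature_map(tab)
}

#' Validate a feature map table
#' @param tab data.frame with transcript_id, gene_id and optionally
#'   cluster_id / homology_id columns.
#' @return validated data.frame (class `feature_map`).
#' @export
as_feature_map <- function(tab) {
  need <- c("transcript_id", "gene_id")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("feature map is missing columns: ", paste(miss, collapse = ", "))
  fm <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (is.null(fm$homology_id)) fm$homology_id <- ""
  fm$homology_id[is.na(fm$homology_id)] <- ""
  if (is.null(fm$cluster_id)) {
    parsed <- try(parse_trinity_id(fm$transcript_id), silent = TRUE)
    fm$cluster_id <- if (inherits(parsed, "try-error")) fm$gene_id
                     else parsed$cluster_id
  }
  if (anyDuplicated(fm$transcript_id))
    stop("transcript mapped more than once in feature map")
  class(fm) <- c("feature_map", "data.frame")
  fm
}

#' Write a feature map as TSV
#' @param fm feature map data.frame.
#' @param path Output path.
#' @export
write_feature_map <- function(fm, path) {
  cols <- intersect(c("transcript_id", "cluster_id", "gene_id", "homology_id"),
                    colnames(fm))
  write.table(as.data.frame(fm)[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a righting-response trial table
#'
#' Columns `individual_id`, `period` (ambient_pre / elevated / ambient_post),
#' `replicate`, `time_s`. Times above 3600 s encode trials in which the
#' animal never righted itself within the one-hour observation window.
#'
#' @param path Path to a TSV file.
#' @return data.frame of righting records.
#' @export
read_righting <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("individual_id", "period", "replicate", "time_s")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("righting table is missing columns: ", paste(miss, collapse = ", "))
  tab$period <- canonical_enum(tab$period, PERIOD_LEVELS, "period")
  tab$time_s <- as.numeric(tab$time_s)
  if (any(!is.finite(tab$time_s)) || any(tab$time_s <= 0))
    stop("righting times must be positive")
  tab
}

#' Write a righting table as TSV
#' @param records righting data.frame.
#' @param path Output path.
#' @export
write_righting <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# align a count matrix with a metadata table, erroring on mismatch
align_meta <- function(counts, meta) {
  missing_meta <- setdiff(colnames(counts), meta$library_id)
  if (length(missing_meta))
    stop("libraries without metadata: ", paste(missing_meta, collapse = ", "))
  meta[match(colnames(counts), meta$library_id), , drop = FALSE]
}
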