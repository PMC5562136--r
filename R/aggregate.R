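#' Parse Trinity-style transcript identifiers
#'
#' Trinity names transcripts `<prefix>_c<int>_g<int>_i<int>`; the cluster is
#' the prefix through the `_c` component and the gene nests inside the
#' cluster.
#'
#' @param transcript_id Character vector of transcript ids.
#' @return data.frame with columns `transcript_id`, `cluster_id`, `gene_id`,
#'   `isoform_index`.
#' @examples
#' parse_trinity_id("TRINITY_DN1000_c1_g2_i3")
#' @export
parse_trinity_id <- function(transcript_id) {
  pat <- "^(.+_c[0-9]+)_g([0-9]+)_i([0-9]+)$"
  ok <- grepl(pat, transcript_id)
  if (!all(ok))
    stop("not a Trinity-style id: ",
         paste(utils::head(transcript_id[!ok], 3L), collapse = ", "))
  cluster <- sub(pat, "\\1", transcript_id)
  gene <- paste0(cluster, "_g", sub(pat, "\\2", transcript_id))
  iso <- as.integer(sub(pat, "\\3", transcript_id))
  data.frame(transcript_id = transcript_id, cluster_id = cluster,
             gene_id = gene, isoform_index = iso, stringsAsFactors = FALSE)
}

#' Collapse a count matrix to cluster, gene, or homology level
#'
#' Counts of rows sharing the target-level identifier are summed per library,
#' so per-library totals are conserved at every level. At `homology` level,
#' rows without a homology annotation keep their gene id as the row key, so
#' unannotated genes survive the collapse.
#'
#' @param counts Fragment-by-library count matrix (transcript-level rows for
#'   `cluster`/`gene`, gene-level rows allowed for `homology`).
#' @param map Feature map (see [as_feature_map()]); may be `NULL` at `gene`
#'   or `cluster` level when row ids parse as Trinity ids.
#' @param level One of `"cluster"`, `"gene"`, `"homology"`.
#' @return Collapsed count matrix; row order follows first appearance of each
#'   group id.
#' @export
collapse_counts <- function(counts, map = NULL,
                            level = c("gene", "cluster", "homology")) {
  level <- match.arg(level)
  validate_counts(counts)
  ids <- rownames(counts)
  if (is.null(map)) {
    if (level == "homology")
      stop("homology collapse requires a feature map")
    map <- parse_trinity_id(ids)
    map$homology_id <- ""
  }
  map <- as_feature_map(map)
  if (level == "homology" && !all(ids %in% map$transcript_id)) {
    # gene-level input: allow lookup by gene id
    by_gene <- !duplicated(map$gene_id)
    gm <- map[by_gene, , drop = FALSE]
    gm$transcript_id <- gm$gene_id
    map <- as_feature_map(rbind(as.data.frame(map), as.data.frame(gm)))
  }
  hit <- match(ids, map$transcript_id)
  if (anyNA(hit)) {
    off <- ids[is.na(hit)]
    stop("fragments missing from feature map: ",
         paste(utils::head(off, 5L), collapse = ", "),
         if (length(off) > 5L) sprintf(" (and %d more)", length(off) - 5L))
  }
  key <- switch(level,
    cluster = map$cluster_id[hit],
    gene = map$gene_id[hit],
    homology = ifelse(map$homology_id[hit] == "", map$gene_id[hit],
                      map$homology_id[hit]))
  groups <- unique(key)
  out <- rowsum(counts, group = factor(key, levels = groups), reorder = FALSE)
  storage.mode(out) <- "integer"
  rownames(out) <- groups
  validate_counts(out)
}
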