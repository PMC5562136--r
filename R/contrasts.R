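#' Genotype contrast with threshold summaries
#'
#' Runs the exact-test pipeline on wild (class A) versus ins (class B)
#' libraries — by default the ambient-treatment libraries only, the
#' constitutive-expression comparison — and summarizes DE counts, direction
#' asymmetry and abundance of the DE sets at each FDR threshold. Positive
#' logFC means higher expression in ins unless `positive_class = "wild"`
#' flips the orientation.
#'
#' @param counts Count matrix (unfiltered is fine; the CPM filter is applied
#'   to the selected libraries).
#' @param meta `library_meta` covering the columns.
#' @param thresholds FDR thresholds for the summary.
#' @param treatment `"ambient"` (default), `"elevated"`, or `"both"`.
#' @param positive_class `"ins"` (default) or `"wild"`.
#' @param exclude_library Optional library ids dropped before analysis.
#' @param reassign_library Optional library id whose individual's genotype
#'   label is flipped before analysis.
#' @param dispersion,prior_df Passed to [nb_exact_de()].
#' @param cpm_threshold,min_libraries Expression filter settings.
#' @return List of class `contrast_result` with `de` (a `de_result`) and
#'   `summary` (a `contrast_summary` data.frame, one row per threshold).
#' @export
genotype_contrast <- function(counts, meta, thresholds = c(0.01, 1e-4),
                              treatment = c("ambient", "elevated", "both"),
                              positive_class = c("ins", "wild"),
                              exclude_library = NULL,
                              reassign_library = NULL,
                              dispersion = "tagwise", prior_df = 10,
                              cpm_threshold = 1, min_libraries = 2L) {
  treatment <- match.arg(treatment)
  positive_class <- match.arg(positive_class)
  meta <- align_meta(counts, meta)
  if (!is.null(reassign_library)) {
    j <- match(reassign_library, meta$library_id)
    if (is.na(j)) stop("unknown library: ", reassign_library)
    ind <- meta$individual_id[j]
    flip <- meta$individual_id == ind
    meta$genotype[flip] <- setdiff(GENOTYPE_LEVELS, meta$genotype[j])
  }
  if (!is.null(exclude_library)) {
    if (!all(exclude_library %in% meta$library_id))
      stop("unknown library in exclude_library")
    keep <- !(meta$library_id %in% exclude_library)
    meta <- meta[keep, , drop = FALSE]
    counts <- counts[, meta$library_id, drop = FALSE]
  }
  if (treatment != "both") {
    meta <- meta[meta$treatment == treatment, , drop = FALSE]
    counts <- counts[, meta$library_id, drop = FALSE]
  }
  if (any(table(factor(meta$genotype, GENOTYPE_LEVELS)) < 2L))
    stop("each genotype needs at least two libraries")
  filtered <- filter_expressed(counts, cpm_threshold, min_libraries)
  grp <- factor(meta$genotype, levels = GENOTYPE_LEVELS)
  de <- nb_exact_de(filtered, grp, dispersion = dispersion,
                    prior_df = prior_df)
  summary <- summarize_contrast(de, thresholds)
  if (positive_class == "wild") de$logFC <- -de$logFC
  structure(list(de = de, summary = summary,
                 positive_class = positive_class,
                 libraries = meta$library_id),
            class = "contrast_result")
}

# direction split and per-side abundance at each threshold; side B = ins
# (or elevated for treatment contrasts) regardless of display orientation
summarize_contrast <- function(de, thresholds, lfc_summaries = FALSE) {
  rows <- lapply(sort(thresholds, decreasing = TRUE), function(th) {
    hit <- de$fdr < th
    up_b <- hit & de$logFC > 0
    up_a <- hit & de$logFC <= 0
    data.frame(
      threshold = th,
      n_total = sum(hit),
      n_higher_in_B = sum(up_b),
      n_higher_in_A = sum(up_a),
      mean_logCPM_higher_in_B = mean_or_na(de$logCPM[up_b]),
      max_logCPM_higher_in_B = max_or_na(de$logCPM[up_b]),
      mean_logCPM_higher_in_A = mean_or_na(de$logCPM[up_a]),
      max_logCPM_higher_in_A = max_or_na(de$logCPM[up_a]),
      mean_logFC_sig = mean_or_na(de$logFC[hit]),
      sd_logFC_sig = if (sum(hit) > 1L) sd(de$logFC[hit]) else NA_real_,
      mean_logFC_all = mean(de$logFC),
      sd_logFC_all = sd(de$logFC))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_summary", "data.frame")
  out
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
max_or_na <- function(x) if (length(x)) max(x) else NA_real_

#' Within-genotype temperature-response contrast
#'
#' Ambient (class A) versus elevated (class B) libraries of one genotype;
#' positive logFC means higher expression after warming. Uses the exact NB
#' test on the two treatment groups, or the paired likelihood-ratio test
#' when `paired = TRUE`. The summary reports, per threshold, the DE count
#' and the mean and sd of logFC over significant loci and over all tested
#' loci.
#'
#' @param counts Count matrix.
#' @param meta `library_meta`.
#' @param genotype `"wild"` or `"ins"`.
#' @param thresholds FDR thresholds (default 0.01 and 0.1).
#' @param paired Use the paired NB LRT instead of the exact test.
#' @param exclude_library Optional library ids to drop.
#' @param dispersion,prior_df,cpm_threshold,min_libraries As in
#'   [genotype_contrast()].
#' @return `contrast_result` list with `de` and `summary`.
#' @export
temperature_response <- function(counts, meta, genotype = c("wild", "ins"),
                                 thresholds = c(0.01, 0.1), paired = FALSE,
                                 exclude_library = NULL,
                                 dispersion = "tagwise", prior_df = 10,
                                 cpm_threshold = 1, min_libraries = 2L) {
  genotype <- match.arg(genotype)
  meta <- align_meta(counts, meta)
  if (!is.null(exclude_library)) {
    drop_ind <- meta$individual_id[meta$library_id %in% exclude_library]
    meta <- meta[!(meta$library_id %in% exclude_library) &
                   !(paired & meta$individual_id %in% drop_ind), ,
                 drop = FALSE]
  }
  meta <- meta[meta$genotype == genotype, , drop = FALSE]
  counts <- counts[, meta$library_id, drop = FALSE]
  if (any(table(factor(meta$treatment, TREATMENT_LEVELS)) < 2L))
    stop("genotype subset needs both treatments")
  filtered <- filter_expressed(counts, cpm_threshold, min_libraries)
  grp <- factor(meta$treatment, levels = TREATMENT_LEVELS)
  if (paired) {
    factors <- tmm_factors(filtered)
    phi_c <- estimate_common_dispersion(filtered, grp, factors)
    phi_tag <- estimate_tagwise_dispersion(attr(phi_c, "pseudo"), grp,
                                           as.numeric(phi_c),
                                           prior_df = prior_df)
    phi_use <- if (dispersion == "tagwise") phi_tag
               else rep(as.numeric(phi_c), nrow(filtered))
    de <- paired_lrt(filtered, meta, phi_use, factors)
  } else {
    de <- nb_exact_de(filtered, grp, dispersion = dispersion,
                      prior_df = prior_df)
  }
  structure(list(de = de, summary = summarize_contrast(de, thresholds),
                 genotype = genotype, libraries = meta$library_id),
            class = "contrast_result")
}

#' Size of the intersection of two id sets
#'
#' @param ids_a,ids_b Character vectors.
#' @return Integer `|A intersect B|`.
#' @export
set_overlap <- function(ids_a, ids_b) {
  length(intersect(unique(ids_a), unique(ids_b)))
}

#' Influence analysis for a single library
#'
#' Re-runs the genotype contrast with the named library excluded, or with
#' its individual's genotype label flipped, and reports the DE counts next
#' to the observed partition's — the leave-one-out diagnostic for libraries
#' whose expression profile contradicts their genotype label.
#'
#' @param counts Count matrix.
#' @param meta `library_meta`.
#' @param library_id Library to perturb.
#' @param mode `"exclude"` or `"reassign"`.
#' @param alpha FDR threshold for the reported counts.
#' @param ... Passed to [genotype_contrast()].
#' @return List of class `influence_result`: `mode`, `library_id`,
#'   `observed` and `perturbed` contrast results, `de_count_observed`,
#'   `de_count_perturbed`.
#' @export
influence_analysis <- function(counts, meta, library_id,
                               mode = c("exclude", "reassign"),
                               alpha = 0.01, ...) {
  mode <- match.arg(mode)
  observed <- genotype_contrast(counts, meta, thresholds = alpha, ...)
  perturbed <- if (mode == "exclude")
    genotype_contrast(counts, meta, thresholds = alpha,
                      exclude_library = library_id, ...)
  else
    genotype_contrast(counts, meta, thresholds = alpha,
                      reassign_library = library_id, ...)
  structure(list(mode = mode, library_id = library_id,
                 observed = observed, perturbed = perturbed,
                 de_count_observed = observed$summary$n_total[1L],
                 de_count_perturbed = perturbed$summary$n_total[1L]),
            class = "influence_result")
}

#' @export
print.influence_result <- function(x, ...) {
  cat(sprintf("DE at FDR<%g: observed %d, %s %s %d\n",
              x$observed$summary$threshold[1L], x$de_count_observed,
              x$library_id,
              if (x$mode == "exclude") "excluded" else "reassigned",
              x$de_count_perturbed))
  invisible(x)
}

#' Ranked locus report
#'
#' Orders a DE result by FDR (ties broken by larger |logFC|), optionally
#' joins homology annotations, and adds a `neg_log10_p` column for
#' volcano-style plotting.
#'
#' @param de A `de_result`.
#' @param annotations Optional named character vector or data.frame
#'   (`fragment_id`, `homology_id`) of annotations.
#' @return data.frame, one row per tested fragment.
#' @export
locus_report <- function(de, annotations = NULL) {
  out <- as.data.frame(de)
  out$neg_log10_p <- -log10(out$pvalue)
  ord <- order(out$fdr, -abs(out$logFC))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(annotations) && length(annotations)) {
    if (is.data.frame(annotations)) {
      ann <- setNames(annotations$homology_id, annotations$fragment_id)
    } else ann <- annotations
    out$homology_id <- unname(ann[out$fragment_id])
  }
  out
}
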