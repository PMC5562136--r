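#' DE-count statistic for a library partition
#'
#' Runs the full exact-test pipeline (TMM factors, library equalization,
#' common and tagwise dispersion, exact NB test, BH adjustment) on the given
#' two-class partition and counts the fragments below the FDR threshold.
#' Normalization and dispersions are recomputed for every partition, so
#' permuted partitions are scored by exactly the procedure applied to the
#' observed one.
#'
#' @param counts Filtered count matrix.
#' @param partition List with `class_a` and `class_b` character vectors of
#'   library ids (see [make_partition()]).
#' @param alpha FDR threshold (default 0.01).
#' @param dispersion Passed to [nb_exact_de()].
#' @return Integer count of fragments with `fdr < alpha`.
#' @export
de_count_statistic <- function(counts, partition, alpha = 0.01,
                               dispersion = "tagwise") {
  libs <- c(partition$class_a, partition$class_b)
  if (length(partition$class_a) < 2L || length(partition$class_b) < 2L)
    stop("each class needs at least two libraries")
  if (anyDuplicated(libs) || !all(libs %in% colnames(counts)))
    stop("partition classes must be disjoint known libraries")
  sub <- counts[, libs, drop = FALSE]
  grp <- factor(rep(c("A", "B"), c(length(partition$class_a),
                                   length(partition$class_b))),
                levels = c("A", "B"))
  res <- nb_exact_de(sub, grp, dispersion = dispersion)
  sum(res$fdr < alpha)
}

#' Build a partition object
#'
#' @param class_a,class_b Character vectors of library ids.
#' @param category Partition category label.
#' @param moved Library ids whose class differs from the observed partition.
#' @return List of class `partition`.
#' @export
make_partition <- function(class_a, class_b,
                           category = c("observed", "move1", "swap1",
                                        "swap2", "random"),
                           moved = character(0)) {
  category <- match.arg(category)
  if (length(intersect(class_a, class_b)))
    stop("partition classes overlap")
  structure(list(class_a = sort(class_a), class_b = sort(class_b),
                 category = category, moved = sort(moved)),
            class = "partition")
}

#' Enumerate sorted label reassignments
#'
#' Generates all near-observed partitions of the sorted permutation test:
#' (a) single libraries moved into the other class (`move1`), (b) reciprocal
#' swaps of one library from each class (`swap1`), and (c) reciprocal swaps
#' of two libraries from each class (`swap2`). The observed partition is
#' excluded; with class sizes `n_A`, `n_B` the counts are `n_A + n_B`,
#' `n_A * n_B` and `choose(n_A, 2) * choose(n_B, 2)`.
#'
#' @param labels Named character vector (or factor) of class labels per
#'   library; the first unique label is class A.
#' @return List of `partition` objects.
#' @export
enumerate_sorted_reassignments <- function(labels) {
  if (is.null(names(labels))) stop("labels must be named by library id")
  lev <- unique(as.character(labels))
  if (length(lev) != 2L) stop("need exactly two classes")
  A <- names(labels)[labels == lev[1L]]
  B <- names(labels)[labels == lev[2L]]
  if (length(A) < 2L || length(B) < 2L)
    stop("swap2 requires at least two libraries per class")
  out <- list()
  add <- function(a, b, cat, moved)
    out[[length(out) + 1L]] <<- make_partition(a, b, cat, moved)
  for (x in A) add(setdiff(A, x), c(B, x), "move1", x)
  for (x in B) add(c(A, x), setdiff(B, x), "move1", x)
  for (x in A) for (y in B)
    add(c(setdiff(A, x), y), c(setdiff(B, y), x), "swap1", c(x, y))
  pa <- combn(A, 2L, simplify = FALSE)
  pb <- combn(B, 2L, simplify = FALSE)
  for (x in pa) for (y in pb)
    add(c(setdiff(A, x), y), c(setdiff(B, y), x), "swap2", c(x, y))
  out
}

#' Sorted permutation test of a two-class partition
#'
#' Scores the observed genotype partition and every sorted reassignment
#' (single moves, reciprocal single swaps, reciprocal double swaps) by the
#' DE-count statistic and reports where the observed value falls. The
#' percentile counts permutations with strictly fewer DE fragments than
#' observed (`ties = "strict"`, the default) or splits ties evenly
#' (`ties = "midpoint"`). `libraries_in_exceeding` collects the libraries
#' moved in every permutation that strictly exceeds the observed count —
#' the influence diagnostic for suspect libraries.
#'
#' @param counts Filtered count matrix (analysis libraries only).
#' @param meta `library_meta`; genotype defines the observed partition
#'   (class A = wild, class B = ins).
#' @param alpha FDR threshold for the statistic.
#' @param ties `"strict"` or `"midpoint"` percentile convention.
#' @param dispersion Passed to the DE pipeline.
#' @return List of class `permutation_result`: `observed_stat`, `alpha`,
#'   `entries` (data.frame: category, moved, de_count), `percentile`,
#'   `libraries_in_exceeding`.
#' @export
sorted_permutation_test <- function(counts, meta, alpha = 0.01,
                                    ties = c("strict", "midpoint"),
                                    dispersion = "tagwise") {
  ties <- match.arg(ties)
  meta <- align_meta(counts, meta)
  labels <- setNames(meta$genotype, meta$library_id)
  observed <- make_partition(names(labels)[labels == "wild"],
                             names(labels)[labels == "ins"], "observed")
  obs_stat <- de_count_statistic(counts, observed, alpha, dispersion)
  perms <- enumerate_sorted_reassignments(labels)
  de_counts <- vapply(perms, function(p) {
    de_count_statistic(counts, p, alpha, dispersion)
  }, integer(1))
  entries <- data.frame(
    category = vapply(perms, `[[`, "", "category"),
    moved = vapply(perms, function(p) paste(p$moved, collapse = ","), ""),
    de_count = de_counts, stringsAsFactors = FALSE)
  exceeding <- perms[de_counts > obs_stat]
  structure(list(
    observed_stat = obs_stat, alpha = alpha, mode = "sorted",
    entries = entries,
    percentile = percentile_from_counts(obs_stat, de_counts, ties),
    libraries_in_exceeding =
      sort(unique(unlist(lapply(exceeding, `[[`, "moved"))))),
    class = "permutation_result")
}

#' Unsorted (random repartition) permutation test
#'
#' Draws `K` random equal-size splits of the libraries (uniform over the
#' distinct unordered splits; the observed split may recur), scores each by
#' the DE-count statistic, and reports the percentile of the observed
#' partition.
#'
#' @param counts Filtered count matrix (even number of libraries).
#' @param meta `library_meta` defining the observed genotype partition.
#' @param K Number of random splits (default 500).
#' @param alpha FDR threshold.
#' @param seed Integer seed for the draws.
#' @param ties Percentile tie convention, as in
#'   [sorted_permutation_test()].
#' @param dispersion Passed to the DE pipeline.
#' @return `permutation_result` (entries carry category `"random"`).
#' @export
unsorted_permutation_test <- function(counts, meta, K = 500L, alpha = 0.01,
                                      seed = 1L,
                                      ties = c("strict", "midpoint"),
                                      dispersion = "tagwise") {
  ties <- match.arg(ties)
  meta <- align_meta(counts, meta)
  libs <- meta$library_id
  if (length(libs) %% 2L != 0L)
    stop("unsorted permutation test needs an even library count")
  half <- length(libs) %/% 2L
  observed <- make_partition(libs[meta$genotype == "wild"],
                             libs[meta$genotype == "ins"], "observed")
  obs_stat <- de_count_statistic(counts, observed, alpha, dispersion)
  set.seed(as.integer(seed))
  draws <- replicate(K, sample(libs), simplify = FALSE)
  de_counts <- integer(K)
  moved <- character(K)
  for (k in seq_len(K)) {
    a <- draws[[k]][seq_len(half)]
    b <- draws[[k]][-seq_len(half)]
    part <- make_partition(a, b, "random",
                           moved = setdiff(a, observed$class_a))
    de_counts[k] <- de_count_statistic(counts, part, alpha, dispersion)
    moved[k] <- paste(part$moved, collapse = ",")
  }
  structure(list(
    observed_stat = obs_stat, alpha = alpha, mode = "unsorted",
    entries = data.frame(category = "random", moved = moved,
                         de_count = de_counts, stringsAsFactors = FALSE),
    percentile = percentile_from_counts(obs_stat, de_counts, ties),
    libraries_in_exceeding = character(0)),
    class = "permutation_result")
}

percentile_from_counts <- function(observed, permuted, ties = "strict") {
  below <- sum(permuted < observed)
  if (ties == "midpoint") below <- below + sum(permuted == observed) / 2
  100 * below / length(permuted)
}

#' Randomized probability integral transform of a permutation result
#'
#' For a discrete statistic the strictly-less percentile is not uniform
#' under the null, because ties (typically at zero DE fragments) carry
#' mass. Splitting ties uniformly at random — the randomized PIT
#' `(#\{perm < obs\} + U * (#\{perm = obs\} + 1)) / (K + 1)` with
#' `U ~ Unif(0,1)` — is exactly uniform when the observed partition is
#' exchangeable with the permuted ones, and is the quantity checked by the
#' calibration diagnostics.
#'
#' @param result A `permutation_result`.
#' @param u Optional uniform deviate (drawn if missing).
#' @return A value in (0, 1).
#' @export
pit_randomized <- function(result, u = runif(1)) {
  x <- result$entries$de_count
  (sum(x < result$observed_stat) +
     u * (sum(x == result$observed_stat) + 1)) / (length(x) + 1)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s permutation test: observed DE count %d (FDR < %g)\n",
              x$mode, x$observed_stat, x$alpha))
  cat(sprintf("  %d permutations; observed at the %.1f percentile\n",
              nrow(x$entries), x$percentile))
  if (length(x$libraries_in_exceeding))
    cat("  libraries in exceeding permutations:",
        paste(x$libraries_in_exceeding, collapse = ", "), "\n")
  invisible(x)
}
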