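#' Counts per million
#'
#' @param counts Count matrix.
#' @param factors Optional named normalization factors (see [tmm_factors()]);
#'   `NULL` means unit factors, i.e. raw library sizes.
#' @param lib_size Optional library sizes; defaults to column sums.
#' @return Real matrix of CPM values.
#' @export
cpm <- function(counts, factors = NULL, lib_size = NULL) {
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (!is.null(names(factors)) && !is.null(colnames(counts)))
    factors <- factors[colnames(counts)]
  eff <- lib_size * factors
  if (any(!is.finite(eff)) || any(eff <= 0))
    stop("effective library sizes must be positive")
  sweep(counts, 2L, eff, "/") * 1e6
}

#' Filter fragments by minimum expression
#'
#' Keeps fragments whose unnormalized CPM exceeds `cpm_threshold` (strictly)
#' in at least `min_libraries` libraries — the expression filter applied
#' before dispersion estimation and testing.
#'
#' @param counts Count matrix.
#' @param cpm_threshold CPM cutoff (default 1).
#' @param min_libraries Minimum number of libraries above the cutoff
#'   (default 2).
#' @return The retained rows of `counts`, original order preserved.
#' @export
filter_expressed <- function(counts, cpm_threshold = 1, min_libraries = 2L) {
  keep <- rowSums(cpm(counts) > cpm_threshold) >= min_libraries
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: each library is compared with a reference
#' library through per-fragment log2 ratios (M) and average log2 abundances
#' (A); after trimming the most extreme 30% of M values and 5% of A values,
#' the factor is two to the power of the precision-weighted mean of the
#' surviving M values, with weights from the delta-method binomial variances.
#' Factors are rescaled so their geometric mean is one. The reference is the
#' library whose upper-quartile CPM is closest to the mean upper-quartile,
#' unless named explicitly.
#'
#' @param counts Count matrix with at least two libraries.
#' @param trim_M Two-sided trim fraction for log-ratios (default 0.30).
#' @param trim_A Two-sided trim fraction for average abundance (default 0.05).
#' @param ref Reference library id, or `NULL` for automatic choice.
#' @return Named numeric vector of factors with attribute `lib_size`.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05, ref = NULL) {
  validate_counts(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least two libraries")
  lib_size <- colSums(counts)
  if (any(lib_size == 0)) stop("library with all-zero counts")
  if (is.null(ref)) {
    uq <- apply(cpm(counts), 2L, quantile, probs = 0.75)
    ref_j <- which.min(abs(uq - mean(uq)))
  } else {
    ref_j <- match(ref, colnames(counts))
    if (is.na(ref_j)) stop("unknown reference library: ", ref)
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref_j], lib_size[j], lib_size[ref_j],
             trim_M, trim_A)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  attr(f, "lib_size") <- lib_size
  f
}

# one library against the reference; weighted trimmed mean of M values
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_M, trim_A) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  M <- log2(p_obs[keep] / p_ref[keep])
  A <- (log2(p_obs[keep]) + log2(p_ref[keep])) / 2
  v <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
       (n_ref - ref[keep]) / (n_ref * ref[keep])
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  in_trim <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(in_trim)) return(1)
  f <- sum(M[in_trim] / v[in_trim], na.rm = TRUE) /
       sum(1 / v[in_trim], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

# effective library sizes for a factor vector aligned to a matrix
effective_sizes <- function(counts, factors = NULL) {
  lib_size <- colSums(counts)
  if (is.null(factors)) return(lib_size)
  if (!is.null(names(factors))) factors <- factors[colnames(counts)]
  lib_size * factors
}
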