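#' Conditional negative-binomial log-likelihood of one fragment in one group
#'
#' The likelihood of the within-group counts conditional on their sum, as a
#' function of the dispersion phi (variance = mu + phi * mu^2). Because the
#' conditioning removes the mean, this is the quantity maximized by
#' quantile-adjusted conditional maximum likelihood (qCML) once libraries
#' have been equalized to a common size. Constant terms not involving phi
#' are dropped.
#'
#' @param group_counts Non-negative counts of one fragment across the
#'   libraries of one group (pseudo-counts; need not be integral).
#' @param phi Dispersion, > 0.
#' @return The conditional log-likelihood (a finite scalar).
#' @export
conditional_loglik <- function(group_counts, phi) {
  if (!is.finite(phi) || phi <= 0) stop("phi must be positive")
  if (any(group_counts < 0)) stop("counts must be non-negative")
  y <- as.numeric(group_counts)
  n <- length(y)
  r <- 1 / phi
  sum(lgamma(y + r)) + lgamma(n * r) - lgamma(sum(y) + n * r) - n * lgamma(r)
}

# vectorized over fragments: Y is G x n, phi scalar or length-G
cond_ll_rows <- function(Y, phi) {
  r <- 1 / phi
  n <- ncol(Y)
  rowSums(lgamma(Y + r)) + lgamma(n * r) - lgamma(rowSums(Y) + n * r) -
    n * lgamma(r)
}

# sum over groups of per-fragment conditional log-likelihoods
cond_ll_groups <- function(Y, groups, phi) {
  out <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    if (length(idx) > 1L)
      out <- out + cond_ll_rows(Y[, idx, drop = FALSE], phi)
  }
  out
}

#' Quantile-to-quantile mapping of negative-binomial counts
#'
#' Maps a count observed under one NB mean to the equivalent quantile under
#' another NB mean at the same dispersion, averaging a normal and a gamma
#' continuous approximation. Used to rescale raw counts to a common
#' effective library size ("pseudo-counts") so the exact conditional test
#' applies.
#'
#' @param x Counts (matrix or vector).
#' @param input_mean,output_mean Means under the observed and target sizes
#'   (same shape as `x` after recycling).
#' @param dispersion NB dispersion (scalar, per-row vector, or same shape).
#' @return Pseudo-counts with the shape of `x`.
#' @export
q2qnbinom <- function(x, input_mean, output_mean, dispersion = 0) {
  if (any(dispersion < 0)) stop("dispersion must be non-negative")
  x <- as.matrix(x)
  expand <- function(v) {
    if (length(v) == 1L) return(array(v, dim(x)))
    if (is.matrix(v)) return(v)
    if (length(v) == nrow(x)) return(matrix(v, nrow(x), ncol(x)))
    stop("cannot align argument with counts")
  }
  input_mean <- expand(input_mean); output_mean <- expand(output_mean)
  dispersion <- expand(dispersion)
  zero <- input_mean < 1e-14 | output_mean < 1e-14
  input_mean[zero] <- input_mean[zero] + 0.25
  output_mean[zero] <- output_mean[zero] + 0.25
  ri <- 1 + dispersion * input_mean
  vi <- input_mean * ri
  ro <- 1 + dispersion * output_mean
  vo <- output_mean * ro
  out <- x
  up <- x >= input_mean
  for (side in c(TRUE, FALSE)) {
    idx <- if (side) up else !up
    if (!any(idx)) next
    lower <- !side
    p1 <- pnorm(x[idx], mean = input_mean[idx], sd = sqrt(vi[idx]),
                lower.tail = lower, log.p = TRUE)
    p2 <- pgamma(x[idx], shape = input_mean[idx] / ri[idx], scale = ri[idx],
                 lower.tail = lower, log.p = TRUE)
    q1 <- qnorm(p1, mean = output_mean[idx], sd = sqrt(vo[idx]),
                lower.tail = lower, log.p = TRUE)
    q2 <- qgamma(p2, shape = output_mean[idx] / ro[idx], scale = ro[idx],
                 lower.tail = lower, log.p = TRUE)
    out[idx] <- (q1 + q2) / 2
  }
  out[out < 0] <- 0
  out
}

#' Equalize libraries to a common effective size
#'
#' Rescales counts to pseudo-counts at the geometric mean of the effective
#' library sizes via [q2qnbinom()], estimating each fragment's per-group
#' mean by a one-group NB fit at the current dispersion. With equal
#' effective sizes the pseudo-counts equal the raw counts.
#'
#' @param counts Count matrix.
#' @param groups Factor over columns defining the classes.
#' @param eff_sizes Effective library sizes (library size x normalization
#'   factor); defaults to column sums.
#' @param dispersion Current NB dispersion (scalar or per-fragment).
#' @return List with `pseudo` (matrix) and `common_size` (scalar).
#' @export
equalize_libraries <- function(counts, groups, eff_sizes = NULL,
                               dispersion = 0.01) {
  if (is.null(eff_sizes)) eff_sizes <- colSums(counts)
  if (any(eff_sizes <= 0)) stop("effective sizes must be positive")
  groups <- as.factor(groups)
  common <- exp(mean(log(eff_sizes)))
  pseudo <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    y <- counts[, idx, drop = FALSE]
    m <- one_group_rate(y, eff_sizes[idx], dispersion)
    in_mean <- outer(m, eff_sizes[idx])
    out_mean <- matrix(m * common, nrow(y), length(idx))
    pseudo[, idx] <- q2qnbinom(y, in_mean, out_mean, dispersion)
  }
  list(pseudo = pseudo, common_size = common)
}

# per-fragment NB mean rate (per unit effective size) for one group,
# Newton iterations on the log rate; zero rows return rate 0
one_group_rate <- function(y, eff, dispersion) {
  tot <- rowSums(y)
  m <- tot / sum(eff)
  pos <- which(tot > 0)
  if (length(pos) == 0L || all(dispersion == 0)) return(m)
  phi <- if (length(dispersion) == nrow(y)) dispersion[pos]
         else rep(dispersion[1L], length(pos))
  beta <- log(m[pos])
  yp <- y[pos, , drop = FALSE]
  for (it in 1:30) {
    mu <- exp(beta) %o% eff
    denom <- 1 + phi * mu
    score <- rowSums((yp - mu) / denom)
    info <- rowSums(mu * (1 + phi * yp) / denom^2)
    step <- score / pmax(info, 1e-10)
    step <- pmin(pmax(step, -3), 3)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  m[pos] <- exp(beta)
  m
}

#' Common dispersion by quantile-adjusted conditional maximum likelihood
#'
#' Counts are first equalized to a common library size at a small starting
#' dispersion, the common dispersion is estimated by maximizing the summed
#' conditional log-likelihood, libraries are re-equalized at that estimate,
#' and the dispersion is estimated once more (one round of alternation).
#'
#' @param counts Count matrix (filtered).
#' @param groups Factor over columns; each class needs >= 2 libraries.
#' @param factors Optional TMM factors; `NULL` for unit factors.
#' @param interval Search bounds for phi.
#' @return The common dispersion (scalar), with attributes `pseudo` and
#'   `common_size` carrying the matching pseudo-counts.
#' @export
estimate_common_dispersion <- function(counts, groups, factors = NULL,
                                       interval = c(1e-6, 10)) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop("groups must have one entry per library")
  if (any(table(groups) < 2L))
    stop("each group needs at least two libraries")
  if (all(counts == 0)) stop("all counts are zero")
  eff <- effective_sizes(counts, factors)
  maximize <- function(pseudo) {
    opt <- optimize(function(lp) sum(cond_ll_groups(pseudo, groups, exp(lp))),
                    interval = log(interval), maximum = TRUE, tol = 1e-4)
    exp(opt$maximum)
  }
  eq0 <- equalize_libraries(counts, groups, eff, dispersion = 0.01)
  phi1 <- maximize(eq0$pseudo)
  eq1 <- equalize_libraries(counts, groups, eff, dispersion = phi1)
  phi <- maximize(eq1$pseudo)
  attr(phi, "pseudo") <- eq1$pseudo
  attr(phi, "common_size") <- eq1$common_size
  phi
}

#' Tagwise dispersions by weighted-likelihood empirical Bayes
#'
#' Each fragment's dispersion maximizes its own conditional log-likelihood
#' plus `W` times the mean conditional log-likelihood over all fragments,
#' shrinking noisy per-fragment estimates toward the common value. The
#' default weight is `prior_df / residual_df` with `prior_df = 10` and
#' `residual_df = sum over groups of (n_k - 1)`.
#'
#' @param pseudo Equalized pseudo-count matrix.
#' @param groups Factor over columns.
#' @param phi_common Common dispersion (used only as a reference point for
#'   degenerate inputs).
#' @param prior_df Prior degrees of freedom for the default weight.
#' @param W Explicit prior weight (>= 0, may be `Inf`); overrides
#'   `prior_df`.
#' @param interval Search bounds for phi.
#' @param grid_length Number of log-spaced grid points for the likelihood
#'   profiles (a quadratic refinement is applied around the maximum).
#' @return Numeric vector of per-fragment dispersions.
#' @export
estimate_tagwise_dispersion <- function(pseudo, groups, phi_common,
                                        prior_df = 10, W = NULL,
                                        interval = c(1e-6, 10),
                                        grid_length = 64L) {
  groups <- as.factor(groups)
  if (is.null(W)) {
    resid_df <- length(groups) - nlevels(groups)
    if (resid_df <= 0) stop("no residual degrees of freedom")
    W <- prior_df / resid_df
  }
  if (is.na(W) || W < 0) stop("prior weight must be non-negative")
  lgrid <- seq(log(interval[1L]), log(interval[2L]), length.out = grid_length)
  L <- vapply(lgrid, function(lp) cond_ll_groups(pseudo, groups, exp(lp)),
              numeric(nrow(pseudo)))
  lbar <- colMeans(L)
  obj <- if (is.infinite(W)) matrix(lbar, nrow(pseudo), grid_length,
                                    byrow = TRUE)
         else L + W * matrix(lbar, nrow(pseudo), grid_length, byrow = TRUE)
  k <- max.col(obj, ties.method = "first")
  lphi <- lgrid[k]
  # quadratic refinement around the grid maximum
  inner <- which(k > 1L & k < grid_length)
  if (length(inner)) {
    i <- inner
    y1 <- obj[cbind(i, k[i] - 1L)]
    y2 <- obj[cbind(i, k[i])]
    y3 <- obj[cbind(i, k[i] + 1L)]
    denom <- y1 - 2 * y2 + y3
    shift <- ifelse(abs(denom) > 1e-12, 0.5 * (y1 - y3) / denom, 0)
    step <- lgrid[2L] - lgrid[1L]
    lphi[i] <- lphi[i] + pmin(pmax(shift, -1), 1) * step
  }
  phi <- exp(lphi)
  names(phi) <- rownames(pseudo)
  phi
}

#' Exact negative-binomial two-group test
#'
#' For each fragment the class pseudo-sums are compared conditionally on
#' their total: under the null every split of the total between the classes
#' follows a convolution of two NB laws with a shared per-library mean, and
#' the two-sided p-value accumulates all outcomes whose probability does not
#' exceed that of the observed split.
#'
#' @param pseudo Equalized pseudo-count matrix.
#' @param groups Factor over columns with exactly two levels; the first
#'   level is class A (reference), the second class B, and positive logFC
#'   means higher expression in class B.
#' @param dispersion Per-fragment (or scalar) NB dispersion.
#' @param common_size Common effective library size used for logCPM;
#'   defaults to the geometric mean of column sums.
#' @return A `de_result` data.frame with columns `fragment_id`, `logFC`
#'   (log2 B over A, prior count 0.5 per class mean), `logCPM` (log2 average
#'   CPM, prior 0.25), `pvalue`, `fdr` (Benjamini-Hochberg).
#' @export
exact_test <- function(pseudo, groups, dispersion, common_size = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exact test needs exactly two groups")
  a <- which(groups == levels(groups)[1L])
  b <- which(groups == levels(groups)[2L])
  if (length(a) < 1L || length(b) < 1L) stop("empty group")
  if (is.null(common_size))
    common_size <- exp(mean(log(colSums(pseudo))))
  zA <- rowSums(pseudo[, a, drop = FALSE])
  zB <- rowSums(pseudo[, b, drop = FALSE])
  phi <- if (length(dispersion) == 1L) rep(dispersion, nrow(pseudo))
         else dispersion
  if (length(phi) != nrow(pseudo))
    stop("dispersion must be scalar or per-fragment")
  p <- exact_nb_pvals_cpp(zA, zB, length(a), length(b), as.numeric(phi))
  logFC <- log2(((zB + 0.5) / length(b)) / ((zA + 0.5) / length(a)))
  logFC[zA + zB == 0] <- 0
  logCPM <- log2((rowMeans(pseudo) + 0.25) / common_size * 1e6)
  de_result(rownames(pseudo), logFC, logCPM, p)
}

de_result <- function(id, logFC, logCPM, pvalue) {
  res <- data.frame(fragment_id = id, logFC = logFC, logCPM = logCPM,
                    pvalue = pvalue, fdr = bh_fdr(pvalue),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: the i-th smallest p-value becomes
#' `min over j >= i of p_(j) * m / j`, capped at one.
#'
#' @param pvalues Numeric vector with values in (0, 1].
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Full exact-test differential expression pipeline for one two-class contrast
#'
#' Chains TMM normalization, library equalization, qCML common dispersion,
#' empirical Bayes tagwise dispersion, the exact NB test, and BH adjustment.
#'
#' @param counts Filtered count matrix.
#' @param groups Factor over columns with two levels (first = class A).
#' @param factors TMM factors, or `NULL` to compute them.
#' @param dispersion `"tagwise"` (default) or `"common"`.
#' @param prior_df Prior degrees of freedom for tagwise shrinkage.
#' @return `de_result` with attributes `phi_common`, `phi_tagwise`,
#'   `factors`, `common_size`.
#' @export
nb_exact_de <- function(counts, groups, factors = NULL,
                        dispersion = c("tagwise", "common"), prior_df = 10) {
  dispersion <- match.arg(dispersion)
  groups <- as.factor(groups)
  if (is.null(factors)) factors <- tmm_factors(counts)
  phi_c <- estimate_common_dispersion(counts, groups, factors)
  pseudo <- attr(phi_c, "pseudo")
  common_size <- attr(phi_c, "common_size")
  phi_tag <- estimate_tagwise_dispersion(pseudo, groups, as.numeric(phi_c),
                                         prior_df = prior_df)
  phi_use <- if (dispersion == "tagwise") phi_tag
             else rep(as.numeric(phi_c), nrow(counts))
  res <- exact_test(pseudo, groups, phi_use, common_size)
  attr(res, "phi_common") <- as.numeric(phi_c)
  attr(res, "phi_tagwise") <- phi_tag
  attr(res, "factors") <- factors
  attr(res, "common_size") <- common_size
  res
}

#' Paired negative-binomial likelihood-ratio test
#'
#' Fits, per fragment, the NB log-linear model
#' `log mu = log(effective size) + individual + treatment` by iteratively
#' reweighted least squares at fixed dispersion, and tests the treatment
#' effect against the individual-only null model with a 1-df chi-square
#' likelihood ratio.
#'
#' @param counts Count matrix covering both treatments of every individual.
#' @param meta `library_meta` for the columns.
#' @param dispersion Per-fragment (or scalar) dispersion, held fixed.
#' @param factors Optional TMM factors.
#' @return `de_result` (logFC = log2 elevated over ambient) with attribute
#'   `converged` (logical per fragment; non-converged rows get p = 1).
#' @export
paired_lrt <- function(counts, meta, dispersion, factors = NULL) {
  meta <- align_meta(counts, meta)
  tab <- table(meta$individual_id, meta$treatment)
  if (!all(tab == 1L))
    stop("every individual needs exactly one library per treatment")
  eff <- effective_sizes(counts, factors)
  indiv <- factor(meta$individual_id)
  treat <- factor(meta$treatment, levels = TREATMENT_LEVELS)
  X_full <- stats::model.matrix(~ indiv + treat)
  X_null <- stats::model.matrix(~ indiv)
  offset <- log(eff)
  G <- nrow(counts)
  phi <- if (length(dispersion) == 1L) rep(dispersion, G) else dispersion
  pval <- rep(1, G)
  lfc <- numeric(G)
  conv <- logical(G)
  for (g in seq_len(G)) {
    y <- counts[g, ]
    full <- nb_irls(y, X_full, offset, phi[g])
    null <- nb_irls(y, X_null, offset, phi[g])
    conv[g] <- full$converged && null$converged
    if (conv[g]) {
      lrt <- max(null$deviance - full$deviance, 0)
      pval[g] <- pchisq(lrt, df = 1L, lower.tail = FALSE)
      lfc[g] <- full$coef[ncol(X_full)] / log(2)
    }
  }
  pval[pval <= 0] <- .Machine$double.xmin
  logCPM <- log2(rowMeans(cpm(counts, factors)) + 0.25)
  res <- de_result(rownames(counts), lfc, logCPM, pval)
  attr(res, "converged") <- conv
  res
}

nb_deviance <- function(y, mu, phi) {
  r <- 1 / phi
  mu <- pmax(mu, 1e-10)
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + r) * log((y + r) / (mu + r))
  2 * sum(t1 - t2)
}

nb_irls <- function(y, X, offset, phi, maxit = 50L, tol = 1e-8) {
  mu <- pmax(y, 1 / 6)
  eta <- log(mu)
  dev <- nb_deviance(y, mu, phi)
  beta <- NULL
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    if (anyNA(beta_new)) break
    eta_new <- offset + pmin(pmax(drop(X %*% beta_new), -30), 30)
    mu_new <- exp(eta_new)
    dev_new <- nb_deviance(y, mu_new, phi)
    # step-halve toward the previous deviance if needed
    half <- 0L
    while (!is.finite(dev_new) || (dev_new > dev + 1e-10 && half < 10L)) {
      if (is.null(beta)) break
      beta_new <- (beta_new + beta) / 2
      eta_new <- offset + pmin(pmax(drop(X %*% beta_new), -30), 30)
      mu_new <- exp(eta_new)
      dev_new <- nb_deviance(y, mu_new, phi)
      half <- half + 1L
    }
    done <- is.finite(dev_new) && abs(dev - dev_new) < tol * (abs(dev) + 0.1)
    beta <- beta_new; eta <- eta_new; mu <- mu_new; dev <- dev_new
    if (done) { converged <- TRUE; break }
  }
  list(coef = beta, deviance = dev, converged = converged, mu = mu)
}
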