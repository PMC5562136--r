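#' Exclude individuals with unresponsive righting trials
#'
#' An individual with any trial exceeding the cutoff (one hour by default)
#' is considered unresponsive and removed entirely from analysis.
#'
#' @param records Righting data.frame (individual_id, period, replicate,
#'   time_s).
#' @param cutoff_s Unresponsiveness cutoff in seconds (default 3600).
#' @return List with `kept` (records of responsive individuals) and
#'   `excluded` (character vector of individual ids).
#' @export
filter_unresponsive <- function(records, cutoff_s = 3600) {
  if (nrow(records) == 0L)
    return(list(kept = records, excluded = character(0)))
  bad <- unique(records$individual_id[records$time_s > cutoff_s |
                                        !is.finite(records$time_s)])
  list(kept = records[!(records$individual_id %in% bad), , drop = FALSE],
       excluded = sort(bad))
}

#' Per-individual righting summaries
#'
#' Minimum, mean and sd of righting times per individual, per trial period
#' and overall. The sd of a single trial is reported as missing.
#'
#' @param records Filtered righting records.
#' @return data.frame with columns individual_id, period (including
#'   `"overall"`), n_trials, min_time, mean_time, sd_time.
#' @export
righting_summary <- function(records) {
  summarize_block <- function(df, period) {
    data.frame(individual_id = df$individual_id[1L], period = period,
               n_trials = nrow(df), min_time = min(df$time_s),
               mean_time = mean(df$time_s),
               sd_time = if (nrow(df) > 1L) sd(df$time_s) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (ind in unique(records$individual_id)) {
    sub <- records[records$individual_id == ind, , drop = FALSE]
    for (per in intersect(PERIOD_LEVELS, unique(sub$period)))
      out[[length(out) + 1L]] <-
        summarize_block(sub[sub$period == per, , drop = FALSE], per)
    out[[length(out) + 1L]] <- summarize_block(sub, "overall")
  }
  do.call(rbind, out)
}

# per-individual overall value of the chosen statistic
individual_values <- function(summary, statistic) {
  overall <- summary[summary$period == "overall", , drop = FALSE]
  setNames(overall[[if (statistic == "mean") "mean_time" else "min_time"]],
           overall$individual_id)
}

genotype_of <- function(meta) {
  ind <- unique(data.frame(individual_id = meta$individual_id,
                           genotype = meta$genotype,
                           stringsAsFactors = FALSE))
  setNames(ind$genotype, ind$individual_id)
}

#' Compare righting times across genotypes
#'
#' Welch two-sample t-test on per-individual righting statistics, plus the
#' ratio of class means oriented so that faster ins righting gives a ratio
#' above one (mean wild time over mean ins time).
#'
#' @param summary Output of [righting_summary()].
#' @param meta data.frame with `individual_id` and `genotype` (a
#'   `library_meta` works; it is de-duplicated by individual).
#' @param statistic `"mean"` (default) or `"min"` per-individual time.
#' @return List: `t`, `p_value`, `ratio_wild_over_ins`, `n_wild`, `n_ins`,
#'   `mean_wild`, `mean_ins`.
#' @export
genotype_compare <- function(summary, meta, statistic = c("mean", "min")) {
  statistic <- match.arg(statistic)
  vals <- individual_values(summary, statistic)
  geno <- genotype_of(meta)[names(vals)]
  if (anyNA(geno)) stop("individual without genotype metadata")
  wild <- vals[geno == "wild"]
  ins <- vals[geno == "ins"]
  if (length(wild) < 2L || length(ins) < 2L)
    stop("need at least two individuals per genotype")
  if (sd(wild) == 0 && sd(ins) == 0) {
    tt <- list(statistic = c(t = if (mean(wild) == mean(ins)) 0 else Inf *
                               sign(mean(wild) - mean(ins))),
               p.value = if (mean(wild) == mean(ins)) 1 else 0)
  } else {
    tt <- t.test(wild, ins)
  }
  list(t = unname(tt$statistic), p_value = tt$p.value,
       ratio_wild_over_ins = mean(wild) / mean(ins),
       n_wild = length(wild), n_ins = length(ins),
       mean_wild = mean(wild), mean_ins = mean(ins))
}

#' Permutation test of the genotype difference in righting times
#'
#' Distribution-free companion to the t-test: the absolute difference in
#' class means is compared with its distribution under genotype-label
#' shuffling. All distinct assignments are enumerated when there are at
#' most `exhaustive_limit` of them; otherwise `K` random shuffles are drawn
#' and the observed assignment is included in the reference set, so the
#' smallest attainable p-value is `1 / (K + 1)` (or one over the number of
#' assignments when enumerating).
#'
#' @param summary Output of [righting_summary()].
#' @param meta Individual genotype table as in [genotype_compare()].
#' @param statistic `"mean"` or `"min"`.
#' @param K Number of random shuffles when not enumerating.
#' @param seed Integer seed.
#' @param exhaustive_limit Enumerate exhaustively when the number of
#'   distinct label assignments is at most this.
#' @return List: `p_value`, `observed_diff`, `n_reference`, `exhaustive`.
#' @export
genotype_permutation <- function(summary, meta, statistic = c("mean", "min"),
                                 K = 1e4L, seed = 1L,
                                 exhaustive_limit = 1000L) {
  statistic <- match.arg(statistic)
  vals <- individual_values(summary, statistic)
  geno <- genotype_of(meta)[names(vals)]
  n_wild <- sum(geno == "wild")
  n <- length(vals)
  obs <- abs(mean(vals[geno == "wild"]) - mean(vals[geno == "ins"]))
  diff_for <- function(wild_idx)
    abs(mean(vals[wild_idx]) - mean(vals[-wild_idx]))
  n_assign <- choose(n, n_wild)
  if (n_assign <= exhaustive_limit) {
    combs <- combn(n, n_wild, simplify = FALSE)
    ref <- vapply(combs, diff_for, numeric(1))
    p <- sum(ref >= obs - 1e-12) / length(ref)
    exhaustive <- TRUE
  } else {
    set.seed(as.integer(seed))
    ref <- replicate(K, diff_for(sample.int(n, n_wild)))
    p <- (sum(ref >= obs - 1e-12) + 1) / (K + 1)
    exhaustive <- FALSE
  }
  list(p_value = p, observed_diff = obs, n_reference = length(ref),
       exhaustive = exhaustive)
}
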