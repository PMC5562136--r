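#' Simulation parameters for the paired two-genotype study design
#'
#' Defaults emulate the study design the package analyzes: five individuals
#' per genotype, each sequenced at ambient and elevated temperature;
#' log-normal baseline abundance; NB counts with tagwise dispersion spread
#' around a common value; a small planted minority of genotype-affected
#' fragments with strongly asymmetric direction (most lower in `ins`
#' heterozygotes); genotype-specific temperature responsiveness (many more
#' responders in `wild` than in `ins`, partially overlapping); and an
#' optional "recombinant" wild-labelled individual whose genotype-effect
#' fragments follow the `ins` class means.
#'
#' @param n_per_genotype Individuals per genotype (each contributes one
#'   library per treatment).
#' @param n_fragments Number of fragments G.
#' @param library_size_log_mean,library_size_log_sd Log-normal parameters of
#'   expected library sizes; the default mean scales with `n_fragments` so
#'   the average per-fragment depth stays near 250 reads.
#' @param abundance_log_sd Log-normal sd of baseline relative abundance.
#' @param phi0 Common NB dispersion (variance = mu + phi mu^2).
#' @param phi_log_sd Log-normal spread of tagwise dispersions around `phi0`.
#' @param pi_de Fraction of fragments with a genotype effect.
#' @param rho Fraction of affected fragments with lower expression in `ins`.
#' @param lfc_mean,lfc_sd Magnitude distribution of |log2 fold change| for
#'   genotype-affected fragments (normal, truncated below 0.25).
#' @param k_wild,k_ins Number of temperature-responsive fragments per
#'   genotype.
#' @param temp_overlap Fraction of the `ins` responders shared with the
#'   `wild` responder set.
#' @param temp_lfc_mean_wild,temp_lfc_mean_ins,temp_lfc_sd Normal parameters
#'   of the temperature log2 fold changes per genotype.
#' @param individual_log_sd Log-normal per-individual, per-fragment random
#'   effect (0 disables; positive values induce within-pair correlation).
#' @param outlier_library If `TRUE`, one wild individual's genotype-effect
#'   fragments are drawn with the `ins` class means in both its libraries.
#' @param seed Integer seed; expanded into per-stage substreams.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_per_genotype = 5L,
                       n_fragments = 2000L,
                       library_size_log_mean = log(250 * n_fragments),
                       library_size_log_sd = 0.25,
                       abundance_log_sd = 1.2,
                       phi0 = 0.2,
                       phi_log_sd = 0.1,
                       pi_de = 0.02,
                       rho = 0.85,
                       lfc_mean = 2,
                       lfc_sd = 0,
                       k_wild = 46L,
                       k_ins = 6L,
                       temp_overlap = 0.5,
                       temp_lfc_mean_wild = -0.5,
                       temp_lfc_mean_ins = 0.3,
                       temp_lfc_sd = 1.9,
                       individual_log_sd = 0,
                       outlier_library = FALSE,
                       seed = 1L) {
  p <- as.list(environment())
  num <- vapply(p[setdiff(names(p), "outlier_library")], is.numeric, TRUE)
  if (!all(num)) stop("simulation parameters must be numeric")
  if (any(!vapply(p[names(num)[num]], function(v) all(is.finite(v)), TRUE)))
    stop("non-finite simulation parameter")
  stopifnot(p$n_per_genotype >= 1, p$n_fragments >= 1,
            p$phi0 > 0, p$pi_de >= 0, p$pi_de <= 1,
            p$rho >= 0, p$rho <= 1, p$temp_overlap >= 0, p$temp_overlap <= 1,
            p$k_wild >= 0, p$k_ins >= 0)
  class(p) <- "sim_params"
  p
}

# stage substreams from a single global seed
stage_seeds <- function(seed, n = 8L) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a paired two-genotype RNA-seq experiment
#'
#' Generates counts `y ~ NB(mean = s_j * q_g * f(genotype, treatment),
#' dispersion = phi_g)` for the design described in [sim_params()], together
#' with metadata and the planted ground truth used by recovery tests.
#'
#' @param params A [sim_params()] object (or arguments forwarded to it).
#' @param ... Convenience overrides passed to [sim_params()] when `params`
#'   is missing.
#' @return List with `counts` (matrix), `meta` (`library_meta`) and `truth`
#'   (list: `affected` data.frame of fragment/true_lfc/direction,
#'   `temperature` per-genotype fragment sets with true logFCs,
#'   `outlier_individual`, `outlier_library`, `params`).
#' @export
simulate_experiment <- function(params = sim_params(...), ...) {
  p <- params
  if (!inherits(p, "sim_params")) p <- do.call(sim_params, as.list(params))
  ss <- stage_seeds(p$seed)
  G <- as.integer(p$n_fragments)
  n <- as.integer(p$n_per_genotype)
  frag_ids <- sprintf("frag_%04d", seq_len(G))

  individuals <- c(paste0("wild_", seq_len(n)), paste0("ins_", seq_len(n)))
  genotype <- rep(GENOTYPE_LEVELS, each = n)
  meta <- data.frame(
    library_id = paste(rep(individuals, each = 2L),
                       rep(c("amb", "elev"), times = 2L * n), sep = "_"),
    individual_id = rep(individuals, each = 2L),
    genotype = rep(genotype, each = 2L),
    treatment = rep(TREATMENT_LEVELS, times = 2L * n),
    stringsAsFactors = FALSE)
  meta <- as_library_meta(meta)

  set.seed(ss[1L])
  lib_size <- exp(rnorm(nrow(meta), p$library_size_log_mean,
                        p$library_size_log_sd))
  set.seed(ss[2L])
  q <- exp(rnorm(G, 0, p$abundance_log_sd))
  q <- q / sum(q)
  set.seed(ss[3L])
  phi_g <- p$phi0 * exp(rnorm(G, 0, p$phi_log_sd) - p$phi_log_sd^2 / 2)

  # planted genotype effects: true_lfc = log2(ins / wild), mostly negative
  set.seed(ss[4L])
  n_de <- round(p$pi_de * G)
  affected <- sort(sample.int(G, n_de))
  down_in_ins <- rbinom(n_de, 1L, p$rho) == 1L
  mag <- pmax(rnorm(n_de, p$lfc_mean, p$lfc_sd), 0.25)
  true_lfc <- ifelse(down_in_ins, -mag, mag)

  # temperature responders per genotype: true logFC = log2(elevated/ambient)
  set.seed(ss[5L])
  k_w <- min(as.integer(p$k_wild), G)
  k_i <- min(as.integer(p$k_ins), G)
  temp_wild <- sort(sample.int(G, k_w))
  # overlap target, raised if the non-responder pool cannot host the rest
  n_shared <- min(max(round(p$temp_overlap * k_i), k_i - (G - k_w)), k_w, k_i)
  shared <- temp_wild[sample.int(k_w, n_shared)]
  rest_pool <- setdiff(seq_len(G), temp_wild)
  temp_ins <- sort(c(shared, rest_pool[sample.int(length(rest_pool),
                                                  k_i - n_shared)]))
  tlfc_wild <- rnorm(k_w, p$temp_lfc_mean_wild, p$temp_lfc_sd)
  tlfc_ins <- rnorm(k_i, p$temp_lfc_mean_ins, p$temp_lfc_sd)

  set.seed(ss[6L])
  outlier_ind <- if (isTRUE(p$outlier_library))
    sample(individuals[genotype == "wild"], 1L) else NA_character_

  # expected means per (fragment, library)
  mu <- q %o% lib_size
  geno_mult <- matrix(1, G, nrow(meta))
  is_ins_profile <- meta$genotype == "ins" |
    (!is.na(outlier_ind) & meta$individual_id == outlier_ind)
  geno_mult[affected, is_ins_profile] <- 2^true_lfc
  temp_mult <- matrix(1, G, nrow(meta))
  elev <- meta$treatment == "elevated"
  temp_mult[temp_wild, elev & meta$genotype == "wild"] <- 2^tlfc_wild
  temp_mult[temp_ins, elev & meta$genotype == "ins"] <- 2^tlfc_ins
  mu <- mu * geno_mult * temp_mult

  if (p$individual_log_sd > 0) {
    set.seed(ss[7L])
    for (ind in individuals) {
      re <- exp(rnorm(G, 0, p$individual_log_sd) - p$individual_log_sd^2 / 2)
      mu[, meta$individual_id == ind] <-
        mu[, meta$individual_id == ind] * re
    }
  }

  set.seed(ss[8L])
  counts <- matrix(rnbinom(G * nrow(meta), mu = mu, size = rep(1 / phi_g,
                   nrow(meta))), G, nrow(meta),
                   dimnames = list(frag_ids, meta$library_id))
  storage.mode(counts) <- "integer"

  truth <- list(
    affected = data.frame(fragment_id = frag_ids[affected],
                          true_lfc = true_lfc,
                          direction = ifelse(down_in_ins, "down_in_ins",
                                             "up_in_ins"),
                          stringsAsFactors = FALSE),
    temperature = list(
      wild = data.frame(fragment_id = frag_ids[temp_wild],
                        true_lfc = tlfc_wild, stringsAsFactors = FALSE),
      ins = data.frame(fragment_id = frag_ids[temp_ins],
                       true_lfc = tlfc_ins, stringsAsFactors = FALSE)),
    phi = setNames(phi_g, frag_ids),
    outlier_individual = outlier_ind,
    outlier_library = if (is.na(outlier_ind)) NA_character_
                      else paste0(outlier_ind, "_amb"),
    params = p)
  list(counts = counts, meta = meta, truth = truth)
}

#' Simulate righting-response trials
#'
#' Three trial periods (ambient before, elevated, ambient after) with three
#' replicates per individual per period. Wild times are `ratio` times the
#' ins times on average; noise acts multiplicatively at the individual level
#' (sd `noise_sd` on the log scale) and at half that spread per replicate.
#' A small probability of an unresponsive trial (> 3600 s) exercises the
#' one-hour exclusion rule.
#'
#' @param n_ins,n_wild Individuals per genotype.
#' @param ratio Mean wild righting time over mean ins time.
#' @param noise_sd Log-scale individual-level noise sd.
#' @param seed Integer seed.
#' @param base_time_ins Mean ins righting time in seconds at ambient.
#' @param period_mult Multipliers for the three periods.
#' @param unresponsive_prob Per-trial probability of exceeding one hour.
#' @return List with `records` (data.frame: individual_id, period,
#'   replicate, time_s) and `meta` (individual_id, genotype).
#' @export
simulate_righting <- function(n_ins = 5L, n_wild = 5L, ratio = 1.8,
                              noise_sd = 0.3, seed = 1L,
                              base_time_ins = 250,
                              period_mult = c(ambient_pre = 1,
                                              elevated = 1.25,
                                              ambient_post = 1),
                              unresponsive_prob = 0.01) {
  if (ratio <= 0) stop("ratio must be positive")
  set.seed(as.integer(seed))
  ids <- c(paste0("ins_", seq_len(n_ins)), paste0("wild_", seq_len(n_wild)))
  genotype <- rep(c("ins", "wild"), c(n_ins, n_wild))
  class_mean <- ifelse(genotype == "ins", base_time_ins, base_time_ins * ratio)
  ind_mult <- if (noise_sd > 0)
    exp(rnorm(length(ids), 0, noise_sd) - noise_sd^2 / 2) else rep(1, length(ids))
  rows <- list()
  for (i in seq_along(ids)) {
    for (per in PERIOD_LEVELS) {
      for (rep_k in 1:3) {
        noise <- if (noise_sd > 0)
          exp(rnorm(1, 0, noise_sd / 2) - (noise_sd / 2)^2 / 2) else 1
        t_s <- class_mean[i] * ind_mult[i] * period_mult[[per]] * noise
        if (unresponsive_prob > 0 && runif(1) < unresponsive_prob)
          t_s <- 3600 + runif(1, 60, 600)
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = ids[i], period = per, replicate = rep_k,
          time_s = round(t_s, 1), stringsAsFactors = FALSE)
      }
    }
  }
  list(records = do.call(rbind, rows),
       meta = data.frame(individual_id = ids, genotype = genotype,
                         stringsAsFactors = FALSE))
}

#' Generate a Trinity-style feature map
#'
#' Transcript ids follow the `TRINITY_DN<k>_c0_g<j>_i<i>` convention; a
#' fraction of genes share a homology id so homology-level collapse strictly
#' reduces the row count while unannotated genes survive under their own id.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Isoforms per gene.
#' @param homology_sharing Fraction of genes annotated with a (shared)
#'   homology id; shared ids cover pairs of genes.
#' @param seed Integer seed.
#' @return `feature_map` data.frame.
#' @export
make_feature_map <- function(n_genes, isoforms_per_gene = 2L,
                             homology_sharing = 0.5, seed = 1L) {
  stopifnot(n_genes >= 1, isoforms_per_gene >= 1)
  set.seed(as.integer(seed))
  cluster <- sprintf("TRINITY_DN%d_c0", seq_len(n_genes))
  gene <- paste0(cluster, "_g1")
  homology <- rep("", n_genes)
  n_annot <- round(homology_sharing * n_genes)
  if (n_annot >= 2L) {
    annot <- sort(sample.int(n_genes, n_annot))
    gi <- paste0("gi:", 1000 + ceiling(seq_along(annot) / 2))
    homology[annot] <- gi
  }
  fm <- data.frame(
    transcript_id = paste0(rep(gene, each = isoforms_per_gene), "_i",
                           rep(seq_len(isoforms_per_gene), times = n_genes)),
    cluster_id = rep(cluster, each = isoforms_per_gene),
    gene_id = rep(gene, each = isoforms_per_gene),
    homology_id = rep(homology, each = isoforms_per_gene),
    stringsAsFactors = FALSE)
  as_feature_map(fm)
}
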