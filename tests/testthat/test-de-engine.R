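test_that("conditional log-likelihood matches direct log-gamma evaluation", {
  # all-zero group collapses to zero for any dispersion
  expect_equal(conditional_loglik(c(0, 0), 0.5), 0)
  expect_equal(conditional_loglik(c(0, 0, 0), 3), 0)
  y <- c(3, 3); phi <- 0.1; r <- 1 / phi
  direct <- sum(lgamma(y + r)) + lgamma(2 * r) - lgamma(6 + 2 * r) -
    2 * lgamma(r)
  expect_equal(conditional_loglik(y, phi), direct)
  y2 <- c(7, 0, 2, 11)
  expect_equal(conditional_loglik(y2, 0.3),
               conditional_loglik(rev(y2), 0.3))
  expect_error(conditional_loglik(y2, 0), "positive")
})

test_that("equalization is the identity at equal sizes and tracks scaling", {
  m <- random_counts(G = 100, n = 4, mu = 50, seed = 1)
  eq <- equalize_libraries(m, factor(rep("g", 4)),
                           eff_sizes = rep(1e5, 4), dispersion = 0.2)
  expect_equal(eq$pseudo, m, ignore_attr = TRUE, tolerance = 1e-12)
  # a library at double size is brought back by roughly direct rescaling
  set.seed(2)
  y <- rnbinom(200, mu = 100, size = 5)
  m2 <- cbind(L1 = y, L2 = y, L3 = 2L * y)
  rownames(m2) <- paste0("g", seq_len(200))
  eq2 <- equalize_libraries(m2, factor(rep("g", 3)), dispersion = 0.2)
  direct <- sweep(m2, 2, eq2$common_size / colSums(m2), "*")
  expect_lt(max(abs(eq2$pseudo - direct)), 1)
  # every pseudo library sits at the common size
  expect_equal(unname(colSums(eq2$pseudo)),
               rep(eq2$common_size, 3), tolerance = 0.02)
})

test_that("common dispersion hits the Poisson boundary and recovers truth", {
  set.seed(3)
  G <- 1500
  pois <- matrix(rpois(G * 8, lambda = 80), G, 8,
                 dimnames = list(paste0("g", 1:G), paste0("L", 1:8)))
  storage.mode(pois) <- "integer"
  grp <- factor(rep(c("A", "B"), each = 4))
  expect_lt(as.numeric(estimate_common_dispersion(pois, grp)), 1e-3)

  sim <- simulate_experiment(sim_params(seed = 4, pi_de = 0, k_wild = 0,
                                        k_ins = 0, phi_log_sd = 0))
  a <- ambient_subset(sim)
  counts <- filter_expressed(a$counts)
  phi <- estimate_common_dispersion(counts,
                                    factor(a$meta$genotype,
                                           c("wild", "ins")))
  expect_gt(as.numeric(phi), 0.15)
  expect_lt(as.numeric(phi), 0.25)
  # invariant to fragment order
  ord <- sample(nrow(counts))
  phi2 <- estimate_common_dispersion(counts[ord, ],
                                     factor(a$meta$genotype,
                                            c("wild", "ins")))
  expect_equal(as.numeric(phi), as.numeric(phi2), tolerance = 1e-8)
})

test_that("tagwise dispersion has the right shrinkage limits", {
  sim <- simulate_experiment(sim_params(seed = 5, n_fragments = 300))
  a <- ambient_subset(sim)
  counts <- filter_expressed(a$counts)
  grp <- factor(a$meta$genotype, c("wild", "ins"))
  phi_c <- estimate_common_dispersion(counts, grp)
  pseudo <- attr(phi_c, "pseudo")
  # W -> Inf collapses every fragment onto the pooled maximizer
  tw_inf <- estimate_tagwise_dispersion(pseudo, grp, as.numeric(phi_c),
                                        W = Inf)
  expect_lt(diff(range(tw_inf)), 1e-8)
  expect_equal(unname(tw_inf[1]), as.numeric(phi_c), tolerance = 0.05)
  # W = 0 gives the per-fragment conditional ML estimate
  tw0 <- estimate_tagwise_dispersion(pseudo, grp, as.numeric(phi_c), W = 0)
  for (g in c(3L, 57L, 140L)) {
    ml <- exp(optimize(function(lp) {
      conditional_loglik(pseudo[g, grp == "wild"], exp(lp)) +
        conditional_loglik(pseudo[g, grp == "ins"], exp(lp))
    }, log(c(1e-6, 10)), maximum = TRUE, tol = 1e-7)$maximum)
    expect_equal(unname(tw0[g]), ml, tolerance = 0.02)
  }
  expect_error(estimate_tagwise_dispersion(pseudo, grp,
                                           as.numeric(phi_c), W = -1),
               "non-negative")
})

test_that("tagwise shrinkage is monotone in the prior weight", {
  sim <- simulate_experiment(sim_params(seed = 6, n_fragments = 200,
                                        phi_log_sd = 0.6))
  a <- ambient_subset(sim)
  counts <- filter_expressed(a$counts)
  grp <- factor(a$meta$genotype, c("wild", "ins"))
  phi_c <- estimate_common_dispersion(counts, grp)
  pseudo <- attr(phi_c, "pseudo")
  ws <- c(0, 1, 5, 50)
  ests <- sapply(ws, function(w)
    estimate_tagwise_dispersion(pseudo, grp, as.numeric(phi_c), W = w))
  center <- estimate_tagwise_dispersion(pseudo, grp, as.numeric(phi_c),
                                        W = Inf)[1]
  dist <- abs(log(ests) - log(center))
  for (j in seq_len(length(ws) - 1))
    expect_true(all(dist[, j + 1] <= dist[, j] + 0.06))
})

test_that("exact test is symmetric, modal at balance, and safe at zero", {
  m <- rbind(bal = c(10L, 12L, 11L, 11L), zero = c(0L, 0L, 0L, 0L),
             shift = c(40L, 38L, 2L, 3L))
  colnames(m) <- paste0("L", 1:4)
  grp <- factor(c("A", "A", "B", "B"))
  res <- exact_test(m, grp, dispersion = 0.1, common_size = 1e4)
  expect_equal(res$pvalue[res$fragment_id == "zero"], 1)
  expect_equal(res$logFC[res$fragment_id == "zero"], 0)
  # balanced pseudo-sums are modal: p = 1
  m2 <- rbind(eq = c(9L, 5L, 5L, 9L)); colnames(m2) <- paste0("L", 1:4)
  expect_equal(exact_test(m2, grp, 0.2)$pvalue, 1)
  # swapping class labels preserves p and negates logFC
  swapped <- exact_test(m, factor(c("B", "B", "A", "A"), c("A", "B")),
                        dispersion = 0.1, common_size = 1e4)
  expect_equal(swapped$pvalue, res$pvalue, tolerance = 1e-12)
  expect_equal(swapped$logFC, -res$logFC, tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.004, 0.9, 0.03, 0.2, 0.0011)
  q <- bh_fdr(p)
  m <- length(p); o <- order(p)
  hand <- rev(cummin(rev(p[o] * m / seq_len(m))))[order(o)]
  expect_equal(q, pmin(hand, 1))
  expect_true(all(q >= p))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("paired LRT matches a fixed-theta NB GLM and nests deviances", {
  sim <- simulate_experiment(sim_params(seed = 7, n_fragments = 80))
  meta <- sim$meta[sim$meta$genotype == "wild", , drop = FALSE]
  counts <- filter_expressed(sim$counts[, meta$library_id])
  indiv <- factor(meta$individual_id)
  treat <- factor(meta$treatment, c("ambient", "elevated"))
  X_full <- stats::model.matrix(~ indiv + treat)
  X_null <- stats::model.matrix(~ indiv)
  off <- log(colSums(counts))
  for (g in c(2L, 30L, 61L)) {
    y <- counts[g, ]; phi <- 0.15
    ours_full <- pisasterDE:::nb_irls(y, X_full, off, phi)
    ours_null <- pisasterDE:::nb_irls(y, X_null, off, phi)
    ref <- glm(y ~ X_full - 1 + offset(off),
               family = MASS::negative.binomial(theta = 1 / phi))
    expect_equal(ours_full$deviance, ref$deviance, tolerance = 1e-6)
    expect_equal(max(abs(ours_full$coef - coef(ref))), 0, tolerance = 1e-5)
    expect_lte(ours_full$deviance, ours_null$deviance + 1e-8)
  }
  expect_error(paired_lrt(counts[, -1], meta[-1, ], 0.1),
               "one library per treatment")
})

test_that("paired LRT is calibrated under the null and powered when planted", {
  sim <- simulate_experiment(sim_params(seed = 8, pi_de = 0, k_wild = 0,
                                        k_ins = 0))
  meta <- sim$meta[sim$meta$genotype == "wild", , drop = FALSE]
  counts <- filter_expressed(sim$counts[, meta$library_id])
  grp <- factor(meta$treatment, c("ambient", "elevated"))
  factors <- tmm_factors(counts)
  phi_c <- estimate_common_dispersion(counts, grp, factors)
  phi_tag <- estimate_tagwise_dispersion(attr(phi_c, "pseudo"), grp,
                                         as.numeric(phi_c))
  res <- paired_lrt(counts, meta, phi_tag, factors)
  typeI <- mean(res$pvalue < 0.05)
  expect_gte(typeI, 0.03)
  expect_lte(typeI, 0.07)
  # a planted 4-fold paired treatment effect is found at FDR < 0.05
  sim2 <- simulate_experiment(sim_params(seed = 9, pi_de = 0, k_wild = 60,
                                         k_ins = 0, temp_lfc_mean_wild = 2,
                                         temp_lfc_sd = 0))
  meta2 <- sim2$meta[sim2$meta$genotype == "wild", , drop = FALSE]
  res2 <- temperature_response(sim2$counts, sim2$meta, "wild",
                               paired = TRUE)
  hits <- res2$de$fragment_id[res2$de$fdr < 0.05]
  planted <- sim2$truth$temperature$wild$fragment_id
  expect_gt(mean(planted %in% hits), 0.5)
})

test_that("the full exact-test chain is label-exchange symmetric", {
  sim <- simulate_experiment(sim_params(seed = 10, n_fragments = 250))
  a <- ambient_subset(sim)
  counts <- filter_expressed(a$counts)
  grp <- factor(a$meta$genotype, c("wild", "ins"))
  de1 <- nb_exact_de(counts, grp)
  de2 <- nb_exact_de(counts, factor(as.character(grp), c("ins", "wild")))
  expect_equal(de2$pvalue, de1$pvalue, tolerance = 1e-10)
  expect_equal(de2$logFC, -de1$logFC, tolerance = 1e-10)
})
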