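test_that("genotype contrast nests thresholds and splits directions", {
  sim <- simulate_experiment(sim_params(seed = 30))
  res <- genotype_contrast(sim$counts, sim$meta)
  s <- res$summary
  expect_equal(s$n_higher_in_A + s$n_higher_in_B, s$n_total)
  loose <- s$n_total[s$threshold == 0.01]
  strict <- s$n_total[s$threshold == 1e-4]
  expect_gte(loose, strict)
  strict_ids <- res$de$fragment_id[res$de$fdr < 1e-4]
  loose_ids <- res$de$fragment_id[res$de$fdr < 0.01]
  expect_true(all(strict_ids %in% loose_ids))
  expect_identical(res$libraries,
                   sim$meta$library_id[sim$meta$treatment == "ambient"])
})

test_that("positive-class flag flips the displayed orientation only", {
  sim <- simulate_experiment(sim_params(seed = 31, n_fragments = 300))
  res_ins <- genotype_contrast(sim$counts, sim$meta)
  res_wild <- genotype_contrast(sim$counts, sim$meta,
                                positive_class = "wild")
  expect_equal(res_wild$de$logFC, -res_ins$de$logFC)
  expect_equal(res_wild$de$pvalue, res_ins$de$pvalue)
  expect_equal(res_wild$summary$n_higher_in_B, res_ins$summary$n_higher_in_B)
})

test_that("abundance asymmetry of the DE sides is recovered by construction", {
  # plant high-abundance fragments higher in wild, low-abundance higher in
  # ins, as the study reports for its DE sets
  set.seed(32)
  G <- 300
  mu <- rep(80, G); mu[1:10] <- 2000; mu[11:20] <- 40
  m <- sapply(1:10, function(j) {
    f <- rep(1, G)
    wild <- j <= 5
    f[1:10] <- if (wild) 2.5 else 0.4   # high-abundance, down in ins
    f[11:20] <- if (wild) 0.4 else 2.5  # low-abundance, up in ins
    rnbinom(G, mu = mu * f, size = 1 / 0.05)
  })
  dimnames(m) <- list(sprintf("g%03d", 1:G), paste0("L", 1:10))
  storage.mode(m) <- "integer"
  meta <- two_class_meta()
  meta$library_id <- colnames(m)
  res <- genotype_contrast(m, meta, thresholds = 0.01)
  s <- res$summary
  expect_gt(s$mean_logCPM_higher_in_A, s$mean_logCPM_higher_in_B)
  expect_gt(s$n_total, 10)
})

test_that("temperature response orders genotypes and nests thresholds", {
  sim <- simulate_experiment(sim_params(seed = 33))
  rw <- temperature_response(sim$counts, sim$meta, "wild")
  ri <- temperature_response(sim$counts, sim$meta, "ins")
  n_wild <- rw$summary$n_total[rw$summary$threshold == 0.01]
  n_ins <- ri$summary$n_total[ri$summary$threshold == 0.01]
  expect_gt(n_wild, n_ins)
  expect_gte(rw$summary$n_total[rw$summary$threshold == 0.1], n_wild)
  expect_gte(ri$summary$n_total[ri$summary$threshold == 0.1], n_ins)
  # planted mean direction per genotype is recovered in sign
  expect_lt(rw$summary$mean_logFC_sig[rw$summary$threshold == 0.1], 0)
  expect_true(is.finite(rw$summary$sd_logFC_all[1]))
})

test_that("set overlap is plain intersection size", {
  expect_equal(set_overlap(c("a", "b", "c"), c("b", "c", "d")), 2L)
  expect_equal(set_overlap(c("a"), c("b")), 0L)
  expect_equal(set_overlap(c("a", "b"), c("a", "b", "z")), 2L)
})

test_that("influence analysis perturbs and restores exactly", {
  sim <- simulate_experiment(sim_params(seed = 34, n_fragments = 300,
                                        outlier_library = TRUE))
  out_lib <- sim$truth$outlier_library
  inf <- influence_analysis(sim$counts, sim$meta, out_lib, "exclude")
  expect_false(out_lib %in% inf$perturbed$libraries)
  expect_true(out_lib %in% inf$observed$libraries)
  # identical inputs give identical summaries (pure function)
  again <- influence_analysis(sim$counts, sim$meta, out_lib, "exclude")
  expect_identical(inf$de_count_observed, again$de_count_observed)
  expect_identical(inf$de_count_perturbed, again$de_count_perturbed)
  # reassignment flips the whole individual and keeps all libraries
  re <- influence_analysis(sim$counts, sim$meta, out_lib, "reassign")
  expect_length(re$perturbed$libraries, 10L)
  expect_error(influence_analysis(sim$counts, sim$meta, "nope", "exclude"),
               "unknown library")
})

test_that("locus report ranks by FDR then effect size and joins annotation", {
  de <- data.frame(fragment_id = c("a", "b", "c", "d"),
                   logFC = c(1, -3, 2, 0.5),
                   logCPM = c(5, 6, 7, 8),
                   pvalue = c(0.01, 0.001, 0.001, 0.2),
                   fdr = c(0.02, 0.004, 0.004, 0.2))
  rep <- locus_report(de)
  expect_equal(rep$fragment_id, c("b", "c", "a", "d"))
  expect_equal(nrow(rep), 4L)
  expect_false("homology_id" %in% colnames(rep))
  rep2 <- locus_report(de, c(a = "gi:1", b = "gi:2", c = "", d = "gi:3"))
  expect_equal(rep2$homology_id[1], "gi:2")
  expect_equal(rep2$neg_log10_p, -log10(rep2$pvalue))
})
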