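test_that("sorted reassignments hit the closed-form category counts", {
  for (nA in 2:6) for (nB in 2:6) {
    labels <- setNames(rep(c("wild", "ins"), c(nA, nB)),
                       paste0("L", seq_len(nA + nB)))
    perms <- enumerate_sorted_reassignments(labels)
    cats <- table(vapply(perms, `[[`, "", "category"))
    expect_equal(unname(cats["move1"]), nA + nB)
    expect_equal(unname(cats["swap1"]), nA * nB)
    expect_equal(unname(cats["swap2"]), choose(nA, 2) * choose(nB, 2))
  }
  # the study design: 5 vs 5 gives 10 + 25 + 100
  labels <- setNames(rep(c("wild", "ins"), each = 5), paste0("L", 1:10))
  expect_length(enumerate_sorted_reassignments(labels), 135L)
})

test_that("2 vs 2 reassignments are distinct and exclude the observed", {
  labels <- setNames(c("wild", "wild", "ins", "ins"), c("a", "b", "c", "d"))
  perms <- enumerate_sorted_reassignments(labels)
  expect_length(perms, 9L)
  keys <- vapply(perms, function(p) paste(p$class_a, collapse = ","), "")
  expect_false(any(duplicated(keys)))
  observed_key <- "a,b"
  expect_false(observed_key %in% keys)
})

test_that("percentile follows the strictly-less convention", {
  expect_equal(pisasterDE:::percentile_from_counts(5L, c(rep(0L, 96),
                                                         rep(7L, 4))), 96)
  expect_equal(pisasterDE:::percentile_from_counts(0L, rep(0L, 10)), 0)
  expect_equal(pisasterDE:::percentile_from_counts(0L, rep(0L, 10),
                                                   ties = "midpoint"), 50)
  # adding a permutation below the observed cannot lower the percentile
  x <- c(0L, 1L, 3L)
  expect_gte(pisasterDE:::percentile_from_counts(2L, c(x, 1L)),
             pisasterDE:::percentile_from_counts(2L, x) *
               length(x) / (length(x) + 1))
})

test_that("the DE-count statistic is label-symmetric and needs 2 per class", {
  sim <- simulate_experiment(sim_params(seed = 20, n_fragments = 200))
  a <- ambient_subset(sim)
  counts <- filter_expressed(a$counts)
  wild <- a$meta$library_id[a$meta$genotype == "wild"]
  ins <- a$meta$library_id[a$meta$genotype == "ins"]
  s1 <- de_count_statistic(counts, make_partition(wild, ins))
  s2 <- de_count_statistic(counts, make_partition(ins, wild))
  expect_identical(s1, s2)
  expect_error(de_count_statistic(counts,
                                  make_partition(wild[1], c(ins, wild[-1]))),
               "at least two")
})

test_that("a strong planted effect dominates every sorted permutation", {
  sim <- simulate_experiment(sim_params(seed = 21, n_fragments = 300,
                                        pi_de = 0.1, lfc_mean = 3))
  a <- ambient_subset(sim)
  counts <- filter_expressed(a$counts)
  res <- sorted_permutation_test(counts, a$meta)
  expect_gt(res$observed_stat,
            max(res$entries$de_count))
  expect_equal(res$percentile, 100)
  expect_length(res$libraries_in_exceeding, 0L)
})

test_that("unsorted permutation test is seeded, bounded and well-formed", {
  sim <- simulate_experiment(sim_params(seed = 22, n_fragments = 200))
  a <- ambient_subset(sim)
  counts <- filter_expressed(a$counts)
  r1 <- unsorted_permutation_test(counts, a$meta, K = 8, seed = 5)
  r2 <- unsorted_permutation_test(counts, a$meta, K = 8, seed = 5)
  expect_identical(r1$entries, r2$entries)
  expect_identical(r1$percentile, r2$percentile)
  expect_gte(r1$percentile, 0)
  expect_lte(r1$percentile, 100)
  expect_equal(nrow(r1$entries), 8L)
  # odd library count is rejected
  expect_error(unsorted_permutation_test(counts[, -1], a$meta[-1, ], K = 4),
               "even")
  # the 10-library design has C(10,5)/2 = 126 distinct unordered splits
  expect_equal(choose(10, 5) / 2, 126)
  splits <- replicate(400, {
    s <- sort(sample(colnames(counts), 5))
    paste(s, collapse = ",")
  })
  expect_lte(length(unique(splits)), 252)  # ordered labellings of 126 splits
})

test_that("randomized PIT lands in (0,1) and respects tie mass", {
  fake <- structure(list(observed_stat = 0L, alpha = 0.01,
                         entries = data.frame(category = "random",
                                              moved = "",
                                              de_count = rep(0L, 9))),
                    class = "permutation_result")
  expect_equal(pit_randomized(fake, u = 0.5), 0.5)
  expect_equal(pit_randomized(fake, u = 0.1), 0.1)
  fake$entries$de_count <- c(rep(0L, 4), rep(2L, 5))
  expect_equal(pit_randomized(fake, u = 1), 0.5)
})
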