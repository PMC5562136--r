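# Shared fixtures, built in code.

tiny_counts <- function() {
  m <- matrix(c(1L, 3L, 2L, 4L), nrow = 2,
              dimnames = list(c("fragA", "fragB"), c("L1", "L2")))
  m
}

# deterministic NB count matrix with named dims
random_counts <- function(G = 50, n = 4, mu = 50, phi = 0.2, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(G * n, mu = mu, size = 1 / phi), G, n,
              dimnames = list(sprintf("g%03d", seq_len(G)),
                              paste0("L", seq_len(n))))
  storage.mode(m) <- "integer"
  m
}

# a 2-genotype, ambient-only metadata table for a count matrix whose columns
# are named w1..wk, i1..ik
two_class_meta <- function(n_wild = 5, n_ins = 5) {
  as_library_meta(data.frame(
    library_id = c(paste0("w", seq_len(n_wild)), paste0("i", seq_len(n_ins))),
    individual_id = c(paste0("W", seq_len(n_wild)),
                      paste0("I", seq_len(n_ins))),
    genotype = rep(c("wild", "ins"), c(n_wild, n_ins)),
    treatment = "ambient", stringsAsFactors = FALSE))
}

# brute-force small-p exact NB p-value by enumeration of all Z + 1 outcomes
enumerate_exact_pval <- function(s1, s2, nA, nB, phi) {
  Z <- s1 + s2
  if (Z == 0) return(1)
  mu <- Z / (nA + nB)
  lp <- dnbinom(0:Z, size = nA / phi, mu = nA * mu, log = TRUE) +
    dnbinom(Z:0, size = nB / phi, mu = nB * mu, log = TRUE)
  pr <- exp(lp - max(lp))
  sum(pr[lp <= lp[s1 + 1]]) / sum(pr)
}

ambient_subset <- function(sim) {
  meta <- sim$meta[sim$meta$treatment == "ambient", , drop = FALSE]
  list(counts = sim$counts[, meta$library_id, drop = FALSE], meta = meta)
}
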