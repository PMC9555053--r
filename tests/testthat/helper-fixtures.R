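# Shared fixtures and independent oracles used across the suite.

# Deterministic toy gene: ATG followed by n_codons - 1 sense codons.
toy_gene <- function(n_codons, seed = 1) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  sense <- setdiff(sense, "ATG")
  set.seed(seed)
  paste0("ATG", paste(sample(sense, n_codons - 1, replace = TRUE),
                      collapse = ""))
}

toy_spec <- function(n_codons = 8, seed = 1, ...) {
  operon_spec("toy", toy_gene(n_codons, seed),
              mutagenized_positions = 2:n_codons, ...)
}

# Two-family toy usage table: Ala (GCT 0.6 max, GCA 0.2),
# Gly (GGT 0.7 max, GGA 0.1).
toy_usage <- function() {
  usage_table(data.frame(codon = c("GCT", "GCA", "GGT", "GGA"),
                         fraction = c(0.6, 0.2, 0.7, 0.1)))
}

# Brute-force Gotoh local alignment (affine gaps: open + len * extend),
# returning only the optimal score. Independent of Biostrings.
sw_oracle <- function(a, b, match = 5, mismatch = -4,
                      gap_open = 20, gap_extend = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)      # best ending in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)    # gap in b (a aligned to '-')
  Y <- matrix(NEG, n + 1, m + 1)    # gap in a
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(nx + ny, nx) group assignments (tie-free data only).
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- combn(nx + ny, nx)
  u_null <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  p_le <- mean(u_null <= u_obs)
  p_ge <- mean(u_null >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Direct Poisson tail summation (no ppois).
poisson_tail_oracle <- function(lambda, k_exclusive) {
  # P(X > k) by summing the complement explicitly
  terms <- exp(-lambda) * lambda^(0:k_exclusive) /
    factorial(0:k_exclusive)
  1 - sum(terms)
}

min_reads_oracle <- function(total_reads, q, alpha = 0.05,
                             strictly_greater = TRUE) {
  lambda <- total_reads * 10^(-q / 10) / 4
  k <- 0
  repeat {
    tail <- if (strictly_greater) poisson_tail_oracle(lambda, k)
            else 1 - sum(exp(-lambda) * lambda^(0:max(k - 1, -1)) /
                           factorial(0:max(k - 1, -1)))
    if (k == 0 && !strictly_greater) tail <- 1
    if (tail < alpha) return(k)
    k <- k + 1
  }
}

# Small simulated study used by several tests: library + counts + truth.
toy_study <- function(n_codons = 17, depth = 1e5, n_replicates = 3,
                      rcu_coefficient = 2, noise_sd = 1.2,
                      wt_fraction = 0.1, seed = 7) {
  spec <- toy_spec(n_codons)
  variants <- enumerate_nnk_variants(spec)
  usage <- load_usage_table()
  lib <- assign_true_effects(
    variants, effect_model(rcu_coefficient = rcu_coefficient,
                           noise_sd = noise_sd, seed = seed),
    usage, wt_fraction)
  cfg <- sim_config(depth_per_replicate = depth,
                    n_replicates = n_replicates, seed = seed + 1)
  list(spec = spec, variants = variants, usage = usage, lib = lib,
       cfg = cfg, counts = simulate_counts(lib, cfg))
}
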