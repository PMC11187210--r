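# shared in-code fixtures for the test suite

toy_metadata <- function(conditions, replicates = 2L, reference = conditions[1]) {
  conds <- rep(conditions, each = replicates)
  reps <- rep(seq_len(replicates), times = length(conditions))
  data.frame(sample_id = paste0(conds, "_r", reps), condition_id = conds,
             replicate = reps, batch = "batch1",
             is_reference = conds == reference)
}

# a vector with an exact sample correlation rho to `v` (via residualization)
vector_with_cor <- function(v, rho, seed = 1) {
  set.seed(seed)
  u <- stats::rnorm(length(v))
  r <- stats::resid(stats::lm(u ~ v))
  as.numeric(rho * scale(v) + sqrt(1 - rho ^ 2) * scale(r))
}

# brute-force one-sided hypergeometric tail by direct summation
hyper_tail_oracle <- function(x, regulon_size, members_size, background_size) {
  ks <- x:min(regulon_size, members_size)
  sum(choose(regulon_size, ks) *
        choose(background_size - regulon_size, members_size - ks)) /
    choose(background_size, members_size)
}

# planted rank-k matrix with sparse weight modules (for ICA unit tests)
planted_decomposable <- function(n_genes, n_samples, k, seed,
                                 module_size = 20L, noise = 0) {
  set.seed(seed)
  M0 <- matrix(0, n_genes, k)
  genes <- sample(n_genes)
  for (j in seq_len(k)) {
    idx <- genes[((j - 1) * module_size + 1):(j * module_size)]
    M0[idx, j] <- stats::runif(module_size, 0.5, 1) *
      sample(c(-1, 1), module_size, TRUE, prob = c(0.2, 0.8))
  }
  M0 <- sweep(M0, 2, sqrt(colSums(M0 ^ 2)), "/")
  A0 <- matrix(stats::rexp(k * n_samples) - stats::rexp(k * n_samples),
               k, n_samples)
  X <- M0 %*% A0
  if (noise > 0) X <- X + matrix(stats::rnorm(length(X), 0, noise), nrow(X))
  rownames(X) <- rownames(M0) <- sprintf("g%04d", seq_len(n_genes))
  colnames(X) <- paste0("s", seq_len(n_samples))
  list(X = X, M0 = M0, A0 = A0)
}
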