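# shared fixtures, built once per test run

ped_fix <- simulate_pedigree(seed = 11)
panel_fix <- simulate_genotypes(ped_fix, n_markers = 1500,
                                missing_rate = 0, invariant_fraction = 0,
                                seed = 12)
W_fix <- impute_missing(panel_fix$genotypes)

# phenotype with a marker-based genetic signal of heritability h2 (unit total)
planted_trait <- function(W, n_qtl, h2, seed) {
  set.seed(seed)
  qtl <- sample.int(ncol(W), n_qtl)
  g <- drop(W[, qtl, drop = FALSE] %*% stats::rnorm(n_qtl))
  g <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) * sqrt(h2) else g * 0
  y <- g + stats::rnorm(nrow(W), 0, sqrt(1 - h2))
  names(y) <- names(g) <- rownames(W)
  list(y = y, g = g)
}

# small random ridge instance for solver oracles
random_instance <- function(seed, n = 20, p = 50) {
  set.seed(seed)
  W <- matrix(stats::rbinom(n * p, 2, stats::runif(1, 0.2, 0.5)), n, p,
              dimnames = list(paste0("i", seq_len(n)), paste0("m", seq_len(p))))
  list(W = W, y = stats::rnorm(n), X = matrix(1, n, 1),
       sg = stats::runif(1, 0.2, 2), se = stats::runif(1, 0.5, 2))
}
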