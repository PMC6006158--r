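# Shared fixtures and independent oracles.  Everything is generated in
# code; nothing is read from disk.

# small mixed cohort with both strata represented
tiny_cohort <- function(n = 60, seed = 42, max_visits = 3, ...) {
  sc <- sim_scenario(n_subjects = n, n_snps = 5, seed = seed,
                     max_visits = max_visits, ...)
  g <- simulate_genotypes(sc)
  list(scenario = sc, geno = g, pheno = simulate_cohort(sc, g))
}

# Brute-force MVN log-likelihood: builds each subject's full covariance
# from the natural parameters and evaluates the dense Gaussian density
# via determinant() and solve(), independently of the whitened/profiled
# path inside the package.
oracle_loglik <- function(bundle, beta, cov_params) {
  ll <- 0
  r <- bundle$y - as.vector(bundle$X %*% beta)
  for (b in bundle$blocks) {
    par <- cov_params[[b$group]]
    V <- switch(par$structure,
      independence = diag(par$sigma2, b$m),
      random_intercept = {
        sup <- bundle$group_visits[[b$group]]
        matrix(par$sigma2, b$m, b$m) +
          diag(par$d[match(b$visits, sup)], b$m)
      },
      unstructured = {
        sup <- bundle$group_visits[[b$group]]
        i <- match(b$visits, sup)
        par$V[i, i, drop = FALSE]
      })
    Vi <- solve(V)
    ldet <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
    rm <- matrix(r[b$idx], nrow = b$m)      # columns are subjects
    for (j in seq_len(b$ns)) {
      rj <- rm[, j]
      ll <- ll - 0.5 * (b$m * log(2 * pi) + ldet +
                        drop(crossprod(rj, Vi %*% rj)))
    }
  }
  ll
}

# Exact Hardy-Weinberg enumeration oracle: the closed-form conditional
# probability of each heterozygote count given the allele counts,
#   P(h | n, nA) = n! 2^h nA! na! / (nAA! h! naa! (2n)!),
# computed without any normalization (the probabilities must sum to 1 on
# their own, which the tests assert) — an independent route from the
# normalized multinomial kernel used by the implementation.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  nr <- (rare - hets) / 2           # rare-homozygote count
  nc <- n - nr - hets               # common-homozygote count
  lp <- lgamma(n + 1) + hets * log(2) + lgamma(rare + 1) +
    lgamma(2 * n - rare + 1) - lgamma(nr + 1) - lgamma(hets + 1) -
    lgamma(nc + 1) - lgamma(2 * n + 1)
  pr <- exp(lp)
  stopifnot(abs(sum(pr) - 1) < 1e-9)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}
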