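test_that("marginal_covariance closed forms", {
  expect_equal(marginal_covariance("independence", list(sigma2 = 1), 1:3),
               diag(3))
  # random intercept 2 + diagonal (1,1) on visits {1,3}
  expect_equal(
    marginal_covariance("random_intercept", list(sigma2 = 2, d = c(1, 1)),
                        visits = c(1, 3)),
    matrix(c(3, 2, 2, 3), 2))
  V <- matrix(c(4, 1, 0.5, 1, 3, 0.8, 0.5, 0.8, 2), 3)
  expect_equal(marginal_covariance("unstructured", list(V = V), visits = 2),
               V[2, 2, drop = FALSE])
  expect_error(
    marginal_covariance("unstructured",
                        list(V = matrix(c(1, 2, 2, 1), 2)), visits = 1:2),
    "PD error")
})

test_that("loglik matches the dense MVN oracle on all three structures", {
  fx <- tiny_cohort(n = 20, seed = 7)
  V0 <- matrix(0.03, 3, 3) + diag(c(0.05, 0.06, 0.07))
  params <- list(
    independence = list(structure = "independence", sigma2 = 0.3),
    random_intercept = list(structure = "random_intercept", sigma2 = 0.1,
                            d = c(0.2, 0.25, 0.3)),
    unstructured = list(structure = "unstructured", V = V0))
  for (cv in names(params)) {
    spec <- spec_testing(snp = FALSE, pcs = FALSE, covariance = cv)
    bundle <- build_design(fx$pheno, spec)
    cp <- list(params[[cv]], params[[cv]])
    names(cp) <- names(bundle$group_visits)
    for (g in seq_along(cp)) cp[[g]]$support <- bundle$group_visits[[g]]
    beta <- setNames(rep(0.01, ncol(bundle$X)), colnames(bundle$X))
    beta[1] <- 2.9
    expect_lt(abs(lmm_loglik(bundle, beta, cp) -
                  oracle_loglik(bundle, beta, cp)), 1e-8)
  }
  # the profiled fit agrees with the direct evaluation at its own optimum
  bundle <- build_design(fx$pheno,
                         spec_testing(snp = FALSE, pcs = FALSE,
                                      covariance = "random_intercept"))
  fit <- fit_ml(bundle)
  expect_true(fit$converged)
  ll <- lmm_loglik(bundle, fit$beta_hat, fit$cov_params)
  expect_lt(abs(ll - fit$loglik), 1e-8)
  expect_lt(abs(ll - oracle_loglik(bundle, fit$beta_hat, fit$cov_params)),
            1e-8)
})

test_that("single observation with unit variance gives the standard normal density", {
  df <- data.frame(subject_id = "a", visit = 1L, time = 0, fev1 = 5,
                   age0 = 50, sex = 1, height = 160, bmi = 24,
                   smoking = "never", pack_years = 0,
                   stringsAsFactors = FALSE)
  spec <- model_spec("age", smoking_coding = "none",
                     covariance = "independence")
  bundle <- build_design(df, spec)
  beta <- c(5 - 50, 1)  # intercept + age * 50 == 5, residual 0
  expect_equal(lmm_loglik(bundle, beta, list(list(structure = "independence",
                                                  sigma2 = 1))),
               -0.5 * log(2 * pi))
})

test_that("loglik depends on data only through residuals", {
  fx <- tiny_cohort(n = 15, seed = 3)
  spec <- spec_testing(snp = FALSE, pcs = FALSE,
                       covariance = "random_intercept")
  b1 <- build_design(fx$pheno, spec)
  fit <- fit_ml(b1)
  ph2 <- fx$pheno
  ph2$fev1 <- ph2$fev1 + 1        # shift response and intercept together
  b2 <- build_design(ph2, spec)
  beta2 <- fit$beta_hat
  beta2[1] <- beta2[1] + 1
  expect_equal(lmm_loglik(b2, beta2, fit$cov_params),
               lmm_loglik(b1, fit$beta_hat, fit$cov_params))
})

test_that("analytic gradient of the profile deviance matches finite differences", {
  fx <- tiny_cohort(n = 40, seed = 11)
  for (cv in c("independence", "random_intercept", "unstructured")) {
    spec <- spec_testing(snp = FALSE, pcs = FALSE, covariance = cv)
    bundle <- build_design(fx$pheno, spec)
    core <- hetgwis:::.make_profile_deviance(bundle)
    th <- fit_ml(bundle)$theta + 0.05  # off-optimum point
    num <- vapply(seq_along(th), function(k) {
      h <- 1e-6; e <- numeric(length(th)); e[k] <- h
      (core(th + e) - core(th - e)) / (2 * h)
    }, 0)
    expect_equal(core(th, "grad"), num, tolerance = 1e-5)
  }
})

test_that("fit_ml is consistent, stationary, and beats the truth in likelihood", {
  set.seed(5)
  n <- 1500
  sc <- sim_scenario(n_subjects = n, n_snps = 2, max_visits = 1,
                     dropout_prob = 0, seed = 21,
                     sigma2_never = 1e-8, sigma2_ever = 1e-8,
                     Sigma_never = matrix(1), Sigma_ever = matrix(1))
  g <- simulate_genotypes(sc)
  ph <- simulate_cohort(sc, g)
  spec <- model_spec(c("age", "sex", "smoking"), covariance = "independence",
                     heteroscedastic = FALSE)
  bundle <- build_design(ph, spec)
  fit <- fit_ml(bundle)
  expect_true(fit$converged)
  # total variance is sigma2 + Sigma ~= 1
  expect_gt(fit$cov_params[[1]]$sigma2, 0.9)
  expect_lt(fit$cov_params[[1]]$sigma2, 1.1)
  refit <- fit_ml(bundle, init = fit)
  expect_lt(abs(refit$loglik - fit$loglik), 1e-8)
  # ML optimality vs the generative parameters
  truth <- list(all = list(structure = "independence", sigma2 = 1))
  beta_true <- fit$beta_hat * 0  # arbitrary fixed point, worse than MLE
  expect_gte(fit$loglik + 1e-6,
             lmm_loglik(bundle, beta_true, truth))
})

test_that("degenerate and collinear designs raise errors naming columns", {
  fx <- tiny_cohort(n = 30, seed = 13)
  spec <- spec_testing(snp = TRUE, pcs = FALSE)
  zero_snp <- setNames(rep(0, 30), unique(fx$pheno$subject_id))
  bundle <- build_design(fx$pheno, spec, snp = zero_snp)
  expect_error(fit_ml(bundle), "snp")
  const_snp <- setNames(rep(2, 30), unique(fx$pheno$subject_id))
  expect_error(fit_ml(build_design(fx$pheno, spec, snp = const_snp)),
               "collinear")
})

test_that("lrt matches chi-square reference points and rejects bad nesting", {
  f1 <- list(loglik = -100); f0 <- list(loglik = -100)
  t0 <- lrt(f1, f0, df = 3)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p, 1)
  # chi-square 95th percentiles: 7.81 (3 df), 3.84 (1 df)
  t1 <- lrt(list(loglik = -100 + 7.81 / 2), f0, df = 3)
  expect_equal(t1$p, 0.05, tolerance = 1e-2)
  t2 <- lrt(list(loglik = -100 + 3.84 / 2), f0, df = 1)
  expect_equal(t2$p, 0.05, tolerance = 1e-2)
  expect_error(lrt(list(loglik = -101), f0, df = 1),
               "optimization-quality")
})

test_that("wald_joint: zero subset, scalar identity, large-df F limit", {
  fx <- tiny_cohort(n = 80, seed = 17)
  snp <- setNames(as.numeric(fx$geno$dosages[, 1]),
                  fx$geno$sample_ids)
  bundle <- build_design(fx$pheno, spec_testing(snp = TRUE, pcs = FALSE),
                         snp = snp)
  fit <- fit_ml(bundle)
  # scalar case equals the squared z statistic
  w1 <- wald_joint(fit, "snp")
  z <- fit$beta_hat[["snp"]] / sqrt(fit$vcov_beta["snp", "snp"])
  expect_equal(w1$statistic, z^2, tolerance = 1e-10)
  # artificial fit with zero coefficients
  fake <- fit
  fake$beta_hat[c("snp", "snp:ever")] <- 0
  w0 <- wald_joint(fake, c("snp", "snp:ever"))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)
  # chi-square and F forms converge for large residual df
  fake2 <- fit
  fake2$n_obs <- 20000 + fit$rank
  w2 <- wald_joint(fake2, c("snp", "snp:ever", "snp:pack_years"))
  expect_equal(w2$p, w2$p_chisq, tolerance = 1e-3)
})

test_that("AIC identities", {
  fx <- tiny_cohort(n = 40, seed = 19)
  snp <- setNames(as.numeric(fx$geno$dosages[, 2]), fx$geno$sample_ids)
  b_full <- build_design(fx$pheno, spec_testing(snp = TRUE, pcs = FALSE),
                         snp = snp)
  b_red <- build_design(fx$pheno, spec_testing(snp = FALSE, pcs = FALSE))
  f_red <- fit_ml(b_red)
  f_full <- fit_ml(b_full, init = f_red)
  expect_equal(aic_of(f_full), -2 * f_full$loglik + 2 * f_full$k)
  # nested models: AIC difference = 2 * ddf - LRT statistic
  stat <- lrt(f_full, f_red, 3)$statistic
  ddf <- f_full$k - f_red$k
  expect_equal(aic_of(f_full) - aic_of(f_red), 2 * ddf - stat,
               tolerance = 1e-6)
})

test_that("1-DF LRT null distribution matches chi-square(1)", {
  # cross-sectional independence-structure nulls, 1000 replicates
  set.seed(101)
  n <- 120
  stats <- vapply(seq_len(1000), function(i) {
    x <- cbind(1, rnorm(n), rbinom(n, 2, 0.3))
    y <- rnorm(n) + x[, 2] * 0.5
    df <- data.frame(subject_id = sprintf("s%03d", seq_len(n)), visit = 1L,
                     time = 0, fev1 = y, age0 = x[, 2], sex = 0,
                     height = 160, bmi = 24, smoking = "never",
                     pack_years = 0, stringsAsFactors = FALSE)
    snp <- setNames(x[, 3], df$subject_id)
    spec_f <- model_spec(c("age", "snp"), smoking_coding = "none",
                         covariance = "independence")
    spec_r <- model_spec("age", smoking_coding = "none",
                         covariance = "independence")
    ff <- fit_ml(build_design(df, spec_f, snp = snp))
    fr <- fit_ml(build_design(df, spec_r))
    lrt(ff, fr, 1)$statistic
  }, 0)
  expect_gt(suppressWarnings(
    stats::ks.test(stats, pchisq, df = 1)$p.value), 0.01)
})

test_that("testing-step design matches the published term count", {
  # intercept + 15 covariate/SNP slots + 11 PC slots = 27 columns under
  # the two-level coding on longitudinal data
  sc <- sim_scenario(n_subjects = 40, n_snps = 30, seed = 23)
  geno <- simulate_genotypes(sc)
  fx <- list(geno = geno, pheno = simulate_cohort(sc, geno))
  snp <- setNames(as.numeric(fx$geno$dosages[, 1]), fx$geno$sample_ids)
  pcs <- grm_pca(fx$geno, 10)$scores
  bundle <- build_design(fx$pheno, spec_testing(snp = TRUE, pcs = TRUE),
                         snp = snp, pcs = pcs)
  expect_equal(ncol(bundle$X), 1 + 15 + 11)
  expect_true(all(c("snp", "snp:ever", "snp:pack_years", "pc10",
                    "pc1:ever", "time:ever") %in% colnames(bundle$X)))
  # never-smoker rows have zero SNP-by-pack-years by construction
  never_rows <- fx$pheno$smoking[fx$pheno$subject_id %in%
                                   bundle$subject_ids] == "never"
  expect_true(all(bundle$X[never_rows, "snp:pack_years"] == 0))
  # dummy coding contract
  expect_true(all(bundle$X[never_rows, "ever"] == 0))
  expect_true(all(bundle$X[!never_rows, "ever"] == 1))
})
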