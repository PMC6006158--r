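test_that("compute_maf folds to the minor allele and ignores missing", {
  expect_equal(compute_maf(c(0, 1, 2)), 0.5)
  expect_equal(compute_maf(c(0, 0, 0)), 0)
  expect_equal(compute_maf(c(2, 2, NA)), 0)        # folded from 1
  expect_equal(compute_maf(c(1, NA, NA)), 0.5)
  expect_error(compute_maf(c(NA, NA)), "screening error")
  set.seed(71)
  d <- rbinom(1e4, 2, 0.384)
  se <- sqrt(0.384 * (1 - 0.384) / (2 * 1e4))
  expect_lt(abs(compute_maf(d) - 0.384), 3 * se)
})

test_that("hwe_exact_test matches the enumeration oracle on sampled triples", {
  expect_equal(hwe_exact_test(25, 0, 0), 1)
  set.seed(73)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    cnt <- as.vector(rmultinom(1, n, c(0.3, 0.5, 0.2)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
  # all-heterozygote departure: boundary of significance at n = 7
  # (computed with the enumeration oracle)
  expect_lt(hwe_exact_test(0, 7, 0), 0.05)
  expect_gt(hwe_exact_test(0, 6, 0), 0.05)
  expect_lt(hwe_exact_test(0, 23, 0), 1e-5)
})

test_that("grm_pca equals a dense-oracle eigendecomposition and flags duplicates", {
  sc <- sim_scenario(n_subjects = 60, n_snps = 120, seed = 79)
  g <- simulate_genotypes(sc)
  # duplicate one sample
  d <- g$dosages
  d[2, ] <- d[1, ]
  g2 <- genotype_matrix(d)
  pca <- grm_pca(g2, n_pcs = 4)
  expect_equal(pca$scores[1, ], pca$scores[2, ], tolerance = 1e-8)
  # oracle route: svd of the standardized matrix
  f <- colMeans(d) / 2
  keep <- f > 0 & f < 1
  Z <- sweep(sweep(d[, keep], 2, 2 * f[keep]), 2,
             sqrt(2 * f[keep] * (1 - f[keep])), "/")
  sv <- svd(Z / sqrt(sum(keep)))
  expect_equal(pca$eigenvalues, sv$d[1:4]^2, tolerance = 1e-8)
  expect_equal(unname(abs(pca$scores)),
               abs(sv$u[, 1:4] %*% diag(sv$d[1:4])), tolerance = 1e-6)
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  # orthogonal score columns
  cp <- crossprod(pca$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_error(grm_pca(genotype_matrix(matrix(0L, 30, 2,
    dimnames = list(sprintf("s%d", 1:30), c("a", "b")))), 2),
    "PCA error")
})

test_that("structureless genotypes yield near-flat PCA spectra", {
  sc <- sim_scenario(n_subjects = 500, n_snps = 1000, seed = 83)
  pca <- grm_pca(simulate_genotypes(sc), n_pcs = 10)
  # Marchenko-Pastur scale: top-10 share stays below ~6% for n/M = 0.5
  expect_lt(sum(pca$variance_explained), 0.065)
})

test_that("significance_threshold reproduces the genome-wide Bonferroni level", {
  expect_equal(significance_threshold(0.05, 310515), 1.61e-7,
               tolerance = 5e-3)
  expect_equal(significance_threshold(0.05, 1), 0.05)
  expect_equal(significance_threshold(0.05, 20), 0.0025)
  n <- c(1, 10, 100, 1e5)
  expect_true(all(diff(significance_threshold(0.05, n)) < 0))
})

test_that("three_df_test decomposes exactly and matches lmmcore primitives", {
  fx <- tiny_cohort(n = 90, seed = 89)
  snp <- setNames(as.numeric(fx$geno$dosages[, 1]), fx$geno$sample_ids)
  td <- three_df_test(snp, fx$pheno)
  expect_identical(td$test$statistic,
                   td$lrt_ever$statistic + td$lrt_never$statistic)
  expect_equal(td$lrt_ever$statistic,
               lrt(td$fits$fit_ever, td$fits$fit_ever_reduced, 2)$statistic)
  expect_equal(td$test$p,
               pchisq(td$test$statistic, 3, lower.tail = FALSE))
  expect_gte(td$test$statistic, 0)
  # empty stratum is a test error pointing at the pooled test
  smokers <- fx$pheno[fx$pheno$smoking != "never", ]
  expect_error(three_df_test(snp, smokers), "pooled")
})

test_that("pooled tests expose coefficients, Wald and overall F results", {
  fx <- tiny_cohort(n = 120, seed = 97, max_visits = 2)
  snp <- setNames(as.numeric(fx$geno$dosages[, 3]), fx$geno$sample_ids)
  pt <- pooled_heteroscedastic_test(snp, fx$pheno)
  expect_named(pt$coef_tests, c("snp", "snp:ever", "snp:pack_years"))
  ct <- pt$coef_tests[["snp"]]
  expect_equal(ct$p, 2 * pnorm(-abs(ct$estimate / ct$se)))
  expect_equal(pt$overall$kind, "F")
  expect_true(pt$overall$p >= 0 && pt$overall$p <= 1)
  # three-level coding yields two interaction dummies
  pt3 <- pooled_heteroscedastic_test(snp, fx$pheno, coding = "three_level")
  expect_named(pt3$coef_tests,
               c("snp", "snp:former", "snp:current", "snp:pack_years"))
  ht <- homoscedastic_test(snp, fx$pheno)
  expect_equal(ht$test$df, 3)
  expect_equal(ht$test$p,
               pchisq(ht$test$statistic, 3, lower.tail = FALSE))
})

test_that("run_gwis accounting: screens, ranks, and carries top k", {
  sc <- sim_preset("kare_like", n_subjects = 150, n_snps = 10, seed = 101)
  g <- simulate_genotypes(sc)
  # make one SNP monomorphic
  g$dosages[, 4] <- 0L
  ph <- simulate_cohort(sc, g)
  scan <- suppressMessages(
    run_gwis(g, ph, run_config(n_pcs = 2, filter_top_k = 3)))
  expect_equal(nrow(scan$filtering), 9)           # polymorphic SNPs only
  expect_false("snp00004" %in% scan$filtering$snp_id)
  expect_equal(nrow(scan$testing), 3)
  expect_equal(scan$testing$p_3df, sort(scan$testing$p_3df))
  expect_equal(scan$threshold, 0.05 / 9)
  expect_true(all(c("maf", "hwe_p", "stat_3df", "p_3df", "p_homo",
                    "converged") %in% colnames(scan$filtering)))
})

test_that("missing dosages trigger SNP-wise complete-case analysis", {
  fx <- tiny_cohort(n = 70, seed = 151)
  ids <- fx$geno$sample_ids
  snp <- setNames(as.numeric(fx$geno$dosages[, 1]), ids)
  snp[c(3, 10, 25)] <- NA
  td_na <- three_df_test(snp, fx$pheno)
  # equals the analysis that drops those subjects explicitly
  keep <- names(snp)[!is.na(snp)]
  td_sub <- three_df_test(snp[keep],
                          fx$pheno[fx$pheno$subject_id %in% keep, ])
  expect_equal(td_na$test$statistic, td_sub$test$statistic,
               tolerance = 1e-6)
  expect_equal(td_na$fits$fit_ever$n_subjects,
               td_sub$fits$fit_ever$n_subjects)
})

test_that("homoscedastic and 3-DF tests agree in the homoscedastic limit", {
  # identical variances and covariate effects across strata
  S <- 0.3 * sqrt(outer(c(0.05, 0.055, 0.06), c(0.05, 0.055, 0.06)))
  diag(S) <- c(0.05, 0.055, 0.06)
  ce <- default_covariate_effects()
  ce[c("smoking", "age_smoking", "sex_smoking", "height_smoking",
       "time_smoking")] <- 0
  sc <- sim_scenario(n_subjects = 350, n_snps = 150, seed = 157,
                     covariate_effects = ce,
                     sigma2_never = 0.04, sigma2_ever = 0.04,
                     Sigma_never = S, Sigma_ever = S)
  g <- simulate_genotypes(sc)
  ph <- simulate_cohort(sc, g)
  scan <- suppressMessages(
    run_gwis(g, ph, run_config(n_pcs = 0, filter_top_k = 1)))
  f <- scan$filtering[scan$filtering$converged, ]
  x <- sort(-log10(f$p_3df))
  y <- sort(-log10(f$p_homo))
  slope <- sum(x * y) / sum(x * x)   # QQ regression through the origin
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})
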