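#' Minor-allele frequency of a dosage vector
#'
#' Allele frequency of the counted allele among non-missing dosages,
#' folded to `min(f, 1 - f)` so the result is always the minor-allele
#' frequency.
#'
#' @param dosages vector of 0/1/2 dosages, `NA` = missing.
#' @return Frequency in \[0, 0.5\].
#' @export
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("screening error: all dosages missing")
  f <- mean(d) / 2
  min(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the allele counts, the probability of
#' every heterozygote count at least as improbable as the observed one is
#' summed.  Chosen over the chi-square test for robustness at small
#' genotype counts.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, sum >= 1).
#' @return Exact p-value; 1 for monomorphic input (single attainable
#'   configuration).
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || n_AA + n_Aa + n_aa < 1)
    stop("genotype counts must be non-negative and sum to >= 1")
  n <- n_AA + n_Aa + n_aa
  rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het | allele counts) up to a constant:
  # multinomial genotype probability with 2^het phase factor
  lp <- -lgamma((rare - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (rare + hets) / 2 + 1) + hets * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

#' Principal components of the genetic relationship matrix
#'
#' Standardizes each SNP column to mean zero and variance `2 f (1 - f)`
#' (missing dosages mean-imputed, monomorphic SNPs dropped), forms the GRM
#' `Z Z' / M`, and eigendecomposes it.  Scores are eigenvectors scaled by
#' the square root of their eigenvalues; the leading scores serve as
#' ancestry covariates in the association models.
#'
#' @param genotypes a [genotype_matrix()].
#' @param n_pcs number of components to return.
#' @return List of class `"hetgwis_pca"`: `scores` (samples x n_pcs,
#'   rownames = sample ids), `eigenvalues`, `variance_explained`
#'   (eigenvalue fractions of the GRM trace), `grm`.
#' @export
grm_pca <- function(genotypes, n_pcs = 10) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  d <- genotypes$dosages
  n <- nrow(d)
  if (n < n_pcs + 1)
    stop("PCA error: need at least n_pcs + 1 samples")
  storage.mode(d) <- "double"
  f <- colMeans(d, na.rm = TRUE) / 2
  poly <- is.finite(f) & f > 0 & f < 1
  if (!any(poly)) stop("PCA error: no polymorphic SNPs")
  d <- d[, poly, drop = FALSE]
  f <- f[poly]
  Z <- sweep(d, 2, 2 * f)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * f * (1 - f)), "/")
  M <- ncol(Z)
  grm <- tcrossprod(Z) / M
  e <- eigen(grm, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  if (n_pcs > 0 && ev[n_pcs] <= 1e-12 * max(ev))
    stop("PCA error: GRM rank below n_pcs (too few polymorphic SNPs)")
  scores <- e$vectors[, seq_len(n_pcs), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(n_pcs)]), n_pcs)
  dimnames(scores) <- list(genotypes$sample_ids,
                           paste0("pc", seq_len(n_pcs)))
  structure(list(scores = scores, eigenvalues = ev[seq_len(n_pcs)],
                 variance_explained = ev[seq_len(n_pcs)] /
                   sum(diag(grm)),
                 grm = grm),
            class = "hetgwis_pca")
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
significance_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

## ---- scan engine ------------------------------------------------------
## Reduced (SNP-free) models are shared by every SNP, so they are fitted
## once; each SNP then only needs warm-started full-model fits.

.scan_prepare <- function(records, pcs = NULL, covariance = "unstructured",
                          coding = "two_level", with_homo = TRUE) {
  use_pcs <- !is.null(pcs)
  records <- records[order(records$subject_id, records$visit), ,
                     drop = FALSE]
  rec_never <- records[records$smoking == "never", , drop = FALSE]
  rec_ever <- records[records$smoking != "never", , drop = FALSE]
  if (nrow(rec_never) == 0 || nrow(rec_ever) == 0)
    stop("test error: empty smoking stratum; use the pooled ",
         "heteroscedastic test instead of the stratified 3-DF test")
  eng <- list(rec_all = records, rec_never = rec_never,
              rec_ever = rec_ever, pcs = pcs,
              covariance = covariance, coding = coding, use_pcs = use_pcs)
  eng$b_ever <- build_design(rec_ever,
                             spec_filter_ever(snp = FALSE, pcs = use_pcs,
                                              covariance), pcs = pcs)
  eng$b_never <- build_design(rec_never,
                              spec_filter_never(snp = FALSE, pcs = use_pcs,
                                                covariance), pcs = pcs)
  eng$f_ever <- fit_ml(eng$b_ever)
  eng$f_never <- fit_ml(eng$b_never)
  if (with_homo) {
    eng$b_homo <- build_design(records,
                               spec_homoscedastic(snp = FALSE, pcs = use_pcs,
                                                  coding, covariance),
                               pcs = pcs)
    eng$f_homo <- fit_ml(eng$b_homo)
  }
  eng
}

# append SNP columns to a cached SNP-free bundle (fast path: no missing
# dosages, so the block structure is unchanged)
.with_snp_cols <- function(bundle, records, snp, cols) {
  v <- unname(snp[records$subject_id])
  add <- lapply(cols, function(cn) switch(cn,
    snp = v,
    "snp:pack_years" = v * records$pack_years,
    "snp:ever" = v * (records$smoking != "never"),
    "snp:former" = v * (records$smoking == "former"),
    "snp:current" = v * (records$smoking == "current")))
  X <- cbind(bundle$X, do.call(cbind, add))
  colnames(X) <- c(colnames(bundle$X), cols)
  out <- bundle
  out$X <- X
  out
}

.snp_cols_for_coding <- function(coding) {
  c("snp",
    switch(coding, two_level = "snp:ever",
           three_level = c("snp:former", "snp:current"),
           smokers_only = "snp:current"),
    "snp:pack_years")
}

# one SNP through the filtering-step machinery; returns component fits
.scan_one <- function(eng, snp) {
  if (anyNA(snp)) {                      # complete-case fallback per SNP
    ids <- names(snp)[!is.na(snp)]
    sub_eng <- .scan_prepare(
      rbind(eng$rec_never[eng$rec_never$subject_id %in% ids, ],
            eng$rec_ever[eng$rec_ever$subject_id %in% ids, ]),
      pcs = eng$pcs, covariance = eng$covariance, coding = eng$coding,
      with_homo = !is.null(eng$f_homo))
    return(.scan_one(sub_eng, snp[!is.na(snp)]))
  }
  be <- .with_snp_cols(eng$b_ever, eng$rec_ever, snp,
                       c("snp", "snp:pack_years"))
  bn <- .with_snp_cols(eng$b_never, eng$rec_never, snp, "snp")
  fe <- fit_ml(be, init = eng$f_ever)
  fn <- fit_ml(bn, init = eng$f_never)
  out <- list(fit_ever = fe, fit_never = fn,
              fit_ever_reduced = eng$f_ever,
              fit_never_reduced = eng$f_never)
  if (!is.null(eng$f_homo)) {
    bh <- .with_snp_cols(eng$b_homo, eng$rec_all, snp,
                         .snp_cols_for_coding(eng$coding))
    out$fit_homo <- fit_ml(bh, init = eng$f_homo)
    out$fit_homo_reduced <- eng$f_homo
  }
  out
}

#' Stratified 3-degree-of-freedom interaction filtering test
#'
#' The filtering-step statistic of the scan: ever smokers are fitted with
#' and without the SNP main effect and SNP-by-pack-years interaction
#' (2-DF likelihood-ratio test), never smokers with and without the SNP
#' main effect (1-DF), each stratum with its own covariance parameters, so
#' heteroscedasticity by smoking status holds by construction.  The two
#' statistics are summed and referred to chi-square with 3 degrees of
#' freedom.
#'
#' @param snp named per-subject dosage vector.
#' @param records validated phenotype data.frame covering both strata.
#' @param pcs optional PC score matrix (rownames = subject ids) appended
#'   as covariates in both strata.
#' @param covariance covariance structure for both strata (default
#'   unstructured, the structure selected for longitudinal FEV1).
#' @return List of class `"hetgwis_3df"`: `test` (the 3-DF result),
#'   `lrt_ever` (2 DF), `lrt_never` (1 DF), and the four stratum fits.
#' @export
three_df_test <- function(snp, records, pcs = NULL,
                          covariance = "unstructured") {
  eng <- .scan_prepare(records, pcs = pcs, covariance = covariance,
                       with_homo = FALSE)
  fits <- .scan_one(eng, snp)
  le <- lrt(fits$fit_ever, fits$fit_ever_reduced, df = 2)
  ln <- lrt(fits$fit_never, fits$fit_never_reduced, df = 1)
  stat <- le$statistic + ln$statistic
  structure(list(test = .test_result(stat, 3,
                                     pchisq(stat, 3, lower.tail = FALSE),
                                     "LRT"),
                 lrt_ever = le, lrt_never = ln,
                 fits = fits[c("fit_ever", "fit_ever_reduced",
                               "fit_never", "fit_never_reduced")]),
            class = "hetgwis_3df")
}

#' Pooled homoscedastic comparator test
#'
#' Fits the pooled mixed model that assumes a common residual covariance
#' and common covariate coefficients across smoking strata, and tests the
#' SNP main effect, SNP-by-smoking-status and SNP-by-pack-years terms
#' jointly by a 3-DF likelihood-ratio test.  Used to demonstrate the
#' inflation incurred by ignoring smoking-status heteroscedasticity.
#'
#' @inheritParams three_df_test
#' @param coding smoking coding of the pooled model (default `two_level`,
#'   which keeps the comparison at 3 DF).
#' @return List: `test` (3-DF LRT), `fit`, `fit_reduced`.
#' @export
homoscedastic_test <- function(snp, records, pcs = NULL,
                               coding = "two_level",
                               covariance = "unstructured") {
  eng <- .scan_prepare(records, pcs = pcs, covariance = covariance,
                       coding = coding, with_homo = TRUE)
  fits <- .scan_one(eng, snp)
  df <- length(.snp_cols_for_coding(coding))
  tst <- lrt(fits$fit_homo, fits$fit_homo_reduced, df = df)
  list(test = tst, fit = fits$fit_homo, fit_reduced = fits$fit_homo_reduced)
}

#' Pooled heteroscedastic testing-step model
#'
#' Fits the pooled mixed model with smoking-group-specific covariance and
#' covariate-by-smoking interactions, plus SNP main, SNP-by-status and
#' SNP-by-pack-years terms.  Reports a two-sided Wald test per SNP
#' coefficient and the joint F test of all SNP terms ("overall effects").
#'
#' @inheritParams three_df_test
#' @param coding smoking coding (`smokers_only` for cohorts without never
#'   smokers, where former smokers are the reference level).
#' @param init optional warm start (a fit of the same model without SNP
#'   terms).
#' @return List of class `"hetgwis_pooled"`: `fit`, `coef_tests` (named
#'   list with `estimate`, `se`, `p` per SNP term), `overall`.
#' @export
pooled_heteroscedastic_test <- function(snp, records, pcs = NULL,
                                        coding = "two_level",
                                        covariance = "unstructured",
                                        init = NULL) {
  use_pcs <- !is.null(pcs)
  spec <- spec_testing(snp = TRUE, pcs = use_pcs, coding = coding,
                       covariance = covariance)
  bundle <- build_design(records, spec, snp = snp, pcs = pcs)
  fit <- fit_ml(bundle, init = init)
  snp_terms <- intersect(.snp_cols_for_coding(coding),
                         names(fit$beta_hat))
  coef_tests <- lapply(snp_terms, function(tm) {
    b <- fit$beta_hat[[tm]]
    se <- sqrt(fit$vcov_beta[tm, tm])
    z <- b / se
    .test_result(z^2, 1, 2 * pnorm(-abs(z)), "Wald",
                 extra = list(estimate = b, se = se, z = z))
  })
  names(coef_tests) <- snp_terms
  structure(list(fit = fit, coef_tests = coef_tests,
                 overall = wald_joint(fit, snp_terms)),
            class = "hetgwis_pooled")
}

#' Run the two-phase genome-wide interaction scan
#'
#' Screens SNPs (minor-allele frequency and exact Hardy-Weinberg p-value;
#' monomorphic SNPs are excluded, HWE is reported but not filtered on),
#' computes GRM principal components once, applies the stratified 3-DF
#' filtering test and the homoscedastic comparator to every SNP, ranks by
#' the 3-DF p-value (ties broken by larger statistic, then SNP id), and
#' carries the top `filter_top_k` SNPs into the pooled heteroscedastic
#' testing step.
#'
#' @param genotypes a [genotype_matrix()].
#' @param records validated phenotype data.frame; subjects must appear in
#'   `genotypes`.
#' @param config a [run_config()].
#' @return List of class `"hetgwis_scan"`: `filtering` (one row per
#'   screened SNP: maf, hwe_p, stat_3df, p_3df, p_homo, converged),
#'   `testing` (coefficient table for the top SNPs), `testing_details`,
#'   `threshold` (Bonferroni at `config$alpha`), `pcs`, `n_tested`.
#' @export
run_gwis <- function(genotypes, records, config = run_config()) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  records <- validate_phenotypes(records, max_visits = config$max_visits)
  subjects <- unique(records$subject_id)
  missing_geno <- setdiff(subjects, genotypes$sample_ids)
  if (length(missing_geno))
    stop("validation error: subjects without genotypes: ",
         paste(utils::head(missing_geno, 5), collapse = ", "))
  d <- genotypes$dosages[subjects, , drop = FALSE]

  maf <- apply(d, 2, compute_maf)
  hwe <- apply(d, 2, function(x) {
    x <- x[!is.na(x)]
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  })
  keep <- maf > 0 & maf >= config$maf_min
  snp_ids <- genotypes$snp_ids[keep]

  pcs <- NULL
  if (config$n_pcs > 0) {
    sub_g <- genotype_matrix(d)
    pcs <- grm_pca(sub_g, config$n_pcs)$scores
  }

  eng <- .scan_prepare(records, pcs = pcs,
                       covariance = config$covariance,
                       coding = config$smoking_coding, with_homo = TRUE)
  M <- length(snp_ids)
  res <- vector("list", M)
  for (i in seq_len(M)) {
    sid <- snp_ids[i]
    snp <- setNames(as.numeric(d[, sid]), subjects)
    row <- tryCatch({
      fits <- .scan_one(eng, snp)
      le <- lrt(fits$fit_ever, fits$fit_ever_reduced, 2)
      ln <- lrt(fits$fit_never, fits$fit_never_reduced, 1)
      lh <- lrt(fits$fit_homo, fits$fit_homo_reduced,
                length(.snp_cols_for_coding(eng$coding)))
      conv <- fits$fit_ever$converged && fits$fit_never$converged &&
        fits$fit_homo$converged
      stat <- le$statistic + ln$statistic
      data.frame(snp_id = sid, maf = maf[[sid]], hwe_p = hwe[[sid]],
                 stat_3df = stat,
                 p_3df = pchisq(stat, 3, lower.tail = FALSE),
                 p_homo = lh$p, converged = conv,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(snp_id = sid, maf = maf[[sid]], hwe_p = hwe[[sid]],
                 stat_3df = NA_real_, p_3df = NA_real_, p_homo = NA_real_,
                 converged = FALSE, stringsAsFactors = FALSE))
    res[[i]] <- row
    if (i %% 100 == 0) message("run_gwis: scanned ", i, "/", M, " SNPs")
  }
  filtering <- do.call(rbind, res)
  rownames(filtering) <- NULL

  ok <- filtering$converged & !is.na(filtering$p_3df)
  ord <- order(!ok, filtering$p_3df, -filtering$stat_3df,
               filtering$snp_id)
  top <- filtering$snp_id[ord][seq_len(min(config$filter_top_k,
                                           sum(ok)))]

  red_spec <- spec_testing(snp = FALSE, pcs = !is.null(pcs),
                           coding = config$smoking_coding,
                           covariance = config$covariance)
  red_fit <- fit_ml(build_design(records, red_spec, pcs = pcs))
  details <- lapply(top, function(sid) {
    snp <- setNames(as.numeric(d[, sid]), subjects)
    pooled_heteroscedastic_test(snp, records, pcs = pcs,
                                coding = config$smoking_coding,
                                covariance = config$covariance,
                                init = red_fit)
  })
  names(details) <- top
  testing <- do.call(rbind, lapply(top, function(sid) {
    dt <- details[[sid]]
    est <- vapply(dt$coef_tests, `[[`, 0, "estimate")
    pv <- vapply(dt$coef_tests, `[[`, 0, "p")
    out <- data.frame(snp_id = sid,
                      p_3df = filtering$p_3df[filtering$snp_id == sid],
                      overall_p = dt$overall$p, stringsAsFactors = FALSE)
    for (tm in names(est)) {
      out[[paste0("beta_", tm)]] <- est[[tm]]
      out[[paste0("p_", tm)]] <- pv[[tm]]
    }
    out
  }))

  structure(list(filtering = filtering, testing = testing,
                 testing_details = details,
                 threshold = significance_threshold(config$alpha, M),
                 pcs = pcs, n_tested = M, config = config),
            class = "hetgwis_scan")
}

#' @export
print.hetgwis_scan <- function(x, ...) {
  cat("Genome-wide interaction scan:", x$n_tested, "SNPs tested\n")
  cat("  Bonferroni threshold:", format(x$threshold, digits = 3), "\n")
  cat("  top SNPs (testing step):\n")
  print(x$testing, digits = 3)
  invisible(x)
}
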