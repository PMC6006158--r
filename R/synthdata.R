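#' Define a simulation scenario
#'
#' A scenario states the generative world for a synthetic cohort: genotypes
#' in Hardy-Weinberg proportions, longitudinal covariates, smoking strata
#' with their own random-intercept variance and residual covariance, and
#' optional SNP main/interaction effects.  The response is generated as
#'
#' \deqn{y_{gij} = x_{ij}'\beta + b_{gi} + \varepsilon_{gij},\quad
#'   b_{gi} \sim N(0, \sigma_g^2),\quad
#'   \varepsilon_{gi\cdot} \sim MVN(0, \Sigma_g[v_i, v_i])}
#'
#' with \eqn{g} indexing never vs ever smokers and \eqn{v_i} the observed
#' visit pattern.  The fixed-effect mean mirrors the pooled
#' covariate-by-smoking model used by the testing step (age, sex, BMI,
#' height, time, pack-years, sex-by-age, and smoking-status interactions
#' with age/sex/height/time); a causal SNP adds
#' `beta_snp * SNP + beta_snp_smoking * SNP * ever +
#' beta_snp_packyears * SNP * pack_years`.
#' Setting all three SNP effects to 0 makes every SNP null for the joint
#' 3-DF interaction test.
#'
#' @param n_subjects,n_snps cohort and panel size.
#' @param maf_range interval in (0, 0.5] from which per-SNP minor-allele
#'   frequencies are drawn uniformly.
#' @param smoking_proportions probabilities over never/former/current
#'   (must sum to 1; never may be 0, as in heavy-smoker cohorts).
#' @param max_visits 1 = cross-sectional; 3 = triennial-style longitudinal.
#' @param visit_spacing_years years between scheduled visits.
#' @param beta_snp,beta_snp_smoking,beta_snp_packyears causal SNP effects
#'   (liters per minor allele; interaction per allele for ever smokers /
#'   per allele per pack-year).
#' @param covariate_effects named list of fixed-effect coefficients; see
#'   [default_covariate_effects()].
#' @param sigma2_never,sigma2_ever random-intercept variances (liters^2).
#' @param Sigma_never,Sigma_ever residual covariance matrices
#'   (`max_visits x max_visits`, symmetric positive definite).
#' @param dropout_prob probability that each post-baseline visit is missing
#'   (independently; missing-completely-at-random).
#' @param packyears_update `"update"`: current smokers accumulate pack-years
#'   over follow-up; `"baseline"`: carried forward from baseline.
#' @param seed integer seed or `NULL` to use the current RNG stream.
#' @return An object of class `"SimScenario"` (a validated list).
#' @export
sim_scenario <- function(n_subjects = 1000, n_snps = 100,
                         maf_range = c(0.05, 0.5),
                         smoking_proportions = c(never = 0.577,
                                                 former = 0.204,
                                                 current = 0.219),
                         max_visits = 3, visit_spacing_years = 2,
                         beta_snp = 0, beta_snp_smoking = 0,
                         beta_snp_packyears = 0,
                         covariate_effects = default_covariate_effects(),
                         sigma2_never = 0.04, sigma2_ever = 0.16,
                         Sigma_never = NULL, Sigma_ever = NULL,
                         dropout_prob = 0.1,
                         packyears_update = c("update", "baseline"),
                         seed = NULL) {
  packyears_update <- match.arg(packyears_update)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("scenario error: maf_range must lie within (0, 0.5]")
  smoking_proportions <- setNames(as.numeric(smoking_proportions),
                                  .smoking_levels)
  if (abs(sum(smoking_proportions) - 1) > 1e-8)
    stop("scenario error: smoking_proportions must sum to 1")
  if (any(smoking_proportions < 0))
    stop("scenario error: negative smoking proportion")
  Sigma_never <- Sigma_never %||% .default_sigma(max_visits, scale = 1)
  Sigma_ever <- Sigma_ever %||% .default_sigma(max_visits, scale = 4)
  for (S in list(Sigma_never, Sigma_ever)) {
    if (!isTRUE(all.equal(S, t(S))) ||
        any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("scenario error: Sigma matrices must be symmetric positive definite")
    if (nrow(S) != max_visits)
      stop("scenario error: Sigma dimension must equal max_visits")
  }
  structure(list(
    n_subjects = n_subjects, n_snps = n_snps, maf_range = maf_range,
    smoking_proportions = smoking_proportions, max_visits = max_visits,
    visit_spacing_years = visit_spacing_years, beta_snp = beta_snp,
    beta_snp_smoking = beta_snp_smoking,
    beta_snp_packyears = beta_snp_packyears,
    covariate_effects = covariate_effects, sigma2_never = sigma2_never,
    sigma2_ever = sigma2_ever, Sigma_never = Sigma_never,
    Sigma_ever = Sigma_ever, dropout_prob = dropout_prob,
    packyears_update = packyears_update, seed = seed), class = "SimScenario")
}

# visit-to-visit residual covariance: mildly increasing variances,
# exchangeable correlation 0.3; `scale` multiplies the whole matrix
.default_sigma <- function(m, scale = 1) {
  v <- 0.05 + 0.005 * (seq_len(m) - 1)
  S <- 0.3 * sqrt(outer(v, v))
  diag(S) <- v
  scale * S
}

#' Default fixed-effect coefficients for the generator
#'
#' Liters-scale coefficients loosely calibrated to published descriptive
#' statistics of middle-aged cohorts (baseline FEV1 near 2.9 L): age
#' -0.025 L/yr, male +0.55 L, BMI -0.012 L per kg/m2, height +0.015 L/cm,
#' time -0.035 L/yr, pack-years -0.002 L/PY, plus small sex-by-age and
#' smoking-status interaction terms.  Fully overridable; tests depend only
#' on declared scenario parameters, never on these defaults.
#'
#' @return Named list of coefficients.
#' @export
default_covariate_effects <- function() {
  list(intercept = 2.0, age = -0.025, sex = 0.55, bmi = -0.012,
       height = 0.015, time = -0.035, pack_years = -0.002,
       sex_age = -0.003, smoking = -0.08, age_smoking = -0.003,
       sex_smoking = 0.03, height_smoking = 0.0005, time_smoking = -0.012)
}

#' Study-design presets for simulation scenarios
#'
#' Presets mirror the printed designs of four lung-function cohorts:
#' `kare_like` (8,534 subjects, up to 3 visits ~2 years apart, never/former/
#' current = 4926/1742/1866), `genie_like` (5,971 subjects, repeated visits,
#' three strata), `mesa_like` (1,033 subjects, single visit, three strata)
#' and `copdgene_like` (6,670 subjects, single visit, former/current only —
#' no never smokers).  All presets are heteroscedastic by smoking status
#' (ever-smoker variances 4x never-smoker) and SNP-null unless overridden.
#'
#' @param name preset name.
#' @param ... overrides passed to [sim_scenario()] (e.g. `n_subjects`,
#'   `seed`, SNP effects).
#' @return A `SimScenario`.
#' @export
sim_preset <- function(name = c("kare_like", "genie_like", "mesa_like",
                                "copdgene_like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    kare_like = list(n_subjects = 8534,
                     smoking_proportions = c(4926, 1742, 1866) / 8534,
                     max_visits = 3),
    genie_like = list(n_subjects = 5971,
                      smoking_proportions = c(3396, 1804, 771) / 5971,
                      max_visits = 3),
    mesa_like = list(n_subjects = 1033,
                     smoking_proportions = c(459, 468, 106) / 1033,
                     max_visits = 1),
    copdgene_like = list(n_subjects = 6670,
                         smoking_proportions = c(0, 4054, 2616) / 6670,
                         max_visits = 1))
  args <- utils::modifyList(base, list(...))
  do.call(sim_scenario, args)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Per SNP, a minor-allele frequency is drawn uniformly from
#' `scenario$maf_range` and dosages are i.i.d. Binomial(2, MAF), so expected
#' genotype frequencies follow Hardy-Weinberg proportions.
#'
#' @param scenario a [sim_scenario()].
#' @return A [genotype_matrix()] with random allele labels; the drawn MAFs
#'   are attached as attribute `"maf"`.
#' @export
simulate_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "SimScenario"))
  if (scenario$n_subjects < 2) stop("scenario error: n_subjects must be >= 2")
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n_subjects; M <- scenario$n_snps
  sample_ids <- sprintf("S%05d", seq_len(n))
  snp_ids <- sprintf("snp%05d", seq_len(M))
  mafs <- runif(M, scenario$maf_range[1], scenario$maf_range[2])
  d <- matrix(rbinom(n * M, 2L, rep(mafs, each = n)), nrow = n,
              dimnames = list(sample_ids, snp_ids))
  pairs <- replicate(M, sample(c("A", "C", "G", "T"), 2))
  g <- genotype_matrix(d, minor = if (M) pairs[1, ] else NULL,
                       major = if (M) pairs[2, ] else NULL)
  attr(g, "maf") <- setNames(mafs, snp_ids)
  g
}

#' Simulate a longitudinal cohort
#'
#' Generates covariates and FEV1 (liters) for the subjects of `genotypes`
#' under `scenario` (see [sim_scenario()] for the generative model).
#' Covariates: baseline age ~ Uniform(40, 69); sex ~ Bernoulli(0.5);
#' height ~ N(160, 8.7^2) cm (constant within subject); BMI ~ N(24.6,
#' 3.1^2) plus small visit-level drift; visit times are
#' `(visit - 1) * visit_spacing_years`; pack-years are 0 for never smokers
#' and lognormal (median 15) for ever smokers, accumulating over follow-up
#' for current smokers when `packyears_update = "update"`.  Post-baseline
#' visits are dropped independently with probability `dropout_prob`, so
#' interior visit gaps (e.g. visits 1,3) occur by design.
#'
#' @param scenario a [sim_scenario()].
#' @param genotypes a [genotype_matrix()] covering the cohort subjects.
#' @param causal_snp SNP id receiving the scenario's SNP effects, or `NULL`
#'   for a fully null cohort.
#' @return Phenotype data.frame passing [validate_phenotypes()], with the
#'   per-subject generative group and true mean attached as attributes
#'   `"group"` and `"true_mean"`.
#' @export
simulate_cohort <- function(scenario, genotypes, causal_snp = NULL) {
  stopifnot(inherits(scenario, "SimScenario"),
            inherits(genotypes, "GenotypeMatrix"))
  if (!is.null(causal_snp) && !(causal_snp %in% genotypes$snp_ids))
    stop("key error: causal_snp '", causal_snp, "' not in genotypes")
  if (!is.null(scenario$seed)) set.seed(scenario$seed + 1L)
  ids <- genotypes$sample_ids
  n <- length(ids)
  ce <- scenario$covariate_effects
  mv <- scenario$max_visits

  smoking <- .smoking_levels[
    max.col(t(rmultinom(n, 1L, scenario$smoking_proportions)))]
  ever <- smoking != "never"
  age0 <- runif(n, 40, 69)
  sex <- rbinom(n, 1L, 0.5)
  height0 <- rnorm(n, 160, 8.7)
  bmi0 <- rnorm(n, 24.6, 3.1)
  py0 <- ifelse(ever, rlnorm(n, log(15), 0.7), 0)

  # observed visit pattern per subject: baseline always, later visits MCAR
  keep <- matrix(TRUE, n, mv)
  if (mv > 1)
    keep[, -1] <- matrix(runif(n * (mv - 1)) >= scenario$dropout_prob,
                         n, mv - 1)
  pats <- apply(keep, 1L, which, simplify = FALSE)

  snp <- if (!is.null(causal_snp))
    as.numeric(genotypes$dosages[, causal_snp]) else numeric(n)
  snp[is.na(snp)] <- 0

  bi <- rnorm(n, 0, sqrt(ifelse(ever, scenario$sigma2_ever,
                                scenario$sigma2_never)))
  Ln <- chol(scenario$Sigma_never)
  Le <- chol(scenario$Sigma_ever)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- pats[[i]]
    tt <- (v - 1) * scenario$visit_spacing_years
    bmi <- bmi0[i] + rnorm(length(v), 0, 0.3) * (v > 1)
    py <- if (smoking[i] == "current" && scenario$packyears_update == "update")
      py0[i] + 0.75 * tt else rep(py0[i], length(v))
    mu <- ce$intercept + ce$age * age0[i] + ce$sex * sex[i] +
      ce$bmi * bmi + ce$height * height0[i] + ce$time * tt +
      ce$pack_years * py + ce$sex_age * sex[i] * age0[i] +
      ever[i] * (ce$smoking + ce$age_smoking * age0[i] +
                 ce$sex_smoking * sex[i] + ce$height_smoking * height0[i] +
                 ce$time_smoking * tt)
    if (!is.null(causal_snp))
      mu <- mu + scenario$beta_snp * snp[i] +
        scenario$beta_snp_smoking * snp[i] * ever[i] +
        scenario$beta_snp_packyears * snp[i] * py
    eps <- drop(crossprod(if (ever[i]) Le else Ln, rnorm(mv)))[v]
    rows[[i]] <- data.frame(
      subject_id = ids[i], visit = v, time = tt, fev1 = mu + bi[i] + eps,
      age0 = age0[i], sex = sex[i], height = height0[i], bmi = bmi,
      smoking = smoking[i], pack_years = py, stringsAsFactors = FALSE)
    rows[[i]]$.mu <- mu
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df <- validate_phenotypes(df, max_visits = mv)  # also reorders rows
  true_mean <- df$.mu
  df$.mu <- NULL
  attr(df, "group") <- setNames(ifelse(ever, "ever", "never"), ids)
  attr(df, "true_mean") <- true_mean
  df
}
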