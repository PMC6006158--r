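#' Declare a linear mixed model for longitudinal FEV1
#'
#' A `ModelSpec` names the fixed-effect terms, the smoking coding that
#' expands the `smoking` term into dummies, and the per-group marginal
#' covariance structure.  Term vocabulary: `age`, `sex`, `bmi`, `height`,
#' `time`, `pack_years`, `sex:age`, `smoking`, `age:smoking`,
#' `sex:smoking`, `height:smoking`, `time:smoking`, `snp`, `snp:smoking`,
#' `snp:pack_years`, `pcs` (all principal-component scores supplied to
#' [build_design()]), `pc1:smoking`.
#'
#' Smoking codings and their dummy/reference conventions:
#' * `two_level`: one dummy `ever` (never smokers are the reference);
#' * `three_level`: dummies `former`, `current` (never reference);
#' * `smokers_only`: one dummy `current` (former reference; for cohorts
#'   without never smokers);
#' * `none`: no smoking fixed effects or grouping (single-stratum fits).
#'
#' Covariance structures (per group when `heteroscedastic`, shared
#' otherwise): `independence` (sigma^2 I), `random_intercept` (sigma^2 J
#' plus a per-visit diagonal), `unstructured` (a full positive-definite
#' visit-by-visit marginal covariance; a random intercept added to an
#' unstructured residual is not separately identified, so the single
#' marginal matrix is estimated directly).
#'
#' @param fixed_terms character vector from the vocabulary above.
#' @param smoking_coding one of `"two_level"`, `"three_level"`,
#'   `"smokers_only"`, `"none"`.
#' @param covariance covariance structure name.
#' @param heteroscedastic if `TRUE`, each smoking stratum of the coding has
#'   its own covariance parameters; if `FALSE`, one shared set.
#' @param response response column name.
#' @return An object of class `"ModelSpec"`.
#' @export
model_spec <- function(fixed_terms,
                       smoking_coding = c("two_level", "three_level",
                                          "smokers_only", "none"),
                       covariance = c("unstructured", "random_intercept",
                                      "independence"),
                       heteroscedastic = TRUE,
                       response = "fev1") {
  smoking_coding <- match.arg(smoking_coding)
  covariance <- match.arg(covariance)
  vocab <- c("age", "sex", "bmi", "height", "time", "pack_years", "sex:age",
             "smoking", "age:smoking", "sex:smoking", "height:smoking",
             "time:smoking", "snp", "snp:smoking", "snp:pack_years", "pcs",
             "pc1:smoking")
  bad <- setdiff(fixed_terms, vocab)
  if (length(bad))
    stop("design error: unknown fixed terms: ", paste(bad, collapse = ", "))
  if (smoking_coding == "none" &&
      any(grepl("smoking", fixed_terms)))
    stop("design error: smoking terms require a smoking coding")
  if (smoking_coding == "none") heteroscedastic <- FALSE
  structure(list(fixed_terms = fixed_terms, smoking_coding = smoking_coding,
                 covariance = covariance, heteroscedastic = heteroscedastic,
                 response = response),
            class = "ModelSpec")
}

.covariate_terms <- c("age", "sex", "bmi", "height", "time", "sex:age")

#' Canned model specifications for the scan and testing steps
#'
#' `spec_filter_ever()` / `spec_filter_never()` are the stratified
#' filtering-step models: covariates (age, sex, BMI, height, time,
#' sex-by-age, PCs; plus pack-years for ever smokers) with SNP main effect
#' and, for ever smokers, SNP-by-pack-years.  `spec_homoscedastic()` pools
#' the strata with shared covariance and common covariate coefficients.
#' `spec_testing()` is the pooled heteroscedastic testing-step model with
#' covariate-by-smoking interactions.  `spec_selection()` is the
#' testing-step model without any SNP terms, used for AIC model selection.
#'
#' @param snp include SNP terms (set `FALSE` for reduced/null models).
#' @param pcs include principal-component score terms.
#' @param coding smoking coding for pooled models.
#' @param covariance,heteroscedastic covariance structure options.
#' @return A [model_spec()].
#' @name canned_specs
NULL

#' @rdname canned_specs
#' @export
spec_filter_ever <- function(snp = TRUE, pcs = TRUE,
                             covariance = "unstructured") {
  terms <- c(.covariate_terms, "pack_years",
             if (snp) c("snp", "snp:pack_years"), if (pcs) "pcs")
  model_spec(terms, smoking_coding = "none", covariance = covariance)
}

#' @rdname canned_specs
#' @export
spec_filter_never <- function(snp = TRUE, pcs = TRUE,
                              covariance = "unstructured") {
  terms <- c(.covariate_terms, if (snp) "snp", if (pcs) "pcs")
  model_spec(terms, smoking_coding = "none", covariance = covariance)
}

#' @rdname canned_specs
#' @export
spec_homoscedastic <- function(snp = TRUE, pcs = TRUE,
                               coding = "two_level",
                               covariance = "unstructured") {
  terms <- c(.covariate_terms, "pack_years", "smoking", "sex:smoking",
             if (snp) c("snp", "snp:smoking", "snp:pack_years"),
             if (pcs) c("pcs", "pc1:smoking"))
  model_spec(terms, smoking_coding = coding, covariance = covariance,
             heteroscedastic = FALSE)
}

#' @rdname canned_specs
#' @export
spec_testing <- function(snp = TRUE, pcs = TRUE, coding = "two_level",
                         covariance = "unstructured",
                         heteroscedastic = TRUE) {
  terms <- c(.covariate_terms, "pack_years", "smoking", "age:smoking",
             "sex:smoking", "height:smoking", "time:smoking",
             if (snp) c("snp", "snp:smoking", "snp:pack_years"),
             if (pcs) c("pcs", "pc1:smoking"))
  model_spec(terms, smoking_coding = coding, covariance = covariance,
             heteroscedastic = heteroscedastic)
}

#' @rdname canned_specs
#' @export
spec_selection <- function(coding = "two_level", covariance = "unstructured",
                           heteroscedastic = TRUE, pcs = FALSE) {
  spec_testing(snp = FALSE, pcs = pcs, coding = coding,
               covariance = covariance, heteroscedastic = heteroscedastic)
}

# smoking dummies for a coding; returns matrix (n x k) with named columns
.smoking_dummies <- function(smoking, coding) {
  switch(coding,
    none = NULL,
    two_level = cbind(ever = as.numeric(smoking != "never")),
    three_level = cbind(former = as.numeric(smoking == "former"),
                        current = as.numeric(smoking == "current")),
    smokers_only = cbind(current = as.numeric(smoking == "current")))
}

# covariance grouping implied by a spec
.cov_groups <- function(smoking, spec) {
  if (!spec$heteroscedastic) return(factor(rep("all", length(smoking))))
  switch(spec$smoking_coding,
    two_level = factor(ifelse(smoking == "never", "never", "ever"),
                       levels = c("never", "ever")),
    three_level = factor(smoking, levels = .smoking_levels),
    smokers_only = factor(smoking, levels = c("former", "current")),
    none = factor(rep("all", length(smoking))))
}

#' Build the design bundle for a mixed-model fit
#'
#' Expands a [model_spec()] against validated phenotype records into the
#' stacked response/design matrices plus the block structure (covariance
#' group by visit pattern) that the likelihood machinery consumes.
#' Subject-level SNP dosages and PC scores are merged by subject id;
#' subjects with a missing SNP dosage are dropped (SNP-wise complete-case
#' analysis).  Identically-zero covariate columns (e.g. `time:smoking` in a
#' cross-sectional cohort) are dropped and recorded in `$dropped_terms`;
#' the `snp` column itself is never silently dropped, so a degenerate SNP
#' surfaces as a collinearity error in [fit_ml()].
#'
#' @param records phenotype data.frame (see [validate_phenotypes()]).
#' @param spec a [model_spec()].
#' @param snp named numeric vector of per-subject dosages (required iff the
#'   spec has SNP terms).
#' @param pcs matrix of PC scores with subject ids as rownames (required
#'   iff the spec has the `pcs` term).
#' @return A list of class `"hetgwis_design"` with elements `X`, `y`,
#'   `subject_ids`, `groups` (per-subject covariance group factor),
#'   `blocks`, `group_visits`, `max_visit`, `n_obs`, `spec`,
#'   `dropped_terms`.
#' @export
build_design <- function(records, spec, snp = NULL, pcs = NULL) {
  stopifnot(inherits(spec, "ModelSpec"))
  records <- records[order(records$subject_id, records$visit), , drop = FALSE]
  terms <- spec$fixed_terms
  need_snp <- any(grepl("^snp", terms))
  if (need_snp) {
    if (is.null(snp) || is.null(names(snp)))
      stop("design error: spec has SNP terms but no named `snp` vector given")
    keep_ids <- names(snp)[!is.na(snp)]
    records <- records[records$subject_id %in% keep_ids, , drop = FALSE]
    if (nrow(records) == 0)
      stop("design error: no subjects with observed SNP dosage")
  }
  if ("pcs" %in% terms && is.null(pcs))
    stop("design error: spec has `pcs` term but no PC score matrix given")

  sub <- factor(records$subject_id, levels = unique(records$subject_id))
  n <- nlevels(sub)
  first <- match(levels(sub), records$subject_id)
  smoking_sub <- records$smoking[first]

  # reference-stratum checks for pooled codings
  if (spec$smoking_coding %in% c("two_level", "three_level") &&
      !any(smoking_sub == "never"))
    stop("design error: empty reference stratum 'never' for coding ",
         spec$smoking_coding)
  if (spec$smoking_coding == "three_level")
    for (lv in .smoking_levels)
      if (!any(smoking_sub == lv))
        stop("design error: empty stratum '", lv,
             "' for three_level coding")
  if (spec$smoking_coding == "smokers_only") {
    if (any(smoking_sub == "never"))
      stop("design error: smokers_only coding on a cohort with never smokers")
    if (!any(smoking_sub == "former"))
      stop("design error: empty reference stratum 'former'")
  }

  dum <- .smoking_dummies(records$smoking, spec$smoking_coding)
  snp_row <- if (need_snp) unname(snp[records$subject_id]) else NULL
  pc_row <- if ("pcs" %in% terms || "pc1:smoking" %in% terms) {
    if (any(!levels(sub) %in% rownames(pcs)))
      stop("design error: PC scores missing for some subjects")
    pcs[records$subject_id, , drop = FALSE]
  } else NULL

  cols <- list("(Intercept)" = rep(1, nrow(records)))
  add <- function(nm, v) cols[[nm]] <<- v
  for (tm in terms) {
    switch(tm,
      age = add("age", records$age0),
      sex = add("sex", records$sex),
      bmi = add("bmi", records$bmi),
      height = add("height", records$height),
      time = add("time", records$time),
      pack_years = add("pack_years", records$pack_years),
      "sex:age" = add("sex:age", records$sex * records$age0),
      smoking = for (j in colnames(dum)) add(j, dum[, j]),
      "age:smoking" = for (j in colnames(dum))
        add(paste0("age:", j), records$age0 * dum[, j]),
      "sex:smoking" = for (j in colnames(dum))
        add(paste0("sex:", j), records$sex * dum[, j]),
      "height:smoking" = for (j in colnames(dum))
        add(paste0("height:", j), records$height * dum[, j]),
      "time:smoking" = for (j in colnames(dum))
        add(paste0("time:", j), records$time * dum[, j]),
      snp = add("snp", snp_row),
      "snp:smoking" = for (j in colnames(dum))
        add(paste0("snp:", j), snp_row * dum[, j]),
      "snp:pack_years" = add("snp:pack_years",
                             snp_row * records$pack_years),
      pcs = for (k in seq_len(ncol(pc_row)))
        add(paste0("pc", k), pc_row[, k]),
      "pc1:smoking" = for (j in colnames(dum))
        add(paste0("pc1:", j), pc_row[, 1] * dum[, j]))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  zero <- colnames(X) != "snp" & colSums(X != 0) == 0
  dropped <- colnames(X)[zero]
  if (any(zero)) X <- X[, !zero, drop = FALSE]

  groups <- .cov_groups(smoking_sub, spec)
  groups <- droplevels(groups)
  visits_by_sub <- split(records$visit, sub)
  group_visits <- lapply(levels(groups), function(g)
    sort(unique(unlist(visits_by_sub[groups == g], use.names = FALSE))))
  names(group_visits) <- levels(groups)

  pat_key <- paste(as.integer(groups),
                   vapply(visits_by_sub, paste, "", collapse = ","),
                   sep = "|")
  row_of_sub <- split(seq_len(nrow(records)), sub)
  blocks <- lapply(split(seq_len(n), pat_key), function(sids) {
    v <- visits_by_sub[[sids[1]]]
    list(group = as.integer(groups[sids[1]]), visits = v, m = length(v),
         ns = length(sids),
         idx = unlist(row_of_sub[sids], use.names = FALSE),
         subjects = levels(sub)[sids])
  })

  structure(list(X = X, y = records[[spec$response]],
                 subject_ids = levels(sub), groups = groups,
                 blocks = unname(blocks), group_visits = group_visits,
                 max_visit = max(records$visit), n_obs = nrow(records),
                 spec = spec, dropped_terms = dropped),
            class = "hetgwis_design")
}
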