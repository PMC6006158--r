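#' Candidate model grid for AIC selection
#'
#' Builds the SNP-free candidate models over smoking codings, covariance
#' structures, and shared vs per-group variance, excluding codings that
#' are incompatible with the cohort's observed strata (`two_level` /
#' `three_level` need never smokers; `smokers_only` requires their
#' absence and a former-smoker reference).  SNP terms are never part of
#' candidates, so model selection cannot bias downstream SNP inference.
#'
#' @param records validated phenotype data.frame.
#' @param codings,structures,groupings grids to span; `groupings` elements
#'   are `"shared"` or `"by_status"`.
#' @return List of class `"hetgwis_candidates"` of [model_spec()]s with a
#'   `label` attribute per candidate.
#' @export
candidate_models <- function(records,
                             codings = c("two_level", "three_level",
                                         "smokers_only"),
                             structures = c("independence",
                                            "random_intercept",
                                            "unstructured"),
                             groupings = c("shared", "by_status")) {
  smk <- unique(records$smoking)
  admissible <- character()
  if ("never" %in% smk && length(smk) > 1)
    admissible <- c(admissible, "two_level",
                    if (all(.smoking_levels %in% smk)) "three_level")
  if (!("never" %in% smk) && "former" %in% smk)
    admissible <- c(admissible, "smokers_only")
  codings <- intersect(codings, admissible)
  if (!length(codings))
    stop("selection error: no admissible smoking coding for this cohort")
  grid <- expand.grid(coding = codings, structure = structures,
                      grouping = groupings, stringsAsFactors = FALSE)
  cands <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- spec_selection(coding = grid$coding[i],
                         covariance = grid$structure[i],
                         heteroscedastic = grid$grouping[i] == "by_status")
    attr(sp, "label") <- paste(grid$coding[i], grid$structure[i],
                               grid$grouping[i], sep = "/")
    sp
  })
  structure(cands, class = "hetgwis_candidates")
}

#' Select the cohort model by AIC
#'
#' Fits every candidate (all SNP-free; a candidate containing SNP terms is
#' a contract violation) and returns the minimum-AIC specification among
#' converged fits.  Ties are broken by fewer parameters, then candidate
#' order.
#'
#' @param records validated phenotype data.frame.
#' @param candidates a [candidate_models()] list.
#' @param pcs optional PC score matrix passed to each candidate.
#' @return List of class `"hetgwis_selection"`: `spec` (selected),
#'   `fit`, `aic_table` (label, aic, k, converged, selected).
#' @export
select_model <- function(records, candidates = candidate_models(records),
                         pcs = NULL) {
  for (sp in candidates)
    if (any(grepl("^snp", sp$fixed_terms)))
      stop("contract error: candidate models must not contain SNP terms")
  fits <- lapply(candidates, function(sp)
    tryCatch(fit_ml(build_design(records, sp, pcs = pcs)),
             error = function(e) NULL))
  aic <- vapply(fits, function(f)
    if (is.null(f) || !f$converged) NA_real_ else f$aic, 0)
  k <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$k, 0)
  if (all(is.na(aic)))
    stop("selection error: no candidate model converged")
  ord <- order(aic, k, seq_along(aic), na.last = TRUE)
  best <- ord[1]
  tab <- data.frame(
    label = vapply(candidates, function(sp) attr(sp, "label") %||% "", ""),
    aic = aic, k = k,
    converged = !is.na(aic),
    selected = seq_along(aic) == best,
    stringsAsFactors = FALSE)
  structure(list(spec = candidates[[best]], fit = fits[[best]],
                 aic_table = tab),
            class = "hetgwis_selection")
}

#' @export
print.hetgwis_selection <- function(x, ...) {
  cat("AIC model selection (SNP-free candidates):\n")
  print(x$aic_table, digits = 6)
  invisible(x)
}

#' One-tailed Wald test in a stated direction
#'
#' Directional replication test: with `z = beta / se`, the p-value is the
#' probability, under the null, of an estimate at least as extreme in the
#' expected direction.  It equals half the two-tailed Wald p-value when
#' the estimate matches the expected sign and one minus that half
#' otherwise; an estimate of exactly zero gives p = 0.5.
#'
#' @param fit a [fit_ml()] result.
#' @param term coefficient name.
#' @param expected_sign `"+"` or `"-"`, taken from the discovery cohort.
#' @return Test result with `kind = "one_tailed_Wald"` and the estimate,
#'   standard error and direction attached.
#' @export
one_tailed_p <- function(fit, term, expected_sign = c("-", "+")) {
  expected_sign <- match.arg(expected_sign)
  if (!term %in% names(fit$beta_hat))
    stop("unknown coefficient: ", term)
  b <- fit$beta_hat[[term]]
  se <- sqrt(fit$vcov_beta[term, term])
  if (!is.finite(se) || se <= 0)
    stop("numeric error: zero standard error for ", term)
  z <- b / se
  p <- if (expected_sign == "-") pnorm(z) else pnorm(-z)
  .test_result(z^2, 1, p, "one_tailed_Wald",
               extra = list(estimate = b, se = se, z = z,
                            tail = expected_sign))
}

#' Replicate discovery SNPs in an independent cohort
#'
#' For each SNP, fits the cohort's AIC-selected model augmented with SNP
#' main, SNP-by-status and SNP-by-pack-years terms, and tests each term
#' one-tailed in the discovery direction (two-tailed where no direction
#' transfers: all terms of `smokers_only` cohorts, whose
#' former-vs-current contrast has no never-smoker-referenced discovery
#' analogue, and any term without a supplied direction).  The overall
#' effect is the joint F test of all SNP terms.
#'
#' @param genotypes cohort [genotype_matrix()].
#' @param records cohort phenotype data.frame.
#' @param snp_ids SNPs carried from discovery.
#' @param directions named character vector of expected signs (`"+"`/`"-"`)
#'   for terms `snp`, `snp:smoking`, `snp:pack_years` (the status
#'   direction is applied to every status dummy).
#' @param selection optional [select_model()] result (computed from
#'   `records` when omitted).
#' @param pcs optional PC score matrix.
#' @return data.frame of class `"hetgwis_replication"`: one row per SNP
#'   with estimates, per-term p-values (tagged one-/two-tailed), and the
#'   overall p; SNPs absent from the cohort genotypes yield an `NA` row.
#' @export
replicate_snps <- function(genotypes, records, snp_ids, directions = NULL,
                           selection = NULL, pcs = NULL) {
  records <- validate_phenotypes(records)
  selection <- selection %||% select_model(records, pcs = pcs)
  spec0 <- selection$spec
  coding <- spec0$smoking_coding
  two_tailed_all <- coding == "smokers_only"
  spec <- model_spec(c(spec0$fixed_terms, "snp", "snp:smoking",
                       "snp:pack_years"),
                     smoking_coding = coding,
                     covariance = spec0$covariance,
                     heteroscedastic = spec0$heteroscedastic)
  subjects <- unique(records$subject_id)
  rows <- lapply(snp_ids, function(sid) {
    if (!sid %in% genotypes$snp_ids)
      return(data.frame(snp_id = sid, present = FALSE, maf = NA_real_,
                        overall_p = NA_real_, stringsAsFactors = FALSE))
    snp <- setNames(as.numeric(genotypes$dosages[subjects, sid]), subjects)
    bundle <- build_design(records, spec, snp = snp, pcs = pcs)
    fit <- fit_ml(bundle, init = selection$fit)
    snp_terms <- intersect(.snp_cols_for_coding(coding),
                           names(fit$beta_hat))
    out <- data.frame(snp_id = sid, present = TRUE,
                      maf = compute_maf(snp),
                      overall_p = wald_joint(fit, snp_terms)$p,
                      stringsAsFactors = FALSE)
    for (tm in snp_terms) {
      dir_key <- if (tm == "snp") "snp" else
        if (tm == "snp:pack_years") "snp:pack_years" else "snp:smoking"
      dir <- if (!two_tailed_all && dir_key %in% names(directions))
        directions[[dir_key]] else NULL
      b <- fit$beta_hat[[tm]]
      se <- sqrt(fit$vcov_beta[tm, tm])
      if (is.null(dir)) {
        p <- 2 * pnorm(-abs(b / se))
        tail <- "two_tailed"
      } else {
        p <- one_tailed_p(fit, tm, dir)$p
        tail <- paste0("one_tailed_", dir)
      }
      out[[paste0("beta_", tm)]] <- b
      out[[paste0("p_", tm)]] <- p
      out[[paste0("tail_", tm)]] <- tail
    }
    out
  })
  nm <- unique(unlist(lapply(rows, colnames)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(nm, colnames(r))) r[[cn]] <- NA
    r[, nm]
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hetgwis_replication", class(out))
  out
}
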