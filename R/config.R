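#' Run configuration for the scan pipeline
#'
#' @param n_pcs number of GRM principal components included as covariates
#'   (default 10).
#' @param alpha family-wise significance level for the Bonferroni
#'   threshold.
#' @param filter_top_k number of top-ranked SNPs carried from the
#'   filtering step to the pooled testing step (default 4).
#' @param max_visits maximum visits per subject accepted by validation.
#' @param seed integer seed recorded in manifests and used by `simulate`.
#' @param smoking_coding smoking coding of the pooled models.
#' @param covariance covariance structure used by the scan.
#' @param maf_min optional minor-allele-frequency screen (default 0: only
#'   monomorphic SNPs are excluded; Hardy-Weinberg p-values are reported,
#'   not filtered on).
#' @return List of class `"hetgwis_config"`.
#' @export
run_config <- function(n_pcs = 10, alpha = 0.05, filter_top_k = 4,
                       max_visits = 3, seed = NULL,
                       smoking_coding = c("two_level", "three_level",
                                          "smokers_only"),
                       covariance = c("unstructured", "random_intercept",
                                      "independence"),
                       maf_min = 0) {
  smoking_coding <- match.arg(smoking_coding)
  covariance <- match.arg(covariance)
  if (n_pcs < 0) stop("config error: n_pcs must be >= 0")
  if (filter_top_k < 1) stop("config error: filter_top_k must be >= 1")
  if (alpha <= 0 || alpha >= 1)
    stop("config error: alpha must lie in (0, 1)")
  structure(list(n_pcs = as.integer(n_pcs), alpha = alpha,
                 filter_top_k = as.integer(filter_top_k),
                 max_visits = max_visits, seed = seed,
                 smoking_coding = smoking_coding, covariance = covariance,
                 maf_min = maf_min),
            class = "hetgwis_config")
}

# build a run_config from a parsed JSON list, rejecting unknown keys
.config_from_list <- function(lst) {
  lst <- lst %||% list()
  known <- names(formals(run_config))
  bad <- setdiff(names(lst), known)
  if (length(bad))
    stop("config error: unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, lst)
}

.scenario_from_list <- function(lst) {
  lst <- lst %||% list()
  preset <- lst$preset
  lst$preset <- NULL
  for (nm in c("Sigma_never", "Sigma_ever"))
    if (!is.null(lst[[nm]])) lst[[nm]] <- as.matrix(lst[[nm]])
  if (!is.null(lst$smoking_proportions))
    lst$smoking_proportions <- unlist(lst$smoking_proportions)
  known <- c(names(formals(sim_scenario)), "causal_snp")
  bad <- setdiff(names(lst), known)
  if (length(bad))
    stop("config error: unknown scenario keys: ",
         paste(bad, collapse = ", "))
  causal <- lst$causal_snp
  lst$causal_snp <- NULL
  sc <- if (!is.null(preset)) do.call(sim_preset, c(list(name = preset), lst))
        else do.call(sim_scenario, lst)
  list(scenario = sc, causal_snp = causal)
}
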