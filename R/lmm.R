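#' Marginal covariance of a subject's observed visits
#'
#' Builds the model-implied covariance of one subject's response vector for
#' a covariance structure on the natural scale, restricted to the observed
#' visit subset.
#'
#' @param structure `"independence"`, `"random_intercept"` or
#'   `"unstructured"`.
#' @param params natural-scale parameter list: `sigma2` (independence);
#'   `sigma2` and `d` (random_intercept: random-intercept variance plus
#'   per-visit diagonal residual variances); `V` (unstructured: the full
#'   visit-by-visit marginal covariance).
#' @param visits integer vector of observed visit indices.
#' @param support visit indices that `d`/`V` are parameterized over
#'   (defaults to `1:length(d)` / `1:nrow(V)`; `visits` must be a subset).
#' @return Symmetric positive-definite matrix of dimension
#'   `length(visits)`.
#' @export
marginal_covariance <- function(structure, params, visits, support = NULL) {
  m <- length(visits)
  V <- switch(structure,
    independence = diag(params$sigma2, m),
    random_intercept = {
      d <- params$d
      if (length(d) == m && is.null(support)) dd <- d
      else {
        support <- support %||% seq_along(d)
        dd <- d[match(visits, support)]
      }
      if (anyNA(dd)) stop("visits outside the parameter support")
      matrix(params$sigma2, m, m) + diag(dd, m)
    },
    unstructured = {
      support <- support %||% seq_len(nrow(params$V))
      i <- match(visits, support)
      if (anyNA(i)) stop("visits outside the parameter support")
      params$V[i, i, drop = FALSE]
    },
    stop("unknown covariance structure: ", structure))
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("PD error: marginal covariance is not positive definite")
  V
}

## ---- raw parameterization --------------------------------------------
## independence:      theta = log sigma2                       (1)
## random_intercept:  theta = (log sigma2, log d_1..d_m)       (1 + m)
## unstructured:      theta = log-Cholesky of V, upper triangle,
##                    diagonal on log scale                    (m (m+1) / 2)

.theta_len <- function(structure, m) {
  switch(structure, independence = 1L, random_intercept = 1L + m,
         unstructured = (m * (m + 1L)) %/% 2L)
}

.theta_to_V <- function(structure, th, m) {
  switch(structure,
    independence = diag(exp(th), m),
    random_intercept = matrix(exp(th[1]), m, m) + diag(exp(th[-1]), m),
    unstructured = {
      U <- matrix(0, m, m)
      ut <- upper.tri(U, diag = TRUE)
      U[ut] <- th
      diag(U) <- exp(diag(U))
      crossprod(U)
    })
}

# dNLL/dtheta from G = dNLL/dV (m x m symmetric)
.theta_grad <- function(structure, th, m, G) {
  switch(structure,
    independence = exp(th) * sum(diag(G)),
    random_intercept = c(exp(th[1]) * sum(G), exp(th[-1]) * diag(G)),
    unstructured = {
      U <- matrix(0, m, m)
      ut <- upper.tri(U, diag = TRUE)
      U[ut] <- th
      diag(U) <- exp(diag(U))
      UG <- 2 * (U %*% G)
      diag(UG) <- diag(UG) * diag(U)
      UG[ut]
    })
}

.V_to_theta <- function(structure, V, m) {
  switch(structure,
    independence = log(mean(diag(V))),
    random_intercept = {
      off <- V[upper.tri(V)]
      s2 <- if (length(off)) max(mean(off), 1e-4 * mean(diag(V))) else
        0.1 * mean(diag(V))
      d <- pmax(diag(V) - s2, 1e-4 * mean(diag(V)))
      log(c(s2, d))
    },
    unstructured = {
      U <- chol(V)
      diag(U) <- log(diag(U))
      U[upper.tri(U, diag = TRUE)]
    })
}

# make a symmetric matrix safely positive definite
.pd_fix <- function(C) {
  C[is.na(C)] <- 0
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  floor <- max(1e-4 * mean(diag(C)), 1e-8)
  e$vectors %*% (pmax(e$values, floor) * t(e$vectors))
}

## ---- fit preparation --------------------------------------------------

# Per-block sufficient statistics for the profile deviance.  With
# Z = [X y] and Z_a the rows of a block observed at visit position a,
# every whitened cross-product the likelihood needs is a linear
# combination of C_ab = Z_a' Z_b weighted by entries of V^{-1}:
#   sum_i Z_i' V^{-1} Z_i = sum_ab (V^{-1})_ab C_ab .
# Precomputing the C_ab once per fit makes each objective/gradient
# evaluation O(m^2 p^2), independent of the number of subjects.
.prep_blocks <- function(bundle) {
  Z <- cbind(bundle$X, bundle$y)
  gv <- bundle$group_visits
  lapply(bundle$blocks, function(b) {
    Zm <- matrix(Z[b$idx, , drop = FALSE], nrow = b$m)
    p1 <- ncol(Z)
    Zl <- lapply(seq_len(b$m), function(a) matrix(Zm[a, ], b$ns, p1))
    pairs <- which(upper.tri(diag(b$m), diag = TRUE), arr.ind = TRUE)
    C <- lapply(seq_len(nrow(pairs)), function(k) {
      a <- pairs[k, 1]; bb <- pairs[k, 2]
      cc <- crossprod(Zl[[a]], Zl[[bb]])
      if (a == bb) cc else cc + t(cc)   # symmetrized off-diagonal pair
    })
    list(group = b$group, m = b$m, ns = b$ns,
         vidx = match(b$visits, gv[[b$group]]),
         pairs = pairs, C = C)
  })
}

.theta_layout <- function(bundle) {
  structure_name <- bundle$spec$covariance
  ms <- lengths(bundle$group_visits)
  lens <- vapply(ms, function(m) .theta_len(structure_name, m), 1L)
  ends <- cumsum(lens)
  list(structure = structure_name, ms = ms, lens = lens,
       starts = ends - lens + 1L, ends = ends, total = sum(lens))
}

# Closure evaluating the profile deviance (negative profiled
# log-likelihood) and its analytic gradient for a design bundle.
# `want`: "obj" (default), "grad", or "full" (objective + whitened
# cross-products + GLS coefficients).  Gradients use the chain rule
# through dV: for each block, dNLL/dV = 0.5 (ns V^{-1} - V^{-1} R V^{-1})
# with R the per-visit residual cross-product matrix, mapped to the raw
# scale by .theta_grad.
.make_profile_deviance <- function(bundle) {
  prep <- .prep_blocks(bundle)
  lay <- .theta_layout(bundle)
  n_obs <- bundle$n_obs
  p <- ncol(bundle$X)
  p1 <- p + 1L
  function(th, want = "obj") {
    Vs <- lapply(seq_along(lay$ms), function(g)
      .theta_to_V(lay$structure, th[lay$starts[g]:lay$ends[g]], lay$ms[g]))
    XtX <- matrix(0, p1, p1)
    ld <- 0
    Wis <- if (want == "grad") vector("list", length(prep))
    for (bi in seq_along(prep)) {
      b <- prep[[bi]]
      Vb <- Vs[[b$group]][b$vidx, b$vidx, drop = FALSE]
      Ub <- chol(Vb)
      Wi <- chol2inv(Ub)
      for (k in seq_along(b$C))
        XtX <- XtX + Wi[b$pairs[k, 1], b$pairs[k, 2]] * b$C[[k]]
      ld <- ld + 2 * b$ns * sum(log(diag(Ub)))
      if (want == "grad") Wis[[bi]] <- Wi
    }
    A <- XtX[1:p, 1:p, drop = FALSE]
    aty <- XtX[1:p, p1]
    bh <- solve(A, aty)
    rss <- max(XtX[p1, p1] - sum(bh * aty), 1e-12)
    obj <- 0.5 * (n_obs * log(2 * pi) + ld + rss)
    if (want == "obj") return(obj)
    if (want == "grad") {
      beta1 <- c(-bh, 1)                 # residual = Z %*% beta1
      oo <- tcrossprod(beta1)
      Gs <- lapply(lay$ms, function(m) matrix(0, m, m))
      for (bi in seq_along(prep)) {
        b <- prep[[bi]]
        R <- matrix(0, b$m, b$m)         # per-visit residual cross-products
        for (k in seq_along(b$C)) {
          a <- b$pairs[k, 1]; bb <- b$pairs[k, 2]
          q <- sum(b$C[[k]] * oo)
          if (a == bb) R[a, a] <- q else {
            R[a, bb] <- q / 2; R[bb, a] <- q / 2
          }
        }
        Wi <- Wis[[bi]]
        Ablk <- 0.5 * (b$ns * Wi - Wi %*% R %*% Wi)
        g <- b$group
        Gs[[g]][b$vidx, b$vidx] <- Gs[[g]][b$vidx, b$vidx] + Ablk
      }
      return(unlist(lapply(seq_along(lay$ms), function(g)
        .theta_grad(lay$structure, th[lay$starts[g]:lay$ends[g]],
                    lay$ms[g], Gs[[g]]))))
    }
    list(obj = obj, XtX = XtX, beta = bh)
  }
}

#' Maximum-likelihood fit of a heteroscedastic linear mixed model
#'
#' Fits the model described by a design bundle by full maximum likelihood
#' (not REML, so that likelihood-ratio tests of fixed effects and AIC
#' comparisons across fixed-effect sets are valid).  Fixed effects are
#' profiled out by generalized least squares at every covariance-parameter
#' proposal; covariance parameters (log variances; log-Cholesky factors
#' for unstructured matrices, which keeps every iterate positive definite)
#' are optimized by quasi-Newton with analytic gradients.  Convergence is
#' declared when the profile-deviance gradient infinity-norm falls below
#' `1e-6 * n_obs`; non-convergence is reported through the `converged`
#' flag, never as an error, so genome-wide loops are not interrupted.
#'
#' @param bundle a [build_design()] bundle.
#' @param init optional warm start: a raw covariance-parameter vector or a
#'   previous fit on the same grouping/structure (its `$theta` is reused).
#' @param control list; `gtol` overrides the gradient tolerance.
#' @return Object of class `"hetgwis_fit"`: `beta_hat`, `vcov_beta`,
#'   `cov_params` (per-group natural-scale estimates incl. the marginal
#'   covariance `V`), `loglik`, `k`, `aic`, `converged`, `grad_norm`,
#'   `theta`, `n_subjects`, `n_obs`, `rank`, `spec`, `group_visits`.
#' @export
fit_ml <- function(bundle, init = NULL, control = list()) {
  stopifnot(inherits(bundle, "hetgwis_design"))
  X <- bundle$X
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("fit error: collinear or degenerate design columns: ",
         paste(bad, collapse = ", "))
  }
  if (bundle$n_obs <= p)
    stop("fit error: fewer observations than fixed-effect columns")
  core <- .make_profile_deviance(bundle)
  obj_safe <- function(th) {
    if (any(!is.finite(th)) || any(abs(th) > 30)) return(1e10)
    v <- tryCatch(core(th), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  grad_safe <- function(th) {
    g <- tryCatch(core(th, "grad"), error = function(e) NULL)
    if (is.null(g) || any(!is.finite(g))) rep(0, length(th)) else g
  }
  lay <- .theta_layout(bundle)
  n_obs <- bundle$n_obs

  if (!is.null(init)) {
    th0 <- if (inherits(init, "hetgwis_fit")) init$theta else init
    if (length(th0) != lay$total)
      stop("fit error: init has wrong covariance-parameter length")
  } else {
    r <- qr.resid(qrX, bundle$y)
    th0 <- unlist(lapply(seq_along(lay$ms), function(g) {
      m <- lay$ms[g]
      Remp <- matrix(NA_real_, 0, m)
      for (b in bundle$blocks)
        if (b$group == g) {
          vi <- match(b$visits, bundle$group_visits[[g]])
          Ri <- matrix(NA_real_, b$ns, m)
          Ri[, vi] <- t(matrix(r[b$idx], nrow = b$m))
          Remp <- rbind(Remp, Ri)
        }
      C <- if (nrow(Remp) > 1)
        suppressWarnings(cov(Remp, use = "pairwise.complete.obs")) else
          diag(stats::var(r), m)
      .V_to_theta(lay$structure, .pd_fix(C), m)
    }))
  }

  gtol <- control$gtol %||% (1e-6 * max(1, n_obs))
  opt <- tryCatch(
    nlminb(th0, obj_safe, grad_safe,
           control = list(iter.max = control$maxit %||% 500,
                          rel.tol = control$rel_tol %||% 1e-10)),
    error = function(e) NULL)
  th <- if (is.null(opt)) th0 else opt$par
  gn <- max(abs(grad_safe(th)))
  if (gn > gtol) {                       # polish from a different method
    pol <- tryCatch(
      optim(th, obj_safe, grad_safe, method = "BFGS",
            control = list(maxit = 200, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= obj_safe(th)) th <- pol$par
    gn <- max(abs(grad_safe(th)))
  }

  fin <- core(th, want = "full")
  XtX <- fin$XtX
  A <- XtX[1:p, 1:p, drop = FALSE]
  vcov_beta <- solve(A)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  beta_hat <- setNames(fin$beta, colnames(X))
  loglik <- -fin$obj
  k <- p + lay$total
  cov_params <- lapply(seq_along(lay$ms), function(g) {
    thg <- th[lay$starts[g]:lay$ends[g]]
    V <- .theta_to_V(lay$structure, thg, lay$ms[g])
    out <- list(structure = lay$structure, V = V,
                support = bundle$group_visits[[g]])
    if (lay$structure == "independence") out$sigma2 <- exp(thg)
    if (lay$structure == "random_intercept") {
      out$sigma2 <- exp(thg[1]); out$d <- exp(thg[-1])
    }
    out
  })
  names(cov_params) <- names(bundle$group_visits)
  structure(list(beta_hat = beta_hat, vcov_beta = vcov_beta,
                 cov_params = cov_params, loglik = loglik, k = k,
                 aic = -2 * loglik + 2 * k,
                 converged = is.finite(loglik) && gn <= gtol,
                 grad_norm = gn, theta = th, n_subjects =
                   length(bundle$subject_ids), n_obs = n_obs, rank = p,
                 spec = bundle$spec,
                 group_visits = bundle$group_visits),
            class = "hetgwis_fit")
}

#' @export
print.hetgwis_fit <- function(x, ...) {
  cat("Linear mixed model fit (", x$spec$covariance,
      if (x$spec$heteroscedastic) ", heteroscedastic" else ", shared",
      " covariance)\n", sep = "")
  cat("  subjects:", x$n_subjects, " observations:", x$n_obs, "\n")
  cat("  logLik:", format(x$loglik, digits = 8), "  AIC:",
      format(x$aic, digits = 8), "  converged:", x$converged, "\n")
  print(round(x$beta_hat, 4))
  invisible(x)
}

#' Joint multivariate-normal log-likelihood at given parameters
#'
#' Evaluates (without profiling) the exact log-likelihood of a design
#' bundle at fixed-effect vector `beta` and natural-scale covariance
#' parameters, summing each subject's multivariate normal log-density with
#' mean `X_i beta` and the [marginal_covariance()] of its observed visits.
#'
#' @param bundle a [build_design()] bundle.
#' @param beta fixed-effect vector (aligned to `colnames(bundle$X)`).
#' @param cov_params list of per-group natural parameter lists, named by
#'   covariance group, each as in [marginal_covariance()] (fits return
#'   this format in `$cov_params`).
#' @return Scalar log-likelihood.
#' @export
lmm_loglik <- function(bundle, beta, cov_params) {
  stopifnot(inherits(bundle, "hetgwis_design"))
  r <- bundle$y - drop(bundle$X %*% beta)
  ll <- 0
  for (b in bundle$blocks) {
    gname <- names(bundle$group_visits)[b$group]
    par <- cov_params[[gname]] %||% cov_params[[b$group]]
    V <- marginal_covariance(par$structure, par, b$visits,
                             support = par$support %||%
                               bundle$group_visits[[b$group]])
    Ub <- chol(V)
    rw <- backsolve(Ub, matrix(r[b$idx], nrow = b$m), transpose = TRUE)
    ll <- ll - 0.5 * (b$ns * b$m * log(2 * pi) +
                      2 * b$ns * sum(log(diag(Ub))) + sum(rw^2))
  }
  ll
}

.test_result <- function(statistic, df, p, kind, df2 = NA_real_,
                         extra = NULL) {
  structure(c(list(statistic = statistic, df = df, df2 = df2, p = p,
                   kind = kind), extra), class = "hetgwis_test")
}

#' @export
print.hetgwis_test <- function(x, ...) {
  cat(x$kind, " test: statistic = ", format(x$statistic, digits = 5),
      ", df = ", x$df,
      if (!is.na(x$df2)) paste0("/", format(x$df2, digits = 6)),
      ", p = ", format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio test of nested fits
#'
#' @param full,reduced converged [fit_ml()] results, `reduced` nested in
#'   `full` (same data).
#' @param df degrees of freedom of the comparison.
#' @return A test result with `statistic = 2 * (loglik_full -
#'   loglik_reduced)` (clipped at zero) referred to chi-square(`df`).  A
#'   full-model log-likelihood materially below the reduced one signals an
#'   optimizer failure and raises an error instead of returning a negative
#'   statistic.
#' @export
lrt <- function(full, reduced, df) {
  stat <- 2 * (full$loglik - reduced$loglik)
  tol <- 1e-5 * max(1, abs(full$loglik))
  if (stat < -tol)
    stop("optimization-quality error: full-model log-likelihood below ",
         "reduced (", format(stat / 2, digits = 6), "); refit needed")
  stat <- max(stat, 0)
  .test_result(stat, df, pchisq(stat, df, lower.tail = FALSE), "LRT")
}

#' Joint Wald / F test of a coefficient subset
#'
#' Tests that a subset of fixed-effect coefficients is zero via
#' `W = beta' V^{-1} beta` on the estimated coefficient covariance.  The
#' statistic is referred both to chi-square(q) and, as `W/q`, to
#' F(q, n_obs - rank(X)); the F-form p-value is reported as `$p` (the
#' residual denominator df is an approximation to software defaults) with
#' the chi-square form in `$p_chisq`.
#'
#' @param fit a [fit_ml()] result.
#' @param terms character vector of coefficient names.
#' @return Test result with `kind = "F"`.
#' @export
wald_joint <- function(fit, terms) {
  idx <- match(terms, names(fit$beta_hat))
  if (anyNA(idx))
    stop("unknown coefficient(s): ",
         paste(terms[is.na(idx)], collapse = ", "))
  b <- fit$beta_hat[idx]
  V <- fit$vcov_beta[idx, idx, drop = FALSE]
  W <- tryCatch(drop(crossprod(b, solve(V, b))),
                error = function(e)
                  stop("numeric error: singular coefficient covariance"))
  q <- length(idx)
  df2 <- fit$n_obs - fit$rank
  .test_result(W, q, pf(W / q, q, df2, lower.tail = FALSE), "F", df2 = df2,
               extra = list(p_chisq = pchisq(W, q, lower.tail = FALSE)))
}

#' Akaike information criterion of a fit
#'
#' `-2 * loglik + 2 * k`, with `k` the number of fixed-effect columns plus
#' free covariance parameters.  Model selection across smoking codings and
#' covariance structures compares this value on ML fits.
#'
#' @param fit a converged [fit_ml()] result.
#' @return Numeric AIC.
#' @export
aic_of <- function(fit) {
  if (!isTRUE(fit$converged))
    warning("AIC of a non-converged fit")
  -2 * fit$loglik + 2 * fit$k
}
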