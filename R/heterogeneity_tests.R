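## ---------------------------------------------------------------------------
## Heterogeneity tests: marker-specific Wald tests, fixed global test,
## mixed-effect global score test at the variance-component boundary,
## BH-FDR, and fixed-effect multivariate meta-analysis.
## ---------------------------------------------------------------------------

#' Marker-specific heterogeneity tests
#'
#' Wald z and two-sided normal p-value for each case-case parameter of
#' a main-effects fit (ER, PR, HER2, grade), each adjusted for the
#' others through the joint fit.
#'
#' @param fit a converged `twostage_fit` with `main_effects` design.
#' @return data.frame(marker, theta, se, z, p).
#' @export
marker_tests <- function(fit) {
  stopifnot(inherits(fit, "twostage_fit"))
  if (!identical(fit$design_kind, "main_effects"))
    stop("marker_tests needs a main_effects fit")
  if (!isTRUE(fit$converged))
    stop("fit did not converge; marker tests would be unreliable")
  idx <- which(fit$labels != "baseline")
  th <- fit$theta[idx]; se <- fit$se_theta[idx]
  z <- th / se
  data.frame(marker = fit$labels[idx], theta = unname(th), se = unname(se),
             z = unname(z), p = unname(2 * pnorm(-abs(z))),
             row.names = NULL)
}

#' Fixed-effect global heterogeneity test
#'
#' Wald quadratic form over the four case-case parameters of a
#' main-effects fit (baseline excluded), referred to chi-square with
#' 4 degrees of freedom.  The null is that the genotype log OR is
#' identical across all tumor cells.
#'
#' @param fit a `twostage_fit` with `main_effects` design.
#' @return list of class `global_test`: statistic, df, p_value, method.
#' @export
global_test_fixed <- function(fit) {
  stopifnot(inherits(fit, "twostage_fit"))
  if (!identical(fit$design_kind, "main_effects"))
    stop("global_test_fixed needs a main_effects fit")
  idx <- which(fit$labels != "baseline")
  th <- fit$theta[idx]
  V <- fit$cov_theta[idx, idx, drop = FALSE]
  stat <- tryCatch(drop(t(th) %*% solve(V, th)),
                   error = function(e) stop("singular case-case covariance"))
  structure(list(statistic = stat, df = length(idx),
                 p_value = pchisq(stat, df = length(idx), lower.tail = FALSE),
                 method = "wald_fixed_df4"), class = "global_test")
}

#' @export
print.global_test <- function(x, ...) {
  cat(sprintf("global heterogeneity test (%s): statistic %.4f, p = %.3g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Efficient score of the case-case parameters under the global null
#'
#' Fits the null model (baseline genotype effect only: a common log OR
#' across all cells, free intercepts and covariate effects) and returns
#' the observed-data score vector for the four case-case parameters of
#' the main-effects design together with its efficient covariance (the
#' Schur complement of the observed information over the nuisance
#' block).  Under the null, `U ~ N(0, V)` asymptotically.  Scores from
#' independent strata may be summed, which is how the per-array
#' meta-analyzed global test is built.
#'
#' @inheritParams fit_twostage
#' @return list of class `global_score`: `U` (length 4, named), `V`
#'   (4 x 4), `null_fit`.
#' @export
global_score_null <- function(status, g, markers, x = NULL,
                              schema = default_schema(), control = list()) {
  cells <- enumerate_cells(schema)
  des_full <- second_stage_design(cells, "main_effects", schema)
  A0 <- des_full$A[, 1, drop = FALSE]          # baseline column only
  des0 <- structure(list(kind = "null_baseline", A = A0,
                         labels = "baseline"),
                    class = "second_stage_design")
  nf <- fit_twostage(status, g, markers, x, design = des0, schema = schema,
                     method = "direct", control = control)
  if (!nf$converged) stop("null fit did not converge")

  ## evaluate full-model score/information at the null optimum
  X <- if (is.null(x)) NULL else as.matrix(x)
  Cmask <- ts_case_mask(as.integer(status), markers, schema)
  reach <- nf$reachable
  Cm <- Cmask[, reach, drop = FALSE]
  A <- des_full$A[reach, , drop = FALSE]
  q <- if (is.null(X)) 0L else ncol(X)
  prep <- list(g = g, X = X, Cmask = Cm, A = A,
               is_case = as.integer(status) == 1L,
               M = sum(reach), p = ncol(A), q = q)
  psi <- c(nf$alpha[reach], nf$theta[1], rep(0, 4), nf$xi)
  ev <- ts_eval(psi, prep)
  gr <- ts_grad(ev$W - ev$P, prep)
  info <- ts_blockinfo(ev$P, prep) - ts_blockinfo(ev$W, prep)
  M <- sum(reach)
  i_cc <- M + 2:5                               # ER, PR, HER2, grade
  i_nu <- setdiff(seq_along(psi), i_cc)
  U <- gr[i_cc]
  V <- info[i_cc, i_cc] -
    info[i_cc, i_nu] %*% solve(info[i_nu, i_nu], info[i_nu, i_cc])
  nm <- des_full$labels[-1]
  names(U) <- nm; dimnames(V) <- list(nm, nm)
  structure(list(U = U, V = (V + t(V)) / 2, null_fit = nf),
            class = "global_score")
}

## Imhof (1961) tail probability of sum_j lambda_j chi2_1 at q;
## falls back to the Kuonen saddlepoint approximation when the
## oscillatory integral does not converge (far tails)
imhof_pvalue <- function(q, lambda) {
  lambda <- lambda[abs(lambda) > 1e-10 * max(abs(lambda))]
  if (!length(lambda)) return(1)
  integrand <- function(u) {
    th <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(th) / (u * rho)
  }
  val <- tryCatch(
    integrate(integrand, 0, Inf, subdivisions = 5000L,
              rel.tol = 1e-9, abs.tol = 1e-12)$value,
    error = function(e) NULL)
  if (!is.null(val)) {
    p <- 0.5 + val / pi
    ## the quadrature loses accuracy once p is of the order of its
    ## absolute error; hand far tails to the saddlepoint
    if (p > 1e-8) return(min(max(p, 1e-14), 1))
  }
  saddlepoint_pvalue(q, lambda)
}

## Kuonen (1999) saddlepoint tail approximation for sum lambda_j chi2_1
saddlepoint_pvalue <- function(q, lambda) {
  if (q <= sum(lambda) * (1 + 1e-8)) {
    ## at/below the mean the saddlepoint degenerates; use Imhof with a
    ## loose tolerance (the integral is well behaved here)
    integrand <- function(u) {
      th <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
      rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
      sin(th) / (u * rho)
    }
    val <- integrate(integrand, 0, Inf, subdivisions = 5000L,
                     rel.tol = 1e-6)$value
    return(min(max(0.5 + val / pi, 1e-14), 1))
  }
  kp <- function(s) sum(lambda / (1 - 2 * s * lambda))
  smax <- 1 / (2 * max(lambda))
  sh <- stats::uniroot(function(s) kp(s) - q,
                       lower = 0, upper = smax * (1 - 1e-10),
                       tol = 1e-14)$root
  K <- -0.5 * sum(log1p(-2 * sh * lambda))
  K2 <- 2 * sum(lambda^2 / (1 - 2 * sh * lambda)^2)
  w <- sqrt(2 * (sh * q - K))
  v <- sh * sqrt(K2)
  min(max(pnorm(w + log(v / w) / w, lower.tail = FALSE), 1e-300), 1)
}

#' Mixed-effect global heterogeneity test
#'
#' Score test of the global null (no heterogeneity by any marker) under
#' the mixed-effect two-stage formulation: the ER case-case parameter
#' is fixed, while the PR, HER2 and grade parameters share a common
#' mean `mu` and a common random variance `sigma^2`.  The null
#' `theta_ER = 0, mu = 0, sigma^2 = 0` lies on the boundary; the
#' statistic combines the efficient-score quadratic form for
#' `(theta_ER, mu)` with a residualized variance-component score, and
#' its null distribution is the implied weighted chi-square mixture,
#' evaluated by Imhof integration (`method = "mixture_chisq"`) or by
#' Monte Carlo draws from the null Gaussian score
#' (`method = "monte_carlo"`).
#'
#' @param score a [global_score_null()] result, or a list with elements
#'   `U` (length-4 score, order ER/PR/HER2/grade) and `V` (4 x 4).
#' @param method p-value evaluation.
#' @param n_mc Monte Carlo draws.
#' @return list of class `global_test`: statistic, p_value, components
#'   (fixed and variance-component parts), lambda (mixture weights),
#'   method.
#' @export
global_test_mixed <- function(score, method = c("mixture_chisq", "monte_carlo"),
                              n_mc = 1e5) {
  method <- match.arg(method)
  U <- score$U; V <- score$V
  stopifnot(length(U) == 4L, all(dim(V) == 4L))
  L <- rbind(ER = c(1, 0, 0, 0), mu = c(0, 1, 1, 1))
  D <- diag(c(0, 1, 1, 1))
  LVL <- L %*% V %*% t(L)
  Mf <- t(L) %*% solve(LVL) %*% L
  Pres <- diag(4) - V %*% t(L) %*% solve(LVL, L)
  Mvc_raw <- t(Pres) %*% D %*% Pres
  sc <- sum(diag(D %*% V))                     # scale so both parts are O(1)
  Mvc <- Mvc_raw / sc
  Mtot <- Mf + Mvc
  stat_f <- drop(t(U) %*% Mf %*% U)
  stat_v <- drop(t(U) %*% Mvc %*% U)
  stat <- stat_f + stat_v
  es <- eigen(V, symmetric = TRUE)
  Vh <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  lambda <- eigen((Vh %*% Mtot %*% Vh + t(Vh %*% Mtot %*% Vh)) / 2,
                  symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-12 * max(lambda)]
  if (method == "mixture_chisq") {
    p <- imhof_pvalue(stat, lambda)
  } else {
    Z <- matrix(rnorm(4L * n_mc), n_mc, 4L) %*% Vh
    Tmc <- rowSums((Z %*% Mtot) * Z)
    p <- (1 + sum(Tmc >= stat)) / (n_mc + 1)
  }
  structure(list(statistic = stat, p_value = p,
                 components = c(fixed_part = stat_f, random_part = stat_v),
                 lambda = lambda, method = method),
            class = "global_test")
}

#' Meta-analyzed mixed-effect global test
#'
#' Strata share no parameters, so their efficient scores are
#' independent; summing scores and efficient informations across strata
#' and applying the mixture machinery of [global_test_mixed()] gives
#' the per-array meta-analyzed global test.
#'
#' @param scores list of [global_score_null()] results (one per stratum).
#' @inheritParams global_test_mixed
#' @return `global_test`.
#' @export
meta_global_mixed <- function(scores, method = c("mixture_chisq", "monte_carlo"),
                              n_mc = 1e5) {
  stopifnot(length(scores) >= 1L)
  nm <- names(scores[[1]]$U)
  for (s in scores)
    if (!identical(names(s$U), nm))
      stop("strata use different parameterizations")
  U <- Reduce(`+`, lapply(scores, `[[`, "U"))
  V <- Reduce(`+`, lapply(scores, `[[`, "V"))
  global_test_mixed(list(U = U, V = V), method = match.arg(method), n_mc = n_mc)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment across the family of all variants screened in
#' one run; selection at `q < alpha` reproduces the classical step-up
#' rule.
#'
#' @param pvals p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Fixed-effect multivariate meta-analysis
#'
#' Inverse-variance combination of per-stratum estimates:
#' `Sigma_meta = (sum_k Sigma_k^-1)^-1`,
#' `theta_meta = Sigma_meta sum_k Sigma_k^-1 theta_k`.
#'
#' @param estimates list of `list(theta=, cov=)` per stratum (scalars
#'   allowed: `cov` may be a scalar variance).
#' @return list(theta, cov).
#' @export
meta_fixed <- function(estimates) {
  stopifnot(length(estimates) >= 1L)
  d <- length(estimates[[1]]$theta)
  Wsum <- matrix(0, d, d); b <- rep(0, d)
  for (e in estimates) {
    Sig <- e$cov
    if (is.null(dim(Sig))) Sig <- diag(Sig, d)
    if (length(e$theta) != d || !all(dim(Sig) == d))
      stop("non-conformable estimates")
    Wi <- tryCatch(solve(Sig), error = function(err)
      stop("singular covariance in meta-analysis"))
    Wsum <- Wsum + Wi
    b <- b + drop(Wi %*% e$theta)
  }
  cov <- solve(Wsum)
  th <- drop(cov %*% b)
  names(th) <- names(estimates[[1]]$theta)
  list(theta = th, cov = cov)
}
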