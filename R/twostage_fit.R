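## ---------------------------------------------------------------------------
## Two-stage polytomous likelihood core.
##
## Categories: control (reference, linear predictor 0) plus M tumor cells.
## Subject i, cell m:  eta_im = alpha_m + (A theta)_m * g_i + xi' x_i,
## P(cell m) = exp(eta_im) / (1 + sum_j exp(eta_ij)).
## Cases with partially observed markers contribute
## log sum_{m in S_i} P(cell m), S_i = cells consistent with the observed
## pattern; the same observed-data likelihood is maximized either directly
## (safeguarded Newton on the exact analytic Hessian) or by EM over cell
## membership.
## ---------------------------------------------------------------------------

ts_control <- function(control = list()) {
  ctrl <- list(max_iter = 500L, em_max_iter = 500L, ll_tol = 1e-8,
               score_tol = 2e-6, newton_max = 100L, param_cap = 30,
               alpha_floor = -15, ridge = 1e-8, em_warmup = 3L)
  ctrl[names(control)] <- control
  ctrl
}

## consistency mask (n x M, 0/1) for case rows; control rows all zero
ts_case_mask <- function(status, markers, schema) {
  cells <- enumerate_cells(schema)
  mk <- names(schema$markers)
  M <- nrow(cells)
  n <- length(status)
  if (!all(mk %in% names(markers)))
    stop("markers data.frame must contain columns ",
         paste(mk, collapse = ", "))
  Cmask <- matrix(0, n, M)
  idx_case <- which(status == 1L)
  if (!length(idx_case)) return(Cmask)
  mm <- as.matrix(markers[idx_case, mk, drop = FALSE])
  for (j in seq_along(mk)) {
    v <- mm[, j]
    ok <- is.na(v) | v %in% schema$markers[[mk[j]]]
    if (!all(ok))
      stop(sprintf("invalid %s value(s): %s", mk[j],
                   paste(unique(v[!ok]), collapse = ", ")))
  }
  key <- apply(mm, 1L, paste, collapse = "|")
  for (k in unique(key)) {
    rows <- idx_case[key == k]
    pat <- mm[match(k, key), ]
    ids <- consistent_cells(stats::setNames(as.list(pat), mk), schema)
    Cmask[rows, ids + 1L] <- 1
  }
  Cmask
}

## eta, probabilities, posterior weights and loglik in one pass
ts_eval <- function(psi, prep) {
  M <- prep$M; p <- prep$p; q <- prep$q
  alpha <- psi[seq_len(M)]
  theta <- psi[M + seq_len(p)]
  beta <- drop(prep$A %*% theta)
  eta <- outer(prep$g, beta)
  eta <- sweep(eta, 2L, alpha, "+")
  if (q > 0) {
    xb <- drop(prep$X %*% psi[M + p + seq_len(q)])
    eta <- eta + xb
  }
  n <- nrow(eta)
  rmax <- eta[cbind(seq_len(n), max.col(eta, ties.method = "first"))]
  rmax <- pmax(rmax, 0)
  E <- exp(eta - rmax)
  denom <- exp(-rmax) + rowSums(E)
  P <- E / denom
  EC <- E * prep$Cmask
  num_case <- rowSums(EC)                   # zero for controls
  ic <- prep$is_case
  ll <- sum(log(num_case[ic])) - sum(log(denom[ic])) -
    sum(rmax[!ic]) - sum(log(denom[!ic]))
  W <- EC / pmax(num_case, 1e-300)
  list(ll = ll, P = P, W = W)
}

ts_grad <- function(S, prep) {
  ga <- colSums(S)
  gt <- drop(crossprod(prep$A, colSums(S * prep$g)))
  if (prep$q > 0) gx <- drop(crossprod(prep$X, rowSums(S))) else gx <- NULL
  c(ga, gt, gx)
}

## sum_i Z_i' (diag(v_i) - v_i v_i') Z_i for V an n x M weight matrix,
## Z_i = [I_M, g_i A, 1_M x_i']
ts_blockinfo <- function(V, prep) {
  M <- prep$M; p <- prep$p; q <- prep$q
  g <- prep$g
  cs <- colSums(V); csg <- colSums(V * g); csg2 <- colSums(V * g^2)
  VA <- V %*% prep$A
  BD <- matrix(0, M + p + q, M + p + q)
  ia <- seq_len(M); it <- M + seq_len(p)
  BD[ia, ia] <- diag(cs, nrow = M)
  BD[ia, it] <- csg * prep$A
  BD[it, ia] <- t(BD[ia, it])
  BD[it, it] <- crossprod(prep$A, prep$A * csg2)
  if (q > 0) {
    ix <- M + p + seq_len(q)
    rs <- rowSums(V)
    BD[ia, ix] <- crossprod(V, prep$X)
    BD[ix, ia] <- t(BD[ia, ix])
    BD[it, ix] <- crossprod(VA * g, prep$X)
    BD[ix, it] <- t(BD[it, ix])
    BD[ix, ix] <- crossprod(prep$X, prep$X * rs)
    U <- cbind(V, VA * g, prep$X * rs)
  } else {
    U <- cbind(V, VA * g)
  }
  BD - crossprod(U)
}

## Newton direction restricted to free (non-floored) parameters
ts_dir <- function(info, gr, free, ridge) {
  d <- numeric(length(gr))
  d[free] <- ts_solve(info[free, free, drop = FALSE], gr[free], ridge)
  d
}

ts_solve <- function(H, b, ridge) {
  out <- tryCatch(solve(H, b), error = function(e) NULL)
  if (is.null(out))
    out <- solve(H + diag(ridge * max(diag(H), 1), nrow(H)), b)
  out
}

## one safeguarded ascent pass: Newton direction + step halving on `llfun`.
## Cell intercepts are clamped at `floor` (boundary MLEs for cells whose
## posterior mass vanishes); divergence is judged on the remaining
## parameters only.
ts_ascend <- function(psi, d, llfun, ll0, cap, ia, floor_a) {
  step <- 1
  for (k in 1:30) {
    cand <- psi + step * d
    cand[ia] <- pmax(cand[ia], floor_a)
    if (max(abs(cand[-ia])) <= cap || length(cand) == length(ia)) {
      llc <- llfun(cand)
      if (is.finite(llc) && llc >= ll0 - 1e-12) return(list(psi = cand, ll = llc))
    }
    step <- step / 2
  }
  list(psi = psi, ll = ll0)
}

## when the guarded Newton line search stalls, cells whose posterior case
## mass is negligible and whose intercept gradient still points down have
## a boundary MLE (alpha -> -Inf): send them straight to the floor if the
## observed loglik does not decrease
ts_boundary_push <- function(psi, ev, prep, llfun, ia_idx, floor_a) {
  mass <- colSums(ev$W)
  gr <- ts_grad(ev$W - ev$P, prep)
  push <- ia_idx[mass < 0.5 & gr[ia_idx] < 0 & psi[ia_idx] > floor_a + 1e-8]
  if (!length(push)) return(NULL)
  cand <- psi
  cand[push] <- floor_a
  llc <- llfun(cand)
  if (is.finite(llc) && llc >= ev$ll - 1e-12) return(cand)
  NULL
}

ts_fit_core <- function(status, g, X, Cmask, A, labels,
                        method = c("direct", "EM"), control = list(),
                        cell_labels = NULL) {
  method <- match.arg(method)
  ctrl <- ts_control(control)
  is_case <- status == 1L
  if (!any(is_case) || all(is_case))
    stop("need at least one case and one control")
  ## drop cells unreachable under every observed case pattern: their
  ## intercept MLE is -Inf and they carry no information
  reach <- colSums(Cmask[is_case, , drop = FALSE]) > 0
  A_full <- A
  M_full <- ncol(Cmask)
  Cmask <- Cmask[, reach, drop = FALSE]
  A <- A[reach, , drop = FALSE]
  keep_par <- colSums(A != 0) > 0
  dropped_par <- !keep_par
  A <- A[, keep_par, drop = FALSE]
  if (qr(A)$rank < ncol(A))
    stop("second-stage design is rank deficient on the reachable cells")
  M <- ncol(Cmask); p <- ncol(A)
  q <- if (is.null(X)) 0L else ncol(X)
  n <- length(status)
  prep <- list(g = g, X = X, Cmask = Cmask, A = A, is_case = is_case,
               M = M, p = p, q = q)
  ia_idx <- seq_len(M)
  free_idx <- function(ps) which(!(seq_along(ps) %in% ia_idx &
                                     ps <= ctrl$alpha_floor + 1e-8))
  ## convergence of the score: tight on (theta, xi); intercept gradients
  ## are judged on an absolute scale (units of expected case counts)
  score_ok <- function(gr, ps) {
    fr <- free_idx(ps)
    fa <- fr[fr %in% ia_idx]
    ft <- fr[!fr %in% ia_idx]
    (length(ft) == 0L ||
       max(abs(gr[ft])) / sqrt(max(1, n)) < ctrl$score_tol) &&
      (length(fa) == 0L ||
         max(abs(gr[fa])) < max(0.01, ctrl$score_tol * sqrt(max(1, n))))
  }

  ## init: smoothed log frequency of fully-observed cases per cell vs
  ## controls, unless a warm start is supplied (e.g. from a null fit)
  if (!is.null(ctrl$init)) {
    alpha0 <- pmax(ctrl$init$alpha[reach], ctrl$alpha_floor)
    alpha0[!is.finite(alpha0)] <- ctrl$alpha_floor
    th0 <- rep(0, p)
    if (!is.null(ctrl$init$theta)) {
      ti <- ctrl$init$theta[keep_par]
      th0[is.finite(ti)] <- ti[is.finite(ti)]
    }
    xi0 <- if (q > 0 && length(ctrl$init$xi) == q) ctrl$init$xi else rep(0, q)
    psi <- c(alpha0, th0, xi0)
    ctrl$em_warmup <- 0L
  } else {
    single <- is_case & rowSums(Cmask) == 1
    cnt <- colSums(Cmask[single, , drop = FALSE])
    n0 <- sum(!is_case)
    alpha0 <- log((cnt + 0.5) / (n0 + 0.5))
    psi <- c(alpha0, rep(0, p + q))
  }

  llfun <- function(ps) ts_eval(ps, prep)$ll
  ev <- ts_eval(psi, prep)
  trace_ll <- ev$ll
  n_iter <- 0L; converged <- FALSE

  if (method == "EM") {
    ## generalized EM: each M-step takes guarded Newton steps on
    ## Q(psi | W) = sum_i sum_m W_im log P_im + (1 - sum_m W_im) log P_i0,
    ## which is concave; any Q increase increases the observed loglik
    qfun_mk <- function(W) function(ps) {
      e <- ts_eval(ps, prep)
      sum(W * log(pmax(e$P, 1e-300))) +
        sum((1 - rowSums(W)) * log(pmax(1 - rowSums(e$P), 1e-300)))
    }
    for (it in seq_len(ctrl$em_max_iter)) {
      W <- ev$W
      qfun <- qfun_mk(W)
      for (nw in seq_len(3L)) {
        e <- ts_eval(psi, prep)
        grq <- ts_grad(W - e$P, prep)
        if (max(abs(grq)) < 1e-8 * max(1, n)) break
        d <- ts_dir(ts_blockinfo(e$P, prep), grq, free_idx(psi), ctrl$ridge)
        st <- ts_ascend(psi, d, qfun, qfun(psi), ctrl$param_cap, ia_idx,
                        ctrl$alpha_floor)
        if (identical(st$psi, psi)) break
        psi <- st$psi
      }
      ev <- ts_eval(psi, prep)
      trace_ll <- c(trace_ll, ev$ll)
      n_iter <- it
      rel <- abs(ev$ll - trace_ll[length(trace_ll) - 1L]) /
        (abs(ev$ll) + 1e-12)
      if (rel < ctrl$ll_tol) break
    }
    ## Newton refinement of the final EM iterate on the observed
    ## loglik: lands on the exact optimum while keeping the trace
    ## monotone (guarded ascent steps never decrease the loglik)
    for (it in seq_len(ctrl$newton_max)) {
      gr <- ts_grad(ev$W - ev$P, prep)
      if (score_ok(gr, psi)) {
        converged <- TRUE
        break
      }
      info <- ts_blockinfo(ev$P, prep) - ts_blockinfo(ev$W, prep)
      d <- ts_dir(info, gr, free_idx(psi), ctrl$ridge)
      st <- ts_ascend(psi, d, llfun, ev$ll, ctrl$param_cap, ia_idx,
                      ctrl$alpha_floor)
      if (identical(st$psi, psi)) {
        ## observed information can be indefinite away from the optimum;
        ## retry along the PSD complete-data curvature (an EM-type step,
        ## guaranteed ascent), then try the boundary push
        d2 <- ts_dir(ts_blockinfo(ev$P, prep), gr, free_idx(psi), ctrl$ridge)
        st <- ts_ascend(psi, d2, llfun, ev$ll, ctrl$param_cap, ia_idx,
                        ctrl$alpha_floor)
        if (identical(st$psi, psi)) {
          cand <- ts_boundary_push(psi, ev, prep, llfun, ia_idx,
                                   ctrl$alpha_floor)
          if (is.null(cand)) break
          psi <- cand
        } else psi <- st$psi
      } else psi <- st$psi
      ev <- ts_eval(psi, prep)
      trace_ll <- c(trace_ll, ev$ll)
    }
  } else {
    ## a few EM warm-up sweeps stabilize Newton far from the optimum
    for (it in seq_len(ctrl$em_warmup)) {
      W <- ev$W
      qq_info <- ts_blockinfo(ev$P, prep)
      d <- ts_dir(qq_info, ts_grad(W - ev$P, prep), free_idx(psi), ctrl$ridge)
      st <- ts_ascend(psi, d, llfun, ev$ll, ctrl$param_cap, ia_idx,
                      ctrl$alpha_floor)
      psi <- st$psi
      ev <- ts_eval(psi, prep)
      trace_ll <- c(trace_ll, ev$ll)
    }
    for (it in seq_len(ctrl$newton_max)) {
      gr <- ts_grad(ev$W - ev$P, prep)
      info <- ts_blockinfo(ev$P, prep) - ts_blockinfo(ev$W, prep)
      d <- ts_dir(info, gr, free_idx(psi), ctrl$ridge)
      st <- ts_ascend(psi, d, llfun, ev$ll, ctrl$param_cap, ia_idx,
                      ctrl$alpha_floor)
      n_iter <- it
      if (identical(st$psi, psi)) {
        ## observed information can be indefinite away from the optimum;
        ## retry along the PSD complete-data curvature (an EM-type step,
        ## guaranteed ascent), then try the boundary push
        d2 <- ts_dir(ts_blockinfo(ev$P, prep), gr, free_idx(psi), ctrl$ridge)
        st <- ts_ascend(psi, d2, llfun, ev$ll, ctrl$param_cap, ia_idx,
                        ctrl$alpha_floor)
        if (identical(st$psi, psi)) {
          cand <- ts_boundary_push(psi, ev, prep, llfun, ia_idx,
                                   ctrl$alpha_floor)
          if (is.null(cand)) break
          psi <- cand
        } else psi <- st$psi
      } else psi <- st$psi
      ev <- ts_eval(psi, prep)
      trace_ll <- c(trace_ll, ev$ll)
      rel <- abs(ev$ll - trace_ll[length(trace_ll) - 1L]) /
        (abs(ev$ll) + 1e-12)
      gr <- ts_grad(ev$W - ev$P, prep)
      if (rel < ctrl$ll_tol && score_ok(gr, psi)) {
        converged <- TRUE
        break
      }
    }
  }

  if (max(abs(psi[-ia_idx])) >= ctrl$param_cap - 1e-6)
    stop("parameter norm divergence (possible separation / unbounded likelihood)")

  ## observed information of the observed-data log-likelihood.  A
  ## non-positive-definite information (flat ridge or saddle, e.g. all
  ## cases missing the marker a contrast needs) is reported, and the
  ## corresponding directions get deliberately inflated variances.
  info <- ts_blockinfo(ev$P, prep) - ts_blockinfo(ev$W, prep)
  ## boundary intercepts and intercepts of cells with negligible
  ## posterior case mass carry no meaningful curvature: the likelihood
  ## is flat there and their second derivatives are numerical noise
  mass <- colSums(ev$W)
  fri <- setdiff(free_idx(psi), ia_idx[mass < 0.5])
  info_f <- info[fri, fri, drop = FALSE]
  ei <- eigen((info_f + t(info_f)) / 2, symmetric = TRUE)
  emax <- max(ei$values, 1e-12)
  ## negative curvature = saddle or ridge: contrasts the data cannot
  ## separate (e.g. a grade model with no observed grades).  Tiny
  ## positive eigenvalues from near-empty cells are legitimate boundary
  ## behavior and only inflate those cells' own intercept variances.
  singular_info <- min(ei$values) < -emax * 1e-6
  if (singular_info) {
    warning("observed information is not positive definite at the solution; ",
            "some parameters are weakly identified and their standard ",
            "errors are inflated")
    converged <- FALSE
  }
  cov_all <- matrix(0, length(psi), length(psi))
  cov_all[fri, fri] <- ei$vectors %*% (t(ei$vectors) /
                                         pmax(ei$values, emax * 1e-12))
  it_theta <- M + seq_len(p)
  cov_theta_r <- cov_all[it_theta, it_theta, drop = FALSE]

  ## re-expand to the full design dimension
  p_full <- ncol(A_full)
  theta <- rep(NA_real_, p_full)
  theta[keep_par] <- psi[M + seq_len(p)]
  cov_theta <- matrix(NA_real_, p_full, p_full)
  cov_theta[keep_par, keep_par] <- cov_theta_r
  alpha <- rep(-Inf, M_full)
  alpha[reach] <- psi[seq_len(M)]
  beta <- rep(NA_real_, M_full)
  beta[reach] <- drop(A %*% psi[M + seq_len(p)])
  names(theta) <- labels
  dimnames(cov_theta) <- list(labels, labels)

  structure(list(
    alpha = alpha, theta = theta,
    xi = if (q > 0) psi[M + p + seq_len(q)] else numeric(0),
    beta = beta, cov_theta = cov_theta,
    se_theta = sqrt(pmax(diag(cov_theta), 0)),
    loglik = ev$ll, trace = trace_ll, n_iter = n_iter,
    converged = converged, method = method,
    reachable = reach, dropped_par = dropped_par,
    singular_info = singular_info,
    n = n, n_cases = sum(is_case), n_controls = sum(!is_case),
    labels = labels, cell_labels = cell_labels),
    class = "twostage_fit")
}

#' Fit the two-stage polytomous model
#'
#' First stage: multinomial logistic model of case cell membership
#' versus controls, with one intercept per cell and covariates entering
#' as a common shift.  Second stage: the per-cell genotype log odds
#' ratios are constrained to `beta = A theta` for the chosen design.
#' Cases with missing tumor markers contribute through the observed-data
#' likelihood, summed over all cells consistent with their observed
#' pattern (markers missing at random).
#'
#' @param status 0 = control, 1 = case.
#' @param g per-subject genotype dosage in \[0, 2\].
#' @param markers data.frame with one column per schema marker
#'   (ER/PR/HER2 in {0,1}, grade in {1,2,3} for the default schema);
#'   `NA` = missing.  Ignored for control rows.
#' @param x optional covariate matrix (e.g. ancestry PCs).
#' @param design a [second_stage_design()] or its kind string.
#' @param schema a [marker_schema()].
#' @param method `"direct"` (safeguarded Newton on the observed-data
#'   log-likelihood, the default) or `"EM"` (expectation-maximization
#'   over cell membership; slower, monotone in the log-likelihood).
#' @param control list overriding convergence settings: `ll_tol`
#'   (relative log-likelihood change, 1e-8), `score_tol` (max
#'   per-subject score, 1e-5), `em_max_iter` (500), `newton_max` (100).
#' @return object of class `twostage_fit` with elements `alpha`
#'   (per-cell intercepts; `-Inf` for cells no case pattern reaches),
#'   `theta` (second-stage parameters), `xi`, `beta = A theta`,
#'   `cov_theta`, `se_theta`, `loglik`, `trace` (log-likelihood per
#'   iteration), `n_iter`, `converged`, `method`.
#' @examples
#' sim <- simulate_cohort(simulation_config(n_cases = 400, n_controls = 400,
#'   n_strata = 1, n_pcs = 0, seed = 1))
#' f <- fit_twostage(sim$phenotypes$status, sim$dosages[1, ],
#'                   sim$phenotypes, design = "main_effects")
#' f$theta
#' @export
fit_twostage <- function(status, g, markers, x = NULL,
                         design = "main_effects",
                         schema = default_schema(),
                         method = c("direct", "EM"), control = list()) {
  method <- match.arg(method)
  status <- as.integer(status)
  stopifnot(all(status %in% 0:1), length(g) == length(status))
  if (any(!is.finite(g)) || any(g < 0 | g > 2))
    stop("dosages must be finite and in [0, 2]")
  if (stats::var(g) == 0) stop("no genotype variation")
  if (is.character(design))
    design <- second_stage_design(enumerate_cells(schema), design, schema)
  stopifnot(inherits(design, "second_stage_design"))
  X <- if (is.null(x)) NULL else as.matrix(x)
  Cmask <- ts_case_mask(status, markers, schema)
  cells <- enumerate_cells(schema)
  fit <- ts_fit_core(status, g, X, Cmask, design$A, design$labels,
                     method = method, control = control,
                     cell_labels = paste0("cell", cells$cell_id))
  fit$design_kind <- design$kind
  fit$design <- design
  fit$schema <- schema
  fit
}

#' Complete-case standard polytomous fit
#'
#' Sensitivity-analysis companion to [fit_twostage()]: cases are
#' assigned to a category only when their observed markers determine it
#' uniquely; all other cases are dropped, and a standard multinomial
#' logistic model (categories vs controls) is fitted with one intercept
#' and one genotype log OR per category.
#'
#' @inheritParams fit_twostage
#' @param categories `"intrinsic5"` (the five intrinsic-like subtypes)
#'   or `"cells"` (the 24 fully-observed cells).
#' @return `twostage_fit` with extra fields `n_dropped` (ambiguous
#'   cases removed) and `categories`.
#' @export
fit_complete_case_polytomous <- function(status, g, markers, x = NULL,
                                         categories = c("intrinsic5", "cells"),
                                         schema = default_schema(),
                                         control = list()) {
  categories <- match.arg(categories)
  status <- as.integer(status)
  mk <- names(schema$markers)
  mm <- markers[, mk, drop = FALSE]
  n <- length(status)
  if (categories == "cells") {
    Cfull <- ts_case_mask(status, markers, schema)
    uniq <- rowSums(Cfull) == 1
    keep <- status == 0L | (status == 1L & uniq)
    Cmask <- Cfull[keep, , drop = FALSE]
    labs <- paste0("cell", enumerate_cells(schema)$cell_id)
  } else {
    if (!is_default_schema(schema))
      stop("intrinsic5 categories need the default schema")
    sub <- rep(NA_character_, n)
    ic <- which(status == 1L)
    sets <- lapply(ic, function(i)
      consistent_intrinsic(stats::setNames(as.list(mm[i, ]), mk), schema))
    ok <- lengths(sets) == 1L
    sub[ic[ok]] <- unlist(sets[ok])
    keep <- status == 0L | !is.na(sub)
    labs <- intrinsic_subtypes()
    Cmask <- matrix(0, sum(keep), 5L)
    si <- match(sub[keep], labs)
    case_rows <- which(status[keep] == 1L)
    Cmask[cbind(case_rows, si[case_rows])] <- 1
  }
  n_dropped <- sum(status == 1L) - sum(status[keep] == 1L)
  empty <- colSums(Cmask) == 0 & seq_len(ncol(Cmask)) > 0
  X <- if (is.null(x)) NULL else as.matrix(x)[keep, , drop = FALSE]
  fit <- ts_fit_core(status[keep], g[keep], X, Cmask,
                     A = diag(ncol(Cmask)), labels = labs,
                     method = "direct", control = control,
                     cell_labels = labs)
  fit$design_kind <- "saturated"
  fit$categories <- categories
  fit$n_dropped <- n_dropped
  if (any(!fit$reachable))
    warning("categories with no retained cases: ",
            paste(labs[!fit$reachable], collapse = ", "))
  fit
}

#' @export
print.twostage_fit <- function(x, ...) {
  cat(sprintf("two-stage polytomous fit (%s, %s): %d cases / %d controls\n",
              x$method, x$design_kind %||% "?", x$n_cases, x$n_controls))
  cat(sprintf("loglik %.4f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  tab <- data.frame(theta = x$theta, se = x$se_theta)
  print(round(tab, 4))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-cell log odds for one subject
#'
#' Linear predictors of the M tumor cells relative to the control
#' category: `alpha + (A theta) g + xi' x`.  Softmax over
#' (control, cells) gives the category probabilities.
#'
#' @param params list with `alpha` (length M), `theta`, optional `xi`.
#' @param g scalar dosage.
#' @param x covariate vector (NULL if no covariates).
#' @param design a [second_stage_design()].
#' @return numeric length-M vector.
#' @export
cell_logodds <- function(params, g, x = NULL, design) {
  beta <- drop(design$A %*% params$theta)
  eta <- params$alpha + beta * g
  if (!is.null(x) && length(params$xi %||% numeric(0)))
    eta <- eta + sum(params$xi * x)
  eta
}

#' Observed-data log-likelihood
#'
#' Controls contribute `log P(control)`; cases contribute the log of
#' the total probability of all cells consistent with their observed
#' marker pattern.
#'
#' @inheritParams fit_twostage
#' @param params list with `alpha`, `theta`, optional `xi`.
#' @return scalar log-likelihood.
#' @export
observed_loglik <- function(params, status, g, markers, x = NULL,
                            design, schema = default_schema()) {
  if (is.character(design))
    design <- second_stage_design(enumerate_cells(schema), design, schema)
  X <- if (is.null(x)) NULL else as.matrix(x)
  Cmask <- ts_case_mask(as.integer(status), markers, schema)
  q <- if (is.null(X)) 0L else ncol(X)
  prep <- list(g = g, X = X, Cmask = Cmask, A = design$A,
               is_case = as.integer(status) == 1L,
               M = ncol(Cmask), p = ncol(design$A), q = q)
  psi <- c(params$alpha, params$theta,
           if (q > 0) params$xi else NULL)
  ts_eval(psi, prep)$ll
}

#' E-step posterior cell weights for one case
#'
#' Posterior probability of each consistent cell for a case with a
#' partially observed pattern, given current parameters:
#' `w_m` proportional to `exp(eta_m)` over the consistent set.
#'
#' @inheritParams cell_logodds
#' @param pattern named marker values with `NA` for missing.
#' @param schema a [marker_schema()].
#' @return named numeric vector over consistent cells, summing to 1.
#' @export
estep_weights <- function(params, pattern, g, x = NULL, design,
                          schema = default_schema()) {
  ids <- consistent_cells(pattern, schema)
  if (!length(ids)) stop("pattern is consistent with no cell")
  eta <- cell_logodds(params, g, x, design)[ids + 1L]
  w <- exp(eta - max(eta))
  stats::setNames(w / sum(w), paste0("cell", ids))
}

#' Serialize a two-stage fit to JSON
#'
#' @param fit a `twostage_fit`.
#' @param path optional file; if NULL the JSON string is returned.
#' @return path (invisibly) or JSON string.
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(alpha = fit$alpha, theta = as.list(fit$theta),
              xi = fit$xi, beta = fit$beta,
              cov_theta = fit$cov_theta, loglik = fit$loglik,
              n_iter = fit$n_iter, converged = fit$converged,
              method = fit$method, design = fit$design_kind %||% NA)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
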