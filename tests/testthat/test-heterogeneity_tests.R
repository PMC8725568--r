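# hand-built fit object for arithmetic-level tests
fake_fit <- function(theta, se, kind = "main_effects",
                     labels = c("baseline", "ER", "PR", "HER2", "grade")) {
  V <- diag(se^2)
  dimnames(V) <- list(labels, labels)
  structure(list(theta = stats::setNames(theta, labels),
                 se_theta = stats::setNames(se, labels),
                 cov_theta = V, labels = labels, converged = TRUE,
                 design_kind = kind),
            class = "twostage_fit")
}

test_that("marker tests give Wald z and two-sided normal p", {
  f <- fake_fit(c(0, 0.1, 0, -0.2, 0.05), c(1, 0.05, 0.1, 0.1, 0.02))
  mt <- marker_tests(f)
  expect_equal(mt$marker, c("ER", "PR", "HER2", "grade"))
  expect_equal(mt$z[1], 2)
  expect_equal(mt$p[1], 0.04550026, tolerance = 1e-7)
  expect_equal(mt$z[2], 0)
  expect_equal(mt$p[2], 1)
  # independent normal-tail oracle by quadrature
  for (k in seq_len(4)) {
    tail_p <- 2 * stats::integrate(stats::dnorm, abs(mt$z[k]), Inf,
                                   rel.tol = 1e-12)$value
    expect_equal(mt$p[k], tail_p, tolerance = 1e-10)
  }
  # p monotone decreasing in |z|
  o <- order(abs(mt$z))
  expect_true(all(diff(mt$p[o]) <= 0))
  f2 <- fake_fit(rep(0, 5), rep(1, 5)); f2$converged <- FALSE
  expect_error(marker_tests(f2), "converge")
})

test_that("fixed global test is a df-4 Wald quadratic form", {
  f0 <- fake_fit(c(0.4, 0, 0, 0, 0), rep(1, 5))
  g0 <- global_test_fixed(f0)
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p_value, 1)

  f1 <- fake_fit(c(0, 1, 0, 0, 0), rep(1, 5))
  g1 <- global_test_fixed(f1)
  expect_equal(g1$statistic, 1)
  expect_equal(g1$p_value, stats::pchisq(1, 4, lower.tail = FALSE))
  expect_equal(g1$p_value, 0.9097959, tolerance = 1e-7)

  # invariance under marker reordering
  perm <- c(1, 3, 5, 2, 4)
  fp <- fake_fit(c(0, 0.3, -0.1, 0.2, 0.05)[perm],
                 c(1, 0.1, 0.2, 0.15, 0.05)[perm],
                 labels = c("baseline", "ER", "PR", "HER2", "grade")[perm])
  fo <- fake_fit(c(0, 0.3, -0.1, 0.2, 0.05), c(1, 0.1, 0.2, 0.15, 0.05))
  expect_equal(global_test_fixed(fp)$statistic,
               global_test_fixed(fo)$statistic, tolerance = 1e-12)
})

test_that("BH q-values reproduce the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.16 / 3, 0.5), tolerance = 1e-12)
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")

  # property: matches the closed-form step-up computation and never
  # drops below the raw p-value
  step_up <- function(p) {
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(31)
  for (r in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, step_up(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("fixed-effect meta-analysis matches inverse-variance arithmetic", {
  m <- meta_fixed(list(list(theta = 0.2, cov = 0.01),
                       list(theta = 0.4, cov = 0.04)))
  expect_equal(m$theta, 0.24, tolerance = 1e-12)
  expect_equal(drop(m$cov), 0.008, tolerance = 1e-12)

  # K identical strata shrink the covariance by exactly 1/K
  V <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
  th <- c(0.1, -0.3)
  for (K in c(2, 5)) {
    mk <- meta_fixed(rep(list(list(theta = th, cov = V)), K))
    expect_equal(mk$theta, th, tolerance = 1e-12)
    expect_equal(mk$cov, V / K, tolerance = 1e-12)
  }
  m1 <- meta_fixed(list(list(theta = th, cov = V)))
  expect_equal(m1$theta, th)
  expect_equal(m1$cov, V)

  # vector case against hand arithmetic
  V1 <- diag(c(0.01, 0.04)); V2 <- diag(c(0.02, 0.02))
  t1 <- c(0.1, 0.2); t2 <- c(0.3, -0.1)
  mh <- meta_fixed(list(list(theta = t1, cov = V1),
                        list(theta = t2, cov = V2)))
  W <- solve(V1) + solve(V2)
  expect_equal(mh$cov, solve(W), tolerance = 1e-12)
  expect_equal(mh$theta, drop(solve(W, solve(V1) %*% t1 + solve(V2) %*% t2)),
               tolerance = 1e-12)
  expect_error(meta_fixed(list(list(theta = 1, cov = 0))), "singular")
})

test_that("mixture and Monte Carlo p-values of the mixed test agree", {
  set.seed(77)
  for (r in 1:12) {
    A <- matrix(rnorm(16), 4)
    V <- crossprod(A) + diag(4) * runif(1, 0.2, 1)
    U <- drop(rnorm(4) %*% chol(V)) * runif(1, 0.5, 2)
    sc <- list(U = U, V = V)
    p1 <- global_test_mixed(sc, method = "mixture_chisq")$p_value
    p2 <- global_test_mixed(sc, method = "monte_carlo", n_mc = 2e5)$p_value
    expect_lt(abs(p1 - p2), 0.005)
  }
})

test_that("mixed-test statistic decomposes and scales additively over strata", {
  set.seed(5)
  A <- matrix(rnorm(16), 4); V <- crossprod(A) + diag(4)
  U <- c(1, -0.5, 0.3, 0.2)
  sc <- list(U = U, V = V)
  g1 <- global_test_mixed(sc)
  expect_equal(unname(sum(g1$components)), g1$statistic, tolerance = 1e-12)
  expect_gte(min(g1$lambda), 0)
  # single stratum: meta equals the plain test
  gm <- meta_global_mixed(list(sc))
  expect_equal(gm$statistic, g1$statistic, tolerance = 1e-12)
  expect_equal(gm$p_value, g1$p_value, tolerance = 1e-12)
  # duplicated stratum: scores and informations add, statistic doubles
  g2 <- meta_global_mixed(list(sc, sc))
  expect_equal(g2$statistic, 2 * g1$statistic, tolerance = 1e-10)
  bad <- list(U = stats::setNames(U, c("a", "b", "c", "d")), V = V)
  expect_error(meta_global_mixed(list(
    list(U = stats::setNames(U, c("ER", "PR", "HER2", "grade")), V = V), bad)),
    "parameterizations")
})

test_that("weighted chi-square tail probabilities match simulation", {
  lam <- c(1, 1, 0.35, 0.1)
  set.seed(123)
  Q <- colSums(lam * matrix(rchisq(4 * 4e5, df = 1), 4))
  for (q in c(2, 5, 9)) {
    p_imhof <- tumorHet:::imhof_pvalue(q, lam)
    expect_lt(abs(p_imhof - mean(Q >= q)), 0.003)
  }
  # saddlepoint continues the mixture into the far tail
  p_tail <- tumorHet:::saddlepoint_pvalue(60, lam)
  expect_lt(p_tail, 1e-9)
  expect_gt(p_tail, 0)
  # saddlepoint and Imhof agree where both are reliable
  for (q in c(6, 10, 16))
    expect_lt(abs(tumorHet:::saddlepoint_pvalue(q, lam) -
                  tumorHet:::imhof_pvalue(q, lam)) /
              tumorHet:::imhof_pvalue(q, lam), 0.05)
})

test_that("the null score has the right structure on cohort data", {
  sim <- small_cohort(seed = 13, n = 1200)
  sc <- global_score_null(sim$phenotypes$status, sim$dosages[1, ],
                          sim$phenotypes)
  expect_named(sc$U, c("ER", "PR", "HER2", "grade"))
  expect_equal(sc$V, t(sc$V), tolerance = 1e-10)
  expect_gt(min(eigen(sc$V, symmetric = TRUE, only.values = TRUE)$values), 0)
  gt <- global_test_mixed(sc)
  expect_gte(gt$statistic, 0)
  expect_true(gt$p_value >= 0 && gt$p_value <= 1)
  # constant dosage is refused
  expect_error(global_score_null(sim$phenotypes$status,
                                 rep(1, nrow(sim$phenotypes)),
                                 sim$phenotypes),
               "no genotype variation")
})

test_that("global tests gain power under pure ER heterogeneity", {
  nrep <- 40
  rej_m <- rej_f <- 0L
  pm_all <- pf_all <- rep(NA_real_, nrep)
  for (r in seq_len(nrep)) {
    cfg <- simulation_config(
      n_cases = 2500, n_controls = 2500, n_strata = 1, n_pcs = 0,
      variants = data.frame(maf = 0.25, theta1 = 0, theta2 = 0.15,
                            theta3 = 0, theta4 = 0, theta5 = 0),
      seed = 60000 + r)
    sim <- simulate_cohort(cfg)
    st <- sim$phenotypes$status
    g <- sim$dosages[1, ]
    sc <- tryCatch(global_score_null(st, g, sim$phenotypes),
                   error = function(e) NULL)
    if (!is.null(sc)) pm_all[r] <- global_test_mixed(sc)$p_value
    f <- tryCatch(fit_twostage(st, g, sim$phenotypes,
                               design = "main_effects"),
                  error = function(e) NULL)
    if (!is.null(f)) pf_all[r] <- global_test_fixed(f)$p_value
  }
  rej_m <- sum(pm_all < 0.05, na.rm = TRUE)
  rej_f <- sum(pf_all < 0.05, na.rm = TRUE)
  # both tests reject more often than their nominal size; the fixed
  # test has modest power at this effect (it spends df on all four
  # markers), so the sharper evidence of improvement over alpha is
  # Fisher's combination of the replicate p-values, which is uniform
  # under a null-behaved test
  fisher_p <- function(p) {
    p <- p[!is.na(p)]
    stats::pchisq(-2 * sum(log(p)), 2 * length(p), lower.tail = FALSE)
  }
  expect_gte(rej_m, 5L)
  expect_gte(rej_f, 3L)
  expect_lt(fisher_p(pm_all), 1e-4)
  expect_lt(fisher_p(pf_all), 0.01)
})
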