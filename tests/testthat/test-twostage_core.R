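cells24 <- enumerate_cells()
des_main <- second_stage_design(cells24, "main_effects")
des_sat <- second_stage_design(cells24, "saturated")

test_that("cell log-odds and softmax probabilities behave as documented", {
  p0 <- list(alpha = rep(0, 24), theta = rep(0, 5), xi = numeric(0))
  eta <- cell_logodds(p0, g = 1.3, design = des_main)
  expect_equal(eta, rep(0, 24))
  pr <- exp(c(0, eta)) / sum(exp(c(0, eta)))
  expect_equal(pr, rep(1 / 25, 25), tolerance = 1e-12)
  expect_equal(sum(pr), 1, tolerance = 1e-12)

  ps <- list(alpha = rnorm(24), theta = rnorm(24), xi = numeric(0))
  expect_equal(cell_logodds(ps, 1, design = des_sat),
               ps$alpha + ps$theta)
  # genotype term is linear in dosage
  pth <- list(alpha = rep(0, 24), theta = c(0.3, 0.1, -0.2, 0.05, 0.02),
              xi = numeric(0))
  expect_equal(cell_logodds(pth, 2, design = des_main),
               2 * cell_logodds(pth, 1, design = des_main))
})

test_that("observed log-likelihood handles controls, full and partial cases", {
  p0 <- list(alpha = rep(0, 24), theta = rep(0, 5))
  mk1 <- data.frame(ER = NA, PR = NA, HER2 = NA, grade = NA)
  # single control with flat parameters: log of the control probability 1/25
  expect_equal(
    observed_loglik(p0, status = 0, g = 1, markers = mk1, design = des_main),
    log(1 / 25))
  # fully observed case: standard polytomous term
  mk2 <- data.frame(ER = 1, PR = 0, HER2 = 0, grade = 2)
  expect_equal(
    observed_loglik(p0, status = 1, g = 0.5, markers = mk2, design = des_main),
    log(1 / 25))
  # permutation invariance
  sim <- small_cohort(seed = 4, n = 300)
  st <- sim$phenotypes$status
  pr <- list(alpha = rnorm(24, -2), theta = rnorm(5, 0, 0.1))
  ll1 <- observed_loglik(pr, st, sim$dosages[1, ], sim$phenotypes,
                         design = des_main)
  o <- sample(length(st))
  ll2 <- observed_loglik(pr, st[o], sim$dosages[1, o], sim$phenotypes[o, ],
                         design = des_main)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("E-step weights equal the brute-force posterior over consistent cells", {
  p0 <- list(alpha = rep(0, 24), theta = rep(0, 5))
  w <- estep_weights(p0, c(ER = 1), g = 1, design = des_main)
  expect_length(w, 12L)
  expect_equal(unname(w), rep(1 / 12, 12))
  w1 <- estep_weights(p0, c(ER = 0, PR = 1, HER2 = 1, grade = 2), g = 1,
                      design = des_main)
  expect_equal(unname(w1), 1)

  set.seed(99)
  pr <- list(alpha = rnorm(24, -1), theta = rnorm(5, 0, 0.3))
  for (pat in list(c(ER = 1, grade = 2), c(HER2 = 0), c(PR = 0, HER2 = 1))) {
    g <- runif(1, 0, 2)
    w <- estep_weights(pr, pat, g, design = des_main)
    ids <- consistent_cells(pat)
    eta <- pr$alpha + drop(des_main$A %*% pr$theta) * g
    brute <- exp(eta[ids + 1]) / sum(exp(eta[ids + 1]))
    expect_equal(unname(w), brute, tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("two-cell toy recovers the closed-form log odds ratios", {
  sch <- marker_schema(list(ER = c(0, 1)))
  status <- c(rep(0, 200), rep(1, 250))
  g <- c(rep(0, 100), rep(1, 100), rep(0, 50), rep(1, 100), rep(0, 50), rep(1, 50))
  mk <- data.frame(ER = c(rep(NA, 200), rep(0, 150), rep(1, 100)))
  sat2 <- second_stage_design(enumerate_cells(sch), "saturated", sch)
  f <- fit_twostage(status, g, mk, design = sat2, schema = sch)
  expect_equal(unname(f$theta), c(log(2), 0), tolerance = 1e-6)

  A2 <- structure(list(kind = "custom", A = matrix(c(1, 1, 0, 1), 2, 2),
                       labels = c("t1", "t2")), class = "second_stage_design")
  f2 <- fit_twostage(status, g, mk, design = A2, schema = sch)
  expect_equal(unname(f2$theta), c(log(2), -log(2)), tolerance = 1e-6)
  # reparametrized fits reach the same maximum
  expect_equal(f$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("EM and direct optimizers agree and EM is monotone", {
  for (sd in 1:3) {
    sim <- small_cohort(seed = sd, n = 2000)
    st <- sim$phenotypes$status
    g <- sim$dosages[1, ]
    fD <- fit_twostage(st, g, sim$phenotypes, design = "main_effects",
                       method = "direct")
    fE <- fit_twostage(st, g, sim$phenotypes, design = "main_effects",
                       method = "EM")
    expect_true(fD$converged)
    expect_true(fE$converged)
    expect_lt(max(abs(fD$theta - fE$theta)), 1e-5)
    expect_true(all(diff(fE$trace) > -1e-10))
    expect_equal(fD$loglik, fE$loglik, tolerance = 1e-7)
  }
})

test_that("saturated fit equals the independent multinomial MLE (complete data)", {
  sim <- small_cohort(seed = 11, n = 3000, missing = FALSE)
  st <- sim$phenotypes$status
  g <- sim$dosages[1, ]
  ci <- rep(NA_integer_, length(st))
  ci[st == 1] <- cell_index_of(sim$phenotypes[st == 1, ])
  cnt <- tabulate(ci, 24)
  keep <- st == 0 | cnt[ci] >= 10     # boundary (separated) cells excluded
  f <- fit_twostage(st[keep], g[keep], sim$phenotypes[keep, ],
                    design = "saturated")
  oracle <- poisson_multinom_betas(st[keep], g[keep], ci[keep])
  lev <- as.integer(names(oracle))
  expect_lt(max(abs(f$theta[lev] - unname(oracle))), 1e-6)
})

test_that("null simulation keeps estimates within 3 SE of zero", {
  sim <- small_cohort(seed = 5, n = 2000)
  f <- fit_twostage(sim$phenotypes$status, sim$dosages[1, ],
                    sim$phenotypes, design = "main_effects")
  expect_true(all(abs(f$theta) <= 3 * f$se_theta))
})

test_that("degenerate inputs are rejected with clear errors", {
  sim <- small_cohort(seed = 6, n = 200)
  st <- sim$phenotypes$status
  expect_error(fit_twostage(st, rep(1, length(st)), sim$phenotypes,
                            design = "main_effects"),
               "no genotype variation")
  expect_error(fit_twostage(st, rep(3, length(st)), sim$phenotypes,
                            design = "main_effects"),
               "\\[0, 2\\]")
})

test_that("complete-case fit reduces to the saturated fit without missingness", {
  sim <- small_cohort(seed = 7, n = 1500, missing = FALSE)
  st <- sim$phenotypes$status
  g <- sim$dosages[1, ]
  # rare cells can be empty at this n: the fit flags them and drops them
  suppressWarnings(
    fcc <- fit_complete_case_polytomous(st, g, sim$phenotypes,
                                        categories = "cells"))
  fem <- fit_twostage(st, g, sim$phenotypes, design = "saturated",
                      method = "EM")
  expect_equal(fcc$n_dropped, 0L)
  ok <- is.finite(fcc$theta) & is.finite(fem$theta)
  expect_lt(max(abs(fcc$theta[ok] - fem$theta[ok])), 1e-5)
})

test_that("complete-case drops exactly the subtype-ambiguous cases", {
  sim <- small_cohort(seed = 8, n = 1200)
  st <- sim$phenotypes$status
  fcc <- fit_complete_case_polytomous(st, sim$dosages[1, ], sim$phenotypes,
                                      categories = "intrinsic5")
  mk <- sim$phenotypes[st == 1, c("ER", "PR", "HER2", "grade")]
  amb <- sum(vapply(seq_len(nrow(mk)), function(i)
    length(consistent_intrinsic(as.list(mk[i, ]))) > 1L, TRUE))
  expect_equal(fcc$n_dropped, amb)
})

test_that("a two-stage fit serializes to JSON and back", {
  sim <- small_cohort(seed = 9, n = 600)
  f <- fit_twostage(sim$phenotypes$status, sim$dosages[1, ], sim$phenotypes,
                    design = "main_effects")
  js <- jsonlite::fromJSON(fit_to_json(f))
  expect_equal(unlist(js$theta), f$theta[is.finite(f$theta)], tolerance = 1e-12)
  expect_equal(js$loglik, f$loglik, tolerance = 1e-12)
  expect_true(js$converged)
})

test_that("analytic observed information matches numerical differentiation", {
  sim <- small_cohort(seed = 10, n = 400)
  st <- sim$phenotypes$status
  g <- sim$dosages[1, ]
  schema <- default_schema()
  des <- second_stage_design(enumerate_cells(), "main_effects")
  f <- fit_twostage(st, g, sim$phenotypes, design = "main_effects")
  Cmask <- tumorHet:::ts_case_mask(as.integer(st), sim$phenotypes, schema)
  reach <- f$reachable
  prep <- list(g = g, X = NULL, Cmask = Cmask[, reach, drop = FALSE],
               A = des$A[reach, , drop = FALSE], is_case = st == 1L,
               M = sum(reach), p = 5L, q = 0L)
  psi <- c(f$alpha[reach], f$theta)
  grad_at <- function(ps) {
    e <- tumorHet:::ts_eval(ps, prep)
    tumorHet:::ts_grad(e$W - e$P, prep)
  }
  ev <- tumorHet:::ts_eval(psi, prep)
  info <- tumorHet:::ts_blockinfo(ev$P, prep) -
    tumorHet:::ts_blockinfo(ev$W, prep)
  h <- 1e-5
  num <- matrix(NA_real_, length(psi), length(psi))
  for (j in seq_along(psi)) {
    e1 <- psi; e1[j] <- e1[j] + h
    e2 <- psi; e2[j] <- e2[j] - h
    num[, j] <- -(grad_at(e1) - grad_at(e2)) / (2 * h)
  }
  expect_lt(max(abs(info - (num + t(num)) / 2)), 1e-4 * max(abs(info)))
})
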