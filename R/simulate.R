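## ---------------------------------------------------------------------------
## Synthetic cohort generator: latent-Gaussian correlated tumor markers,
## Hardy-Weinberg genotypes, case genotypes tilted by the second-stage
## effects, ancestry-PC covariates, strata, and MAR masking of markers.
## ---------------------------------------------------------------------------

#' Default latent-Gaussian marker model
#'
#' Joint distribution of (ER, PR, HER2, grade) among cases: a 4-variate
#' standard normal latent vector is thresholded per marker (double
#' thresholds for grade).  Thresholds reproduce the reference marker
#' prevalences (ER+ 81\%, PR+ 68\%, HER2+ 17\%, grade 20/49/31) and the
#' latent correlation matrix is calibrated so the Pearson correlations
#' of the coded markers reproduce the reference values
#' (ER-PR 0.61, ER-HER2 -0.16, ER-grade -0.39) and the implied
#' intrinsic-like subtype shares (about 54/13/13/6/14) within
#' tolerance.
#'
#' @param prevalence named positive-marker prevalences for ER/PR/HER2.
#' @param grade_probs length-3 grade distribution.
#' @param latent_cor 4x4 positive-definite latent correlation matrix
#'   (order ER, PR, HER2, grade).
#' @return list of class `marker_model` (thresholds, grade cuts,
#'   correlation matrix).
#' @export
default_marker_model <- function(
    prevalence = c(ER = 0.81, PR = 0.68, HER2 = 0.17),
    grade_probs = c(0.20, 0.49, 0.31),
    latent_cor = NULL) {
  if (is.null(latent_cor)) {
    latent_cor <- matrix(c(
      1.0000, 0.8955, -0.2985, -0.6421,
      0.8955, 1.0000,  0.1373, -0.4730,
     -0.2985, 0.1373,  1.0000,  0.2576,
     -0.6421, -0.4730, 0.2576,  1.0000), 4, 4,
      dimnames = list(c("ER", "PR", "HER2", "grade"),
                      c("ER", "PR", "HER2", "grade")))
  }
  stopifnot(all(abs(grade_probs) <= 1), abs(sum(grade_probs) - 1) < 1e-8)
  ev <- eigen(latent_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("latent correlation matrix is not positive definite")
  structure(list(
    prevalence = prevalence,
    grade_probs = grade_probs,
    thresholds = qnorm(1 - prevalence),
    grade_cuts = qnorm(cumsum(grade_probs)[1:2]),
    latent_cor = latent_cor), class = "marker_model")
}

#' Simulate correlated tumor markers
#'
#' @param n number of cases.
#' @param model a [default_marker_model()].
#' @return data.frame(ER, PR, HER2, grade) of integer codes.
#' @export
simulate_markers <- function(n, model = default_marker_model()) {
  Z <- matrix(rnorm(n * 4L), n, 4L) %*% chol(model$latent_cor)
  data.frame(
    ER = as.integer(Z[, 1] > model$thresholds[1]),
    PR = as.integer(Z[, 2] > model$thresholds[2]),
    HER2 = as.integer(Z[, 3] > model$thresholds[3]),
    grade = findInterval(Z[, 4], model$grade_cuts) + 1L)
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' @param n number of subjects.
#' @param maf minor-allele frequency in (0, 0.5].
#' @param noise_sd if > 0, adds mean-preserving imputation-style noise
#'   (truncated normal) while keeping dosages in \[0, 2\].
#' @return numeric dosages.
#' @export
simulate_genotypes <- function(n, maf, noise_sd = 0) {
  stopifnot(maf > 0, maf <= 0.5)
  pr <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  g <- sample(0:2, n, replace = TRUE, prob = pr)
  if (noise_sd > 0)
    g <- pmin(2, pmax(0, g + rnorm(n, 0, noise_sd)))
  g
}

#' Simulation configuration
#'
#' Study conditions for a synthetic two-array case-control cohort.
#' Defaults mirror the reference study design: two strata (arrays),
#' correlated markers from [default_marker_model()], ten ancestry PCs,
#' and marker missingness rates (ER 0.19, PR 0.27, HER2 0.46,
#' grade 0.27) under MAR.
#'
#' @param n_cases,n_controls per-stratum counts.
#' @param n_strata number of strata (arrays).
#' @param variants data.frame with columns `maf` and `theta.*` columns
#'   (one per second-stage parameter of `design_kind`), or NULL for a
#'   single null variant with maf 0.25.
#' @param design_kind design on which `theta` is specified.
#' @param marker_model a [default_marker_model()].
#' @param missing_rates per-marker masking probabilities; set all to 0
#'   for complete data.
#' @param stratum_missing_shift additive logit shift of PR/HER2/grade
#'   missingness in strata beyond the first (MAR driver: stratum).
#' @param er_missing_shift additive logit shift of PR/HER2/grade
#'   missingness for cases whose ER is itself missing (MAR driver:
#'   ER observation indicator, never a masked value).
#' @param n_pcs ancestry PCs per subject (standard normal).
#' @param seed integer RNG seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 2500, n_controls = 2500,
                              n_strata = 2, variants = NULL,
                              design_kind = "main_effects",
                              marker_model = default_marker_model(),
                              missing_rates = c(ER = 0.19, PR = 0.27,
                                                HER2 = 0.46, grade = 0.27),
                              stratum_missing_shift = 0,
                              er_missing_shift = 0,
                              n_pcs = 10, seed = 1) {
  if (is.null(variants)) {
    p <- ncol(second_stage_design(enumerate_cells(), design_kind)$A)
    variants <- data.frame(maf = 0.25,
                           matrix(0, 1, p,
                                  dimnames = list(NULL, paste0("theta", seq_len(p)))))
  }
  stopifnot(all(variants$maf > 0 & variants$maf <= 0.5),
            all(missing_rates >= 0 & missing_rates < 1))
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_strata = n_strata, variants = variants,
                 design_kind = design_kind, marker_model = marker_model,
                 missing_rates = missing_rates,
                 stratum_missing_shift = stratum_missing_shift,
                 er_missing_shift = er_missing_shift,
                 n_pcs = n_pcs, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Mask tumor markers at random (MAR)
#'
#' Per-marker Bernoulli masking.  Rates may depend only on always
#' observed drivers: the stratum label and the ER observation
#' indicator (ER's own masking is drawn first and independently), so
#' the mechanism is missing-at-random by construction; a dependence on
#' the masked values themselves cannot be expressed.
#'
#' @param markers data.frame(ER, PR, HER2, grade).
#' @param rates named per-marker masking probabilities.
#' @param stratum optional integer stratum per row.
#' @param stratum_shift logit shift of PR/HER2/grade rates for strata
#'   beyond the first.
#' @param er_shift logit shift of PR/HER2/grade rates when ER is masked.
#' @return `markers` with masked entries set to NA.
#' @export
apply_mar <- function(markers, rates, stratum = NULL,
                      stratum_shift = 0, er_shift = 0) {
  stopifnot(all(rates >= 0 & rates < 1))
  n <- nrow(markers)
  out <- markers
  er_missing <- runif(n) < rates[["ER"]]
  out$ER[er_missing] <- NA
  shift <- rep(0, n)
  if (!is.null(stratum) && stratum_shift != 0)
    shift <- shift + stratum_shift * (as.integer(factor(stratum)) > 1L)
  if (er_shift != 0) shift <- shift + er_shift * er_missing
  for (mk in c("PR", "HER2", "grade")) {
    r <- rates[[mk]]
    pr <- if (r == 0) rep(0, n) else stats::plogis(stats::qlogis(r) + shift)
    out[[mk]][runif(n) < pr] <- NA
  }
  out
}

#' Simulate a case-control cohort with genotype effects
#'
#' Controls draw Hardy-Weinberg genotypes at each variant.  Cases first
#' draw a tumor cell from the marker model, then a genotype from the
#' tilted distribution `P(g | case, cell m) \%\propto\% f(g) exp(beta_m g)`
#' with `beta = A theta_true` (exact three-point enumeration).  PCs are
#' standard normal, markers are masked by [apply_mar()], and the truth
#' (theta, per-cell beta, subtype-collapsed log ORs) is recorded.
#'
#' @param config a [simulation_config()].
#' @return list of class `cohort_data`: `phenotypes` (data.frame with
#'   sample_id, status, stratum, ER, PR, HER2, grade, PC columns),
#'   `dosages` (variants x samples matrix), `variants`, `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cells <- enumerate_cells()
  des <- second_stage_design(cells, config$design_kind)
  nv <- nrow(config$variants)
  tcols <- grep("^theta", names(config$variants))
  Theta <- as.matrix(config$variants[, tcols, drop = FALSE])
  if (ncol(Theta) != ncol(des$A))
    stop(sprintf("variants must carry %d theta columns for design '%s'",
                 ncol(des$A), config$design_kind))
  Beta <- Theta %*% t(des$A)                     # nv x 24 true log ORs

  ph_list <- list(); dos <- NULL
  for (s in seq_len(config$n_strata)) {
    n1 <- config$n_cases; n0 <- config$n_controls
    mk <- simulate_markers(n1, config$marker_model)
    cell_idx <- ts_cell_index(mk, cells)
    G <- matrix(0, nv, n0 + n1)
    for (v in seq_len(nv)) {
      maf <- config$variants$maf[v]
      pr0 <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
      G[v, seq_len(n0)] <- sample(0:2, n0, TRUE, pr0)
      gcase <- integer(n1)
      for (m in unique(cell_idx)) {
        rows <- which(cell_idx == m)
        w <- pr0 * exp(Beta[v, m] * (0:2))
        gcase[rows] <- sample(0:2, length(rows), TRUE, w / sum(w))
      }
      G[v, n0 + seq_len(n1)] <- gcase
    }
    mk_obs <- apply_mar(mk, config$missing_rates,
                        stratum = rep(s, n1),
                        stratum_shift = config$stratum_missing_shift,
                        er_shift = config$er_missing_shift)
    ph <- data.frame(
      sample_id = sprintf("S%d_%05d", s, seq_len(n0 + n1)),
      status = rep(c(0L, 1L), c(n0, n1)),
      stratum = s,
      ER = c(rep(NA_integer_, n0), mk_obs$ER),
      PR = c(rep(NA_integer_, n0), mk_obs$PR),
      HER2 = c(rep(NA_integer_, n0), mk_obs$HER2),
      grade = c(rep(NA_integer_, n0), mk_obs$grade))
    if (config$n_pcs > 0) {
      pcs <- matrix(rnorm((n0 + n1) * config$n_pcs), n0 + n1)
      colnames(pcs) <- paste0("PC", seq_len(config$n_pcs))
      ph <- cbind(ph, pcs)
    }
    ph_list[[s]] <- ph
    dos <- cbind(dos, G)
  }
  phenotypes <- do.call(rbind, ph_list)
  rownames(phenotypes) <- NULL
  variant_id <- sprintf("var%03d", seq_len(nv))
  dimnames(dos) <- list(variant_id, phenotypes$sample_id)

  ## truth: per-subtype collapsed log OR = case-distribution-weighted
  ## mean of beta within subtype
  sub <- map_intrinsic(cells)
  cellp <- ts_cell_probs(config$marker_model)
  collapse <- t(vapply(seq_len(nv), function(v) {
    vapply(split(seq_len(24L), sub), function(ix)
      sum(Beta[v, ix] * cellp[ix]) / sum(cellp[ix]), 0)
  }, numeric(5L)))
  colnames(collapse) <- intrinsic_subtypes()

  structure(list(
    phenotypes = phenotypes,
    dosages = dos,
    variants = data.frame(variant_id = variant_id,
                          effect_allele = "A",
                          maf = config$variants$maf),
    truth = list(theta = Theta, beta = Beta,
                 subtype_logor = collapse,
                 design_kind = config$design_kind),
    pc_cols = if (config$n_pcs > 0) paste0("PC", seq_len(config$n_pcs))
              else character(0),
    config = config), class = "cohort_data")
}

## row -> cell index (1-based) for fully observed marker data.frames
ts_cell_index <- function(mk, cells = enumerate_cells()) {
  key <- paste(cells$ER, cells$PR, cells$HER2, cells$grade)
  match(paste(mk$ER, mk$PR, mk$HER2, mk$grade), key)
}

## implied cell probabilities of the latent marker model (monte carlo,
## fixed internal stream so results are reproducible but cheap)
ts_cell_probs_cache <- new.env(parent = emptyenv())

ts_cell_probs <- function(model, n = 2e5) {
  key <- paste(format(c(model$thresholds, model$grade_cuts,
                        model$latent_cor), digits = 12), collapse = "|")
  hit <- ts_cell_probs_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  st <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", st, envir = globalenv()))
  set.seed(20260920)
  mk <- simulate_markers(n, model)
  out <- tabulate(ts_cell_index(mk), 24L) / n
  ts_cell_probs_cache[[key]] <- out
  out
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (%d cases), %d strata, %d variant(s)\n",
              nrow(x$phenotypes), sum(x$phenotypes$status == 1L),
              length(unique(x$phenotypes$stratum)), nrow(x$dosages)))
  invisible(x)
}
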