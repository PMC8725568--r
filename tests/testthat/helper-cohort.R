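# small simulated cohorts used across tests

small_cohort <- function(seed = 1, n = 800, n_pcs = 0, theta = NULL,
                         missing = TRUE, maf = 0.25,
                         design_kind = "main_effects") {
  p <- ncol(tumorHet::second_stage_design(tumorHet::enumerate_cells(),
                                          design_kind)$A)
  if (is.null(theta)) theta <- rep(0, p)
  v <- data.frame(maf = maf)
  for (j in seq_len(p)) v[[paste0("theta", j)]] <- theta[j]
  rates <- if (missing) c(ER = 0.19, PR = 0.27, HER2 = 0.46, grade = 0.27)
           else c(ER = 0, PR = 0, HER2 = 0, grade = 0)
  tumorHet::simulate_cohort(tumorHet::simulation_config(
    n_cases = n / 2, n_controls = n / 2, n_strata = 1,
    variants = v, design_kind = design_kind,
    missing_rates = rates, n_pcs = n_pcs, seed = seed))
}

cohort_X <- function(sim) {
  if (length(sim$pc_cols))
    as.matrix(sim$phenotypes[, sim$pc_cols, drop = FALSE])
  else NULL
}

# independent multinomial-logistic oracle for the saturated model:
# Poisson log-linear equivalence fit (one Poisson count per
# category x dosage-level cell), slopes taken relative to controls
poisson_multinom_betas <- function(status, g, cell_index) {
  lab <- ifelse(status == 1L, sprintf("c%02d", cell_index), "a_ctrl")
  tab <- as.data.frame(table(cell = factor(lab), g = factor(g, levels = 0:2)))
  tab$gnum <- as.numeric(as.character(tab$g))
  gl <- stats::glm(Freq ~ g + cell + cell:gnum, family = stats::poisson,
                   data = tab, control = list(epsilon = 1e-12, maxit = 500))
  cf <- stats::coef(gl)
  cf[is.na(cf)] <- 0
  bn <- grep("^cellc[0-9]+:gnum$", names(cf), value = TRUE)
  stats::setNames(cf[bn] - cf["cella_ctrl:gnum"],
                  as.integer(substr(bn, 6, 7)))
}

# case rows -> 1-based cell index for fully observed markers
cell_index_of <- function(markers) {
  cells <- tumorHet::enumerate_cells()
  key <- paste(cells$ER, cells$PR, cells$HER2, cells$grade)
  match(paste(markers$ER, markers$PR, markers$HER2, markers$grade), key)
}
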