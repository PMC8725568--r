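## ---------------------------------------------------------------------------
## The per-variant screen: mixed-effect global test per stratum ->
## meta-analysis -> BH-FDR gate -> marker-specific tests and subtype ORs
## for significant variants -> grade ORs for grade-only variants ->
## |z| clustering and report rendering.
## ---------------------------------------------------------------------------

#' Run the variant heterogeneity screen
#'
#' For every variant: fits the null model per stratum, meta-analyzes
#' the mixed-effect global score test across strata, and adjusts the
#' global p-values by Benjamini-Hochberg across all screened variants.
#' For variants passing the FDR gate it fits the fixed-effect
#' main-effects model (marker-specific case-case tests, per stratum +
#' inverse-variance meta) and the intrinsic-like subtype model; for
#' variants whose only marker-specific signal (p < `marker_p`) is
#' grade, it additionally fits the by-grade model.  Variants failing to
#' converge in any stratum are reported with `NA` p-values and a
#' status note rather than aborting the screen.
#'
#' @param cohort a `cohort_data`.
#' @param fdr_alpha FDR threshold for the global gate (default 0.05).
#' @param marker_p marker-specific descriptive threshold (default 0.05).
#' @param p_method p-value evaluation for the mixed global test.
#' @param by_stratum analyze strata separately and meta-analyze
#'   (default); FALSE pools all subjects.
#' @param method optimizer passed to the fits.
#' @param control fit control list.
#' @return list of class `screen_result`: `screen` (the ScreenTable
#'   data.frame), `zmat` (|z|-clusterable marker z matrix for
#'   FDR-significant variants), `subtype_or`, `grade_or` (tidy OR
#'   tables), `thresholds`.
#' @export
run_screen <- function(cohort, fdr_alpha = 0.05, marker_p = 0.05,
                       p_method = c("mixture_chisq", "monte_carlo"),
                       by_stratum = TRUE, method = "direct",
                       control = list()) {
  p_method <- match.arg(p_method)
  stopifnot(inherits(cohort, "cohort_data"),
            fdr_alpha > 0, fdr_alpha < 1, marker_p > 0, marker_p < 1)
  ph <- cohort$phenotypes
  if (all(ph$status == 0L)) stop("all-control data")
  if (nrow(cohort$dosages) == 0L) stop("zero variants to screen")
  strata <- if (by_stratum) sort(unique(ph$stratum)) else "pooled"
  srows <- lapply(strata, function(s)
    if (identical(s, "pooled")) seq_len(nrow(ph)) else which(ph$stratum == s))
  X_of <- function(rows)
    if (length(cohort$pc_cols)) as.matrix(ph[rows, cohort$pc_cols, drop = FALSE])
    else NULL
  mk_of <- function(rows) ph[rows, c("ER", "PR", "HER2", "grade"), drop = FALSE]

  vids <- rownames(cohort$dosages)
  nv <- length(vids)
  markers4 <- c("ER", "PR", "HER2", "grade")
  p_global <- rep(NA_real_, nv)
  status_note <- rep("ok", nv)
  scores <- vector("list", nv)

  for (v in seq_len(nv)) {
    g <- cohort$dosages[v, ]
    sc <- tryCatch(
      lapply(srows, function(rows)
        global_score_null(ph$status[rows], g[rows], mk_of(rows),
                          X_of(rows), control = control)),
      error = function(e) e)
    if (inherits(sc, "error")) {
      status_note[v] <- conditionMessage(sc)
      next
    }
    scores[[v]] <- sc
    p_global[v] <- meta_global_mixed(sc, method = p_method)$p_value
  }
  q_global <- rep(NA_real_, nv)
  ok <- !is.na(p_global)
  q_global[ok] <- bh_fdr(p_global[ok])
  fdr_sig <- !is.na(q_global) & q_global < fdr_alpha

  ## model-2 style marker tests + subtype ORs for the significant set
  zp <- matrix(NA_real_, nv, 8,
               dimnames = list(vids, c(rbind(paste0("z_", markers4),
                                             paste0("p_", markers4)))))
  theta_cols <- list()
  sub_list <- list(); grade_list <- list()
  grade_only <- logical(nv)
  for (v in which(fdr_sig)) {
    g <- cohort$dosages[v, ]
    res <- tryCatch({
      ests <- lapply(srows, function(rows) {
        f <- fit_twostage(ph$status[rows], g[rows], mk_of(rows), X_of(rows),
                          design = "main_effects", method = method,
                          control = control)
        list(theta = f$theta, cov = f$cov_theta)
      })
      meta <- meta_fixed(ests)
      list(ests = ests, meta = meta)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status_note[v] <- conditionMessage(res)
      next
    }
    se <- sqrt(diag(res$meta$cov))
    z <- res$meta$theta / se
    pm <- 2 * pnorm(-abs(z))
    for (k in seq_along(markers4)) {
      zp[v, paste0("z_", markers4[k])] <- z[markers4[k]]
      zp[v, paste0("p_", markers4[k])] <- pm[markers4[k]]
    }
    row <- list()
    for (s in seq_along(strata))
      for (nm in names(res$meta$theta))
        row[[sprintf("theta_s%s_%s", strata[s], nm)]] <- res$ests[[s]]$theta[[nm]]
    for (nm in names(res$meta$theta))
      row[[paste0("theta_meta_", nm)]] <- res$meta$theta[[nm]]
    theta_cols[[vids[v]]] <- row
    sig_mk <- markers4[pm[markers4] < marker_p]
    grade_only[v] <- identical(sig_mk, "grade")

    sub <- tryCatch({
      ests <- lapply(srows, function(rows) {
        f <- fit_model_subtypes(ph$status[rows], g[rows], mk_of(rows),
                                X_of(rows), method = method,
                                control = control)$fit
        list(theta = f$theta, cov = f$cov_theta)
      })
      meta <- meta_fixed(ests)
      se <- sqrt(diag(meta$cov))
      cbind(data.frame(variant_id = vids[v],
                       category = names(meta$theta),
                       log_or = unname(meta$theta), se = unname(se)),
            or_ci(meta$theta, se),
            p = unname(2 * pnorm(-abs(meta$theta / se))))
    }, error = function(e) NULL)
    if (!is.null(sub)) sub_list[[vids[v]]] <- sub
  }
  for (v in which(grade_only)) {
    g <- cohort$dosages[v, ]
    gr <- tryCatch({
      ests <- lapply(srows, function(rows) {
        f <- fit_model_grade(ph$status[rows], g[rows], mk_of(rows),
                             X_of(rows), method = method,
                             control = control)$fit
        list(theta = f$theta, cov = f$cov_theta)
      })
      meta <- meta_fixed(ests)
      se <- sqrt(diag(meta$cov))
      cbind(data.frame(variant_id = vids[v],
                       category = names(meta$theta),
                       log_or = unname(meta$theta), se = unname(se)),
            or_ci(meta$theta, se),
            p = unname(2 * pnorm(-abs(meta$theta / se))))
    }, error = function(e) NULL)
    if (!is.null(gr)) grade_list[[vids[v]]] <- gr
  }

  screen <- data.frame(variant_id = vids,
                       effect_allele = cohort$variants$effect_allele,
                       p_global = p_global, q_global = q_global,
                       fdr_sig = fdr_sig, zp, grade_only = grade_only,
                       status = status_note, check.names = FALSE)
  tc_names <- unique(unlist(lapply(theta_cols, names)))
  for (nm in tc_names)
    screen[[nm]] <- vapply(vids, function(id)
      theta_cols[[id]][[nm]] %||% NA_real_, 0)
  zmat <- zp[fdr_sig, paste0("z_", markers4), drop = FALSE]
  colnames(zmat) <- markers4
  structure(list(screen = screen, zmat = zmat,
                 subtype_or = if (length(sub_list))
                   do.call(rbind, c(sub_list, make.row.names = FALSE)) else NULL,
                 grade_or = if (length(grade_list))
                   do.call(rbind, c(grade_list, make.row.names = FALSE)) else NULL,
                 thresholds = c(fdr_alpha = fdr_alpha, marker_p = marker_p),
                 strata = strata), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("variant screen: %d variants, %d FDR-significant (q < %s)\n",
              nrow(x$screen), sum(x$screen$fdr_sig),
              x$thresholds["fdr_alpha"]))
  invisible(x)
}

#' Summarize a screen
#'
#' Bookkeeping counts of the screening flow: how many variants showed
#' global heterogeneity at the FDR gate (and the percentage), how many
#' were attributed to each marker, and how many only to grade.
#'
#' @param x a `screen_result` or its `screen` data.frame.
#' @return list with `n_variants`, `n_heterogeneous`,
#'   `pct_heterogeneous` (1 decimal), per-marker counts, `n_grade_only`.
#' @export
screen_summary <- function(x) {
  sc <- if (inherits(x, "screen_result")) x$screen else x
  mk <- c("ER", "PR", "HER2", "grade")
  nsig <- sum(sc$fdr_sig, na.rm = TRUE)
  per <- vapply(mk, function(m)
    sum(sc$fdr_sig & sc[[paste0("p_", m)]] < 0.05, na.rm = TRUE), 0L)
  list(n_variants = nrow(sc), n_heterogeneous = nsig,
       pct_heterogeneous = round(100 * nsig / nrow(sc), 1),
       marker_counts = per,
       n_grade_only = sum(sc$grade_only, na.rm = TRUE))
}

#' Cluster a z-statistic matrix
#'
#' Hierarchical agglomerative clustering of variants (rows) and markers
#' or subtypes (columns) on Euclidean distances between absolute
#' z-statistics, as used to order the screen's heatmaps.  Sign-flipped
#' rows cluster identically since distances are computed on |z|.
#'
#' @param z numeric matrix (variants x markers/subtypes), finite.
#' @param linkage hclust agglomeration method (default "complete").
#' @return list: `row_order`, `col_order`, `row_hclust`, `col_hclust`
#'   (column entries NULL when fewer than 3 columns).
#' @export
cluster_zmatrix <- function(z, linkage = "complete") {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("need at least 2 rows to cluster")
  if (any(!is.finite(z))) stop("z matrix contains non-finite values")
  az <- abs(z)
  rh <- hclust(dist(az), method = linkage)
  if (ncol(z) >= 3L) {
    ch <- hclust(dist(t(az)), method = linkage)
    col_order <- ch$order
  } else {
    ch <- NULL
    col_order <- seq_len(ncol(z))
  }
  list(row_order = rh$order, col_order = col_order,
       row_hclust = rh, col_hclust = ch)
}

#' Write screen outputs and figures
#'
#' Writes the ScreenTable, subtype/grade OR tables and the clustered
#' z-matrix as TSV (the machine-readable contract), plus a clustered
#' signed-z heatmap (PNG) and per-variant forest plots of subtype ORs
#' on a log OR axis with a reference line at 1 (PDF).
#'
#' @param result a `screen_result`.
#' @param dir output directory.
#' @param linkage clustering linkage for the heatmap.
#' @return character vector of files written, invisibly.
#' @export
render_reports <- function(result, dir, linkage = "complete") {
  stopifnot(inherits(result, "screen_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "screen.tsv")
  write.table(result$screen, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  if (!is.null(result$zmat) && nrow(result$zmat) >= 2) {
    cl <- cluster_zmatrix(result$zmat, linkage)
    zo <- result$zmat[cl$row_order, cl$col_order, drop = FALSE]
    f <- file.path(dir, "zmatrix_clustered.tsv")
    write.table(data.frame(variant_id = rownames(zo), zo, check.names = FALSE),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "heatmap_z.png")
    grDevices::png(f, width = 900, height = 200 + 24 * nrow(zo))
    pheatmap::pheatmap(result$zmat,
                       cluster_rows = cl$row_hclust,
                       cluster_cols = if (is.null(cl$col_hclust)) FALSE
                                      else cl$col_hclust,
                       main = "case-case z statistics (clustered on |z|)")
    grDevices::dev.off()
    files <- c(files, f)
  }
  if (!is.null(result$subtype_or)) {
    f <- file.path(dir, "subtype_or.tsv")
    write.table(result$subtype_or, f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
    d <- result$subtype_or
    gp <- ggplot2::ggplot(d, ggplot2::aes(x = OR, y = category)) +
      ggplot2::geom_point() +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = lo, xmax = hi),
                              height = 0.2) +
      ggplot2::geom_vline(xintercept = 1, linetype = 2) +
      ggplot2::scale_x_log10() +
      ggplot2::facet_wrap(~variant_id) +
      ggplot2::labs(x = "odds ratio (log scale)", y = NULL)
    f <- file.path(dir, "forest_subtypes.pdf")
    ggplot2::ggsave(f, gp, width = 8,
                    height = 2 + 1.2 * ceiling(length(unique(d$variant_id)) / 3))
    files <- c(files, f)
  }
  if (!is.null(result$grade_or)) {
    f <- file.path(dir, "grade_or.tsv")
    write.table(result$grade_or, f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
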