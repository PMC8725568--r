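## ---------------------------------------------------------------------------
## File formats.  Phenotype TSV: sample_id, status, stratum, ER, PR, HER2,
## grade, PC columns; ER/PR/HER2 in {0,1}, grade in {1,2,3}, missing = NA
## or empty.  Dosage TSV: variant_id, effect_allele, then one column per
## sample with dosages in [0,2].  VCF: dosages in the DS FORMAT field.
## ---------------------------------------------------------------------------

#' Write a cohort to disk
#'
#' Writes `phenotypes.tsv`, `dosages.tsv` and (for simulated cohorts)
#' `truth.json` under `dir`.
#'
#' @param cohort a `cohort_data` (from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dos <- data.frame(variant_id = rownames(cohort$dosages),
                    effect_allele = cohort$variants$effect_allele,
                    cohort$dosages, check.names = FALSE)
  write.table(dos, file.path(dir, "dosages.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth)) {
    js <- jsonlite::toJSON(cohort$truth, auto_unbox = TRUE, digits = NA)
    writeLines(js, file.path(dir, "truth.json"))
  }
  invisible(dir)
}

#' Read a cohort from phenotype + genotype files
#'
#' Validates marker codes, dosage range and sample identity, and
#' returns the same `cohort_data` structure [simulate_cohort()]
#' produces.  Genotypes may be a dosage TSV or a VCF whose FORMAT
#' carries a `DS` field (requires the vcfR package).
#'
#' @param pheno_path phenotype TSV path.
#' @param geno_path dosage TSV or VCF path.
#' @param pc_cols covariate column names; by default every column
#'   matching `^PC`.
#' @return `cohort_data`.
#' @export
read_cohort <- function(pheno_path, geno_path,
                        pc_cols = NULL) {
  ph <- read.delim(pheno_path, sep = "\t", check.names = FALSE)
  need <- c("sample_id", "status", "stratum", "ER", "PR", "HER2", "grade")
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ph$sample_id))
    stop("duplicated sample IDs: ",
         paste(unique(ph$sample_id[duplicated(ph$sample_id)]), collapse = ", "))
  if (!all(ph$status %in% 0:1)) stop("status must be 0 (control) or 1 (case)")
  sch <- default_schema()
  for (mk in names(sch$markers)) {
    v <- ph[[mk]]
    bad <- which(!(is.na(v) | v %in% sch$markers[[mk]]))
    if (length(bad))
      stop(sprintf("invalid %s value '%s' in phenotype row %d",
                   mk, v[bad[1]], bad[1]))
  }
  if (is.null(pc_cols)) pc_cols <- grep("^PC", names(ph), value = TRUE)

  if (grepl("\\.vcf(\\.gz)?$", geno_path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF input requires the vcfR package")
    vc <- vcfR::read.vcfR(geno_path, verbose = FALSE)
    ds <- vcfR::extract.gt(vc, element = "DS", as.numeric = TRUE)
    dos <- t(t(ds))                       # variants x samples
    rownames(dos) <- vcfR::getID(vc)
    variants <- data.frame(variant_id = rownames(dos),
                           effect_allele = vcfR::getALT(vc))
  } else {
    gt <- read.delim(geno_path, sep = "\t", check.names = FALSE)
    if (!all(c("variant_id", "effect_allele") %in% names(gt)))
      stop("dosage file needs variant_id and effect_allele columns")
    dos <- as.matrix(gt[, setdiff(names(gt), c("variant_id", "effect_allele")),
                        drop = FALSE])
    rownames(dos) <- gt$variant_id
    variants <- data.frame(variant_id = gt$variant_id,
                           effect_allele = gt$effect_allele)
  }
  if (anyDuplicated(rownames(dos)))
    stop("duplicated variant IDs in genotype file")
  if (!all(ph$sample_id %in% colnames(dos)))
    stop("genotype file lacks sample(s): ",
         paste(utils::head(setdiff(ph$sample_id, colnames(dos)), 5),
               collapse = ", "))
  dos <- dos[, ph$sample_id, drop = FALSE]
  bad <- which(!is.finite(dos) | dos < 0 | dos > 2, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("dosage outside [0,2] for variant %s, sample %s",
                 rownames(dos)[bad[1, 1]], colnames(dos)[bad[1, 2]]))

  structure(list(phenotypes = ph, dosages = dos, variants = variants,
                 truth = NULL, pc_cols = pc_cols, config = NULL),
            class = "cohort_data")
}

#' Write dosages as a minimal VCF with a DS FORMAT field
#'
#' @param cohort a `cohort_data`.
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(cohort, path) {
  dos <- cohort$dosages
  samples <- colnames(dos)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(dos)), function(v) {
    paste(c("1", as.character(v), rownames(dos)[v], "G",
            cohort$variants$effect_allele[v], ".", "PASS", ".", "DS",
            formatC(dos[v, ], format = "g", digits = 8)), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Reference case marker distribution
#'
#' Aggregate counts of ER, PR, HER2, grade and intrinsic-like subtype
#' from a large published European-ancestry breast cancer case series;
#' these counts are the calibration targets of
#' [default_marker_model()] and the default missingness rates.
#'
#' @return data.frame(variable, level, count).
#' @export
reference_marker_counts <- function() {
  path <- system.file("extdata", "reference_case_marker_counts.tsv",
                      package = "tumorHet")
  read.delim(path, sep = "\t")
}

#' Percentages implied by a marker count table
#'
#' For each variable, computes each known level's percentage among
#' cases with that variable observed, plus the missing fraction among
#' all cases of the variable.
#'
#' @param counts data.frame(variable, level, count), levels including
#'   `"unknown"` rows for missing data (as from
#'   [reference_marker_counts()]).
#' @return data.frame(variable, level, count, pct, missing_fraction).
#' @export
marker_distribution_summary <- function(counts = reference_marker_counts()) {
  out <- do.call(rbind, lapply(split(counts, counts$variable), function(d) {
    known <- d$level != "unknown"
    tot_known <- sum(d$count[known])
    tot <- sum(d$count)
    data.frame(variable = d$variable, level = d$level, count = d$count,
               pct = ifelse(known, 100 * d$count / tot_known, NA_real_),
               missing_fraction = ifelse(known, NA_real_,
                                         d$count / tot))
  }))
  rownames(out) <- NULL
  out
}
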