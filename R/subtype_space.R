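#' Tumor-marker schema
#'
#' A marker schema lists the tumor markers that define the
#' cross-classification of case subtypes, together with the admissible
#' levels of each marker.  The default schema is the clinical one used
#' throughout the package: ER, PR and HER2 as binary markers coded
#' 0 (negative) / 1 (positive), and histologic grade as an ordinal
#' marker with levels 1, 2, 3.  Crossing the default levels yields
#' 2 x 2 x 2 x 3 = 24 tumor cells.
#'
#' @param markers named list of numeric level vectors, one per marker,
#'   in the order that defines the (lexicographic) cell enumeration.
#' @param ordinal logical vector flagging ordinal markers (same length
#'   and order as `markers`).
#' @return An object of class `marker_schema`.
#' @examples
#' sch <- default_schema()
#' nrow(enumerate_cells(sch))  # 24
#' @export
marker_schema <- function(markers, ordinal = NULL) {
  if (!is.list(markers) || is.null(names(markers)) ||
      anyDuplicated(names(markers)))
    stop("`markers` must be a named list with unique names")
  nl <- vapply(markers, length, 1L)
  if (any(nl < 2L))
    stop("every marker needs at least 2 levels: ",
         paste(names(markers)[nl < 2L], collapse = ", "))
  if (is.null(ordinal)) ordinal <- rep(FALSE, length(markers))
  stopifnot(length(ordinal) == length(markers))
  structure(list(markers = markers, ordinal = as.logical(ordinal)),
            class = "marker_schema")
}

#' @rdname marker_schema
#' @export
default_schema <- function() {
  marker_schema(
    markers = list(ER = c(0, 1), PR = c(0, 1), HER2 = c(0, 1),
                   grade = c(1, 2, 3)),
    ordinal = c(FALSE, FALSE, FALSE, TRUE))
}

is_default_schema <- function(schema) {
  identical(unclass(schema), unclass(default_schema()))
}

#' @export
print.marker_schema <- function(x, ...) {
  cat("marker schema:",
      paste(sprintf("%s{%s}", names(x$markers),
                    vapply(x$markers, function(l) paste(l, collapse = ","), "")),
            collapse = " x "),
      sprintf("-> %d cells\n", prod(vapply(x$markers, length, 1L))))
  invisible(x)
}

#' Enumerate tumor cells
#'
#' Enumerates every combination of marker levels (a "tumor cell") in
#' deterministic lexicographic order: the first marker of the schema is
#' the most significant digit, the last varies fastest, and levels are
#' taken in their stated order.  Cell ids run 0..M-1.
#'
#' @param schema a [marker_schema()].
#' @return data.frame with column `cell_id` followed by one column per
#'   marker, M rows.
#' @export
enumerate_cells <- function(schema = default_schema()) {
  stopifnot(inherits(schema, "marker_schema"))
  lv <- schema$markers
  g <- expand.grid(rev(lv), KEEP.OUT.ATTRS = FALSE)  # first arg fastest
  g <- g[, rev(seq_along(lv)), drop = FALSE]
  names(g) <- names(lv)
  cbind(cell_id = seq_len(nrow(g)) - 1L, g)
}

#' Cells consistent with a partially observed marker pattern
#'
#' A case whose tumor markers are incompletely assayed is compatible
#' with every cell that matches its observed values; missing markers
#' (NA) match any level.
#'
#' @param pattern named vector/list of marker values, `NA` = missing.
#'   Names must be schema markers; omitted markers count as missing.
#' @param schema a [marker_schema()].
#' @return integer vector of matching `cell_id`s (0-based).
#' @examples
#' consistent_cells(c(ER = 1), default_schema())  # the 12 ER+ cells
#' @export
consistent_cells <- function(pattern, schema = default_schema()) {
  cells <- enumerate_cells(schema)
  keep <- rep(TRUE, nrow(cells))
  pattern <- unlist(pattern)
  bad <- setdiff(names(pattern), names(schema$markers))
  if (length(bad)) stop("unknown marker(s): ", paste(bad, collapse = ", "))
  for (mk in names(pattern)) {
    v <- pattern[[mk]]
    if (is.na(v)) next
    if (!v %in% schema$markers[[mk]])
      stop(sprintf("value %s is not a level of marker %s", v, mk))
    keep <- keep & cells[[mk]] == v
  }
  cells$cell_id[keep]
}

#' Intrinsic-like subtype labels
#' @return character vector of the five labels in canonical order.
#' @export
intrinsic_subtypes <- function() {
  c("luminalA", "luminalB_HER2neg", "luminalB_HER2pos",
    "HER2pos_nonluminal", "triple_negative")
}

#' Map tumor cells to intrinsic-like subtypes
#'
#' The five clinical surrogate subtypes partition the 24 cells:
#' luminal A-like (ER+ and/or PR+, HER2-, grade 1 or 2; 6 cells),
#' luminal B-like/HER2-negative (ER+ and/or PR+, HER2-, grade 3; 3),
#' luminal B-like/HER2-positive (ER+ and/or PR+, HER2+, any grade; 9),
#' HER2-positive/non-luminal (ER- and PR-, HER2+; 3) and
#' triple-negative (ER-, PR-, HER2-; 3).
#'
#' @param cells data.frame from [enumerate_cells()] (default schema),
#'   or any data.frame with ER/PR/HER2/grade columns.
#' @return factor of subtype labels, one per row of `cells`.
#' @export
map_intrinsic <- function(cells = enumerate_cells()) {
  need <- c("ER", "PR", "HER2", "grade")
  if (!all(need %in% names(cells)))
    stop("intrinsic subtypes need the default ER/PR/HER2/grade schema")
  lum <- cells$ER == 1 | cells$PR == 1
  lab <- ifelse(lum & cells$HER2 == 0 & cells$grade <= 2, "luminalA",
         ifelse(lum & cells$HER2 == 0, "luminalB_HER2neg",
         ifelse(lum, "luminalB_HER2pos",
         ifelse(cells$HER2 == 1, "HER2pos_nonluminal", "triple_negative"))))
  factor(lab, levels = intrinsic_subtypes())
}

#' Intrinsic subtypes consistent with a partial pattern
#'
#' Union of [map_intrinsic()] over [consistent_cells()]; the set of
#' subtypes a case with incompletely observed markers could belong to.
#' Used by the complete-case sensitivity analysis, which keeps only
#' cases whose set is a singleton.
#'
#' @inheritParams consistent_cells
#' @return character vector of subtype labels.
#' @export
consistent_intrinsic <- function(pattern, schema = default_schema()) {
  if (!is_default_schema(schema))
    stop("intrinsic subtypes are defined for the default schema only")
  cells <- enumerate_cells(schema)
  ids <- consistent_cells(pattern, schema)
  sub <- map_intrinsic(cells)
  lv <- intrinsic_subtypes()
  lv[lv %in% unique(as.character(sub[cells$cell_id %in% ids]))]
}

#' Second-stage design matrix
#'
#' Maps the M per-cell genotype log odds ratios to a low-dimensional
#' parameter vector: `beta = A theta`.  Kinds:
#' \describe{
#'   \item{main_effects}{columns (baseline, ER, PR, HER2, grade) with
#'     binary markers coded 0/1 and grade coded 0/1/2 (grade 1 is the
#'     reference); theta[-1] are the marker-specific case-case
#'     parameters, mutually adjusted.}
#'   \item{subtype_indicators}{24 x 5 one-hot over intrinsic-like
#'     subtypes; theta are subtype-specific case-control log ORs.}
#'   \item{grade_indicators}{24 x 3 one-hot over grade; theta are
#'     grade-specific case-control log ORs.}
#'   \item{saturated}{identity; one free log OR per cell.}
#' }
#'
#' @param cells data.frame from [enumerate_cells()].
#' @param kind design kind (see above).
#' @param schema the schema `cells` came from.
#' @return object of class `second_stage_design`: list(kind, A, labels).
#' @export
second_stage_design <- function(cells = enumerate_cells(),
                                kind = c("main_effects",
                                         "subtype_indicators",
                                         "grade_indicators", "saturated"),
                                schema = default_schema()) {
  kind <- match.arg(kind)
  M <- nrow(cells)
  if (kind == "saturated") {
    A <- diag(M)
    labels <- paste0("cell", cells$cell_id)
  } else if (kind == "main_effects") {
    mk <- names(schema$markers)
    cols <- lapply(seq_along(mk), function(j) {
      lv <- schema$markers[[j]]
      # level index minus 1: binary neg=0/pos=1, grade 0/1/2
      match(cells[[mk[j]]], lv) - 1
    })
    A <- cbind(baseline = 1, do.call(cbind, cols))
    colnames(A) <- c("baseline", mk)
    labels <- colnames(A)
  } else if (kind == "subtype_indicators") {
    if (!is_default_schema(schema))
      stop("subtype_indicators requires the default schema")
    sub <- map_intrinsic(cells)
    A <- stats::model.matrix(~ sub - 1)
    colnames(A) <- levels(sub)
    labels <- levels(sub)
  } else { # grade_indicators
    if (!"grade" %in% names(cells)) stop("grade_indicators needs a grade marker")
    gr <- factor(cells$grade, levels = schema$markers$grade)
    A <- stats::model.matrix(~ gr - 1)
    colnames(A) <- paste0("grade", levels(gr))
    labels <- colnames(A)
  }
  A <- unname(cbind(A))
  dimnames(A) <- list(NULL, labels)
  structure(list(kind = kind, A = A, labels = labels),
            class = "second_stage_design")
}

#' @export
print.second_stage_design <- function(x, ...) {
  cat(sprintf("second-stage design '%s': %d cells -> %d parameters (%s)\n",
              x$kind, nrow(x$A), ncol(x$A), paste(x$labels, collapse = ", ")))
  invisible(x)
}
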