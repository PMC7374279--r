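#' Construct an expression study object
#'
#' Bundles one case-control expression dataset: a gene-by-sample matrix of
#' log2 intensities, per-sample group and sex labels, and study-level
#' metadata. This is the unit that the effect-size and mega-analysis stages
#' consume, one object per dataset.
#'
#' @param study_id Character scalar identifying the study (e.g. a GEO
#'   accession or a simulation label).
#' @param matrix Numeric matrix of log2 expression values, rows = genes
#'   (rownames required), columns = samples (colnames required).
#' @param groups Character or factor vector, one entry per column of
#'   `matrix`, each `"case"` or `"control"`.
#' @param sex Optional character vector per sample, values in
#'   `c("F", "M", "unknown")`. Defaults to `"unknown"`.
#' @param meta Named list of study-level metadata. Recognised fields:
#'   `country`, `year`, `tissue`. Counts `n_case`/`n_ctrl` are derived from
#'   `groups` and need not be supplied.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `study_id`, `matrix`, `groups`, `sex`, `meta` (with `n_case` and
#'   `n_ctrl` filled in).
#'
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("PPARA", "PPARD", "PPARG"), paste0("s", 1:4)))
#' st <- expression_study("demo", m, c("case", "case", "control", "control"))
#' st$meta$n_case
#' @export
expression_study <- function(study_id, matrix, groups, sex = NULL,
                             meta = list()) {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("`matrix` must have gene rownames and sample colnames", call. = FALSE)
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(matrix)) {
    stop("`groups` must have one label per sample column", call. = FALSE)
  }
  if (!all(groups %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  }
  if (is.null(sex)) sex <- rep("unknown", ncol(matrix))
  sex <- as.character(sex)
  if (length(sex) != ncol(matrix)) {
    stop("`sex` must have one label per sample column", call. = FALSE)
  }
  if (!all(sex %in% c("F", "M", "unknown"))) {
    stop("sex labels must be 'F', 'M' or 'unknown'", call. = FALSE)
  }
  if (any(apply(matrix, 1L, function(x) all(is.na(x))))) {
    stop("`matrix` contains gene rows that are entirely missing", call. = FALSE)
  }
  meta$n_case <- sum(groups == "case")
  meta$n_ctrl <- sum(groups == "control")
  structure(
    list(study_id = study_id, matrix = matrix, groups = groups,
         sex = sex, meta = meta),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s: %d genes x %d samples (%d case / %d control)\n",
              x$study_id, nrow(x$matrix), ncol(x$matrix),
              x$meta$n_case, x$meta$n_ctrl))
  extra <- x$meta[setdiff(names(x$meta), c("n_case", "n_ctrl"))]
  if (length(extra)) {
    cat("  meta:", paste(names(extra), unlist(extra), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}
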