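#' Read one expression study from disk
#'
#' Loads a gene-by-sample TSV matrix (first column = gene symbol, header =
#' sample ids) together with its sample sheet (columns `sample_id`,
#' `group`, optionally `sex`) and assembles an [expression_study()].
#' Matrix columns are reordered to sheet order; samples present in the
#' matrix but absent from the sheet are dropped with a message. Duplicate
#' gene rows are aggregated (mean by default) with a warning.
#'
#' @param matrix_path Path to the expression TSV.
#' @param sheet_path Path to the sample sheet TSV.
#' @param meta Named list of study metadata (`country`, `year`, `tissue`).
#' @param study_id Study identifier; defaults to the matrix file name.
#' @param dup_fun Aggregation for duplicated gene symbols: `"mean"`
#'   (default) or `"median"`.
#' @param log2_transform Apply [normalize_log2()] scale detection after
#'   reading (default `TRUE`).
#' @return An [expression_study()].
#' @export
read_study <- function(matrix_path, sheet_path, meta = list(),
                       study_id = NULL, dup_fun = c("mean", "median"),
                       log2_transform = TRUE) {
  dup_fun <- match.arg(dup_fun)
  if (is.null(study_id)) {
    study_id <- sub("\\.[^.]*$", "", basename(matrix_path))
  }
  tab <- readr::read_tsv(matrix_path, col_types = readr::cols(),
                         progress = FALSE)
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes

  if (anyDuplicated(genes)) {
    ndup <- sum(duplicated(genes))
    warning(ndup, " duplicated gene symbol(s) aggregated by ", dup_fun,
            call. = FALSE)
    f <- if (dup_fun == "mean") colMeans else
      function(x) apply(x, 2L, stats::median)
    m <- do.call(rbind, lapply(split(seq_along(genes), genes), function(ix) {
      if (length(ix) == 1L) m[ix, , drop = TRUE] else f(m[ix, , drop = FALSE])
    }))
    # split() orders by symbol; keep first-appearance order instead
    m <- m[unique(genes), , drop = FALSE]
  }

  sheet <- readr::read_tsv(sheet_path, col_types = readr::cols(),
                           progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    stop("sample sheet needs columns sample_id and group", call. = FALSE)
  }
  absent <- setdiff(sheet$sample_id, colnames(m))
  if (length(absent)) {
    stop("sample sheet references sample(s) missing from the matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  dropped <- setdiff(colnames(m), sheet$sample_id)
  if (length(dropped)) {
    message(length(dropped), " matrix sample(s) absent from the sheet ",
            "were dropped")
  }
  m <- m[, sheet$sample_id, drop = FALSE]
  if (log2_transform) m <- normalize_log2(m)
  if (!any(sheet$group == "case") || !any(sheet$group == "control")) {
    stop("study must contain both case and control samples", call. = FALSE)
  }
  sex <- if ("sex" %in% names(sheet)) sheet$sex else NULL
  expression_study(study_id, m, sheet$group, sex = sex, meta = meta)
}

#' Write an expression study to disk
#'
#' Inverse of [read_study()]: writes the matrix TSV (first column `gene`)
#' and the sample sheet TSV.
#'
#' @param study An [expression_study()].
#' @param matrix_path,sheet_path Output paths.
#' @return Invisibly, the study.
#' @export
write_study <- function(study, matrix_path, sheet_path) {
  stopifnot(inherits(study, "expression_study"))
  tab <- tibble::as_tibble(study$matrix, rownames = "gene")
  readr::write_tsv(tab, matrix_path, progress = FALSE)
  sheet <- tibble::tibble(sample_id = colnames(study$matrix),
                          group = study$groups, sex = study$sex)
  readr::write_tsv(sheet, sheet_path, progress = FALSE)
  invisible(study)
}

#' Detect linear-scale data and log2-transform if necessary
#'
#' Microarray matrices arrive either already log2-transformed (values
#' typically below ~20) or on the linear intensity scale (values in the
#' thousands). If the 99th percentile of the values exceeds `threshold`
#' the matrix is judged linear-scale and replaced by `log2(x + 1)`;
#' otherwise it is returned unchanged. The operation is idempotent: a
#' transformed matrix never re-triggers the heuristic.
#'
#' @param matrix Numeric matrix.
#' @param threshold Scale-detection cut on the 99th percentile
#'   (default 30; log2 intensities rarely exceed ~20).
#' @param quiet Suppress the transform message.
#' @return The matrix, on the log2 scale.
#' @export
normalize_log2 <- function(matrix, threshold = 30, quiet = TRUE) {
  q99 <- stats::quantile(matrix, 0.99, na.rm = TRUE, names = FALSE)
  if (is.na(q99) || q99 <= threshold) return(matrix)
  if (any(matrix < 0, na.rm = TRUE)) {
    stop("matrix judged linear-scale but contains negative values",
         call. = FALSE)
  }
  if (!quiet) message("matrix judged linear-scale; applying log2(x + 1)")
  log2(matrix + 1)
}

#' Quantile-normalise the columns of a matrix
#'
#' Optional pre-step replacing each column's values by the mean of the
#' column-wise order statistics, so every sample shares one empirical
#' distribution. Ties receive the mean of the reference values at their
#' tied positions. Off by default throughout the pipeline.
#'
#' @param matrix Numeric matrix without missing values.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(matrix) {
  if (anyNA(matrix)) stop("quantile normalisation requires complete data",
                          call. = FALSE)
  ref <- rowMeans(apply(matrix, 2L, sort))
  out <- apply(matrix, 2L, function(x) {
    r <- rank(x, ties.method = "average")
    stats::approx(seq_along(ref), ref, xout = r, rule = 2)$y
  })
  dimnames(out) <- dimnames(matrix)
  out
}
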