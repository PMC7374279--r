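#' Per-study log fold change and its variance
#'
#' The unit of meta-analytic pooling: for one gene in one study, the
#' case-minus-control difference of mean log2 expression (the log fold
#' change, LFC) together with the variance of that difference. The
#' default variance is the Welch (unpooled) form
#' \deqn{v = s_c^2 / n_c + s_k^2 / n_k}
#' with sample standard deviations (n - 1 denominator); a pooled-variance
#' alternative is available since the two are equivalent only at equal
#' group variances.
#'
#' Missing values are handled pairwise-complete per gene; the gene yields
#' a missing-effect record (all statistics `NA`) if fewer than 2
#' observations remain in either group, and likewise if the gene is
#' absent from the study, so a study can contribute to some genes only.
#'
#' @param study An [expression_study()].
#' @param gene Gene symbol.
#' @param variance `"welch"` (default) or `"pooled"`.
#' @return One-row tibble: `study_id`, `gene`, `lfc`, `var`, `se`,
#'   `n_case`, `n_ctrl`, `mean_case`, `sd_case`, `mean_ctrl`, `sd_ctrl`.
#' @examples
#' st <- simulate_expression_studies(sim_config(n_studies = 1, seed = 2))[[1]]
#' compute_study_effect(st, "PPARG")
#' @export
compute_study_effect <- function(study, gene,
                                 variance = c("welch", "pooled")) {
  variance <- match.arg(variance)
  stopifnot(inherits(study, "expression_study"))
  missing_row <- tibble::tibble(
    study_id = study$study_id, gene = gene, lfc = NA_real_,
    var = NA_real_, se = NA_real_, n_case = NA_integer_,
    n_ctrl = NA_integer_, mean_case = NA_real_, sd_case = NA_real_,
    mean_ctrl = NA_real_, sd_ctrl = NA_real_)
  if (!gene %in% rownames(study$matrix)) return(missing_row)
  x <- study$matrix[gene, study$groups == "case"]
  y <- study$matrix[gene, study$groups == "control"]
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nc <- length(x)
  nk <- length(y)
  if (nc < 2L || nk < 2L) return(missing_row)
  sc <- stats::sd(x)
  sk <- stats::sd(y)
  v <- if (variance == "welch") {
    sc^2 / nc + sk^2 / nk
  } else {
    sp2 <- ((nc - 1) * sc^2 + (nk - 1) * sk^2) / (nc + nk - 2)
    sp2 * (1 / nc + 1 / nk)
  }
  tibble::tibble(
    study_id = study$study_id, gene = gene, lfc = mean(x) - mean(y),
    var = v, se = sqrt(v), n_case = nc, n_ctrl = nk,
    mean_case = mean(x), sd_case = sc, mean_ctrl = mean(y), sd_ctrl = sk)
}

#' Effect table over studies and genes
#'
#' Applies [compute_study_effect()] to every (study, gene) pair. Genes a
#' study cannot contribute to appear as missing-effect rows (statistics
#' `NA`) so the per-gene count of contributing studies is visible.
#'
#' @param studies List of [expression_study()] objects.
#' @param genes Character vector of gene symbols; defaults to the union of
#'   gene names across studies.
#' @inheritParams compute_study_effect
#' @return A tibble, one row per (study, gene).
#' @export
effect_table <- function(studies, genes = NULL,
                         variance = c("welch", "pooled")) {
  variance <- match.arg(variance)
  if (length(studies) == 0L) {
    return(tibble::tibble(
      study_id = character(), gene = character(), lfc = double(),
      var = double(), se = double(), n_case = integer(),
      n_ctrl = integer(), mean_case = double(), sd_case = double(),
      mean_ctrl = double(), sd_ctrl = double()))
  }
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(studies, function(s) rownames(s$matrix))))
  }
  dplyr::bind_rows(lapply(studies, function(s) {
    dplyr::bind_rows(lapply(genes, function(g) {
      compute_study_effect(s, g, variance = variance)
    }))
  }))
}
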