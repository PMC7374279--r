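#' Fixed-effect inverse-variance pooling
#'
#' Pools per-study effects under the fixed-effect model (FEM): with
#' weights \eqn{w_i = 1/v_i}, the pooled effect is
#' \eqn{\hat\theta = \sum w_i y_i / \sum w_i} with variance
#' \eqn{1/\sum w_i}. Reported weights are normalised to sum to 1.
#'
#' @param y Per-study effect sizes (log2 fold changes).
#' @param v Per-study variances, all `> 0`.
#' @return List with `pooled`, `var`, `weights` (normalised).
#' @export
fixed_effect_pool <- function(y, v) {
  check_yv(y, v)
  w <- 1 / v
  list(pooled = sum(w * y) / sum(w), var = 1 / sum(w),
       weights = w / sum(w))
}

#' Cochran's Q heterogeneity statistics
#'
#' Computes \eqn{Q = \sum w_i (y_i - \hat\theta_{FEM})^2} with FEM weights
#' \eqn{w_i = 1/v_i}, its degrees of freedom \eqn{df = k - 1}, the
#' between-study variance share
#' \eqn{I^2 = 100\,(Q - df)/Q}, clamped to 0 whenever \eqn{Q \le df},
#' and the upper-tail chi-square probability of Q on df degrees of
#' freedom (`p_Q`, the probability that the observed variance is
#' explained by within-study variance alone).
#'
#' A single study is handled by convention: `Q = 0`, `df = 0`, `ISq = 0`,
#' `p_Q = 1`.
#'
#' @inheritParams fixed_effect_pool
#' @return List with `Q`, `df`, `ISq` (percent in [0, 100)), `p_Q`.
#' @export
heterogeneity <- function(y, v) {
  check_yv(y, v)
  k <- length(y)
  if (k == 1L) return(list(Q = 0, df = 0L, ISq = 0, p_Q = 1))
  w <- 1 / v
  pooled <- sum(w * y) / sum(w)
  Q <- sum(w * (y - pooled)^2)
  df <- k - 1L
  ISq <- if (Q <= df) 0 else 100 * (Q - df) / Q
  list(Q = Q, df = df, ISq = ISq,
       p_Q = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Random-effects pooling (DerSimonian-Laird)
#'
#' Estimates the between-study variance by the DerSimonian-Laird moment
#' estimator
#' \deqn{\hat\tau^2 = \max\left(0,\; \frac{Q - df}
#'   {\sum w_i - \sum w_i^2 / \sum w_i}\right)}
#' with FEM weights \eqn{w_i = 1/v_i}, then pools with the augmented
#' weights \eqn{w_i^* = 1/(v_i + \hat\tau^2)}. When \eqn{Q \le df} the
#' estimate is 0 and the result coincides exactly with the fixed-effect
#' pool.
#'
#' @inheritParams fixed_effect_pool
#' @return List with `pooled`, `var`, `tau2`, `weights` (normalised).
#' @export
random_effects_pool <- function(y, v) {
  check_yv(y, v)
  het <- heterogeneity(y, v)
  w <- 1 / v
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (length(y) == 1L || denom <= 0) 0 else {
    max(0, (het$Q - het$df) / denom)
  }
  ws <- 1 / (v + tau2)
  list(pooled = sum(ws * y) / sum(ws), var = 1 / sum(ws), tau2 = tau2,
       weights = ws / sum(ws))
}

#' Mega-analysis of one gene across studies
#'
#' The pooling stage of a mega-analysis — meta-analysis in which effect
#' sizes are recomputed from the original expression matrices rather than
#' taken from published results. Computes the fixed-effect pool and the
#' heterogeneity statistics, then applies the model-selection rule: when
#' the total variance Q is at most its expectation under homogeneity
#' (df), I-squared is clamped to 0 and the fixed-effect model is
#' selected; otherwise the DerSimonian-Laird random-effects model is
#' used. The pooled effect is tested against 0 with a two-sided normal
#' (Wald) test and reported with a 95% CI `pooled +/- 1.96 se`.
#'
#' @param effects Either a tibble with columns `lfc` and `var` (rows with
#'   `NA` effect are dropped, as from [effect_table()]), or a numeric
#'   vector of effects with `v` supplied separately.
#' @param v Per-study variances when `effects` is a numeric vector.
#' @param gene Optional gene label for the result row.
#' @return A one-row tibble of class `mega_result`: `gene`, `k`, `model`
#'   (`"FEM"` or `"REM"`), `pooled_lfc`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, `Q`, `df`, `ISq`, `p_Q`, `tau2`, plus the per-study
#'   normalised `weights` and inputs in the attribute `"studies"`.
#' @examples
#' mega_analyze(c(0.5, 1.0), v = c(0.1, 0.1))
#' @export
mega_analyze <- function(effects, v = NULL, gene = NA_character_) {
  if (is.data.frame(effects)) {
    eff <- effects[!is.na(effects$lfc), , drop = FALSE]
    y <- eff$lfc
    vv <- eff$var
    ids <- if ("study_id" %in% names(eff)) eff$study_id else
      as.character(seq_along(y))
    if (is.na(gene) && "gene" %in% names(eff) && nrow(eff) > 0L) {
      gene <- eff$gene[1L]
    }
  } else {
    y <- effects
    vv <- v
    ids <- as.character(seq_along(y))
  }
  check_yv(y, vv)
  fem <- fixed_effect_pool(y, vv)
  het <- heterogeneity(y, vv)
  use_rem <- het$Q > het$df
  if (use_rem) {
    rem <- random_effects_pool(y, vv)
    pooled <- rem$pooled; pv <- rem$var; tau2 <- rem$tau2; wts <- rem$weights
  } else {
    pooled <- fem$pooled; pv <- fem$var; tau2 <- 0; wts <- fem$weights
  }
  se <- sqrt(pv)
  out <- tibble::tibble(
    gene = gene, k = length(y), model = if (use_rem) "REM" else "FEM",
    pooled_lfc = pooled, se = se,
    ci_low = pooled - 1.96 * se, ci_high = pooled + 1.96 * se,
    p_value = 2 * stats::pnorm(abs(pooled) / se, lower.tail = FALSE),
    Q = het$Q, df = het$df, ISq = het$ISq, p_Q = het$p_Q, tau2 = tau2)
  attr(out, "studies") <- tibble::tibble(study_id = ids, lfc = y, var = vv,
                                         weight = wts)
  class(out) <- c("mega_result", class(out))
  out
}

#' Forest-plot data for a mega-analysis
#'
#' Per-study effect sizes with 95% CIs (`y_i +/- 1.96 sqrt(v_i)`) and the
#' normalised weights of the selected model, followed by the pooled
#' summary row — the numbers a forest plot displays.
#'
#' @param result A [mega_analyze()] result.
#' @return A tibble with columns `study_id`, `lfc`, `ci_low`, `ci_high`,
#'   `weight`, `is_summary`.
#' @export
forest_data <- function(result) {
  stopifnot(inherits(result, "mega_result"))
  st <- attr(result, "studies")
  per_study <- tibble::tibble(
    study_id = st$study_id, lfc = st$lfc,
    ci_low = st$lfc - 1.96 * sqrt(st$var),
    ci_high = st$lfc + 1.96 * sqrt(st$var),
    weight = st$weight, is_summary = FALSE)
  summary_row <- tibble::tibble(
    study_id = paste0("Pooled (", result$model, ")"),
    lfc = result$pooled_lfc, ci_low = result$ci_low,
    ci_high = result$ci_high, weight = 1, is_summary = TRUE)
  dplyr::bind_rows(per_study, summary_row)
}

#' Mega-analysis over an effect table
#'
#' Convenience wrapper running [mega_analyze()] gene by gene over the
#' output of [effect_table()].
#'
#' @param effects Tibble from [effect_table()].
#' @param genes Genes to analyse; defaults to all present.
#' @return A tibble with one `mega_result` row per gene.
#' @export
mega_analyze_genes <- function(effects, genes = unique(effects$gene)) {
  dplyr::bind_rows(lapply(genes, function(g) {
    mega_analyze(effects[effects$gene == g, , drop = FALSE], gene = g)
  }))
}

check_yv <- function(y, v) {
  if (length(y) == 0L) stop("at least one study is required", call. = FALSE)
  if (length(y) != length(v)) {
    stop("effects and variances must have equal length", call. = FALSE)
  }
  if (any(!is.finite(y)) || any(!is.finite(v))) {
    stop("effects and variances must be finite", call. = FALSE)
  }
  if (any(v <= 0)) stop("all variances must be > 0", call. = FALSE)
  invisible(TRUE)
}
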