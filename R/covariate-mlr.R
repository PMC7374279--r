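#' Encode study-level covariates as a regression design matrix
#'
#' Builds the design for regressing per-study effect sizes on study-level
#' descriptors: total sample size (`n_case + n_ctrl`, numeric), study age
#' (`reference_year - publication year`, numeric), and country and sample
#' source (tissue) as integer category codes, one regressor per factor.
#' Integer coding yields a single coefficient and p-value per factor,
#' matching how a single per-factor p-value is conventionally reported;
#' set `encoding = "onehot"` for dummy coding (one column per non-reference
#' level), the statistically preferable alternative, with a per-factor
#' F-test available from [fit_mlr()].
#'
#' Constant columns (a factor with one observed level, or identical sample
#' sizes) are dropped with a warning rather than sent to a rank-deficient
#' fit. An intercept column is always included.
#'
#' @param meta Data frame with one row per study and columns `study_id`,
#'   `n_case`, `n_ctrl`, `country`, `year`, `tissue`.
#' @param reference_year Year the study ages are measured from.
#' @param encoding `"integer"` (default) or `"onehot"`.
#' @return A numeric design matrix with rownames = study ids and an
#'   attribute `"factor_assign"` mapping columns to factors (used for
#'   per-factor F-tests).
#' @export
encode_covariates <- function(meta, reference_year = 2020L,
                              encoding = c("integer", "onehot")) {
  encoding <- match.arg(encoding)
  need <- c("study_id", "n_case", "n_ctrl", "country", "year", "tissue")
  for (f in need) {
    if (!f %in% names(meta)) {
      stop("study metadata lacks field '", f, "'", call. = FALSE)
    }
    bad <- which(is.na(meta[[f]]))
    if (length(bad)) {
      stop("study '", meta$study_id[bad[1L]], "' has missing field '", f,
           "'", call. = FALSE)
    }
  }
  cols <- list("(Intercept)" = rep(1, nrow(meta)),
               sample_size = meta$n_case + meta$n_ctrl,
               study_age = reference_year - meta$year)
  assign <- c("(Intercept)", "sample_size", "study_age")
  for (f in c("country", "tissue")) {
    lev <- unique(meta[[f]])
    label <- if (f == "tissue") "sample_source" else f
    if (length(lev) < 2L) {
      warning("factor '", label, "' is constant across studies; dropped",
              call. = FALSE)
      next
    }
    if (encoding == "integer") {
      cols[[label]] <- match(meta[[f]], lev) - 1L
      assign <- c(assign, label)
    } else {
      for (l in lev[-1L]) {
        nm <- paste0(label, ":", l)
        cols[[nm]] <- as.numeric(meta[[f]] == l)
        assign <- c(assign, label)
      }
    }
  }
  # numeric covariates can degenerate too (e.g. equal sample sizes)
  keep <- vapply(cols, function(x) length(unique(x)) > 1L, logical(1))
  keep[1L] <- TRUE
  if (any(!keep)) {
    warning("constant covariate(s) dropped: ",
            paste(names(cols)[!keep], collapse = ", "), call. = FALSE)
  }
  X <- do.call(cbind, cols[keep])
  rownames(X) <- meta$study_id
  attr(X, "factor_assign") <- assign[keep]
  X
}

#' Ordinary least squares of effect sizes on study covariates
#'
#' Fits `y ~ X` by OLS (unweighted, as a plain multiple linear regression
#' of per-study effect sizes on study descriptors). Per-term t-tests use
#' `k - p` degrees of freedom and 95% CIs are
#' `beta +/- t(0.975, k - p) * se`. With one-hot encoded factors a
#' per-factor partial F-test is reported alongside the per-column t-tests.
#'
#' With about a dozen studies and four covariates the residual degrees of
#' freedom are small; a warning flags fits with fewer than 5.
#'
#' @param y Per-study response (e.g. the per-study log fold change of one
#'   gene).
#' @param X Design matrix from [encode_covariates()] (intercept included).
#' @param response_gene Optional label carried into the result.
#' @return List of class `mlr_result`: `terms` (tibble with `name`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p`), `factor_tests` (per-factor
#'   F-tests, `NULL` for integer encoding), `k`, `r2`, `response_gene`,
#'   and the underlying `lm` fit in `$fit`.
#' @export
fit_mlr <- function(y, X, response_gene = NA_character_) {
  stopifnot(is.numeric(y), is.matrix(X))
  k <- length(y)
  if (k != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  p <- ncol(X)
  if (k <= p) {
    stop("need more studies (", k, ") than design columns (", p, ")",
         call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < p) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  if (k - p < 5L) {
    warning("only ", k - p, " residual degrees of freedom; ",
            "coefficient tests are fragile", call. = FALSE)
  }
  fit <- stats::lm(y ~ X - 1)
  sm <- summary(fit)
  co <- sm$coefficients
  # summary.lm reports the uncentered R^2 for intercept-free formulas;
  # the intercept lives in X here, so compute the centered version
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  tq <- stats::qt(0.975, df = k - p)
  terms <- tibble::tibble(
    name = colnames(X), beta = unname(co[, 1L]), se = unname(co[, 2L]),
    ci_low = unname(co[, 1L] - tq * co[, 2L]),
    ci_high = unname(co[, 1L] + tq * co[, 2L]), p = unname(co[, 4L]))
  assign <- attr(X, "factor_assign")
  factor_tests <- NULL
  if (!is.null(assign) && anyDuplicated(assign)) {
    multi <- unique(assign[duplicated(assign)])
    factor_tests <- dplyr::bind_rows(lapply(multi, function(f) {
      drop_cols <- which(assign == f)
      X0 <- X[, -drop_cols, drop = FALSE]
      fit0 <- stats::lm(y ~ X0 - 1)
      av <- stats::anova(fit0, fit)
      tibble::tibble(factor = f, F = av$F[2L], df1 = av$Df[2L],
                     df2 = fit$df.residual, p = av$`Pr(>F)`[2L])
    }))
  }
  structure(
    list(response_gene = response_gene, terms = terms,
         factor_tests = factor_tests, k = k, r2 = r2, fit = fit),
    class = "mlr_result")
}

#' @export
print.mlr_result <- function(x, ...) {
  cat(sprintf("<mlr_result> %s: k = %d studies, R^2 = %.3f\n",
              ifelse(is.na(x$response_gene), "(unnamed)", x$response_gene),
              x$k, x$r2))
  print(x$terms)
  if (!is.null(x$factor_tests)) {
    cat("per-factor F-tests:\n")
    print(x$factor_tests)
  }
  invisible(x)
}

#' Covariate regression for each gene of an effect table
#'
#' Joins the per-study effects of one gene to the study metadata and runs
#' [fit_mlr()]. Studies with a missing effect for the gene are dropped.
#'
#' @param effects Tibble from [effect_table()].
#' @param meta Study metadata (see [encode_covariates()]).
#' @param gene Gene symbol.
#' @inheritParams encode_covariates
#' @return An `mlr_result`.
#' @export
mlr_for_gene <- function(effects, meta, gene, reference_year = 2020L,
                         encoding = c("integer", "onehot")) {
  eff <- effects[effects$gene == gene & !is.na(effects$lfc), , drop = FALSE]
  meta <- meta[match(eff$study_id, meta$study_id), , drop = FALSE]
  X <- encode_covariates(meta, reference_year = reference_year,
                         encoding = match.arg(encoding))
  fit_mlr(eff$lfc, X, response_gene = gene)
}
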