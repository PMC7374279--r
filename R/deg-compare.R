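#' One-way ANOVA for two groups
#'
#' Equal-variance one-way ANOVA with two groups: the F statistic is
#' MS_between / MS_within on (1, n - 2) degrees of freedom and equals the
#' square of the pooled two-sample t statistic. `variance = "welch"`
#' switches to the Welch-corrected form.
#'
#' Degenerate inputs follow fixed conventions: zero within-group variance
#' with equal means gives `p = 1`; zero within-group variance with
#' unequal means is the p -> 0 limit and is reported as the smallest
#' representable double with a warning.
#'
#' @param values_case,values_ctrl Numeric vectors, each of length >= 2.
#' @param variance `"equal"` (default) or `"welch"`.
#' @return List with `F`, `p`, `df1`, `df2`.
#' @examples
#' anova_two_group(c(1, 2, 3), c(4, 5, 6))  # F = 13.5
#' @export
anova_two_group <- function(values_case, values_ctrl,
                            variance = c("equal", "welch")) {
  variance <- match.arg(variance)
  x <- values_case[!is.na(values_case)]
  y <- values_ctrl[!is.na(values_ctrl)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  msw <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (msw == 0) {
    if (mean(x) == mean(y)) {
      return(list(F = 0, p = 1, df1 = 1L, df2 = n1 + n2 - 2L))
    }
    warning("zero within-group variance with unequal means; ",
            "p reported as the smallest representable value", call. = FALSE)
    return(list(F = Inf, p = .Machine$double.xmin, df1 = 1L,
                df2 = n1 + n2 - 2L))
  }
  if (variance == "equal") {
    gm <- (n1 * mean(x) + n2 * mean(y)) / (n1 + n2)
    msb <- n1 * (mean(x) - gm)^2 + n2 * (mean(y) - gm)^2
    Fst <- msb / msw
    df2 <- n1 + n2 - 2L
  } else {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    Fst <- unname(tt$statistic)^2
    df2 <- unname(tt$parameter)
  }
  list(F = Fst, p = stats::pf(Fst, 1, df2, lower.tail = FALSE),
       df1 = 1L, df2 = df2)
}

#' Two-group comparison with the differential-expression rule
#'
#' For each gene, compares case against control expression: log fold
#' change (difference of group means on the log2 scale), one-way ANOVA
#' p-value, group means/SDs, and the differential-expression call
#' `is_deg = (lfc >= 1 | lfc <= -1) & p < 0.05`. With
#' `stratify_by_sex = TRUE` the comparison is additionally run within the
#' female and male strata; a stratum with fewer than 2 samples in either
#' group is skipped with a message.
#'
#' @param study An [expression_study()].
#' @param genes Genes to compare; defaults to all rows.
#' @param stratify_by_sex Also run per-sex comparisons.
#' @param lfc_cut,p_cut The rule's thresholds (defaults 1 and 0.05).
#' @inheritParams anova_two_group
#' @return A tibble with one row per (comparison, gene): `comparison`,
#'   `gene`, `lfc`, `p`, `mean_case`, `sd_case`, `mean_ctrl`, `sd_ctrl`,
#'   `n_case`, `n_ctrl`, `is_deg`.
#' @export
compare_groups <- function(study, genes = rownames(study$matrix),
                           stratify_by_sex = FALSE, lfc_cut = 1,
                           p_cut = 0.05, variance = c("equal", "welch")) {
  variance <- match.arg(variance)
  stopifnot(inherits(study, "expression_study"))
  strata <- list(All = rep(TRUE, ncol(study$matrix)))
  if (stratify_by_sex) {
    strata$Female <- study$sex == "F"
    strata$Male <- study$sex == "M"
  }
  dplyr::bind_rows(lapply(names(strata), function(sname) {
    keep <- strata[[sname]]
    is_case <- keep & study$groups == "case"
    is_ctrl <- keep & study$groups == "control"
    if (sum(is_case) < 2L || sum(is_ctrl) < 2L) {
      message("stratum '", sname, "' skipped: fewer than 2 samples ",
              "per group")
      return(NULL)
    }
    dplyr::bind_rows(lapply(genes, function(g) {
      x <- study$matrix[g, is_case]
      y <- study$matrix[g, is_ctrl]
      a <- anova_two_group(x, y, variance = variance)
      lfc <- mean(x) - mean(y)
      tibble::tibble(
        comparison = sname, gene = g, lfc = lfc, p = a$p,
        mean_case = mean(x), sd_case = stats::sd(x),
        mean_ctrl = mean(y), sd_ctrl = stats::sd(y),
        n_case = sum(is_case), n_ctrl = sum(is_ctrl),
        is_deg = (lfc >= lfc_cut | lfc <= -lfc_cut) & a$p < p_cut)
    }))
  }))
}

#' Exact power of the two-sample t-test
#'
#' Power of a two-sided, equal-n, equal-variance two-sample t-test at
#' level `alpha` against a mean shift `delta` with common standard
#' deviation `sd`, computed from the noncentral t distribution with
#' noncentrality \eqn{\delta / (sd \sqrt{2/n})} on \eqn{2n - 2} degrees
#' of freedom.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param delta Detectable mean difference (log2 fold change units).
#' @param sd Common within-group standard deviation.
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
power_two_sample_t <- function(n_per_group, delta, sd, alpha = 0.05) {
  stopifnot(n_per_group >= 2, delta >= 0, sd > 0, alpha > 0, alpha < 1)
  df <- 2 * n_per_group - 2
  ncp <- delta / (sd * sqrt(2 / n_per_group))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tc, df, ncp = ncp)
}

#' Smallest group size achieving a target power
#'
#' Scans n upward from 2 and returns the smallest integer group size for
#' which the exact two-sample t-test power ([power_two_sample_t()])
#' reaches the target. Used to check that a planned comparison — e.g.
#' detecting an absolute log2 fold change of at least 1 against a
#' genome-wide LFC distribution with mean 0 and SD 0.5 — is adequately
#' powered.
#'
#' @param delta Detectable mean difference (> 0).
#' @param sd Common standard deviation (> 0).
#' @param alpha Two-sided level (default 0.05).
#' @param power Target power (default 0.80).
#' @param n_max Scan bound; powers that remain unattainable by `n_max`
#'   raise an error.
#' @return List with `n_per_group`, `achieved_power`, and the inputs.
#' @examples
#' sample_size_for_power(delta = 1, sd = 0.5)  # n_per_group = 6
#' @export
sample_size_for_power <- function(delta, sd, alpha = 0.05, power = 0.80,
                                  n_max = 10000L) {
  if (delta <= 0) stop("delta must be > 0", call. = FALSE)
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)", call. = FALSE)
  for (n in 2:n_max) {
    pw <- power_two_sample_t(n, delta, sd, alpha)
    if (pw >= power) {
      return(list(n_per_group = n, achieved_power = pw, delta = delta,
                  sd = sd, alpha = alpha, power = power))
    }
  }
  stop("target power not attainable with n <= ", n_max, call. = FALSE)
}

#' Packaged PBMC group summary statistics
#'
#' Group-level summary statistics (per-gene mean and SD of log2
#' expression for the patient and control groups, with the published log
#' fold change and p-value) for the three PPAR genes in peripheral-blood
#' samples of early-onset schizophrenia patients versus matched healthy
#' controls, for the All / Female / Male comparisons. These are inputs:
#' the package recomputes LFCs from the means and parameterises the PBMC
#' simulator ([simulate_pbmc_groups()]) from them.
#'
#' @param comparison Restrict to one of `"All"`, `"Female"`, `"Male"`;
#'   default returns all rows.
#' @return A tibble with columns `comparison`, `gene`, `lfc`, `p`,
#'   `mean_case`, `sd_case`, `mean_ctrl`, `sd_ctrl`.
#' @export
pbmc_reference_stats <- function(comparison = NULL) {
  path <- system.file("extdata", "pbmc_group_stats.tsv",
                      package = "megexpress")
  tab <- readr::read_tsv(path, col_types = readr::cols(
    comparison = "c", gene = "c", .default = "d"), progress = FALSE)
  if (!is.null(comparison)) {
    tab <- tab[tab$comparison == comparison, , drop = FALSE]
  }
  tab
}
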