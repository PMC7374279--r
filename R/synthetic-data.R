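#' Simulation configuration for the synthetic-data generators
#'
#' Collects every knob of the generative model in one validated object. The
#' expression generator draws, for study \eqn{i} and gene \eqn{g}, control
#' samples from \eqn{N(\mu_g, \sigma^2)} and case samples from
#' \eqn{N(\mu_g + \delta_g + u_{ig}, \sigma^2)} where \eqn{\delta_g} is the
#' true log2 fold change and \eqn{u_{ig} \sim N(0, \tau^2)} is a study-level
#' random shift of the case effect — the heterogeneity structure the
#' random-effects pooling model assumes. The GWAS generator emits a
#' summary-statistics table of null p-values (uniform) with optional
#' enriched loci.
#'
#' Seeds split deterministically: study \eqn{i} uses `seed + i`, the GWAS
#' table uses `seed` itself, so equal seeds give bit-identical output.
#'
#' @param n_studies Number of expression studies to simulate (>= 1).
#' @param genes Character vector of gene symbols.
#' @param n_case,n_ctrl Per-study group sizes; scalars are recycled to
#'   `n_studies`, vectors must have length `n_studies`. All entries must be
#'   positive.
#' @param true_lfc Per-gene true case-minus-control log2 fold change;
#'   recycled to `length(genes)`.
#' @param tau2 Between-study variance of the true effect (squared log2
#'   units, >= 0).
#' @param sigma Within-group standard deviation on the log2 scale (> 0).
#' @param baseline_mean Per-gene control-group mean log2 intensity;
#'   recycled to `length(genes)`.
#' @param seed Integer seed driving all randomness.
#' @param gwas_m Total number of GWAS variants to simulate (>= 1).
#' @param gwas_signal_loci Optional list of enriched regions, each a list
#'   with elements `locus` (a [gene_locus()]), `n` (variant count to place
#'   inside the locus) and `beta_a` (shape of the Beta(a, 1) p-value
#'   distribution, a < 1 for enrichment).
#' @param chromosomes Data frame with columns `chrom` and `length_bp`
#'   giving the chromosome model for variant placement. The default covers
#'   chromosomes 3, 6 and 22 — the chromosomes carrying the three PPAR
#'   loci — at their full lengths.
#' @param countries,tissues Character vectors the per-study metadata is
#'   drawn from.
#' @param years Integer vector of possible publication years.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_expression_studies()], [simulate_gwas_summary()],
#'   [simulate_pbmc_groups()]
#' @export
sim_config <- function(n_studies = 13L,
                       genes = c("PPARA", "PPARD", "PPARG"),
                       n_case = 40L, n_ctrl = 45L,
                       true_lfc = 0, tau2 = 0, sigma = 1,
                       baseline_mean = 7, seed = 1L,
                       gwas_m = 10000L, gwas_signal_loci = list(),
                       chromosomes = default_chromosomes(),
                       countries = c("Japan", "United Kingdom", "U.S.A.",
                                     "China", "Brazil"),
                       tissues = c("Prefrontal cortex", "Parietal cortex",
                                   "Frontal cortex", "BA10", "BA22"),
                       years = 2008:2017) {
  n_studies <- as.integer(n_studies)
  if (n_studies < 1L) stop("n_studies must be >= 1", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (tau2 < 0) stop("tau2 must be >= 0", call. = FALSE)
  gwas_m <- as.integer(gwas_m)
  if (gwas_m < 1L) stop("gwas_m must be >= 1", call. = FALSE)
  n_case <- recycle_to(as.integer(n_case), n_studies, "n_case")
  n_ctrl <- recycle_to(as.integer(n_ctrl), n_studies, "n_ctrl")
  if (any(n_case <= 0L) || any(n_ctrl <= 0L)) {
    stop("per-study sample sizes must be positive", call. = FALSE)
  }
  true_lfc <- recycle_to(true_lfc, length(genes), "true_lfc")
  baseline_mean <- recycle_to(baseline_mean, length(genes), "baseline_mean")
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length_bp") %in% names(chromosomes)))
  for (sl in gwas_signal_loci) {
    if (!all(c("locus", "n") %in% names(sl))) {
      stop("each signal locus needs elements `locus` and `n`", call. = FALSE)
    }
    row <- match(sl$locus$chromosome, chromosomes$chrom)
    if (is.na(row)) {
      stop("signal locus chromosome '", sl$locus$chromosome,
           "' is not in the chromosome table", call. = FALSE)
    }
    if (sl$locus$end_bp > chromosomes$length_bp[row]) {
      stop("signal locus '", sl$locus$symbol,
           "' extends beyond its chromosome length", call. = FALSE)
    }
  }
  total_signal <- sum(vapply(gwas_signal_loci, function(s) as.integer(s$n),
                             integer(1)))
  if (total_signal > gwas_m) {
    stop("signal-locus variant counts exceed gwas_m", call. = FALSE)
  }
  structure(
    list(n_studies = n_studies, genes = genes, n_case = n_case,
         n_ctrl = n_ctrl, true_lfc = true_lfc, tau2 = tau2, sigma = sigma,
         baseline_mean = baseline_mean, seed = as.integer(seed),
         gwas_m = gwas_m, gwas_signal_loci = gwas_signal_loci,
         chromosomes = chromosomes, countries = countries,
         tissues = tissues, years = years),
    class = "sim_config"
  )
}

recycle_to <- function(x, n, what) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) {
    stop("`", what, "` must have length 1 or ", n, call. = FALSE)
  }
  x
}

#' Default chromosome model for variant simulation
#'
#' Chromosomes 3, 6 and 22 at their GRCh38 lengths; the three PPAR loci
#' all live on these chromosomes.
#'
#' @return A tibble with columns `chrom` and `length_bp`.
#' @export
default_chromosomes <- function() {
  tibble::tibble(chrom = c("3", "6", "22"),
                 length_bp = c(198295559, 170805979, 50818468))
}

#' Simulate a set of case-control expression studies
#'
#' Draws `config$n_studies` studies under the generative model documented
#' in [sim_config()]: Gaussian log2 intensities, a shared per-gene true
#' effect, and a per-study random shift of the case effect with variance
#' `tau2`. Study metadata (country, year, tissue) is drawn from the
#' configured lists. Output is deterministic for a fixed seed; study
#' \eqn{i} is seeded with `seed + i` so individual studies can be
#' regenerated independently.
#'
#' @param config A [sim_config()] object.
#' @return A list of [expression_study()] objects, named by study id.
#' @examples
#' studies <- simulate_expression_studies(
#'   sim_config(n_studies = 2, n_case = 5, n_ctrl = 5, seed = 7))
#' studies[[1]]
#' @export
simulate_expression_studies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- length(config$genes)
  lapply(seq_len(config$n_studies), function(i) {
    set.seed(config$seed + i)
    nc <- config$n_case[i]
    nk <- config$n_ctrl[i]
    u <- stats::rnorm(g, 0, sqrt(config$tau2))
    case <- matrix(stats::rnorm(g * nc,
                                mean = rep(config$baseline_mean +
                                             config$true_lfc + u, nc),
                                sd = config$sigma), nrow = g)
    ctrl <- matrix(stats::rnorm(g * nk,
                                mean = rep(config$baseline_mean, nk),
                                sd = config$sigma), nrow = g)
    m <- cbind(case, ctrl)
    id <- sprintf("SIM%02d", i)
    dimnames(m) <- list(config$genes,
                        sprintf("%s_S%03d", id, seq_len(nc + nk)))
    expression_study(
      study_id = id, matrix = m,
      groups = c(rep("case", nc), rep("control", nk)),
      sex = sample(c("F", "M"), nc + nk, replace = TRUE),
      meta = list(country = sample(config$countries, 1L),
                  year = sample(config$years, 1L),
                  tissue = sample(config$tissues, 1L))
    )
  }) |> stats::setNames(sprintf("SIM%02d", seq_len(config$n_studies)))
}

#' Simulate a GWAS summary-statistics table
#'
#' Emits `config$gwas_m` variants. Null variants get p-values uniform on
#' (0, 1) and positions uniform over the configured chromosomes (chromosome
#' chosen with probability proportional to its length). Variants assigned
#' to an enriched locus are placed uniformly inside that locus and draw
#' their p-value from Beta(`beta_a`, 1), which concentrates near zero when
#' `beta_a < 1`.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `SNP`, `CHR`, `BP`, `P` (the conventional
#'   summary-statistics header).
#' @export
simulate_gwas_summary <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$gwas_m
  chrom_tab <- config$chromosomes
  sig <- config$gwas_signal_loci
  n_sig <- sum(vapply(sig, function(s) as.integer(s$n), integer(1)))

  chr <- character(m)
  bp <- integer(m)
  p <- numeric(m)
  at <- 0L
  for (s in sig) {
    n <- as.integer(s$n)
    idx <- at + seq_len(n)
    chr[idx] <- s$locus$chromosome
    bp[idx] <- as.integer(floor(stats::runif(
      n, s$locus$start_bp, s$locus$end_bp + 1)))
    a <- if (is.null(s$beta_a)) 1 else s$beta_a
    p[idx] <- stats::rbeta(n, a, 1)
    at <- at + n
  }
  n_null <- m - n_sig
  if (n_null > 0L) {
    idx <- at + seq_len(n_null)
    which_chr <- sample.int(nrow(chrom_tab), n_null, replace = TRUE,
                            prob = chrom_tab$length_bp)
    chr[idx] <- chrom_tab$chrom[which_chr]
    bp[idx] <- as.integer(floor(stats::runif(
      n_null, 1, chrom_tab$length_bp[which_chr] + 1)))
    p[idx] <- stats::runif(n_null)
  }
  # p must lie in (0, 1]; the uniform/beta draws never return exact 0
  tibble::tibble(SNP = sprintf("rs%07d", seq_len(m)),
                 CHR = chr, BP = bp, P = p)
}

#' Simulate a two-group, sex-labelled expression study
#'
#' Generates Gaussian log2 expression for a case group and a control group
#' from per-gene, per-group means and standard deviations — the design of
#' a blood-sample comparison between early-onset patients and matched
#' healthy controls. Group sizes are honoured exactly, and supplying zero
#' standard deviations yields samples exactly at the group means.
#'
#' @param stats_table Data frame with columns `gene`, `mean_case`,
#'   `sd_case`, `mean_ctrl`, `sd_ctrl` (log2 scale). See
#'   [pbmc_reference_stats()] for the packaged in-paper parameterisation.
#' @param n_case,n_ctrl Group sizes (>= 1 each).
#' @param sex_case,sex_ctrl Character vectors of per-sample sex labels
#'   (`"F"`/`"M"`), with lengths `n_case` and `n_ctrl` respectively, or
#'   `NULL` for `"unknown"`.
#' @param seed Integer seed.
#' @param study_id Identifier for the resulting study object.
#' @return An [expression_study()].
#' @export
simulate_pbmc_groups <- function(stats_table, n_case, n_ctrl,
                                 sex_case = NULL, sex_ctrl = NULL,
                                 seed = 1L, study_id = "PBMC_SIM") {
  need <- c("gene", "mean_case", "sd_case", "mean_ctrl", "sd_ctrl")
  if (!all(need %in% names(stats_table))) {
    stop("stats_table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  n_case <- as.integer(n_case)
  n_ctrl <- as.integer(n_ctrl)
  if (n_case < 1L || n_ctrl < 1L) {
    stop("group sizes must be >= 1", call. = FALSE)
  }
  if (!is.null(sex_case) && length(sex_case) != n_case) {
    stop("sex_case must have length n_case (", n_case, "), got ",
         length(sex_case), call. = FALSE)
  }
  if (!is.null(sex_ctrl) && length(sex_ctrl) != n_ctrl) {
    stop("sex_ctrl must have length n_ctrl (", n_ctrl, "), got ",
         length(sex_ctrl), call. = FALSE)
  }
  if (is.null(sex_case)) sex_case <- rep("unknown", n_case)
  if (is.null(sex_ctrl)) sex_ctrl <- rep("unknown", n_ctrl)
  set.seed(seed)
  g <- nrow(stats_table)
  case <- matrix(stats::rnorm(g * n_case,
                              mean = rep(stats_table$mean_case, n_case),
                              sd = rep(stats_table$sd_case, n_case)),
                 nrow = g)
  ctrl <- matrix(stats::rnorm(g * n_ctrl,
                              mean = rep(stats_table$mean_ctrl, n_ctrl),
                              sd = rep(stats_table$sd_ctrl, n_ctrl)),
                 nrow = g)
  m <- cbind(case, ctrl)
  dimnames(m) <- list(stats_table$gene,
                      sprintf("%s_S%03d", study_id, seq_len(n_case + n_ctrl)))
  expression_study(
    study_id = study_id, matrix = m,
    groups = c(rep("case", n_case), rep("control", n_ctrl)),
    sex = c(as.character(sex_case), as.character(sex_ctrl))
  )
}
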