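#' Default all-simulated pipeline configuration
#'
#' A complete [run_pipeline()] configuration whose every input is drawn
#' from the synthetic-data module: 14 brain-style expression studies with
#' the packaged case/control sizes ([brain_study_descriptors()]), a GWAS
#' summary table over chromosomes 3/6/22 with the packaged PPAR loci, and
#' a PBMC-style two-group study parameterised by the packaged group
#' summary statistics.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for all simulation.
#' @return A config list accepted by [validate_config()] /
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir, seed = 1L) {
  desc <- brain_study_descriptors()
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    force = FALSE,
    loci = ppar_loci(),
    gwas = list(simulate = list(gwas_m = 50000L)),
    studies = list(simulate = list(
      n_studies = nrow(desc), n_case = desc$n_case, n_ctrl = desc$n_ctrl,
      true_lfc = c(0.08, 0.012, 0.0067), tau2 = 0, sigma = 1)),
    pbmc = list(simulate = list(n_case = 19L, n_ctrl = 18L)),
    flags = list(variance = "welch", encoding = "integer",
                 power_target = 0.80, alpha = 0.05, lfc_cut = 1,
                 p_cut = 0.05, reference_year = 2020L)
  )
}

#' Packaged brain-study descriptors
#'
#' Case/control counts, tissue and country for the 14 public brain
#' expression datasets the mega-analysis arm emulates; used to give the
#' simulator realistic per-study sample sizes and metadata.
#'
#' @return A tibble with columns `study_id`, `n_case`, `n_ctrl`,
#'   `tissue`, `country`.
#' @export
brain_study_descriptors <- function() {
  path <- system.file("extdata", "brain_study_descriptors.tsv",
                      package = "megexpress")
  readr::read_tsv(path, col_types = readr::cols(
    study_id = "c", n_case = "i", n_ctrl = "i", tissue = "c",
    country = "c"), progress = FALSE)
}

#' Validate a pipeline configuration
#'
#' Checks a [run_pipeline()] config without running anything. Problems
#' are data, not errors: each element of the returned character vector
#' names the offending field and the cause, and an empty vector means the
#' config is runnable.
#'
#' @param config A config list (see [default_pipeline_config()]).
#' @return Character vector of problems (empty iff valid).
#' @export
validate_config <- function(config) {
  problems <- character()
  say <- function(...) problems <<- c(problems, paste0(...))
  if (is.null(config$out_dir)) say("out_dir: missing")
  if (is.null(config$seed) || !is.finite(config$seed)) {
    say("seed: missing or non-numeric")
  }
  if (is.null(config$loci)) {
    say("loci: missing (a locus table or a path)")
  } else if (is.character(config$loci) && !file.exists(config$loci)) {
    say("loci: file not found: ", config$loci)
  }
  for (arm in c("gwas", "studies", "pbmc")) {
    a <- config[[arm]]
    if (is.null(a)) { say(arm, ": missing"); next }
    if (is.null(a$simulate) && is.null(a$path) && is.null(a$manifest)) {
      say(arm, ": needs either a `simulate` spec or input path(s)")
    }
  }
  sim <- config$studies$simulate
  if (!is.null(sim)) {
    if (any(sim$n_case < 2) || any(sim$n_ctrl < 2)) {
      say("studies: per-group sizes must be >= 2 for variance estimation")
    }
  }
  psim <- config$pbmc$simulate
  if (!is.null(psim) && (psim$n_case < 2 || psim$n_ctrl < 2)) {
    say("pbmc: per-group sizes must be >= 2 for variance estimation")
  }
  fl <- config$flags
  if (!is.null(fl$alpha) && (fl$alpha <= 0 || fl$alpha >= 1)) {
    say("flags$alpha: must be in (0, 1), got ", fl$alpha)
  }
  if (!is.null(fl$power_target) &&
      (fl$power_target <= 0 || fl$power_target >= 1)) {
    say("flags$power_target: must be in (0, 1), got ", fl$power_target)
  }
  st <- config$studies$manifest
  if (!is.null(st)) {
    for (p in c(st$matrix, st$sheet)) {
      if (!file.exists(p)) say("studies: file not found: ", p)
    }
  }
  problems
}

#' Run the three-arm pipeline
#'
#' Orchestrates the full evaluation from one configuration: (1) GWAS
#' region lookup over the configured loci, (2) effect-size computation
#' and mega-analysis across the expression studies plus the covariate
#' regression, (3) the two-group comparison with the
#' differential-expression rule and the power check. All result tables
#' are written as TSV under `config$out_dir`, together with a JSON
#' manifest recording the seed, flags and package version. Outputs are
#' deterministic for a fixed seed; the only timestamp lives in the
#' manifest.
#'
#' @param config Config list, e.g. from [default_pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with elements `locus_summary`, `effects`,
#'   `mega`, `forest`, `mlr`, `deg`, `power`, `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid pipeline config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  out <- config$out_dir
  if (dir.exists(out) && length(dir(out)) &&
      !isTRUE(config$force)) {
    stop("output directory ", out,
         " exists and is non-empty; set force = TRUE to overwrite",
         call. = FALSE)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) if (!quiet) message(...)
  fl <- config$flags %||% list()
  variance <- fl$variance %||% "welch"
  seed <- as.integer(config$seed)

  loci <- if (is.character(config$loci)) read_loci(config$loci) else
    config$loci

  # --- arm 1: GWAS region lookup -----------------------------------
  gwas <- tryCatch({
    if (!is.null(config$gwas$simulate)) {
      g <- config$gwas$simulate
      cfg <- sim_config(seed = seed, gwas_m = g$gwas_m %||% 50000L,
                        gwas_signal_loci = g$signal_loci %||% list())
      simulate_gwas_summary(cfg)
    } else {
      read_gwas_summary(config$gwas$path)
    }
  }, error = function(e) stop("stage gwas-lookup (input): ",
                              conditionMessage(e), call. = FALSE))
  m_total <- config$gwas$m_total %||% nrow(gwas)
  locus_summary <- tryCatch(
    gwas_locus_summary(gwas, loci, m_total = m_total),
    error = function(e) stop("stage gwas-lookup: ", conditionMessage(e),
                             call. = FALSE))
  readr::write_tsv(locus_summary, file.path(out, "locus_summary.tsv"),
                   progress = FALSE)
  jsonlite::write_json(locus_summary, file.path(out, "locus_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  note("arm 1: ", nrow(locus_summary), " loci summarised over ",
       nrow(gwas), " variants")

  # --- arm 2: mega-analysis + covariate regression -----------------
  studies <- tryCatch({
    if (!is.null(config$studies$simulate)) {
      s <- config$studies$simulate
      cfg <- sim_config(
        n_studies = s$n_studies, genes = s$genes %||%
          c("PPARA", "PPARD", "PPARG"),
        n_case = s$n_case, n_ctrl = s$n_ctrl,
        true_lfc = s$true_lfc %||% 0, tau2 = s$tau2 %||% 0,
        sigma = s$sigma %||% 1, seed = seed)
      simulate_expression_studies(cfg)
    } else {
      st <- config$studies$manifest
      lapply(seq_len(nrow(st)), function(i) {
        read_study(st$matrix[i], st$sheet[i],
                   meta = list(country = st$country[i], year = st$year[i],
                               tissue = st$tissue[i]),
                   study_id = st$study_id[i])
      })
    }
  }, error = function(e) stop("stage ingest: ", conditionMessage(e),
                              call. = FALSE))
  effects <- effect_table(studies, variance = variance)
  readr::write_tsv(effects, file.path(out, "effects.tsv"), progress = FALSE)
  mega <- tryCatch({
    genes <- unique(effects$gene)
    res <- lapply(genes, function(g) {
      mega_analyze(effects[effects$gene == g, , drop = FALSE], gene = g)
    })
    names(res) <- genes
    res
  }, error = function(e) stop("stage megalyze: ", conditionMessage(e),
                              call. = FALSE))
  mega_tab <- dplyr::bind_rows(lapply(mega, function(r) {
    tibble::as_tibble(unclass(r))
  }))
  readr::write_tsv(mega_tab, file.path(out, "mega_results.tsv"),
                   progress = FALSE)
  forest <- dplyr::bind_rows(lapply(names(mega), function(g) {
    dplyr::mutate(forest_data(mega[[g]]), gene = g, .before = 1L)
  }))
  readr::write_tsv(forest, file.path(out, "forest_data.tsv"),
                   progress = FALSE)
  note("arm 2: pooled ", length(mega), " gene(s) over ",
       length(studies), " studies")

  meta_tab <- tibble::tibble(
    study_id = vapply(studies, `[[`, character(1), "study_id"),
    n_case = vapply(studies, function(s) s$meta$n_case, integer(1)),
    n_ctrl = vapply(studies, function(s) s$meta$n_ctrl, integer(1)),
    country = vapply(studies, function(s) s$meta$country %||% NA_character_,
                     character(1)),
    year = vapply(studies, function(s) as.integer(s$meta$year %||% NA),
                  integer(1)),
    tissue = vapply(studies, function(s) s$meta$tissue %||% NA_character_,
                    character(1)))
  mlr <- tryCatch({
    lapply(stats::setNames(nm = unique(effects$gene)), function(g) {
      mlr_for_gene(effects, meta_tab, g,
                   reference_year = fl$reference_year %||% 2020L,
                   encoding = fl$encoding %||% "integer")
    })
  }, error = function(e) stop("stage mlr: ", conditionMessage(e),
                              call. = FALSE))
  mlr_tab <- dplyr::bind_rows(lapply(names(mlr), function(g) {
    dplyr::mutate(mlr[[g]]$terms, gene = g, r2 = mlr[[g]]$r2, .before = 1L)
  }))
  readr::write_tsv(mlr_tab, file.path(out, "mlr_results.tsv"),
                   progress = FALSE)

  # --- arm 3: two-group comparison + power -------------------------
  deg <- tryCatch({
    pb <- if (!is.null(config$pbmc$simulate)) {
      p <- config$pbmc$simulate
      stats_tab <- p$stats %||% pbmc_reference_stats("All")
      nC <- p$n_case
      nK <- p$n_ctrl
      simulate_pbmc_groups(stats_tab, nC, nK,
                           sex_case = p$sex_case %||%
                             rep(c("F", "M"), length.out = nC),
                           sex_ctrl = p$sex_ctrl %||%
                             rep(c("F", "M"), length.out = nK),
                           seed = seed + 1000L)
    } else {
      read_study(config$pbmc$matrix, config$pbmc$sheet,
                 study_id = "PBMC")
    }
    compare_groups(pb, stratify_by_sex = TRUE,
                   lfc_cut = fl$lfc_cut %||% 1, p_cut = fl$p_cut %||% 0.05,
                   variance = fl$deg_variance %||% "equal")
  }, error = function(e) stop("stage deg: ", conditionMessage(e),
                              call. = FALSE))
  readr::write_tsv(deg, file.path(out, "deg_results.tsv"), progress = FALSE)
  pw <- sample_size_for_power(delta = fl$lfc_cut %||% 1, sd = 0.5,
                              alpha = fl$alpha %||% 0.05,
                              power = fl$power_target %||% 0.80)
  note("arm 3: ", sum(deg$is_deg), " DEG call(s); adequate n >= ",
       pw$n_per_group, " per group")

  manifest <- list(
    package = "megexpress",
    version = as.character(utils::packageVersion("megexpress")),
    seed = seed, flags = fl,
    created = format(Sys.time(), tz = "UTC"),
    outputs = c("locus_summary.tsv", "locus_summary.json", "effects.tsv",
                "mega_results.tsv", "forest_data.tsv", "mlr_results.tsv",
                "deg_results.tsv", "power.json"))
  jsonlite::write_json(pw, file.path(out, "power.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(locus_summary = locus_summary, effects = effects,
                 mega = mega_tab, forest = forest, mlr = mlr_tab,
                 deg = deg, power = pw, out_dir = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
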