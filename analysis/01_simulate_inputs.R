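#!/usr/bin/env Rscript

# Generate every input the three analysis arms consume: a GWAS
# summary-statistics table over chromosomes 3/6/22, fourteen case-control
# brain expression studies with the packaged per-study sample sizes, and
# a PBMC-style two-group study parameterised by the packaged group
# statistics. Everything is written as plain TSV under results/data/.

suppressPackageStartupMessages(library(megexpress))
suppressPackageStartupMessages(library(readr))

seed <- 20240101L
data_dir <- file.path("results", "data")
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

## GWAS summary statistics: mostly null background, with variants placed
## inside each PPAR locus so the lookup arm has something to find.
loci <- ppar_loci()
signal <- lapply(seq_len(nrow(loci)), function(i) {
  list(locus = gene_locus(loci$symbol[i], loci$chrom[i], loci$start_bp[i],
                          loci$end_bp[i]),
       n = c(77L, 278L, 423L)[i],  # in-locus variant counts to emulate
       beta_a = 1)                 # no enrichment: null association
})
cfg_gwas <- sim_config(seed = seed, gwas_m = 200000L,
                       gwas_signal_loci = signal)
gwas <- simulate_gwas_summary(cfg_gwas)
write_tsv(gwas, file.path(data_dir, "gwas_summary.tsv"))
cat("GWAS table:", nrow(gwas), "variants on chromosomes",
    paste(unique(gwas$CHR), collapse = ", "), "\n")

## Fourteen brain expression studies with realistic group sizes. True
## effects are set to the small pooled LFCs the brain analysis reports,
## with no between-study heterogeneity.
desc <- brain_study_descriptors()
cfg_expr <- sim_config(
  n_studies = nrow(desc), genes = c("PPARA", "PPARD", "PPARG"),
  n_case = desc$n_case, n_ctrl = desc$n_ctrl,
  true_lfc = c(0.08, 0.012, 0.0067), tau2 = 0, sigma = 1, seed = seed)
studies <- simulate_expression_studies(cfg_expr)
manifest <- list()
for (i in seq_along(studies)) {
  st <- studies[[i]]
  st$study_id <- desc$study_id[i]  # label with the emulated accession
  mp <- file.path(data_dir, paste0(st$study_id, "_matrix.tsv"))
  sp <- file.path(data_dir, paste0(st$study_id, "_sheet.tsv"))
  write_study(st, mp, sp)
  manifest[[i]] <- data.frame(
    study_id = st$study_id, matrix = mp, sheet = sp,
    country = desc$country[i], year = st$meta$year,
    tissue = desc$tissue[i])
}
manifest <- do.call(rbind, manifest)
write_tsv(manifest, file.path(data_dir, "study_manifest.tsv"))
cat("Expression studies:", length(studies), "sets,",
    sum(desc$n_case), "cases /", sum(desc$n_ctrl), "controls in total\n")

## PBMC-style study: 19 patients vs 18 controls, parameterised by the
## packaged per-group means/SDs, with sexes interleaved.
pbmc <- simulate_pbmc_groups(
  pbmc_reference_stats("All"), n_case = 19, n_ctrl = 18,
  sex_case = rep(c("F", "M"), length.out = 19),
  sex_ctrl = rep(c("F", "M"), length.out = 18),
  seed = seed + 1000L, study_id = "PBMC")
write_study(pbmc, file.path(data_dir, "PBMC_matrix.tsv"),
            file.path(data_dir, "PBMC_sheet.tsv"))
cat("PBMC study: 19 cases / 18 controls,", nrow(pbmc$matrix), "genes\n")
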