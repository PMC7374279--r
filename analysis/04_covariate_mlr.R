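#!/usr/bin/env Rscript

# Arm 2b: regress each gene's per-study log fold changes on study-level
# covariates (total sample size, country, study age, sample source) by
# ordinary least squares, reporting coefficients, 95% CIs and p-values.

suppressPackageStartupMessages(library(megexpress))
suppressPackageStartupMessages(library(readr))
suppressPackageStartupMessages(library(dplyr))

effects <- read_tsv(file.path("results", "effects.tsv"),
                    show_col_types = FALSE)
meta <- read_tsv(file.path("results", "data", "study_manifest.tsv"),
                 show_col_types = FALSE) |>
  left_join(summarise(group_by(effects, study_id),
                      n_case = first(n_case), n_ctrl = first(n_ctrl)),
            by = "study_id")

mlr_tab <- bind_rows(lapply(unique(effects$gene), function(g) {
  fit <- mlr_for_gene(effects, meta, g, reference_year = 2020L)
  mutate(fit$terms, gene = g, r2 = fit$r2, .before = 1)
}))
write_tsv(mlr_tab, file.path("results", "mlr_results.tsv"))

cat("Covariate regression per gene (k = 14 studies, 4 covariates):\n")
print(as.data.frame(mlr_tab[mlr_tab$name != "(Intercept)",
                            c("gene", "name", "beta", "ci_low", "ci_high",
                              "p")]), digits = 2)
cat("\nUnder the null simulation no covariate should systematically",
    "explain the per-study effects; with 14 studies the tests have",
    "little power and wide intervals, which the output reflects.\n")
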