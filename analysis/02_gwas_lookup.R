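#!/usr/bin/env Rscript

# Arm 1: select the variants falling inside each PPAR locus from the
# simulated GWAS summary table, correct their p-values genome-wide (BH)
# and rank them against the full scan. Writes the per-locus summary and
# the matched variant records.

suppressPackageStartupMessages(library(megexpress))
suppressPackageStartupMessages(library(readr))
suppressPackageStartupMessages(library(dplyr))

gwas <- read_gwas_summary(file.path("results", "data", "gwas_summary.tsv"))
loci <- ppar_loci()

summary_tab <- gwas_locus_summary(gwas, loci, m_total = nrow(gwas))
write_tsv(summary_tab, file.path("results", "locus_summary.tsv"))

matched <- match_variants(gwas, loci, quiet = TRUE)
detail <- bind_rows(lapply(names(matched), function(sym) {
  m <- matched[[sym]]
  if (nrow(m) == 0) return(NULL)
  rs <- rank_statistics(m$P, gwas$P)
  tibble::tibble(symbol = sym, SNP = m$SNP, CHR = m$CHR, BP = m$BP,
                 P = m$P, q = bh_qvalues(m$P, m = nrow(gwas)),
                 rank = rs$rank, rank_pct = rs$rank_pct)
}))
write_tsv(detail, file.path("results", "locus_variants.tsv"))

cat("Per-locus summary over", nrow(gwas), "simulated variants:\n")
print(as.data.frame(summary_tab), digits = 3)
cat("\nUnder this null simulation no locus variant reaches a small",
    "genome-wide q-value, mirroring a negative candidate-gene lookup.\n")
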