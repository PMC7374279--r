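make_variants <- function(chr, bp, p = runif(length(bp))) {
  tibble::tibble(SNP = sprintf("rs%d", seq_along(bp)), CHR = chr,
                 BP = bp, P = p)
}

test_that("interval matching is closed at both ends and chromosome-aware", {
  pparg <- gene_locus("PPARG", "3", 12287485, 12434356)
  v <- make_variants(c("3", "3", "3", "3", "6"),
                     c(12299345, 12287484, 12287485, 12434357, 12299345),
                     p = rep(0.5, 5))
  m <- match_variants(v, pparg, quiet = TRUE)[["PPARG"]]
  expect_setequal(m$SNP, c("rs1", "rs3"))  # inside + inclusive start
  # one below start, one past end, wrong chromosome: all excluded
  expect_false(any(c("rs2", "rs4", "rs5") %in% m$SNP))
})

test_that("unknown chromosomes match nothing and are reported", {
  v <- make_variants(c("3", "17"), c(12299345, 100), p = c(0.1, 0.2))
  expect_message(
    m <- match_variants(v, gene_locus("PPARG", "3", 12287485, 12434356)),
    "no configured locus")
  expect_equal(nrow(m[["PPARG"]]), 1)
})

test_that("matching agrees with a naive per-variant scan on random inputs", {
  set.seed(401)
  for (rep in 1:25) {
    v <- make_variants(sample(c("1", "2"), 60, TRUE),
                       sample.int(1000, 60, TRUE))
    s <- sort(sample.int(1000, 2))
    locus <- gene_locus("L", sample(c("1", "2"), 1), s[1], s[2])
    got <- match_variants(v, locus, quiet = TRUE)[["L"]]
    expect_identical(got$SNP, match_brute(v, locus)$SNP)
  }
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.5), 0.5)
  # subset corrected against a genome-wide m
  expect_equal(bh_qvalues(c(0.01, 0.02), m = 10),
               bh_brute(c(0.01, 0.02), m = 10))
  expect_error(bh_qvalues(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_qvalues(c(0.1, 1.2)), "\\(0, 1\\]")
  expect_error(bh_qvalues(c(0.1, 0.2), m = 1), "m must be")
})

test_that("BH matches the brute-force oracle and is monotone on sorted input", {
  set.seed(402)
  for (rep in 1:200) {
    n <- sample.int(50, 1)
    p <- runif(n)
    m <- n + sample(c(0L, 10L, 1000L), 1)
    expect_equal(bh_qvalues(p, m = m), bh_brute(p, m = m),
                 tolerance = 1e-12)
    q_sorted <- bh_qvalues(sort(p), m = m)
    expect_true(all(diff(q_sorted) >= -1e-15))
  }
})

test_that("ranks use the minimal-tie rule and percentages scale by the total", {
  rs <- rank_statistics(c(0.2, 0.1), c(0.1, 0.2, 0.3, 0.2))
  expect_equal(rs$rank, c(2, 1))
  expect_equal(rs$rank_pct, 100 * c(2, 1) / 4)
  expect_equal(rank_statistics(0.3, rep(0.3, 5))$rank, 1)  # all tied
  expect_equal(rank_statistics(0.3, rep(0.3, 5), ties = "average")$rank, 3)
  expect_error(rank_statistics(0.1, numeric(0)), "non-empty")
  expect_error(rank_statistics(0.15, c(0.1, 0.2)), "absent")
})

test_that("a published rank exceeds its printed percentage bound", {
  # best rank 290,658 among 9,444,230 assayed variants
  pct <- 100 * 290658 / 9444230
  expect_gt(pct, 3.00)
  expect_equal(pct, 3.0776, tolerance = 1e-4)
})

test_that("locus summaries handle empty, singleton and synthetic Table-style input", {
  empty <- summarize_locus(make_variants(character(0), integer(0),
                                         numeric(0)), "X", p_all = c(0.5))
  expect_equal(empty$n_snps, 0L)
  expect_true(is.na(empty$min_p) && is.na(empty$min_q))

  one <- summarize_locus(make_variants("3", 5L, 0.5), "X", p_all = 0.5)
  expect_equal(one$min_p, 0.5)
  expect_equal(one$min_q, 0.5)
  expect_equal(one$best_rank, 1)
  expect_equal(one$best_rank_pct, 100)

  # a locus holding 423 variants reports n_snps = 423
  set.seed(403)
  locus <- gene_locus("PPARG", "3", 12287485, 12434356)
  cfg <- sim_config(gwas_m = 2000, seed = 7, gwas_signal_loci = list(
    list(locus = locus, n = 423, beta_a = 1)))
  g <- simulate_gwas_summary(cfg)
  summ <- gwas_locus_summary(g, ppar_loci(), m_total = nrow(g))
  expect_equal(summ$n_snps[summ$symbol == "PPARG"], 423L)
  expect_true(all(summ$best_rank_pct > 0 & summ$best_rank_pct <= 100,
                  na.rm = TRUE))
})

test_that("disjoint loci partition their union of variants", {
  set.seed(404)
  v <- make_variants(rep("1", 500), sample.int(10000, 500))
  loci <- tibble::tibble(symbol = c("A", "B", "C"), chrom = "1",
                         start_bp = c(1, 3001, 7001),
                         end_bp = c(3000, 7000, 10000))
  matched <- match_variants(v, loci, quiet = TRUE)
  expect_equal(sum(vapply(matched, nrow, integer(1))), 500L)
})

test_that("locus and GWAS readers parse the standard layouts", {
  loci <- ppar_loci()
  expect_equal(loci$symbol, c("PPARA", "PPARD", "PPARG"))
  expect_equal(loci$start_bp[loci$symbol == "PPARG"], 12287485)

  bed <- tempfile(fileext = ".bed")
  writeLines("3\t12287484\t12434356\tPPARG", bed)
  conv <- read_loci(bed, format = "bed")
  expect_equal(conv$start_bp, 12287485)  # 0-based half-open -> 1-based closed
  expect_equal(conv$end_bp, 12434356)

  f <- tempfile(fileext = ".tsv")
  readr::write_tsv(make_variants(c("3", "6"), c(100L, 200L), c(0.5, 0.7)), f)
  tab <- read_gwas_summary(f)
  expect_equal(tab$CHR, c("3", "6"))
  f2 <- tempfile()
  writeLines(c("SNP CHR BP", "rs1 1 100"), f2)
  expect_error(read_gwas_summary(f2), "lacks column")
})
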