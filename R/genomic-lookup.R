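#' Define a gene locus
#'
#' A named genomic interval used to select variants from a GWAS summary
#' table. Coordinates are 1-based and the interval is closed at both ends
#' (the GeneCards convention); see [read_loci()] for converting BED input.
#'
#' @param symbol Gene symbol.
#' @param chromosome Chromosome name (character; "3", not "chr3").
#' @param start_bp,end_bp Integer interval bounds, 1-based inclusive,
#'   `start_bp <= end_bp`, `start_bp >= 1`.
#' @return A list of class `gene_locus`.
#' @export
gene_locus <- function(symbol, chromosome, start_bp, end_bp) {
  start_bp <- as.numeric(start_bp)
  end_bp <- as.numeric(end_bp)
  if (start_bp < 1) stop("start_bp must be >= 1", call. = FALSE)
  if (start_bp > end_bp) stop("start_bp must be <= end_bp", call. = FALSE)
  structure(list(symbol = as.character(symbol),
                 chromosome = as.character(chromosome),
                 start_bp = start_bp, end_bp = end_bp),
            class = "gene_locus")
}

#' Packaged PPAR gene loci
#'
#' The three PPAR-encoding loci (GeneCards coordinates): PPARA on
#' chromosome 22 (46,594,280-46,631,277), PPARD on chromosome 6
#' (35,342,558-35,428,191) and PPARG on chromosome 3
#' (12,287,485-12,434,356).
#'
#' @return A tibble with columns `symbol`, `chrom`, `start_bp`, `end_bp`.
#' @export
ppar_loci <- function() {
  path <- system.file("extdata", "ppar_loci.tsv", package = "megexpress")
  read_loci(path)
}

#' Read a gene-locus table
#'
#' Reads a TSV of loci (columns `symbol`, `chrom`, `start_bp`, `end_bp`)
#' or a 4-column BED file (`chrom`, `start`, `end`, `name`). BED intervals
#' are 0-based half-open and are converted to the package's 1-based closed
#' convention (`start + 1`, `end`).
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return A tibble with columns `symbol`, `chrom`, `start_bp`, `end_bp`.
#' @export
read_loci <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "symbol"),
                           col_types = "ciic", progress = FALSE)
    out <- tibble::tibble(symbol = bed$symbol, chrom = as.character(bed$chrom),
                          start_bp = bed$start + 1, end_bp = bed$end)
  } else {
    out <- readr::read_tsv(path, col_types = readr::cols(
      symbol = "c", chrom = "c", start_bp = "d", end_bp = "d"),
      progress = FALSE)
  }
  if (any(out$start_bp > out$end_bp) || any(out$start_bp < 1)) {
    stop("invalid locus intervals in ", path, call. = FALSE)
  }
  out
}

loci_table_to_list <- function(loci) {
  if (is.data.frame(loci)) {
    loci <- lapply(seq_len(nrow(loci)), function(i) {
      gene_locus(loci$symbol[i], loci$chrom[i], loci$start_bp[i],
                 loci$end_bp[i])
    })
  }
  if (inherits(loci, "gene_locus")) loci <- list(loci)
  stats::setNames(loci, vapply(loci, `[[`, character(1), "symbol"))
}

#' Read a GWAS summary-statistics table
#'
#' Accepts tab- or whitespace-delimited text whose header contains at
#' least the columns `SNP`, `CHR`, `BP` and `P` (the layout of the usual
#' "daner"-style association files). Extra columns are preserved.
#'
#' @param path File path.
#' @return A tibble with at least columns `SNP`, `CHR` (character), `BP`,
#'   `P`.
#' @export
read_gwas_summary <- function(path) {
  tab <- readr::read_table(path, col_types = readr::cols(), progress = FALSE)
  need <- c("SNP", "CHR", "BP", "P")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("GWAS summary file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$CHR <- as.character(tab$CHR)
  if (any(tab$P <= 0 | tab$P > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  tab
}

#' Match variants to gene loci
#'
#' A variant matches a locus when its chromosome is equal and its position
#' falls inside the closed interval `[start_bp, end_bp]`. A variant may
#' match several overlapping loci. Variants on chromosomes absent from the
#' locus table simply match nothing; their count is reported via a
#' message.
#'
#' @param variants Data frame with columns `SNP`, `CHR`, `BP`, `P`.
#' @param loci Locus table (as from [read_loci()] / [ppar_loci()]), a list
#'   of [gene_locus()] objects, or a single locus.
#' @param quiet Suppress the unmatched-chromosome message.
#' @return Named list (one element per locus symbol) of tibbles of matched
#'   variants.
#' @export
match_variants <- function(variants, loci, quiet = FALSE) {
  loci <- loci_table_to_list(loci)
  chr <- as.character(variants$CHR)
  known <- chr %in% unique(vapply(loci, `[[`, character(1), "chromosome"))
  if (!quiet && any(!known)) {
    message(sum(!known),
            " variant(s) lie on chromosomes with no configured locus")
  }
  lapply(loci, function(L) {
    hit <- chr == L$chromosome & variants$BP >= L$start_bp &
      variants$BP <= L$end_bp
    tibble::as_tibble(variants[hit, , drop = FALSE])
  })
}

#' Benjamini-Hochberg q-values
#'
#' FDR-adjusted p-values by the step-up rule
#' \eqn{q_{(i)} = \min_{j \ge i} \{ p_{(j)} \, m / j \}} clipped at 1,
#' where \eqn{m} is the total number of tests. `m` may exceed `length(p)`:
#' q-values for a materialised subset can be computed against the full
#' genome-wide test count, which is how locus-level q-values on a
#' several-million-variant scan are reported. Output order matches input
#' order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param m Total test count, `m >= length(p)`. Defaults to `length(p)`.
#' @param method `"BH"` (default) or `"BY"`.
#' @return Numeric vector of q-values in (0, 1].
#' @export
bh_qvalues <- function(p, m = length(p), method = c("BH", "BY")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m < length(p)) stop("m must be >= length(p)", call. = FALSE)
  stats::p.adjust(p, method = method, n = m)
}

#' Ranks and rank percentages of a p-value subset
#'
#' The rank of a variant is 1 plus the number of variants in the full
#' vector with strictly smaller p-value; tied p-values share the minimal
#' rank (an average-rank alternative is available). The rank percentage is
#' `100 * rank / length(p_all)`.
#'
#' @param p_subset P-values of the variants of interest; every value must
#'   occur in `p_all`.
#' @param p_all The full p-value vector the ranking is taken over.
#' @param ties `"min"` (default) or `"average"`.
#' @return A tibble with columns `p`, `rank`, `rank_pct`.
#' @export
rank_statistics <- function(p_subset, p_all, ties = c("min", "average")) {
  ties <- match.arg(ties)
  if (length(p_all) == 0L) stop("p_all must be non-empty", call. = FALSE)
  r_all <- rank(p_all, ties.method = ties)
  idx <- match(p_subset, p_all)
  if (anyNA(idx)) {
    stop("p_subset contains values absent from p_all", call. = FALSE)
  }
  r <- r_all[idx]
  tibble::tibble(p = p_subset, rank = r,
                 rank_pct = 100 * r / length(p_all))
}

#' Summarise the variants matched to one locus
#'
#' Collapses a matched-variant table to the per-locus summary row: the
#' number of matched variants, the minimum p- and q-value, and the best
#' (smallest) genome-wide rank with its percentage. With zero matches the
#' minima are reported as `NA`.
#'
#' @param matched Tibble of matched variants (columns `SNP`, `P`, and
#'   optionally precomputed `q`, `rank`, `rank_pct`).
#' @param symbol Locus symbol for the output row.
#' @param p_all Full p-value vector used for ranking and, when `m_total`
#'   is not given, for the correction denominator.
#' @param m_total Total test count for the BH correction; defaults to
#'   `length(p_all)`.
#' @return One-row tibble: `symbol`, `n_snps`, `min_p`, `min_q`,
#'   `best_rank`, `best_rank_pct`.
#' @export
summarize_locus <- function(matched, symbol, p_all,
                            m_total = length(p_all)) {
  if (nrow(matched) == 0L) {
    return(tibble::tibble(symbol = symbol, n_snps = 0L, min_p = NA_real_,
                          min_q = NA_real_, best_rank = NA_real_,
                          best_rank_pct = NA_real_))
  }
  q <- bh_qvalues(matched$P, m = m_total)
  rs <- rank_statistics(matched$P, p_all)
  tibble::tibble(symbol = symbol, n_snps = nrow(matched),
                 min_p = min(matched$P), min_q = min(q),
                 best_rank = min(rs$rank),
                 best_rank_pct = min(rs$rank_pct))
}

#' Locus-level GWAS lookup
#'
#' End-to-end arm one: match every configured locus against a GWAS
#' summary table and emit the per-locus summary rows (variant count,
#' minimum p and q, best rank and rank percentage).
#'
#' @inheritParams match_variants
#' @param m_total Total test count for the BH correction; defaults to
#'   `nrow(variants)`. Supply the full assay size when `variants` is
#'   itself a subset of a larger scan.
#' @return A tibble, one row per locus.
#' @examples
#' cfg <- sim_config(gwas_m = 2000, seed = 3)
#' gwas <- simulate_gwas_summary(cfg)
#' gwas_locus_summary(gwas, ppar_loci())
#' @export
gwas_locus_summary <- function(variants, loci, m_total = nrow(variants),
                               quiet = TRUE) {
  loci <- loci_table_to_list(loci)
  matched <- match_variants(variants, loci, quiet = quiet)
  dplyr::bind_rows(lapply(names(matched), function(sym) {
    summarize_locus(matched[[sym]], sym, p_all = variants$P,
                    m_total = m_total)
  }))
}
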