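# Binomial-law enrichment statistics.

#' Binomial-law p-value
#'
#' Computes the point probability P(X = k) and the upper tail P(X >= k) of
#' a Binomial(n, p) count, in log space for numerical stability. The
#' default reported mode is the point probability; both quantities are
#' always returned.
#'
#' @param k observed successes (0 <= k <= n).
#' @param n number of trials.
#' @param p success probability in \[0, 1\].
#' @param mode which probability `pvalue` reports: `"point"` (default) or
#'   `"upper_tail"`.
#' @return a `binomial_result`: list(k, n, p, point_prob, upper_tail,
#'   mode, pvalue).
#' @export
binomial_pvalue <- function(k, n, p, mode = c("point", "upper_tail")) {
  mode <- match.arg(mode)
  if (!is_count(k) || !is_count(n) || k > n)
    ps_validation_error("require integers 0 <= k <= n")
  if (!(is.numeric(p) && length(p) == 1 && !is.na(p) && p >= 0 && p <= 1))
    ps_validation_error("require 0 <= p <= 1")
  point <- exp(dbinom(k, n, p, log = TRUE))
  upper <- if (k == 0) 1 else
    exp(pbinom(k - 1, n, p, lower.tail = FALSE, log.p = TRUE))
  structure(list(k = as.integer(k), n = as.integer(n), p = p,
                 point_prob = point, upper_tail = upper, mode = mode,
                 pvalue = if (mode == "point") point else upper),
            class = "binomial_result")
}

#' @export
print.binomial_result <- function(x, ...) {
  cat(sprintf(
    "<binomial_result> k=%d n=%d p=%g: P(X=k) = %.3g, P(X>=k) = %.3g (mode %s)\n",
    x$k, x$n, x$p, x$point_prob, x$upper_tail, x$mode))
  invisible(x)
}

#' Binomial test of gene-set enrichment in a set of loci
#'
#' Tests whether a gene set (for example a dispensable genome) is biased
#' towards a declared set of loci (for example mobile-element hotspots):
#' with n = |gene set|, k = genes of the set inside the loci and p = the
#' loci's share of the genome's genes, reports the binomial-law p-value.
#'
#' @param gene_set character vector of gene ids (non-empty).
#' @param loci list of character vectors of gene ids (the loci).
#' @param genome_size_genes total number of genes in the genome.
#' @param mode passed to [binomial_pvalue()].
#' @return a `binomial_result` with extra fields `locus_genes` (size of
#'   the loci union) and `overlap` (the gene ids counted in k).
#' @export
locus_overlap_test <- function(gene_set, loci, genome_size_genes,
                               mode = c("point", "upper_tail")) {
  mode <- match.arg(mode)
  if (length(gene_set) == 0)
    ps_validation_error("gene_set must be non-empty")
  if (!is_count(genome_size_genes) || genome_size_genes < 1)
    ps_validation_error("genome_size_genes must be a positive integer")
  locus_union <- unique(unlist(loci))
  overlap <- intersect(gene_set, locus_union)
  res <- binomial_pvalue(k = length(overlap), n = length(unique(gene_set)),
                         p = length(locus_union) / genome_size_genes,
                         mode = mode)
  res$locus_genes <- length(locus_union)
  res$overlap <- overlap
  res
}
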