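# Somatic-call inclusion rules and gene-level CNV thresholding.

#' Somatic filtering policy
#'
#' Bundles the inclusion thresholds applied to candidate somatic calls and
#' the log2-ratio threshold for gene-level CNV calling. The defaults encode a
#' conservative deep-sequencing policy: a call is retained only when it is
#' supported by at least 100x coverage and at least five supporting reads,
#' and is neither a catalogued dbSNP variant nor present in the patient's
#' germline (blood) DNA. Gene CNVs require |log2 ratio| strictly above 0.7.
#'
#' @param min_coverage minimum read depth for retention (default 100; calls
#'   with *less than* this coverage are excluded, so the boundary is kept).
#' @param min_alt_reads minimum number of supporting reads (default 5;
#'   *fewer than* this many are excluded, boundary kept).
#' @param exclude_dbsnp drop calls catalogued in dbSNP (default `TRUE`).
#' @param exclude_germline drop calls found in the germline sample
#'   (default `TRUE`).
#' @param low_af_cutoff allele-frequency threshold used by
#'   [low_af_fraction()]; strictly-below counts as low (default 0.05).
#' @param cnv_log2_threshold magnitude above which a gene's read-depth log2
#'   ratio is called a gain (`> +t`) or loss (`< -t`) (default 0.7).
#' @param support_reads whether the `min_alt_reads` rule counts
#'   variant-supporting reads (`"alt"`, default) or total reads at the locus
#'   (`"total"`).
#' @param sd_type standard-deviation convention for coverage summaries:
#'   `"sample"` (n-1 divisor, default) or `"population"` (n divisor).
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(min_coverage = 100, min_alt_reads = 5,
                          exclude_dbsnp = TRUE, exclude_germline = TRUE,
                          low_af_cutoff = 0.05, cnv_log2_threshold = 0.7,
                          support_reads = c("alt", "total"),
                          sd_type = c("sample", "population")) {
  support_reads <- match.arg(support_reads)
  sd_type <- match.arg(sd_type)
  if (min_coverage < 0 || min_alt_reads < 0 || cnv_log2_threshold < 0)
    stopf("filter thresholds must be >= 0")
  if (!(low_af_cutoff > 0 && low_af_cutoff < 1))
    stopf("low_af_cutoff must lie in (0, 1)")
  structure(list(min_coverage = min_coverage, min_alt_reads = min_alt_reads,
                 exclude_dbsnp = isTRUE(exclude_dbsnp),
                 exclude_germline = isTRUE(exclude_germline),
                 low_af_cutoff = low_af_cutoff,
                 cnv_log2_threshold = cnv_log2_threshold,
                 support_reads = support_reads, sd_type = sd_type),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat("Somatic filter policy\n")
  cat(sprintf("  coverage >= %g, %s reads >= %g\n", x$min_coverage,
              if (x$support_reads == "alt") "supporting" else "total",
              x$min_alt_reads))
  cat(sprintf("  exclude dbSNP: %s; exclude germline: %s\n",
              x$exclude_dbsnp, x$exclude_germline))
  cat(sprintf("  low-AF cutoff: %g; gene CNV |log2| > %g\n",
              x$low_af_cutoff, x$cnv_log2_threshold))
  invisible(x)
}

#' Apply the somatic inclusion filter
#'
#' Retains exactly the candidates with coverage at or above the policy
#' minimum, supporting reads at or above the policy minimum, and (when the
#' corresponding exclusions are active) absent from dbSNP and from the
#' germline sample. Each candidate is judged independently; there is no
#' rescue of low-support calls shared across lesions. Row order is preserved
#' and the operation is idempotent.
#'
#' @param candidates a validated mutation `data.frame`
#'   (see [read_mutation_table()]).
#' @param policy a [filter_policy()].
#' @return the retained subset, same columns, original order.
#' @export
filter_mutations <- function(candidates, policy = filter_policy()) {
  validate_mutations(candidates, what = "candidate mutations")
  stopifnot(inherits(policy, "filter_policy"))
  if (nrow(candidates) == 0) return(candidates)
  support <- if (policy$support_reads == "alt") candidates$alt_reads
             else candidates$coverage
  keep <- candidates$coverage >= policy$min_coverage &
    support >= policy$min_alt_reads
  if (policy$exclude_dbsnp) keep <- keep & !candidates$in_dbsnp
  if (policy$exclude_germline) keep <- keep & !candidates$in_germline
  candidates[keep, , drop = FALSE]
}

#' Call a gene-level CNV from a read-depth log2 ratio
#'
#' A gene is called a gain iff its log2 ratio is strictly greater than the
#' policy threshold, a loss iff strictly smaller than minus the threshold,
#' and neutral otherwise. The function is antisymmetric: negating the input
#' swaps gain and loss and fixes neutral.
#'
#' @param log2_ratio numeric vector of signed read-depth log2 ratios.
#' @param policy a [filter_policy()]; only `cnv_log2_threshold` is used.
#' @return character vector in `c("gain", "loss", "neutral")`.
#' @export
#' @examples
#' call_gene_cnv(c(0.71, 0.7, -0.71))
call_gene_cnv <- function(log2_ratio, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (any(!is.finite(log2_ratio)))
    stopf("log2_ratio must be finite")
  t <- policy$cnv_log2_threshold
  ifelse(log2_ratio > t, "gain", ifelse(log2_ratio < -t, "loss", "neutral"))
}

#' Fraction of mutations with low allele frequency
#'
#' Proportion of calls whose allele frequency is strictly below the policy
#' cutoff (default 0.05).
#'
#' @param mutations a non-empty mutation `data.frame`.
#' @param policy a [filter_policy()].
#' @return a fraction in \[0, 1\].
#' @export
low_af_fraction <- function(mutations, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (is.null(mutations) || nrow(mutations) == 0)
    stopf("low_af_fraction is undefined for an empty mutation set")
  mean(mutations$allele_frequency < policy$low_af_cutoff)
}

#' Summarize one lesion's filtered events
#'
#' Counts of mutations (total, exonic, distinct genes), mean and standard
#' deviation of coverage, allele-frequency ranges by region class, and gene
#' CNV counts by direction. For a single mutation the standard deviation is
#' reported as 0 by convention.
#'
#' @param mutations a (filtered) mutation `data.frame` for one lesion.
#' @param gene_cnvs optional gene CNV `data.frame` (`gene`, `direction`).
#' @param policy a [filter_policy()]; `sd_type` selects the n-1 (`"sample"`)
#'   or n (`"population"`) divisor for the coverage standard deviation.
#' @return an object of class `lesion_summary` (a list).
#' @export
summarize_lesion <- function(mutations, gene_cnvs = NULL,
                             policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  n <- if (is.null(mutations)) 0L else nrow(mutations)
  af_range <- function(cls) {
    af <- mutations$allele_frequency[mutations$region_class == cls]
    if (length(af) == 0) c(NA_real_, NA_real_) else range(af)
  }
  cov_sd <- if (n <= 1) 0 else {
    s <- sd(mutations$coverage)
    if (policy$sd_type == "population") s * sqrt((n - 1) / n) else s
  }
  out <- list(
    n_mutations = n,
    n_exon = if (n) sum(mutations$region_class == "exon") else 0L,
    n_genes = if (n) length(unique(mutations$gene)) else 0L,
    coverage_mean = if (n) mean(mutations$coverage) else NA_real_,
    coverage_sd = if (n) cov_sd else NA_real_,
    af_range_exon = if (n) af_range("exon") else c(NA_real_, NA_real_),
    af_range_non_exon = if (n) af_range("non-exon") else c(NA_real_, NA_real_),
    n_gene_gain = if (is.null(gene_cnvs)) 0L
                  else sum(gene_cnvs$direction == "gain"),
    n_gene_loss = if (is.null(gene_cnvs)) 0L
                  else sum(gene_cnvs$direction == "loss"))
  structure(out, class = "lesion_summary")
}

#' @export
print.lesion_summary <- function(x, ...) {
  cat(sprintf("Lesion summary: %d mutations (%d exonic) in %d genes\n",
              x$n_mutations, x$n_exon, x$n_genes))
  if (x$n_mutations)
    cat(sprintf("  coverage %.1f +/- %.1f\n", x$coverage_mean, x$coverage_sd))
  cat(sprintf("  gene CNVs: %d gains, %d losses\n",
              x$n_gene_gain, x$n_gene_loss))
  invisible(x)
}
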