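#' Test for nonsense-mediated decay from gDNA/cDNA allele balance
#'
#' In a heterozygous carrier, genomic DNA shows the two alleles at a 1:1
#' ratio; depletion of the mutant allele in cDNA indicates degradation of the
#' mutant transcript. Counts are compared with exact tests (suitable for
#' small depths): each source against 0.5 by a two-sided exact binomial test,
#' and gDNA against cDNA by Fisher's exact test on the 2x2 table. Reported
#' p-values are two-sided; the direction (mutant *under*-representation) is
#' applied at classification time.
#'
#' Classification rules (mutant = alt allele):
#' * `complete_absence`: no mutant cDNA reads and gDNA consistent with 0.5;
#' * `partial_nmd`: cDNA mutant fraction significantly below 0.5, gDNA not
#'   significantly off 0.5, and gDNA vs cDNA significantly different;
#' * `no_depletion`: no test significant;
#' * `inconclusive`: anything else.
#'
#' @param gdna,cdna [allele_counts()] with positive totals.
#' @param alpha significance level (default 0.05).
#' @return List of class `"nmd_result"`: `gdna_alt_fraction`,
#'   `cdna_alt_fraction`, `p_gdna_vs_half`, `p_cdna_vs_half`,
#'   `p_gdna_vs_cdna`, `classification`.
#' @examples
#' nmd_classify(allele_counts("gdna", 50, 50), allele_counts("cdna", 80, 20))
#' @export
nmd_classify <- function(gdna, cdna, alpha = 0.05) {
  ng <- gdna$ref_count + gdna$alt_count
  nc <- cdna$ref_count + cdna$alt_count
  if (ng <= 0 || nc <= 0) stop("both sources need a positive total count")
  p_g <- stats::binom.test(gdna$alt_count, ng, p = 0.5)$p.value
  p_c <- stats::binom.test(cdna$alt_count, nc, p = 0.5)$p.value
  p_gc <- stats::fisher.test(matrix(c(gdna$ref_count, gdna$alt_count,
                                      cdna$ref_count, cdna$alt_count),
                                    nrow = 2))$p.value
  f_g <- gdna$alt_count / ng
  f_c <- cdna$alt_count / nc
  gdna_balanced <- p_g >= alpha
  cdna_depleted <- p_c < alpha && f_c < 0.5
  classification <- if (cdna$alt_count == 0 && gdna_balanced) {
    "complete_absence"
  } else if (cdna_depleted && gdna_balanced && p_gc < alpha) {
    "partial_nmd"
  } else if (p_g >= alpha && p_c >= alpha && p_gc >= alpha) {
    "no_depletion"
  } else {
    "inconclusive"
  }
  structure(list(gdna_alt_fraction = f_g, cdna_alt_fraction = f_c,
                 p_gdna_vs_half = p_g, p_cdna_vs_half = p_c,
                 p_gdna_vs_cdna = p_gc, classification = classification),
            class = "nmd_result")
}

#' @method print nmd_result
#' @export
print.nmd_result <- function(x, ...) {
  cat(sprintf("<nmd_result> %s\n  gDNA alt fraction %.3f (p vs 0.5 = %.3g)\n  cDNA alt fraction %.3f (p vs 0.5 = %.3g)\n  gDNA vs cDNA p = %.3g\n",
              x$classification, x$gdna_alt_fraction, x$p_gdna_vs_half,
              x$cdna_alt_fraction, x$p_cdna_vs_half, x$p_gdna_vs_cdna))
  invisible(x)
}
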