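#' Analysis thresholds
#'
#' Bundles every tunable cut-off of the pipeline in one place. Defaults are
#' the operating values of the published protocol this package implements:
#' mapping and base qualities must exceed 20 (Phred), a partial haplotype
#' needs at least 70% of its bases to be rescued, genomic samples need more
#' than 20x accepted coverage per locus and plasma at least 1000x, maternal
#' haplotypes must keep a relative frequency of at least 12% in plasma, and
#' the paternally inherited foetal haplotype is searched in the 1--12%
#' relative-frequency window (half of a 2--24% total foetal fraction).
#'
#' @param mapq_min minimum mapping quality; reads are kept when mapq is
#'   strictly greater than this value.
#' @param baseq_min minimum base quality; bases with Phred quality strictly
#'   below this are masked to `"-"`.
#' @param min_known_frac minimum fraction of non-`"-"` symbols for a partial
#'   haplotype to be eligible for pairing with a total haplotype.
#' @param genomic_min_cov accepted-read coverage a genomic (mother/father)
#'   locus must strictly exceed to be callable.
#' @param plasma_min_cov minimum accepted-read coverage for a plasma locus.
#' @param maternal_cutoff minimum plasma relative frequency for each
#'   confirmed maternal haplotype; any non-maternal haplotype above this
#'   dismisses the locus.
#' @param ff_low,ff_high relative-frequency window (inclusive) in which a
#'   non-maternal plasma haplotype counts as a candidate paternal haplotype.
#' @param minor_min relative frequency a haplotype must strictly exceed to
#'   count towards the genotype rule table.
#' @param hom_frac relative frequency a haplotype must strictly exceed for a
#'   homozygous call.
#' @param het_low,het_high inclusive band in which two haplotypes are called
#'   heterozygous.
#' @param three_hap threshold (strict) selecting two haplotypes out of three
#'   in the three-haplotype heterozygous rule.
#' @param mutation_rate per-locus per-generation SNP mutation rate used when
#'   a paternal mismatch is attributed to mutation.
#' @param min_freq lowest population frequency a haplotype is assumed to
#'   have (2e-4, one observation in 5008 panel chromosomes).
#' @param min_loci number of informative loci below which a report is
#'   flagged as under-powered.
#' @param w_report probability-of-paternity reporting threshold for
#'   inclusion.
#' @return A named list of class `"mh_thresholds"`.
#' @examples
#' th <- mh_thresholds()
#' th$maternal_cutoff
#' @export
mh_thresholds <- function(mapq_min = 20L,
                          baseq_min = 20L,
                          min_known_frac = 0.70,
                          genomic_min_cov = 20L,
                          plasma_min_cov = 1000L,
                          maternal_cutoff = 0.12,
                          ff_low = 0.01,
                          ff_high = 0.12,
                          minor_min = 0.10,
                          hom_frac = 0.80,
                          het_low = 0.20,
                          het_high = 0.80,
                          three_hap = 0.35,
                          mutation_rate = 1e-8,
                          min_freq = 2e-4,
                          min_loci = 15L,
                          w_report = 0.99) {
  th <- list(mapq_min = mapq_min, baseq_min = baseq_min,
             min_known_frac = min_known_frac,
             genomic_min_cov = genomic_min_cov,
             plasma_min_cov = plasma_min_cov,
             maternal_cutoff = maternal_cutoff,
             ff_low = ff_low, ff_high = ff_high,
             minor_min = minor_min, hom_frac = hom_frac,
             het_low = het_low, het_high = het_high,
             three_hap = three_hap,
             mutation_rate = mutation_rate, min_freq = min_freq,
             min_loci = min_loci, w_report = w_report)
  stopifnot(th$mutation_rate > 0, th$min_freq > 0,
            th$ff_low <= th$ff_high, th$min_known_frac > 0,
            th$min_known_frac <= 1)
  class(th) <- "mh_thresholds"
  th
}
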