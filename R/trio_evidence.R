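#' Classical trio evidence at one locus from full genotypes
#'
#' Evaluates paternity evidence when the child's genotype is known
#' directly (as in genotype-level simulations), rather than observed
#' through the plasma admixture. The possible paternal haplotypes are the
#' child haplotypes whose partner haplotype can have come from the mother;
#' the alleged father is discrepant when he carries none of them. The
#' paternity index is the classical trio likelihood ratio
#' `PI = T(P) / F(P)`: `T(P)` the fraction of the father's two haplotype
#' copies in the possible-paternal set `P`, `F(P)` the summed population
#' frequency of `P` (capped at 1). For a child `a/b` with only `b`
#' maternal this reduces to the textbook `T(a)/p_a`.
#'
#' @param mother_gt,child_gt,father_gt length-2 haplotype vectors.
#' @param freq_table the locus [haplotype_frequencies()] table.
#' @return A list: `verdict` (`"consistent"`/`"discrepant"`),
#'   `possible_paternal` (character), `pi` (`NA` when discrepant).
#' @export
trio_evidence <- function(mother_gt, child_gt, father_gt, freq_table) {
  a <- child_gt[1L]; b <- child_gt[2L]
  poss <- unique(c(if (b %in% mother_gt) a, if (a %in% mother_gt) b))
  if (length(poss) == 0L)
    stop("child genotype incompatible with the mother at ",
         freq_table$locus_id)
  tr <- mean(father_gt %in% poss)
  if (tr == 0) {
    return(list(verdict = "discrepant", possible_paternal = poss,
                pi = NA_real_))
  }
  FP <- min(1, sum(vapply(poss, function(h) lookup_frequency(freq_table, h),
                          0)))
  list(verdict = "consistent", possible_paternal = poss, pi = tr / FP)
}
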