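#' Call a microhaplotype genotype from a genomic-sample profile
#'
#' Applies the sequential rule table used to identify haplotypes from
#' amplicon read profiles of the mother or the alleged father. Coverage
#' must strictly exceed `genomic_min_cov` (default 20x). Let `k` be the
#' number of haplotypes with relative frequency strictly above 10%:
#'
#' * `k = 1` and that haplotype above 80%: homozygous;
#' * `k = 2` and one haplotype above 80%: homozygous for it;
#' * `k = 2` and both within 20--80% (inclusive): heterozygous;
#' * `k = 3` and exactly two above 35%: heterozygous for those two;
#' * anything else: `no_call`.
#'
#' @param profile a `"locus_profile"` from [build_locus_profile()].
#' @param thresholds an [mh_thresholds()] list.
#' @return A list of class `"genotype_call"`: `locus_id`, `status`
#'   (`"called"`, `"no_call"`, `"low_coverage"`), `haplotypes` (1 string if
#'   homozygous, 2 if heterozygous), `zygosity`.
#' @export
call_genotype <- function(profile, thresholds = mh_thresholds()) {
  th <- thresholds
  out <- list(locus_id = profile$locus_id, status = "no_call",
              haplotypes = character(0L), zygosity = NA_character_)
  class(out) <- "genotype_call"
  if (profile$coverage <= th$genomic_min_cov) {
    out$status <- "low_coverage"
    return(out)
  }
  f <- sort(profile$rel_freqs, decreasing = TRUE)
  major <- f[f > th$minor_min]
  k <- length(major)
  if (k == 1L && major[1L] > th$hom_frac) {
    out$status <- "called"; out$zygosity <- "homozygous"
    out$haplotypes <- names(major)[1L]
  } else if (k == 2L) {
    if (sum(major > th$hom_frac) == 1L) {
      out$status <- "called"; out$zygosity <- "homozygous"
      out$haplotypes <- names(major)[which(major > th$hom_frac)]
    } else if (all(major >= th$het_low & major <= th$het_high)) {
      out$status <- "called"; out$zygosity <- "heterozygous"
      out$haplotypes <- names(major)[1:2]
    }
  } else if (k == 3L && sum(major > th$three_hap) == 2L) {
    out$status <- "called"; out$zygosity <- "heterozygous"
    out$haplotypes <- names(major)[major > th$three_hap]
  }
  out
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(x$locus_id, ": ", x$status,
      if (x$status == "called")
        paste0(" (", x$zygosity, " ",
               paste(x$haplotypes, collapse = "/"), ")"),
      "\n", sep = "")
  invisible(x)
}

genotype_haplotypes <- function(call) {
  # the two transmitted copies (homozygous call duplicated)
  if (length(call$haplotypes) == 1L) rep(call$haplotypes, 2L)
  else call$haplotypes
}

#' Analyze a maternal-plasma locus profile
#'
#' Maternal plasma carries maternal cell-free DNA plus a minor foetal
#' component, half of which is the paternally inherited haplotype. A locus
#' is interpretable only when plasma coverage reaches 1000x, every
#' confirmed maternal haplotype keeps a relative frequency of at least 12%,
#' and no non-maternal haplotype rises above that 12% cut-off (such a locus
#' is dismissed: a genuine paternal haplotype that high would imply an
#' implausible total foetal fraction, so it is treated as an artefact).
#' Non-maternal haplotypes with relative frequency inside the foetal
#' detection window (1--12%, inclusive) are the candidate paternal
#' haplotypes.
#'
#' @param profile a plasma `"locus_profile"`.
#' @param mother_call the mother's `"genotype_call"` at the locus (must be
#'   `called`).
#' @param thresholds an [mh_thresholds()] list.
#' @return A list of class `"plasma_profile"`: `locus_id`, `usable`,
#'   `dismiss_reason` (`"none"`, `"low_coverage"`,
#'   `"maternal_below_cutoff"`, `"foreign_above_cutoff"`),
#'   `maternal_haplotypes` (named rel freqs), `candidate_paternal`
#'   (named rel freqs inside the window), `coverage`.
#' @export
analyze_plasma_locus <- function(profile, mother_call,
                                 thresholds = mh_thresholds()) {
  th <- thresholds
  if (!inherits(mother_call, "genotype_call") ||
      mother_call$status != "called")
    stop("mother genotype not called at ", profile$locus_id,
         ": plasma locus cannot be interpreted")
  mhaps <- unique(mother_call$haplotypes)
  mfreq <- stats::setNames(
    ifelse(mhaps %in% names(profile$rel_freqs),
           profile$rel_freqs[mhaps], 0), mhaps)
  out <- list(locus_id = profile$locus_id, usable = FALSE,
              dismiss_reason = "none",
              maternal_haplotypes = mfreq,
              candidate_paternal = numeric(0L),
              coverage = profile$coverage)
  class(out) <- "plasma_profile"
  if (profile$coverage < th$plasma_min_cov) {
    out$dismiss_reason <- "low_coverage"
    return(out)
  }
  if (any(mfreq < th$maternal_cutoff)) {
    out$dismiss_reason <- "maternal_below_cutoff"
    return(out)
  }
  other <- profile$rel_freqs[setdiff(names(profile$rel_freqs), mhaps)]
  if (any(other > th$maternal_cutoff)) {
    out$dismiss_reason <- "foreign_above_cutoff"
    return(out)
  }
  out$usable <- TRUE
  out$candidate_paternal <- other[other >= th$ff_low & other <= th$ff_high]
  out
}

#' @export
print.plasma_profile <- function(x, ...) {
  cat("Plasma locus ", x$locus_id, ": ",
      if (x$usable) "usable" else paste0("dismissed (", x$dismiss_reason, ")"),
      ", coverage ", x$coverage, "\n", sep = "")
  if (length(x$maternal_haplotypes))
    cat("  maternal:",
        paste(names(x$maternal_haplotypes),
              signif(x$maternal_haplotypes, 3), sep = "=", collapse = " "),
        "\n")
  if (length(x$candidate_paternal))
    cat("  candidate paternal:",
        paste(names(x$candidate_paternal),
              signif(x$candidate_paternal, 3), sep = "=", collapse = " "),
        "\n")
  invisible(x)
}

#' Estimate the foetal fraction from plasma candidate haplotypes
#'
#' At loci where a plasma candidate haplotype matches the alleged father
#' (and, by construction, differs from the mother) its relative frequency
#' estimates the paternally inherited half of the foetal fraction. The
#' per-locus values are summarized by their median -- robust to the
#' locus-to-locus noise sequencing errors introduce -- and doubled to give
#' the total foetal fraction.
#'
#' @param plasma_profiles named list of `"plasma_profile"` objects.
#' @param father_calls named list of the father's `"genotype_call"`s.
#' @return A list of class `"foetal_fraction"`: `available`, `per_locus`
#'   (named numeric, paternal-haplotype rel freq per informative locus),
#'   `paternal_fraction` (median), `total_ff` (2x the median).
#' @export
estimate_foetal_fraction <- function(plasma_profiles, father_calls) {
  per <- numeric(0L)
  for (loc in names(plasma_profiles)) {
    pp <- plasma_profiles[[loc]]
    fc <- father_calls[[loc]]
    if (is.null(pp) || !pp$usable || is.null(fc) || fc$status != "called")
      next
    cand <- pp$candidate_paternal
    hit <- cand[names(cand) %in% fc$haplotypes]
    if (length(hit)) per[loc] <- max(hit)
  }
  if (length(per) == 0L)
    return(structure(list(available = FALSE, per_locus = per,
                          paternal_fraction = NA_real_,
                          total_ff = NA_real_),
                     class = "foetal_fraction"))
  pf <- stats::median(per)
  structure(list(available = TRUE, per_locus = per,
                 paternal_fraction = pf, total_ff = 2 * pf),
            class = "foetal_fraction")
}

#' @export
print.foetal_fraction <- function(x, ...) {
  if (!x$available) {
    cat("Foetal fraction: unavailable (no informative locus)\n")
  } else {
    cat("Foetal fraction: total ", signif(100 * x$total_ff, 3),
        "% (paternal half ", signif(100 * x$paternal_fraction, 3),
        "%, ", length(x$per_locus), " informative loci)\n", sep = "")
  }
  invisible(x)
}
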