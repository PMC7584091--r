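#' Evaluate the paternity evidence at one locus
#'
#' Classifies the locus by the combination of (a) `shared_count`, the
#' number of haplotypes the alleged father has in common with the mother,
#' and (b) `ff_count`, the number of plasma candidate haplotypes (non-
#' maternal, inside the foetal window) that match the alleged father. Only
#' the combination (0, 0) -- no shared haplotype and no matching foetal
#' candidate -- is evidence against paternity (`discrepant`); every other
#' combination is `consistent`.
#'
#' The obligate paternal haplotype is the matching candidate when there is
#' exactly one; with two matching candidates one of them must be an
#' artefact and the one with the higher population frequency is taken as
#' the true paternal haplotype. When no candidate is seen but the parents
#' share haplotypes, the paternal haplotype is masked by the maternal
#' signal: the possible paternal haplotypes under paternity are recorded
#' as the ambiguity set (shared haplotypes).
#'
#' @param father_call,mother_call `"genotype_call"` objects (both
#'   `called`).
#' @param plasma_profile a usable `"plasma_profile"`.
#' @param freq_table the locus [haplotype_frequencies()] table.
#' @return A list of class `"locus_evidence"`: `locus_id`, `shared_count`,
#'   `ff_count`, `verdict` (`"consistent"`/`"discrepant"`),
#'   `obligate_haplotype` (character, possibly length > 1 for an ambiguity
#'   set, length 0 when discrepant), `ambiguous` (logical), `pi`
#'   (paternity index; `NA` for discrepant loci), `unmatched_candidates`
#'   (plasma candidates matching no father haplotype, logged).
#' @export
evaluate_locus <- function(father_call, mother_call, plasma_profile,
                           freq_table) {
  if (father_call$status != "called" || mother_call$status != "called")
    stop("both parents must be called at ", plasma_profile$locus_id)
  if (!plasma_profile$usable)
    stop("plasma locus ", plasma_profile$locus_id,
         " was dismissed (", plasma_profile$dismiss_reason, ")")
  fhaps <- unique(father_call$haplotypes)
  mhaps <- unique(mother_call$haplotypes)
  shared <- intersect(fhaps, mhaps)
  cand <- plasma_profile$candidate_paternal
  match_f <- names(cand)[names(cand) %in% fhaps]
  unmatched <- names(cand)[!names(cand) %in% fhaps]
  shared_count <- length(shared)
  ff_count <- length(match_f)
  ev <- list(locus_id = plasma_profile$locus_id,
             shared_count = shared_count, ff_count = ff_count,
             verdict = "consistent", obligate_haplotype = character(0L),
             ambiguous = FALSE, pi = NA_real_,
             unmatched_candidates = unmatched)
  class(ev) <- "locus_evidence"
  if (shared_count == 0L && ff_count == 0L) {
    ev$verdict <- "discrepant"
    return(ev)
  }
  if (ff_count == 1L) {
    ev$obligate_haplotype <- match_f
  } else if (ff_count >= 2L) {
    pf <- vapply(match_f, function(h) lookup_frequency(freq_table, h), 0)
    ev$obligate_haplotype <- match_f[which.max(pf)]
  } else {                       # ff_count == 0, shared_count >= 1
    ev$obligate_haplotype <- shared
    ev$ambiguous <- TRUE
  }
  ev$pi <- locus_pi(ev, father_call, freq_table,
                    mother_call = mother_call)
  ev
}

#' Paternity index of a consistent locus
#'
#' The per-locus likelihood ratio of the plasma evidence under "the
#' alleged father is the father" versus "a random man is the father".
#'
#' With an unambiguous obligate paternal haplotype `h` of population
#' frequency `p`, `pi = T/p` where the transmission probability `T` is 1
#' for a father homozygous for `h` and 0.5 for a heterozygous carrier.
#'
#' When the paternal haplotype is masked by the maternal signal (no
#' plasma candidate, parents share haplotypes), the foetus's paternal
#' haplotype can be any maternal haplotype: `pi = T(M)/F(M)`, where `T(M)`
#' is the fraction of the father's two haplotype copies lying in the
#' maternal set `M` and `F(M)` is the summed population frequency of `M`
#' (capped at 1). This reduces to `T/p` when `M` has one element and
#' agrees with the likelihood ratio obtained by enumerating all paternal
#' transmissions consistent with the plasma pattern.
#'
#' @param evidence a consistent `"locus_evidence"`.
#' @param father_call the father's `"genotype_call"`.
#' @param freq_table the locus [haplotype_frequencies()] table.
#' @param mother_call the mother's `"genotype_call"`; required for the
#'   masked (ambiguous) case.
#' @return The paternity index (positive).
#' @export
locus_pi <- function(evidence, father_call, freq_table,
                     mother_call = NULL) {
  if (evidence$verdict != "consistent")
    stop("locus ", evidence$locus_id,
         " is discrepant; use mutation_pi() for the audit value")
  fcopies <- genotype_haplotypes(father_call)
  if (!evidence$ambiguous) {
    h <- evidence$obligate_haplotype
    tr <- mean(fcopies == h)
    p <- lookup_frequency(freq_table, h)
    return(tr / p)
  }
  if (is.null(mother_call))
    stop("mother_call needed for a masked paternal haplotype")
  M <- unique(mother_call$haplotypes)
  tr <- mean(fcopies %in% M)
  FM <- min(1, sum(vapply(M, function(h) lookup_frequency(freq_table, h), 0)))
  tr / FM
}

#' Paternity index attributed to mutation
#'
#' When no paternal haplotype is consistent with the plasma evidence, the
#' mismatch can be attributed to a germ-line mutation. The index is the
#' SNP mutation rate divided by the lowest population frequency a
#' haplotype can take; with the defaults (1e-8 per locus per generation
#' and 2e-4) this gives 5e-5. Multiple mismatching SNPs still count as a
#' single mutation event, so the value does not depend on the number of
#' differing positions.
#'
#' @param mutation_rate SNP mutation rate per locus per generation.
#' @param min_freq minimum haplotype population frequency.
#' @return The mutation paternity index.
#' @export
mutation_pi <- function(mutation_rate = 1e-8, min_freq = 2e-4) {
  if (mutation_rate <= 0 || min_freq <= 0)
    stop("mutation_rate and min_freq must be positive")
  mutation_rate / min_freq
}

#' Combine per-locus evidence into a paternity report
#'
#' Two or more discrepant loci exclude paternity; exactly one is
#' inconclusive (a single mismatch may be a mutation or an artefact). With
#' no discrepancy the combined paternity index CPI is the product of the
#' per-locus indices (accumulated in log space) and the probability of
#' paternity is `W = CPI / (1 + CPI)` under 1:1 prior odds. For an
#' inconclusive case W over the consistent loci is still reported,
#' flagged; optionally the discrepant locus can contribute
#' [mutation_pi()] to that value. Reports based on fewer informative loci
#' than `min_loci` carry a low-marker flag.
#'
#' @param evidences list of `"locus_evidence"` objects.
#' @param thresholds an [mh_thresholds()] list.
#' @param case_id label for the report.
#' @param include_mutation_pi logical; if `TRUE`, discrepant loci
#'   contribute [mutation_pi()] to the reported W of non-exclusion cases
#'   (default `FALSE`: audit only).
#' @return A list of class `"paternity_report"`: `case_id`, `evidences`,
#'   `n_used`, `n_discrepant`, `decision` (`"exclusion"`,
#'   `"inconclusive"`, `"inclusion"`), `log10_cpi`, `cpi`, `w`,
#'   `low_marker_flag`, `audit_mutation_pi`.
#' @export
combine_evidence <- function(evidences, thresholds = mh_thresholds(),
                             case_id = "case",
                             include_mutation_pi = FALSE) {
  if (length(evidences) == 0L) stop("no locus evidence supplied")
  verdicts <- vapply(evidences, `[[`, "", "verdict")
  n_disc <- sum(verdicts == "discrepant")
  used <- evidences[verdicts == "consistent"]
  n_used <- length(used)
  mu_pi <- mutation_pi(thresholds$mutation_rate, thresholds$min_freq)
  lcpi <- sum(vapply(used, function(e) log10(e$pi), 0))
  if (include_mutation_pi) lcpi <- lcpi + n_disc * log10(mu_pi)
  decision <- if (n_disc >= 2L) "exclusion"
  else if (n_disc == 1L) "inconclusive"
  else "inclusion"
  w <- if (decision == "exclusion") NA_real_
  else 1 / (1 + 10^(-lcpi))            # cpi/(1+cpi), log-space safe
  rep <- list(case_id = case_id, evidences = evidences,
              n_used = n_used, n_discrepant = n_disc,
              decision = decision,
              log10_cpi = if (decision == "exclusion") NA_real_ else lcpi,
              cpi = if (decision == "exclusion") NA_real_ else 10^lcpi,
              w = w,
              low_marker_flag = n_used < thresholds$min_loci,
              audit_mutation_pi = mu_pi)
  class(rep) <- "paternity_report"
  rep
}

#' @export
print.paternity_report <- function(x, ...) {
  cat("Paternity report '", x$case_id, "': ", toupper(x$decision), "\n",
      sep = "")
  cat("  loci used: ", x$n_used, " consistent, ", x$n_discrepant,
      " discrepant", if (x$low_marker_flag) "  [fewer than recommended markers]",
      "\n", sep = "")
  if (!is.na(x$w))
    cat("  CPI = ", signif(x$cpi, 4), " (log10 ", round(x$log10_cpi, 3),
        "), W = ", signif(100 * x$w, 6), "%",
        if (x$decision == "inconclusive") "  [inconclusive: one discrepant locus]",
        "\n", sep = "")
  invisible(x)
}

#' @export
summary.paternity_report <- function(object, ...) {
  ev <- object$evidences
  tab <- data.frame(
    locus_id = vapply(ev, `[[`, "", "locus_id"),
    shared = vapply(ev, `[[`, 0L, "shared_count"),
    ff = vapply(ev, `[[`, 0L, "ff_count"),
    verdict = vapply(ev, `[[`, "", "verdict"),
    obligate = vapply(ev, function(e)
      paste(e$obligate_haplotype, collapse = "|"), ""),
    pi = vapply(ev, `[[`, 0, "pi"),
    stringsAsFactors = FALSE)
  out <- list(case_id = object$case_id, decision = object$decision,
              table = tab, cpi = object$cpi, w = object$w,
              low_marker_flag = object$low_marker_flag)
  class(out) <- "summary.paternity_report"
  out
}

#' @export
print.summary.paternity_report <- function(x, ...) {
  cat("Case ", x$case_id, " -- decision: ", x$decision, "\n", sep = "")
  print(x$table, row.names = FALSE)
  if (!is.na(x$w))
    cat("CPI = ", signif(x$cpi, 4), ", W = ", signif(100 * x$w, 6),
        "%\n", sep = "")
  invisible(x)
}

#' Write a paternity report to JSON and TSV
#'
#' @param report a `"paternity_report"`.
#' @param json_path,tsv_path output paths (`NULL` to skip either).
#' @return Invisibly, the written paths.
#' @export
write_paternity_report <- function(report, json_path = NULL,
                                   tsv_path = NULL) {
  s <- summary(report)
  if (!is.null(json_path)) {
    obj <- list(case_id = report$case_id, decision = report$decision,
                n_used = report$n_used,
                n_discrepant = report$n_discrepant,
                cpi = report$cpi, w = report$w,
                low_marker_flag = report$low_marker_flag,
                loci = s$table)
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(tsv_path))
    utils::write.table(s$table, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(json_path, tsv_path))
}
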