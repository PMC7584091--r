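#' Wrap a known genotype as a called genotype object
#'
#' Adapter used by the genotype-level simulations: turns an ordered pair of
#' haplotype strings into a `"genotype_call"` as if it had been called from
#' reads.
#'
#' @param locus_id locus label.
#' @param haplotypes character vector of 1 or 2 haplotype strings (a pair
#'   with equal strings collapses to a homozygous call).
#' @return A `"genotype_call"` with status `"called"`.
#' @export
as_genotype_call <- function(locus_id, haplotypes) {
  h <- unique(haplotypes)
  structure(list(locus_id = locus_id, status = "called",
                 haplotypes = h,
                 zygosity = if (length(h) == 1L) "homozygous"
                 else "heterozygous"),
            class = "genotype_call")
}

#' Simulate a mother/father/child trio from a reference panel
#'
#' Draws a mother and a father uniformly from the panel (from the same
#' population in `per_population` mode, from the pooled panel in `random`
#' mode) and builds a child who inherits, at every locus, one haplotype
#' from each parent chosen uniformly.
#'
#' Uses the current RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param panel a [reference_panel()].
#' @param mode `"random"` or `"per_population"`.
#' @return A list of class `"simulated_trio"`: `mother_id`, `father_id`,
#'   `population` (`NA` in random mode), and `mother`, `father`, `child` --
#'   named lists of length-2 haplotype vectors per locus (`child` ordered
#'   maternal then paternal). Loci where a drawn parent is uncalled are
#'   `NA`.
#' @export
simulate_trio <- function(panel, mode = c("random", "per_population")) {
  mode <- match.arg(mode)
  if (mode == "per_population") {
    if (is.null(panel$populations))
      stop("per_population mode needs population labels")
    sizes <- table(panel$populations)
    ok <- names(sizes)[sizes >= 2L]
    if (length(ok) == 0L)
      stop("no population has at least 2 samples")
    pop <- sample(ok, 1L)
    pool <- panel$samples[panel$populations == pop]
  } else {
    pop <- NA_character_
    pool <- panel$samples
    if (length(pool) < 2L) stop("panel needs at least 2 samples")
  }
  ids <- sample(pool, 2L)
  gt_of <- function(id) lapply(panel$haplotypes, function(h) h[id, ])
  mother <- gt_of(ids[1L])
  father <- gt_of(ids[2L])
  child <- mapply(function(m, f) {
    if (anyNA(m) || anyNA(f)) return(c(NA_character_, NA_character_))
    c(m[sample.int(2L, 1L)], f[sample.int(2L, 1L)])
  }, mother, father, SIMPLIFY = FALSE)
  structure(list(mother_id = ids[1L], father_id = ids[2L],
                 population = pop, mother = mother, father = father,
                 child = child),
            class = "simulated_trio")
}

#' Idealized plasma profile from mother and child genotypes
#'
#' Adapter letting genotype-level simulations feed the evidence machinery
#' without simulating reads: maternal haplotypes are placed at high
#' relative frequency and the child's non-maternal (paternal) haplotype,
#' when it exists, appears as a candidate at a configurable in-window
#' frequency.
#'
#' @param mother_gt,child_gt length-2 haplotype vectors.
#' @param locus_id locus label.
#' @param cand_freq relative frequency given to the paternal candidate
#'   (default 0.05, the middle of the detection window).
#' @return A usable `"plasma_profile"`.
#' @export
genotypes_to_ideal_plasma <- function(mother_gt, child_gt, locus_id,
                                      cand_freq = 0.05) {
  mhaps <- unique(mother_gt)
  paternal <- child_gt[2L]
  has_cand <- !paternal %in% mhaps
  rest <- if (has_cand) 1 - cand_freq else 1
  mfreq <- stats::setNames(rep(rest / length(mhaps), length(mhaps)), mhaps)
  cand <- if (has_cand) stats::setNames(cand_freq, paternal) else numeric(0L)
  structure(list(locus_id = locus_id, usable = TRUE,
                 dismiss_reason = "none",
                 maternal_haplotypes = mfreq,
                 candidate_paternal = cand,
                 coverage = NA_integer_),
            class = "plasma_profile")
}

#' True/false paternity power curve
#'
#' Repeats the trio simulation and evaluates the paternity decision as a
#' function of the number of microhaplotypes used. Per replicate a trio is
#' drawn; under `false_father` a second man, distinct from the true father
#' (and from the same population in `per_population` mode), is evaluated
#' against the mother-plasma duo. For each `n_loci` the first `n_loci`
#' panel loci feed [evaluate_locus()] via [genotypes_to_ideal_plasma()];
#' when W is tabulated, discrepant loci contribute [mutation_pi()]. A
#' false inclusion is a `false_father` replicate whose decision is
#' inclusion with `w > 0.99`.
#'
#' @param panel a [reference_panel()].
#' @param n_reps number of replicates.
#' @param mode `"random"` or `"per_population"`.
#' @param hypothesis `"true_father"` or `"false_father"`.
#' @param seed integer seed.
#' @param evidence `"trio"` (default) scores each locus from the full
#'   simulated child genotype with [trio_evidence()], matching how the
#'   simulated-trio experiment is defined; `"plasma"` instead pushes the
#'   genotypes through [genotypes_to_ideal_plasma()] and
#'   [evaluate_locus()], i.e. through the masked-plasma evidence rules
#'   used on real cases, which is deliberately weaker (a candidate
#'   haplotype can always be an artefact, so sharing a haplotype with the
#'   mother keeps a man consistent) and yields more false inclusions at a
#'   given marker count.
#' @param freq_tables optional precomputed pooled [haplotype_frequencies()]
#'   tables (named by locus); computed from the panel when `NULL`.
#' @param thresholds an [mh_thresholds()] list.
#' @param shuffle_loci if `TRUE`, a random locus order is drawn per
#'   replicate instead of panel order.
#' @param cand_freq candidate frequency for the ideal plasma adapter.
#' @return A list of class `"simulation_result"`: `mode`, `hypothesis`,
#'   `seed`, `results` (long data.frame: `replicate`, `n_loci`, `w`,
#'   `decision`), `false_inclusions` (named count per `n_loci`),
#'   `n_reps`.
#' @export
paternity_power_curve <- function(panel, n_reps, mode = "random",
                                  hypothesis = c("true_father",
                                                 "false_father"),
                                  seed = 1L,
                                  evidence = c("trio", "plasma"),
                                  freq_tables = NULL,
                                  thresholds = mh_thresholds(),
                                  shuffle_loci = FALSE,
                                  cand_freq = 0.05) {
  hypothesis <- match.arg(hypothesis)
  evidence <- match.arg(evidence)
  stopifnot(n_reps >= 1L)
  loci <- names(panel$haplotypes)
  L <- length(loci)
  if (is.null(freq_tables))
    freq_tables <- stats::setNames(
      lapply(loci, function(l) haplotype_frequencies(panel, l)), loci)
  mu_pi <- mutation_pi(thresholds$mutation_rate, thresholds$min_freq)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- vector("list", n_reps)
  fi <- stats::setNames(integer(L), seq_len(L))
  for (r in seq_len(n_reps)) {
    trio <- simulate_trio(panel, mode)
    alleged <- trio$father
    if (hypothesis == "false_father") {
      pool <- if (!is.na(trio$population))
        panel$samples[panel$populations == trio$population]
      else panel$samples
      # the second man is a man: neither the true father nor the mother
      pool <- setdiff(pool, c(trio$father_id, trio$mother_id))
      if (length(pool) == 0L) stop("no candidate second man available")
      id2 <- if (length(pool) == 1L) pool else sample(pool, 1L)
      alleged <- lapply(panel$haplotypes, function(h) h[id2, ])
    }
    order_loci <- if (shuffle_loci) sample(loci) else loci
    lpi <- numeric(L); disc <- logical(L)
    for (j in seq_len(L)) {
      loc <- order_loci[j]
      if (anyNA(trio$mother[[loc]]) || anyNA(alleged[[loc]]) ||
          anyNA(trio$child[[loc]])) {
        lpi[j] <- 0; disc[j] <- FALSE   # uncalled locus contributes nothing
        next
      }
      if (evidence == "trio") {
        ev <- trio_evidence(trio$mother[[loc]], trio$child[[loc]],
                            alleged[[loc]], freq_tables[[loc]])
      } else {
        mc <- as_genotype_call(loc, trio$mother[[loc]])
        fc <- as_genotype_call(loc, alleged[[loc]])
        pp <- genotypes_to_ideal_plasma(trio$mother[[loc]],
                                        trio$child[[loc]], loc, cand_freq)
        ev <- evaluate_locus(fc, mc, pp, freq_tables[[loc]])
      }
      if (ev$verdict == "discrepant") {
        disc[j] <- TRUE
        lpi[j] <- log10(mu_pi)
      } else {
        lpi[j] <- log10(ev$pi)
      }
    }
    cum_l <- cumsum(lpi)
    cum_d <- cumsum(disc)
    decision <- ifelse(cum_d >= 2L, "exclusion",
                       ifelse(cum_d == 1L, "inconclusive", "inclusion"))
    w <- 1 / (1 + 10^(-cum_l))
    if (hypothesis == "false_father") {
      hit <- decision == "inclusion" & w > thresholds$w_report
      fi <- fi + as.integer(hit)
    }
    rows[[r]] <- data.frame(replicate = r, n_loci = seq_len(L),
                            w = w, decision = decision,
                            stringsAsFactors = FALSE)
  }
  structure(list(mode = mode, hypothesis = hypothesis, seed = seed,
                 evidence = evidence,
                 results = do.call(rbind, rows),
                 false_inclusions = fi, n_reps = n_reps),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Paternity simulation: ", x$n_reps, " replicates, mode=", x$mode,
      ", hypothesis=", x$hypothesis, "\n", sep = "")
  med <- tapply(x$results$w, x$results$n_loci, stats::median)
  show <- unique(pmin(length(med), c(1, 5, 10, 13, 15, length(med))))
  cat("  median W by n_loci:\n")
  print(signif(med[as.character(show)], 4))
  if (x$hypothesis == "false_father") {
    cat("  false inclusions by n_loci:\n")
    print(x$false_inclusions[as.character(show)])
  }
  invisible(x)
}

#' Cross-evaluate mother-plasma duos against all alleged fathers
#'
#' Pairs every mother-plasma duo with every alleged father across a set of
#' processed cases and scores each pair with the probability of paternity
#' (exclusions score 0). Pairs with exactly one discrepant locus are
#' inconclusive and are excluded. For each minimum-marker cutoff, pairs
#' with fewer evaluated loci are dropped and an ROC curve over the
#' remaining pairs is computed (true pairings are the positives).
#'
#' @param cases list of case objects; each a list with `case_id`,
#'   `mother_calls`, `father_calls` (named lists of `"genotype_call"`),
#'   `plasma` (named list of `"plasma_profile"`), and `freq_tables`
#'   (named list of `"freq_table"`).
#' @param min_loci_values integer vector of minimum-marker cutoffs.
#' @param thresholds an [mh_thresholds()] list.
#' @return A list of class `"cross_evaluation"`: `pairs` (data.frame with
#'   `duo`, `father`, `true_pair`, `n_loci`, `n_discrepant`, `decision`,
#'   `score`) and `roc` (named list per cutoff: `auc`, `points`, `n_pairs`;
#'   `auc = NA` when a cutoff leaves fewer than one positive or one
#'   negative pair).
#' @export
cross_evaluate <- function(cases, min_loci_values = c(1L, 10L, 13L, 15L),
                           thresholds = mh_thresholds()) {
  if (length(cases) < 2L) stop("need at least 2 cases to cross-evaluate")
  rows <- list()
  for (i in seq_along(cases)) {
    duo <- cases[[i]]
    for (j in seq_along(cases)) {
      af <- cases[[j]]
      evs <- list()
      for (loc in names(duo$plasma)) {
        mc <- duo$mother_calls[[loc]]
        fc <- af$father_calls[[loc]]
        pp <- duo$plasma[[loc]]
        if (is.null(mc) || mc$status != "called" ||
            is.null(fc) || fc$status != "called" ||
            is.null(pp) || !pp$usable) next
        evs[[loc]] <- evaluate_locus(fc, mc, pp, duo$freq_tables[[loc]])
      }
      if (length(evs) == 0L) next
      rep <- combine_evidence(evs, thresholds,
                              case_id = paste0(duo$case_id, "x", af$case_id))
      rows[[length(rows) + 1L]] <- data.frame(
        duo = duo$case_id, father = af$case_id, true_pair = i == j,
        n_loci = rep$n_used + rep$n_discrepant,
        n_discrepant = rep$n_discrepant,
        decision = rep$decision,
        score = if (rep$decision == "exclusion") 0 else rep$w,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  usable <- pairs[pairs$decision != "inconclusive", , drop = FALSE]
  roc <- lapply(min_loci_values, function(m) {
    sub <- usable[usable$n_loci >= m, , drop = FALSE]
    if (nrow(sub) == 0L || length(unique(sub$true_pair)) < 2L)
      return(list(auc = NA_real_, points = NULL, n_pairs = nrow(sub)))
    r <- roc_points(sub$true_pair, sub$score)
    list(auc = r$auc, points = r$points, n_pairs = nrow(sub))
  })
  names(roc) <- as.character(min_loci_values)
  structure(list(pairs = pairs, roc = roc), class = "cross_evaluation")
}

#' @export
print.cross_evaluation <- function(x, ...) {
  cat("Cross-evaluation: ", nrow(x$pairs), " duo-father pairs (",
      sum(x$pairs$true_pair), " true)\n", sep = "")
  for (m in names(x$roc))
    cat("  min loci ", m, ": AUC = ",
        if (is.na(x$roc[[m]]$auc)) "undefined"
        else signif(x$roc[[m]]$auc, 4),
        " (", x$roc[[m]]$n_pairs, " pairs)\n", sep = "")
  invisible(x)
}

#' ROC points and AUC
#'
#' Standard threshold sweep over the distinct scores (ties grouped),
#' returning (false-positive rate, true-positive rate) points and the
#' trapezoid area under the curve.
#'
#' @param labels logical (or 0/1) vector; `TRUE` marks positives.
#' @param scores numeric scores, higher meaning more positive.
#' @return A list: `points` (data.frame `threshold`, `fpr`, `tpr`,
#'   starting at (0,0)) and `auc`.
#' @export
roc_points <- function(labels, scores) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("need at least one positive and one negative label")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels & scores >= t), 0)
  fp <- vapply(thr, function(t) sum(!labels & scores >= t), 0)
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       auc = auc)
}
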