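#' Build a phased reference panel object
#'
#' A reference panel holds, for every microhaplotype locus, the two phased
#' haplotype strings of each diploid sample. It is the population backdrop
#' against which case haplotypes are assigned frequencies for the paternity
#' index.
#'
#' @param samples character vector of sample ids (ordered).
#' @param haplotypes named list, one element per locus: a character matrix
#'   with `length(samples)` rows and 2 columns (phase 1, phase 2), row names
#'   the sample ids. `NA` marks a sample dropped at that locus (missing or
#'   unphased genotype).
#' @param populations optional named character vector mapping sample id to
#'   population label.
#' @return A list of class `"reference_panel"`.
#' @export
reference_panel <- function(samples, haplotypes, populations = NULL) {
  samples <- as.character(samples)
  stopifnot(is.list(haplotypes), length(haplotypes) >= 1)
  for (loc in names(haplotypes)) {
    h <- haplotypes[[loc]]
    if (!is.matrix(h) || ncol(h) != 2L || nrow(h) != length(samples))
      stop("locus ", loc, ": haplotypes must be an n_samples x 2 matrix")
    ok <- !is.na(h)
    if (any(ok) && length(unique(nchar(h[ok]))) > 1L)
      stop("locus ", loc, ": haplotype strings differ in length")
    # diploid phased: a sample is either fully called or fully dropped
    if (any(xor(is.na(h[, 1L]), is.na(h[, 2L]))))
      stop("locus ", loc, ": half-called sample")
    rownames(haplotypes[[loc]]) <- samples
  }
  if (!is.null(populations)) {
    populations <- populations[samples]
    if (anyNA(populations)) stop("populations must cover every sample")
  }
  structure(list(samples = samples, populations = populations,
                 haplotypes = haplotypes),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference panel: ", length(x$samples), " samples, ",
      length(x$haplotypes), " loci", sep = "")
  if (!is.null(x$populations))
    cat(", ", length(unique(x$populations)), " populations", sep = "")
  cat("\n")
  invisible(x)
}

#' Extract per-locus phased haplotypes from a multi-sample VCF
#'
#' Reads a phased VCF (plain or bgzipped) and, for each locus definition,
#' concatenates the phase-1 alleles at the SNP positions in order into
#' haplotype 1 and the phase-2 alleles into haplotype 2. Samples with a
#' missing allele at any SNP of a locus are dropped from that locus;
#' unphased genotypes are either dropped the same way (default) or abort
#' the extraction.
#'
#' @param vcf path to a VCF file, or a `vcfR::vcfR` object.
#' @param defs a [microhap_defs()] table whose SNP positions are all
#'   present in the VCF.
#' @param populations optional named character vector sample -> population.
#' @param on_unphased `"drop"` (drop the sample at that locus) or
#'   `"abort"`.
#' @return A [reference_panel()].
#' @export
extract_panel_haplotypes <- function(vcf, defs, populations = NULL,
                                     on_unphased = c("drop", "abort")) {
  on_unphased <- match.arg(on_unphased)
  if (is.character(vcf)) vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcf@gt[, -1L, drop = FALSE]
  samples <- colnames(gt)
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  alleles <- lapply(seq_len(nrow(fix)), function(i)
    c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]))
  # GT is the first colon-separated field
  gt_only <- sub(":.*$", "", gt)
  haps <- list()
  for (i in seq_len(nrow(defs))) {
    d <- def_row(defs, defs$locus_id[i])
    rows <- match(paste(d$chrom, d$snp_positions), key)
    if (anyNA(rows))
      stop("locus ", d$locus_id, ": SNP position(s) ",
           paste(d$snp_positions[is.na(rows)], collapse = ", "),
           " not present in the VCF")
    h1 <- matrix("", length(samples), length(rows))
    h2 <- h1
    drop <- rep(FALSE, length(samples))
    for (j in seq_along(rows)) {
      g <- gt_only[rows[j], ]
      miss <- is.na(g) | g %in% c(".", "./.", ".|.")
      unph <- !miss & grepl("/", g, fixed = TRUE)
      if (any(unph) && on_unphased == "abort")
        stop("locus ", d$locus_id, ": unphased genotype for sample(s) ",
             paste(samples[unph], collapse = ", "))
      drop <- drop | miss | unph
      parts <- strsplit(g, "|", fixed = TRUE)
      idx1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
      idx2 <- suppressWarnings(as.integer(vapply(parts, function(p)
        if (length(p) >= 2L) p[2L] else NA_character_, "")))
      al <- alleles[[rows[j]]]
      h1[, j] <- al[idx1 + 1L]
      h2[, j] <- al[idx2 + 1L]
      drop <- drop | is.na(h1[, j]) | is.na(h2[, j])
    }
    m <- cbind(apply(h1, 1L, paste, collapse = ""),
               apply(h2, 1L, paste, collapse = ""))
    m[drop, ] <- NA_character_
    haps[[d$locus_id]] <- m
  }
  reference_panel(samples, haps, populations)
}

#' Haplotype frequency table for one locus
#'
#' Counts phased chromosomes (two per retained sample) at a locus,
#' optionally restricted to one population, and derives relative
#' frequencies and the effective number of alleles A_e = 1 / sum(p_i^2).
#' Haplotypes are ordered by descending frequency, ties broken
#' lexicographically.
#'
#' @param panel a [reference_panel()].
#' @param locus_id locus to tabulate.
#' @param population optional population label to filter on (`NULL` pools
#'   all samples).
#' @return A list of class `"freq_table"` with elements `locus_id`,
#'   `haplotype`, `count`, `frequency`, `n_chromosomes`, `a_e`.
#' @examples
#' p <- reference_panel(c("s1", "s2"),
#'   list(L1 = matrix(c("AT", "GT", "AT", "GT"), 2, 2)))
#' haplotype_frequencies(p, "L1")
#' @export
haplotype_frequencies <- function(panel, locus_id, population = NULL) {
  h <- panel$haplotypes[[locus_id]]
  if (is.null(h)) stop("unknown locus: ", locus_id)
  keep <- rep(TRUE, length(panel$samples))
  if (!is.null(population)) {
    if (is.null(panel$populations))
      stop("panel has no population labels")
    keep <- panel$populations == population
    if (!any(keep))
      stop("no samples in population '", population, "'")
  }
  chroms <- as.vector(h[keep, , drop = FALSE])
  chroms <- chroms[!is.na(chroms)]
  if (length(chroms) == 0L)
    stop("locus ", locus_id, ": no called chromosomes after filtering")
  cnt <- table(chroms)
  ord <- order(-as.integer(cnt), names(cnt))
  cnt <- cnt[ord]
  freq <- as.numeric(cnt) / sum(cnt)
  structure(list(locus_id = locus_id,
                 haplotype = names(cnt),
                 count = as.integer(cnt),
                 frequency = freq,
                 n_chromosomes = as.integer(sum(cnt)),
                 a_e = 1 / sum(freq^2)),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Haplotype frequencies at ", x$locus_id, " (",
      x$n_chromosomes, " chromosomes, A_e = ", round(x$a_e, 2), ")\n",
      sep = "")
  print(data.frame(haplotype = x$haplotype, count = x$count,
                   frequency = signif(x$frequency, 4)), row.names = FALSE)
  invisible(x)
}

#' Population frequency of a haplotype, with the unseen-haplotype rule
#'
#' An observed haplotype gets its panel frequency. A haplotype never seen
#' in the panel is assigned `1 / (n_chromosomes + 1)`; with the 2504-sample
#' (5008-chromosome) panel used for the published frequencies this is
#' 1/5009.
#'
#' @param table a [haplotype_frequencies()] result.
#' @param haplotype query haplotype string (same length as the locus).
#' @return A single frequency in (0, 1].
#' @export
lookup_frequency <- function(table, haplotype) {
  stopifnot(inherits(table, "freq_table"), length(haplotype) == 1L)
  if (length(table$haplotype) &&
      nchar(haplotype) != nchar(table$haplotype[1L]))
    stop("haplotype length ", nchar(haplotype),
         " does not match locus haplotype length ",
         nchar(table$haplotype[1L]))
  i <- match(haplotype, table$haplotype)
  if (is.na(i)) 1 / (table$n_chromosomes + 1) else table$frequency[i]
}

#' Effective number of alleles
#'
#' A_e = 1 / sum(p_i^2), the inverse expected homozygosity: the number of
#' equifrequent alleles that would give the locus the same diversity.
#'
#' @param table a `"freq_table"`, or a numeric vector of frequencies
#'   summing to 1.
#' @return A_e, between 1 and the number of distinct haplotypes.
#' @export
effective_alleles <- function(table) {
  p <- if (inherits(table, "freq_table")) table$frequency else table
  if (length(p) == 0L) stop("empty frequency table")
  if (abs(sum(p) - 1) > 1e-9) stop("frequencies must sum to 1")
  1 / sum(p^2)
}

# chi-square distance of genotype counts from Hardy-Weinberg expectations
# given the allele counts; `geno` is an n x 2 matrix of integer allele codes
hwe_stat <- function(geno, k, n) {
  a <- pmin(geno[, 1L], geno[, 2L])
  b <- pmax(geno[, 1L], geno[, 2L])
  obs <- tabulate((a - 1L) * k + b, nbins = k * k)
  cnt <- tabulate(c(geno), nbins = k)
  p <- cnt / (2 * n)
  exp_mat <- n * (p %o% p)         # unordered pair (a,b), a<b gets 2*n*pa*pb
  exp_u <- exp_mat + t(exp_mat)
  diag(exp_u) <- diag(exp_mat)
  exp_u[lower.tri(exp_u)] <- 0
  e <- as.vector(t(exp_u))         # row-major to match (a-1)*k+b indexing
  use <- e > 0
  sum((obs[use] - e[use])^2 / e[use])
}

# all perfect matchings of 2n labelled tokens, as an iterator via recursion
enumerate_pairings <- function(tokens) {
  if (length(tokens) == 2L) return(list(matrix(tokens, 1L, 2L)))
  out <- list()
  first <- tokens[1L]
  rest <- tokens[-1L]
  for (j in seq_along(rest)) {
    sub <- enumerate_pairings(rest[-j])
    out <- c(out, lapply(sub, function(m)
      rbind(c(first, rest[j]), m)))
  }
  out
}

#' Hardy-Weinberg equilibrium test for a multi-allelic locus
#'
#' Microhaplotypes routinely carry many haplotypes, so asymptotic
#' chi-square on the genotype table is unreliable. The test statistic is
#' the chi-square distance of the observed genotype counts from their
#' Hardy-Weinberg expectations given the allele counts; the null
#' distribution is obtained by randomly re-pairing the pooled alleles into
#' genotypes (a permutation-exact test). For tiny panels all distinct
#' pairings can be enumerated instead (`method = "exact"`).
#'
#' @param panel a [reference_panel()].
#' @param locus_id locus to test.
#' @param population optional population filter.
#' @param seed integer seed for the Monte-Carlo permutations.
#' @param nperm number of permutations (`method = "mc"`).
#' @param method `"mc"` (default) or `"exact"` (full enumeration of allele
#'   pairings; only feasible for a handful of samples).
#' @return The p-value. Monomorphic loci return 1 with a warning.
#' @export
hwe_test <- function(panel, locus_id, population = NULL, seed = 1L,
                     nperm = 2000L, method = c("mc", "exact")) {
  method <- match.arg(method)
  h <- panel$haplotypes[[locus_id]]
  if (is.null(h)) stop("unknown locus: ", locus_id)
  if (!is.null(population)) {
    if (is.null(panel$populations)) stop("panel has no population labels")
    h <- h[panel$populations == population, , drop = FALSE]
  }
  h <- h[!is.na(h[, 1L]), , drop = FALSE]
  n <- nrow(h)
  if (n < 2L) stop("need at least 2 called samples at ", locus_id)
  lev <- sort(unique(as.vector(h)))
  k <- length(lev)
  if (k == 1L) {
    warning("locus ", locus_id, " is monomorphic; HWE p = 1")
    return(1)
  }
  geno <- matrix(match(h, lev), n, 2L)
  obs_stat <- hwe_stat(geno, k, n)
  pool <- c(geno)
  if (method == "exact") {
    pairings <- enumerate_pairings(seq_along(pool))
    stats <- vapply(pairings, function(m)
      hwe_stat(cbind(pool[m[, 1L]], pool[m[, 2L]]), k, n), 0)
    return(mean(stats >= obs_stat - 1e-12))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(nperm)) {
    perm <- sample(pool)
    g <- matrix(perm, n, 2L)
    if (hwe_stat(g, k, n) >= obs_stat - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (nperm + 1)
}

#' Linkage-equilibrium test between two loci
#'
#' Tests independence of the joint haplotype distribution of two loci over
#' phased chromosomes (two per sample, phase kept together across loci)
#' with a contingency chi-square; when any expected cell count is small
#' the p-value is computed from a seeded Monte-Carlo null instead of the
#' asymptotic distribution.
#'
#' @param panel a [reference_panel()].
#' @param locus_a,locus_b locus ids.
#' @param seed integer seed for the Monte-Carlo null.
#' @param nsim Monte-Carlo replicates.
#' @param population optional population filter.
#' @return The p-value.
#' @export
le_test <- function(panel, locus_a, locus_b, seed = 1L, nsim = 2000L,
                    population = NULL) {
  ha <- panel$haplotypes[[locus_a]]
  hb <- panel$haplotypes[[locus_b]]
  if (is.null(ha) || is.null(hb))
    stop("unknown locus: ", if (is.null(ha)) locus_a else locus_b)
  keep <- !is.na(ha[, 1L]) & !is.na(hb[, 1L])
  if (!is.null(population)) {
    if (is.null(panel$populations)) stop("panel has no population labels")
    keep <- keep & panel$populations == population
  }
  if (sum(keep) < 2L) stop("fewer than 2 samples called at both loci")
  a <- as.vector(ha[keep, ])
  b <- as.vector(hb[keep, ])
  tab <- table(a, b)
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(1)
  suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    ct <- stats::chisq.test(tab, simulate.p.value = TRUE, B = nsim)
  }
  unname(ct$p.value)
}

#' Panel quality-control report
#'
#' Per-locus summary used to screen a marker panel: called samples,
#' distinct haplotypes, effective number of alleles, HWE p-value with raw
#' and Bonferroni-adjusted pass flags.
#'
#' @param panel a [reference_panel()].
#' @param population optional population filter.
#' @param seed seed passed to [hwe_test()].
#' @param alpha significance level for the pass flags.
#' @param nperm permutations per HWE test.
#' @return A data.frame with columns `locus_id`, `n_samples`,
#'   `n_haplotypes`, `a_e`, `hwe_p`, `pass`, `pass_bonferroni`.
#' @export
panel_qc <- function(panel, population = NULL, seed = 1L, alpha = 0.05,
                     nperm = 2000L) {
  loci <- names(panel$haplotypes)
  rows <- lapply(seq_along(loci), function(i) {
    ft <- haplotype_frequencies(panel, loci[i], population)
    p <- suppressWarnings(
      hwe_test(panel, loci[i], population, seed = seed + i, nperm = nperm))
    data.frame(locus_id = loci[i],
               n_samples = ft$n_chromosomes %/% 2L,
               n_haplotypes = length(ft$haplotype),
               a_e = ft$a_e, hwe_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pass <- out$hwe_p >= alpha
  out$pass_bonferroni <- out$hwe_p >= alpha / nrow(out)
  out
}

#' Write per-locus frequency tables as TSV
#'
#' One file per locus with columns `locus_id`, `haplotype`, `count`,
#' `frequency`.
#'
#' @param panel a [reference_panel()].
#' @param dir output directory (created if needed).
#' @param population optional population filter.
#' @return The written paths, invisibly.
#' @export
write_frequency_tables <- function(panel, dir, population = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(panel$haplotypes), function(loc) {
    ft <- haplotype_frequencies(panel, loc, population)
    path <- file.path(dir, paste0(loc, "_freqs.tsv"))
    utils::write.table(
      data.frame(locus_id = ft$locus_id, haplotype = ft$haplotype,
                 count = ft$count, frequency = ft$frequency),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }, "")
  invisible(paths)
}

# save/restore the global RNG state so seeded helpers do not perturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
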