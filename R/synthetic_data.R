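#' Specification for a synthetic reference panel
#'
#' Describes a population panel the generator draws: loci with 2+ SNPs and
#' at least three haplotypes each (the defining property of an informative
#' microhaplotype), per-population haplotype frequencies from a symmetric
#' Dirichlet, and diploid samples drawn under Hardy-Weinberg equilibrium
#' within each population.
#'
#' @param n_loci number of microhaplotype loci.
#' @param n_haplotypes integer vector; the number of distinct haplotypes
#'   per locus is drawn uniformly from it (default 4--6, giving effective
#'   allele numbers around 3--5 at the default concentration).
#' @param n_snps integer vector; SNPs per locus drawn uniformly from it.
#' @param alpha symmetric Dirichlet concentration for the haplotype
#'   frequencies (larger = more even).
#' @param populations named integer vector of population sizes.
#' @param seed integer seed.
#' @return A list of class `"synth_panel_spec"`.
#' @export
synth_panel_spec <- function(n_loci = 20L, n_haplotypes = 4:6,
                             n_snps = 2:4, alpha = 3,
                             populations = c(POP1 = 50L, POP2 = 50L),
                             seed = 1L) {
  stopifnot(n_loci >= 1L, min(n_haplotypes) >= 3L, min(n_snps) >= 2L,
            alpha > 0, sum(populations) >= 2L)
  structure(list(n_loci = as.integer(n_loci),
                 n_haplotypes = as.integer(n_haplotypes),
                 n_snps = as.integer(n_snps), alpha = alpha,
                 populations = populations, seed = as.integer(seed)),
            class = "synth_panel_spec")
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

# distinct haplotype strings over per-SNP biallelic choices; every SNP
# segregates among the returned haplotypes. SNP count is raised when
# 2^n_snps cannot host n_hap distinct haplotypes.
make_haplotype_set <- function(n_hap, n_snps) {
  bases <- c("A", "C", "G", "T")
  n_snps <- max(n_snps, ceiling(log2(n_hap)))
  allele <- replicate(n_snps, sample(bases, 2L), simplify = FALSE)
  combos <- as.matrix(expand.grid(lapply(allele, identity),
                                  stringsAsFactors = FALSE))
  for (try in 1:200) {
    m <- combos[sample.int(nrow(combos), n_hap), , drop = FALSE]
    poly <- all(vapply(seq_len(n_snps),
                       function(j) length(unique(m[, j])) > 1L, TRUE))
    if (poly)
      return(list(haps = unname(apply(m, 1L, paste, collapse = "")),
                  alleles = allele))
  }
  stop("could not build a polymorphic haplotype set")
}

#' Generate a synthetic phased reference panel
#'
#' Builds locus definitions (amplicons of 80--180 bp on one synthetic
#' contig per locus, with reference sequences for the read simulator),
#' draws per-population haplotype frequencies from a symmetric Dirichlet,
#' and samples phased diploid individuals under Hardy-Weinberg equilibrium
#' within each population.
#'
#' @param spec a [synth_panel_spec()].
#' @return A list of class `"synth_panel"`: `panel` (a
#'   [reference_panel()]), `defs` (a [microhap_defs()] table),
#'   `true_freqs` (per locus, a population x haplotype frequency matrix),
#'   `spec`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "synth_panel_spec"))
  if (sum(spec$populations) < 2L) stop("need at least 2 samples")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  n_samp <- sum(spec$populations)
  pops <- rep(names(spec$populations), spec$populations)
  samples <- sprintf("S%04d", seq_len(n_samp))
  names(pops) <- samples
  defs_rows <- vector("list", spec$n_loci)
  haps_list <- list()
  true_freqs <- list()
  for (i in seq_len(spec$n_loci)) {
    locus_id <- sprintf("MH%02d", i)
    n_snps <- if (length(spec$n_snps) == 1L) spec$n_snps
    else sample(spec$n_snps, 1L)
    n_hap <- if (length(spec$n_haplotypes) == 1L) spec$n_haplotypes
    else sample(spec$n_haplotypes, 1L)
    hs <- make_haplotype_set(n_hap, n_snps)
    n_snps <- length(hs$alleles)   # may have been raised to host n_hap
    len <- sample(80:180, 1L)
    start <- 21L
    end <- start + len - 1L
    snp_off <- sort(sample(seq(5L, len - 4L), n_snps))
    snp_pos <- start + snp_off - 1L
    ref <- sample(bases, len, replace = TRUE)
    # reference base at each SNP is the first of its two alleles
    for (j in seq_len(n_snps))
      ref[snp_off[j]] <- hs$alleles[[j]][1L]
    freq <- do.call(rbind, lapply(names(spec$populations), function(p)
      rdirichlet1(n_hap, spec$alpha)))
    dimnames(freq) <- list(names(spec$populations), hs$haps)
    # phased diploid draws under HWE within population
    m <- matrix(NA_character_, n_samp, 2L)
    for (p in names(spec$populations)) {
      idx <- which(pops == p)
      m[idx, 1L] <- sample(hs$haps, length(idx), replace = TRUE,
                           prob = freq[p, ])
      m[idx, 2L] <- sample(hs$haps, length(idx), replace = TRUE,
                           prob = freq[p, ])
    }
    haps_list[[locus_id]] <- m
    true_freqs[[locus_id]] <- freq
    defs_rows[[i]] <- list(locus_id = locus_id,
                           chrom = sprintf("mh%02d", i),
                           start = start, end = end,
                           ref_seq = paste(ref, collapse = ""),
                           snp_positions = snp_pos)
  }
  defs <- microhap_defs(
    locus_id = vapply(defs_rows, `[[`, "", "locus_id"),
    chrom = vapply(defs_rows, `[[`, "", "chrom"),
    start = vapply(defs_rows, `[[`, 0L, "start"),
    end = vapply(defs_rows, `[[`, 0L, "end"),
    snp_positions = lapply(defs_rows, `[[`, "snp_positions"),
    ref_seq = vapply(defs_rows, `[[`, "", "ref_seq"))
  structure(list(panel = reference_panel(samples, haps_list, pops),
                 defs = defs, true_freqs = true_freqs, spec = spec),
            class = "synth_panel")
}

#' @export
print.synth_panel <- function(x, ...) {
  cat("Synthetic panel (seed ", x$spec$seed, ")\n", sep = "")
  print(x$panel)
  print(x$defs)
  invisible(x)
}

#' Write a panel as a phased multi-sample VCF
#'
#' Emits one biallelic-or-multiallelic SNP row per defined SNP position
#' with phased `GT` fields; round-trips through
#' [extract_panel_haplotypes()] to the identical panel.
#'
#' @param panel a [reference_panel()].
#' @param defs the matching [microhap_defs()] table.
#' @param path output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, defs, path) {
  lines <- c("##fileformat=VCFv4.2",
             "##source=mhpaternity synthetic panel")
  for (i in seq_len(nrow(defs)))
    lines <- c(lines, sprintf("##contig=<ID=%s,length=%d>",
                              defs$chrom[i], defs$end[i] + 100L))
  lines <- c(lines,
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$samples), collapse = "\t"))
  for (i in seq_len(nrow(defs))) {
    d <- def_row(defs, defs$locus_id[i])
    h <- panel$haplotypes[[d$locus_id]]
    for (j in seq_along(d$snp_positions)) {
      called <- !is.na(h[, 1L])
      b1 <- substr(h[, 1L], j, j)
      b2 <- substr(h[, 2L], j, j)
      seen <- unique(c(b1[called], b2[called]))
      ref_base <- if (!is.na(d$ref_seq)) {
        off <- d$snp_positions[j] - d$start + 1L
        substr(d$ref_seq, off, off)
      } else seen[1L]
      alleles <- c(ref_base, setdiff(sort(seen), ref_base))
      alt <- if (length(alleles) > 1L)
        paste(alleles[-1L], collapse = ",") else "."
      gt <- ifelse(called,
                   paste(match(b1, alleles) - 1L,
                         match(b2, alleles) - 1L, sep = "|"),
                   ".|.")
      lines <- c(lines, paste(c(
        d$chrom, d$snp_positions[j],
        paste0(d$locus_id, "_", j), ref_base, alt, ".", "PASS", ".",
        "GT", gt), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a family (trio plus alleged father) from a panel
#'
#' The mother and the true father are panel samples; the child inherits
#' one haplotype from each at every locus. When `true_father = FALSE` the
#' alleged father is an independent panel sample distinct from the true
#' father.
#'
#' @param panel a [reference_panel()].
#' @param true_father logical; is the alleged father the true father?
#' @param same_population draw all individuals from one population
#'   (requires labels).
#' @return A list of class `"synth_family"`: `mother`, `father`
#'   (true father), `alleged_father`, `child` -- named per-locus length-2
#'   haplotype vectors -- plus the sample ids and `true_father`.
#' @export
generate_family <- function(panel, true_father = TRUE,
                            same_population = FALSE) {
  trio <- simulate_trio(panel,
                        if (same_population) "per_population" else "random")
  alleged <- trio$father
  alleged_id <- trio$father_id
  if (!true_father) {
    pool <- if (same_population)
      panel$samples[panel$populations == trio$population]
    else panel$samples
    pool <- setdiff(pool, c(trio$father_id, trio$mother_id))
    if (length(pool) == 0L) stop("panel too small for a second man")
    alleged_id <- if (length(pool) == 1L) pool else sample(pool, 1L)
    alleged <- lapply(panel$haplotypes, function(h) h[alleged_id, ])
  }
  structure(list(mother = trio$mother, father = trio$father,
                 alleged_father = alleged, child = trio$child,
                 mother_id = trio$mother_id, father_id = trio$father_id,
                 alleged_father_id = alleged_id,
                 population = trio$population,
                 true_father = true_father),
            class = "synth_family")
}

#' Specification for the synthetic read simulator
#'
#' Controls the error structure of simulated amplicon reads: coverage,
#' per-base substitution errors at the typed SNP positions, a two-point
#' base-quality mixture (so some bases fall under the masking threshold),
#' fractions of low-mapping-quality / truncated / secondary / indel reads
#' (exercising every filter reject reason), and the foetal fraction of
#' plasma mixtures.
#'
#' @param coverage reads per genomic-sample locus.
#' @param plasma_coverage reads per plasma locus.
#' @param error_rate per-base substitution probability at SNP positions.
#' @param frac_lowq fraction of SNP bases given Phred quality 10 (below
#'   the masking threshold); others get quality 37.
#' @param frac_low_mapq fraction of reads with mapping quality drawn in
#'   0--20 (rejected by the strict > 20 rule).
#' @param frac_truncated fraction of reads truncated to a prefix or suffix
#'   of the amplicon (producing partial haplotypes).
#' @param frac_secondary fraction of reads flagged secondary.
#' @param frac_indel fraction of reads given an insertion-bearing CIGAR.
#' @param foetal_fraction total foetal fraction of plasma (0--0.5).
#' @return A list of class `"read_sim_spec"`.
#' @export
read_sim_spec <- function(coverage = 200L, plasma_coverage = 2000L,
                          error_rate = 0.005, frac_lowq = 0.05,
                          frac_low_mapq = 0.02, frac_truncated = 0.05,
                          frac_secondary = 0, frac_indel = 0,
                          foetal_fraction = 0.08) {
  stopifnot(foetal_fraction >= 0, foetal_fraction <= 0.5,
            error_rate >= 0, error_rate <= 0.1)
  structure(list(coverage = as.integer(coverage),
                 plasma_coverage = as.integer(plasma_coverage),
                 error_rate = error_rate, frac_lowq = frac_lowq,
                 frac_low_mapq = frac_low_mapq,
                 frac_truncated = frac_truncated,
                 frac_secondary = frac_secondary,
                 frac_indel = frac_indel,
                 foetal_fraction = foetal_fraction),
            class = "read_sim_spec")
}

# core read factory: one read per element of `source_haps`
make_locus_reads <- function(source_haps, locus, spec, id_prefix = "R") {
  n <- length(source_haps)
  len <- locus$end - locus$start + 1L
  if (is.na(locus$ref_seq) || nchar(locus$ref_seq) != len)
    stop("locus ", locus$locus_id,
         " has no reference sequence of amplicon length; ",
         "simulated panels carry one")
  snp_off <- locus$snp_positions - locus$start + 1L
  # template amplicon per distinct haplotype
  uh <- unique(source_haps)
  templ <- vapply(uh, function(h) {
    s <- locus$ref_seq
    for (j in seq_along(snp_off))
      substr(s, snp_off[j], snp_off[j]) <- substr(h, j, j)
    s
  }, "")
  seq <- unname(templ[match(source_haps, uh)])
  qual <- strrep(rawToChar(as.raw(37L + 33L)), len)
  qual <- rep(qual, n)
  bases <- c("A", "C", "G", "T")
  lowq_char <- rawToChar(as.raw(10L + 33L))
  for (j in seq_along(snp_off)) {
    err <- stats::runif(n) < spec$error_rate
    if (any(err)) {
      cur <- substr(seq[err], snp_off[j], snp_off[j])
      new <- vapply(cur, function(b) sample(setdiff(bases, b), 1L), "",
                    USE.NAMES = FALSE)
      substr(seq[err], snp_off[j], snp_off[j]) <- new
    }
    low <- stats::runif(n) < spec$frac_lowq
    if (any(low))
      substr(qual[low], snp_off[j], snp_off[j]) <- lowq_char
  }
  pos <- rep(locus$start, n)
  rlen <- rep(len, n)
  trunc <- stats::runif(n) < spec$frac_truncated
  if (any(trunc)) {
    first <- snp_off[1L]; last <- snp_off[length(snp_off)]
    for (i in which(trunc)) {
      if (stats::runif(1) < 0.5) {        # keep a prefix, lose tail SNPs
        cut <- sample(seq(first, last - 1L), 1L)
        seq[i] <- substr(seq[i], 1L, cut)
        qual[i] <- substr(qual[i], 1L, cut)
        rlen[i] <- cut
      } else {                            # keep a suffix, lose head SNPs
        from <- sample(seq(first + 1L, last), 1L)
        seq[i] <- substr(seq[i], from, len)
        qual[i] <- substr(qual[i], from, len)
        pos[i] <- locus$start + from - 1L
        rlen[i] <- len - from + 1L
      }
    }
  }
  mapq <- rep(60L, n)
  lowm <- stats::runif(n) < spec$frac_low_mapq
  mapq[lowm] <- sample(0:20, sum(lowm), replace = TRUE)
  flag <- rep(0L, n)
  flag[stats::runif(n) < spec$frac_secondary] <- 256L
  cigar <- paste0(rlen, "M")
  ind <- stats::runif(n) < spec$frac_indel & rlen > 20L
  if (any(ind)) cigar[ind] <- paste0("10M1I", rlen[ind] - 11L, "M")
  data.frame(qname = sprintf("%s_%s_%05d", id_prefix, locus$locus_id,
                             seq_len(n)),
             flag = flag, rname = locus$chrom, pos = pos, mapq = mapq,
             cigar = cigar, seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

#' Simulate aligned amplicon reads for a genomic sample at one locus
#'
#' Each read is drawn from one of the two haplotype copies with equal
#' probability; substitution errors, base-quality mixtures, truncations
#' and mapping-quality/flag/CIGAR artefacts follow the [read_sim_spec()].
#' Uses the current RNG stream.
#'
#' @param genotype length-2 character vector of haplotype copies (equal
#'   strings for a homozygote).
#' @param locus a single-locus view (from [def_row] semantics) or one-row
#'   [microhap_defs()]; must carry `ref_seq`.
#' @param spec a [read_sim_spec()].
#' @param coverage number of reads (defaults to `spec$coverage`).
#' @param id_prefix read-name prefix.
#' @return A data.frame of alignment records compatible with
#'   [filter_reads()] / [write_sam()].
#' @export
generate_sample_reads <- function(genotype, locus, spec = read_sim_spec(),
                                  coverage = spec$coverage,
                                  id_prefix = "G") {
  if (inherits(locus, "microhap_defs")) locus <- def_row(locus, locus$locus_id[1L])
  stopifnot(length(genotype) == 2L)
  src <- genotype[sample.int(2L, coverage, replace = TRUE)]
  make_locus_reads(src, locus, spec, id_prefix)
}

#' Simulate maternal-plasma reads (maternal/foetal admixture) at one locus
#'
#' Each read originates from the child's haplotypes with probability equal
#' to the foetal fraction, otherwise from the mother's (uniform within the
#' source pair). The paternal-only haplotype therefore has expected
#' relative frequency of half the foetal fraction.
#'
#' @param mother_gt,child_gt length-2 haplotype vectors.
#' @param locus single-locus view with `ref_seq`.
#' @param spec a [read_sim_spec()] (uses `plasma_coverage` and
#'   `foetal_fraction`).
#' @param coverage number of reads (defaults to `spec$plasma_coverage`).
#' @return A data.frame of alignment records.
#' @export
generate_plasma_reads <- function(mother_gt, child_gt, locus,
                                  spec = read_sim_spec(),
                                  coverage = spec$plasma_coverage) {
  if (inherits(locus, "microhap_defs")) locus <- def_row(locus, locus$locus_id[1L])
  foetal <- stats::runif(coverage) < spec$foetal_fraction
  pick <- sample.int(2L, coverage, replace = TRUE)
  src <- ifelse(foetal, child_gt[pick], mother_gt[pick])
  make_locus_reads(src, locus, spec, id_prefix = "P")
}

#' Write alignment records as a SAM file
#'
#' Minimal coordinate-sorted SAM with one `@SQ` line per locus contig;
#' readable back through [read_alignments()].
#'
#' @param reads data.frame of alignment records (possibly several loci).
#' @param defs the [microhap_defs()] table (for contig headers).
#' @param path output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, defs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", defs$chrom, defs$end + 100L))
  ord <- order(match(reads$rname, defs$chrom), reads$pos)
  r <- reads[ord, , drop = FALSE]
  body <- paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar,
                "*", 0L, 0L, r$seq, r$qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a complete case (mother, alleged father, plasma reads)
#'
#' Draws a family from the panel and generates per-locus reads for the
#' mother's and alleged father's genomic DNA and for the maternal plasma
#' (a maternal/foetal admixture at the spec's foetal fraction). Uses the
#' current RNG stream.
#'
#' @param sp a `"synth_panel"` from [generate_panel()].
#' @param spec a [read_sim_spec()].
#' @param true_father logical.
#' @return A list of class `"synth_case"`: `family`, `reads` (list with
#'   data.frames `mother`, `father`, `plasma` spanning all loci), `spec`.
#' @export
simulate_case <- function(sp, spec = read_sim_spec(), true_father = TRUE) {
  fam <- generate_family(sp$panel, true_father = true_father)
  defs <- sp$defs
  m_reads <- list(); f_reads <- list(); p_reads <- list()
  for (loc in defs$locus_id) {
    d <- def_row(defs, loc)
    m_reads[[loc]] <- generate_sample_reads(fam$mother[[loc]], d, spec,
                                            id_prefix = "M")
    f_reads[[loc]] <- generate_sample_reads(fam$alleged_father[[loc]], d,
                                            spec, id_prefix = "F")
    p_reads[[loc]] <- generate_plasma_reads(fam$mother[[loc]],
                                            fam$child[[loc]], d, spec)
  }
  structure(list(family = fam,
                 reads = list(mother = do.call(rbind, m_reads),
                              father = do.call(rbind, f_reads),
                              plasma = do.call(rbind, p_reads)),
                 spec = spec),
            class = "synth_case")
}

#' Run the full pipeline on a case
#'
#' Profiles the three read sets, calls the parental genotypes, analyzes
#' the plasma loci against the maternal calls, evaluates the per-locus
#' paternity evidence where mother and alleged father are called and the
#' plasma locus is usable, and combines it into a paternity report with a
#' foetal-fraction estimate.
#'
#' @param case a `"synth_case"` (or any list with `reads$mother`,
#'   `reads$father`, `reads$plasma` alignment data.frames).
#' @param defs the [microhap_defs()] table.
#' @param freq_tables named list of [haplotype_frequencies()] tables.
#' @param thresholds an [mh_thresholds()] list.
#' @param case_id report label.
#' @return A list of class `"case_analysis"`: `report`
#'   (a `"paternity_report"`), `foetal_fraction`, `mother_calls`,
#'   `father_calls`, `plasma`, `evidences`.
#' @export
analyze_case <- function(case, defs, freq_tables,
                         thresholds = mh_thresholds(),
                         case_id = "case") {
  mprof <- build_sample_profiles(case$reads$mother, defs, "mother",
                                 thresholds)
  fprof <- build_sample_profiles(case$reads$father, defs, "father",
                                 thresholds)
  pprof <- build_sample_profiles(case$reads$plasma, defs, "plasma",
                                 thresholds)
  mcalls <- lapply(mprof, call_genotype, thresholds = thresholds)
  fcalls <- lapply(fprof, call_genotype, thresholds = thresholds)
  plasma <- list(); evs <- list()
  for (loc in defs$locus_id) {
    if (mcalls[[loc]]$status != "called") next
    pl <- analyze_plasma_locus(pprof[[loc]], mcalls[[loc]], thresholds)
    plasma[[loc]] <- pl
    if (!pl$usable || fcalls[[loc]]$status != "called") next
    evs[[loc]] <- evaluate_locus(fcalls[[loc]], mcalls[[loc]], pl,
                                 freq_tables[[loc]])
  }
  if (length(evs) == 0L)
    stop("no informative locus: cannot evaluate the case")
  report <- combine_evidence(evs, thresholds, case_id = case_id)
  ff <- estimate_foetal_fraction(plasma, fcalls)
  structure(list(report = report, foetal_fraction = ff,
                 mother_calls = mcalls, father_calls = fcalls,
                 plasma = plasma, evidences = evs),
            class = "case_analysis")
}

#' @export
print.case_analysis <- function(x, ...) {
  print(x$report)
  print(x$foetal_fraction)
  invisible(x)
}
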