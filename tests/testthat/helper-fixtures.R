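# Fixture builders and brute-force oracles used across the suite.

make_profile <- function(locus_id, freqs, coverage = 1000L,
                         sample_id = "s") {
  counts <- as.integer(round(freqs * coverage))
  structure(list(locus_id = locus_id, sample_id = sample_id,
                 accepted = stats::setNames(counts, names(freqs)),
                 coverage = sum(counts),
                 rel_freqs = stats::setNames(counts / sum(counts),
                                             names(freqs)),
                 rejected = integer(0L)),
            class = "locus_profile")
}

make_freq_table <- function(locus_id, freqs, n_chromosomes = 1000L) {
  counts <- as.integer(round(freqs * n_chromosomes))
  f <- counts / sum(counts)
  ord <- order(-f, names(freqs))
  structure(list(locus_id = locus_id, haplotype = names(freqs)[ord],
                 count = counts[ord], frequency = f[ord],
                 n_chromosomes = as.integer(sum(counts)),
                 a_e = 1 / sum(f^2)),
            class = "freq_table")
}

mk_plasma <- function(cand, mhaps = c(A = 0.5, B = 0.45), loc = "L") {
  structure(list(locus_id = loc, usable = TRUE, dismiss_reason = "none",
                 maternal_haplotypes = mhaps, candidate_paternal = cand,
                 coverage = 2000L),
            class = "plasma_profile")
}

# a tiny deterministic phased panel: 4 samples, 2 loci
tiny_panel <- function() {
  h1 <- matrix(c("AT", "AT", "GT", "GT",
                 "AT", "GT", "GT", "AT"), 4, 2)
  h2 <- matrix(c("CC", "CG", "CC", "CG",
                 "CG", "CC", "CG", "CC"), 4, 2)
  reference_panel(c("s1", "s2", "s3", "s4"),
                  list(L1 = h1, L2 = h2),
                  populations = c(s1 = "P1", s2 = "P1",
                                  s3 = "P2", s4 = "P2"))
}

# write a small phased VCF for two biallelic SNPs per locus
write_tiny_vcf <- function(path, gts, chrom = "chr1",
                           pos = c(1010L, 1050L),
                           ref = c("A", "C"), alt = c("G", "T")) {
  samples <- names(gts)
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=2000>", chrom),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples),
                   collapse = "\t"))
  for (i in seq_along(pos)) {
    row <- vapply(gts, `[[`, "", i)
    lines <- c(lines, paste(c(chrom, pos[i], ".", ref[i], alt[i], ".",
                              "PASS", ".", "GT", row), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# brute-force partial/total matcher: enumerates every (partial, total)
# agreement pair independently of resolve_partials()
brute_resolve <- function(obs, min_known_frac = 0.70) {
  L <- nchar(obs[1L])
  known <- function(x) sum(strsplit(x, "")[[1L]] != "-")
  is_total <- vapply(obs, known, 0L) == L
  totals <- obs[is_total]
  acc <- table(totals)
  accepted <- stats::setNames(as.integer(acc), names(acc))
  rejected <- c(too_partial = 0L, ambiguous_partial = 0L)
  agree <- function(p, t) {
    ps <- strsplit(p, "")[[1L]]; ts <- strsplit(t, "")[[1L]]
    all(ps == "-" | ps == ts)
  }
  totals_set <- unique(totals)
  for (p in obs[!is_total]) {
    if (known(p) / L < min_known_frac) {
      rejected["too_partial"] <- rejected["too_partial"] + 1L
      next
    }
    hits <- totals_set[vapply(totals_set, function(t) agree(p, t), TRUE)]
    if (length(hits) == 1L) accepted[hits] <- accepted[hits] + 1L
    else rejected["ambiguous_partial"] <- rejected["ambiguous_partial"] + 1L
  }
  list(accepted = accepted, rejected = rejected)
}

# brute-force likelihood-ratio oracle for the paternity index: enumerates
# every haplotype in the table and asks whether transmitting it explains
# the plasma pattern (a seen candidate, or any maternal haplotype when
# the paternal signal is masked)
brute_pi <- function(father_haps, mother_haps, candidate, ft) {
  all_h <- ft$haplotype
  consistent <- if (!is.null(candidate)) all_h == candidate
  else all_h %in% unique(mother_haps)
  fcop <- if (length(father_haps) == 1L) rep(father_haps, 2L) else father_haps
  trans <- vapply(all_h, function(h) mean(fcop == h), 0)
  num <- sum(trans[consistent])
  den <- sum(ft$frequency[consistent])
  num / den
}

# brute-force trio LR: paternal haplotype h explains the child iff the
# other child haplotype can come from the mother
brute_trio_pi <- function(mother_gt, child_gt, father_gt, ft) {
  all_h <- ft$haplotype
  explains <- vapply(all_h, function(h) {
    (h == child_gt[1L] && child_gt[2L] %in% mother_gt) ||
      (h == child_gt[2L] && child_gt[1L] %in% mother_gt)
  }, TRUE)
  trans <- vapply(all_h, function(h) mean(father_gt == h), 0)
  num <- sum(trans[explains])
  den <- sum(ft$frequency[explains])
  if (num == 0) NA_real_ else num / den
}

# Mann-Whitney AUC: fraction of (positive, negative) pairs ranked
# correctly, ties counting a half
auc_mannwhitney <- function(labels, scores) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# one aligned read record
read_rec <- function(pos, seq, qual = strrep("I", nchar(seq)),
                     mapq = 60L, cigar = paste0(nchar(seq), "M"),
                     flag = 0L, rname = "chr1", qname = "r") {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

test_defs <- function() {
  microhap_defs("MH01", "chr1", 1000L, 1120L,
                list(c(1010L, 1050L, 1100L)))
}
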