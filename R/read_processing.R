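#' Read aligned amplicon reads from a SAM or BAM file
#'
#' Thin wrapper over `Rsamtools`: a text SAM file is converted to BAM on
#' the fly, then the fields the pipeline needs are loaded into a plain
#' data.frame (one row per alignment record).
#'
#' @param path path to a `.sam` or `.bam` file.
#' @return A data.frame with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual` (qualities as Phred+33 strings).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  data.frame(qname = b$qname, flag = b$flag,
             rname = as.character(b$rname), pos = b$pos, mapq = b$mapq,
             cigar = b$cigar, seq = as.character(b$seq),
             qual = as.character(b$qual), stringsAsFactors = FALSE)
}

cigar_ref_len <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  mapply(function(l, o) sum(as.integer(l)[o %in% c("M", "=", "X", "D", "N")]),
         lens, ops, USE.NAMES = FALSE)
}

cigar_match_only <- function(cigar) {
  !grepl("[IDNSHP]", cigar)
}

#' Filter aligned reads for haplotype extraction
#'
#' A read is usable for microhaplotype calling only if it overlaps the
#' locus, is the read's single reported alignment (not secondary or
#' supplementary), has mapping quality strictly greater than `mapq_min`,
#' and its CIGAR reports nothing but alignment matches/mismatches
#' (`M`/`=`/`X`) -- indels and clips shift the SNP coordinates and are
#' rejected outright.
#'
#' @param reads data.frame as returned by [read_alignments()].
#' @param locus a single-locus view from a [microhap_defs()] table (or the
#'   table itself with one row).
#' @param mapq_min strict lower bound on mapping quality (default 20).
#' @return Character vector, one element per read: `"ok"` or a reject
#'   reason (`"off_target"`, `"not_unique"`, `"low_mapq"`, `"cigar"`).
#' @export
filter_reads <- function(reads, locus, mapq_min = 20L) {
  if (inherits(locus, "microhap_defs")) locus <- def_row(locus, locus$locus_id[1L])
  n <- nrow(reads)
  reason <- rep("ok", n)
  span <- cigar_ref_len(reads$cigar)
  off <- reads$rname != locus$chrom | reads$pos > locus$end |
    (reads$pos + span - 1L) < locus$start
  reason[off] <- "off_target"
  nu <- bitwAnd(reads$flag, 0x100L) != 0L | bitwAnd(reads$flag, 0x800L) != 0L
  reason[reason == "ok" & nu] <- "not_unique"
  reason[reason == "ok" & reads$mapq <= mapq_min] <- "low_mapq"
  reason[reason == "ok" & !cigar_match_only(reads$cigar)] <- "cigar"
  reason
}

#' Extract masked haplotype symbols from filtered reads
#'
#' For each read (already CIGAR-clean, so reference position maps directly
#' onto read offset) the base at every SNP position of the locus is taken;
#' bases with Phred quality strictly below `baseq_min`, and SNP positions
#' the read does not cover, become the unknown symbol `"-"`. The result is
#' one symbol string per read: a *total* haplotype when no `"-"` remains,
#' otherwise a *partial* haplotype.
#'
#' @param reads data.frame of reads that passed [filter_reads()].
#' @param locus single-locus definition view.
#' @param baseq_min base-quality masking threshold (default 20; bases with
#'   quality lower than this are masked).
#' @return Character vector of symbol strings over `{A,C,G,T,-}`, length
#'   `nrow(reads)`.
#' @export
extract_read_haplotypes <- function(reads, locus, baseq_min = 20L) {
  if (inherits(locus, "microhap_defs")) locus <- def_row(locus, locus$locus_id[1L])
  n <- nrow(reads)
  snps <- locus$snp_positions
  if (n == 0L) return(character(0L))
  sym <- matrix("-", n, length(snps))
  rlen <- nchar(reads$seq)
  for (j in seq_along(snps)) {
    off <- snps[j] - reads$pos + 1L
    cov <- off >= 1L & off <= rlen
    if (!any(cov)) next
    base <- substr(reads$seq[cov], off[cov], off[cov])
    q <- utf8ToInt_phred(reads$qual[cov], off[cov])
    base[q < baseq_min] <- "-"
    sym[cov, j] <- base
  }
  apply(sym, 1L, paste, collapse = "")
}

# Phred score of the character at position `off` of each quality string
utf8ToInt_phred <- function(qual, off) {
  if (length(qual) == 0L) return(integer(0L))
  qc <- substr(qual, off, off)
  as.integer(charToRaw(paste(qc, collapse = ""))) - 33L
}

#' Resolve partial haplotypes against the observed total haplotypes
#'
#' Total haplotypes (no `"-"`) are counted directly. A partial haplotype
#' with less than `min_known_frac` of its bases known is discarded
#' (`too_partial`); otherwise it is compared against the distinct total
#' haplotypes observed in the same read list (agreement at every known
#' position) and counted as a total only when it matches exactly one
#' (`ambiguous_partial` otherwise -- zero or several matches).
#'
#' @param observations character vector of symbol strings from
#'   [extract_read_haplotypes()].
#' @param min_known_frac minimum known fraction for a partial to be
#'   eligible for pairing (default 0.70; strictly less is discarded).
#' @return List with `accepted` (named integer counts over complete
#'   haplotypes) and `rejected` (named counts for `too_partial` and
#'   `ambiguous_partial`).
#' @export
resolve_partials <- function(observations, min_known_frac = 0.70) {
  rejected <- c(too_partial = 0L, ambiguous_partial = 0L)
  if (length(observations) == 0L)
    return(list(accepted = integer(0L), rejected = rejected))
  L <- nchar(observations[1L])
  n_known <- L - nchar(gsub("[^-]", "", observations))
  is_total <- n_known == L
  acc <- table(observations[is_total])
  accepted <- stats::setNames(as.integer(acc), names(acc))
  totals <- names(accepted)
  partials <- observations[!is_total]
  if (length(partials)) {
    pk <- n_known[!is_total]
    too <- pk / L < min_known_frac
    rejected["too_partial"] <- sum(too)
    partials <- partials[!too]
    if (length(partials)) {
      upart <- table(partials)
      tot_mat <- if (length(totals))
        do.call(rbind, strsplit(totals, "")) else
        matrix(character(0L), 0L, L)
      for (i in seq_along(upart)) {
        psym <- strsplit(names(upart)[i], "")[[1L]]
        known <- psym != "-"
        hits <- which(apply(tot_mat[, known, drop = FALSE], 1L,
                            function(t) all(t == psym[known])))
        if (length(hits) == 1L) {
          accepted[totals[hits]] <- accepted[totals[hits]] +
            as.integer(upart[i])
        } else {
          rejected["ambiguous_partial"] <-
            rejected["ambiguous_partial"] + as.integer(upart[i])
        }
      }
    }
  }
  list(accepted = accepted, rejected = rejected)
}

#' Per-locus haplotype observation profile for one sample
#'
#' Composes the full read-level pipeline: [filter_reads()] (uniqueness,
#' mapping quality, CIGAR), [extract_read_haplotypes()] (base-quality
#' masking), [resolve_partials()] (partial/total pairing), then tallies
#' accepted complete haplotypes into counts and relative frequencies.
#'
#' @param reads data.frame of alignment records for one sample.
#' @param locus single-locus definition view (or one-row
#'   [microhap_defs()]).
#' @param sample_id label stored in the profile.
#' @param thresholds an [mh_thresholds()] list.
#' @return A list of class `"locus_profile"`: `locus_id`, `sample_id`,
#'   `accepted` (named counts), `coverage`, `rel_freqs`, `rejected`
#'   (named reason counts). Zero accepted reads give `coverage = 0`.
#' @export
build_locus_profile <- function(reads, locus, sample_id = "sample",
                                thresholds = mh_thresholds()) {
  if (inherits(locus, "microhap_defs")) locus <- def_row(locus, locus$locus_id[1L])
  reason <- filter_reads(reads, locus, thresholds$mapq_min)
  keep <- reason == "ok"
  obs <- extract_read_haplotypes(reads[keep, , drop = FALSE], locus,
                                 thresholds$baseq_min)
  res <- resolve_partials(obs, thresholds$min_known_frac)
  filt <- table(reason[!keep])
  rejected <- c(stats::setNames(as.integer(filt), names(filt)),
                res$rejected)
  coverage <- sum(res$accepted)
  rel <- if (coverage > 0) res$accepted / coverage else numeric(0L)
  structure(list(locus_id = locus$locus_id, sample_id = sample_id,
                 accepted = res$accepted, coverage = coverage,
                 rel_freqs = rel, rejected = rejected),
            class = "locus_profile")
}

#' @export
print.locus_profile <- function(x, ...) {
  cat("Locus profile ", x$locus_id, " (", x$sample_id, "): coverage ",
      x$coverage, "\n", sep = "")
  if (x$coverage > 0) {
    ord <- order(-x$rel_freqs)
    print(data.frame(haplotype = names(x$accepted)[ord],
                     count = as.integer(x$accepted)[ord],
                     rel_freq = signif(unname(x$rel_freqs[ord]), 4)),
          row.names = FALSE)
  }
  if (sum(x$rejected) > 0)
    cat("  rejected:",
        paste(names(x$rejected), x$rejected, sep = "=", collapse = " "),
        "\n")
  invisible(x)
}

#' Build profiles for every locus from one sample's alignments
#'
#' @param reads data.frame of alignment records (all loci, one sample).
#' @param defs a [microhap_defs()] table.
#' @param sample_id sample label.
#' @param thresholds an [mh_thresholds()] list.
#' @return Named list of `"locus_profile"` objects, one per locus.
#' @export
build_sample_profiles <- function(reads, defs, sample_id = "sample",
                                  thresholds = mh_thresholds()) {
  out <- lapply(defs$locus_id, function(loc) {
    d <- def_row(defs, loc)
    sub <- reads[reads$rname == d$chrom, , drop = FALSE]
    build_locus_profile(sub, d, sample_id, thresholds)
  })
  stats::setNames(out, defs$locus_id)
}

#' Write locus profiles as TSV
#'
#' Emits a haplotype table (`locus_id`, `haplotype`, `count`, `rel_freq`,
#' `coverage`) and a companion rejects table (`locus_id`, `reason`,
#' `count`).
#'
#' @param profiles named list of `"locus_profile"` objects.
#' @param dir output directory.
#' @return Paths of the two files, invisibly.
#' @export
write_profiles <- function(profiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sid <- profiles[[1L]]$sample_id
  hap <- do.call(rbind, lapply(profiles, function(p)
    if (p$coverage > 0)
      data.frame(locus_id = p$locus_id, haplotype = names(p$accepted),
                 count = as.integer(p$accepted),
                 rel_freq = unname(p$rel_freqs), coverage = p$coverage)
    else NULL))
  rej <- do.call(rbind, lapply(profiles, function(p)
    if (length(p$rejected))
      data.frame(locus_id = p$locus_id, reason = names(p$rejected),
                 count = as.integer(p$rejected))
    else NULL))
  f1 <- file.path(dir, paste0(sid, "_profiles.tsv"))
  f2 <- file.path(dir, paste0(sid, "_rejects.tsv"))
  utils::write.table(hap, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rej, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}
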