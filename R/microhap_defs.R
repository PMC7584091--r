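#' Construct a microhaplotype definition table
#'
#' A microhaplotype is a short genomic segment (typically under 200 bp)
#' containing two or more SNPs whose phased allele combination acts as a
#' multi-allelic marker. A definition holds the amplicon interval and the
#' ordered SNP positions; the haplotype alphabet at the locus is the set of
#' base strings read off at those positions.
#'
#' @param locus_id character vector of unique locus labels.
#' @param chrom chromosome / contig name per locus.
#' @param start,end 1-based inclusive amplicon coordinates.
#' @param snp_positions list of strictly increasing integer vectors
#'   (1-based reference positions), at least two per locus, all inside
#'   `[start, end]`.
#' @param ref_seq optional reference sequence of each amplicon (used by the
#'   read simulator; `NA` otherwise).
#' @return A data.frame of class `"microhap_defs"` with one row per locus;
#'   `snp_positions` is a list column.
#' @details Amplicons outside the 80--180 bp range used by the assay are
#'   accepted with a warning: they are legal markers but fall outside the
#'   size window suited to cell-free DNA fragments.
#' @seealso [load_microhap_defs()]
#' @export
microhap_defs <- function(locus_id, chrom, start, end, snp_positions,
                          ref_seq = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (!is.list(snp_positions)) snp_positions <- list(snp_positions)
  snp_positions <- lapply(snp_positions, function(p) as.integer(sort(p)))
  n <- length(locus_id)
  stopifnot(length(chrom) == n, length(start) == n, length(end) == n,
            length(snp_positions) == n)
  if (anyDuplicated(locus_id))
    stop("duplicate locus_id: ",
         paste(unique(locus_id[duplicated(locus_id)]), collapse = ", "))
  for (i in seq_len(n)) {
    p <- snp_positions[[i]]
    if (length(p) < 2L)
      stop("locus ", locus_id[i], ": needs at least 2 SNP positions")
    if (anyDuplicated(p))
      stop("locus ", locus_id[i], ": duplicated SNP positions")
    if (min(p) < start[i] || max(p) > end[i])
      stop("locus ", locus_id[i], ": SNP position outside [start, end]")
  }
  len <- end - start + 1L
  if (any(len < 80L | len > 180L))
    warning("amplicon length outside 80-180 bp for: ",
            paste(locus_id[len < 80L | len > 180L], collapse = ", "))
  out <- data.frame(locus_id = as.character(locus_id),
                    chrom = as.character(chrom),
                    start = start, end = end,
                    ref_seq = rep_len(as.character(ref_seq), n),
                    stringsAsFactors = FALSE)
  out$snp_positions <- snp_positions
  class(out) <- c("microhap_defs", "data.frame")
  out
}

#' Load microhaplotype definitions from a tab- or comma-separated file
#'
#' Expects columns `locus_id`, `chrom`, `start`, `end`, `snp_positions`
#' (the latter a comma-separated list of positions). Row order is preserved.
#'
#' @param path path to the definition file (TSV; `snp_positions` may use
#'   commas inside the field).
#' @return A [microhap_defs()] table.
#' @export
load_microhap_defs <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("locus_id", "chrom", "start", "end", "snp_positions")
  if (!all(need %in% names(tab)))
    stop("definition file must have columns: ", paste(need, collapse = ", "))
  snps <- lapply(strsplit(as.character(tab$snp_positions), ","),
                 function(x) as.integer(trimws(x)))
  microhap_defs(tab$locus_id, tab$chrom, tab$start, tab$end, snps,
                ref_seq = if ("ref_seq" %in% names(tab)) tab$ref_seq else NA)
}

#' Write microhaplotype definitions to a TSV file
#' @param defs a [microhap_defs()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_microhap_defs <- function(defs, path) {
  tab <- data.frame(locus_id = defs$locus_id, chrom = defs$chrom,
                    start = defs$start, end = defs$end,
                    snp_positions = vapply(defs$snp_positions, paste,
                                           "", collapse = ","),
                    ref_seq = defs$ref_seq, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.microhap_defs <- function(x, ...) {
  cat("Microhaplotype definitions: ", nrow(x), " loci\n", sep = "")
  n_snps <- vapply(x$snp_positions, length, 1L)
  cat("  SNPs per locus: ", paste(range(n_snps), collapse = "-"),
      "; amplicon length: ",
      paste(range(x$end - x$start + 1L), collapse = "-"), " bp\n", sep = "")
  invisible(x)
}

def_row <- function(defs, locus_id) {
  i <- match(locus_id, defs$locus_id)
  if (is.na(i)) stop("unknown locus: ", locus_id)
  list(locus_id = defs$locus_id[i], chrom = defs$chrom[i],
       start = defs$start[i], end = defs$end[i],
       ref_seq = defs$ref_seq[i], snp_positions = defs$snp_positions[[i]])
}
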