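locus <- test_defs()   # MH01 chr1:1000-1120, SNPs 1010/1050/1100

full_read <- function(seq120 = strrep("A", 121), ...) {
  read_rec(pos = 1000L, seq = seq120, ...)
}

test_that("filter_reads applies uniqueness, mapq and cigar rules", {
  r <- rbind(full_read(mapq = 30L),
             full_read(mapq = 20L),
             full_read(mapq = 45L, cigar = "50M2I69M"),
             full_read(mapq = 45L, flag = 256L),
             read_rec(pos = 5000L, seq = strrep("A", 100)))
  expect_equal(filter_reads(r, locus),
               c("ok", "low_mapq", "cigar", "not_unique", "off_target"))
  # mapq strictly greater than the threshold is required
  expect_equal(filter_reads(full_read(mapq = 21L), locus), "ok")
})

test_that("extract_read_haplotypes masks low-quality and uncovered SNPs", {
  seq <- strrep("T", 121)
  substr(seq, 11, 11) <- "A"    # 1010
  substr(seq, 51, 51) <- "C"    # 1050
  substr(seq, 101, 101) <- "G"  # 1100
  hi <- strrep("I", 121)        # Q40
  expect_equal(extract_read_haplotypes(full_read(seq, qual = hi), locus),
               "ACG")
  lo <- hi
  substr(lo, 51, 51) <- "0"     # Q15 < 20 masks the middle SNP
  expect_equal(extract_read_haplotypes(full_read(seq, qual = lo), locus),
               "A-G")
  # read covering only SNPs 1-2: third symbol unknown
  short <- read_rec(pos = 1000L, seq = substr(seq, 1, 60))
  expect_equal(extract_read_haplotypes(short, locus), "AC-")
  # base quality exactly at the threshold is kept
  edge <- hi
  substr(edge, 11, 11) <- "5"   # Q20
  expect_equal(extract_read_haplotypes(full_read(seq, qual = edge), locus),
               "ACG")
})

test_that("resolve_partials pairs unambiguous partials and discards the rest", {
  obs <- c(rep("ACGT", 10), rep("TCGT", 10), "A-GT")  # 75% known: eligible
  res <- resolve_partials(obs)
  expect_equal(res$accepted[["ACGT"]], 11L)
  expect_equal(res$accepted[["TCGT"]], 10L)
  # matches both totals: ambiguous
  res2 <- resolve_partials(c("ACGT", "TCGT", "-CGT"))
  expect_equal(res2$rejected[["ambiguous_partial"]], 1L)
  # less than 70% known: discarded before pairing, so one masked base on
  # a 3-SNP haplotype (66.7%) never reaches the matcher
  res3 <- resolve_partials(c("ACG", "A-G"))
  expect_equal(res3$rejected[["too_partial"]], 1L)
  # a 2-SNP locus with 1 known base (50%) is below the 70% rule
  res4 <- resolve_partials(c("AC", "A-"))
  expect_equal(res4$rejected[["too_partial"]], 1L)
  # partial matching no total is discarded too
  res5 <- resolve_partials(c("ACGT", "T-TT"))
  expect_equal(res5$rejected[["ambiguous_partial"]], 1L)
})

test_that("resolve_partials is order-independent and conserves reads", {
  set.seed(11)
  syms <- c("A", "C", "-")
  for (rep in 1:20) {
    obs <- replicate(sample(5:20, 1),
                     paste(sample(syms, 3, TRUE), collapse = ""))
    res <- resolve_partials(obs)
    resp <- resolve_partials(sample(obs))
    expect_equal(res$accepted[sort(names(res$accepted))],
                 resp$accepted[sort(names(resp$accepted))])
    expect_equal(sum(res$accepted) + sum(res$rejected), length(obs))
  }
})

test_that("resolve_partials matches the brute-force matcher on small inputs", {
  set.seed(23)
  syms <- c("A", "C", "G", "-")
  for (rep in 1:30) {
    L <- sample(2:4, 1)
    obs <- replicate(sample(3:20, 1),
                     paste(sample(syms, L, TRUE), collapse = ""))
    res <- resolve_partials(obs)
    bf <- brute_resolve(obs)
    expect_equal(res$accepted[sort(names(res$accepted))],
                 bf$accepted[sort(names(bf$accepted))])
    expect_equal(res$rejected, bf$rejected)
  }
})

test_that("build_locus_profile composes filtering, masking and pairing", {
  seqA <- strrep("T", 121)
  substr(seqA, 11, 11) <- "A"; substr(seqA, 51, 51) <- "C"
  substr(seqA, 101, 101) <- "G"
  clean <- do.call(rbind, replicate(100, full_read(seqA), simplify = FALSE))
  prof <- build_locus_profile(clean, locus, "s1")
  expect_equal(prof$coverage, 100L)
  expect_equal(unname(prof$rel_freqs["ACG"]), 1)

  seqB <- seqA; substr(seqB, 11, 11) <- "G"   # GCG
  mixed <- rbind(clean[1:50, ],
                 do.call(rbind, replicate(50, full_read(seqB),
                                          simplify = FALSE)),
                 # one masked base on a 3-SNP haplotype leaves 66.7% of
                 # symbols known: under the 70% rule it is discarded
                 do.call(rbind, replicate(10, {
                   r <- full_read(seqA)
                   q <- strrep("I", 121); substr(q, 11, 11) <- "0"
                   r$qual <- q; r
                 }, simplify = FALSE)))
  prof2 <- build_locus_profile(mixed, locus, "s1")
  expect_equal(prof2$coverage, 100L)
  expect_equal(unname(prof2$rel_freqs[c("ACG", "GCG")]), c(0.5, 0.5))
  expect_equal(prof2$rejected[["too_partial"]], 10L)

  lowm <- clean; lowm$mapq <- 10L
  prof3 <- build_locus_profile(lowm, locus, "s1")
  expect_equal(prof3$coverage, 0L)
  expect_equal(prof3$rejected[["low_mapq"]], 100L)
})

test_that("read accounting conserves every overlapping input read", {
  set.seed(5)
  sp <- generate_panel(synth_panel_spec(n_loci = 2, seed = 9))
  d <- sp$defs[1, ]
  spec <- read_sim_spec(frac_low_mapq = 0.2, frac_truncated = 0.3,
                        frac_secondary = 0.05, frac_indel = 0.05)
  fam <- generate_family(sp$panel)
  loc <- sp$defs$locus_id[1]
  reads <- generate_sample_reads(fam$mother[[loc]], d, spec, coverage = 300L)
  prof <- build_locus_profile(reads, d, "m")
  expect_equal(prof$coverage + sum(prof$rejected), 300L)
  expect_true(all(c("low_mapq", "not_unique", "cigar") %in%
                    names(prof$rejected)))
})

test_that("error-free reads from a heterozygote split near 50/50", {
  set.seed(99)
  sp <- generate_panel(synth_panel_spec(n_loci = 1, seed = 4))
  d <- sp$defs[1, ]
  loc <- sp$defs$locus_id[1]
  spec0 <- read_sim_spec(error_rate = 0, frac_lowq = 0, frac_low_mapq = 0,
                         frac_truncated = 0)
  ft <- haplotype_frequencies(sp$panel, loc)
  het <- ft$haplotype[1:2]
  for (i in 1:5) {
    reads <- generate_sample_reads(het, d, spec0, coverage = 150L)
    prof <- build_locus_profile(reads, d, "s")
    expect_equal(prof$coverage, 150L)
    expect_equal(sort(names(prof$accepted)), sort(het))
    expect_true(all(prof$rel_freqs >= 0.4 & prof$rel_freqs <= 0.6))
  }
})

test_that("SAM files round-trip through Rsamtools", {
  set.seed(2)
  sp <- generate_panel(synth_panel_spec(n_loci = 2, seed = 2))
  fam <- generate_family(sp$panel)
  loc <- sp$defs$locus_id[1]
  reads <- generate_sample_reads(fam$mother[[loc]], sp$defs[1, ],
                                 read_sim_spec(), coverage = 50L)
  f <- tempfile(fileext = ".sam")
  write_sam(reads, sp$defs, f)
  back <- read_alignments(f)
  expect_equal(nrow(back), 50L)
  ord <- order(back$qname); ord0 <- order(reads$qname)
  expect_equal(back$seq[ord], reads$seq[ord0])
  expect_equal(back$pos[ord], reads$pos[ord0])
  expect_equal(back$qual[ord], reads$qual[ord0])
  prof_sam <- build_locus_profile(back, sp$defs[1, ], "m")
  prof_mem <- build_locus_profile(reads, sp$defs[1, ], "m")
  expect_equal(prof_sam$accepted[sort(names(prof_sam$accepted))],
               prof_mem$accepted[sort(names(prof_mem$accepted))])
})
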