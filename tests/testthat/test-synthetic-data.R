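test_that("panel specs validate their inputs", {
  expect_error(synth_panel_spec(n_haplotypes = 2), "n_haplotypes")
  expect_error(synth_panel_spec(populations = c(P = 1L)))
  expect_error(read_sim_spec(foetal_fraction = 0.7), "foetal_fraction")
  expect_error(read_sim_spec(error_rate = 0.5), "error_rate")
})

test_that("a high Dirichlet concentration gives near-equal frequencies", {
  sp <- generate_panel(synth_panel_spec(n_loci = 6, n_haplotypes = 4L,
                                        alpha = 50, seed = 3,
                                        populations = c(P = 200L)))
  for (loc in sp$defs$locus_id) {
    ft <- haplotype_frequencies(sp$panel, loc)
    expect_gt(ft$a_e, 3.4)          # close to the 4 haplotypes present
  }
})

test_that("generated panels round-trip through VCF extraction", {
  sp <- generate_panel(synth_panel_spec(n_loci = 4, seed = 8))
  f <- tempfile(fileext = ".vcf")
  write_panel_vcf(sp$panel, sp$defs, f)
  back <- extract_panel_haplotypes(f, sp$defs,
                                   populations = sp$panel$populations)
  expect_identical(back$haplotypes, sp$panel$haplotypes)
  expect_identical(back$samples, sp$panel$samples)
})

test_that("generated panels sit at Hardy-Weinberg equilibrium", {
  # the generator draws genotypes as independent haplotype pairs, so the
  # HWE test should reject at about its nominal level
  rej <- logical(60)
  for (r in seq_along(rej)) {
    sp <- generate_panel(synth_panel_spec(n_loci = 1, seed = 1000 + r,
                                          populations = c(P = 60L)))
    p <- suppressWarnings(hwe_test(sp$panel, sp$defs$locus_id[1],
                                   seed = r, nperm = 199))
    rej[r] <- p < 0.05
  }
  expect_lt(mean(rej), 0.15)
})

test_that("families follow Mendelian rules and alleged-father switching", {
  sp <- generate_panel(synth_panel_spec(n_loci = 5, seed = 12))
  set.seed(4)
  fam_t <- generate_family(sp$panel, true_father = TRUE)
  expect_identical(fam_t$alleged_father, fam_t$father)
  for (loc in names(fam_t$child))
    expect_true(fam_t$child[[loc]][1] %in% fam_t$mother[[loc]])
  fam_f <- generate_family(sp$panel, true_father = FALSE)
  expect_false(fam_f$alleged_father_id == fam_f$father_id)
  expect_false(fam_f$alleged_father_id == fam_f$mother_id)
})

test_that("clean reads recover the genotype exactly", {
  sp <- generate_panel(synth_panel_spec(n_loci = 1, seed = 6))
  d <- sp$defs[1, ]
  loc <- sp$defs$locus_id[1]
  ft <- haplotype_frequencies(sp$panel, loc)
  het <- ft$haplotype[1:2]
  spec0 <- read_sim_spec(error_rate = 0, frac_lowq = 0, frac_low_mapq = 0,
                         frac_truncated = 0)
  set.seed(7)
  reads <- generate_sample_reads(het, d, spec0, coverage = 100L)
  prof <- build_locus_profile(reads, d, "s")
  expect_equal(prof$coverage, 100L)
  expect_equal(sort(names(prof$accepted)), sort(het))
  g <- call_genotype(prof)
  expect_equal(g$status, "called")
  expect_equal(sort(g$haplotypes), sort(het))
})

test_that("genotype calling stays accurate under default noise", {
  sp <- generate_panel(synth_panel_spec(n_loci = 1, seed = 16))
  d <- sp$defs[1, ]
  loc <- sp$defs$locus_id[1]
  spec <- read_sim_spec()
  set.seed(8)
  ok <- logical(60)
  for (i in seq_along(ok)) {
    fam <- generate_family(sp$panel)
    truth <- sort(unique(fam$mother[[loc]]))
    g <- call_genotype(build_locus_profile(
      generate_sample_reads(fam$mother[[loc]], d, spec), d, "m"))
    ok[i] <- g$status == "called" && identical(sort(g$haplotypes), truth)
  }
  expect_gte(mean(ok), 0.95)
})

test_that("truncated reads produce partial-haplotype rejections", {
  sp <- generate_panel(synth_panel_spec(n_loci = 1, n_snps = 4L, seed = 26))
  d <- sp$defs[1, ]
  ft <- haplotype_frequencies(sp$panel, sp$defs$locus_id[1])
  spec <- read_sim_spec(frac_truncated = 0.3, error_rate = 0,
                        frac_lowq = 0, frac_low_mapq = 0)
  set.seed(9)
  reads <- generate_sample_reads(ft$haplotype[1:2], d, spec,
                                 coverage = 200L)
  prof <- build_locus_profile(reads, d, "s")
  expect_gt(prof$rejected[["too_partial"]] +
              prof$rejected[["ambiguous_partial"]], 0L)
  expect_lt(prof$coverage, 200L)
})

test_that("plasma reads carry the paternal haplotype at half the foetal fraction", {
  sp <- generate_panel(synth_panel_spec(n_loci = 1, seed = 18))
  d <- sp$defs[1, ]
  ft <- haplotype_frequencies(sp$panel, sp$defs$locus_id[1])
  h <- ft$haplotype
  mother <- c(h[1], h[2]); child <- c(h[1], h[3])
  spec <- read_sim_spec(error_rate = 0, frac_lowq = 0, frac_low_mapq = 0,
                        frac_truncated = 0, foetal_fraction = 0.08)
  set.seed(10)
  est <- replicate(10, {
    reads <- generate_plasma_reads(mother, child, d, spec,
                                   coverage = 2000L)
    prof <- build_locus_profile(reads, d, "p")
    unname(prof$rel_freqs[h[3]])
  })
  expect_equal(mean(est), 0.04, tolerance = 0.01)
  # f = 0 degenerates to a purely maternal profile
  spec0 <- read_sim_spec(error_rate = 0, frac_lowq = 0, frac_low_mapq = 0,
                         frac_truncated = 0, foetal_fraction = 0)
  reads0 <- generate_plasma_reads(mother, child, d, spec0,
                                  coverage = 1000L)
  prof0 <- build_locus_profile(reads0, d, "p")
  expect_equal(sort(names(prof0$accepted)), sort(c(h[1], h[2])))
})

test_that("a 30% foetal fraction trips the foreign-haplotype dismissal", {
  sp <- generate_panel(synth_panel_spec(n_loci = 1, seed = 28))
  d <- sp$defs[1, ]
  ft <- haplotype_frequencies(sp$panel, sp$defs$locus_id[1])
  h <- ft$haplotype
  mother <- c(h[1], h[2]); child <- c(h[1], h[3])
  spec <- read_sim_spec(error_rate = 0, frac_lowq = 0, frac_low_mapq = 0,
                        frac_truncated = 0, foetal_fraction = 0.30)
  set.seed(11)
  reads <- generate_plasma_reads(mother, child, d, spec, coverage = 3000L)
  pl <- analyze_plasma_locus(build_locus_profile(reads, d, "p"),
                             as_genotype_call(d$locus_id, mother))
  expect_false(pl$usable)
  expect_equal(pl$dismiss_reason, "foreign_above_cutoff")
})

test_that("generators are deterministic under a fixed seed", {
  sp <- generate_panel(synth_panel_spec(n_loci = 3, seed = 30))
  sp2 <- generate_panel(synth_panel_spec(n_loci = 3, seed = 30))
  expect_identical(sp$panel$haplotypes, sp2$panel$haplotypes)
  expect_identical(sp$defs$ref_seq, sp2$defs$ref_seq)
  set.seed(55)
  c1 <- simulate_case(sp, read_sim_spec(), TRUE)
  set.seed(55)
  c2 <- simulate_case(sp, read_sim_spec(), TRUE)
  expect_identical(c1$reads, c2$reads)
})

test_that("a full synthetic case analyzes end to end", {
  sp <- generate_panel(synth_panel_spec(n_loci = 8, seed = 33))
  fts <- stats::setNames(lapply(sp$defs$locus_id, function(l)
    haplotype_frequencies(sp$panel, l)), sp$defs$locus_id)
  set.seed(12)
  res <- analyze_case(simulate_case(sp, read_sim_spec(), TRUE),
                      sp$defs, fts, case_id = "T01")
  expect_s3_class(res$report, "paternity_report")
  expect_true(res$report$decision %in% c("inclusion", "inconclusive"))
  expect_true(res$report$n_used + res$report$n_discrepant <= 8L)
  out <- capture.output(print(res))
  expect_true(any(grepl("Paternity report", out)))
})
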