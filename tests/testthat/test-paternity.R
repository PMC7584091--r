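gcall <- function(haps) as_genotype_call("L", haps)

ft6 <- make_freq_table("L", c(A = 0.30, B = 0.25, C = 0.20, D = 0.10,
                              E = 0.10, F = 0.05), 1000L)

test_that("evaluate_locus reproduces the haplotype-combination verdicts", {
  # father C/D, mother A/B, plasma shows C: consistent, obligate C
  e1 <- evaluate_locus(gcall(c("C", "D")), gcall(c("A", "B")),
                       mk_plasma(c(C = 0.04)), ft6)
  expect_equal(e1$verdict, "consistent")
  expect_equal(e1$shared_count, 0L)
  expect_equal(e1$ff_count, 1L)
  expect_equal(e1$obligate_haplotype, "C")
  # no shared haplotype and no matching candidate: cannot be the father
  e2 <- evaluate_locus(gcall(c("C", "D")), gcall(c("A", "B")),
                       mk_plasma(numeric(0)), ft6)
  expect_equal(e2$verdict, "discrepant")
  expect_equal(c(e2$shared_count, e2$ff_count), c(0L, 0L))
  # both father haplotypes seen: the more frequent one is the true one
  e3 <- evaluate_locus(gcall(c("C", "D")), gcall(c("A", "B")),
                       mk_plasma(c(C = 0.03, D = 0.05)), ft6)
  expect_equal(e3$obligate_haplotype, "C")   # freq(C)=0.20 > freq(D)=0.10
  expect_equal(e3$ff_count, 2L)
  # shared haplotype, no candidate: masked paternal signal
  e4 <- evaluate_locus(gcall(c("A", "C")), gcall(c("A", "B")),
                       mk_plasma(numeric(0)), ft6)
  expect_equal(e4$verdict, "consistent")
  expect_equal(e4$shared_count, 1L)
  expect_true(e4$ambiguous)
  expect_equal(e4$obligate_haplotype, "A")
  # a candidate matching no father haplotype is logged, not counted
  e5 <- evaluate_locus(gcall(c("A", "C")), gcall(c("A", "B")),
                       mk_plasma(c(E = 0.03)), ft6)
  expect_equal(e5$ff_count, 0L)
  expect_equal(e5$unmatched_candidates, "E")
})

test_that("locus_pi gives the textbook values for obligate haplotypes", {
  ft <- make_freq_table("L", c(A = 0.25, B = 0.25, C = 0.5), 1000L)
  e <- evaluate_locus(gcall(c("A", "C")), gcall(c("B", "C")),
                      mk_plasma(c(A = 0.05), mhaps = c(B = 0.5, C = 0.45)),
                      ft)
  expect_equal(e$pi, 0.5 / 0.25)   # heterozygous carrier, p = 0.25
  ft2 <- make_freq_table("L", c(A = 0.5, B = 0.5), 1000L)
  e2 <- evaluate_locus(gcall("A"), gcall("B"),
                       mk_plasma(c(A = 0.05), mhaps = c(B = 0.95)), ft2)
  expect_equal(e2$pi, 1 / 0.5)     # homozygous father, p = 0.5
})

test_that("locus_pi equals the enumerated likelihood ratio", {
  set.seed(17)
  haps <- c("A", "B", "C", "D", "E", "F")
  for (rep in 1:40) {
    k <- sample(3:6, 1)
    fr <- rgamma(k, 1.5); fr <- fr / sum(fr)
    ft <- make_freq_table("L", stats::setNames(fr, haps[1:k]), 2000L)
    mother <- sample(ft$haplotype, 2, replace = TRUE)
    father <- sample(ft$haplotype, 2, replace = TRUE)
    mhf <- stats::setNames(rep(0.45, length(unique(mother))),
                           unique(mother))
    # masked case: no candidate
    ev <- evaluate_locus(gcall(father), gcall(mother), mk_plasma(
      numeric(0), mhaps = mhf), ft)
    if (ev$verdict == "consistent")
      expect_equal(ev$pi, brute_pi(father, mother, NULL, ft),
                   tolerance = 1e-12)
    # observed-candidate case: the father transmits a non-maternal hap
    cand <- setdiff(father, mother)
    if (length(cand)) {
      ev2 <- evaluate_locus(gcall(father), gcall(mother), mk_plasma(
        stats::setNames(0.05, cand[1]), mhaps = mhf), ft)
      expect_equal(ev2$pi, brute_pi(father, mother, cand[1], ft),
                   tolerance = 1e-12)
    }
  }
})

test_that("trio_evidence equals the enumerated trio likelihood ratio", {
  set.seed(19)
  haps <- c("A", "B", "C", "D", "E")
  for (rep in 1:40) {
    k <- sample(3:5, 1)
    fr <- rgamma(k, 1.5); fr <- fr / sum(fr)
    ft <- make_freq_table("L", stats::setNames(fr, haps[1:k]), 2000L)
    mother <- sample(ft$haplotype, 2, replace = TRUE)
    truef <- sample(ft$haplotype, 2, replace = TRUE)
    child <- c(sample(mother, 1), sample(truef, 1))
    father <- sample(ft$haplotype, 2, replace = TRUE)  # any alleged man
    tv <- trio_evidence(mother, child, father, ft)
    bf <- brute_trio_pi(mother, child, father, ft)
    if (tv$verdict == "consistent")
      expect_equal(tv$pi, bf, tolerance = 1e-12)
    else expect_true(is.na(bf))
  }
})

test_that("mutation_pi follows the mutation-rate over minimum-frequency ratio", {
  expect_equal(mutation_pi(), 5e-5)
  expect_equal(mutation_pi(1e-8, 1e-4), 1e-4)
  expect_error(mutation_pi(0, 1e-4), "positive")
  expect_error(mutation_pi(1e-8, -1), "positive")
})

test_that("discrepant loci refuse a paternity index", {
  e <- evaluate_locus(gcall(c("C", "D")), gcall(c("A", "B")),
                      mk_plasma(numeric(0)), ft6)
  expect_error(locus_pi(e, gcall(c("C", "D")), ft6), "discrepant")
})

mk_ev <- function(pi, verdict = "consistent", loc = "L") {
  structure(list(locus_id = loc, shared_count = 0L,
                 ff_count = if (verdict == "consistent") 1L else 0L,
                 verdict = verdict, obligate_haplotype = "X",
                 ambiguous = FALSE, pi = pi,
                 unmatched_candidates = character(0)),
            class = "locus_evidence")
}

test_that("combine_evidence computes CPI, W and the decision rules", {
  evs <- lapply(1:7, function(i) mk_ev(2, loc = paste0("L", i)))
  rep7 <- combine_evidence(evs)
  expect_equal(rep7$decision, "inclusion")
  expect_equal(rep7$cpi, 128, tolerance = 1e-9)
  expect_equal(rep7$w, 128 / 129, tolerance = 1e-12)
  expect_true(rep7$low_marker_flag)   # 7 < 15 loci
  # a single uninformative locus gives even odds
  expect_equal(combine_evidence(list(mk_ev(1)))$w, 0.5)
  # two discrepant loci exclude; W is not reported
  exc <- combine_evidence(c(lapply(1:5, function(i) mk_ev(2)),
                            list(mk_ev(NA_real_, "discrepant"),
                                 mk_ev(NA_real_, "discrepant"))))
  expect_equal(exc$decision, "exclusion")
  expect_true(is.na(exc$w))
  # one discrepant among 15 is inconclusive, W flagged but present
  inc <- combine_evidence(c(lapply(1:14, function(i) mk_ev(2)),
                            list(mk_ev(NA_real_, "discrepant"))))
  expect_equal(inc$decision, "inconclusive")
  expect_false(is.na(inc$w))
  expect_error(combine_evidence(list()), "no locus evidence")
})

test_that("W is permutation-invariant and monotone in added evidence", {
  set.seed(3)
  pis <- c(2, 0.5, 3, 1.2, 10)
  evs <- lapply(seq_along(pis), function(i) mk_ev(pis[i],
                                                  loc = paste0("L", i)))
  w0 <- combine_evidence(evs)$w
  expect_equal(combine_evidence(sample(evs))$w, w0)
  expect_equal(combine_evidence(c(evs, list(mk_ev(1))))$w, w0)
  expect_gt(combine_evidence(c(evs, list(mk_ev(1.5))))$w, w0)
  expect_lt(combine_evidence(c(evs, list(mk_ev(0.5))))$w, w0)
})

test_that("log-space accumulation survives 100 extreme loci", {
  set.seed(4)
  pis <- 10^runif(100, -5, 5)
  rep100 <- combine_evidence(lapply(seq_along(pis), function(i)
    mk_ev(pis[i], loc = paste0("L", i))))
  expect_equal(rep100$log10_cpi, sum(log10(pis)), tolerance = 1e-9)
  expect_true(is.finite(rep100$log10_cpi))
  expect_false(is.nan(rep100$w))
  expect_true(rep100$w >= 0 && rep100$w <= 1)
  # a strongly positive stack stays distinguishable from 1 in log space
  big <- combine_evidence(lapply(1:100, function(i)
    mk_ev(10, loc = paste0("B", i))))
  expect_equal(big$log10_cpi, 100)
})

test_that("reports serialize to JSON and TSV", {
  evs <- lapply(1:3, function(i) mk_ev(2, loc = paste0("L", i)))
  rep3 <- combine_evidence(evs, case_id = "T01")
  j <- tempfile(fileext = ".json"); tsv <- tempfile(fileext = ".tsv")
  write_paternity_report(rep3, j, tsv)
  got <- jsonlite::read_json(j)
  expect_equal(got$decision, "inclusion")
  expect_equal(got$w, 8 / 9, tolerance = 1e-9)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 3L)
})
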