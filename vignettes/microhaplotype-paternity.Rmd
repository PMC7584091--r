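---
title: "Noninvasive prenatal paternity testing with microhaplotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive prenatal paternity testing with microhaplotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhpaternity)
```

## The problem

During pregnancy, maternal plasma carries cell-free DNA that is a mixture
of maternal DNA and a minor foetal component (the foetal fraction,
typically around 10% at the ninth gestational week). Half of the foetal
component is the haplotype the foetus inherited from its father. A
paternity question can therefore be answered without an invasive
procedure: sequence the mother's and the alleged father's genomic DNA and
the maternal plasma, find the haplotype in plasma that cannot be the
mother's, and ask whether the alleged father carries it.

SNP-based noninvasive tests need hundreds of markers because a biallelic
SNP carries little information per locus. This package implements the
alternative of *microhaplotypes*: amplicons of 80--180 bp containing two
or more SNPs whose phased base combination forms a multi-allelic marker
with at least three haplotypes. Because each locus has many alleles, far
fewer loci (15--20) suffice, and the short amplicons match the fragment
sizes of cell-free DNA (maternal ~166 bp, foetal ~145 bp), which rule out
most STR markers.

## Pipeline overview

1. **Panel statistics** (`extract_panel_haplotypes`,
   `haplotype_frequencies`, `hwe_test`, `le_test`): phased haplotypes are
   read from a multi-sample reference VCF; per-locus haplotype frequency
   tables supply the population frequencies used in the paternity index,
   plus the effective number of alleles $A_e = 1/\sum_i p_i^2$ and
   equilibrium screens.
2. **Read processing** (`filter_reads`, `extract_read_haplotypes`,
   `resolve_partials`, `build_locus_profile`): amplicon alignments are
   turned into per-locus haplotype observation profiles.
3. **Genotyping** (`call_genotype`, `analyze_plasma_locus`,
   `estimate_foetal_fraction`): rule-table genotype calls for the
   parents; confirmation of the maternal haplotypes in plasma and
   detection of candidate paternal haplotypes in the foetal window.
4. **Paternity evaluation** (`evaluate_locus`, `locus_pi`,
   `combine_evidence`): per-locus evidence, paternity indices, the
   combined index and the probability of paternity, and the
   exclusion/inconclusive/inclusion decision.
5. **Simulation** (`simulate_trio`, `paternity_power_curve`,
   `cross_evaluate`): marker-count justification experiments.
6. **Synthetic data** (`generate_panel`, `generate_family`,
   `generate_sample_reads`, `generate_plasma_reads`): everything above is
   testable without external downloads.

## Read filtering and haplotype extraction

A read contributes to a locus only if it is the aligner's single reported
alignment for that fragment, its mapping quality is strictly greater than
20 (Phred), and its CIGAR contains only alignment match/mismatch
operations (`M`, `=`, `X`). Indel- or clip-bearing reads are rejected
outright because any gap shifts the SNP coordinates within the read; the
pipeline deliberately performs no realignment.

At each SNP position of the locus the read's base is taken; bases with
Phred quality below 20, and positions the read does not cover, become the
unknown symbol `-`. A read with no unknown symbols is a *total*
haplotype; otherwise it is a *partial* haplotype. A partial with less
than 70% of its bases known is discarded. An eligible partial is compared
with the distinct total haplotypes observed in the same sample and locus
(agreement at every known position); it is rescued only when it matches
exactly one total, otherwise it is discarded as ambiguous. The 70%
boundary is applied as stated (strictly less discarded), which means a
single unknown base already discards 2-SNP and 3-SNP haplotypes — only
loci with four or more SNPs can have partials rescued. Matching against
sample-local totals, rather than the population panel, keeps the rescue
step independent of the reference data.

## Genotype calls and plasma interpretation

Parental genotypes are called from the relative frequencies of accepted
haplotypes, with coverage required to exceed 20x. Writing $k$ for the
number of haplotypes above 10% relative frequency:

| condition 1 | condition 2 | call |
|---|---|---|
| one haplotype > 10% | same haplotype > 80% | homozygous |
| two haplotypes > 10% | one haplotype > 80% | homozygous |
| two haplotypes > 10% | both within 20--80% | heterozygous |
| three haplotypes > 10% | exactly two > 35% | heterozygous |

Any other configuration (including $k = 0$ or $k > 3$, which the original
rule table leaves unstated) is a no-call. Boundary conventions: the
comparisons "> 10%", "> 80%", "> 35%" are strict; the heterozygous band
20--80% is inclusive.

A plasma locus is interpretable when coverage reaches 1000x, every
confirmed maternal haplotype keeps at least 12% relative frequency, and
no non-maternal haplotype exceeds 12% (the 12% maternal cut-off applied
per haplotype). A non-maternal haplotype above 12% would imply a total
foetal fraction around 25%, implausible at the relevant gestational ages,
so such loci are dismissed as artefacts rather than reinterpreted.
Candidate paternal haplotypes are the non-maternal haplotypes with
relative frequency in the inclusive 1--12% window. Sequencing errors
produce spurious haplotypes in exactly this window too, which is why a
candidate alone is never treated as proof: the evidence rules below keep
a locus consistent when a candidate fails to match the alleged father but
a shared haplotype could carry the paternal signal.

The per-locus relative frequency of the candidate matching the father
estimates the paternally inherited half of the foetal fraction; the
package summarizes informative loci by their median (robust to the
locus-to-locus error noise) and doubles it for the total foetal fraction.

## Evidence and the probability of paternity

For a locus $m$, with $|SP_m \cap M_m|$ the haplotypes shared by alleged
father and mother and $|FF_m|$ the plasma candidates matching the father:

| $|SP_m \cap M_m|$ | $|FF_m|$ | result |
|---|---|---|
| 0 | 0 | cannot be the father |
| any other combination | | can be the father |

With two matching candidates, one must be an artefact; the haplotype with
the higher population frequency is taken as the true paternal one. At
least two discrepant loci are required for exclusion; exactly one gives
an inconclusive result, since a single mismatch can be a mutation or an
artefact.

The paternity index of a consistent locus is the likelihood ratio of the
evidence under "alleged father" versus "random man". For an unambiguous
obligate haplotype $h$ with population frequency $p$:
$PI = T/p$, with transmission probability $T = 1$ (father homozygous for
$h$) or $T = 1/2$ (heterozygous carrier). When no candidate is visible
and the parents share haplotypes, the paternal haplotype is masked by the
maternal signal and can be any maternal haplotype $h \in M$:
$PI = T(M)/F(M)$ where $T(M)$ is the fraction of the father's two
haplotype copies in $M$ and $F(M) = \min(1, \sum_{h \in M} p_h)$. This is
the form that agrees with the brute-force likelihood ratio enumerated
over all haplotypes (the suite checks this equivalence), and it reduces
to $T/p$ when $M$ has a single element; restricting the denominator to
the haplotypes the father happens to carry would overstate the evidence.

Population frequencies come from the panel's pooled frequency tables by
default (population-specific tables by argument). A haplotype absent from
a panel of $n$ chromosomes is assigned frequency $1/(n+1)$ — with the
2504-sample, 5008-chromosome panel used for the published frequency
tables this is $1/5009$, and the smallest observable frequency is
$2 \times 10^{-4}$. When no paternal haplotype is consistent with plasma,
the mismatch is priced as a mutation: $PI = \mu / f_{\min}$ with SNP
mutation rate $\mu = 10^{-8}$ per locus per generation and
$f_{\min} = 2 \times 10^{-4}$, giving $5 \times 10^{-5}$ regardless of
how many SNPs differ (multiple simultaneous mutations are not priced
lower than one).

The combined index is the product of per-locus indices, accumulated in
log space so a hundred loci with indices between $10^{-5}$ and $10^{5}$
cannot overflow, and the probability of paternity is
$W = CPI/(1+CPI)$ under 1:1 prior odds (the forensic convention).
$W$ is reported for inclusions, reported with a prominent flag for
inconclusive cases (the discrepant locus is kept out of the product by
default; a configuration switch can include its mutation index), and not
reported for exclusions. Reports resting on fewer than 15 informative
loci carry a low-marker flag, reflecting the marker count at which false
inclusions become rare (below).

## Simulation experiments

`paternity_power_curve` draws a mother and father from the reference
panel (pooled, or within one population), builds a child that inherits
one haplotype from each, and evaluates either the true father or an
unrelated second man (distinct from both parents) as the alleged father,
for every marker count from 1 to the panel size. A false inclusion is a
non-father reaching an inclusion decision with $W > 0.99$, the same
threshold at which inclusions are reported.

Two evidence routes are provided. The default, `evidence = "trio"`,
scores each locus from the full simulated child genotype with the
classical trio likelihood ratio (`trio_evidence`), which is how a
genotype-level simulation of a trio is naturally defined; under it the
false-inclusion rate collapses with marker count and is below 1% from 13
markers on under the default panel conditions. The alternative,
`evidence = "plasma"`, pushes the simulated genotypes through the
masked-plasma evidence rules used on real cases
(`genotypes_to_ideal_plasma` + `evaluate_locus`). The plasma route is
deliberately weaker — a man who shares any haplotype with the mother can
never be excluded at that locus, because an observed candidate might
always be an artefact — and its false-inclusion rate at a given marker
count is correspondingly higher. The package keeps both because the
first matches the marker-count justification experiment and the second
measures what the case-level decision rules can do.

`cross_evaluate` mirrors the real-data check: every mother--plasma duo is
paired with every alleged father, pairs with exactly one discrepant locus
are set aside as inconclusive, exclusions score 0 and other pairs score
$W$, and an ROC curve is drawn for each minimum marker count.

## The synthetic-data generator

`generate_panel` builds loci of 2--4 SNPs carrying 4--6 distinct
haplotypes whose frequencies are drawn from a symmetric Dirichlet with
concentration 3, independently per population (two populations of 50 by
default). These defaults put the effective allele number of most loci in
the 3--5 range, the informativeness regime multi-allelic markers are
selected for, and give the panel mild population structure. Individuals
are phased diploid draws under Hardy--Weinberg equilibrium within their
population, so the HWE screen rejects at its nominal level on generated
panels.

`generate_sample_reads` and `generate_plasma_reads` emit aligned amplicon
records with controllable noise: per-base substitution errors (default
0.5%), a two-point base-quality mixture (Q37 / Q10, the low point falling
under the masking threshold; default 5% of SNP bases), truncated reads
producing partials (5%), low-mapping-quality reads (2%), and optional
secondary-flag and indel-CIGAR reads so every filter rejection path is
exercised. Plasma reads are drawn from the child's haplotypes with
probability equal to the foetal fraction (default 8%), otherwise from the
mother's, so the paternal-only haplotype appears at half the foetal
fraction in expectation. Substitution errors are injected at the typed
SNP positions only: an error elsewhere in the amplicon cannot change the
extracted haplotype, and the CIGAR filter ignores mismatches, so off-SNP
errors would cost time without exercising any code path. No PCR
duplicates, GC bias or fragment-length structure are simulated; the
generator's purpose is to exercise the pipeline's decision rules, not to
benchmark aligners.

What passing tests on this synthetic data do **not** show about real
data: amplicon-specific error hotspots and strand biases, true
population-level linkage between nearby loci, maternal copy-number
anomalies and vanishing-twin artefacts, and the empirical haplotype
diversity of any particular population are all outside the generator's
scope. The headline numbers obtained on real reference-panel data (a
false-inclusion count of a few per tens of thousands at 13 markers, and
$W > 99\%$ in genuine trios) therefore have scaled-down analogues here,
not reproductions.

## Numerical and design choices

* **Coordinates** are 1-based inclusive throughout, matching SAM and VCF;
  conversion happens only inside file readers.
* **HWE test**: microhaplotypes are highly multi-allelic, so asymptotic
  chi-square on genotype tables is unreliable. The statistic is the
  chi-square distance of genotype counts from their expectations given
  the allele counts; its null distribution comes from randomly re-pairing
  the pooled alleles (Monte-Carlo with the add-one correction, seeded).
  For five or fewer individuals, all distinct pairings are enumerated
  (`method = "exact"`), which doubles as the oracle in the suite. The QC
  report gives raw and Bonferroni-adjusted pass flags; no particular
  correction is imposed.
* **LE test**: contingency chi-square over phased chromosome pairs, with
  `chisq.test`'s Monte-Carlo null whenever an expected cell is small.
* **Locus coverage** for the genotype rules is the accepted complete
  haplotype count, which bounds every SNP's read depth from below.
* **Degenerate inputs**: zero accepted reads yield a coverage-0 profile
  that downstream calls treat as uncallable; monomorphic loci return HWE
  p = 1 with a warning; an uncalled mother makes the plasma locus a hard
  error since nothing can be interpreted without her haplotypes.
* **Tie-breaks**: frequency tables order by descending frequency, ties
  lexicographic, so outputs are byte-stable; with two candidate paternal
  haplotypes the higher population frequency wins.
* **Problem sizes** used by the test suite and the acceptance script:
  power curves with 500 true and 500 false replicates on a 20-locus
  panel; an end-to-end read-level benchmark of 40 true-father and 40
  non-father cases at 200x genomic and 2000x plasma coverage; foetal
  fraction recovery at 4/8/12% over 50 replicates of 8 loci; 200
  genotype-accuracy calls. These sizes give the binomial resolution the
  assertions need while keeping the default run quick.

## A worked example

```{r example}
sp <- generate_panel(synth_panel_spec(seed = 7))
freq_tables <- setNames(
  lapply(sp$defs$locus_id, function(l) haplotype_frequencies(sp$panel, l)),
  sp$defs$locus_id)

set.seed(42)
case <- simulate_case(sp, read_sim_spec(), true_father = TRUE)
res <- analyze_case(case, sp$defs, freq_tables, case_id = "demo")
res
summary(res$report)$table[1:5, ]
```

## Known limitations

* No probabilistic genotype likelihoods: calls are rule-table decisions,
  faithful to the protocol but blunt near the thresholds.
* No co-ancestry (theta) correction and no kinship hypotheses beyond
  father versus unrelated man; a brother of the true father would score
  deceptively well.
* The mutation index prices any mismatch as one mutation event; loci with
  genuinely elevated mutability are not modelled.
* Exactly one discrepant locus always yields "inconclusive" regardless of
  how extreme the remaining evidence is.
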