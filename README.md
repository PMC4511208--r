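# snpdrift

Tests for negative selection at a small candidate SNP set, from sparse
multi-cohort genotype panels.

## The problem

Suppose three variants are known to increase an individual's dependence on a
limiting dietary nutrient, and you suspect they have been selected *against*
in a population whose traditional diet is poor in that nutrient. Dense
genotype data around the candidates — the raw material of haplotype-based
selection scans — is not available; what you have is a sparse panel of a few
hundred unlinked SNPs genotyped in three cohorts:

* `G` — the target cohort (restricted nutrient access),
* `C` — a reference cohort that fixes the minor-allele definition,
* `M` — a third cohort genetically close to the target but without the
  dietary restriction.

`snpdrift` tests whether the candidate SNPs' minor-allele frequencies are
lower in the target cohort than genetic drift can explain, using the other
genotyped SNPs as an empirical neutral background.

## The two tests

**Test 1 — cross-cohort MAF change.** For each SNP *j*,
δm<sup>j</sup> = m<sub>A</sub><sup>j</sup> − m<sub>B</sub><sup>j</sup>. The
candidate statistic is the mean δm over the 3 candidate SNPs; its null
distribution is the same mean over **all** C(n, 3) subsets of the
post-filter panel, and P is the proportion of subsets at least as small.
A Welch-type variant, t<sup>j</sup> = δm<sup>j</sup> /
√(s²<sub>A</sub>/4n<sub>A</sub> + s²<sub>B</sub>/4n<sub>B</sub>),
down-weights noisily estimated SNPs; the empirical P is invariant to the
variance scale convention.

**Test 2 — beta-binomial drift model.** The cohorts share an ancestral
frequency p<sub>A</sub> (uniform prior, integrated numerically); each
cohort's frequency is Beta-distributed with mean p<sub>A</sub> and variance
d<sub>X</sub> p<sub>A</sub>(1 − p<sub>A</sub>) (Balding–Nichols), and counts
are binomial — so counts are beta-binomial given (p<sub>A</sub>,
d<sub>X</sub>). The drift triple (d<sub>G</sub>, d<sub>C</sub>,
d<sub>M</sub>) is fitted by maximum likelihood over a 3-D geometric grid
across all retained SNPs. Each fully observed SNP then gets a conditional
tail probability q = Pr(X<sub>G</sub> ≤ x<sub>G</sub> | x<sub>C</sub>,
x<sub>M</sub>, d̂), and the candidate triple's mean q is ranked against all
C(n, 3) subset means (strict <).

Both tests sit behind the filtering cascades they assume (call rate ≥ 90 %,
polymorphic, LD-pruned at r² < 0.8), implemented exactly as two variants:
removal (pairwise test) versus per-cohort masking (drift model). See the
vignette in `vignettes/drift-selection-tests.Rmd` for the model details,
numerical choices, and what the synthetic calibration does and does not
establish.

## Worked example

Simulate the bundled scenario whose three candidate SNPs match the
motivating study's worked-example frequencies (reference cohort
0.29/0.46/0.43, target 0.09/0.18/0.12, third cohort 0.23/0.40/0.15;
sample sizes 241/159/95 individuals), then run everything:

```r
library(snpdrift)
sc <- make_paper_like_scenario(seed = 4)
td <- tempfile(); dir.create(td)
for (r in c("G", "C", "M"))
  write_genotype_table(sc$panels[[r]], file.path(td, paste0(r, ".tsv")))

mf <- run_all(list(
  panels = list(G = file.path(td, "G.tsv"), C = file.path(td, "C.tsv"),
                M = file.path(td, "M.tsv")),
  candidates = sc$candidates, seed = 4))
print(mf)
```

```
<run_manifest> snpdrift 0.1.0
 comparison      method                                        null_hypothesis
     G_vs_C  maf_change          candidate MAFs not reduced in G relative to C
     G_vs_M  maf_change          candidate MAFs not reduced in G relative to M
     M_vs_C  maf_change          candidate MAFs not reduced in M relative to C
   G_vs_C+M drift_model candidate MAFs in G follow neutral drift given C and M
   M_vs_G+C drift_model candidate MAFs in M follow neutral drift given G and C
 n_snps p_unadjusted p_adjusted_or_permutation
    213 1.259457e-06              1.259457e-06
    213 8.466070e-03              8.335086e-03
    212 1.430104e-03              2.339648e-03
    214           NA              3.539133e-04
    214           NA              8.642202e-01
```

Reading the five rows: the first three are the MAF-change test (unadjusted
and Welch-adjusted empirical P over all 3-SNP subsets of the n retained
SNPs); the candidate reduction in the target cohort is extreme against both
comparators (P ≤ 0.008 everywhere), and the weaker `M_vs_C` signal reflects
the third cohort's intermediate frequencies. The last two rows are the
drift-model permutation P: the target cohort's candidate counts are far
below neutral expectation given the other cohorts (P = 3.5 × 10⁻⁴), while
the third cohort shows no such reduction (P = 0.86) — the same asymmetry the
motivating study reports. Candidate MAFs as realized in this simulation:

```r
print(mf$maf_table)
#>       snp_id alleles maf_G maf_C maf_M
#> 1    rs12676    G(A)  0.08  0.32  0.24
#> 2  rs2236225    G(A)  0.16  0.49  0.38
#> 3 rs12325817    G(A)  0.11  0.41  0.10
```

## Command line

`inst/cli/snpdrift.R` exposes `simulate`, `filter pairwise|threeway`,
`test-m1`, `test-m2` and `run-all` subcommands over the same functions,
reading TSV or VCF panels and emitting JSON.
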