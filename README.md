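# hlafreq

Maximum-likelihood estimation of multi-locus HLA haplotype frequencies
from unphased, ambiguous, mixed-resolution genotype records — the kind of
data held by hematopoietic stem cell donor registries — plus the
simulation and comparison machinery to validate the estimates on
populations with known frequencies.

**Who it is for.** Immunogeneticists and registry bioinformaticians who
need population haplotype frequencies for donor search optimization,
registry planning, or population genetics, starting from typing records
that mix one- to four-field allele names, G/P/g allele-group codes, NMDP
multiple allele codes (MACs) and genotype list (GL) strings.

## The method

Under Hardy-Weinberg equilibrium, an unordered haplotype pair
(*diplotype*) d = {h₁, h₂} has probability

    P(d | f) = (2 − δ_{h₁h₂}) f_{h₁} f_{h₂}

where f_h is the frequency of haplotype h. Preprocessing converts each
individual into candidate diplotypes with expansion weights w_d: records
are split into single-locus genotypes, MACs and GL strings are expanded,
an optional implicit-ambiguity filter is applied, alleles are translated
locus-wise to a uniform target resolution (1f/2f/3f/4f or G/P/g groups),
and the loci are recombined by Cartesian product, each step splitting
weight equally over its outcomes. An EM algorithm then maximizes the
observed-data likelihood Π_i Σ_d w_d P(d | f): the E-step apportions each
individual's weight over its diplotypes by their HWE priors, the M-step
re-counts haplotype frequencies from expected chromosomes, until the
maximal frequency change drops below a user-set stop criterion. Final
frequencies below a cutoff are removed and optionally renormalized.

The package also implements the validation observables — the L1 distance
d, the maximal absolute difference Δ, the first rank ρ with relative
deviation above a threshold, additional/missing haplotype counts, and the
Hardy-Weinberg effect size W_n — together with artificial population
builders (combinatorial construction at integer HWE counts, and random
haplotype pairing), resolution heterogenization, MAC masking, and a
generator for self-consistent miniature nomenclature tables.

## A worked example

Three donors: one typed with the MAC `A*31:VSCB` (which encodes A\*31:01,
A\*31:41 and A\*31:68), one with a mixed-resolution g-group typing, one
unambiguous homozygote. Estimation at g-group resolution:

```r
library(hlafreq)
tbls <- fixture_nomenclature()          # miniature nomenclature tables

pop <- tibble::tibble(
  id   = c("D001", "D002", "D003"),
  A.1  = c("31:VSCB", "01:01",  "01:01"),
  A.2  = c("31:01",   "02:01g", "01:01"),
  B.1  = c("07:01",   "07:02",  "07:01"),
  B.2  = c("07:01",   "07:01",  "07:01")
)

fit <- estimate_haplotype_frequencies(pop, tbls, resolution = "g",
  loci = c("A", "B"), epsilon = 1e-8, seed = 1)
tidy(fit)
#> # A tibble: 5 × 3
#>   haplotype         frequency  rank
#>   <chr>                 <dbl> <int>
#> 1 A*01:01g~B*07:01g 0.5           1
#> 2 A*31:01g~B*07:01g 0.333         2
#> 3 A*02:01g~B*07:02g 0.167         3
#> 4 A*31:41g~B*07:01g 0.0000289     4
#> 5 A*31:68g~B*07:01g 0.0000289     5
```

The six chromosomes split 3 : 2 : 1 over the three supported haplotypes
(0.5 / 0.333 / 0.167). D001's MAC is resolved almost entirely to A\*31:01g
— its other chromosome already carries A\*31:01, so the homozygous
explanation dominates — leaving only trace frequencies on the two
alternative decodings A\*31:41g and A\*31:68g. `glance(fit)` reports 5772
EM iterations to convergence at a 1e-8 stop criterion and the final
log-likelihood −6.47; `autoplot(fit)` draws the monotone likelihood trace.

File-based workflows use the same functions via
`inst/cli/hlafreq.R` (`prepare`, `estimate`,
`simulate model1|model2|mask|heterogenize|fixtures`, `compare`), with
haplotype frequency files (`haplotype<TAB>frequency`) as the shared
interchange format.

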