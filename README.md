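# rorscan

Cluster-region scans, per-mutation penetrance and founder-mutation dating
for BRCA1/2 case-control carrier cohorts.

Carriers of deleterious BRCA1/2 germline mutations do not share one cancer
risk. Mutations clustered in some parts of the coding sequence shift risk
toward ovarian cancer (ovarian cancer cluster regions, OCCRs), others
toward breast cancer (BCCRs), and individual recurrent founder mutations
range from near-baseline to complete penetrance. `rorscan` is for genetic
epidemiologists working with carrier screening cohorts — subject tables
with clinical status and variant tables with HGVS cDNA descriptions — who
want to locate such regions, estimate mutation-specific risk, and date
founder mutations.

## What it computes

**The ROR scan.** The gene's observed deleterious-carrier positions
(5'-most affected CDS base per variant, intronic offsets preserved) are
partitioned into bins of roughly equal carrier count. For each bin, with
`b`/`o` breast/ovarian cases carrying a variant in the bin and `B`/`O` the
gene-wide non-carriers in those arms, the scan statistic is the ratio of
the bin's breast-cancer and ovarian-cancer odds ratios; the shared
cancer-free arm cancels, so

    ROR = (b / B) / (o / O)

with a Woolf 95% CI and two-sided z-test on log ROR, Benjamini–Hochberg
adjustment per gene, and calls: adjusted p < 0.05 with ROR < 1 is an OCCR,
ROR > 1 a BCCR.

**Bayes allelic penetrance.** For one mutation with carrier frequencies
`f_case` (among cases) and `f_ctrl` (among cancer-free controls) and a
population lifetime risk `K` (default 0.053):

    penetrance = f_case * K / (f_case * K + f_ctrl * (1 - K))

reported against the conventional 0.35 carrier-risk lower bound, with
family-history stratification.

**Founder dating.** Average annual growth rates from historical census
records, `X = ((P2 - P1)/P1)^(1/n) - 1` with `P2 = 1.4e9` by default, and
the best-correlation rule selecting, among externally estimated
(growth-rate, age) pairs, the record minimising |estimated age − elapsed
years|.

**Plus** STR allele-frequency chi-square tests and founder core-haplotype
sharing summaries, per-province carrier maps with sample-size masking, and
a seed-deterministic synthetic cohort generator (`simulate_cohort()`,
`simulate_str_panel()`) that makes every stage testable without protected
data.

## Worked example

Simulate a study-scale cohort with a designed ovarian cluster region at
c.1154–c.2111 (ROR 0.3) and a founder hotspot, then scan:

```r
library(rorscan)

cfg <- sim_config(
  seed = 11,
  regions  = data.frame(start = 1154, end = 2111, ror = 0.3),
  hotspots = data.frame(position = 5470L, fraction = 0.08,
                        label = "c.5470_5477delATTGGGCA")
)
sim <- simulate_cohort(cfg) # 7,738 subjects, 854 variant calls
scan_regions(sim$subjects, sim$variants, "BRCA1", n_bins = 9)
#>   bin n_carriers start  end   ror ci_low ci_high   p_adj call
#> 1   1         95    25  595 0.942  0.609   1.456 0.92861 none
#> 2   2         94   598 1264 1.206  0.771   1.885 0.92799 none
#> 3   3         96  1270 2344 0.415  0.263   0.656 0.00152 OCCR
#> 4   4         95  2364 2921 0.882  0.580   1.343 0.92861 none
#> 5   5         94  2955 3628 1.409  0.892   2.226 0.42606 none
#> 6   6         95  3629 4255 0.980  0.636   1.511 0.92861 none
#> 7   7         93  4259 4810 0.917  0.595   1.412 0.92861 none
#> 8   8         93  4816 5460 0.623  0.395   0.982 0.18746 none
#> 9   9         99  5470 5587 1.029  0.674   1.570 0.92861 none
```

The bin overlapping the designed region (bin 3) is the only call: its
estimated ROR of 0.415 is the designed 0.3 diluted by the null flanks the
bin absorbs, and the adjusted p-value survives BH across the nine bins.
The founder hotspot dominates recurrence:

```r
recurrent_fraction(sim$variants, "BRCA1", "c.5470_5477delATTGGGCA")$label
#> [1] "9.5% (81/854)"
```

Dating a founder mutation from the bundled historical census records
(growth rates in per mille, externally estimated ages per record):

```r
tab <- growth_rate_table(historical_populations())
sel <- select_best_rate(tab)
#> Selected record: 2 A.D. (estimated age 2090 years, |age - elapsed| = 72)
years_to_calendar(sel$age)
#> [1] "70 B.C."
```

And the penetrance boundary for a mutation absent from controls:

```r
bayes_penetrance(f_case = 0.004, f_ctrl = 0)
#> Bayes allelic penetrance: 1.000 (at or above the 0.35 reference; K = 0.053)
```

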