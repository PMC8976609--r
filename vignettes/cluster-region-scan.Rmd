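---
title: "Methods: cluster-region scans, penetrance and founder dating with rorscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-region scans, penetrance and founder dating with rorscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorscan)
```

Carriers of deleterious BRCA1/2 germline mutations do not share a single
cancer risk: mutations in some stretches of the coding sequence are
associated with relatively more ovarian cancer (ovarian cancer cluster
regions, OCCRs), others with relatively more breast cancer (BCCRs), and
individual recurrent founder mutations span the range from near-baseline to
complete penetrance. `rorscan` implements the statistical machinery for
asking these questions of a case-control carrier screening cohort: a
ratio-of-odds-ratios scan along the CDS, a Bayes allelic penetrance
estimator, and the demographic bookkeeping used to date a founder mutation.

## The ROR scan

### Binning

All deleterious mutations (pathogenic or likely pathogenic; large
rearrangements are excluded upstream because they span multiple bins) are
reduced to a representative CDS coordinate: the 5'-most affected base of
the variant, with intronic boundary positions keeping their signed offset
(`c.5468-1G>A` sits just before base 5468). Binning then partitions the
observed carrier-position multiset into `n_bins` contiguous bins of roughly
equal carrier count.

Equal-count binning with indivisible hotspots is a small combinatorial
problem and no particular algorithm is canonical. `build_bins()` cuts at
empirical quantiles of the carrier multiset and then repairs each boundary
locally, moving a cut one observed position left or right whenever that
reduces the max-minus-min count spread, iterating to a fixed point. All
carriers observed at one position always stay together. The test suite
checks the result against an exhaustive search over all cut placements on
small instances; the greedy-plus-repair solution attains the exhaustive
optimum there and by construction never does worse than the plain quantile
cut. Bin intervals are reported as `[first observed position, last
observed position]`, so gaps between consecutive bins are expected. The
bin count is a user parameter (`n_bins`, or a `carriers_per_bin` target,
default 60 — the scale at which the scan has adequate carriers per bin in
cohorts of a few hundred carriers per gene).

### The statistic

For bin $i$, with $b_i$ breast-cancer and $o_i$ ovarian-cancer subjects
carrying a deleterious variant in the bin, $B$ and $O$ the gene-wide
non-carrier counts in those arms, and a cancer-free reference arm, the scan
computes the odds ratio of breast cancer and of ovarian cancer for the bin
and takes their ratio:

$$\mathrm{ROR}_i \;=\; \frac{\mathrm{OR}^{\text{breast}}_i}{\mathrm{OR}^{\text{ovarian}}_i}
 \;=\; \frac{b_i / B}{o_i / O},$$

because the shared cancer-free arm cancels algebraically. The package
computes the confidence interval and p-value on this reduced 2x2 table: a
Woolf (log-normal) 95% interval and the matching two-sided z-test on
$\log \mathrm{ROR}$, so interval and p-value can never disagree. Zero
cells receive the Haldane-Anscombe +0.5 on all four cells. The
cancellation is asserted numerically over random tables in the tests, so
the choice of cancer-free reference counts cannot leak into the scan.

Raw p-values are adjusted per gene with Benjamini-Hochberg (`bh_adjust()`,
a thin wrapper over `stats::p.adjust`, cross-checked in the tests against
an independent from-the-definition step-up implementation on all
permutations of small inputs). A bin with adjusted $p < \alpha$ (default
0.05) is called OCCR when $\mathrm{ROR} < 1$ and BCCR when
$\mathrm{ROR} > 1$.

Two conventions are configurable because the underlying design admits
either reading: subjects with both a breast and an ovarian primary are
excluded from both case arms by default (counting them twice would let one
subject inflate both ORs); and subjects with deleterious variants in more
than one bin are excluded from the phenotype counts with a warning.

```{r scan-example}
cfg <- sim_config(
  seed = 11,
  regions = data.frame(start = 1154, end = 2111, ror = 0.3),
  hotspots = data.frame(
    position = 5470L, fraction = 0.08,
    label = "c.5470_5477delATTGGGCA"
  )
)
sim <- simulate_cohort(cfg)
scan_regions(sim$subjects, sim$variants, "BRCA1", n_bins = 9)[
  , c("bin", "n_carriers", "start", "end", "ror", "p_adj", "call")
]
```

## Bayes allelic penetrance

For a single mutation with carrier frequency $f_{\text{case}}$ among cases
of the target cancer and $f_{\text{ctrl}}$ among cancer-free controls, and
population lifetime risk $K$, Bayes inversion gives the lifetime risk in
carriers:

$$\pi \;=\; \frac{f_{\text{case}}\,K}{f_{\text{case}}\,K + f_{\text{ctrl}}\,(1 - K)}.$$

The exact published form of the allelic model is not reprinted anywhere we
could verify it from, so the implementation is this standard inversion,
documented as an assumption; it reproduces the boundary behaviour the
published results require — complete penetrance (100%) when no control
carries the mutation, and the baseline $K$ when case and control
frequencies agree. Defaults: $K = 0.053$, the estimated mean lifetime
breast cancer risk of Chinese women under the Gail model; the 0.35
conventional lower bound of carrier risk is reported as a reference
comparison (`above_reference`). Controls default to the cancer-free,
family-history-negative subset. Carrier (per-subject) frequencies are
used; at these frequencies the allele-level variant is numerically
indistinguishable at the boundaries. No smoothing is applied by default —
the complete-penetrance boundary requires the uncorrected estimator — but
`smooth = TRUE` offers +0.5/+1 pseudo-counts.

`stratified_penetrance()` repeats the estimate within family-history
strata and flags mutations whose strata straddle the 0.35 reference (the
pattern where high penetrance is confined to carriers with a positive
family history).

### What the recovery test shows

The plug-in estimator is consistent under case-control sampling when the
population prevalence equals $K$; `simulate_penetrance_counts()`
constructs exactly that generative model (non-carrier risk set so
prevalence is $K$). The estimator is, however, a ratio of binomials and
carries a finite-sample (Jensen) bias of order
$\pi(1-\pi)(1-K) / (n_{\text{ctrl}}\, q)$: negligible only when the
control arm's expected carrier count is large. The parameter-recovery test
therefore runs at $q = 0.3$, $K = 0.2$, $\pi = 0.5$ and $n = 2{,}000$ per
arm over 500 replicates, where that bias is well inside the Monte-Carlo
error of the replicate mean; at realistic founder-mutation frequencies
($q \sim 0.005$) the same estimator is visibly biased upward in small
control arms, which is a property of the estimator, not of this
implementation, and is why point estimates from a handful of control
carriers deserve caution.

## Founder-mutation dating

The mutation age itself is estimated externally (a Bayesian MCMC
linkage-disequilibrium method, run once per candidate population growth
rate); `rorscan` implements the two steps around it. First, average annual
growth rates from historical census records, using the equation exactly as
published:

$$X \;=\; \left(\frac{P_2 - P_1}{P_1}\right)^{1/n} - 1,$$

with $P_1$ the census population $n$ years ago and $P_2 = 1.4\times10^9$
the present population. Note the numerator $P_2 - P_1$: this printed form
reproduces every published per-mille rate (1.76 to 7.81), while the
conventional geometric form $(P_2/P_1)^{1/n} - 1$ does not; the latter is
available behind `form = "geometric"`. One data normalisation is baked
into the bundled table: the 1949 census figure (541.67) is stored in
millions, the only unit under which its printed 6.50 per-mille rate is
recovered. Second, `select_best_rate()` picks, among the (elapsed time
$n$, estimated age $\hat n$) pairs, the record minimising
$|\hat n - n|$ — the "best correlation" rule, with ties broken toward the
smaller elapsed time. Calendar conversion uses naive subtraction from the
present year (an age of 2,090 years from 2020 prints "70 B.C.", matching
how such ages are conventionally quoted; a strict no-year-zero count would
shift this by one).

```{r founder}
tab <- growth_rate_table(historical_populations())
tab[, c("label", "growth_rate_permille", "years_till_now", "estimated_age")]
sel <- select_best_rate(tab)
sel$age
years_to_calendar(sel$age)
```

## STR haplotypes and geography

`allele_freq_test()` compares STR allele frequencies between carriers and
controls per marker with a Pearson chi-square on the allele-count table
(two alleles per typed subject; degenerate monomorphic tables are skipped
with a notice, and rare-allele pooling is available but off by default).
No multiple-testing correction is applied across the nine markers unless
requested, matching how per-marker chi-squares are conventionally
reported. Haplotype phasing is out of scope — `core_haplotype_sharing()`
consumes externally phased chromosomes and reports, per marker, the modal
allele among founder chromosomes and its carrier/control frequencies,
flagging a founder effect when carriers exceed controls at three or more
consecutive markers.

`summarize_geography()` tabulates per-province carrier counts for chosen
mutations with the sample-size masking rule used for map displays:
provinces with fewer than 100 subjects are masked light, fewer than 50
dark (nested, dark overriding light; the thresholds are boundary-exact, so
exactly 100 is unmasked). Masked provinces keep their counts and stay in
national totals; the mask is a display flag only.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the scan assumes: fixed arm
sizes (defaults 2,400 breast, 1,697 ovarian, 3,641 cancer-free — the
screening-study scale), carrier status drawn per arm, and carrier
positions drawn from a mixture of a uniform background over the CDS
(default length 5,592 bp) and founder-hotspot point masses. The designed
region map enters as a tilt: ovarian carriers draw positions from the base
density $f$, breast carriers from $f \cdot \rho / Z$, and the breast
carrier odds are scaled by $Z$, which makes the ROR of any interval where
$\rho$ is constant exactly $\rho$ — `true_ror()` returns the designed
value of any interval in closed form, and the recovery tests use it as the
estimand. Default arm odds (0.24 ovarian, 2.5% control carrier frequency)
mirror the study-scale carrier fractions. This is a multinomial
conditional construction, not a liability model: it makes the ROR
identifiable and is fast, but it does not model age structure, family
correlation, population stratification, or ascertainment quirks of real
cohorts — passing recovery tests show the estimators are correct under the
assumed sampling model, not that real data meet those assumptions.

`simulate_str_panel()` uses a single-founder star genealogy: every founder
chromosome descends independently from one ancestral haplotype, and marker
$j$'s allele survives $g$ generations unreplaced with probability
$(1-c_j)^g$, otherwise being redrawn from the population frequencies. The
expected founder-chromosome frequency of the ancestral allele is therefore
$(1-c_j)^g + \left(1-(1-c_j)^g\right) p_j$, which the decay tests compare
against simulation. A star genealogy ignores the shared internal branches
of a real coalescent (it understates the correlation between carriers), so
it is adequate for testing sharing summaries but is deliberately simpler
than the external MCMC dating model.

All generators take a mandatory seed, restore the caller's RNG state, and
are byte-identical across runs given the same configuration.

## Problem sizes and numerical choices

The stochastic checks in the test suite run at: 200 replicates per
designed ROR in $\{0.3, 1, 3\}$ at full study scale for interval coverage,
200 null-scan replicates for the family-wise call rate, 500 replicates for
penetrance recovery, and 200 for STR sharing decay — sizes at which the
Monte-Carlo error bands are a few percent and the whole suite completes in
under a minute. Other numerical conventions: Woolf intervals and z-tests
are mutually consistent by construction; binning boundary repair stops at
a fixed point (at most 20 passes); modal-allele ties break toward the
smaller allele label; and the growth-rate equation refuses $P_2 \le P_1$
(the printed form has no real root there) rather than returning a complex
or negative rate.

## Known limitations

The raw per-bin phenotype counts behind published scan tables are
generally unpublished, so published ROR point estimates and raw p-values
cannot be re-derived — only the adjustment step is exactly checkable, and
it is. The exact test statistic used upstream of published raw p-values is
likewise unknowable; this package's z-test is one defensible choice and
is labelled as such. Penetrance estimates from very small control carrier
counts are biased upward (see above) and the complete-penetrance boundary
value should be read as "no control carriers observed", not as certainty.
The scan assumes a single representative coordinate per variant and
excludes multi-bin carriers; covariate adjustment and survival-style
hazard formulations are out of scope.
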