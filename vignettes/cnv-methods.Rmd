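---
title: "Detecting CNVs and weighing drift against selection: the models behind wormcnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting CNVs and weighing drift against selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormcnv)
library(dplyr)
```

`wormcnv` models one experimental design: pooled DNA from large, evolving
*C. elegans* populations is hybridized against an ancestral reference on
oligonucleotide CGH arrays, candidate copy-number variants (CNVs) are
re-quantified by qPCR and single-worm PCR across archived generations, and
population-genetic theory is used to ask whether the observed frequency
trajectories are compatible with genetic drift. This vignette explains
each model, its assumptions, and the numerical and design choices the
package makes where the procedure leaves latitude.

## The pooled-hybridization observation model

Arrays measure a per-probe log2 intensity ratio of test (pooled
population) DNA against reference DNA. Because the pool mixes carrier and
non-carrier chromosomes, a CNV segregating at per-haploid frequency $q$
changes the *population-average* copy number per haploid genome to
$c = 1 + q\,k$ for duplications carrying $k$ extra copies per carrier
haplotype (default $k = 1$) and $c = 1 - q$ for deletions. With a
single-copy reference the expected probe log2 ratio inside the CNV is
$\log_2 c$ and 0 outside. This is the unique observation model consistent
with converting segment means to average copy numbers via $c = 2^{\bar m}$
and frequencies via $q = c - 1$ (duplication) or $q = 1 - c$ (deletion).
Frequencies are clipped to $[0, 1]$: measurement noise can push $c$
slightly past 2, and a clipped value of 1 is read as fixation.

Assumptions worth keeping in mind: exactly one extra copy per carrier
haplotype (a higher-order amplification at lower frequency produces the
same mean ratio and is indistinguishable from pooled data alone — the
single-worm assay exists precisely to break that confound), no probe
sequence or GC bias, and independent Gaussian probe noise. A fixed
deletion has zero expected intensity, whose log2 ratio is $-\infty$;
probes in fully deleted segments are assigned a finite floor
(`del_floor = -8` by default) mirroring the finite background intensities
real scanners report.

## Segmentation and calling

`quantile_normalize()` replaces each profile's sorted values by the
across-profile mean order statistics (ties averaged; a single profile is
unchanged). The heavy lifting is delegated to
`limma::normalizeQuantiles()`.

`segment_profile()` is bottom-up agglomerative segmentation per
chromosome: every probe starts as a segment, and the adjacent pair with
the largest similarity p-value is merged until no neighboring pair
reaches the threshold, i.e. every remaining adjacent pair has
$p < p_\mathrm{merge}$. Choices the procedure leaves open, and what the
package does:

* **t-test flavor.** Welch's unequal-variance test on segment summary
  statistics. Segments holding fewer than 4 probes get a z test against a
  global robust noise scale instead:
  $\hat\sigma_0 = 1.4826 \cdot \mathrm{median}|\Delta x| / \sqrt 2$ from
  first differences of the chromosome's ratios. The fallback serves two
  purposes. It makes merging from single probes well-defined (a singleton
  has no variance), and it avoids a numerical pathology: a Welch test
  between a 2–3 probe segment and anything else has ~1–2 degrees of
  freedom, so its p-values are so weak that short runs of genuine signal
  at a CNV boundary merge indiscriminately and breakpoints drift by
  several probes.
* **Merge order.** Always the currently most similar adjacent pair
  (largest p), with neighbor similarities recomputed after each merge —
  the canonical agglomerative scheme. Ties in p (e.g. several exact-1
  values early on) break toward the leftmost pair via `which.max`.
* **Threshold default.** $p_\mathrm{merge} = 10^{-5}$. The thresholds are
  user-defined in this kind of pipeline (the original procedure chose
  them by visual inspection of the ratios; the package replaces that step
  with explicit configuration). The default was calibrated once on
  simulated noisy duplications — 50 internal probes, fixed duplication,
  probe noise sd 0.2 — so that the injected breakpoints are recovered
  within ±1 probe in at least 95% of seeded runs; looser thresholds
  (e.g. $10^{-3}$) leave residual interior splits on noisy profiles.
  Segment count is monotone non-increasing as the threshold decreases,
  because the greedy merge sequence does not depend on the threshold —
  only the stopping point does.

`classify_segments()` labels a segment amplified when its mean is at
least `m_min` (default 0.2 log2 units), a one-sample t test against 0
gives $p \le$ `p_class` (default $10^{-3}$), and it holds at least
`min_probes` probes (default 3); deleted is symmetric. Everything else is
neutral. Note a caveat: agglomeration groups similar values, which
deflates within-segment variance and makes classification p-values
anti-conservative on pure noise; the mean filter, not the p filter, is
what keeps the false-call rate low.

`cgh_calls()` reports the *inner* interval (first to last internal probe)
— the minimum extent of the CNV — and an *outer* interval extending to
just inside the adjacent flanking probes (or the chromosome ends),
because the true breakpoint must lie between an internal probe and its
flanking neighbor. On sparse grids that uncertainty can span tens of kb.

## qPCR quantification

Each run comprises four groups of unpaired technical replicates:
reference DNA with reference primers (R/R'), reference DNA with test
primers (R/T'), test DNA with reference primers (T/R') and test DNA with
test primers (T/T'). Group means on the Ct scale enter

$$\Delta\Delta C_t = (\overline{TT'} - \overline{TR'}) -
(\overline{RT'} - \overline{RR'}), \qquad
\text{ratio} = (1+E)^{-\Delta\Delta C_t},$$

with a single amplification efficiency $E$ estimated from the plate's
reference dilution series: $E = 10^{-1/b} - 1$ from the least-squares
slope $b$ of Ct on log10 concentration (perfect doubling: $b = -3.32$,
$E = 1$). Per-primer efficiencies are out of scope — only the reference
is calibrated. A positive or near-zero slope aborts with a
calibration-failure error; efficiencies marginally above 1 (noisy series)
are clipped at 1.1 with a warning.

Confidence intervals are percentile bootstrap, exactly as the protocol
describes: each of the (default 10,000) iterations resamples Ct values
with replacement *within* each of the four groups, preserving group
sizes; the bounds are the 2.5% and 97.5% quantiles of the resampled
ratios. Two properties follow from the arithmetic and are pinned by
tests: the ratio is invariant to adding a constant to all Cts, and
lowering only the T/T' group by one cycle multiplies the ratio by
$(1+E)$.

A known statistical limitation, demonstrated in the test suite: with the
typical 3 replicates per group the percentile bootstrap *undercovers* —
simulated coverage of the nominal 95% interval is ≈ 84%, rising to ≈ 94%
at 10–30 replicates per group. This is the textbook small-sample behavior
of the percentile method (the bootstrap distribution of a mean of 3
values is too narrow), not an implementation artifact; the package
reports the protocol's interval rather than substituting a different
interval type.

## Single-worm PCR frequencies

Only adult males are assayed (eggs carried by outcrossing females are
nonclonal, so a female lysate is not one genotype). For X-linked loci
males are hemizygous and the positive fraction estimates the frequency
directly: $\hat q = k/n$. For autosomal loci, under Hardy–Weinberg the
negative males are the homozygous non-carriers, frequency $(1-q)^2$, so
$\hat q = 1 - \sqrt{1 - k/n}$. Boundary counts need no special-casing
($k = 0 \Rightarrow \hat q = 0$, $k = n \Rightarrow \hat q = 1$), and no
continuity correction is applied — the published tables use the direct
arithmetic, which the package reproduces exactly at two decimals. The
average copy number per haploid follows as $\hat c = 1 + \hat q$
(duplication) or $1 - \hat q$ (deletion). Uncertainty is an exact
Clopper–Pearson interval on the carrier fraction mapped through the same
monotone transform. For identical counts the autosomal estimate never
exceeds the X-linked one ($1 - \sqrt{1-f} \le f$).

## Convergent CNVs

Parallel evolution is detected as same-chromosome, same-type calls from
independent populations overlapping a common region. In
`"intersection"` mode `overlap_clusters()` returns maximal sets of calls
whose common intersection is non-empty — for intervals these are exactly
the maximal cliques of the overlap graph, enumerated by sweeping interval
start points and discarding dominated point-cover sets. `"connected"`
mode returns components of the pairwise overlap graph instead. Types are
never mixed. The shared region of a cluster is
$[\max \text{starts}, \min \text{ends}]$ with inclusive length
$\mathrm{end} - \mathrm{start} + 1$; inclusive arithmetic is used
throughout because it is the convention under which every published span
and shared-region length in the packaged catalogs reproduces exactly
(exclusive arithmetic is off by one on all of them).

## Breakpoints and unequal crossing-over

Tandem duplications formed by unequal crossing-over between two flanking
repeats carry a chimeric repeat at their center. `percent_identity()` and
`informative_sites()` operate on the aligned repeat pair;
`infer_crossover_interval()` scores the chimera at each informative site
and localizes the crossover to the open interval between the last
downstream-matching site and the first upstream-matching site. Chimeras
that match neither repeat at a site, or that switch back (mosaic
patterns suggesting gene conversion or double crossover), abort with an
informative error rather than returning a misleading interval. Distinct
chimeras whose intervals fall in different inter-site gaps demonstrate
independent origins of the same duplication.

## Population genetics

* `fullsib_inbreeding()` iterates
  $F_t = (1 + 2F_{t-1} + F_{t-2})/4$ from $F_0 = F_{-1} = 0$; fifteen
  generations give $F = 0.961$. The recursion is validated against a
  gene-dropping pedigree simulation in the tests.
* `neutral_fixation_time()` returns $4N_e$, the diffusion expectation for
  the mean time to fixation of a new neutral mutation *conditional on
  fixation* — the relevant comparison when arguing that CNVs which fixed
  within ~200 generations in populations of $N_e \ge 1000$ were not
  drifting ($4N_e \ge 4000$).
* `mutation_input_frequency()` gives the frequency reachable by recurrent
  origin alone: $p_t = 1 - (1-\mu)^t$, e.g. ≈ 2% after 200 generations at
  $\mu = 10^{-4}$ per generation (a thousandfold the spontaneous per-gene
  duplication rate of order $10^{-7}$); with a loss rate $\delta$ the
  recursion $p \leftarrow p + \mu(1-p) - \delta p$ plateaus at
  $\mu/(\mu+\delta)$ instead of fixing.
* `simulate_wright_fisher()` uses binomial sampling of $2N_e$ allele
  copies with *genic* (haploid) selection, $p' = p(1+s)/(1+ps)$, applied
  after deterministic gain/loss. Diploid dominance is out of scope.
  Boundaries absorb only when $\mu = \delta = 0$.
  `neutral_trajectory_pvalue()` estimates
  $P(\text{freq} \ge q_{obs} \text{ at generation } t \mid s = 0)$ by
  Monte Carlo with a reported binomial standard error; the one-generation
  case is checked against the exact binomial tail.

## What the synthetic generator does and does not emulate

`simulate_acgh()` produces the pooled observation model above with i.i.d.
Gaussian probe noise; `simulate_qpcr()` inverts the ΔΔCt model at a
chosen efficiency with Gaussian Ct noise; `simulate_worm_sample()` draws
binomial male counts under the hemizygous/Hardy–Weinberg carrier model;
all generators are bit-reproducible under a fixed seed. Real arrays also
exhibit probe-sequence and GC bias, spatially correlated noise, dye bias
and cross-hybridization; real qPCR has between-plate effects and
per-primer efficiencies. None of these are modeled, so a passing
simulation-based test demonstrates correctness of the estimators under
the stated model, not robustness to every array artifact. The probe noise
default (`probe_sd = 0.25`) is a free parameter chosen as a realistic
magnitude for two-color arrays, not a measured value.

## Numerical choices and problem sizes

Degenerate inputs: zero-variance segment pairs with equal means merge
with $p = 1$; with unequal means they fall back to the robust-sd z test.
Empty chromosomes are skipped with a warning; probe positions must be
strictly increasing. Bootstrap quantiles use R's default interpolation
(type 7), so `conf_low <= estimate <= conf_high` holds up to quantile
interpolation on discrete resample distributions. The rank-sum test uses
midranks, the tie-corrected variance, a 0.5 continuity correction, and
reports the signed Z for the first sample; its one-sided p is the
continuity-corrected lower tail, which on continuous data agrees with the
exact permutation tail to within 0.05 down to very small samples (tied,
heavily discrete data is where the normal approximation degrades, and
there the implementation instead matches the tie-corrected normal
reference implementation exactly).

Test-suite problem sizes were chosen to make the statistical assertions
sharp but quick: 100-seed breakpoint-recovery batches on 200-probe
chromosomes, 500-replication bootstrap coverage runs, 200,000-replicate
Wright–Fisher absorption batches at $N_e = 50$ (vectorized over
replicates, a few seconds), and exhaustive permutation/enumeration
oracles at pooled $n \le 12$.

## Known limitations

Breakpoint resolution is bounded by probe spacing; copy numbers between
simple states (mosaic amplifications) are reported as fractional $c$
without further interpretation; the Hardy–Weinberg estimator cannot
separate duplication heterozygotes from homozygotes; convergence is
reported descriptively (no significance test — a null model for interval
re-use would need a breakpoint-process model the data do not constrain);
and the drift p-values condition on a known $N_e$, which in practice is a
conservative lower bound.
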