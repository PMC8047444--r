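---
title: "Models and methods behind naivexit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind naivexit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naivexit)
```

# The experimental design the package models

Mouse embryonic stem cells held in 2i medium occupy the naive pluripotent
state and exit it within roughly 24–32 hours of 2i withdrawal. The package
analyses three coupled data types around that transition: a haploid
transposon mutagenesis screen that nominates regulators of the exit, a
panel of knockout lines profiled by RNA-seq in 2i and at N24 (24 h after
release) alongside wild-type controls, and a wild-type time course sampled
every 2 h from 0 to 32 h that serves as the reference differentiation
axis. All stages below are exercised end-to-end on synthetic data whose
ground truth is planted by the generators in this package.

# Screen enrichment

Integration opportunities are TTAA tetranucleotides. For a gene with $n$
TTAA sites of which $k$ distinct sites carry integrations (pooled over
screens), the enrichment p-value is the exact binomial upper tail
$P(X \ge k)$ at the background rate $p_0$, computed through the stable
survival function so rates down to $10^{-6}$ and $n$ up to $10^4$ do not
underflow. $p_0$ is the fraction of all genic TTAA sites hit in at least
one screen, pooled across screens; a per-screen variant would estimate the
same quantity with more variance, and pooling matches how the hit
catalogue is actually accumulated.

Two candidate streams are combined: genes with at least 26 TTAA sites,
Benjamini–Hochberg-adjusted $p < 0.01$ and hits in at least two
independent screens (the 26-site floor exists because smaller genes reach
nominal significance with a single integration), and genes hit in five or
more screens regardless of the model. How the two streams combine into one
candidate list is a genuine design choice; the package takes the union and
reports both memberships so any other rule can be applied downstream.
Genes with zero insertions carry $p = 1$ and are excluded from the
adjustment by default. The adjustment method is configurable
(`screen_adjust`, BH or Bonferroni).

# The contrast engine

Per gene, log2 expression is regressed by ordinary least squares on group
membership plus batch (a fixed effect). Counts are first transformed to
$\log_2(\mathrm{CPM} + 0.5)$; median-of-ratios size factors are available
by configuration for time-course data. Significance is assessed against
the composite null $|\log_2 FC| < \log_2 1.5$ with a threshold t-test
($p = P(T \ge (|\hat\beta| - \theta)/se) + P(T \ge (|\hat\beta| +
\theta)/se)$ on the residual degrees of freedom), and BH adjustment runs
within each contrast. Interaction contrasts are the difference of the two
simple log2 fold changes with pooled standard error and summed degrees of
freedom — a deliberate convention, slightly conservative relative to a
joint fit.

The engine deliberately omits empirical-Bayes variance moderation: it is
transparent, dependency-light, and any externally computed contrast table
with the same columns can be plugged into every downstream stage. The test
suite cross-checks the fold changes and unmoderated standard errors
against limma's linear fit. Degenerate residual variance is floored at
$10^{-8}$ (logged) so statistics stay finite; batch perfectly confounded
with group, and unreplicated designs, are errors.

The differentiation phenotype score of a knockout is the arithmetic mean
log2 fold change of the seven core naive markers (Esrrb, Nanog, Tfcp2l1,
Tbx3, Prdm14, Klf4, Zfp42) in its N24 contrast; positive scores mean the
naive programme is still up, i.e. delayed differentiation.

# Naive-associated genes

A gene is naive-associated when its log2 fold-change pattern across the
knockout panel at N24 is well predicted by the seven marker patterns:
multiple $R^2$ from an OLS fit, called at $R^2 \ge 0.65$. The regression
includes an intercept — fold-change vectors are not mean-centred across
KOs, and an intercept-free $R^2$ would be inflated for genes with a
uniform offset. Collinear marker columns are handled by pivoted QR
(pseudo-inverse), so $R^2$ is well defined regardless; it is invariant
under any invertible affine recombination of the markers, which the suite
checks. Marker genes themselves are excluded from calls. With $p = 7$
predictors the null expectation of $R^2$ is roughly $7/(n_{KO}-1)$, so
the statistic is only meaningful for panels of a few dozen knockouts —
at 70 KOs the null sits near 0.1, far from the 0.65 cutoff.

Knockout similarity uses total-least-squares (first principal axis)
regression over genes significant in either knockout, which treats both
axes symmetrically; its slope is reciprocal-consistent by construction.

# Differentiation delay

Per-gene log2 fold changes relative to mean 2i expression are smoothed
over time by Gaussian-process regression with a squared-exponential
kernel; hyperparameters (length-scale bounded to [1, 32] h, signal and
noise amplitudes) maximise the marginal likelihood from a fixed set of
deterministic restarts, so smoothing is reproducible without a seed. One
numerical choice matters: a stationary kernel happily explains a sharp
switch-like transition as "noise", biasing the posterior mean at exactly
the inflection the delay mapper relies on. The noise amplitude is
therefore capped at twice the replicate-based standard error of the
time-point means — the noise term models measurement noise, and
measurement noise is estimable from replicates. With noise-free input the
cap drives the fit to interpolation, as it should. A smoothing-spline
alternative is available by configuration.

A knockout's N24-vs-2i profile is compared with the trajectory by
Euclidean distance at each time point, min–max normalised per knockout so
the best match scores 0 and the worst 1. After the coarse minimum (ties
break to the earliest time — the conservative, larger-delay reading), the
trajectory is linearly interpolated every 15 minutes between the two
neighbouring time points only, and the refined minimum is reported;
`delay_h = 24 − t_matched`, positive meaning delayed. Both the coarse and
refined times are returned. Delay estimates from the seven markers alone
are noisy for strongly delayed knockouts (their markers have barely moved,
so early times look alike); the broader differentiation gene set is the
more stable reference, and both are reported with their correlation.

# Pathway footprints and activity

A pathway footprint is the set of the 50 genes responding most
specifically to the pathway's defining perturbation: FDR ≤ 0.05 in the
defining contrast, absolute fold change at least twice the largest
absolute fold change in all remaining knockout contrasts (the stricter
all-others reading; the four-other-definers variant is a configuration
switch), and expression of at least 1 FPKM/CPM in knockout or control.
For Fgf/Erk, defined jointly by Fgfr1 and Ptpn11, every criterion applies
to the lower of the two fold changes and the reference sign is taken from
that weaker contrast. Genes qualifying for two pathways go to the one with
the larger specificity ratio (logged), keeping footprints disjoint.
Fewer than 50 qualifying genes is an error unless explicitly overridden.

Directed activity of knockout $K$ for a footprint with reference fold
changes $r_g$: $\mathrm{dFC}_g(K) = |\mathrm{lfc}_g(K)| \cdot s_g$ with
$s_g = +1$ if the knockout moves gene $g$ in the reference direction and
$-1$ otherwise; activity is $\sum_g \mathrm{dFC}_g(K) / \sum_g |r_g|$
times the pathway orientation (+1 for LIF and mTORC1, −1 for Fgf/Erk, Wnt
and Notch). Reading the fold change as magnitude-times-agreement-sign
guarantees the denominator is positive and the defining knockout scores
exactly ±1. A knockout fold change of exactly 0 contributes 0 either way
and is assigned $s = +1$ by convention. Spearman correlation (Pearson by
option) over the 50 genes, a Fisher-Z p-value at $n = 50$, and Bonferroni
adjustment across all knockout × pathway tests accompany the score. The
phenotype regression is OLS of the naive-marker score on the five
correlation profiles with intercept, reporting coefficients and standard
errors.

# Response modules, clustering and enrichment

N24-induced response genes are significant (FDR ≤ 0.05) at N24 and in the
knockout × condition interaction in at least one knockout — the same
knockout must satisfy both, the stricter reading of "in at least one
knockout condition". Constitutive response genes are significant in the
same direction in both 2i and N24 in at least one knockout, minus the
induced set (induced takes precedence). Three globally acting knockouts
(Eed, Suz12, Csnk1a1) are excluded by default.

Modules come from Ward-linkage (`ward.D2`) hierarchical clustering of the
KO-vs-control N24 fold-change rows. The number of clusters defaults to 12
per group; the automated alternative (`k = NA`) takes the elbow — the
maximum second difference of total within-cluster variance over
k = 2..25 — and both are reported.

Gene-set enrichment is a one-sided Fisher exact (hypergeometric) test
against annotation sets restricted to 5–500 genes within the universe
(for module enrichment, at least five module genes in the set). Terms
whose genes-of-interest memberships differ by five or fewer genes are
merged by complete linkage on the L1 distance of the binary membership
matrix — distances use target members only, not full annotations; the
smallest term by total annotation becomes the primary term independent of
its p-value, and BH adjustment runs over primary terms only. One caveat
this package makes explicit: under a random target, terms with unusual
overlap tend to isolate into their own merge groups, so primary-term
p-values are mildly selection-biased when most terms are near-duplicates
of each other; calibration holds when terms are distinct at the merge
distance.

# Pathway-to-module wiring

Cluster mean fold changes across knockouts are regressed on the five
pathway activities (intercept included); coefficient p-values are
BH-adjusted jointly across all cluster × pathway coefficients and links
with adjusted p > 0.01 are pruned. Surviving links face two temporal
tests against the wild-type time course. Pathway activity along the time
course is, per footprint gene, the log2 fold change relative to that
gene's time-course mean, multiplied by the sign of its defining-contrast
fold change before averaging — without that orientation a bidirectional
footprint would cancel itself — then by the pathway orientation; the
unoriented variant remains available. The predicted cluster trajectory
(pruned-model betas applied to the activity trajectories) must correlate
with the observed cluster trajectory at Pearson r ≥ 0.5 (trend test), and
the lag maximising their cross-correlation over ±8 h in 0.5 h steps must
be non-negative, i.e. pathway activity leads or is simultaneous at the
2 h sampling resolution (precedence test). The thresholds are
configuration keys; the two criteria themselves are structural.
Validation only removes links, never adds them, and each removal carries
a reason (`nonsignificant`, `trend_mismatch`, `no_precedence`).

# Embryo comparison

Fraction of identity solves $\min \|S f - b\|_2$ subject to $f \ge 0$,
$\sum f = 1$ over genes expressed in the sample (log2 FPKM > 0, at least
100 shared genes). Because reference panels hold only a handful of
stages, the solver enumerates all support sets and solves the
equality-constrained KKT system exactly on each — exact to machine
precision, verified in the suite against a brute-force simplex grid.
Variable genes come from a loess trend of squared coefficient of
variation on mean log2 expression with free axis thresholds (the
thresholds are data-set specific and deliberately unset by default). The
PCA is fitted on reference profiles, centred on reference gene means;
panel samples are centred with those same means, making the projection a
true out-of-sample embedding, and loadings are sign-fixed (largest
magnitude positive). Co-regulation between two responses counts genes
moving beyond |log2FC| > 0.1 in both, requiring sign agreement by default
(`signed = FALSE` restores the pure magnitude definition), against the
independence expectation by a chi-square goodness-of-fit test, plus
Spearman rho and the total-least-squares slope and angle.

# The synthetic-data generators

`simulate_timecourse` draws per-gene four-parameter logistic trajectories
(floor, amplitude, inflection at 8–20 h, slope 0.3–0.8 per hour): naive
genes fall 2–4 log2 units, formative genes rise, bystanders stay flat;
log2-scale Gaussian noise (default sd 0.2) is added per replicate. The
first seven genes are the named naive markers. `simulate_ko_panel`
snapshots the noise-free trajectory at $24 - \mathrm{delay}$ h per
knockout, adds per-batch gene offsets (sd 0.1, knockouts assigned to
batches round-robin with wild-type controls in every batch), small
KO-specific 2i offsets (sd 0.05) and sample noise. Pathway blocks are
flat genes shifted by reference fold changes scaled by each knockout's
planted activity; the defining knockout has activity 1. The
naive-associated block plants, per gene, a linear combination of the
marker fold-change vectors (coefficient directions drawn standard normal)
with the signal normalised to unit standard deviation and the noise
variance set so the target $R^2$ refers to the data as analysed — the
fold-change measurement variance the contrast engine will add
($2\sigma^2/n_{rep}$) is part of the noise budget. Without those two
choices the "target" $R^2$ would silently drift with each gene's signal
scale, and planted effects would not be recoverable at the stated rates.

`simulate_ttaa` draws TTAA counts from a shifted negative binomial
(minimum 4, mean ≈ 56, size 2), roughly matching the spread of
integration opportunities across genes of different lengths.
`simulate_insertions` hits every site independently at
$p_0 \times$ multiplier per screen; defaults are $p_0 = 5 \times 10^{-4}$
and 10 screens. `simulate_wiring` builds sparse pathway-to-cluster
diagrams: per-KO activities standard normal, cluster responses as the
wired linear combination plus noise (sd 0.05), and time-course curves in
which each pathway's logistic ramp precedes its clusters by a planted
lag.

What the generators do not emulate: count-level sampling (a Poisson mode
exists but log2 output is the default), gene length and GC biases,
correlated noise between genes beyond the planted structure, single-cell
heterogeneity, and insertion biases beyond the TTAA opportunity model.
Passing the recovery tests therefore demonstrates that the estimators
invert the generative assumptions they state — not that those assumptions
exhaust real data.

# Problem sizes and noise conditions used in the checks

The recovery suite runs at the design scale of the study it models where
that matters statistically, and small elsewhere: the null calibration of
the screen test uses 10,000 genes at $p_0 = 0.008$ over 20 screens (a
rate dense enough that the discrete p-values populate the [0, 0.05]
interval); planted enrichment uses 10 genes at 50-fold rate among 2,000
nulls, planted in screen-testable genes (≥ 26 TTAA sites — an effect in a
5-site gene is invisible to the assay by design); NAG recovery uses 70
knockouts with 150 coupled (target $R^2 = 0.8$) and 150 independent
genes; delay recovery maps noise-free snapshots at 6, 12, 17.4 and 24 h
and noisy ones (sd 0.05, 50 reference genes) over 20 replicate draws;
wiring recovery pools 10 replicate three-pathway, four-cluster diagrams
with 4 h lags at 70 knockouts.

# Known limitations

The contrast engine is not a limma replacement: without variance
moderation its power at two or three replicates is lower, and reproducing
the original analyses' exact differentially-expressed-gene counts is out
of scope (external contrast tables can be injected instead). Marker-based
delay estimates saturate for knockouts delayed beyond the markers' own
inflection times. The simplex deconvolution solver enumerates supports
and is limited to 12 reference stages. The enrichment redundancy rule is
selection-biased under dense term overlap, as noted above. Gene
identifiers are treated as opaque strings throughout; mapping between
annotation vocabularies (or species, via a 1-to-1 orthologue table) is
the caller's responsibility.
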