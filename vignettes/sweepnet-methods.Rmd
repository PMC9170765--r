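---
title: "SweepNet methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SweepNet methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

SweepNet implements three analysis arms around one recurring study design:
a small, phenotypically distinct case population (tens of individuals)
contrasted with a larger, heterogeneous control panel, genotyped genome-wide
and profiled by bulk RNA-seq in a small embryonic time course. The motivating
application is the genetics of rumplessness (absence of the pygostyle, caudal
vertebrae, uropygial gland and tail feathers) in a local chicken breed, with
roughly 20 cases against roughly 98 controls on the genomic side and 9 case
versus 12 control embryos (three development days, two control breeds,
several sequencing lanes) on the transcriptomic side. Everything below is
written so that each stage can be validated at desk scale against planted
ground truth from the package's own simulators.

# Selection scan

## Per-site statistics

For a biallelic site with $m$ called alleles and alternate-allele count $a$
(frequency $\hat p = a/m$), nucleotide diversity uses the unbiased per-site
heterozygosity

$$\pi_{\text{site}} = \frac{m}{m-1}\, 2 \hat p (1 - \hat p),$$

which equals the mean number of differences over all $\binom{m}{2}$ pairs of
sampled alleles. Sites with $m < 2$ in a population are excluded from that
population's sums rather than raising an error.

For differentiation, the default is Hudson's two-population estimator in
numerator/denominator form,

$$N = (\hat p_1 - \hat p_2)^2 - \frac{\hat p_1(1-\hat p_1)}{m_1 - 1}
      - \frac{\hat p_2(1-\hat p_2)}{m_2 - 1}, \qquad
  D = \hat p_1(1-\hat p_2) + \hat p_2(1-\hat p_1),$$

with the Weir–Cockerham (1984) variance components available by flag
(`estimator = "wc84"`). Hudson's form was chosen as the default because it
has a clean closed form, behaves well for two-population scans with very
different sample sizes, and its windowed ratio-of-sums aggregation is the
standard variance-reducing choice. Per-site ratios may be negative and are
not clamped.

## Windows

Windows are 40 kb stepped every 20 kb, anchored at position 0 of each
chromosome, in 0-based half-open coordinates: a site at 1-based position $P$
belongs to window $[s, s + 40000)$ iff $P - 1$ lies in it. Window FST is
$\sum N / \sum D$ over the window's usable sites; window $\pi$ is the sum of
per-site $\pi$ divided by the window width in bp (not by the variant or
callable site count — the common genome-scan convention, so sparse windows
are not inflated); $\Delta\pi = \pi_{\text{control}} - \pi_{\text{case}}$
exactly, so positive values flag diversity loss in cases. Windows with fewer
than `minSites` (default 10) usable sites are dropped. When chromosome
lengths are supplied, a terminal truncated window is kept with its true
width as the per-bp denominator if it is at least half a window long, and
dropped otherwise; without lengths, all windows use the nominal width.

## Candidates, recovery ratio, differentiated sites

The top sets are the upper 1% of windows by FST and by $\Delta\pi$,
computed by the nearest-rank rule (threshold = value at descending rank
$\lceil qn \rceil$); ties at the threshold are included. Candidates are the
intersection of the two top sets.

The recovery ratio guards against candidates that depend on the
composition of the heterogeneous control panel: each of `nReplicates`
(default 1000) replicates redraws 20 controls without replacement, rescans,
and re-derives the top sets. `rr_fst` and `rr_dpi` are the fractions of
replicates in which a candidate re-enters the respective top set, and
`rr_joint` the fraction for the intersection. The selection rule defaults to
requiring both per-statistic ratios $\ge 0.95$; the joint rule is available
by flag. We default to the per-statistic rule because the joint recovery is
necessarily the smaller number and the two per-statistic ratios are the
quantities one inspects per candidate; both are always reported.

The genotype-frequency (GF) filter flags individual SNPs/indels: a site is
eligible iff called in at least 16 of 20 cases ("more than 15") and at
least 51 of 98 controls ("more than 50"); it passes iff, additionally, its
altered-allele ratio is strictly above 0.8 in cases and strictly below 0.06
in controls. The ratio is interpreted as the alternate-*allele* frequency
among called alleles, $(\mathrm{het} + 2\,\mathrm{homAlt})/(2\,n_{\text{called}})$;
a carrier-frequency reading (fraction of individuals with at least one
alternate allele) is available via `ratio = "carrier"` since the phrase is
genuinely ambiguous. SNPs and indels are treated identically and reported
with their type.

# Genotype simulator

Sites are placed as a Poisson process (realized as a Poisson count of
uniform distinct positions). Each site draws an ancestral frequency
$p_0 \sim U(0.05, 0.95)$ and per-population frequencies from the
Balding–Nichols distribution
$\mathrm{Beta}\!\left(p_0 \frac{1-F}{F},\, (1-p_0)\frac{1-F}{F}\right)$
with $F$ = `backgroundFst`. Balding–Nichols was chosen because it gives a
tunable expected differentiation with a closed generative form, so the
simulator itself can be checked against a brute-force re-draw oracle.
Sweeps are modeled as a displacement of the case frequency by `sweepShift`
toward the nearer of $\{0, 1\}$ (truncated) inside the sweep regions —
enough to create the rank signal the scan detects, without coalescent
machinery. Planted highly differentiated sites are made to pass the GF
filter by construction (case frequency 1, control 0 before missingness), so
the filter invariant holds deterministically at zero missingness. Indels
are a site-type flag only. Genotypes are $\mathrm{Binomial}(2, p)$ with
i.i.d. missingness.

Defaults encode the study conditions: 20 cases, 98 controls, one 10.02-Mb
chromosome at 0.005 sites/bp (about 50,000 sites, 501 windows), background
$F = 0.05$, five 40-kb sweep regions aligned to the window grid with
`sweepShift = 0.6`, 50 planted differentiated sites. The truth records the
windows fully contained in a sweep region: windows half-overlapping a sweep
carry a diluted signal and are deliberately not part of the truth set.

The simulator does **not** emulate linkage disequilibrium, demographic
history, or allele sharing between neighboring sites; passing tests
therefore show that the estimators and the selection/validation logic are
correct under the assumed frequency model, not that the scan is robust to
LD-induced autocorrelation in real genomes.

# Expression arm

## Normalization and adjustment

FPKM is $c \cdot 10^9 / (L \cdot N)$ for counts $c$, gene length $L$ and
library size $N$ (per-sample mapped totals, defaulting to column sums). The
expressed-gene filter requires, per supporting sample, union-model counts
$\ge 10$ *and* whole-gene-model counts $\ge 10$ *and* FPKM $> 0$, and
retains a gene iff the supporting samples cover at least 80% of the case
*or* 80% of the control group (fractional comparison, e.g. 8/9 case
samples qualifies).

Normalized values are $\log_2(\mathrm{FPKM} + 1)$; the offset 1 keeps zero
FPKM at zero and is configurable. The optional GC/length correction fits,
per sample, a robust (Huber) regression of the values on GC fraction and
log length and subtracts the centred fit, so systematic trends are removed
while each sample's mean is preserved exactly. This is a transparent
surrogate in the spirit of conditional quantile normalization, not a
re-implementation of its spline/quantile machinery.

Covariate removal fits, per gene, OLS of the normalized values on the
encoded covariates with intercept and subtracts the covariate terms,
keeping intercept plus residual; the operation is idempotent because
residuals are orthogonal to the covariates. The encoding is: development
day as the numeric codes 1, 2, 3; sequencing lane one-hot with the first
level as reference; and breed as *control-subtype* indicators with the case
breed and first control breed at reference. The last choice matters: in
this design breed is perfectly confounded with case/control, so naive
breed dummies would absorb the group contrast and the group coefficient
would be unestimable. Encoding only the control-subtype differences removes
what is removable and leaves the confounded component in the group effect,
where it belongs. The group label itself is never among the adjustment
covariates.

## DEG calling

The linear-model test regresses each gene's normalized values on
(intercept, case indicator, covariates); p-values are classical two-sided
t-tests on the group coefficient (matrix fit via `limma::lmFit`, ordinary
— not moderated — statistics), and q-values are Benjamini–Hochberg,
the standard choice where only "FDR" is specified. A gene is a DEG at
q < 0.05. Fold changes are computed on the FPKM scale as
(higher group mean + 0.01)/(lower group mean + 0.01), reported with the
higher group's label; the pseudo-count keeps genes that are almost
undetectable in one group from producing infinite ratios. A per-gene Welch
t-test is provided as a second, model-free caller, and external DEG lists
(e.g. from count-model tools) can be supplied as gene-id vectors; the final
set is the intersection across methods, with per-set sizes and pairwise
overlap counts reported.

## Expression simulator

Counts are negative binomial around per-gene log2 means composed of: a
Normal baseline (default mean 5, sd 1.5 — from a few to a few hundred
counts); an alternating-sign group effect of `deLog2fc` for planted DE
genes; per-gene day slopes and per-gene control-breed and lane offsets; a
per-sample depth offset; and per-module latent factors. Whole-gene-model
counts add independent Poisson "intronic" reads to the union-model counts,
so the nesting inequality holds by construction. Gene length is
LogUniform(200, $10^5$) bp and GC Uniform(0.3, 0.7).

Three generator choices deserve their rationale:

* **Covariate effects are per gene and the case breed sits at reference.**
  A breed offset shared by all genes and applied to the (single-breed) case
  group would be statistically indistinguishable from a global group
  effect: it would break null calibration of the DEG test and install a
  giant spurious co-expression module. The confounded component of breed
  is therefore part of the group-effect parameter by definition, and the
  breed parameter generates control-subtype differences only — exactly the
  component the covariate encoding can remove.
* **Library sizes model whole-transcriptome depth.** The simulated genes
  stand for a few percent of a real library, so per-sample totals are
  proportional to a depth factor rather than to the column sums of the
  simulated subset. Column-sum library sizes would let the planted modules
  and DE genes drive FPKM denominators, coupling all genes through a
  compositional common factor that no covariate represents.
* **Planted module genes are floored at baseline mean + 1.5 log2 units.**
  Co-expression planted on genes dominated by counting shot noise, or
  removed wholesale by the expressed-gene filter when the shared factor
  swings low, would leave a truth table that does not describe the emitted
  data. Well-expressed module genes match how co-expression hubs look in
  real data.

The expression simulator does not model gene–gene correlation beyond the
planted modules, length/GC biases coupled to the design, or count
overdispersion heterogeneity; null-calibration results therefore speak to
the test's behavior under exchangeable NB noise, not under arbitrary real
data pathologies.

# Co-expression network

The network is signed: $a_{ij} = ((1 + \mathrm{cor}_{ij})/2)^\beta$ with
Pearson correlation throughout and default power $\beta = 12$, the
conventional signed-network default, which can also be selected as the
first power whose scale-free topology fit exceeds $R^2 = 0.8$. The fit
bins $\log_{10} k$ into 10 equal-width bins (empty bins dropped) and
regresses log frequency on log mean connectivity. Topological overlap is

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
  {\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{j \ne i} a_{ij},$$

with unit diagonal.

Modules come from average-linkage hierarchical clustering of
$1 - \mathrm{TOM}$ with a **static** cut (default height 0.95); clusters
of at least 30 genes become modules `M1`, `M2`, … by decreasing size and
everything else is `M0`. A dynamic tree cut was deliberately replaced by
this deterministic simplification; correctness is defined by
planted-module recovery, not by matching any particular tree-cut
implementation gene-for-gene. A cut at a *quantile* of the merge heights
was considered and rejected: any quantile-based cut always leaves a few
clusters regardless of input, so pure noise would be guaranteed to yield a
"module" of half the genes. An absolute height just below the noise floor
(TOM dissimilarity of uncorrelated genes is very close to 1) cuts noise
into singletons while leaving genuine blocks intact.

After merging (iteratively joining the module pair with the most
correlated eigengenes while that correlation exceeds 0.75, ties toward
smaller indices, eigengenes recomputed after each merge), members whose
module membership $|kME| < 0.5$ are moved to `M0` and modules that fall
below the minimum size dissolve. This pruning plays the role of the
"partitioning around medoids" stage of dynamic tree cutting: with ~21
samples, chance correlations reach ±0.4, and a static cut alone lets such
genes ride along with a strong module. The threshold 0.5 sits well above
the chance level ($\approx 2/\sqrt{n}$) and well below genuine member
membership (≈ 0.9 in the planted regime).

The module eigengene is the first principal component of the module's
standardized gene × sample submatrix, unit norm, sign-oriented to
correlate nonnegatively with the module mean profile. Module–trait
association is the Pearson correlation of each eigengene with the binary
trait (case = 1, control = 0), with $t = r\sqrt{(n-2)/(1-r^2)}$ on $n - 2$
df, significant at p < 0.05. Hub genes are module members with gene
significance $|GS| > 0.2$ and $|kME| > 0.8$ (strict bounds), ranked by
intramodular connectivity (adjacency sums within the module — computed
from adjacency, not TOM, the standard definition), and the edge export
writes all pairs among each module's top 50 hubs with TOM > 0.1 as a
three-column TSV loadable by standard network tools.

# Numerical and reproducibility choices

* All randomness flows from explicit integer seeds; resampling replicate
  $r$ uses a deterministic child seed derived from (seed, $r$), so any
  replicate is reproducible in isolation and results do not depend on
  execution order. Identical seeds give byte-identical TSV outputs.
* Quantile thresholds use the nearest-rank rule with ties included;
  ranking ties in hub tables break by gene id; merge ties break toward
  smaller module indices.
* Degenerate inputs are handled explicitly: sites with fewer than two
  called alleles are excluded from sums; zero-variance genes are dropped
  from eigengene computation; an all-equal connectivity vector reports a
  scale-free fit of 0 with a warning; an empty window list yields an empty
  candidate set.
* Validation problem sizes (chosen to make the full suite run in minutes
  on one core): one 10-Mb chromosome with ~50,000 sites for the scan
  experiments, 200 control-resampling replicates, 2000-gene expression
  simulations, and 300-gene network simulations with three 50-gene
  modules. The same code paths scale to genome-sized inputs since all
  per-site work is vectorized.

# Known limitations

* The scan assumes biallelic sites; multiallelic records are dropped (with
  a count), not split, on VCF input.
* No LD modeling in the simulator means recovery-ratio behavior under
  autocorrelated windows is untested here.
* The GC/length correction is a per-sample robust linear fit; strongly
  nonlinear GC effects would need the full quantile-based machinery this
  package intentionally does not reproduce.
* The static cut plus kME pruning recovers well-separated modules; deeply
  nested module structure (modules within modules) is out of scope.
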