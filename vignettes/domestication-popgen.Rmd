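---
title: "Diagnosing a domestication bottleneck: models and methods"
author: "oryzapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing a domestication bottleneck: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

oryzapop implements the population-genomic toolkit used to dissect a crop
domestication event from resequencing data — the African rice system, where
a selfing domesticate (*Oryza glaberrima*) was founded from a structured
wild progenitor (*O. barthii*) roughly three thousand generations ago.
This vignette explains the models behind each module, the defaults and why
they were chosen, what the synthetic-data generator does and does not
emulate, and the numerical conventions a user should know about.

## The synthetic history

Because the original accession panels are not shipped with the package,
every downstream analysis is exercised against a generator
(`simulateHistory()`) whose output has the same statistical anatomy as the
real system. The engine is an event-driven structured coalescent over
piecewise-constant epochs, run independently on non-recombining blocks
(`blockBp`, default 25 kb); blocks are in free recombination with each
other. Mutations follow the infinite-sites model within a block.

The demographic template, going backward in time:

* **Present** — 4 wild demes and 5 domesticate demes, each a 1-D
  stepping-stone chain. Wild demes split the ancestral size `ne`
  (default 1e5 diploids) equally and exchange migrants at
  `migrationWild = 2.5e-6` per generation (4Nm near 0.5: strong,
  geography-preserving structure). Domesticate demes share the expanded
  present size `recoveredNe = 2e6` and mix at `migrationDom = 2e-3`
  (human-mediated seed exchange; the crop demes homogenize on the
  domestication timescale).
* **Recovery** — the domesticate size declines exponentially backward from
  `recoveredNe` to `bottleneckSeverity * ne` at `bottleneckTime`
  (3,000 generations; the species is an annual, so generations are years),
  discretized into six constant steps.
* **Founding pinch** — every domesticate lineage passes through a single
  founding population of `bottleneckSeverity * ne` (default 3e-4, ~30
  plants) for `bottleneckDuration = 100` generations, then joins the first
  wild deme. The pinch guarantees near-complete coalescence at the
  founding: the domesticate genealogy is close to a star, which is what
  gives the strongly negative Tajima's D and the excess of rare variants
  that characterize expansion after a severe bottleneck.
* **Deep history** — wild demes merge into a panmictic ancestor at
  `wildSplitTime = 5e4` generations.

Selfing (rate 0.95, giving inbreeding F = s/(2−s) ≈ 0.90, consistent with
the species' few-percent observed heterozygosity) enters twice: all sizes
are rescaled by 1/(1+F), and with probability F an individual's two
haplotypes are the same coalescent lineage, producing the excess
homozygosity directly.

Two choices deserve emphasis:

* The founding pinch and the large recovered size were chosen so that the
  domesticate sits unambiguously in the expansion-after-bottleneck regime
  (domesticate D < 0 < wild D). The price at desk scale is a π_w/π_c
  ratio in the tens — far above the published real-data value near 2 —
  because a single-founder star genealogy retains almost no standing
  variation. The pipeline's directional diagnostics are unaffected; users
  wanting milder regimes can raise `bottleneckSeverity`.
* Planted hard sweeps are imposed post hoc rather than simulated forward:
  inside a decay window (default ±25 kb) the target population is
  resampled so each flank carries only the beneficial haplotype or a
  single early recombinant lineage (escape probability 0.15 per
  individual per flank, independently on the two flanks). This produces
  exactly the footprint the ω statistic is built to detect — strong LD
  within each flank, none across the sweep centre — without
  forward-simulation cost.

Local introgression (`introgression =`) copies one donor haplotype from a
source deme into both haplotypes of every recipient individual across a
tract, emulating a selfing lineage fixed for a wild segment. The truth log
records sweep positions, subpopulation labels, ancestral/derived alleles,
the outgroup allele (mutated on the outgroup branch with probability
`outgroupDivergence = 0.03`, the divergence of a usable outgroup), the
functional class of every variant (70% noncoding / 25% synonymous /
5% nonsynonymous, replacing an effect predictor), and the full phased
haplotypes.

What the generator does **not** emulate: intra-block recombination (LD is
block-uniform rather than smoothly decaying, so neutral block boundaries
carry some ω signal of their own); sequencing error and allele-dropout
structure in the call annotations (DP/QD/MQ/... are drawn from plausible
but arbitrary distributions, so the filter presets are exercised
mechanically, not calibrated); gene conversion; and any phenotype or
selection model beyond the imposed sweep footprint. Passing tests
therefore validate the statistics and their bookkeeping, not the
biological realism of any particular parameter value.

## Diversity and neutrality statistics

Per-site diversity uses the unbiased pairwise form
π = 2x(1−x)·m/(m−1), with x the alternate-allele frequency among the
m = 2·(called samples) haplotypes; a heterozygote contributes one copy of
each allele, so no phasing is needed. Summing over sites and dividing by
window width (not covered sites) gives windowed π; windows anchor at
position 1, are 1-based inclusive, and the truncated terminal window is
kept. Watterson's estimator is θ_W = S/a₁; Tajima's D uses the 1989
variance constants, with the haplotype count fixed at 2·(samples) (at the
default 2% missingness the bias is negligible; at higher missingness
supply `n` explicitly). D is undefined (NA) in windows without segregating
sites.

`kruskalCompare()` wraps the base rank test (chi-square with 1 df) with an
explicit all-tied guard. The genome-wide π ratio is the ratio of sums, so
windows with π_c = 0 are reported NA rather than infinite.

## Polarization and the unfolded spectrum

`polarize()` consumes an outgroup map table (the simulator emits it
directly; a whole-genome aligner would produce it for real data). A
variant is polarizable iff no alignment flag is set (unaligned / gap
within 5 bp / multi-mapped) and the outgroup allele matches one of the two
observed alleles; the mismatch case is kept as its own discard class for
auditability, and the tally always partitions the input. The neutral
expectation for the unfolded spectrum is θ̂_W/i at derived count i, which
sums to S by construction. The two-sample Kolmogorov-Smirnov comparison
uses the asymptotic formula with effective size n₁n₂/(n₁+n₂) on the binned
ECDFs; fixed-derived sites are retained because the reported
high-frequency classes (> 0.95, > 0.99, and the (0.7, 1] interval —
reported independently, not as a partition) include them. Expected spectra
are computed per population sample size, not pooled.

## The ω sweep scan

Pairwise LD is r² = D²/(p₁p₂q₁q₂) from haplotype frequencies when phased
input is available, and the genotype-correlation surrogate cor(gᵢ,gⱼ)²
otherwise (the mode is recorded on the result). At every grid position
(default spacing 10 kb) the scan takes up to `maxSites = 200` nearest
segregating sites within ±`maxWindowBp` (default 100 kb, the scale at
which LD approaches baseline in highly selfing rice), computes the r²
matrix once, and maximizes ω over all splits with at least two sites on
each side, using cumulative pair sums (O(W²) per position). A zero
cross-term makes the ratio undefined; it is reported capped at 1e6 and
flagged. Outlier calling flags the top 0.5% (the `ceiling(qn)`-th largest
value; threshold ties are all flagged), and `featureProximity()` joins
outliers to features strictly closer than 25 kb that contain at least one
variant of a requested impact class.

## Structure, kinship, geography

LD pruning follows the sliding-window greedy rule (r² > 0.25 in 500-SNP
windows stepping by 50), iterated to a fixpoint so re-application never
removes more SNPs. PCA centres per variant and imputes missing genotypes
to the variant mean (deterministic); PC-geography association uses the
closed-form t-test on Pearson r with n−2 df. Ancestry assignment is the
strict majority rule (> 0.5) on a consumed Q matrix — ancestry estimation
itself is out of scope.

F_ST implements the printed Wright variance form σ²_S/(p(1−p)) as primary
(between-group variance weighted by haplotype counts; genome-wide value as
ratio of sums), with the full Weir-Cockerham (1984) theta available as
`method = "weir_cockerham"` for comparison. Kinship is the within-pair
KING-robust estimator φ = (N_het,het − 2N_opp)/(N_het(i)+N_het(j)), chosen
over the population-frequency form because it is applied across
heterogeneous populations; φ(i,i) = 0.5 exactly. Distances use the
Haversine formula on a sphere of radius 6,378 km; cline splits assign
boundary samples (exactly 11°N or 6°W) to the north/east groups (declared
convention); balanced subsampling draws n = 15 per group uniformly with a
fixed seed, or deterministically by descending coverage when requested.
IBD regression excludes pairs whose *distance* (not kinship) falls outside
the 1.5×IQR fences — two-sided by default, with a one-sided upper-fence
option — then fits ordinary least squares of φ on km.

## Trees and gene haplotypes

The whole-genome distance between two samples evaluates, per shared called
site, the best alignment of the two unordered diploid genotypes
(1 − ½·max(δ_ac+δ_bd, δ_ad+δ_bc), equal to |g₁−g₂|/2 for biallelic
codes), averaged over the L co-called sites. Trees are Saitou-Nei NJ
(BioNJ optional) via ape; additive matrices are recovered exactly, and
negative branch estimates are clamped to zero with a count.

Gene haplotypes use intervals extended by 5 kb flanks. The phasing rule is
deliberately naive and deterministic: missing genotypes are first imputed
to the modal genotype within the sample's own subpopulation (a phasing
model would use LD context; the population mode is the honest desk-scale
stand-in, and it preserves subpopulation-private haplotypes that a global
mode would corrupt), then homozygous sites feed both haplotypes and
heterozygous sites put the reference on haplotype 1. At the study species'
~5% heterozygosity the distortion is bounded, and it is measured against
the simulator's true haplotypes in the tests. Groups are exact string
matches, ranked by count (summing to two per sample); gene trees are NJ on
p-distance with pairwise deletion of ambiguous positions.

The segregating-haplotype rule formalizes a judgement the original
analysis made by eye. Among the five most common haplotypes of a gene, a
group is flagged iff (i) all its domesticated members come from a single
subpopulation, (ii) none of them lie inside the gene tree's major
domesticated clade — defined as the smallest bipartition side containing
at least half of the domesticated leaves (an earlier Youden-index variant
was discarded because it absorbs introgressed clusters that drag few wild
leaves with them), and (iii) the group's nearest wild neighbour in the
gene tree belongs to a different wild subpopulation than the genome tree's
wild sister group (the wild subpopulation with the smallest mean
cophenetic distance to the domesticated leaves). All three parts are
deterministic; the 50% threshold and topN = 5 are configurable.

## Problem sizes and calibration checks

The test suite and the acceptance script run everything at desk scale,
chosen as the package's own working sizes: neutral calibration uses 20
replicates of 50 diploids over 500 kb with θ tuned to ~5,000 SNPs (mean
genome-wide Tajima's D within ±0.15 of zero); the bottleneck sign pattern
(domesticate D < 0 < wild D, π_w/π_c > 1) and the introgression detector
are checked over 20 replicates each; sweep localization uses 20 replicates
of a 400 kb chromosome with one planted sweep in the diverse wild
background (the post-pinch domesticate carries too little flanking
polymorphism for an LD-based scan — itself a faithful property of extreme
bottlenecks); the spectrum calibration uses 2 kb blocks so that sites are
close to independent, as the Kolmogorov-Smirnov test assumes. Every
statistic with a closed form is additionally checked against an
independent brute-force implementation at 1e-12 tolerance.

## Known limitations

* Block-uniform LD means ω has elevated neutral background at block
  boundaries; detection margins are therefore validated empirically
  rather than assumed.
* The KING-robust denominator is small in highly selfed samples (few
  heterozygotes), so individual φ estimates are noisy; IBD conclusions
  rest on regressions over many pairs.
* Filter presets ("full", "strict") are starting points to be tuned with
  `tstvProfile()`; the true thresholds of any given call set depend on its
  error profile, which the generator does not model.
* Tajima's D uses a single haplotype count for a window; under heavy,
  non-uniform missingness, supply `n` or filter first.
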