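---
title: "Methods: low-coverage hybrid-cross linkage mapping and scaffold anchoring"
author: "linkscaf developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-coverage hybrid-cross linkage mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experimental design the package assumes

Conventional linkage analysis needs ~10x coverage per individual just to call
heterozygous genotypes, which makes whole-genome genotyping of hundreds of
offspring prohibitively expensive. The design `linkscaf` serves sidesteps the
problem: offspring are F1 hybrids of two species (or sufficiently divergent
lines, ~98% identity) whose reads can be attributed unambiguously to one
parental genome. At any site where the focal parent is heterozygous, a
*single* attributed read identifies which of that parent's two haplotypes the
offspring inherited. Each parent can therefore be mapped independently, as if
its offspring were a panel of double haploids, from ~1-2x coverage per
individual. Because whole-genome SNPs are used rather than restriction-site
or array markers, marker density (~1 per kb) far exceeds crossover density,
and map resolution is limited only by the number of meioses observed.

The pipeline takes multi-sample genotype calls (VCF with GT and per-sample
DP), a scaffold catalog (FASTA or `.fai`), and optionally a BED mask of
regions where reads from both parental genomes co-map. Offspring calls are
reduced to haplotype evidence: A-only, B-only, both-seen, or missing. A
both-seen call at this coverage is treated as uninformative (a residual
cross-mapped read), not as a diploid heterozygote.

## Marker filtering

`apply_cascade()` applies, in order, with every rule recorded in an attrition
report:

| rule | default | meaning |
|---|---|---|
| cross-mapped mask | input BED | sites indistinguishable between parental genomes |
| high depth | 4 x mean | per-site total depth above 4x the genome-wide mean per-site total (collapsed repeats) |
| parent heterozygosity | on when parent GTs present | a genuine offspring marker must be het in the focal parent |
| presence | >= 10% of individuals | minimum fraction with any call |
| allele balance | minor >= 30% | among homozygous-class calls; distorted or mistyped segregation otherwise |
| heterozygote excess | <= 20% both-seen | multi-copy loci |
| breakpoint noise | <= 10% of phased individuals | a site that is the apparent crossover breakpoint in many individuals is systematic error |

Threshold comparisons are strict (`<`, `>`), so a site exactly at a threshold
survives. The depth rule uses the per-site total as the finest faithful
reading of "regions mapped above four times the average depth"; window
aggregation is intentionally not imposed. The minor-allele denominator
excludes both-seen calls by default (only homozygous-class calls identify the
transmitted haplotype); `count_both_seen_in_minor` flips this. When no parent
genotypes exist (the reference-free mode used when a parent is lost), the
parent rule is skipped; on dense data this changes the marker set by ~0.1%
and the map negligibly. The breakpoint rule needs a preliminary phasing, so
the cascade phases, filters, and re-phases.

## Phasing

Within one scaffold each marker's (REF, ALT) pair maps onto the parent's
haplotype labels with an unknown sign, and the scaffold's 0/1 labelling is
itself arbitrary — every downstream consumer is invariant to a global swap,
and tests assert this equivariance.

1. **Site orientation** (`orient_sites`): sequential greedy. Site 1 is `+`;
   each later site takes the sign maximising agreement, across individuals
   covered at both, with the per-individual majority over the previous
   `window = 20` oriented sites. The window bridges sparse coverage (at 1.8x,
   ~40% of site-individual cells are empty); 20 sites ≈ 18 kb at default
   density, far below the scale at which crossovers would confuse the
   majority. Ties choose `+`; a site sharing no individual with its window is
   flagged low-confidence.
2. **Per-individual run segmentation** (`phase_individual`): a phase switch
   is accepted only when >= `min_switch_support = 2` consecutive informative
   calls support the new phase. Markers are typed from as little as one read,
   so a single call can never evidence a crossover. Rejected singleton
   discordant calls are rewritten to missing; missing calls inside a run are
   imputed to the run's phase (phase is successive except around crossovers).
   Crossovers are reported at the midpoint of the flanking informative
   positions — the data cannot localise them more finely.
3. **End profiles**: per individual, the first/last run phase becomes the
   scaffold's head/tail profile, the objects all linkage rests on.

## Chaining and orientation

Linkage between scaffold ends is the flip-maximised concordance rate: the
fraction of doubly-informative individuals whose phases agree, `max(raw, 1 -
raw)`. Completely linked ends concord at 1; unlinked ends at ~50%
(binomially distributed, which acceptance test 1 verifies).

Ordering scaffolds optimally is NP-hard, so a greedy heuristic is used:
chains seed from the longest unplaced scaffold; at each step all (chain end x
unplaced end) concordances are evaluated and the best pair with rate >=
`threshold` and overlap >= `min_informative = 20` attaches, flipping the
incoming scaffold's labels as needed. The default threshold 0.90 matches a
low-recombination (male) parent; 0.70 is the documented alternative for
high-recombination (female) maps. The live profile at a chain end is the
terminal scaffold's outward end profile, not a consensus — the method is
deliberately two-point. Ties break deterministically: larger overlap, longer
scaffold, lexicographic id, end. All pairs are re-evaluated after each
attachment (N is small enough that a static queue is not worth its staleness
bugs). A scaffold whose head and tail profiles agree wherever both are
informative has no internal crossover in any offspring and cannot be
oriented: it is reported `?` and its sequence is emitted as an N-run of its
full length in the extended FASTA (`--keep-unoriented-sequence` retains the
sequence instead; the literal N-fill is the default). Junction gaps are fixed
100 N (no gap size is implied by linkage data; configurable).

The `min_informative = 20` floor is a design choice the source method leaves
open: on fewer than ~20 doubly-informative individuals the binomial sampling
error of a rate near 0.9 exceeds the margin the threshold is meant to
enforce.

## Genetic map

Within a group, per-individual phases across the ordered scaffold ends are
assembled (flip-normalised) into a chain phase matrix. To exclude false
recombination, phases not matching continuously for `min_run = 3` or more
scaffolds in an individual are set to missing; runs are measured over
non-missing entries, and length is the number of distinct scaffolds a run
extends over (a scaffold hosting an internal crossover is reached by the runs
on both sides), so one- and two-scaffold noise blips are wiped while genuine
runs delimited by nearby crossovers survive. Each junction
then yields a two-point recombination fraction r = switches / informative
pairs (capped at 0.5 and flagged if exceeded), contributing 100·r cM. cM are
summed directly (Morgan additive): with ultra-dense junctions each r is
small, so Haldane/Kosambi corrections are negligible; `haldane = TRUE` is
available. Within-scaffold genetic length (100 x detected internal crossovers
/ phase-informative individuals) is included by default and reported in its
own column, so junction-only totals are also recoverable — whether published
totals include it is not stated by the method's source, so both are emitted.
Physical positions are cumulative scaffold lengths.

## The simulator and what a green test establishes

`simulate_cross()` generates the stated world: heterozygous sites as a
Poisson process at 1/903 bp; 188 offspring; per-offspring crossovers
Poisson(1.3) per chromosome (3.6 documented for the high-recombination
parent), positions uniform or optionally telomere-weighted (Beta(1/2,1/2),
reproducing the larger linkage distances near telomeres); transmitted reads
Poisson(1.8/2) per site (half the combined coverage evidences the focal
parent — missingness ≈ exp(-0.9) ≈ 0.41); per-read miscall 0.5%; 2% of sites
cross-mapped, receiving contaminating reads and emitted in the mask; the
genome fragmented into lognormal scaffolds (sdlog 0.7, N50 15 kb) with
shuffled ids and random orientations, plus full ground truth. One RNG stream
is seeded once, so output is bit-identical per seed.

It does **not** emulate: read alignment or reference bias (cross-mapping is a
mask, not read competition — `interspecies_divergence` is recorded but has no
mechanistic role), crossover interference, indels/structural variation, base
quality, or non-uniform marker density. A green end-to-end test therefore
establishes that the algorithms recover the truth of this idealised
generative process at the stated noise levels, not that they are robust to
alignment artefacts.

## Numerical and test-condition choices

- Map-length identity check (Poisson(1) chromosome ↦ 100 cM): run with zero
  genotyping error, 5x depth, `min_run = 1`. The min-run rule exists to
  delete noise, and on noise-free input it deletes only real short runs
  (terminal runs and tight double crossovers), biasing the clean-data
  identity down ~10%; its effect is tested separately by the monotone-noise
  property (raising error inflates the map; the rule reduces the inflation).
- Exact phase-recovery check: run at zero crossovers, zero error, deep
  coverage. With positive recombination, a crossover between an individual's
  last two markers on a scaffold leaves a terminal singleton run that the
  support-2 rule must reject, so literal 100% end-phase accuracy is almost
  surely unattainable at scale in any recombining world (expected shortfall
  ~0.1-0.2% at default density). The >= 95% check runs at the full default
  noise world.
- Degenerate inputs: a scaffold with one informative call still yields an end
  phase (majority fallback); zero informative calls yield missing profiles
  and the scaffold can never join a chain; a single site is never
  depth-masked (it equals the mean); empty chain sets write valid empty
  outputs.
- Coordinates: VCF 1-based; mask BED 0-based half-open; AGP 1-based
  inclusive — each format's native convention.

## Known limitations

- In worlds whose genetic density per scaffold is far above the real
  genome's (e.g. compressing lambda = 1.3 into 200 kb chromosomes), junction
  concordances between marker-poor scaffolds sit near the 0.90 threshold and
  sampling noise can split a chromosome into two chains; the 22-chromosome
  desk-scale check recovers 22-25 groups rather than exactly 22 for this
  reason (see the decisions notes accompanying the acceptance suite).
- Crossovers beyond the terminal markers of a chain, and even-numbered
  multiple crossovers inside one scaffold between its end markers, are
  invisible to end-phase methods.
- The greedy chain grows through its terminal scaffold's profile; one noisy
  terminal scaffold can stall growth early. Global optimisation is out of
  scope (NP-hard; the method is deliberately heuristic).
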