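# linkscaf

Ultrahigh-density genetic linkage maps — and chromosome-scale scaffold
anchoring — from **very low-coverage (~1–2×) whole-genome genotypes of hybrid
offspring**.

## The problem and the idea

Linkage maps order and orient draft-assembly scaffolds into chromosomes, but
conventional genotyping needs ~10× coverage per offspring just to separate
hetero- from homozygotes, and restriction-site markers (RAD-seq, GBS) are too
sparse to place small scaffolds. If the cross is made between two genomes
divergent enough (~98% identity) that every offspring read can be attributed
to one parent, then at any site heterozygous in the focal parent a **single
attributed read identifies the transmitted haplotype**. Each parent is then
mapped independently, as if its offspring were a panel of double haploids,
from ~1.8× combined coverage — and whole-genome SNP markers (~1 per kb)
make map resolution limited only by the number of crossovers, not markers.

For scaffolds *s* with per-offspring end-phase profiles, linkage is the
flip-maximised **concordance rate** `c = max(m, 1 − m)/n` over the *n*
offspring informative at both ends (unlinked ends ⇒ c ≈ 0.5; completely
linked ends ⇒ c = 1). Scaffolds are greedily chained while `c ≥ 0.9`
(0.7 for a high-recombination parent), oriented wherever an internal
crossover distinguishes their ends, and mapped by summed two-point distances,
`d = 100·r` cM with `r = switches/n` per junction after a run-length noise
rule (phases must match for ≥ 3 consecutive scaffolds).

The package implements the full pipeline — marker filter cascade, rule-based
phasing with crossover detection, concordance chaining, cM mapping, AGP /
extended-FASTA writers — plus a meiosis simulator with ground truth that the
test suite and acceptance report are built on.

## Worked example

```r
library(linkscaf)

cfg <- sim_config(n_chromosomes = 2, chromosome_length = 3e5,
                  n_offspring = 60, seed = 7)
sim <- simulate_cross(cfg)
print(sim)
#> sim_cross: 706 sites x 60 offspring, 60 scaffolds on 2 chromosome(s)

res <- run_pipeline(sim$genotypes, sim$catalog, mask = sim$mask)
print(res$report)
#> marker attrition:
#>              rule sites_before sites_removed sites_after
#>      cross_mapped          706            20         686
#>        high_depth          686             0         686
#>        parent_het          686             0         686
#>          presence          686             0         686
#>    allele_balance          686             7         679
#>        het_excess          679             0         679
#>  breakpoint_noise          679             0         679
print(res$chains)
#> linkage_chain_set: 4 chains (2 non-singleton), 60 scaffolds placed
print(res$map)
#> linkage_map: 4 groups, 60 scaffolds, 205.5 cM, 600000 bp
```

The attrition report mirrors the filter cascade (here the simulator's
cross-mapped 2% of sites and a few distorted markers are removed). The two
simulated chromosomes come back as the two non-singleton chains; the map
totals ~100 cM per chromosome because crossovers were drawn Poisson(1.3) per
chromosome and detected two-point distances add up (Morgan identity). Per
scaffold rows carry positions and orientation — `?` marks scaffolds with no
internal crossover in any offspring, which cannot be oriented:

```r
head(res$map$map[, c("group", "order_index", "scaffold", "orientation",
                     "start_cM", "end_cM")], 5)
#>          group order_index scaffold orientation  start_cM    end_cM
#> scf00040 LG001           1 scf00040           ?  0.000000  0.000000
#> scf00056 LG001           2 scf00056           +  0.000000  3.333333
#> scf00003 LG001           3 scf00003           +  3.333333  5.000000
#> scf00037 LG001           4 scf00037           +  8.333333 11.666667
#> scf00005 LG001           5 scf00005           ? 13.333333 13.333333
```

`write_outputs()` emits the phase table, chain/map TSVs, AGP 2.1 and (given
sequences) the extended FASTA in which oriented scaffolds contribute their
(possibly reverse-complemented) sequence, unoriented scaffolds are N-filled
over their full length, and junctions are 100-N gaps.

### Command line

```sh
Rscript -e 'linkscaf::linkscaf_cli()' simulate --out sim --n-chromosomes 2 --write-fasta --seed 5
Rscript -e 'linkscaf::linkscaf_cli()' all --vcf sim/genotypes.vcf \
    --catalog sim/scaffolds.fai --mask sim/mask.bed --fasta sim/scaffolds.fasta \
    --threshold 0.9 --min-run 3 --out results
```

Subcommands `filter`, `phase`, `chain`, `map`, `assemble` run the stages
individually over plain files and compose byte-identically to `all`.

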