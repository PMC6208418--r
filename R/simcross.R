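# Hybrid-cross simulator. The stated world: two parental genomes divergent
# enough (~98% identity) that every offspring read is attributable to one
# parent; the focal parent is heterozygous at ~1 site per 903 bp; 188
# offspring sequenced at ~1.8x combined coverage (so ~0.9x per parental
# genome); crossovers per chromosome Poisson with mean 1.3 (3.6 for the
# high-recombination parent); a small fraction of sites cross-mapped between
# the genomes and flagged in a mask.

#' Simulation configuration
#'
#' @param n_chromosomes chromosomes of the focal parent (default 4; use 22
#'   for a full-genome-shaped check).
#' @param chromosome_length bp per chromosome (default 1e6, desk scale).
#' @param n_offspring hybrid offspring genotyped (default 188).
#' @param het_site_rate per-bp rate of focal-parent heterozygous sites
#'   (default 1/903).
#' @param interspecies_divergence nucleotide divergence between the parental
#'   genomes (default 0.019). Recorded for provenance; read attribution is
#'   modelled through `cross_mapped_fraction`, not through sequence identity.
#' @param mean_crossovers Poisson mean crossovers per chromosome per meiosis
#'   (default 1.3; 3.6 is the documented high-recombination alternative).
#' @param mean_depth mean combined read depth per offspring (default 1.8;
#'   reads informative for the focal parent arrive at half this rate).
#' @param genotype_error per-read miscall probability (default 0.005).
#' @param cross_mapped_fraction fraction of sites indistinguishable between
#'   the parental genomes (default 0.02); these receive contaminating reads
#'   and are emitted in the exclusion mask.
#' @param scaffold_n50 target N50 of the fragmented (scrambled) assembly
#'   (default 15000 bp; lengths are lognormal with sdlog 0.7).
#' @param telomere_bias place crossovers with a U-shaped (Beta(1/2,1/2))
#'   density instead of uniform, concentrating recombination near chromosome
#'   ends.
#' @param seed RNG seed consumed once at the start of [simulate_cross()] /
#'   [simulate_parents()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 4, chromosome_length = 1e6,
                       n_offspring = 188, het_site_rate = 1 / 903,
                       interspecies_divergence = 0.019,
                       mean_crossovers = 1.3, mean_depth = 1.8,
                       genotype_error = 0.005, cross_mapped_fraction = 0.02,
                       scaffold_n50 = 15000, telomere_bias = FALSE,
                       seed = 1L) {
  rates <- c(het_site_rate, interspecies_divergence, genotype_error,
             cross_mapped_fraction)
  abort_if(any(rates < 0 | rates > 1), "rates must lie in [0, 1]")
  abort_if(mean_crossovers < 0, "mean_crossovers must be >= 0")
  abort_if(mean_depth <= 0, "mean_depth must be > 0")
  abort_if(n_chromosomes < 1 || chromosome_length < 1 || n_offspring < 1,
           "counts must be positive")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = chromosome_length,
                 n_offspring = as.integer(n_offspring),
                 het_site_rate = het_site_rate,
                 interspecies_divergence = interspecies_divergence,
                 mean_crossovers = mean_crossovers, mean_depth = mean_depth,
                 genotype_error = genotype_error,
                 cross_mapped_fraction = cross_mapped_fraction,
                 scaffold_n50 = scaffold_n50,
                 telomere_bias = isTRUE(telomere_bias),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the focal parent's heterozygous sites
#'
#' Seeds the RNG from `config$seed`, then places heterozygous sites along each
#' chromosome as a Poisson process at `het_site_rate`, assigns two distinct
#' alleles per site (allele A on haplotype 0, allele B on haplotype 1) and
#' flags a `cross_mapped_fraction` subset as indistinguishable between the
#' parental genomes.
#'
#' @param config a [sim_config()].
#' @return list with `sites` (data frame `chrom`, `pos`, `allele_a`,
#'   `allele_b`, `cross_mapped`) and `config`.
#' @export
simulate_parents <- function(config) {
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  per_chrom <- lapply(seq_len(config$n_chromosomes), function(ci) {
    n <- stats::rpois(1L, config$chromosome_length * config$het_site_rate)
    n <- min(n, config$chromosome_length)
    if (n == 0L) {
      return(data.frame(chrom = integer(0), pos = integer(0),
                        allele_a = character(0), allele_b = character(0),
                        cross_mapped = logical(0)))
    }
    pos <- sort(sample.int(config$chromosome_length, n))
    a <- sample(bases, n, replace = TRUE)
    b <- vapply(a, function(x) sample(setdiff(bases, x), 1L), "")
    data.frame(chrom = ci, pos = pos, allele_a = a, allele_b = unname(b),
               cross_mapped = stats::runif(n) < config$cross_mapped_fraction,
               stringsAsFactors = FALSE)
  })
  list(sites = do.call(rbind, per_chrom), config = config)
}

#' Simulate meioses (gametes) of the focal parent
#'
#' Per offspring and chromosome, the crossover count is Poisson
#' (`mean_crossovers`) with positions uniform (or telomere-weighted), and the
#' transmitted haplotype starts from a fair Bernoulli draw, alternating at
#' each crossover. No crossover interference is modelled.
#'
#' @param parents result of [simulate_parents()] (continues its RNG stream).
#' @param config a [sim_config()].
#' @return A `sim_truth` skeleton: `start` and `crossover_positions` indexed
#'   `[[chrom]][[offspring]]`, and `crossover_counts` (offspring x chrom).
#' @export
simulate_gametes <- function(parents, config = parents$config) {
  m <- config$n_offspring
  L <- config$chromosome_length
  starts <- vector("list", config$n_chromosomes)
  xpos <- vector("list", config$n_chromosomes)
  counts <- matrix(0L, m, config$n_chromosomes)
  for (ci in seq_len(config$n_chromosomes)) {
    k <- stats::rpois(m, config$mean_crossovers)
    counts[, ci] <- k
    starts[[ci]] <- stats::rbinom(m, 1L, 0.5)
    xpos[[ci]] <- lapply(seq_len(m), function(o) {
      if (k[o] == 0L) return(numeric(0))
      u <- if (config$telomere_bias) stats::rbeta(k[o], 0.5, 0.5)
           else stats::runif(k[o])
      sort(u * L)
    })
  }
  structure(list(start = starts, crossover_positions = xpos,
                 crossover_counts = counts, config = config),
            class = "sim_truth")
}

#' Transmitted haplotype at given chromosome positions
#'
#' @param truth a `sim_truth`.
#' @param chrom chromosome index.
#' @param offspring offspring index.
#' @param pos positions (bp).
#' @return integer vector of haplotype labels (0 = haplotype A, 1 = B); the
#'   painting alternates exactly at the listed crossover positions.
#' @export
truth_painting <- function(truth, chrom, offspring, pos) {
  x <- truth$crossover_positions[[chrom]][[offspring]]
  (truth$start[[chrom]][offspring] + findInterval(pos, x)) %% 2L
}

# fragment each chromosome into lognormal scaffolds, then scramble ids and
# orientations; the N50 of a lognormal length distribution is the median of
# its size-biased version, exp(meanlog + sdlog^2)
fragment_genome <- function(config) {
  sdlog <- 0.7
  meanlog <- log(config$scaffold_n50) - sdlog^2
  rows <- list()
  for (ci in seq_len(config$n_chromosomes)) {
    L <- config$chromosome_length
    lens <- numeric(0)
    while (sum(lens) < L) {
      lens <- c(lens, pmax(200, round(stats::rlnorm(50L, meanlog, sdlog))))
    }
    cut <- which(cumsum(lens) >= L)[1L]
    lens <- lens[seq_len(cut)]
    lens[cut] <- L - sum(lens[-cut])
    if (lens[cut] < 1) lens <- lens[-cut]
    starts <- cumsum(c(0, lens[-length(lens)]))
    rows[[ci]] <- data.frame(chrom = ci, order_index = seq_along(lens),
                             chrom_start = starts, length = lens,
                             orientation = ifelse(stats::runif(length(lens)) <
                                                    0.5, "+", "-"),
                             stringsAsFactors = FALSE)
  }
  scf <- do.call(rbind, rows)
  scf$scaffold <- sprintf("scf%05d", sample.int(nrow(scf)))
  scf[order(scf$scaffold), c("scaffold", "chrom", "order_index",
                             "chrom_start", "length", "orientation")]
}

#' Simulate offspring observations on a scrambled scaffold assembly
#'
#' Fragments the genome into scaffolds (shuffled ids, random orientations),
#' lifts the heterozygous sites onto scaffold coordinates, and draws per-site,
#' per-offspring reads: counts Poisson at `mean_depth / 2` (half the combined
#' coverage evidences the focal parent), zero reads giving a missing call,
#' each read miscalled with probability `genotype_error`; seeing both alleles
#' yields a both-seen call. Cross-mapped sites additionally receive
#' contaminating reads of random allele at the same rate.
#'
#' @param parents result of [simulate_parents()].
#' @param truth result of [simulate_gametes()].
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()], parent genotypes all
#'   het), `catalog` ([scaffold_catalog()] of the scrambled assembly), `mask`
#'   ([site_mask()] of cross-mapped sites in scaffold coordinates) and
#'   `truth` (the input truth extended with `scaffolds` and per-site
#'   `haplotypes`).
#' @export
simulate_observations <- function(parents, truth, config = parents$config) {
  scf <- fragment_genome(config)
  sites <- parents$sites
  m <- config$n_offspring

  # lift chromosome positions onto scaffold coordinates
  lifted <- vector("list", config$n_chromosomes)
  for (ci in seq_len(config$n_chromosomes)) {
    sc <- scf[scf$chrom == ci, , drop = FALSE]
    sc <- sc[order(sc$chrom_start), , drop = FALSE]
    on <- sites[sites$chrom == ci, , drop = FALSE]
    if (!nrow(on)) next
    i <- findInterval(on$pos - 1L, sc$chrom_start)
    off <- on$pos - sc$chrom_start[i]
    scafpos <- ifelse(sc$orientation[i] == "+", off,
                      sc$length[i] - off + 1L)
    lifted[[ci]] <- data.frame(scaffold = sc$scaffold[i], pos = scafpos,
                               allele_a = on$allele_a,
                               allele_b = on$allele_b, chrom = ci,
                               chrom_pos = on$pos,
                               cross_mapped = on$cross_mapped,
                               stringsAsFactors = FALSE)
  }
  ls <- do.call(rbind, lifted)
  ls <- ls[order(ls$scaffold, ls$pos), , drop = FALSE]
  n <- nrow(ls)
  abort_if(n == 0L, "simulation produced no heterozygous sites")

  # true transmitted haplotype per site x offspring
  hap <- matrix(0L, n, m)
  for (ci in unique(ls$chrom)) {
    rows <- which(ls$chrom == ci)
    for (o in seq_len(m)) {
      hap[rows, o] <- truth_painting(truth, ci, o, ls$chrom_pos[rows])
    }
  }

  k <- matrix(stats::rpois(n * m, config$mean_depth / 2), n, m)
  e <- matrix(stats::rbinom(n * m, as.vector(k), config$genotype_error), n, m)
  calls <- matrix(NA_integer_, n, m)
  calls[k > 0L & e == 0L] <- hap[k > 0L & e == 0L]
  calls[k > 0L & e == k] <- 1L - hap[k > 0L & e == k]
  calls[k > 0L & e > 0L & e < k] <- CALL_BOTH
  depths <- k

  cm <- which(ls$cross_mapped)
  if (length(cm)) {
    kc <- matrix(stats::rpois(length(cm) * m, config$mean_depth / 2),
                 length(cm), m)
    ca <- matrix(stats::rbinom(length(cm) * m, as.vector(kc), 0.5),
                 length(cm), m)
    cb <- kc - ca
    sub <- calls[cm, , drop = FALSE]
    seen_a <- (!is.na(sub) & sub != CALL_B) | ca > 0L
    seen_b <- (!is.na(sub) & sub != CALL_A) | cb > 0L
    sub[seen_a & seen_b] <- CALL_BOTH
    sub[seen_a & !seen_b] <- CALL_A
    sub[!seen_a & seen_b] <- CALL_B
    sub[!seen_a & !seen_b] <- NA_integer_
    calls[cm, ] <- sub
    depths[cm, ] <- depths[cm, , drop = FALSE] + kc
  }

  sample_ids <- sprintf("off%03d", seq_len(m))
  gm <- genotype_matrix(ls[, c("scaffold", "pos", "allele_a", "allele_b")],
                        calls, depths, sample_ids,
                        parent = rep("het", n))
  catalog <- scaffold_catalog(scf$scaffold, scf$length)
  mask <- if (any(ls$cross_mapped)) {
    site_mask(ls$scaffold[ls$cross_mapped], ls$pos[ls$cross_mapped] - 1L,
              ls$pos[ls$cross_mapped], "cross_mapped")
  } else site_mask()
  truth$scaffolds <- scf
  truth$haplotypes <- hap
  truth$site_map <- ls[, c("scaffold", "pos", "chrom", "chrom_pos")]
  list(genotypes = gm, catalog = catalog, mask = mask, truth = truth)
}

#' Simulate a complete hybrid-cross dataset
#'
#' Runs [simulate_parents()], [simulate_gametes()] and
#' [simulate_observations()] on one RNG stream seeded from `config$seed`;
#' output is bit-identical for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return A `sim_cross` list: `genotypes`, `catalog`, `mask`, `truth`,
#'   `parents`, `config`.
#' @export
simulate_cross <- function(config = sim_config()) {
  parents <- simulate_parents(config)
  truth <- simulate_gametes(parents, config)
  obs <- simulate_observations(parents, truth, config)
  structure(c(obs, list(parents = parents, config = config)),
            class = "sim_cross")
}

#' @export
print.sim_cross <- function(x, ...) {
  cat(sprintf("sim_cross: %d sites x %d offspring, %d scaffolds on %d chromosome(s)\n",
              n_sites(x$genotypes), n_individuals(x$genotypes),
              nrow(x$catalog), x$config$n_chromosomes))
  invisible(x)
}

#' Generate random scaffold sequences matching a catalog
#'
#' Convenience for exercising the sequence-level writers against simulated
#' catalogs (marker alleles are not embedded; the pipeline never reads the
#' sequence itself).
#'
#' @param catalog a [scaffold_catalog()].
#' @param seed RNG seed.
#' @return a [Biostrings::DNAStringSet] named by scaffold.
#' @export
sim_sequences <- function(catalog, seed = 1L) {
  set.seed(seed)
  seqs <- Biostrings::DNAStringSet(vapply(catalog$length, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, ""))
  names(seqs) <- catalog$scaffold
  seqs
}

#' Write a simulated dataset to disk in pipeline input formats
#'
#' Emits the genotype VCF (parent column included), a faidx-style catalog, the
#' cross-mapped mask BED and ground-truth TSVs (scaffold placement and
#' per-offspring crossover counts). With `write_fasta = TRUE` also emits
#' random scaffold sequences consistent with the catalog.
#'
#' @param sim a `sim_cross`.
#' @param dir output directory.
#' @param write_fasta also write `scaffolds.fasta`.
#' @return named character vector of written paths, invisibly.
#' @export
write_sim <- function(sim, dir, write_fasta = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             fai = file.path(dir, "scaffolds.fai"),
             mask = file.path(dir, "mask.bed"),
             truth_scaffolds = file.path(dir, "truth_scaffolds.tsv"),
             truth_crossovers = file.path(dir, "truth_crossovers.tsv"))
  write_genotype_vcf(sim$genotypes, paths[["vcf"]])
  fai <- data.frame(sim$catalog$scaffold, sim$catalog$length, 0L, 60L, 61L)
  utils::write.table(fai, paths[["fai"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_site_mask(sim$mask, paths[["mask"]])
  utils::write.table(sim$truth$scaffolds, paths[["truth_scaffolds"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  co <- data.frame(offspring = sprintf("off%03d",
                                       seq_len(nrow(sim$truth$crossover_counts))),
                   sim$truth$crossover_counts)
  names(co)[-1L] <- sprintf("chrom%d", seq_len(ncol(sim$truth$crossover_counts)))
  utils::write.table(co, paths[["truth_crossovers"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (write_fasta) {
    paths[["fasta"]] <- file.path(dir, "scaffolds.fasta")
    Biostrings::writeXStringSet(sim_sequences(sim$catalog, sim$config$seed),
                                paths[["fasta"]])
  }
  invisible(paths)
}
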