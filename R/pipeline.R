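#' Run the full analysis on in-memory objects
#'
#' Filter cascade (including preliminary phasing, breakpoint-noise removal and
#' re-phasing), greedy chaining and map construction, in one call.
#'
#' @param genotypes a [genotype_matrix()].
#' @param catalog a [scaffold_catalog()].
#' @param mask optional cross-mapped [site_mask()].
#' @param filter a [filter_config()].
#' @param window,min_switch_support phasing parameters.
#' @param threshold,min_informative chaining parameters.
#' @param min_run map noise rule.
#' @param haldane mapping function switch, see [build_map()].
#' @return list with `genotypes` (filtered), `report`, `phased`, `chains`,
#'   `map`.
#' @export
run_pipeline <- function(genotypes, catalog, mask = NULL,
                         filter = filter_config(), window = 20,
                         min_switch_support = 2, threshold = 0.90,
                         min_informative = 20, min_run = 3,
                         haldane = FALSE) {
  fc <- apply_cascade(genotypes, cross_mask = mask, config = filter,
                      window = window,
                      min_switch_support = min_switch_support)
  chains <- chain_scaffolds(fc$phased, catalog, threshold = threshold,
                            min_informative = min_informative)
  map <- build_map(chains, fc$phased, catalog, min_run = min_run,
                   haldane = haldane)
  list(genotypes = fc$genotypes, report = fc$report, phased = fc$phased,
       chains = chains, map = map)
}

#' Run the pipeline from files to files
#'
#' File-level front end used by the command line: reads the VCF, catalog and
#' optional mask, runs [run_pipeline()] and writes every output (phase, chain
#' and map tables, attrition report, AGP, and extended FASTA when a sequence
#' FASTA is supplied). Identical inputs produce byte-identical outputs.
#'
#' @param vcf input VCF path.
#' @param catalog FASTA or .fai path.
#' @param out output directory.
#' @param mask optional mask BED path.
#' @param fasta optional scaffold sequence FASTA for the extended assembly.
#' @param focal_parent parent sample id in the VCF, or `NULL`.
#' @param gap junction gap size (bp) in AGP/FASTA output.
#' @param keep_unoriented_sequence see [write_extended_fasta()].
#' @inheritParams run_pipeline
#' @return named character vector of written paths, invisibly.
#' @export
run_all <- function(vcf, catalog, out, mask = NULL, fasta = NULL,
                    focal_parent = NULL, filter = filter_config(),
                    window = 20, min_switch_support = 2, threshold = 0.90,
                    min_informative = 20, min_run = 3, gap = 100,
                    keep_unoriented_sequence = FALSE) {
  abort_if(!file.exists(vcf), "missing input: %s", vcf)
  abort_if(!file.exists(catalog), "missing input: %s", catalog)
  gm <- read_genotype_vcf(vcf, focal_parent = focal_parent)
  cat_ <- read_scaffold_catalog(catalog)
  msk <- if (!is.null(mask)) read_site_mask(mask) else NULL
  res <- run_pipeline(gm, cat_, mask = msk, filter = filter, window = window,
                      min_switch_support = min_switch_support,
                      threshold = threshold,
                      min_informative = min_informative, min_run = min_run)
  seqs <- if (!is.null(fasta)) Biostrings::readDNAStringSet(fasta) else NULL
  paths <- write_outputs(res$phased, res$chains, res$map, cat_, out,
                         sequences = seqs, gap = gap,
                         keep_unoriented_sequence = keep_unoriented_sequence)
  paths[["report"]] <- file.path(out, "filter_report.tsv")
  write_filter_report(res$report, paths[["report"]])
  invisible(paths)
}
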