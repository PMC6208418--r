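# Call codes used throughout: 0L = only the focal parent's haplotype-A allele
# seen, 1L = only the haplotype-B allele seen, 2L = both alleles seen,
# NA = no read. At ~1.8x depth these are evidence of which haplotype a read
# came from, not diploid genotypes.
CALL_A <- 0L
CALL_B <- 1L
CALL_BOTH <- 2L

#' Low-depth genotype matrix
#'
#' Sites-by-individuals allele observations anchored to scaffold coordinates,
#' the central container of the pipeline. Calls are coded `0` (allele A only),
#' `1` (allele B only), `2` (both alleles seen) and `NA` (no read).
#'
#' @param sites data frame with columns `scaffold`, `pos` (1-based bp),
#'   `allele_a`, `allele_b`.
#' @param calls integer matrix, sites x individuals, values in {0, 1, 2, NA}.
#' @param depths integer matrix of per-cell read depths (same shape).
#' @param sample_ids character vector of offspring identifiers.
#' @param parent optional character vector per site with the focal parent's
#'   genotype class: one of `"hom_a"`, `"hom_b"`, `"het"`, `NA`.
#' @param validate check invariants (positions strictly increasing within a
#'   scaffold, `both-seen` implies depth >= 2, alleles distinct).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(sites, calls, depths, sample_ids, parent = NULL,
                            validate = TRUE) {
  calls <- as.matrix(calls)
  depths <- as.matrix(depths)
  storage.mode(calls) <- "integer"
  storage.mode(depths) <- "integer"
  dimnames(calls) <- NULL
  dimnames(depths) <- NULL
  gm <- structure(list(sites = as.data.frame(sites), calls = calls,
                       depths = depths,
                       sample_ids = as.character(sample_ids),
                       parent = parent),
                  class = "genotype_matrix")
  if (validate) validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  s <- gm$sites
  abort_if(!all(c("scaffold", "pos", "allele_a", "allele_b") %in% names(s)),
           "sites must have scaffold, pos, allele_a, allele_b")
  abort_if(nrow(s) != nrow(gm$calls) || nrow(s) != nrow(gm$depths),
           "sites/calls/depths row mismatch")
  abort_if(ncol(gm$calls) != length(gm$sample_ids),
           "calls columns must match sample_ids")
  abort_if(any(s$allele_a == s$allele_b), "allele_a must differ from allele_b")
  # strictly increasing positions within each scaffold
  ord_ok <- tapply(s$pos, s$scaffold, function(p) all(diff(p) > 0))
  abort_if(!all(unlist(ord_ok)),
           "positions must be strictly increasing within a scaffold")
  abort_if(any(gm$depths < 0L, na.rm = TRUE), "negative depth")
  both <- !is.na(gm$calls) & gm$calls == CALL_BOTH
  abort_if(any(gm$depths[both] < 2L, na.rm = TRUE),
           "a both-seen call requires depth >= 2")
  if (!is.null(gm$parent)) {
    abort_if(length(gm$parent) != nrow(s), "parent vector length mismatch")
    bad <- !is.na(gm$parent) & !gm$parent %in% c("hom_a", "hom_b", "het")
    abort_if(any(bad), "invalid parent genotype class")
  }
  invisible(gm)
}

#' Dimensions of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return number of sites / individuals.
#' @export
n_sites <- function(gm) nrow(gm$sites)

#' @rdname n_sites
#' @export
n_individuals <- function(gm) length(gm$sample_ids)

#' Keep a subset of sites of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @param keep logical or integer index over sites (order preserved).
#' @return the subsetted `genotype_matrix`.
#' @export
subset_sites <- function(gm, keep) {
  genotype_matrix(gm$sites[keep, , drop = FALSE],
                  gm$calls[keep, , drop = FALSE],
                  gm$depths[keep, , drop = FALSE],
                  gm$sample_ids,
                  parent = if (is.null(gm$parent)) NULL else gm$parent[keep],
                  validate = FALSE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d individuals on %d scaffold(s)%s\n",
              n_sites(x), n_individuals(x),
              length(unique(x$sites$scaffold)),
              if (is.null(x$parent)) "" else " (focal-parent genotypes present)"))
  invisible(x)
}

#' Read offspring genotypes from a VCF file
#'
#' Retains biallelic SNP records only; multiallelic or non-SNP records are
#' skipped and counted in the `n_skipped` attribute of the result. Genotypes
#' are reduced to haplotype-evidence calls: `0/0` -> A-only, `1/1` -> B-only,
#' heterozygous -> both-seen, `./.` -> missing. If `focal_parent` names a
#' sample column, that column populates the per-site parent genotype classes
#' and is excluded from the offspring set.
#'
#' @param path path to a VCF 4.x file with GT and per-sample DP (AD optional;
#'   used as a depth fallback when DP is absent).
#' @param focal_parent sample id of the focal parent, or `NULL`.
#' @return A [genotype_matrix()]; attribute `n_skipped` counts dropped
#'   non-biallelic-SNP records.
#' @export
read_genotype_vcf <- function(path, focal_parent = NULL) {
  abort_if(!file.exists(path), "no such file: %s", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(nalt))
  alt1[nalt == 1L] <- as.character(unlist(altl[nalt == 1L]))
  bases <- c("A", "C", "G", "T")
  snp <- nalt == 1L & ref %in% bases & !is.na(alt1) & alt1 %in% bases
  n_skipped <- sum(!snp)

  g <- VariantAnnotation::geno(vcf)
  abort_if(!"GT" %in% names(g), "VCF has no GT field")
  gt <- g$GT[snp, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[gt == "1/0"] <- "0/1"

  if ("DP" %in% names(g)) {
    dp <- g$DP[snp, , drop = FALSE]
    storage.mode(dp) <- "integer"
  } else if ("AD" %in% names(g)) {
    warning("VCF has no per-sample DP; depths taken as sum of AD")
    ad <- g$AD[snp, , drop = FALSE]
    dp <- matrix(vapply(ad, function(a) as.integer(sum(a, na.rm = TRUE)), 1L),
                 nrow = nrow(ad), ncol = ncol(ad))
  } else {
    warning("VCF has neither DP nor AD; depths set to 0")
    dp <- matrix(0L, nrow(gt), ncol(gt))
  }
  dp[is.na(dp)] <- 0L
  colnames(dp) <- colnames(gt)

  samples <- colnames(gt)
  parent <- NULL
  if (!is.null(focal_parent)) {
    abort_if(!focal_parent %in% samples,
             "focal_parent '%s' is not a sample in the VCF", focal_parent)
    pgt <- gt[, focal_parent]
    parent <- rep(NA_character_, length(pgt))
    parent[pgt == "0/0"] <- "hom_a"
    parent[pgt == "1/1"] <- "hom_b"
    parent[pgt == "0/1"] <- "het"
    offspring <- setdiff(samples, focal_parent)
    gt <- gt[, offspring, drop = FALSE]
    dp <- dp[, offspring, drop = FALSE]
    samples <- offspring
  }

  calls <- matrix(NA_integer_, nrow(gt), ncol(gt))
  calls[gt == "0/0"] <- CALL_A
  calls[gt == "1/1"] <- CALL_B
  calls[gt == "0/1"] <- CALL_BOTH
  # a both-seen claim on fewer than two reads cannot be genuine evidence of
  # both alleles; demote to missing rather than trust it
  demote <- !is.na(calls) & calls == CALL_BOTH & dp < 2L
  if (any(demote)) calls[demote] <- NA_integer_

  sites <- data.frame(scaffold = chrom[snp], pos = pos[snp],
                      allele_a = ref[snp], allele_b = alt1[snp],
                      stringsAsFactors = FALSE)
  ord <- order(sites$scaffold, sites$pos)
  gm <- genotype_matrix(sites[ord, , drop = FALSE],
                        calls[ord, , drop = FALSE],
                        dp[ord, , drop = FALSE],
                        samples,
                        parent = if (is.null(parent)) NULL else parent[ord])
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Write a genotype matrix as VCF (debug/interchange writer)
#'
#' Emits a minimal VCF 4.2 with GT and DP that round-trips through
#' [read_genotype_vcf()]. The focal parent, when present, is written as an
#' extra sample column named by `parent_id` at depth `parent_depth`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param parent_id sample name for the parent column.
#' @param parent_depth depth reported on parent genotypes.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(gm, path, parent_id = "focal_parent",
                               parent_depth = 30L) {
  con <- file(path, "w")
  on.exit(close(con))
  samples <- gm$sample_ids
  has_parent <- !is.null(gm$parent)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples,
                      if (has_parent) parent_id), collapse = "\t"))
  writeLines(header, con)
  gt_code <- c("0/0", "1/1", "0/1")
  for (i in seq_len(n_sites(gm))) {
    cc <- gm$calls[i, ]
    gt <- ifelse(is.na(cc), "./.", gt_code[cc + 1L])
    fields <- paste(gt, gm$depths[i, ], sep = ":")
    if (has_parent) {
      pg <- gm$parent[i]
      pgt <- switch(ifelse(is.na(pg), "missing", pg),
                    hom_a = "0/0", hom_b = "1/1", het = "0/1", "./.")
      fields <- c(fields, paste(pgt, parent_depth, sep = ":"))
    }
    writeLines(paste(c(gm$sites$scaffold[i], gm$sites$pos[i], ".",
                       gm$sites$allele_a[i], gm$sites$allele_b[i], ".",
                       "PASS", ".", "GT:DP", fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Site exclusion mask
#'
#' Half-open 0-based intervals (BED dialect) marking regions whose markers are
#' excluded: cross-mapped regions where reads from both parental genomes
#' align, or regions of anomalously high depth.
#'
#' @param scaffold,start,end interval columns (0-based half-open).
#' @param reason one of `"cross_mapped"`, `"high_depth"` per interval.
#' @return A `site_mask` data frame.
#' @export
site_mask <- function(scaffold = character(), start = integer(),
                      end = integer(), reason = character()) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  abort_if(any(start < 0), "mask start must be >= 0")
  abort_if(any(end <= start), "mask end must exceed start")
  structure(data.frame(scaffold = as.character(scaffold), start = start,
                       end = end,
                       reason = rep_len(as.character(reason),
                                        length(scaffold)),
                       stringsAsFactors = FALSE),
            class = c("site_mask", "data.frame"))
}

#' @rdname site_mask
#' @param path BED3+reason file (tab-separated, no header).
#' @export
read_site_mask <- function(path) {
  abort_if(!file.exists(path), "no such file: %s", path)
  if (file.size(path) == 0L) return(site_mask())
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  site_mask(bed[[1L]], bed[[2L]], bed[[3L]],
            if (ncol(bed) >= 4L) bed[[4L]] else "cross_mapped")
}

#' @rdname site_mask
#' @param mask a `site_mask`.
#' @export
write_site_mask <- function(mask, path) {
  utils::write.table(mask, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# logical vector over sites of gm: TRUE where the (1-based) site position
# falls inside a mask interval on the same scaffold
sites_in_mask <- function(gm, mask) {
  hit <- logical(n_sites(gm))
  if (is.null(mask) || nrow(mask) == 0L) return(hit)
  p0 <- gm$sites$pos - 1L # to 0-based
  for (scf in unique(mask$scaffold)) {
    iv <- mask[mask$scaffold == scf, , drop = FALSE]
    on <- which(gm$sites$scaffold == scf)
    if (!length(on)) next
    for (k in seq_len(nrow(iv))) {
      hit[on] <- hit[on] | (p0[on] >= iv$start[k] & p0[on] < iv$end[k])
    }
  }
  hit
}
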