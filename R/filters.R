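#' Marker filter configuration
#'
#' Thresholds of the marker-attrition cascade. Defaults follow the published
#' regime for a hybrid pufferfish cross: sites in regions above four times the
#' mean depth are suspect repeats; markers seen in fewer than 10% of samples
#' carry too little information; a minor homozygous class under 30% indicates
#' distorted or mistyped segregation; heterozygous (both-allele) calls in more
#' than 20% of individuals suggest a collapsed multi-copy locus; and sites
#' acting as the apparent crossover breakpoint in more than 10% of individuals
#' are treated as noise.
#'
#' All "less than"/"more than" rules are strict, so a site exactly at a
#' threshold is kept.
#'
#' @param depth_multiplier cap on per-site total depth, in multiples of the
#'   genome-wide mean per-site total depth.
#' @param min_presence minimum fraction of individuals with a non-missing call.
#' @param min_minor minimum minor-class fraction among homozygous-class calls.
#' @param max_het maximum fraction of individuals with a both-seen call.
#' @param max_breakpoint maximum fraction of phased individuals for which a
#'   site may be the inferred crossover breakpoint.
#' @param require_parent_het drop sites not heterozygous in the focal parent;
#'   `NA` (default) means "on whenever parent genotypes are present", the mode
#'   used when only offspring data exist omits this rule.
#' @param count_both_seen_in_minor include both-seen individuals in the
#'   denominator of the minor-class rule (off by default; only homozygous
#'   classes identify the transmitted haplotype).
#' @return A `filter_config` list.
#' @export
filter_config <- function(depth_multiplier = 4, min_presence = 0.10,
                          min_minor = 0.30, max_het = 0.20,
                          max_breakpoint = 0.10, require_parent_het = NA,
                          count_both_seen_in_minor = FALSE) {
  fr <- c(min_presence, min_minor, max_het, max_breakpoint)
  abort_if(any(fr < 0 | fr > 1), "filter fractions must lie in [0, 1]")
  abort_if(depth_multiplier <= 0, "depth_multiplier must be > 0")
  structure(list(depth_multiplier = depth_multiplier,
                 min_presence = min_presence, min_minor = min_minor,
                 max_het = max_het, max_breakpoint = max_breakpoint,
                 require_parent_het = require_parent_het,
                 count_both_seen_in_minor = count_both_seen_in_minor),
            class = "filter_config")
}

#' High-depth site mask
#'
#' Masks sites whose total depth (summed over individuals) exceeds
#' `multiplier` times the genome-wide mean per-site total depth. The mean is
#' taken over all site-by-individual cells including zeros, so a single site
#' can never mask itself.
#'
#' @param gm a [genotype_matrix()].
#' @param multiplier depth cap in multiples of the mean (default 4).
#' @return A [site_mask()] with reason `"high_depth"`.
#' @export
depth_mask <- function(gm, multiplier = 4) {
  abort_if(n_sites(gm) == 0L, "empty genotype matrix")
  tot <- rowSums(gm$depths)
  if (all(tot == 0)) {
    warning("all depths are zero; empty depth mask")
    return(site_mask())
  }
  cap <- multiplier * mean(gm$depths) * n_individuals(gm)
  bad <- tot > cap
  if (!any(bad)) return(site_mask())
  site_mask(gm$sites$scaffold[bad], gm$sites$pos[bad] - 1L,
            gm$sites$pos[bad], "high_depth")
}

#' Keep only sites heterozygous in the focal parent
#'
#' Every genuine offspring marker must be heterozygous in the focal parent,
#' since each offspring carries one of that parent's two haplotypes. When no
#' parent genotypes are available (the reference-free mode) the matrix is
#' returned unchanged.
#'
#' @param gm a [genotype_matrix()].
#' @return filtered `genotype_matrix`.
#' @export
parent_informative_filter <- function(gm) {
  if (is.null(gm$parent)) return(gm)
  keep <- !is.na(gm$parent) & gm$parent == "het"
  subset_sites(gm, keep)
}

rule_presence_keep <- function(gm, min_presence) {
  frac <- rowMeans(!is.na(gm$calls))
  frac >= min_presence
}

rule_minor_keep <- function(gm, min_minor, count_both_seen = FALSE) {
  na_ <- rowSums(gm$calls == CALL_A, na.rm = TRUE)
  nb <- rowSums(gm$calls == CALL_B, na.rm = TRUE)
  den <- na_ + nb
  if (count_both_seen) den <- den + rowSums(gm$calls == CALL_BOTH, na.rm = TRUE)
  minor <- ifelse(den > 0, pmin(na_, nb) / den, 0)
  minor >= min_minor
}

rule_het_keep <- function(gm, max_het) {
  # denominator is all individuals, matching "heterozygous in more than 20%
  # of individuals"
  frac <- rowSums(gm$calls == CALL_BOTH, na.rm = TRUE) / n_individuals(gm)
  frac <= max_het
}

#' Presence, allele-balance and heterozygote-excess filters
#'
#' Applies, in order: (1) presence -- fraction of individuals with any call at
#' least `min_presence`; (2) allele balance -- among homozygous-class calls,
#' minor class fraction at least `min_minor`; (3) heterozygote excess --
#' fraction of both-seen individuals at most `max_het`.
#'
#' @param gm a [genotype_matrix()].
#' @param config a [filter_config()].
#' @return list with the filtered `genotypes` and a `report` data frame with
#'   one row per rule.
#' @export
marker_quality_filter <- function(gm, config = filter_config()) {
  report <- list()
  keep <- rule_presence_keep(gm, config$min_presence)
  report[[1L]] <- data.frame(rule = "presence", sites_before = n_sites(gm),
                             sites_removed = sum(!keep))
  gm <- subset_sites(gm, keep)

  keep <- rule_minor_keep(gm, config$min_minor, config$count_both_seen_in_minor)
  report[[2L]] <- data.frame(rule = "allele_balance",
                             sites_before = n_sites(gm),
                             sites_removed = sum(!keep))
  gm <- subset_sites(gm, keep)

  keep <- rule_het_keep(gm, config$max_het)
  report[[3L]] <- data.frame(rule = "het_excess", sites_before = n_sites(gm),
                             sites_removed = sum(!keep))
  gm <- subset_sites(gm, keep)

  rep <- do.call(rbind, report)
  rep$sites_after <- rep$sites_before - rep$sites_removed
  list(genotypes = gm, report = rep)
}

#' Remove recurrent crossover-breakpoint sites
#'
#' A true crossover falls at a different marker in every individual; a site
#' that is the apparent breakpoint in many individuals is a systematic error.
#' Each detected phase switch is attributed to the first informative site of
#' the new run; sites implicated in more than `max_breakpoint` of the
#' phase-informative individuals of their scaffold are removed. Callers should
#' re-phase afterwards.
#'
#' @param gm a [genotype_matrix()].
#' @param phased named list of [phase_scaffold()] results covering `gm`'s
#'   scaffolds.
#' @param max_breakpoint fraction threshold (strict `>`).
#' @return filtered `genotype_matrix`.
#' @export
breakpoint_noise_filter <- function(gm, phased, max_breakpoint = 0.10) {
  keep <- rep(TRUE, n_sites(gm))
  for (ps in phased) {
    on <- gm$sites$scaffold == ps$scaffold_id
    if (!any(on)) next
    n_phased <- sum(ps$n_informative > 0L)
    if (n_phased == 0L) next
    bp_pos <- unlist(lapply(ps$crossovers, function(co) co$right_pos))
    if (!length(bp_pos)) next
    counts <- table(bp_pos)
    bad_pos <- as.numeric(names(counts))[counts / n_phased > max_breakpoint]
    if (length(bad_pos)) {
      keep[on & gm$sites$pos %in% bad_pos] <- FALSE
    }
  }
  subset_sites(gm, keep)
}

#' Full marker-filter cascade
#'
#' Applies, in order: cross-mapped-region mask, high-depth mask,
#' parent-heterozygosity rule, presence, allele balance, heterozygote excess,
#' then a preliminary phasing followed by the recurrent-breakpoint rule and a
#' final re-phasing. Every rule is recorded in an attrition report.
#'
#' @param gm a [genotype_matrix()] (with parent genotypes when available).
#' @param cross_mask optional [site_mask()] of cross-mapped regions.
#' @param config a [filter_config()].
#' @param window,min_switch_support phasing parameters passed to
#'   [phase_scaffold()] for the breakpoint rule and final phasing.
#' @return list with `genotypes` (filtered), `report` (data frame, one row per
#'   rule, columns `rule`, `sites_before`, `sites_removed`, `sites_after`) and
#'   `phased` (final per-scaffold phasing of the retained markers).
#' @export
apply_cascade <- function(gm, cross_mask = NULL, config = filter_config(),
                          window = 20, min_switch_support = 2) {
  rows <- list()
  note <- function(rule, before, removed) {
    rows[[length(rows) + 1L]] <<- data.frame(rule = rule,
                                             sites_before = before,
                                             sites_removed = removed)
  }

  hit <- sites_in_mask(gm, cross_mask)
  note("cross_mapped", n_sites(gm), sum(hit))
  gm <- subset_sites(gm, !hit)

  dm <- if (n_sites(gm) > 0L) depth_mask(gm, config$depth_multiplier)
        else site_mask()
  hit <- sites_in_mask(gm, dm)
  note("high_depth", n_sites(gm), sum(hit))
  gm <- subset_sites(gm, !hit)

  use_parent <- if (is.na(config$require_parent_het)) !is.null(gm$parent)
                else isTRUE(config$require_parent_het) && !is.null(gm$parent)
  before <- n_sites(gm)
  if (use_parent) gm <- parent_informative_filter(gm)
  note("parent_het", before, before - n_sites(gm))

  mq <- marker_quality_filter(gm, config)
  gm <- mq$genotypes
  for (i in seq_len(nrow(mq$report))) {
    note(mq$report$rule[i], mq$report$sites_before[i],
         mq$report$sites_removed[i])
  }

  abort_if(n_sites(gm) == 0L,
           "no markers survive the cascade; consider relaxing thresholds")

  phased <- phase_all(gm, window = window,
                      min_switch_support = min_switch_support)
  before <- n_sites(gm)
  gm <- breakpoint_noise_filter(gm, phased, config$max_breakpoint)
  note("breakpoint_noise", before, before - n_sites(gm))

  abort_if(n_sites(gm) == 0L,
           "no markers survive the cascade; consider relaxing thresholds")
  phased <- phase_all(gm, window = window,
                      min_switch_support = min_switch_support)

  report <- do.call(rbind, rows)
  report$sites_after <- report$sites_before - report$sites_removed
  class(report) <- c("filter_report", "data.frame")
  list(genotypes = gm, report = report, phased = phased)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("marker attrition:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a filter attrition report as TSV
#' @param report the `report` element of [apply_cascade()].
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
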