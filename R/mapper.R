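#' Chain phase matrix
#'
#' Individuals-by-scaffold-ends phase values for one chain, columns in chain
#' order (left-facing end, then right-facing end, of each member) with every
#' member's flip applied so all columns share one labelling. The attribute
#' `scaffold_of` maps columns to member indices.
#'
#' @param chain a `linkage_chain`.
#' @param phased named list of [phase_scaffold()] results.
#' @return integer matrix (individuals x 2*members) with attribute
#'   `scaffold_of`.
#' @export
chain_phase_matrix <- function(chain, phased) {
  names(phased) <- vapply(phased, `[[`, "", "scaffold_id")
  mem <- chain$members
  k <- nrow(mem)
  cols <- vector("list", 2L * k)
  for (i in seq_len(k)) {
    cols[[2L * i - 1L]] <- member_profile(phased, mem$scaffold[i],
                                          mem$internal_orient[i],
                                          mem$flip[i], "left")
    cols[[2L * i]] <- member_profile(phased, mem$scaffold[i],
                                     mem$internal_orient[i],
                                     mem$flip[i], "right")
  }
  m <- do.call(cbind, cols)
  colnames(m) <- paste0(rep(mem$scaffold, each = 2L), c(":L", ":R"))
  attr(m, "scaffold_of") <- rep(seq_len(k), each = 2L)
  m
}

#' Remove phase runs shorter than a minimum scaffold span
#'
#' To exclude false recombination due to noise, phases that do not match
#' continuously for at least `min_run` scaffolds in an individual are set to
#' missing. Runs are measured over non-missing entries only, and their length
#' is counted in scaffolds: the number of distinct scaffolds the run extends
#' over (with `scaffold_of = NULL`, every column counts as one scaffold). A
#' scaffold hosting an internal crossover is reached by the runs on both
#' sides, so a run delimited by crossovers in two scaffolds with one intact
#' scaffold between them spans three scaffolds and survives the default rule,
#' while one- or two-scaffold noise blips are wiped.
#'
#' @param m phase matrix (individuals x ordered columns), values {0,1,NA}.
#' @param min_run minimum run length in scaffolds (default 3).
#' @param scaffold_of optional integer vector mapping columns to scaffolds;
#'   defaults to the matrix's `scaffold_of` attribute, else one scaffold per
#'   column.
#' @return matrix of the same shape; only replaces values with `NA`, never
#'   introduces new phases. Idempotent.
#' @export
eliminate_short_runs <- function(m, min_run = 3, scaffold_of = NULL) {
  abort_if(min_run < 1, "min_run must be >= 1")
  scaffold_of <- scaffold_of %||% attr(m, "scaffold_of") %||% seq_len(ncol(m))
  if (min_run == 1) return(m)
  for (i in seq_len(nrow(m))) {
    v <- m[i, ]
    idx <- which(!is.na(v))
    if (!length(idx)) next
    r <- rle(v[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      cols <- idx[starts[j]:ends[j]]
      n_scaffolds <- length(unique(scaffold_of[cols]))
      if (n_scaffolds < min_run) m[i, cols] <- NA_integer_
    }
  }
  m
}

#' Two-point recombination fraction at a chain junction
#'
#' @param m a (cleaned) [chain_phase_matrix()].
#' @param junction junction index `j` between member `j` and member `j + 1`.
#' @return list `r` (switch fraction, capped at 0.5), `n` (individuals
#'   non-missing on both sides), `flagged` (`TRUE` when `n` is zero or the raw
#'   switch fraction exceeded 0.5).
#' @export
junction_recombination <- function(m, junction) {
  a <- m[, 2L * junction]
  b <- m[, 2L * junction + 1L]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0L) return(list(r = NA_real_, n = 0L, flagged = TRUE))
  raw <- sum(a[ok] != b[ok]) / n
  list(r = min(raw, 0.5), n = n, flagged = raw > 0.5)
}

#' Build a genetic map from chained scaffolds
#'
#' Genetic distance is the sum of two-point distances: across each junction,
#' `100 * r` centimorgans (Morgan additive; with ultra-dense junctions each
#' `r` is small, so mapping-function corrections are negligible -- Haldane's
#' inverse is available behind `haldane = TRUE`), plus a within-scaffold span
#' of `100 * (crossovers summed over individuals) / (phase-informative
#' individuals)`. Physical positions are cumulative scaffold lengths.
#' Junction fractions are computed after [eliminate_short_runs()] noise
#' cleaning.
#'
#' @param chains a `linkage_chain_set` from [chain_scaffolds()].
#' @param phased named list of [phase_scaffold()] results.
#' @param catalog a [scaffold_catalog()].
#' @param min_run noise rule passed to [eliminate_short_runs()].
#' @param haldane use Haldane's mapping function across junctions.
#' @return A `linkage_map`: list with `map` (one row per placed scaffold:
#'   group, order_index, scaffold, orientation, start_cM, end_cM, within_cM,
#'   junction_r, junction_n, start_bp, end_bp) and `groups` (per group totals:
#'   n_scaffolds, total_cM, junction_cM, within_cM, physical_bp).
#' @export
build_map <- function(chains, phased, catalog, min_run = 3, haldane = FALSE) {
  names(phased) <- vapply(phased, `[[`, "", "scaffold_id")
  map_rows <- list()
  grp_rows <- list()
  for (g in seq_along(chains)) {
    ch <- chains[[g]]
    mem <- ch$members
    k <- nrow(mem)
    group <- sprintf("LG%03d", g)
    m <- chain_phase_matrix(ch, phased)
    mc <- eliminate_short_runs(m, min_run = min_run)
    within <- vapply(mem$scaffold, function(s) {
      ps <- phased[[s]]
      n_inf <- sum(ps$n_informative > 0L)
      if (n_inf == 0L) 0 else 100 * sum(ps$n_crossovers) / n_inf
    }, 0)
    jr <- rep(NA_real_, k)
    jn <- rep(NA_integer_, k)
    d <- rep(0, k) # junction distance entering member i
    if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        jx <- junction_recombination(mc, j)
        jr[j + 1L] <- jx$r
        jn[j + 1L] <- jx$n
        rj <- if (is.na(jx$r)) 0 else jx$r
        d[j + 1L] <- if (haldane && rj < 0.5) -50 * log(1 - 2 * rj)
                     else 100 * rj
      }
    }
    start_cM <- numeric(k)
    end_cM <- numeric(k)
    pos <- 0
    lens <- scaffold_length(catalog, mem$scaffold)
    start_bp <- cumsum(c(0, lens[-k])) + 1
    end_bp <- cumsum(lens)
    for (i in seq_len(k)) {
      pos <- pos + d[i]
      start_cM[i] <- pos
      pos <- pos + within[i]
      end_cM[i] <- pos
    }
    map_rows[[g]] <- data.frame(group = group, order_index = seq_len(k),
                                scaffold = mem$scaffold,
                                orientation = mem$orientation,
                                start_cM = start_cM, end_cM = end_cM,
                                within_cM = within, junction_r = jr,
                                junction_n = jn, start_bp = start_bp,
                                end_bp = end_bp, stringsAsFactors = FALSE)
    grp_rows[[g]] <- data.frame(group = group, n_scaffolds = k,
                                total_cM = end_cM[k],
                                junction_cM = sum(d),
                                within_cM = sum(within),
                                physical_bp = sum(lens),
                                stringsAsFactors = FALSE)
  }
  structure(list(map = do.call(rbind, map_rows),
                 groups = do.call(rbind, grp_rows), min_run = min_run),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("linkage_map: %d groups, %d scaffolds, %.1f cM, %.0f bp\n",
              nrow(x$groups), sum(x$groups$n_scaffolds),
              sum(x$groups$total_cM), sum(x$groups$physical_bp)))
  invisible(x)
}

#' Detected crossovers per individual along a chain
#'
#' Counts phase switches between consecutive non-missing entries of each
#' individual's noise-cleaned phase sequence along the chain (covering both
#' within-scaffold and junction switches).
#'
#' @param chain a `linkage_chain`.
#' @param phased named list of [phase_scaffold()] results.
#' @param min_run see [eliminate_short_runs()].
#' @return integer vector of crossover counts per individual.
#' @export
detected_crossovers <- function(chain, phased, min_run = 3) {
  m <- chain_phase_matrix(chain, phased)
  mc <- eliminate_short_runs(m, min_run = min_run)
  apply(mc, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(0L)
    sum(v[-1L] != v[-length(v)])
  })
}

#' Write the map table and per-group totals as TSV
#'
#' `path` receives the per-scaffold map rows; totals (both with and without
#' the within-scaffold contribution) go to `groups_path` when given.
#'
#' @param map a `linkage_map`.
#' @param path output TSV.
#' @param groups_path optional TSV for the per-group totals.
#' @export
write_map_table <- function(map, path, groups_path = NULL) {
  tab <- map$map[order(map$map$group, map$map$order_index), ]
  utils::write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  if (!is.null(groups_path)) {
    utils::write.table(map$groups, groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  }
  invisible(path)
}
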