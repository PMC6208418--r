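# Phasing works per scaffold. Each marker's (allele_a, allele_b) pair maps
# onto the focal parent's haplotype labels (0, 1) with an unknown sign, and
# the per-scaffold labelling itself is arbitrary: all downstream consumers
# are invariant to a global 0/1 swap.

#' Orient marker sites along a scaffold
#'
#' Sequential greedy orientation: the first site is assigned sign `+`; each
#' subsequent site receives the sign that maximises, across individuals
#' covered at both, agreement between its oriented calls and the per-individual
#' majority oriented call over the previous `window` sites. Ties choose `+`.
#' A site sharing no covered individual with its window is assigned `+` and
#' flagged low-confidence.
#'
#' @param calls integer matrix (sites x individuals) of calls in {0,1,2,NA};
#'   both-seen (2) is uninformative for transmission.
#' @param window number of preceding sites consulted (default 20, wide enough
#'   to bridge sparse coverage at ~1.8x depth).
#' @return list with `sign` (`"+"`/`"-"` per site), `oriented` (sites x
#'   individuals matrix over {0,1,NA} with signs applied) and
#'   `low_confidence` (logical per site).
#' @export
orient_sites <- function(calls, window = 20) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  abort_if(n < 1L, "orient_sites needs at least one site")
  m <- ncol(calls)
  V <- matrix(NA_integer_, n, m)
  sign <- rep(1L, n)
  low_conf <- logical(n)
  v <- calls[1L, ]
  v[!is.na(v) & v == CALL_BOTH] <- NA_integer_
  V[1L, ] <- v
  if (n > 1L) {
    for (j in 2:n) {
      v <- calls[j, ]
      v[!is.na(v) & v == CALL_BOTH] <- NA_integer_
      win <- V[max(1L, j - window):(j - 1L), , drop = FALSE]
      ones <- colSums(win == 1L, na.rm = TRUE)
      zeros <- colSums(win == 0L, na.rm = TRUE)
      maj <- ifelse(ones > zeros, 1L, ifelse(zeros > ones, 0L, NA_integer_))
      ok <- !is.na(v) & !is.na(maj)
      if (!any(ok)) {
        low_conf[j] <- TRUE
        V[j, ] <- v
        next
      }
      agree_plus <- sum(v[ok] == maj[ok])
      agree_minus <- sum(ok) - agree_plus
      if (agree_minus > agree_plus) {
        sign[j] <- -1L
        V[j, ] <- 1L - v
      } else {
        V[j, ] <- v
      }
    }
  }
  list(sign = ifelse(sign > 0L, "+", "-"), oriented = V,
       low_confidence = low_conf)
}

#' Phase one individual along one scaffold
#'
#' Segments the individual's oriented calls into runs of constant transmitted
#' haplotype. A phase switch is accepted only when at least
#' `min_switch_support` consecutive informative calls support the new phase;
#' shorter discordant runs are rewritten to missing (single-read errors are
#' expected, since markers are typed from as little as one read). Missing
#' calls inside a run are imputed to the run's phase -- phase is successive
#' except around crossover points. The midpoint between the flanking
#' informative positions of consecutive runs is reported as the crossover
#' position.
#'
#' @param x integer vector over sites in {0,1,NA}: oriented calls of one
#'   individual, positional order.
#' @param pos numeric vector of 1-based bp positions, same length.
#' @param min_switch_support minimum consecutive informative calls to accept a
#'   phase switch (default 2).
#' @return list with `phase` (per-site {0,1,NA} after smoothing/imputation),
#'   `head`, `tail` (first/last run phase, NA when no informative call),
#'   `crossovers` (data frame `left_pos`, `right_pos`, `mid`) and
#'   `n_informative`.
#' @export
phase_individual <- function(x, pos, min_switch_support = 2) {
  n <- length(x)
  inf <- which(!is.na(x))
  empty <- list(phase = rep(NA_integer_, n), head = NA_integer_,
                tail = NA_integer_,
                crossovers = data.frame(left_pos = numeric(0),
                                        right_pos = numeric(0),
                                        mid = numeric(0)),
                n_informative = 0L)
  if (!length(inf)) return(empty)
  y <- x[inf]
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_switch_support
  if (!any(keep)) {
    # no run reaches the support floor: fall back to the majority phase
    # (covers scaffolds with a single informative site)
    val <- majority_value(y)
    if (is.na(val)) val <- y[1L]
    vals <- val
    st <- 1L
    en <- length(y)
  } else {
    vals <- r$values[keep]
    st <- starts[keep]
    en <- ends[keep]
    # merge adjacent surviving runs with equal phase
    if (length(vals) > 1L) {
      grp <- cumsum(c(TRUE, vals[-1L] != vals[-length(vals)]))
      st <- tapply(st, grp, min)
      en <- tapply(en, grp, max)
      vals <- vals[!duplicated(grp)]
      st <- as.integer(st)
      en <- as.integer(en)
    }
  }
  k <- length(vals)
  phase <- rep(NA_integer_, n)
  for (i in seq_len(k)) {
    from <- if (i == 1L) 1L else inf[st[i]]
    to <- if (i == k) n else inf[en[i]]
    phase[from:to] <- vals[i]
  }
  # observed calls conflicting with their covering run are errors -> missing
  conflict <- !is.na(x) & !is.na(phase) & x != phase
  phase[conflict] <- NA_integer_
  crossovers <- if (k > 1L) {
    lp <- pos[inf[en[-k]]]
    rp <- pos[inf[st[-1L]]]
    data.frame(left_pos = lp, right_pos = rp, mid = (lp + rp) / 2)
  } else {
    empty$crossovers
  }
  list(phase = phase, head = vals[1L], tail = vals[k],
       crossovers = crossovers, n_informative = length(inf))
}

#' Phase all individuals of one scaffold
#'
#' Orients the scaffold's sites, then phases every individual and extracts the
#' head/tail end-phase profiles used for linkage. The 0/1 labelling is
#' arbitrary per scaffold.
#'
#' @param gm a [genotype_matrix()] (only rows of `scaffold_id` are used).
#' @param scaffold_id scaffold to phase; default: the only scaffold in `gm`.
#' @param window see [orient_sites()].
#' @param min_switch_support see [phase_individual()].
#' @return A `phased_scaffold`: list with `scaffold_id`, `sign`, `pos`,
#'   `phase` (sites x individuals), `head`, `tail` (per-individual profiles),
#'   `crossovers` (list per individual), `n_crossovers`, `n_informative`
#'   (per-individual informative-call counts), `n_sites` and `sample_ids`.
#' @export
phase_scaffold <- function(gm, scaffold_id = NULL, window = 20,
                           min_switch_support = 2) {
  if (is.null(scaffold_id)) {
    u <- unique(gm$sites$scaffold)
    abort_if(length(u) != 1L,
             "scaffold_id must be given when gm spans several scaffolds")
    scaffold_id <- u
  }
  on <- which(gm$sites$scaffold == scaffold_id)
  abort_if(!length(on), "no sites on scaffold %s", scaffold_id)
  calls <- gm$calls[on, , drop = FALSE]
  pos <- gm$sites$pos[on]
  ori <- orient_sites(calls, window = window)
  m <- ncol(calls)
  phase <- matrix(NA_integer_, length(on), m)
  head_p <- rep(NA_integer_, m)
  tail_p <- rep(NA_integer_, m)
  n_inf <- integer(m)
  n_co <- integer(m)
  crossovers <- vector("list", m)
  for (i in seq_len(m)) {
    tr <- phase_individual(ori$oriented[, i], pos,
                           min_switch_support = min_switch_support)
    phase[, i] <- tr$phase
    head_p[i] <- tr$head
    tail_p[i] <- tr$tail
    n_inf[i] <- tr$n_informative
    n_co[i] <- nrow(tr$crossovers)
    crossovers[[i]] <- tr$crossovers
  }
  structure(list(scaffold_id = scaffold_id, sign = ori$sign,
                 low_confidence = ori$low_confidence, pos = pos,
                 phase = phase, head = head_p, tail = tail_p,
                 crossovers = crossovers, n_crossovers = n_co,
                 n_informative = n_inf, n_sites = length(on),
                 sample_ids = gm$sample_ids),
            class = "phased_scaffold")
}

#' Phase every scaffold of a genotype matrix
#'
#' @inheritParams phase_scaffold
#' @return named list of `phased_scaffold` objects, in the order scaffolds
#'   appear in `gm`.
#' @export
phase_all <- function(gm, window = 20, min_switch_support = 2) {
  scaffolds <- unique(gm$sites$scaffold)
  out <- lapply(scaffolds, function(s) {
    phase_scaffold(gm, s, window = window,
                   min_switch_support = min_switch_support)
  })
  names(out) <- scaffolds
  out
}

#' @export
print.phased_scaffold <- function(x, ...) {
  cat(sprintf("phased_scaffold %s: %d sites, %d/%d individuals informative, %d crossovers\n",
              x$scaffold_id, x$n_sites, sum(x$n_informative > 0L),
              length(x$sample_ids), sum(x$n_crossovers)))
  invisible(x)
}

#' Write per-scaffold, per-individual phase table
#'
#' One row per scaffold x individual with the head/tail end phases and the
#' comma-separated crossover midpoints. This table is sufficient to drive
#' chaining and mapping, so pipeline stages can be resumed from it.
#'
#' @param phased named list of [phase_scaffold()] results.
#' @param path output TSV path.
#' @export
write_phase_table <- function(phased, path) {
  rows <- lapply(phased[order(names(phased))], function(ps) {
    data.frame(scaffold = ps$scaffold_id, individual = ps$sample_ids,
               head_phase = ps$head, tail_phase = ps$tail,
               crossovers = vapply(ps$crossovers, function(co) {
                 paste(co$mid, collapse = ",")
               }, ""),
               n_crossovers = ps$n_crossovers,
               n_informative = ps$n_informative,
               n_sites = ps$n_sites,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Read a phase table back into minimal phased-scaffold objects
#'
#' The result carries end profiles and crossover counts (what chaining and
#' mapping need) but not per-site phase matrices.
#'
#' @param path a TSV written by [write_phase_table()].
#' @return named list of `phased_scaffold` objects.
#' @export
read_phase_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                           stringsAsFactors = FALSE,
                           colClasses = c(scaffold = "character",
                                          individual = "character",
                                          crossovers = "character"))
  out <- lapply(split(tab, tab$scaffold), function(d) {
    structure(list(scaffold_id = d$scaffold[1L],
                   head = as.integer(d$head_phase),
                   tail = as.integer(d$tail_phase),
                   crossovers = lapply(d$crossovers, function(s) {
                     mids <- if (is.na(s) || s == "") numeric(0)
                             else as.numeric(strsplit(s, ",")[[1L]])
                     data.frame(left_pos = rep(NA_real_, length(mids)),
                                right_pos = rep(NA_real_, length(mids)),
                                mid = mids)
                   }),
                   n_crossovers = as.integer(d$n_crossovers),
                   n_informative = as.integer(d$n_informative),
                   n_sites = d$n_sites[1L],
                   sample_ids = d$individual),
              class = "phased_scaffold")
  })
  out[order(names(out))]
}
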