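# Fixture builders and independent brute-force oracles. Oracles deliberately
# use naive per-site / per-pair loops so they share no code with the package
# implementations they check.

# compact genotype matrix builder: calls is sites x individuals (0/1/2/NA)
make_gm <- function(calls, depths = NULL, pos = NULL, scaffold = "s1",
                    parent = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls)
  if (is.null(depths)) {
    depths <- ifelse(is.na(calls), 0L, ifelse(calls == 2L, 2L, 1L))
  }
  if (is.null(pos)) pos <- seq_len(n) * 100L
  sites <- data.frame(scaffold = rep_len(scaffold, n), pos = pos,
                      allele_a = "A", allele_b = "C",
                      stringsAsFactors = FALSE)
  genotype_matrix(sites, calls, depths,
                  sample_ids = sprintf("i%02d", seq_len(ncol(calls))),
                  parent = parent)
}

random_gm <- function(n_sites, n_ind, p_missing = 0.3, p_both = 0.1,
                      parent = FALSE) {
  calls <- matrix(sample(c(NA, 0L, 1L, 2L), n_sites * n_ind, replace = TRUE,
                         prob = c(p_missing, (1 - p_missing - p_both) / 2,
                                  (1 - p_missing - p_both) / 2, p_both)),
                  n_sites, n_ind)
  depths <- matrix(rpois(n_sites * n_ind, 2) + ifelse(is.na(calls), 0L, 1L),
                   n_sites, n_ind)
  depths[!is.na(calls) & calls == 2L] <-
    pmax(depths[!is.na(calls) & calls == 2L], 2L)
  depths[is.na(calls)] <- 0L
  make_gm(calls, depths,
          parent = if (parent) sample(c("het", "hom_a", "hom_b", NA),
                                      n_sites, replace = TRUE,
                                      prob = c(0.7, 0.1, 0.1, 0.1)))
}

# ---- naive filter oracles (site-by-site loops) -------------------------

naive_presence_removed <- function(gm, min_presence) {
  out <- 0L
  for (i in seq_len(nrow(gm$calls))) {
    frac <- sum(!is.na(gm$calls[i, ])) / length(gm$sample_ids)
    if (frac < min_presence) out <- out + 1L
  }
  out
}

naive_minor_removed <- function(gm, min_minor) {
  out <- 0L
  for (i in seq_len(nrow(gm$calls))) {
    x <- gm$calls[i, ]
    a <- sum(x == 0L, na.rm = TRUE)
    b <- sum(x == 1L, na.rm = TRUE)
    frac <- if (a + b == 0L) 0 else min(a, b) / (a + b)
    if (frac < min_minor) out <- out + 1L
  }
  out
}

naive_het_removed <- function(gm, max_het) {
  out <- 0L
  for (i in seq_len(nrow(gm$calls))) {
    frac <- sum(gm$calls[i, ] == 2L, na.rm = TRUE) / length(gm$sample_ids)
    if (frac > max_het) out <- out + 1L
  }
  out
}

naive_depth_removed <- function(gm, multiplier) {
  tot <- numeric(nrow(gm$depths))
  for (i in seq_len(nrow(gm$depths))) tot[i] <- sum(gm$depths[i, ])
  cap <- multiplier * mean(tot)
  sum(tot > cap)
}

naive_parent_removed <- function(gm) {
  if (is.null(gm$parent)) return(0L)
  sum(is.na(gm$parent) | gm$parent != "het")
}

# ---- phased-scaffold builders ------------------------------------------

# minimal phased_scaffold from explicit end profiles
make_phased <- function(id, head, tail, n_crossovers = NULL, n_sites = 10L) {
  if (is.null(n_crossovers)) {
    n_crossovers <- ifelse(!is.na(head) & !is.na(tail) & head != tail, 1L, 0L)
  }
  structure(list(scaffold_id = id, head = as.integer(head),
                 tail = as.integer(tail),
                 crossovers = lapply(n_crossovers, function(k) {
                   data.frame(left_pos = rep(NA_real_, k),
                              right_pos = rep(NA_real_, k),
                              mid = rep(NA_real_, k))
                 }),
                 n_crossovers = as.integer(n_crossovers),
                 n_informative = ifelse(is.na(head) & is.na(tail), 0L, 5L),
                 n_sites = n_sites,
                 sample_ids = sprintf("i%03d", seq_along(head))),
            class = "phased_scaffold")
}

# simulate true end-phase profiles for k scaffolds along one chromosome:
# a Markov chain over 2k ordered ends with switch probability r_between
# across junctions and r_within inside scaffolds; returns profiles in true
# orientation plus scrambled phased_scaffold objects and the truth.
markov_scaffold_profiles <- function(k, n_ind, r_within = 0.15,
                                     r_between = 0.03, scramble = TRUE) {
  ends <- matrix(NA_integer_, n_ind, 2L * k)
  for (i in seq_len(n_ind)) {
    v <- integer(2L * k)
    v[1L] <- rbinom(1L, 1L, 0.5)
    for (j in 2:(2L * k)) {
      r <- if (j %% 2L == 0L) r_within else r_between
      v[j] <- if (runif(1L) < r) 1L - v[j - 1L] else v[j - 1L]
    }
    ends[i, ] <- v
  }
  ids <- sprintf("mk%02d", seq_len(k))
  flip <- if (scramble) runif(k) < 0.5 else rep(FALSE, k)
  revd <- if (scramble) runif(k) < 0.5 else rep(FALSE, k)
  phased <- lapply(seq_len(k), function(s) {
    h <- ends[, 2L * s - 1L]
    t <- ends[, 2L * s]
    if (revd[s]) { tmp <- h; h <- t; t <- tmp }
    if (flip[s]) { h <- 1L - h; t <- 1L - t }
    make_phased(ids[s], h, t)
  })
  names(phased) <- ids
  list(phased = phased, ends = ends, ids = ids, flip = flip, reversed = revd)
}

# exhaustive oracle: maximum total flip-maximised junction concordance over
# all scaffold orders and orientations (orders identified up to reversal)
exhaustive_chain_oracle <- function(phased) {
  k <- length(phased)
  ids <- names(phased)
  # rate table between all 2k ends
  prof <- list()
  for (s in seq_len(k)) {
    prof[[2L * s - 1L]] <- phased[[s]]$head
    prof[[2L * s]] <- phased[[s]]$tail
  }
  rate <- matrix(NA_real_, 2L * k, 2L * k)
  for (a in seq_len(2L * k)) {
    for (b in seq_len(2L * k)) {
      ok <- !is.na(prof[[a]]) & !is.na(prof[[b]])
      if (!sum(ok)) next
      raw <- sum(prof[[a]][ok] == prof[[b]][ok]) / sum(ok)
      rate[a, b] <- max(raw, 1 - raw)
    }
  }
  perms <- permutations_of(seq_len(k))
  best <- -Inf
  best_cfg <- NULL
  for (p in perms) {
    for (mask in 0:(2^k - 1)) {
      orient <- bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L)
      tot <- 0
      for (j in seq_len(k - 1L)) {
        # right-facing end of member j meets left-facing end of member j+1
        ra <- 2L * p[j] - orient[j]        # tail if +, head if -
        rb <- 2L * p[j + 1L] - 1L + orient[j + 1L]
        tot <- tot + rate[ra, rb]
      }
      if (tot > best + 1e-12) {
        best <- tot
        best_cfg <- list(order = p, orient = orient)
      }
    }
  }
  list(total = best, order = best_cfg$order, orient = best_cfg$orient)
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# total junction concordance of a chain result, recomputed from profiles
chain_total_concordance <- function(chains, phased) {
  tot <- 0
  for (ch in chains) {
    if (nrow(ch$members) < 2L) next
    tot <- tot + sum(ch$junctions$rate)
  }
  tot
}

# chromosome-of-scaffold lookup for sim truth
sim_chrom_of <- function(sim, ids) {
  sim$truth$scaffolds$chrom[match(ids, sim$truth$scaffolds$scaffold)]
}
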