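# Chaining vocabulary: a chain is written left-to-right. A member with
# internal orientation "+" has its head end facing left; "-" has its tail
# facing left. `flip` records whether the member's arbitrary 0/1 phase
# labels were complemented to match the chain's labelling.

#' End-phase concordance between two profiles
#'
#' The raw rate is the fraction of individuals, non-missing in both profiles,
#' whose phases agree. Because each scaffold's 0/1 labelling is arbitrary, the
#' reported rate is flip-maximised: `rate = max(raw, 1 - raw)`. Two ends of
#' completely linked scaffolds give rate 1; unlinked ends give a raw rate near
#' 50%.
#'
#' @param a,b integer profiles over the same individuals, values {0,1,NA}.
#' @param min_informative minimum overlapping individuals for the result to be
#'   usable (default 20; below this the rate is too noisy to act on).
#' @return A `concordance` list: `rate`, `raw_rate`, `flip`, `n_informative`,
#'   `usable`.
#' @export
end_concordance <- function(a, b, min_informative = 20) {
  abort_if(length(a) != length(b), "profiles must cover the same individuals")
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0L) {
    return(structure(list(rate = NA_real_, raw_rate = NA_real_, flip = NA,
                          n_informative = 0L, usable = FALSE),
                     class = "concordance"))
  }
  raw <- sum(a[ok] == b[ok]) / n
  structure(list(rate = max(raw, 1 - raw), raw_rate = raw,
                 flip = (1 - raw) > raw, n_informative = n,
                 usable = n >= min_informative),
            class = "concordance")
}

# head/tail profile matrices (individuals x scaffolds) for a phased set
profile_matrices <- function(phased) {
  ids <- vapply(phased, `[[`, "", "scaffold_id")
  H <- vapply(phased, `[[`, integer(length(phased[[1L]]$head)), "head")
  T_ <- vapply(phased, `[[`, integer(length(phased[[1L]]$tail)), "tail")
  colnames(H) <- colnames(T_) <- ids
  list(H = H, T = T_)
}

# vectorised concordance of one profile against every column of M
score_profile <- function(p, M) {
  nn <- colSums(!is.na(M) & !is.na(p))
  ag <- colSums(M == p, na.rm = TRUE)
  raw <- ifelse(nn > 0L, ag / nn, NA_real_)
  list(raw = raw, rate = pmax(raw, 1 - raw), n = nn)
}

# outward-facing (left/right) profiles of a member row, flips applied
member_profile <- function(phased, id, orient, flip, side) {
  ps <- phased[[id]]
  p <- if (side == "left") {
    if (orient == "+") ps$head else ps$tail
  } else {
    if (orient == "+") ps$tail else ps$head
  }
  if (flip) flip_phase(p) else p
}

#' Resolve the reportable orientation of a placed scaffold
#'
#' A scaffold can only be oriented if at least one individual has a crossover
#' inside it, i.e. its two end-phase profiles differ somewhere both are
#' informative. Otherwise the two ends are indistinguishable and the
#' orientation is reported as `"?"`.
#'
#' @param ps a `phased_scaffold`.
#' @param internal_orient the geometric orientation chosen during chaining.
#' @return `"+"`, `"-"` or `"?"`.
#' @export
resolve_orientation <- function(ps, internal_orient = "+") {
  ok <- !is.na(ps$head) & !is.na(ps$tail)
  if (!any(ok) || all(ps$head[ok] == ps$tail[ok])) return("?")
  internal_orient
}

#' Greedily chain scaffolds into linkage groups
#'
#' Seeds a chain from the longest unplaced scaffold, then repeatedly evaluates
#' the flip-maximised end concordance between the chain's two live end
#' profiles and both ends of every unplaced scaffold, attaching the best pair
#' whose rate meets `threshold` (and whose overlap meets `min_informative`).
#' When the chain can no longer grow, the next chain is seeded from the
#' longest remaining scaffold. Ties are broken deterministically: larger
#' overlap, then longer scaffold, then scaffold id, then end.
#'
#' @param phased named list of [phase_scaffold()] results.
#' @param catalog a [scaffold_catalog()] supplying lengths (used for the
#'   descending-length seeding order).
#' @param threshold minimum junction concordance rate (default 0.90; 0.70 is
#'   the documented alternative for high-recombination parents).
#' @param min_informative minimum individuals informative at both ends of a
#'   junction (default 20).
#' @return A `linkage_chain_set`: list of chains, each with `members`
#'   (data frame `scaffold`, `orientation` in {+,-,?}, `internal_orient`,
#'   `flip`) and `junctions` (data frame `rate`, `raw_rate`, `n`, `flip`).
#' @export
chain_scaffolds <- function(phased, catalog, threshold = 0.90,
                            min_informative = 20) {
  abort_if(length(phased) == 0L, "no phased scaffolds")
  names(phased) <- vapply(phased, `[[`, "", "scaffold_id")
  pm <- profile_matrices(phased)
  ids <- colnames(pm$H)
  len <- scaffold_length(catalog, ids)
  names(len) <- ids
  unplaced <- ids[order(-len, ids)]
  chains <- list()

  while (length(unplaced)) {
    seed <- unplaced[1L]
    unplaced <- unplaced[-1L]
    members <- data.frame(scaffold = seed, internal_orient = "+",
                          flip = FALSE, stringsAsFactors = FALSE)
    junctions <- data.frame(rate = numeric(0), raw_rate = numeric(0),
                            n = integer(0), flip = logical(0))
    repeat {
      if (!length(unplaced)) break
      Hu <- pm$H[, unplaced, drop = FALSE]
      Tu <- pm$T[, unplaced, drop = FALSE]
      first <- members[1L, ]
      last <- members[nrow(members), ]
      pL <- member_profile(phased, first$scaffold, first$internal_orient,
                           first$flip, "left")
      pR <- member_profile(phased, last$scaffold, last$internal_orient,
                           last$flip, "right")
      cand <- list()
      for (side in c("R", "L")) {
        p <- if (side == "R") pR else pL
        for (end in c("head", "tail")) {
          sc <- score_profile(p, if (end == "head") Hu else Tu)
          cand[[paste(side, end)]] <- data.frame(
            scaffold = unplaced, side = side, end = end, raw = sc$raw,
            rate = sc$rate, n = sc$n, stringsAsFactors = FALSE)
        }
      }
      cand <- do.call(rbind, cand)
      cand <- cand[!is.na(cand$rate) & cand$n >= min_informative &
                     cand$rate >= threshold, , drop = FALSE]
      if (!nrow(cand)) break
      ord <- order(-cand$rate, -cand$n, -len[cand$scaffold], cand$scaffold,
                   cand$end)
      b <- cand[ord[1L], ]
      flip <- (1 - b$raw) > b$raw
      if (b$side == "R") {
        # appending: the candidate's attaching end faces left in chain coords
        orient <- if (b$end == "head") "+" else "-"
        members <- rbind(members,
                         data.frame(scaffold = b$scaffold,
                                    internal_orient = orient, flip = flip,
                                    stringsAsFactors = FALSE))
        junctions <- rbind(junctions,
                           data.frame(rate = b$rate, raw_rate = b$raw,
                                      n = b$n, flip = flip))
      } else {
        # prepending: the attaching end faces right in chain coords
        orient <- if (b$end == "tail") "+" else "-"
        members <- rbind(data.frame(scaffold = b$scaffold,
                                    internal_orient = orient, flip = flip,
                                    stringsAsFactors = FALSE),
                         members)
        junctions <- rbind(data.frame(rate = b$rate, raw_rate = b$raw,
                                      n = b$n, flip = flip),
                           junctions)
      }
      unplaced <- setdiff(unplaced, b$scaffold)
    }
    members$orientation <- vapply(seq_len(nrow(members)), function(i) {
      resolve_orientation(phased[[members$scaffold[i]]],
                          members$internal_orient[i])
    }, "")
    chains[[length(chains) + 1L]] <- structure(
      list(members = members[, c("scaffold", "orientation",
                                 "internal_orient", "flip")],
           junctions = junctions),
      class = "linkage_chain")
  }
  structure(chains, class = "linkage_chain_set", threshold = threshold,
            min_informative = min_informative)
}

#' @export
print.linkage_chain_set <- function(x, ...) {
  sizes <- vapply(x, function(ch) nrow(ch$members), 1L)
  cat(sprintf("linkage_chain_set: %d chains (%d non-singleton), %d scaffolds placed\n",
              length(x), sum(sizes > 1L), sum(sizes)))
  invisible(x)
}

#' Write / read the chain table
#'
#' One row per placed scaffold: group, order within group, orientation,
#' internal bookkeeping (geometric orientation and phase flip) and the
#' concordance of the junction to the preceding member.
#'
#' @param chains a `linkage_chain_set`.
#' @param path TSV path.
#' @export
write_chain_table <- function(chains, path) {
  rows <- lapply(seq_along(chains), function(g) {
    ch <- chains[[g]]
    k <- nrow(ch$members)
    data.frame(group = sprintf("LG%03d", g), order_index = seq_len(k),
               scaffold = ch$members$scaffold,
               orientation = ch$members$orientation,
               internal_orient = ch$members$internal_orient,
               flip = ch$members$flip,
               junction_rate = c(NA, ch$junctions$rate),
               junction_n = c(NA, ch$junctions$n),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' @rdname write_chain_table
#' @export
read_chain_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                           stringsAsFactors = FALSE,
                           colClasses = c(scaffold = "character",
                                          orientation = "character",
                                          internal_orient = "character"))
  chains <- lapply(split(tab, tab$group), function(d) {
    d <- d[order(d$order_index), ]
    structure(list(members = data.frame(scaffold = d$scaffold,
                                        orientation = d$orientation,
                                        internal_orient = d$internal_orient,
                                        flip = as.logical(d$flip),
                                        stringsAsFactors = FALSE),
                   junctions = data.frame(rate = d$junction_rate[-1L],
                                          raw_rate = rep(NA_real_,
                                                         nrow(d) - 1L),
                                          n = d$junction_n[-1L],
                                          flip = rep(NA, nrow(d) - 1L))),
              class = "linkage_chain")
  })
  structure(unname(chains[order(names(chains))]), class = "linkage_chain_set")
}
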