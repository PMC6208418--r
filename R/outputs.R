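#' Write chains as an AGP 2.1 file
#'
#' One object per linkage group. Scaffold components are type `W` with their
#' chain orientation (`?` for unorientable members); junction gaps are type
#' `N` with `gap_type` "contig" and `linkage` "no".
#'
#' @param chains a `linkage_chain_set`.
#' @param catalog a [scaffold_catalog()].
#' @param path output path.
#' @param gap junction gap size in bp between joined scaffolds (default 100).
#' @export
write_agp <- function(chains, catalog, path, gap = 100) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (g in seq_along(chains)) {
    mem <- chains[[g]]$members
    obj <- sprintf("LG%03d", g)
    beg <- 1
    part <- 1L
    for (i in seq_len(nrow(mem))) {
      len <- scaffold_length(catalog, mem$scaffold[i])
      writeLines(paste(obj, format(beg, scientific = FALSE),
                       format(beg + len - 1, scientific = FALSE), part, "W",
                       mem$scaffold[i], 1,
                       format(len, scientific = FALSE),
                       mem$orientation[i], sep = "\t"), con)
      beg <- beg + len
      part <- part + 1L
      if (i < nrow(mem) && gap > 0) {
        writeLines(paste(obj, format(beg, scientific = FALSE),
                         format(beg + gap - 1, scientific = FALSE), part, "N",
                         gap, "contig", "no", "na", sep = "\t"), con)
        beg <- beg + gap
        part <- part + 1L
      }
    }
  }
  invisible(path)
}

#' Write extended (chromosome-scale) FASTA from chains
#'
#' Each linkage group becomes one record: oriented members contribute their
#' sequence (reverse-complemented for `-`), unoriented members are filled with
#' an N-run over their full length (their internal sequence order cannot be
#' trusted), and junctions are fixed-size N-runs.
#'
#' @param chains a `linkage_chain_set`.
#' @param sequences a [Biostrings::DNAStringSet] of scaffold sequences.
#' @param path output path.
#' @param gap junction gap size in bp (default 100).
#' @param keep_unoriented_sequence emit unoriented members' sequence as-is
#'   (in the geometric orientation chosen by chaining) instead of Ns.
#' @export
write_extended_fasta <- function(chains, sequences, path, gap = 100,
                                 keep_unoriented_sequence = FALSE) {
  names(sequences) <- sub("\\s.*$", "", names(sequences))
  need <- unique(unlist(lapply(chains, function(ch) ch$members$scaffold)))
  missing <- setdiff(need, names(sequences))
  abort_if(length(missing) > 0L,
           "chained scaffold(s) absent from sequence file: %s",
           paste(missing, collapse = ", "))
  out <- Biostrings::DNAStringSet()
  for (g in seq_along(chains)) {
    mem <- chains[[g]]$members
    parts <- character(0)
    for (i in seq_len(nrow(mem))) {
      s <- sequences[[mem$scaffold[i]]]
      ori <- mem$orientation[i]
      if (ori == "?" && keep_unoriented_sequence) ori <- mem$internal_orient[i]
      piece <- switch(ori,
                      "+" = as.character(s),
                      "-" = as.character(Biostrings::reverseComplement(s)),
                      strrep("N", length(s)))
      parts <- c(parts, piece)
      if (i < nrow(mem) && gap > 0) parts <- c(parts, strrep("N", gap))
    }
    rec <- Biostrings::DNAStringSet(paste(parts, collapse = ""))
    names(rec) <- sprintf("LG%03d", g)
    out <- c(out, rec)
  }
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Write the full set of pipeline outputs
#'
#' Emits the phase table, chain table, map table (+ per-group totals), AGP
#' and, when sequences are supplied, the extended FASTA, into `dir` with
#' fixed file names. All writers are deterministic.
#'
#' @param phased named list of [phase_scaffold()] results.
#' @param chains a `linkage_chain_set`.
#' @param map a `linkage_map`.
#' @param catalog a [scaffold_catalog()].
#' @param dir output directory (created if needed).
#' @param sequences optional [Biostrings::DNAStringSet] scaffold sequences.
#' @param gap junction gap size in bp.
#' @param keep_unoriented_sequence see [write_extended_fasta()].
#' @return named character vector of written paths, invisibly.
#' @export
write_outputs <- function(phased, chains, map, catalog, dir,
                          sequences = NULL, gap = 100,
                          keep_unoriented_sequence = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(phases = file.path(dir, "phases.tsv"),
             chains = file.path(dir, "chains.tsv"),
             map = file.path(dir, "map.tsv"),
             groups = file.path(dir, "map_groups.tsv"),
             agp = file.path(dir, "assembly.agp"))
  write_phase_table(phased, paths[["phases"]])
  write_chain_table(chains, paths[["chains"]])
  write_map_table(map, paths[["map"]], paths[["groups"]])
  write_agp(chains, catalog, paths[["agp"]], gap = gap)
  if (!is.null(sequences)) {
    paths[["fasta"]] <- file.path(dir, "extended.fasta")
    write_extended_fasta(chains, sequences, paths[["fasta"]], gap = gap,
                         keep_unoriented_sequence = keep_unoriented_sequence)
  }
  invisible(paths)
}
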