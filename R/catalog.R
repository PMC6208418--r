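#' Scaffold catalog
#'
#' A catalog of assembly scaffolds/contigs with their lengths, the physical
#' backbone that markers are anchored to and that chains are assembled from.
#'
#' @param ids character vector of scaffold identifiers (unique).
#' @param lengths numeric vector of scaffold lengths in base pairs (>= 1).
#' @return A `scaffold_catalog`, a data frame with columns `scaffold` and
#'   `length`.
#' @export
scaffold_catalog <- function(ids, lengths) {
  ids <- as.character(ids)
  lengths <- as.numeric(lengths)
  abort_if(length(ids) == 0L, "empty scaffold catalog")
  abort_if(length(ids) != length(lengths), "ids and lengths differ in length")
  if (anyDuplicated(ids)) {
    stop("duplicate scaffold id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  abort_if(any(!is.finite(lengths)) || any(lengths < 1),
           "scaffold lengths must be finite and >= 1")
  structure(data.frame(scaffold = ids, length = lengths,
                       stringsAsFactors = FALSE),
            class = c("scaffold_catalog", "data.frame"))
}

#' Read a scaffold catalog from FASTA or a samtools .fai index
#'
#' The file type is sniffed from the first line: a `>` header means FASTA
#' (lengths are taken from the sequences), anything else is parsed as a
#' tab-separated faidx index whose first two columns are name and length.
#'
#' @param path path to a FASTA file or a `.fai` index.
#' @return A [scaffold_catalog()].
#' @export
read_scaffold_catalog <- function(path) {
  abort_if(!file.exists(path), "no such file: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  abort_if(length(first) == 0L, "empty file: %s", path)
  if (startsWith(first, ">")) {
    seqs <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(seqs))
    scaffold_catalog(ids, Biostrings::width(seqs))
  } else {
    fai <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    abort_if(ncol(fai) < 2L, "not a faidx index: %s", path)
    scaffold_catalog(fai[[1L]], fai[[2L]])
  }
}

scaffold_length <- function(catalog, ids) {
  i <- match(ids, catalog$scaffold)
  abort_if(anyNA(i), "scaffold(s) absent from catalog: %s",
           paste(ids[is.na(i)], collapse = ", "))
  catalog$length[i]
}

#' @export
print.scaffold_catalog <- function(x, ...) {
  cat(sprintf("scaffold_catalog: %d scaffolds, %.0f bp total\n",
              nrow(x), sum(x$length)))
  invisible(x)
}
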