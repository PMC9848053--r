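#' Assembly container
#'
#' A light container for a set of sequence units (contigs or scaffolds):
#' a table of ids and lengths, optionally the sequences themselves, and
#' optionally the gap intervals inside each unit (present once units are
#' scaffolds with N-gaps; gap chunks are excluded from expected-profile
#' estimation).
#'
#' @param ids character vector of unique unit ids.
#' @param lengths integer vector of unit lengths in bp (>= 1).
#' @param seqs optional [Biostrings::DNAStringSet] named by `ids`.
#' @param gaps optional `data.table(id, start, end)` of 0-based half-open
#'   gap intervals inside units.
#' @return an object of class `hic_assembly`.
#' @export
assembly <- function(ids, lengths, seqs = NULL, gaps = NULL) {
  ids <- as.character(ids)
  lengths <- as.numeric(lengths)
  if (anyDuplicated(ids)) stop("assembly ids must be unique")
  if (length(ids) != length(lengths)) stop("ids and lengths differ in length")
  if (any(lengths < 1)) stop("all unit lengths must be >= 1 bp")
  if (!is.null(seqs)) {
    if (!all(ids %in% names(seqs)))
      stop("sequences missing for: ",
           paste(head(setdiff(ids, names(seqs))), collapse = ", "))
    seqs <- seqs[ids]
    if (!all(Biostrings::width(seqs) == lengths))
      stop("sequence widths disagree with declared lengths")
  }
  if (!is.null(gaps)) {
    gaps <- as.data.table(gaps)
    stopifnot(all(c("id", "start", "end") %in% names(gaps)))
    if (!all(gaps$id %in% ids)) stop("gap interval on unknown unit")
  }
  structure(list(info = data.table(id = ids, length = lengths),
                 seqs = seqs, gaps = gaps),
            class = "hic_assembly")
}

#' @export
print.hic_assembly <- function(x, ...) {
  cat(sprintf("hic_assembly: %d units, %.3f Mb total%s%s\n",
              nrow(x$info), sum(x$info$length) / 1e6,
              if (is.null(x$seqs)) " (no sequences)" else "",
              if (is.null(x$gaps) || nrow(x$gaps) == 0L) ""
              else sprintf(", %d gaps", nrow(x$gaps))))
  invisible(x)
}

#' @export
length.hic_assembly <- function(x) nrow(x$info)

#' Read an assembly from a FASTA file
#'
#' @param path FASTA file of contigs.
#' @return `hic_assembly` with sequences attached (uppercased).
#' @export
read_assembly_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  assembly(names(seqs), Biostrings::width(seqs), seqs = seqs)
}

#' Write an assembly to FASTA
#'
#' @param x `hic_assembly` with sequences.
#' @param path output path; lines wrapped at 60 columns.
#' @export
write_assembly_fasta <- function(x, path) {
  if (is.null(x$seqs)) stop("assembly carries no sequences")
  Biostrings::writeXStringSet(x$seqs, path, width = 60L)
  invisible(path)
}

asm_lengths <- function(x) setNames(x$info$length, x$info$id)
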