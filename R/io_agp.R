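#' Scaffold paths
#'
#' A `scaffold_paths` object is a named list of `data.table(id, orient)`
#' blocks, one per scaffold: ordered member units with orientation
#' `'+'`/`'-'`. Every unit of an assembly appears in exactly one path
#' (singletons included).
#'
#' @param members list of `data.table(id, orient)` (or 2-column
#'   data.frames coercible to it).
#' @param names optional scaffold names; defaults to `scaffold_<i>`.
#' @return `scaffold_paths` object.
#' @export
scaffold_paths <- function(members, names = NULL) {
  members <- lapply(members, function(m) {
    m <- as.data.table(m)
    setnames(m, c("id", "orient"))
    stopifnot(all(m$orient %in% c("+", "-")))
    m
  })
  ids <- unlist(lapply(members, `[[`, "id"))
  if (anyDuplicated(ids))
    stop("unit appears in more than one scaffold path: ",
         ids[duplicated(ids)][1L])
  if (is.null(names)) names <- paste0("scaffold_", seq_along(members))
  names(members) <- names
  structure(members, class = "scaffold_paths")
}

#' @export
print.scaffold_paths <- function(x, ...) {
  cat(sprintf("scaffold_paths: %d scaffolds over %d units\n",
              length(x), sum(vapply(x, nrow, 0L))))
  invisible(x)
}

#' Scaffold lengths implied by paths
#' @param paths `scaffold_paths`.
#' @param asm [assembly()].
#' @param gap_len gap size in bp.
#' @return numeric vector of scaffold lengths.
#' @export
path_lengths <- function(paths, asm, gap_len = 200L) {
  lens <- asm_lengths(asm)
  vapply(paths, function(m) {
    sum(lens[m$id]) + gap_len * max(0L, nrow(m) - 1L)
  }, 0)
}

#' Singleton paths for a whole assembly
#' @param asm [assembly()].
#' @return `scaffold_paths` with one forward singleton per unit.
#' @export
singleton_paths <- function(asm) {
  scaffold_paths(lapply(asm$info$id,
                        function(i) data.table(id = i, orient = "+")),
                 names = asm$info$id)
}

#' Write scaffold paths as AGP v2.1
#'
#' Component (`W`) and gap (`U`) lines alternate; gaps are written with
#' gap_type `scaffold`, linkage `yes` and evidence `proximity_ligation`.
#' Coordinates are 1-based inclusive.
#'
#' @param paths `scaffold_paths`.
#' @param asm [assembly()] providing component lengths.
#' @param gap_len gap size in bp between joined units (default 200).
#' @param file optional output path.
#' @return character vector of AGP lines (invisibly when `file` given).
#' @export
write_agp <- function(paths, asm, gap_len = 200L, file = NULL) {
  lens <- asm_lengths(asm)
  out <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    m <- paths[[k]]
    if (!all(m$id %in% names(lens)))
      stop("path references unknown unit: ",
           setdiff(m$id, names(lens))[1L])
    nm <- names(paths)[k]
    lines <- character(2L * nrow(m) - 1L)
    at <- 0L; pn <- 0L
    for (i in seq_len(nrow(m))) {
      if (i > 1L) {
        pn <- pn + 1L
        lines[2L * i - 2L] <- paste(nm, at + 1L, at + gap_len, pn, "U",
                                    gap_len, "scaffold", "yes",
                                    "proximity_ligation", sep = "\t")
        at <- at + gap_len
      }
      L <- lens[[m$id[i]]]
      pn <- pn + 1L
      lines[2L * i - 1L] <- paste(nm, at + 1L, at + L, pn, "W",
                                  m$id[i], 1L, L, m$orient[i], sep = "\t")
      at <- at + L
    }
    out[[k]] <- lines
  }
  out <- unlist(out)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Parse AGP v2.1 text
#'
#' @param x character vector of AGP lines, or a file path.
#' @return list with `paths` (a `scaffold_paths`), `records` (the parsed
#'   table) and `gap_len` (unique declared gap size, `NA` if none).
#' @export
read_agp <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 9L) stop("AGP lines must have 9 columns")
  rec <- data.table(object = f[[1L]],
                    object_beg = as.integer(f[[2L]]),
                    object_end = as.integer(f[[3L]]),
                    part_number = as.integer(f[[4L]]),
                    component_type = f[[5L]],
                    component_id = f[[6L]],
                    component_beg = suppressWarnings(as.integer(f[[7L]])),
                    component_end = suppressWarnings(as.integer(f[[8L]])),
                    orient = f[[9L]])
  .validate_agp(rec)
  w <- rec[component_type == "W"]
  paths <- scaffold_paths(
    lapply(split(w, by = "object", sorted = FALSE),
           function(s) s[order(part_number), .(id = component_id, orient)]),
    names = unique(w$object))
  gl <- unique(as.integer(rec[component_type == "U"]$component_id))
  list(paths = paths, records = rec,
       gap_len = if (length(gl)) gl[1L] else NA_integer_)
}

.validate_agp <- function(rec) {
  for (obj in unique(rec$object)) {
    r <- rec[object == obj][order(part_number)]
    at <- 0L
    for (i in seq_len(nrow(r))) {
      if (r$object_beg[i] != at + 1L)
        stop("AGP object '", obj, "' does not tile: part ", i,
             " starts at ", r$object_beg[i], ", expected ", at + 1L)
      span <- r$object_end[i] - r$object_beg[i] + 1L
      if (r$component_type[i] == "U" &&
          span != as.integer(r$component_id[i]))
        stop("AGP gap length mismatch in object '", obj, "'")
      at <- r$object_end[i]
    }
  }
  invisible(TRUE)
}

#' Emit scaffold sequences as a DNAStringSet
#'
#' Concatenates oriented member sequences separated by `gap_len` `N`s;
#' `'-'` members are reverse complemented.
#'
#' @inheritParams write_agp
#' @return named [Biostrings::DNAStringSet].
#' @export
emit_scaffold_fasta <- function(paths, asm, gap_len = 200L) {
  if (is.null(asm$seqs)) stop("assembly carries no sequences")
  gap <- strrep("N", gap_len)
  seqs <- vapply(seq_along(paths), function(k) {
    m <- paths[[k]]
    pieces <- vapply(seq_len(nrow(m)), function(i) {
      s <- asm$seqs[[m$id[i]]]
      if (m$orient[i] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, "")
    paste(pieces, collapse = gap)
  }, "")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(paths)
  out
}

#' Flatten paths into a new assembly of scaffold units
#'
#' Builds the scaffold-level [assembly()] implied by `paths`: unit lengths
#' are member lengths plus inter-member gaps, gap intervals are recorded,
#' and sequences are emitted when the input assembly has them.
#'
#' @inheritParams write_agp
#' @param with_seqs emit scaffold sequences when the input assembly has
#'   them (default); set `FALSE` to skip the (costly) concatenation.
#' @return `hic_assembly` of scaffolds.
#' @export
flatten_paths <- function(paths, asm, gap_len = 200L,
                          with_seqs = TRUE) {
  lens <- asm_lengths(asm)
  gaps <- vector("list", length(paths))
  newlen <- numeric(length(paths))
  for (k in seq_along(paths)) {
    m <- paths[[k]]
    L <- lens[m$id]
    ends <- cumsum(L + gap_len) - gap_len   # member end offsets
    newlen[k] <- ends[length(ends)]
    if (nrow(m) > 1L)
      gaps[[k]] <- data.table(id = names(paths)[k],
                              start = ends[-length(ends)],
                              end = ends[-length(ends)] + gap_len)
  }
  gaps <- rbindlist(gaps[!vapply(gaps, is.null, TRUE)])
  if (nrow(gaps) == 0L) gaps <- NULL
  seqs <- if (with_seqs && !is.null(asm$seqs))
    emit_scaffold_fasta(paths, asm, gap_len)
  assembly(names(paths), newlen, seqs = seqs, gaps = gaps)
}
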