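#' Read Hi-C read-pair alignments
#'
#' Reads aligned Hi-C pairs from the canonical 6-column TSV dialect
#' (`contig1 pos1 contig2 pos2 mapq1 mapq2`, 0-based positions), from a
#' name-grouped BAM of paired primary alignments, or from an Arima-style
#' BED where consecutive lines of the two mates of a read pair share the
#' read name. Pairs are filtered on mapping quality and canonicalized so
#' that `(contig1, pos1) <= (contig2, pos2)`.
#'
#' @param path input file.
#' @param format one of `"tsv"`, `"bam"`, `"bed"`.
#' @param mapq_min minimum mapping quality required of *both* mates
#'   (default 10).
#' @param asm optional [assembly()]; when given, contig names and
#'   positions are validated against it and violations are errors.
#' @return `data.table(contig1, pos1, mapq1, contig2, pos2, mapq2)`,
#'   one row per retained pair, in file order.
#' @export
read_pairs <- function(path, format = c("tsv", "bam", "bed"), mapq_min = 10L,
                       asm = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  p <- switch(format,
              tsv = .read_pairs_tsv(path),
              bam = .read_pairs_bam(path),
              bed = .read_pairs_bed(path))
  p <- p[mapq1 >= mapq_min & mapq2 >= mapq_min]
  if (!is.null(asm)) validate_pairs(p, asm)
  canonicalize_pairs(p)
}

.read_pairs_tsv <- function(path) {
  p <- fread(path, header = FALSE, sep = "\t", colClasses = "character",
             showProgress = FALSE)
  if (ncol(p) != 6L)
    stop("pairs TSV must have 6 columns, got ", ncol(p))
  setnames(p, c("contig1", "pos1", "contig2", "pos2", "mapq1", "mapq2"))
  for (col in c("pos1", "pos2", "mapq1", "mapq2")) {
    v <- suppressWarnings(as.integer(p[[col]]))
    bad <- which(is.na(v) & !is.na(p[[col]]))
    if (length(bad))
      stop("malformed pairs TSV line ", bad[1L], " in ", path,
           " (bad ", col, ": '", p[[col]][bad[1L]], "')")
    data.table::set(p, j = col, value = v)
  }
  p[, .(contig1, pos1, mapq1, contig2, pos2, mapq2)]
}

.read_pairs_bam <- function(path) {
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "rname", "pos", "mapq"))
  b <- Rsamtools::scanBam(path, param = param)[[1L]]
  dt <- data.table(qname = b$qname, contig = as.character(b$rname),
                   pos = b$pos - 1L, mapq = as.integer(b$mapq))
  dt <- dt[!is.na(pos)]
  .mate_up(dt)
}

.read_pairs_bed <- function(path) {
  ## Arima-style per-read BED: contig start end readname mapq strand.
  ## Mates carry the same read name (an optional /1 /2 suffix is stripped).
  p <- fread(path, header = FALSE, sep = "\t")
  if (ncol(p) < 5L) stop("pairs BED needs >= 5 columns")
  dt <- data.table(qname = sub("/[12]$", "", as.character(p[[4L]])),
                   contig = as.character(p[[1L]]),
                   pos = as.integer(p[[2L]]),
                   mapq = as.integer(p[[5L]]))
  .mate_up(dt)
}

.mate_up <- function(dt) {
  dt[, idx := .I]
  dt[, n := .N, by = qname]
  dt <- dt[n >= 2L]
  dt[, mate := seq_len(.N), by = qname]
  m1 <- dt[mate == 1L]
  m2 <- dt[mate == 2L]
  setkey(m1, qname); setkey(m2, qname)
  j <- m1[m2]
  setorder(j, idx)
  j[, .(contig1 = contig, pos1 = pos, mapq1 = mapq,
        contig2 = i.contig, pos2 = i.pos, mapq2 = i.mapq)]
}

#' Canonicalize a pairs table
#'
#' Orders each pair so `(contig1, pos1)` sorts at or before
#' `(contig2, pos2)`; idempotent.
#'
#' @param p pairs `data.table`.
#' @return canonicalized copy.
#' @export
canonicalize_pairs <- function(p) {
  p <- as.data.table(p)
  swap <- p$contig2 < p$contig1 |
    (p$contig2 == p$contig1 & p$pos2 < p$pos1)
  if (any(swap)) {
    s <- p[swap]
    p[swap, `:=`(contig1 = s$contig2, pos1 = s$pos2, mapq1 = s$mapq2,
                 contig2 = s$contig1, pos2 = s$pos1, mapq2 = s$mapq1)]
    if (all(c("chr1", "g1", "chr2", "g2") %in% names(p)))
      p[swap, `:=`(chr1 = s$chr2, g1 = s$g2, chr2 = s$chr1, g2 = s$g1)]
  }
  p[]
}

validate_pairs <- function(p, asm) {
  lens <- asm_lengths(asm)
  for (side in c(1L, 2L)) {
    ctg <- p[[paste0("contig", side)]]
    pos <- p[[paste0("pos", side)]]
    unk <- which(!(ctg %in% names(lens)))
    if (length(unk))
      stop("pair record ", unk[1L], ": unknown contig '", ctg[unk[1L]], "'")
    oob <- which(pos < 0 | pos >= lens[ctg])
    if (length(oob))
      stop("pair record ", oob[1L], ": position ", pos[oob[1L]],
           " out of range on '", ctg[oob[1L]], "'")
    mq <- p[[paste0("mapq", side)]]
    if (any(mq < 0 | mq > 255)) stop("mapq outside [0, 255]")
  }
  invisible(TRUE)
}

#' Write pairs in the canonical TSV dialect
#'
#' @param p pairs table.
#' @param path output path.
#' @param provenance keep any truth side-channel columns (those beyond the
#'   canonical six) instead of dropping them.
#' @export
write_pairs <- function(p, path, provenance = FALSE) {
  cols <- c("contig1", "pos1", "contig2", "pos2", "mapq1", "mapq2")
  out <- if (provenance) {
    extra <- setdiff(names(p), cols)
    as.data.table(p)[, c(cols, extra), with = FALSE]
  } else as.data.table(p)[, cols, with = FALSE]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
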