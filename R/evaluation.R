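## Truth-based evaluation: contiguity statistics and classification of
## scaffold adjacencies into relocations (wrong distance/order on the
## same chromosome), inversions (wrong relative orientation) and
## translocations (joins across chromosomes), using the simulator's
## provenance rather than whole-genome alignment.

#' Nx / Lx contiguity statistics
#'
#' Sort lengths descending; `Nx` is the first length at which the
#' cumulative sum reaches `x` percent of the total, `Lx` its 1-based
#' rank.
#'
#' @param lengths positive lengths in bp.
#' @param x percentage (e.g. 50 or 90).
#' @return named numeric `c(Nx, Lx)`.
#' @export
nx_stats <- function(lengths, x = 50) {
  if (!length(lengths)) stop("empty length list")
  stopifnot(all(lengths > 0))
  s <- sort(unname(lengths), decreasing = TRUE)
  k <- which(cumsum(s) >= x / 100 * sum(s))[1L]
  c(Nx = s[k], Lx = k)
}

## dominant truth row (largest contig-interval overlap) per contig
.dominant_truth <- function(truth) {
  tr <- as.data.table(truth)
  tr[, ov := c_end - c_start]
  setorder(tr, contig, -ov, part)
  tr[, .SD[1L], by = contig]
}

#' Classify scaffold adjacencies against truth
#'
#' For each adjacent contig pair in each path: different truth
#' chromosomes give a translocation; inconsistent relative direction
#' along the chromosome an inversion; consistent direction but a gap or
#' order offset beyond `reloc_tol` a relocation; otherwise the
#' adjacency is correct. Contigs with multi-part truth are assigned
#' their dominant (largest) part.
#'
#' @param paths `scaffold_paths` over contigs with truth provenance.
#' @param truth truth map.
#' @param reloc_tol tolerated truth-gap in bp (default 50 kb, i.e.
#'   5 x a 10 kb finest resolution).
#' @return named integer vector `c(relocations, inversions,
#'   translocations, correct)`.
#' @export
classify_adjacencies <- function(paths, truth, reloc_tol = 50e3) {
  dom <- .dominant_truth(truth)
  counts <- c(relocations = 0L, inversions = 0L,
              translocations = 0L, correct = 0L)
  for (m in paths) {
    if (nrow(m) < 2L) next
    tr <- dom[match(m$id, contig)]
    if (anyNA(tr$chr))
      stop("contig without truth provenance: ",
           m$id[which(is.na(tr$chr))[1L]])
    ## direction along the chromosome implied by truth strand and
    ## path orientation: +1 when ascending
    dir <- ifelse((tr$strand == "+") == (m$orient == "+"), 1L, -1L)
    for (i in seq_len(nrow(m) - 1L)) {
      if (tr$chr[i] != tr$chr[i + 1L]) {
        counts["translocations"] <- counts["translocations"] + 1L
      } else if (dir[i] != dir[i + 1L]) {
        counts["inversions"] <- counts["inversions"] + 1L
      } else {
        gap <- if (dir[i] == 1L) tr$g_start[i + 1L] - tr$g_end[i]
               else tr$g_start[i] - tr$g_end[i + 1L]
        if (abs(gap) > reloc_tol)
          counts["relocations"] <- counts["relocations"] + 1L
        else counts["correct"] <- counts["correct"] + 1L
      }
    }
  }
  counts
}

#' Score breakpoint detection against injected junctions
#'
#' An injected junction counts as detected iff some break on its contig
#' lies within `tol` bp; each break is matched to at most one junction
#' (nearest first); unmatched breaks are false positives.
#'
#' @param breaks breakpoint table (`contig`, `pos`).
#' @param errors truth junction table (`contig`, `pos`) from
#'   [introduce_misjoins()].
#' @param tol matching tolerance in bp (default 5 kb, i.e. 5 windows of
#'   1 kb).
#' @return named integer vector `c(detected, false_positives)`.
#' @export
score_correction <- function(breaks, errors, tol = 5e3) {
  br <- as.data.table(breaks)
  er <- as.data.table(errors)
  detected <- 0L
  used_breaks <- rep(FALSE, nrow(br))
  if (nrow(er)) {
    ## nearest-first matching within each contig
    cand <- list()
    for (j in seq_len(nrow(er))) {
      rows <- which(br$contig == er$contig[j] & !is.na(br$pos))
      if (!length(rows)) next
      dist <- abs(br$pos[rows] - er$pos[j])
      cand[[length(cand) + 1L]] <- data.table(
        junction = j, brow = rows, dist = dist)
    }
    if (length(cand)) {
      cand <- rbindlist(cand)[dist <= tol]
      setorder(cand, dist, junction, brow)
      matched_j <- logical(nrow(er))
      for (i in seq_len(nrow(cand))) {
        j <- cand$junction[i]; r <- cand$brow[i]
        if (!matched_j[j] && !used_breaks[r]) {
          matched_j[j] <- TRUE
          used_breaks[r] <- TRUE
          detected <- detected + 1L
        }
      }
    }
  }
  c(detected = detected,
    false_positives = nrow(br) - sum(used_breaks))
}

#' Lift a truth map through a contig-break lift table
#'
#' After [apply_breaks()], fragments inherit the truth intervals they
#' overlap (intersected and re-addressed to fragment coordinates).
#'
#' @param truth truth map over original contigs.
#' @param lift lift table from [apply_breaks()].
#' @return truth map over fragments.
#' @export
lift_truth <- function(truth, lift) {
  tr <- as.data.table(truth)
  lf <- as.data.table(lift)
  out <- list()
  for (i in seq_len(nrow(lf))) {
    t <- tr[contig == lf$orig[i]]
    fs <- lf$start[i]; fe <- lf$end[i]
    ov <- t[c_start < fe & c_end > fs]
    if (!nrow(ov)) next
    o_start <- pmax(ov$c_start, fs)
    o_end <- pmin(ov$c_end, fe)
    g_start2 <- ifelse(ov$strand == "+",
                       ov$g_start + (o_start - ov$c_start),
                       ov$g_start + (ov$c_end - o_end))
    g_end2 <- g_start2 + (o_end - o_start)
    out[[length(out) + 1L]] <- data.table(
      contig = lf$frag[i], part = seq_len(nrow(ov)), chr = ov$chr,
      g_start = g_start2, g_end = g_end2, strand = ov$strand,
      c_start = o_start - fs, c_end = o_end - fs)
  }
  rbindlist(out)
}

#' Full evaluation report
#'
#' @param result `scaffold_result` from [hic_scaffold()].
#' @param truth truth map over the *input* contigs.
#' @param errors injected junction table (or `NULL`).
#' @param reloc_tol,tol see [classify_adjacencies()] and
#'   [score_correction()].
#' @return list with `nx` (N50/L50/N90/L90), `adjacencies`,
#'   `correction`.
#' @export
evaluate_scaffolds <- function(result, truth, errors = NULL,
                               reloc_tol = 50e3, tol = 5e3) {
  lens <- result$scaffolds$info$length
  nx <- c(nx_stats(lens, 50), nx_stats(lens, 90))
  names(nx) <- c("N50", "L50", "N90", "L90")
  tr <- if (!is.null(result$lift)) lift_truth(truth, result$lift)
        else truth
  adj <- classify_adjacencies(result$paths, tr, reloc_tol = reloc_tol)
  corr <- if (!is.null(errors))
    score_correction(result$breaks[kind == "pre_scaffold"], errors,
                     tol = tol)
  else c(detected = NA_integer_, false_positives = NA_integer_)
  list(nx = nx, adjacencies = adj, correction = corr)
}
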