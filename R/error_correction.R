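## Misassembly detection from Hi-C spanning coverage.
##
## A cis pair (both ends on one unit, separation <= max_span) supports
## every window lying fully inside the open interval between its two
## positions. Windows whose coverage collapses relative to their flanks
## mark candidate misjoins: true joins are bridged by many pairs, while
## a junction gluing unrelated sequence receives essentially no
## spanning pairs (only trans noise).

#' Spanning-pair coverage profile of one unit
#'
#' Window `w` (0-based, covering `[w*window, (w+1)*window)` clipped to
#' the unit) is incremented by a cis pair at `p1 < p2` with
#' `p2 - p1 <= max_span` iff the window lies fully inside `(p1, p2)`,
#' i.e. `w*window > p1` and the window end `<= p2`.
#'
#' @param pairs pairs table.
#' @param contig unit id.
#' @param contig_len unit length in bp.
#' @param window window size in bp (default 1000).
#' @param max_span maximum pair separation counted (default 1e6).
#' @return numeric vector of length `ceiling(contig_len / window)`.
#' @export
spanning_coverage <- function(pairs, contig, contig_len, window = 1000L,
                              max_span = 1e6) {
  coverage_profiles(pairs, ids = contig,
                    lens = contig_len, window = window,
                    max_span = max_span)[[contig]]
}

#' Spanning coverage for many units at once
#'
#' @param pairs pairs table.
#' @param asm [assembly()]; alternatively give `ids`/`lens` directly.
#' @param ids,lens unit ids and lengths (used when `asm` is `NULL`).
#' @inheritParams spanning_coverage
#' @return named list of per-unit coverage vectors.
#' @export
coverage_profiles <- function(pairs, asm = NULL, ids = NULL, lens = NULL,
                              window = 1000L, max_span = 1e6) {
  stopifnot(window >= 1L)
  if (!is.null(asm)) {
    ids <- asm$info$id
    lens <- asm$info$length
  }
  p <- as.data.table(pairs)[contig1 == contig2 & contig1 %in% ids]
  p <- p[pmax(pos1, pos2) - pmin(pos1, pos2) <= max_span]
  out <- vector("list", length(ids))
  names(out) <- ids
  spl <- split(seq_len(nrow(p)), factor(p$contig1, levels = ids))
  for (k in seq_along(ids)) {
    nw <- as.integer(ceiling(lens[k] / window))
    cov <- numeric(nw)
    rows <- spl[[k]]
    if (length(rows)) {
      p1 <- pmin(p$pos1[rows], p$pos2[rows])
      p2 <- pmax(p$pos1[rows], p$pos2[rows])
      lo <- p1 %/% window + 1L        # first window fully inside
      hi <- p2 %/% window - 1L        # last window with end <= p2
      hi <- pmin(hi, nw - 1L)
      ## last window of the unit is partial (its end is the unit end);
      ## it can only be fully inside if its end <= p2, i.e. never
      ## (p2 < len), unless the unit length is a window multiple
      hi[hi == nw - 1L & lens[k] %% window != 0L] <- nw - 2L
      ok <- lo <= hi
      if (any(ok)) {
        diffv <- numeric(nw + 1L)
        tab1 <- tabulate(lo[ok] + 1L, nbins = nw + 1L)
        tab2 <- tabulate(hi[ok] + 2L, nbins = nw + 1L)
        cov <- cumsum(tab1 - tab2)[seq_len(nw)]
      }
    }
    out[[k]] <- cov
  }
  out
}

#' Find coverage-valley breakpoints on one unit
#'
#' Candidate windows have coverage below `min_ratio` times the median
#' coverage of the two flanking regions (each `flank` bp, clipped at the
#' unit ends); windows within `end_guard` bp of either end are never
#' candidates. Contiguous candidate runs are merged and a single break
#' is placed at the midpoint of the run's minimum-coverage window.
#'
#' @param profile coverage vector from [spanning_coverage()].
#' @param contig unit id (for the report).
#' @param contig_len unit length in bp.
#' @param window window size the profile was computed at.
#' @param flank flank length in bp (default `10 * window`).
#' @param min_ratio valley threshold relative to flank median
#'   (default 0.1).
#' @param end_guard no-break zone at unit ends in bp
#'   (default `5 * window`).
#' @param kind annotation for the report (default `"pre_scaffold"`).
#' @return `data.table(contig, pos, kind, evidence)`; zero rows when no
#'   valley is found.
#' @export
find_breakpoints <- function(profile, contig, contig_len, window = 1000L,
                             flank = 10L * window, min_ratio = 0.1,
                             end_guard = 5L * window,
                             kind = "pre_scaffold") {
  stopifnot(flank >= window)
  nw <- length(profile)
  fl <- max(1L, as.integer(flank %/% window))
  guard_lo <- as.integer(ceiling(end_guard / window))
  guard_hi <- nw - 1L - guard_lo
  empty <- data.table(contig = character(), pos = numeric(),
                      kind = character(), evidence = numeric())
  if (guard_lo > guard_hi) return(empty)
  ## cheap prefilter: a candidate needs cov < min_ratio * (some flank
  ## median) <= min_ratio * max(profile)
  cand <- which(profile < min_ratio * max(profile)) - 1L
  cand <- cand[cand >= guard_lo & cand <= guard_hi]
  if (!length(cand)) return(empty)
  fmed <- vapply(cand, function(w) {
    left <- profile[max(1L, w - fl + 1L):w]           # windows w-fl .. w-1
    right <- profile[(w + 2L):min(nw, w + 1L + fl)]   # windows w+1 .. w+fl
    median(c(left, right))
  }, 0)
  is_cand <- profile[cand + 1L] < min_ratio * fmed
  cand <- cand[is_cand]
  if (!length(cand)) return(empty)
  ## merge contiguous runs
  runs <- split(cand, cumsum(c(1L, diff(cand) != 1L)))
  out <- lapply(runs, function(ws) {
    wmin <- ws[which.min(profile[ws + 1L])]
    ws_start <- wmin * window
    ws_end <- min((wmin + 1L) * window, contig_len)
    left <- profile[max(1L, wmin - fl + 1L):wmin]
    right <- profile[(wmin + 2L):min(nw, wmin + 1L + fl)]
    fm <- median(c(left, right))
    ev <- if (fm > 0) profile[wmin + 1L] / fm else 0
    data.table(contig = contig, pos = floor((ws_start + ws_end) / 2),
               kind = kind, evidence = min(ev, 1 - 1e-9))
  })
  res <- rbindlist(out)
  res[pos > 0 & pos < contig_len]
}

#' Detect breakpoints across a whole assembly
#'
#' Convenience wrapper: [coverage_profiles()] then [find_breakpoints()]
#' per unit.
#'
#' @param pairs pairs table.
#' @param asm [assembly()].
#' @inheritParams find_breakpoints
#' @inheritParams spanning_coverage
#' @return combined breakpoint `data.table`.
#' @export
detect_breakpoints <- function(pairs, asm, window = 1000L, max_span = 1e6,
                               flank = 10L * window, min_ratio = 0.1,
                               end_guard = 5L * window) {
  profs <- coverage_profiles(pairs, asm, window = window,
                             max_span = max_span)
  res <- lapply(seq_along(profs), function(k)
    find_breakpoints(profs[[k]], asm$info$id[k], asm$info$length[k],
                     window = window, flank = flank,
                     min_ratio = min_ratio, end_guard = end_guard))
  rbindlist(res)
}

#' Break contigs at detected positions
#'
#' Each broken unit is replaced by fragments `<id>_1 .. <id>_k`
#' (coordinate order); sequences, when present, are split accordingly.
#' A lift table maps original coordinates to fragment coordinates.
#'
#' @param asm [assembly()].
#' @param breakpoints breakpoint table (`contig`, `pos`); duplicate
#'   positions are collapsed.
#' @return list with `assembly` (the broken assembly) and `lift`
#'   (`data.table(orig, frag, start, end)`, 0-based half-open intervals
#'   of each fragment on its original unit).
#' @export
apply_breaks <- function(asm, breakpoints) {
  bp <- as.data.table(breakpoints)
  lens <- asm_lengths(asm)
  if (nrow(bp)) {
    if (!all(bp$contig %in% names(lens)))
      stop("breakpoint on unknown contig")
    if (any(bp$pos <= 0 | bp$pos >= lens[bp$contig]))
      stop("breakpoint position outside its contig interior")
  }
  lifts <- vector("list", length(lens))
  for (k in seq_along(lens)) {
    id <- names(lens)[k]
    cuts <- sort(unique(bp[contig == id]$pos))
    starts <- c(0, cuts)
    ends <- c(cuts, lens[[k]])
    frag <- if (length(cuts)) paste0(id, "_", seq_along(starts)) else id
    lifts[[k]] <- data.table(orig = id, frag = frag,
                             start = starts, end = ends)
  }
  lift <- rbindlist(lifts)
  seqs <- NULL
  if (!is.null(asm$seqs)) {
    seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(lift)), function(i)
      Biostrings::subseq(asm$seqs[[lift$orig[i]]],
                         lift$start[i] + 1L, lift$end[i])))
    names(seqs) <- lift$frag
  }
  asm2 <- assembly(lift$frag, lift$end - lift$start, seqs = seqs)
  list(assembly = asm2, lift = lift)
}

#' Re-address pairs through a break lift
#'
#' @param pairs pairs table in original coordinates.
#' @param lift lift table from [apply_breaks()].
#' @return pairs table in fragment coordinates (canonicalized); pair
#'   count is conserved exactly.
#' @export
lift_pairs_breaks <- function(pairs, lift) {
  p <- as.data.table(pairs)
  lift <- as.data.table(lift)
  lift[, fstart := start]
  setkey(lift, orig, start)
  map_side <- function(ctg, pos) {
    q <- data.table(orig = ctg, start = pos)
    hit <- lift[q, on = .(orig, start), roll = Inf]
    if (anyNA(hit$frag)) stop("unmapped position in lift_pairs_breaks")
    list(ctg = hit$frag, pos = pos - hit$fstart)
  }
  s1 <- map_side(p$contig1, p$pos1)
  s2 <- map_side(p$contig2, p$pos2)
  canonicalize_pairs(data.table(
    contig1 = s1$ctg, pos1 = s1$pos, mapq1 = p$mapq1,
    contig2 = s2$ctg, pos2 = s2$pos, mapq2 = p$mapq2))
}

#' Check scaffold joins against bridging Hi-C coverage
#'
#' For every join (gap) in every path, counts pairs whose two ends lie
#' on opposite sides of the gap within `max_span` in scaffold
#' coordinates. Joins supported below `min_join_ratio` times the
#' scaffold's median junction support are flagged for dissolution.
#'
#' @param paths `scaffold_paths` over the units carrying `pairs`.
#' @param pairs pairs table in unit coordinates.
#' @param asm [assembly()] of the units.
#' @param gap_len gap length used when flattening.
#' @param max_span maximum bridging separation (default 1e6).
#' @param min_join_ratio dissolution threshold (default 0.1).
#' @return `data.table(scaffold, junction, contig_before, contig_after,
#'   pos, bridges, ratio, dissolve)`.
#' @export
post_scaffold_check <- function(paths, pairs, asm, gap_len = 200L,
                                max_span = 1e6, min_join_ratio = 0.1) {
  agp <- write_agp(paths, asm, gap_len = gap_len)
  rec <- read_agp(agp)$records
  lifted <- lift_pairs(pairs, rec)
  out <- list()
  for (nm in names(paths)) {
    m <- paths[[nm]]
    if (nrow(m) < 2L) next
    w <- rec[object == nm & component_type == "W"][order(part_number)]
    p <- lifted[contig1 == nm & contig2 == nm]
    sep_ok <- p[pos2 - pos1 <= max_span]
    ## gap g sits between w$object_end[g] and w$object_beg[g+1]
    gs <- w$object_end[-nrow(w)]          # 1-based end of left member
    ge <- w$object_beg[-1L] - 1L          # 1-based start of right member - 1
    bridges <- vapply(seq_along(gs), function(gi)
      sum(sep_ok$pos1 < gs[gi] & sep_ok$pos2 >= ge[gi]), 0)
    out[[nm]] <- data.table(
      scaffold = nm, junction = seq_along(gs),
      contig_before = w$component_id[-nrow(w)],
      contig_after = w$component_id[-1L],
      pos = gs, bridges = bridges)
  }
  if (!length(out))
    return(data.table(scaffold = character(), junction = integer(),
                      contig_before = character(),
                      contig_after = character(), pos = numeric(),
                      bridges = numeric(), ratio = numeric(),
                      dissolve = logical()))
  res <- rbindlist(out)
  res[, ratio := {
    med <- median(bridges)
    if (med > 0) bridges / med else 1
  }, by = scaffold]
  res[, dissolve := ratio < min_join_ratio]
  res[]
}

#' Split paths at dissolved joins
#'
#' @param paths `scaffold_paths`.
#' @param checks result of [post_scaffold_check()].
#' @return new `scaffold_paths` with flagged joins removed; split
#'   scaffolds are renamed `<name>_1..`.
#' @export
dissolve_joins <- function(paths, checks) {
  bad <- checks[dissolve == TRUE]
  if (!nrow(bad)) return(paths)
  members <- list(); nms <- character(0)
  for (nm in names(paths)) {
    m <- paths[[nm]]
    cuts <- sort(bad[scaffold == nm]$junction)
    if (!length(cuts)) {
      members <- c(members, list(m)); nms <- c(nms, nm)
      next
    }
    grp <- cumsum(c(0L, seq_len(nrow(m) - 1L) %in% cuts)) + 1L
    pieces <- split(m, grp)
    members <- c(members, pieces)
    nms <- c(nms, paste0(nm, "_", seq_along(pieces)))
  }
  scaffold_paths(members, names = nms)
}
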