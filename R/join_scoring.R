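## Join scoring.
##
## A candidate join of contigs A and B in one of four orientations is
## scored by comparing the inter-cell contact counts between them with
## the expected intra-cell counts at the same implied separations. With
## both contigs virtually oriented so that their joining ends face each
## other, a cell at chunk distance `a` from A's joining end and `b` from
## B's has implied separation d = a + b + 1 chunks. Using weights
## w(d) = E(d), the weighted mean of obs/E collapses to
##   score = sum(obs) / sum(E)
## over the band d <= D_max. Observed counts in partial (trailing)
## chunks are rescaled by resolution / chunk_length.

.ORIENTATIONS <- c("TH", "HT", "TT", "HH")

#' Reverse an orientation code
#'
#' Orientation codes name the joining ends `(end of A, end of B)` with
#' `H` the coordinate-0 end and `T` the high-coordinate end. Swapping the
#' roles of A and B swaps the letters.
#'
#' @param o orientation code(s).
#' @return reversed code(s).
#' @export
reverse_orientation <- function(o) {
  vapply(strsplit(o, ""), function(x) paste0(x[2L], x[1L]), "")
}

## sum of E over the scoring band and number of band cells, vectorized
## over contig pairs with chunk counts nA, nB
.band_geometry <- function(nA, nB, prof) {
  S <- numeric(length(nA))
  ncell <- numeric(length(nA))
  for (d in seq_len(prof$D_max)) {
    nd <- pmax(0, pmin(nA - 1, d - 1) - pmax(0, d - nB) + 1)
    S <- S + nd * prof$E[d]
    ncell <- ncell + nd
  }
  list(S = S, n = ncell)
}

#' Score one contig join in one orientation
#'
#' @param mat `contact_matrix` (see [build_matrix()]).
#' @param prof `expected_profile` (see [expected_profile()]).
#' @param A,B unit ids; `A == B` is an error.
#' @param orientation one of `"TH"`, `"HT"`, `"TT"`, `"HH"`: the ends of
#'   A and B that are adjoined.
#' @return one-row `data.table(contig_a, contig_b, orientation, score,
#'   n_cells)`.
#' @export
orientation_score <- function(mat, prof, A, B, orientation) {
  stopifnot(orientation %in% .ORIENTATIONS)
  if (A == B) stop("self-joins are not scored")
  idx <- mat$index
  iA <- match(A, idx$ids); iB <- match(B, idx$ids)
  if (is.na(iA) || is.na(iB)) stop("unknown contig in orientation_score")
  lo <- min(iA, iB); hi <- max(iA, iB)
  cells <- mat$cells[ca == lo & cb == hi]
  oA <- if (iA == lo) cells$ia else cells$ib
  oB <- if (iA == lo) cells$ib else cells$ia
  gA <- idx$offset[iA] + oA
  gB <- idx$offset[iB] + oB
  eA <- substr(orientation, 1L, 1L)
  eB <- substr(orientation, 2L, 2L)
  nA <- idx$n_chunks[iA]; nB <- idx$n_chunks[iB]
  aa <- if (eA == "T") nA - 1L - oA else oA
  bb <- if (eB == "T") nB - 1L - oB else oB
  dd <- aa + bb + 1L
  keep <- dd <= prof$D_max
  obs <- cells$count[keep] *
    (idx$resolution / idx$chunk_len[gA[keep] + 1L]) *
    (idx$resolution / idx$chunk_len[gB[keep] + 1L])
  geom <- .band_geometry(nA, nB, prof)
  data.table(contig_a = A, contig_b = B, orientation = orientation,
             score = sum(obs) / geom$S, n_cells = as.integer(geom$n))
}

#' Best-scoring orientation for a contig pair
#'
#' Ties are broken by the fixed orientation order TH, HT, TT, HH.
#'
#' @inheritParams orientation_score
#' @return one-row join-score `data.table`.
#' @export
best_join <- function(mat, prof, A, B) {
  sc <- rbindlist(lapply(.ORIENTATIONS, function(o)
    orientation_score(mat, prof, A, B, o)))
  sc[which.max(score)]
}

#' Score all candidate contig pairs
#'
#' Enumerates every unordered pair of units sharing at least `min_pairs`
#' raw inter contacts, scores all four orientations and keeps the best
#' per pair. Output has `contig_a < contig_b` lexicographically and is
#' sorted by descending score (ties by contig ids).
#'
#' @inheritParams orientation_score
#' @param min_pairs minimum raw shared contacts to consider a pair
#'   (default 5).
#' @return `data.table(contig_a, contig_b, orientation, score, n_cells)`.
#' @export
score_all <- function(mat, prof, min_pairs = 5L) {
  idx <- mat$index
  inter <- mat$cells[ca != cb]
  empty <- data.table(contig_a = character(), contig_b = character(),
                      orientation = character(), score = numeric(),
                      n_cells = integer())
  if (nrow(inter) == 0L) return(empty)
  cand <- inter[, .(n_raw = sum(raw)), by = .(ca, cb)][n_raw >= min_pairs]
  if (nrow(cand) == 0L) return(empty)
  cells <- inter[cand[, .(ca, cb)], on = c("ca", "cb")]
  cells[, `:=`(rf = (idx$resolution / idx$chunk_len[a + 1L]) *
                    (idx$resolution / idx$chunk_len[b + 1L]))]
  cells[, `:=`(nA = idx$n_chunks[ca], nB = idx$n_chunks[cb])]
  geom <- .band_geometry(idx$n_chunks[cand$ca], idx$n_chunks[cand$cb], prof)
  cand[, `:=`(S = geom$S, n_cells = as.integer(geom$n))]
  res <- vector("list", 4L)
  for (k in seq_along(.ORIENTATIONS)) {
    o <- .ORIENTATIONS[k]
    eA <- substr(o, 1L, 1L); eB <- substr(o, 2L, 2L)
    aa <- if (eA == "T") cells$nA - 1L - cells$ia else cells$ia
    bb <- if (eB == "T") cells$nB - 1L - cells$ib else cells$ib
    dd <- aa + bb + 1L
    sub <- cells[dd <= prof$D_max]
    num <- sub[, .(numer = sum(count * rf)), by = .(ca, cb)]
    sc <- num[cand, on = c("ca", "cb")]
    sc[is.na(numer), numer := 0]
    sc[, `:=`(orientation = o, score = numer / S, ord = k)]
    res[[k]] <- sc[, .(ca, cb, orientation, score, n_cells, ord)]
  }
  allsc <- rbindlist(res)
  setorder(allsc, ca, cb, -score, ord)
  best <- allsc[, .SD[1L], by = .(ca, cb)]
  best[, `:=`(contig_a = idx$ids[ca], contig_b = idx$ids[cb])]
  swap <- best$contig_a > best$contig_b
  if (any(swap)) {
    tmp <- best$contig_a[swap]
    best[swap, contig_a := contig_b]
    best[(swap), contig_b := tmp]
    best[(swap), orientation := reverse_orientation(orientation)]
  }
  setorder(best, -score, contig_a, contig_b)
  best[, .(contig_a, contig_b, orientation, score, n_cells)]
}
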