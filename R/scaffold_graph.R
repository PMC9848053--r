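## Scaffolding graph.
##
## Every contig contributes two nodes, its H end (coordinate 0) and its
## T end (high coordinate), connected by an implicit internal link.
## Join edges connect ends of *different* contigs and are weighted by
## join scores. Ends are encoded as integers: contig i has ends
## H = 2i - 1 and T = 2i. The simplification cascade only ever deletes
## edges; after the final stage every end has degree <= 1 and the graph
## decomposes into paths (and possibly cycles, broken at traversal).

.end_H <- function(ci) 2L * ci - 1L
.end_T <- function(ci) 2L * ci
.contig_of <- function(e) (e + 1L) %/% 2L
.opp_end <- function(e) e + ifelse(e %% 2L == 0L, -1L, 1L)
.is_T <- function(e) e %% 2L == 0L

.end_label <- function(e, ids) {
  paste0(ids[.contig_of(e)], ifelse(.is_T(e), ":T", ":H"))
}

.new_graph <- function(ids, edges) {
  edges <- as.data.table(edges)
  structure(list(ids = ids, edges = edges), class = "scaffold_graph")
}

#' @export
print.scaffold_graph <- function(x, ...) {
  cat(sprintf("scaffold_graph: %d contigs, %d join edges\n",
              length(x$ids), nrow(x$edges)))
  invisible(x)
}

.degrees <- function(g) {
  tabulate(c(g$edges$u, g$edges$v), nbins = 2L * length(g$ids))
}

## all (edge row index, other end) incident to end e
.incident <- function(g, e) {
  which(g$edges$u == e | g$edges$v == e)
}

.other_end <- function(g, rows, e) {
  ifelse(g$edges$u[rows] == e, g$edges$v[rows], g$edges$u[rows])
}

#' Build the scaffolding graph from join scores
#'
#' One edge per scored pair (best orientation only), connecting the two
#' specified contig ends, kept when `score >= min_score`.
#'
#' @param scores join-score table from [score_all()].
#' @param asm [assembly()] whose units the scores refer to.
#' @param min_score minimum score for an edge (default 0.1).
#' @return object of class `scaffold_graph`.
#' @export
build_graph <- function(scores, asm, min_score = 0.1) {
  ids <- asm$info$id
  sc <- as.data.table(scores)[score >= min_score]
  if (nrow(sc)) {
    ca <- match(sc$contig_a, ids)
    cb <- match(sc$contig_b, ids)
    if (anyNA(ca) || anyNA(cb)) stop("score references unknown contig")
    if (any(ca == cb)) stop("self-edge in join scores")
    ea <- ifelse(substr(sc$orientation, 1L, 1L) == "T",
                 .end_T(ca), .end_H(ca))
    eb <- ifelse(substr(sc$orientation, 2L, 2L) == "T",
                 .end_T(cb), .end_H(cb))
    edges <- data.table(u = pmin(ea, eb), v = pmax(ea, eb),
                        score = sc$score)
    if (anyDuplicated(edges[, .(u, v)]))
      stop("duplicate (end, end) edge; scores not deduplicated per pair")
  } else {
    edges <- data.table(u = integer(), v = integer(), score = numeric())
  }
  .new_graph(ids, edges)
}

## deterministic ordering key for edges: (score, label_u, label_v)
.edge_labels <- function(g) {
  paste(.end_label(g$edges$u, g$ids), .end_label(g$edges$v, g$ids))
}

#' Trim tips
#'
#' At every junction end (degree >= 2), branches that dead-end within
#' `max_tip_contigs` contigs (a simple chain ending in a free end) are
#' deleted, provided at least one non-tip branch remains at the
#' junction. Iterated to a fixpoint; junctions and branches are
#' processed in deterministic order (ascending edge score, then
#' lexicographic end labels).
#'
#' @param g `scaffold_graph`.
#' @param max_tip_contigs maximum chain length counted as a tip
#'   (default 1).
#' @return simplified graph.
#' @export
trim_tips <- function(g, max_tip_contigs = 1L) {
  repeat {
    deg <- .degrees(g)
    junc <- which(deg >= 2L)
    if (!length(junc)) break
    junc <- junc[order(.end_label(junc, g$ids))]
    drop <- integer(0)
    for (u in junc) {
      rows <- setdiff(.incident(g, u), drop)
      if (length(rows) < 2L) next
      ord <- order(g$edges$score[rows],
                   .end_label(.other_end(g, rows, u), g$ids))
      rows <- rows[ord]
      tip <- vapply(rows, function(r) {
        .branch_is_tip(g, u, .other_end(g, r, u), r,
                       max_tip_contigs, drop)
      }, TRUE)
      if (any(!tip) && any(tip)) drop <- c(drop, rows[tip])
    }
    if (!length(drop)) break
    g$edges <- g$edges[-drop]
  }
  g
}

## is the branch entered at end v (via edge row r0 from the junction) a
## dead-end chain of <= k contigs?
.branch_is_tip <- function(g, u, v, r0, k, dropped) {
  seen <- .contig_of(u)
  entry <- v
  used <- r0
  n <- 0L
  repeat {
    n <- n + 1L
    if (n > k) return(FALSE)
    ci <- .contig_of(entry)
    if (ci %in% seen) return(FALSE)          # cycle
    seen <- c(seen, ci)
    if (length(setdiff(.incident(g, entry), c(used, dropped))) > 0L)
      return(FALSE)                          # entry end branches
    out <- .opp_end(entry)
    rows <- setdiff(.incident(g, out), dropped)
    if (length(rows) == 0L) return(TRUE)     # dead end
    if (length(rows) >= 2L) return(FALSE)    # junction inside branch
    used <- rows
    entry <- .other_end(g, rows, out)
  }
}

#' Trim blunt ends
#'
#' Removes every edge that is not the best-scoring edge at either of its
#' endpoints (non-reciprocal-best edges), in a single pass.
#'
#' @param g `scaffold_graph`.
#' @return simplified graph.
#' @export
trim_blunt_ends <- function(g) {
  if (!nrow(g$edges)) return(g)
  mx <- .end_max_scores(g)
  keep <- g$edges$score >= mx[g$edges$u] | g$edges$score >= mx[g$edges$v]
  g$edges <- g$edges[keep]
  g
}

.end_max_scores <- function(g) {
  mx <- rep(-Inf, 2L * length(g$ids))
  for (side in c("u", "v")) {
    agg <- g$edges[, .(m = max(score)), by = c(side)]
    e <- agg[[side]]
    mx[e] <- pmax(mx[e], agg$m)
  }
  mx
}

#' Isolate repeat-like contigs
#'
#' A contig's contact density is the total matrix mass touching it
#' divided by its length; contigs denser than `repeat_factor` times the
#' median density lose all their edges (they remain as singletons).
#'
#' @param g `scaffold_graph`.
#' @param mat the `contact_matrix` the scores came from.
#' @param repeat_factor density multiple flagging a repeat (default 2).
#' @return simplified graph.
#' @export
solve_repeats <- function(g, mat, repeat_factor = 2) {
  idx <- mat$index
  m1 <- mat$cells[, .(mass = sum(count)), by = .(ci = ca)]
  m2 <- mat$cells[ca != cb, .(mass = sum(count)), by = .(ci = cb)]
  mass <- numeric(length(idx$ids))
  mass[m1$ci] <- mass[m1$ci] + m1$mass
  mass[m2$ci] <- mass[m2$ci] + m2$mass
  dens <- mass / idx$lengths
  flagged <- which(dens > repeat_factor * median(dens))
  if (length(flagged)) {
    fl <- match(idx$ids[flagged], g$ids)
    fl <- fl[!is.na(fl)]
    bad_ends <- c(.end_H(fl), .end_T(fl))
    g$edges <- g$edges[!(u %in% bad_ends | v %in% bad_ends)]
  }
  g
}

#' Remove transitive edges
#'
#' If ends chain `u -- v'` and `v'' -- w` through opposite ends of a
#' middle contig `v`, a direct edge `u -- w` is transitive and removed.
#' All 2-step chains are scanned before any deletion.
#'
#' @param g `scaffold_graph`.
#' @return simplified graph.
#' @export
remove_transitive <- function(g) {
  if (!nrow(g$edges)) return(g)
  drop <- logical(nrow(g$edges))
  ek <- paste(g$edges$u, g$edges$v)
  for (ci in seq_along(g$ids)) {
    h <- .end_H(ci); t <- .end_T(ci)
    U <- .other_end(g, .incident(g, h), h)
    W <- .other_end(g, .incident(g, t), t)
    if (!length(U) || !length(W)) next
    comb <- expand.grid(u = U, w = W)
    key <- paste(pmin(comb$u, comb$w), pmax(comb$u, comb$w))
    drop[match(intersect(key, ek), ek)] <- TRUE
  }
  g$edges <- g$edges[!drop]
  g
}

## enumerate simple scaffold paths (<= max_edges join edges) from end s;
## returns list of list(t = terminal end, rows = edge row indices,
## min_score)
.paths_from <- function(g, s, max_edges) {
  out <- list()
  recurse <- function(cur, rows, contigs, minsc) {
    inc <- .incident(g, cur)
    inc <- setdiff(inc, rows)
    for (r in inc[order(.end_label(.other_end(g, inc, cur), g$ids))]) {
      x <- .other_end(g, r, cur)
      if (.contig_of(x) %in% contigs) next
      msc <- min(minsc, g$edges$score[r])
      out[[length(out) + 1L]] <<- list(t = x, rows = c(rows, r),
                                       min_score = msc)
      if (length(rows) + 1L < max_edges)
        recurse(.opp_end(x), c(rows, r), c(contigs, .contig_of(x)), msc)
    }
  }
  recurse(s, integer(0), .contig_of(s), Inf)
  out
}

#' Pop bubbles
#'
#' Where two edge-disjoint paths of at most `max_bubble_edges` join
#' edges connect the same pair of ends, all edges of the path with the
#' lower minimum edge score are deleted (ties: the lexicographically
#' later path). Repeated until no such pair remains.
#'
#' @param g `scaffold_graph`.
#' @param max_bubble_edges maximum path length in edges (default 3).
#' @return simplified graph.
#' @export
pop_bubbles <- function(g, max_bubble_edges = 3L) {
  repeat {
    if (nrow(g$edges) < 2L) return(g)
    ends <- sort(unique(c(g$edges$u, g$edges$v)))
    ends <- ends[order(.end_label(ends, g$ids))]
    victim <- NULL
    labs <- .edge_labels(g)
    for (s in ends) {
      ps <- .paths_from(g, s, max_bubble_edges)
      if (length(ps) < 2L) next
      ts <- vapply(ps, `[[`, 0L, "t")
      keys <- vapply(ps, function(p)
        paste(labs[p$rows], collapse = "|"), "")
      ord <- order(-vapply(ps, `[[`, 0, "min_score"), keys)
      ps <- ps[ord]; ts <- ts[ord]; keys <- keys[ord]
      for (t in unique(ts[order(.end_label(ts, g$ids))])) {
        grp <- which(ts == t)
        if (length(grp) < 2L) next
        for (i in grp) {
          for (j in grp[grp > i]) {
            if (!length(intersect(ps[[i]]$rows, ps[[j]]$rows))) {
              victim <- ps[[j]]$rows
              break
            }
          }
          if (!is.null(victim)) break
        }
        if (!is.null(victim)) break
      }
      if (!is.null(victim)) break
    }
    if (is.null(victim)) return(g)
    g$edges <- g$edges[-victim]
  }
}

#' Resolve ambiguous orientations
#'
#' When several edges connect the same unordered contig pair through
#' different end combinations, the best is kept only if it beats the
#' second best by at least `ratio`; otherwise all edges between the pair
#' are deleted.
#'
#' @param g `scaffold_graph`.
#' @param ratio required dominance ratio (default 1.5).
#' @return simplified graph.
#' @export
resolve_orientations <- function(g, ratio = 1.5) {
  if (nrow(g$edges) < 2L) return(g)
  e <- copy(g$edges)
  e[, `:=`(pa = pmin(.contig_of(u), .contig_of(v)),
           pb = pmax(.contig_of(u), .contig_of(v)), row = .I)]
  drop <- integer(0)
  for (grp in split(e, by = c("pa", "pb"))) {
    if (nrow(grp) < 2L) next
    s <- sort(grp$score, decreasing = TRUE)
    if (s[1L] >= ratio * s[2L]) {
      best <- grp$row[which.max(grp$score)]
      drop <- c(drop, setdiff(grp$row, best))
    } else {
      drop <- c(drop, grp$row)
    }
  }
  if (length(drop)) g$edges <- g$edges[-drop]
  g
}

#' Trim weak edges
#'
#' Removes every edge scoring below `theta` times the maximum edge score
#' found at either of its endpoints; maxima are computed once before the
#' single pass.
#'
#' @param g `scaffold_graph`.
#' @param theta relative threshold (default 0.75).
#' @return simplified graph.
#' @export
trim_weak_edges <- function(g, theta = 0.75) {
  if (!nrow(g$edges)) return(g)
  mx <- .end_max_scores(g)
  keep <- g$edges$score >= theta * pmax(mx[g$edges$u], mx[g$edges$v])
  g$edges <- g$edges[keep]
  g
}

#' Drop remaining ambiguous edges
#'
#' Final cascade stage: every end still of degree >= 2 loses all its
#' edges; afterwards the maximum end degree is 1.
#'
#' @param g `scaffold_graph`.
#' @return simplified graph with end degree <= 1.
#' @export
drop_ambiguous <- function(g) {
  deg <- .degrees(g)
  bad <- which(deg >= 2L)
  if (length(bad))
    g$edges <- g$edges[!(u %in% bad | v %in% bad)]
  g
}

#' Run the full simplification cascade
#'
#' Stage order: low-score filtering (done at [build_graph()]), tip
#' trimming, blunt-end trimming, repeat solving, transitive-edge
#' removal, bubble popping, orientation resolution, weak-edge trimming,
#' ambiguous-edge removal.
#'
#' @param g `scaffold_graph` (already score-filtered).
#' @param mat `contact_matrix` (for repeat densities).
#' @param max_tip_contigs,repeat_factor,max_bubble_edges,ratio,theta
#'   stage parameters, see the individual stage functions.
#' @param verbose print per-stage edge counts.
#' @return graph with end degree <= 1.
#' @export
simplify_graph <- function(g, mat, max_tip_contigs = 1L, repeat_factor = 2,
                           max_bubble_edges = 3L, ratio = 1.5,
                           theta = 0.75, verbose = FALSE) {
  stages <- list(
    tips        = function(g) trim_tips(g, max_tip_contigs),
    blunt       = trim_blunt_ends,
    repeats     = function(g) solve_repeats(g, mat, repeat_factor),
    transitive  = remove_transitive,
    bubbles     = function(g) pop_bubbles(g, max_bubble_edges),
    orientation = function(g) resolve_orientations(g, ratio),
    weak        = function(g) trim_weak_edges(g, theta),
    ambiguous   = drop_ambiguous)
  for (nm in names(stages)) {
    before <- nrow(g$edges)
    g <- stages[[nm]](g)
    if (verbose)
      message(sprintf("  %-12s %4d -> %4d edges", nm, before,
                      nrow(g$edges)))
  }
  g
}

#' Traverse a simplified graph into scaffold paths
#'
#' Walks maximal paths alternating join edges and internal contig links.
#' Isolated contigs become singletons; cycles are broken at their
#' minimum-score edge. Scaffolds are named `scaffold_1..` by descending
#' scaffold length (member lengths plus gaps).
#'
#' @param g `scaffold_graph` with end degree <= 1.
#' @param asm [assembly()] of the graph's units.
#' @param gap_len gap size used for scaffold-length ranking.
#' @return `scaffold_paths`.
#' @export
traverse <- function(g, asm, gap_len = 200L) {
  deg <- .degrees(g)
  if (any(deg > 1L))
    stop("graph has ends of degree > 1; run the simplification cascade")
  ids <- g$ids
  visited <- logical(length(ids))
  paths <- list()

  walk_from <- function(e) {
    members <- list()
    entry <- e
    repeat {
      ci <- .contig_of(entry)
      visited[ci] <<- TRUE
      members[[length(members) + 1L]] <-
        data.table(id = ids[ci], orient = if (.is_T(entry)) "-" else "+")
      out <- .opp_end(entry)
      rows <- .incident(g, out)
      if (!length(rows)) break
      entry <- .other_end(g, rows[1L], out)
    }
    rbindlist(members)
  }

  free <- which(deg == 0L)
  free <- free[order(.end_label(free, ids))]
  for (e in free) {
    if (visited[.contig_of(e)]) next
    paths[[length(paths) + 1L]] <- walk_from(e)
  }
  ## remaining components are cycles: cut at minimum-score edge
  repeat {
    left <- which(!visited)
    if (!length(left)) break
    rows <- which(.contig_of(g$edges$u) %in% left)
    stopifnot(length(rows) > 0L)
    labs <- .edge_labels(g)[rows]
    r <- rows[order(g$edges$score[rows], labs)][1L]
    cut_ends <- c(g$edges$u[r], g$edges$v[r])
    g$edges <- g$edges[-r]
    start <- cut_ends[order(.end_label(cut_ends, ids))][1L]
    paths[[length(paths) + 1L]] <- walk_from(start)
  }
  sp <- scaffold_paths(paths)
  len <- path_lengths(sp, asm, gap_len)
  first <- vapply(sp, function(m) m$id[1L], "")
  ord <- order(-len, first)
  scaffold_paths(unclass(sp)[ord])
}
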