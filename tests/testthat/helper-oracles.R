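## Independent brute-force oracles. These re-derive the operations'
## contracts with naive loops and are deliberately kept free of the
## package's internal representations.

## ---- join score oracle ------------------------------------------------

## brute-force band sum over all chunk pairs, straight from raw pairs
oracle_join_score <- function(pairs, lens, resolution, E, D_max,
                              A, B, orientation) {
  nA <- ceiling(lens[[A]] / resolution)
  nB <- ceiling(lens[[B]] / resolution)
  clen <- function(id, i) {
    min(resolution, lens[[id]] - i * resolution)
  }
  eA <- substr(orientation, 1, 1)
  eB <- substr(orientation, 2, 2)
  num <- 0; den <- 0; ncell <- 0
  for (i in seq_len(nA) - 1L) {
    for (j in seq_len(nB) - 1L) {
      a <- if (eA == "T") nA - 1 - i else i
      b <- if (eB == "T") nB - 1 - j else j
      d <- a + b + 1
      if (d > D_max) next
      obs <- 0
      for (r in seq_len(nrow(pairs))) {
        p <- pairs[r, ]
        hit <- (p$contig1 == A && p$pos1 %/% resolution == i &&
                p$contig2 == B && p$pos2 %/% resolution == j) ||
               (p$contig1 == B && p$pos1 %/% resolution == j &&
                p$contig2 == A && p$pos2 %/% resolution == i)
        if (hit) obs <- obs + 1
      }
      num <- num + obs * (resolution / clen(A, i)) *
                         (resolution / clen(B, j))
      den <- den + E[d]
      ncell <- ncell + 1
    }
  }
  list(score = num / den, n_cells = ncell)
}

## ---- graph oracles ----------------------------------------------------

## oracle graphs are plain data.frames: edges (u, v, score) over integer
## ends, H = 2i-1, T = 2i for contig i
o_contig <- function(e) (e + 1L) %/% 2L
o_opp <- function(e) ifelse(e %% 2L == 0L, e - 1L, e + 1L)
o_deg <- function(ed, e) sum(ed$u == e | ed$v == e)
o_other <- function(ed, r, e) if (ed$u[r] == e) ed$v[r] else ed$u[r]
o_inc <- function(ed, e) which(ed$u == e | ed$v == e)

oracle_blunt <- function(ed) {
  keep <- logical(nrow(ed))
  for (r in seq_len(nrow(ed))) {
    for (e in c(ed$u[r], ed$v[r])) {
      best <- max(ed$score[o_inc(ed, e)])
      if (ed$score[r] >= best) keep[r] <- TRUE
    }
  }
  ed[keep, , drop = FALSE]
}

oracle_transitive <- function(ed) {
  drop <- logical(nrow(ed))
  n_contig <- max(o_contig(c(ed$u, ed$v)))
  for (v in seq_len(n_contig)) {
    h <- 2L * v - 1L; t <- 2L * v
    for (ru in o_inc(ed, h)) {
      for (rw in o_inc(ed, t)) {
        uu <- o_other(ed, ru, h)
        ww <- o_other(ed, rw, t)
        direct <- which((ed$u == pmin(uu, ww)) & (ed$v == pmax(uu, ww)))
        drop[direct] <- TRUE
      }
    }
  }
  ed[!drop, , drop = FALSE]
}

oracle_weak <- function(ed, theta) {
  keep <- logical(nrow(ed))
  for (r in seq_len(nrow(ed))) {
    m <- max(ed$score[union(o_inc(ed, ed$u[r]), o_inc(ed, ed$v[r]))])
    keep[r] <- ed$score[r] >= theta * m
  }
  ed[keep, , drop = FALSE]
}

oracle_drop_ambiguous <- function(ed) {
  bad <- Filter(function(e) o_deg(ed, e) >= 2L, unique(c(ed$u, ed$v)))
  ed[!(ed$u %in% bad | ed$v %in% bad), , drop = FALSE]
}

oracle_resolve_orient <- function(ed, ratio) {
  key <- paste(pmin(o_contig(ed$u), o_contig(ed$v)),
               pmax(o_contig(ed$u), o_contig(ed$v)))
  keep <- rep(TRUE, nrow(ed))
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) < 2L) next
    s <- sort(ed$score[rows], decreasing = TRUE)
    if (s[1] >= ratio * s[2])
      keep[rows[ed$score[rows] < s[1]]] <- FALSE
    else keep[rows] <- FALSE
  }
  ed[keep, , drop = FALSE]
}

## is the branch entered through edge r0 (from junction u) a dead-end
## chain of at most k contigs? explored by explicit stepping
oracle_is_tip <- function(ed, u, r0, k) {
  entry <- o_other(ed, r0, u)
  used <- r0
  contigs_seen <- o_contig(u)
  count <- 0L
  repeat {
    count <- count + 1L
    if (count > k) return(FALSE)
    ci <- o_contig(entry)
    if (ci %in% contigs_seen) return(FALSE)
    contigs_seen <- c(contigs_seen, ci)
    if (length(setdiff(o_inc(ed, entry), used)) > 0L) return(FALSE)
    nxt <- setdiff(o_inc(ed, o_opp(entry)), integer(0))
    if (length(nxt) == 0L) return(TRUE)
    if (length(nxt) >= 2L) return(FALSE)
    used <- nxt
    entry <- o_other(ed, nxt, o_opp(entry))
  }
}

oracle_trim_tips <- function(ed, k) {
  repeat {
    junc <- Filter(function(e) o_deg(ed, e) >= 2L,
                   sort(unique(c(ed$u, ed$v))))
    removed <- FALSE
    for (u in junc) {
      rows <- o_inc(ed, u)
      if (length(rows) < 2L) next
      tip <- vapply(rows, function(r) oracle_is_tip(ed, u, r, k), TRUE)
      if (any(tip) && any(!tip)) {
        ed <- ed[-rows[tip], , drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) return(ed)
  }
}

## ---- scalar oracles ---------------------------------------------------

oracle_nx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  target <- x / 100 * sum(s)
  acc <- 0
  for (k in seq_along(s)) {
    acc <- acc + s[k]
    if (acc >= target) return(c(Nx = s[k], Lx = k))
  }
}

oracle_spanning <- function(pairs, contig, contig_len, window, max_span) {
  nw <- ceiling(contig_len / window)
  cov <- numeric(nw)
  for (w in seq_len(nw) - 1L) {
    ws <- w * window
    we <- min((w + 1) * window, contig_len)
    for (r in seq_len(nrow(pairs))) {
      p <- pairs[r, ]
      if (p$contig1 != contig || p$contig2 != contig) next
      lo <- min(p$pos1, p$pos2); hi <- max(p$pos1, p$pos2)
      if (hi - lo > max_span) next
      if (ws > lo && we <= hi) cov[w + 1L] <- cov[w + 1L] + 1
    }
  }
  cov
}

oracle_sites <- function(seq, motif, resolution, n_chunks) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
             S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
             D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  to_re <- function(m) paste0("(?=", paste(iupac[strsplit(m, "")[[1]]],
                                           collapse = ""), ")")
  hits <- function(m) {
    g <- gregexpr(to_re(m), seq, perl = TRUE)[[1]]
    if (g[1] == -1) integer(0) else as.integer(g) - 1L
  }
  m2 <- rc(motif)
  pos <- union(hits(motif), hits(m2))
  tabulate(pos %/% resolution + 1L, nbins = n_chunks)
}

## ---- adjacency classification oracle ----------------------------------

oracle_classify <- function(path, truth_one_part, tol) {
  ## path: data.frame(id, orient); truth_one_part: one row per contig
  tr <- truth_one_part[match(path$id, truth_one_part$contig), ]
  out <- c(relocations = 0L, inversions = 0L, translocations = 0L,
           correct = 0L)
  for (i in seq_len(nrow(path) - 1L)) {
    a <- tr[i, ]; b <- tr[i + 1L, ]
    da <- if ((a$strand == "+") == (path$orient[i] == "+")) 1L else -1L
    db <- if ((b$strand == "+") == (path$orient[i + 1L] == "+")) 1L else -1L
    if (a$chr != b$chr) out["translocations"] <- out["translocations"] + 1L
    else if (da != db) out["inversions"] <- out["inversions"] + 1L
    else {
      gap <- if (da == 1L) b$g_start - a$g_end else a$g_start - b$g_end
      if (abs(gap) > tol) out["relocations"] <- out["relocations"] + 1L
      else out["correct"] <- out["correct"] + 1L
    }
  }
  out
}

## ---- random graph builder ---------------------------------------------

## random scaffold_graph over n contigs with m candidate edges and
## distinct scores; returns list(g = scaffold_graph, ed = oracle edges)
random_graph <- function(n, m, seed, multi_orient = FALSE) {
  set.seed(seed)
  ids <- sprintf("c%02d", seq_len(n))
  asm <- assembly(ids, rep(1000, n))
  seen <- character(0)
  seen_pair <- character(0)
  rows <- list()
  tries <- 0
  while (length(rows) < m && tries < 40 * m) {
    tries <- tries + 1
    cab <- sample(n, 2L)
    ea <- sample(c("H", "T"), 1L); eb <- sample(c("H", "T"), 1L)
    u <- 2L * cab[1] - (ea == "H")
    v <- 2L * cab[2] - (eb == "H")
    key <- paste(min(u, v), max(u, v))
    pkey <- paste(min(cab), max(cab))
    if (key %in% seen) next
    if (!multi_orient && pkey %in% seen_pair) next
    seen <- c(seen, key); seen_pair <- c(seen_pair, pkey)
    rows[[length(rows) + 1L]] <- data.frame(
      contig_a = ids[cab[1]], contig_b = ids[cab[2]],
      orientation = paste0(ea, eb), score = 0, u = min(u, v),
      v = max(u, v))
  }
  sc <- do.call(rbind, rows)
  sc$score <- round(runif(nrow(sc), 0.05, 1), 3)
  sc$score <- sc$score + seq_len(nrow(sc)) * 1e-6   # force distinct
  g <- build_graph(sc[, c("contig_a", "contig_b", "orientation",
                          "score")], asm, min_score = 0)
  ed <- data.frame(u = sc$u, v = sc$v, score = sc$score)
  ## align oracle edge order with the graph's internal order
  ed <- ed[order(ed$u, ed$v), , drop = FALSE]
  list(g = g, ed = ed, asm = asm)
}

## compare a scaffold_graph against an oracle edge frame
expect_same_edges <- function(g, ed) {
  got <- g$edges[order(u, v), .(u, v, score)]
  want <- data.table::as.data.table(
    ed[order(ed$u, ed$v), c("u", "v", "score")])
  expect_equal(as.data.frame(got), as.data.frame(want),
               ignore_attr = TRUE)
}
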