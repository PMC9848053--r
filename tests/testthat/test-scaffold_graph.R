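## graphs are built from synthetic score tables via build_graph;
## end encoding in oracle frames: H = 2i - 1, T = 2i for contig i

mk_graph <- function(edges, n = NULL) {
  ## edges: data.frame(ca, cb, o, score) with contig indices
  if (is.null(n)) n <- max(c(edges$ca, edges$cb))
  ids <- sprintf("c%02d", seq_len(n))
  asm <- assembly(ids, rep(1000, n))
  sc <- data.frame(contig_a = ids[edges$ca], contig_b = ids[edges$cb],
                   orientation = edges$o, score = edges$score)
  build_graph(sc, asm, min_score = 0)
}

test_that("build_graph filters by score and rejects duplicates", {
  asm <- assembly(c("A", "B"), c(100, 100))
  sc <- data.frame(contig_a = "A", contig_b = "B", orientation = "TH",
                   score = 0.9)
  g <- build_graph(sc, asm, min_score = 0.1)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(sort(c(g$edges$u, g$edges$v)), c(2L, 3L))  # A.T -- B.H
  expect_equal(nrow(build_graph(sc, asm, min_score = 0.95)$edges), 0L)
  expect_error(build_graph(rbind(sc, sc), asm, 0.1), "duplicate")
  ## on simulation: edge count equals scores passing threshold
  w <- small_world()
  m <- build_matrix(w$pairs, chunk_index(w$assembly, 10e3))
  prof <- expected_profile(m)
  sa <- score_all(m, prof)
  g2 <- build_graph(sa, w$assembly, min_score = 0.1)
  expect_equal(nrow(g2$edges), sum(sa$score >= 0.1))
})

test_that("trim_tips removes short dead-end branches at junctions", {
  ## chain A-B-C-D with spur B-E: C continues (not a tip), E dead-ends
  g <- mk_graph(data.frame(ca = c(1, 2, 3, 2), cb = c(2, 3, 4, 5),
                           o = "TH", score = c(0.9, 0.8, 0.8, 0.3)),
                n = 5)
  g2 <- trim_tips(g, max_tip_contigs = 1L)
  expect_equal(nrow(g2$edges), 3L)
  expect_false(any(g2$edges$u %in% c(9L, 10L) |
                   g2$edges$v %in% c(9L, 10L)))  # E isolated
  ## with a larger tip budget both branches are tips, so neither goes
  g3 <- trim_tips(g, max_tip_contigs = 2L)
  expect_equal(nrow(g3$edges), 4L)
  ## pure path untouched
  gp <- mk_graph(data.frame(ca = c(1, 2), cb = c(2, 3), o = "TH",
                            score = 0.5), n = 3)
  expect_equal(trim_tips(gp, 1L)$edges, gp$edges)
  ## random graphs against the iterative oracle
  for (seed in 1:40) {
    rg <- random_graph(n = sample(5:12, 1), m = sample(4:14, 1),
                       seed = seed)
    for (k in 1:2) {
      got <- trim_tips(rg$g, k)
      want <- oracle_trim_tips(rg$ed, k)
      expect_same_edges(got, want)
    }
  }
})

test_that("trim_blunt_ends keeps only reciprocal-best edges", {
  ## the 0.2 edge is non-best at 1.T (0.9 there) and at 3.H (0.8 there)
  g <- mk_graph(data.frame(ca = c(1, 1, 4), cb = c(2, 3, 3), o = "TH",
                           score = c(0.9, 0.2, 0.8)), n = 4)
  g2 <- trim_blunt_ends(g)
  expect_equal(sort(g2$edges$score), c(0.8, 0.9))
  ## all reciprocal-best: unchanged
  gp <- mk_graph(data.frame(ca = c(1, 2), cb = c(2, 3), o = "TH",
                            score = c(0.5, 0.6)), n = 3)
  expect_equal(trim_blunt_ends(gp)$edges, gp$edges)
  for (seed in 1:40) {
    rg <- random_graph(n = sample(4:12, 1), m = sample(3:14, 1),
                       seed = 100 + seed)
    expect_same_edges(trim_blunt_ends(rg$g), oracle_blunt(rg$ed))
  }
})

test_that("solve_repeats isolates high-density contigs only", {
  w <- small_world()
  idx <- chunk_index(w$assembly, 10e3)
  m <- build_matrix(w$pairs, idx)
  prof <- expected_profile(m)
  sa <- score_all(m, prof)
  g <- build_graph(sa, w$assembly)
  ## uniform coverage: nothing flagged
  expect_equal(nrow(solve_repeats(g, m, repeat_factor = 2)$edges),
               nrow(g$edges))
  ## triple the mass on one contig (a collapsed repeat in disguise)
  victim <- w$assembly$info$id[1L]
  vp <- w$pairs[contig1 == victim | contig2 == victim]
  m3 <- build_matrix(rbind(w$pairs, vp, vp), idx)
  g3 <- solve_repeats(g, m3, repeat_factor = 2)
  vi <- match(victim, w$assembly$info$id)
  bad_ends <- c(2L * vi - 1L, 2L * vi)
  expect_false(any(g3$edges$u %in% bad_ends | g3$edges$v %in% bad_ends))
  ## and only that contig's edges went missing
  lost <- g$edges[!g3$edges, on = c("u", "v")]
  expect_true(all(lost$u %in% bad_ends | lost$v %in% bad_ends))
})

test_that("remove_transitive drops orientation-consistent shortcuts", {
  ## chain A.T-B.H, B.T-C.H plus direct A.T-C.H
  g <- mk_graph(data.frame(ca = c(1, 2, 1), cb = c(2, 3, 3), o = "TH",
                           score = c(0.9, 0.9, 0.4)), n = 3)
  g2 <- remove_transitive(g)
  expect_equal(nrow(g2$edges), 2L)
  expect_false(0.4 %in% g2$edges$score)
  ## inconsistent ends (A.T-C.T) are not transitive
  gk <- mk_graph(data.frame(ca = c(1, 2, 1), cb = c(2, 3, 3),
                            o = c("TH", "TH", "TT"),
                            score = c(0.9, 0.9, 0.4)), n = 3)
  expect_equal(nrow(remove_transitive(gk)$edges), 3L)
  for (seed in 1:40) {
    rg <- random_graph(n = sample(4:12, 1), m = sample(3:16, 1),
                       seed = 200 + seed, multi_orient = TRUE)
    expect_same_edges(remove_transitive(rg$g), oracle_transitive(rg$ed))
  }
})

test_that("pop_bubbles deletes the weaker of two parallel paths", {
  ## A.T--B, A.T--C, B--D.H, C--D.H : two 2-edge paths A -> D
  g <- mk_graph(data.frame(ca = c(1, 1, 2, 3), cb = c(2, 3, 4, 4),
                           o = "TH", score = c(0.9, 0.3, 0.9, 0.35)),
                n = 4)
  g2 <- pop_bubbles(g, max_bubble_edges = 3L)
  expect_equal(sort(g2$edges$score), c(0.9, 0.9))
  ## no parallel paths: unchanged
  gp <- mk_graph(data.frame(ca = c(1, 2), cb = c(2, 3), o = "TH",
                            score = 0.5), n = 3)
  expect_equal(pop_bubbles(gp, 3L)$edges, gp$edges)
  ## a 1-edge shortcut vs a 2-edge detour is also a bubble
  gs <- mk_graph(data.frame(ca = c(1, 2, 1), cb = c(2, 3, 3), o = "TH",
                            score = c(0.9, 0.9, 0.2)), n = 3)
  expect_equal(sort(pop_bubbles(gs, 3L)$edges$score), c(0.9, 0.9))
})

test_that("resolve_orientations needs a dominant orientation", {
  g <- mk_graph(data.frame(ca = c(1, 1), cb = c(2, 2),
                           o = c("TH", "TT"), score = c(0.8, 0.2)))
  g2 <- resolve_orientations(g, ratio = 1.5)
  expect_equal(g2$edges$score, 0.8)
  gq <- mk_graph(data.frame(ca = c(1, 1), cb = c(2, 2),
                            o = c("TH", "TT"), score = c(0.5, 0.4)))
  expect_equal(nrow(resolve_orientations(gq, 1.5)$edges), 0L)
  for (seed in 1:30) {
    rg <- random_graph(n = sample(3:8, 1), m = sample(3:12, 1),
                       seed = 300 + seed, multi_orient = TRUE)
    expect_same_edges(resolve_orientations(rg$g, 1.5),
                      oracle_resolve_orient(rg$ed, 1.5))
  }
})

test_that("trim_weak_edges applies the relative threshold once", {
  g <- mk_graph(data.frame(ca = c(1, 1), cb = c(2, 3), o = "TH",
                           score = c(1.0, 0.5)), n = 3)
  expect_equal(trim_weak_edges(g, 0.7)$edges$score, 1.0)
  ge <- mk_graph(data.frame(ca = c(1, 1), cb = c(2, 3), o = "TH",
                            score = c(0.6, 0.6)), n = 3)
  expect_equal(nrow(trim_weak_edges(ge, 0.7)$edges), 2L)
  for (seed in 1:40) {
    rg <- random_graph(n = sample(4:12, 1), m = sample(3:16, 1),
                       seed = 400 + seed)
    expect_same_edges(trim_weak_edges(rg$g, 0.75),
                      oracle_weak(rg$ed, 0.75))
  }
})

test_that("drop_ambiguous leaves a degree <= 1 graph", {
  g <- mk_graph(data.frame(ca = c(1, 1), cb = c(2, 3), o = "TH",
                           score = c(0.6, 0.6)), n = 3)
  expect_equal(nrow(drop_ambiguous(g)$edges), 0L)
  gp <- mk_graph(data.frame(ca = c(1, 2), cb = c(2, 3), o = "TH",
                            score = 0.5), n = 3)
  expect_equal(drop_ambiguous(gp)$edges, gp$edges)
  for (seed in 1:40) {
    rg <- random_graph(n = sample(4:12, 1), m = sample(3:16, 1),
                       seed = 500 + seed, multi_orient = TRUE)
    got <- drop_ambiguous(rg$g)
    expect_same_edges(got, oracle_drop_ambiguous(rg$ed))
    deg <- tabulate(c(got$edges$u, got$edges$v), 2L * length(got$ids))
    expect_true(all(deg <= 1L))
  }
})

test_that("the full cascade only deletes edges and ends degree <= 1", {
  w <- small_world()
  m <- build_matrix(w$pairs, chunk_index(w$assembly, 10e3))
  prof <- expected_profile(m)
  g <- build_graph(score_all(m, prof), w$assembly)
  g2 <- simplify_graph(g, m)
  expect_true(nrow(g2$edges) <= nrow(g$edges))
  merged <- g$edges[g2$edges, on = c("u", "v"), nomatch = NULL]
  expect_equal(nrow(merged), nrow(g2$edges))    # subset, never adds
  deg <- tabulate(c(g2$edges$u, g2$edges$v), 2L * length(g2$ids))
  expect_true(all(deg <= 1L))
})

test_that("traverse walks paths, flips orientations, breaks cycles", {
  g <- mk_graph(data.frame(ca = c(1, 2), cb = c(2, 3), o = "TH",
                           score = 0.5), n = 3)
  asm <- assembly(sprintf("c%02d", 1:3), rep(1000, 3))
  p <- traverse(g, asm)
  expect_length(p, 1L)
  expect_equal(p[[1L]]$id, sprintf("c%02d", 1:3))
  expect_equal(p[[1L]]$orient, rep("+", 3))
  ## A.T -- B.T joins B reversed
  g2 <- mk_graph(data.frame(ca = 1, cb = 2, o = "TT", score = 0.5))
  asm2 <- assembly(sprintf("c%02d", 1:2), c(1000, 1000))
  p2 <- traverse(g2, asm2)
  expect_equal(p2[[1L]]$orient, c("+", "-"))
  ## 3-cycle: cut at the minimum-score edge (A.H--C.T, 0.2)
  g3 <- mk_graph(data.frame(ca = c(1, 2, 3), cb = c(2, 3, 1),
                            o = c("TH", "TH", "TH"),
                            score = c(0.9, 0.8, 0.2)), n = 3)
  p3 <- traverse(g3, asm)
  expect_length(p3, 1L)
  expect_equal(nrow(p3[[1L]]), 3L)
  expect_equal(p3[[1L]]$id[1L], "c01")          # cut frees A.H first
  ## degree > 1 is an error
  gj <- mk_graph(data.frame(ca = c(1, 1), cb = c(2, 3), o = "TH",
                            score = c(0.6, 0.6)), n = 3)
  expect_error(traverse(gj, asm), "degree")
})

test_that("traverse conserves the contig multiset on random graphs", {
  for (seed in 1:20) {
    rg <- random_graph(n = sample(4:12, 1), m = sample(3:16, 1),
                       seed = 600 + seed, multi_orient = TRUE)
    g <- drop_ambiguous(trim_blunt_ends(rg$g))
    p <- traverse(g, rg$asm)
    expect_setequal(unlist(lapply(p, `[[`, "id")), rg$g$ids)
    expect_equal(sum(vapply(p, nrow, 0L)), length(rg$g$ids))
  }
})

test_that("an error-free simulated chromosome traverses to the true path", {
  ## chromosomes must be long relative to the chunk band: an
  ## end-to-end join scores ~ d * resolution / L under the s^-1 tail,
  ## so L = 1 Mb keeps spurious circularization below min_score
  w <- cached("two_chr_deep", {
    simulate_world(sim_params(n_chromosomes = 2L, chr_len = 1e6,
                              contig_min = 4e4, contig_max = 8e4,
                              n_pairs = 4e5, seed = 21L))
  })
  m <- build_matrix(w$pairs, chunk_index(w$assembly, 10e3))
  prof <- expected_profile(m)
  g <- simplify_graph(build_graph(score_all(m, prof), w$assembly), m)
  paths <- traverse(g, w$assembly)
  tr <- as.data.table(w$truth)[order(chr, g_start)]
  expect_length(paths, 2L)
  for (ch in unique(tr$chr)) {
    want <- tr[chr == ch]$contig
    hit <- Filter(function(m_) m_$id[1L] %in% want ||
                    m_$id[nrow(m_)] %in% want, paths)
    expect_length(hit, 1L)
    m_ <- hit[[1L]]
    if (m_$id[1L] != want[1L])                  # whole-path reversal ok
      m_ <- data.table(id = rev(m_$id),
                       orient = rev(ifelse(m_$orient == "+", "-", "+")))
    expect_equal(m_$id, want)
    expect_equal(m_$orient, rep("+", length(want)))
  }
})
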