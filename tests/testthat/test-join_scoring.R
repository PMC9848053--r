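## A fixed micro-world used by several blocks: contig c0 (10 full
## chunks) pins the expected profile; c1, c2 are the scored pair.
scoring_world <- function(E = c(8, 4, 2), res = 100) {
  asm <- assembly(c("c0", "c1", "c2"), c(1000L, 300L, 300L))
  idx <- chunk_index(asm, res)
  ## intra cells on c0: every (i, i+d) cell gets exactly E[d] pairs
  rows <- list()
  for (d in seq_along(E)) {
    for (i in 0:(9 - d)) {
      if (E[d] > 0)
        rows[[length(rows) + 1L]] <-
          mk_pairs("c0", rep(i * 100, E[d]), "c0", rep((i + d) * 100, E[d]))
    }
  }
  list(asm = asm, idx = idx, intra = rbindlist(rows))
}

test_that("a join whose inter-cells equal the expected values scores 1", {
  sw <- scoring_world()
  ## D_cap = 3 so E = (8, 4, 2) exactly (medians of constant cells)
  ## orientation TH: c1's T end meets c2's H end;
  ## cell (i on c1, j on c2): a = 2 - i, b = j, d = a + b + 1
  rows <- list(sw$intra)
  for (i in 0:2) for (j in 0:2) {
    d <- (2 - i) + j + 1
    if (d <= 3)
      rows[[length(rows) + 1L]] <-
        mk_pairs("c1", rep(i * 100, c(8, 4, 2)[d]),
                 "c2", rep(j * 100, c(8, 4, 2)[d]))
  }
  m <- build_matrix(rbindlist(rows), sw$idx)
  prof <- expected_profile(m, min_support = 1L, D_cap = 3L)
  expect_equal(prof$E, c(8, 4, 2))
  js <- orientation_score(m, prof, "c1", "c2", "TH")
  expect_equal(js$score, 1)
  expect_equal(js$n_cells, 6L)                  # cells with d <= 3
  ## empty band scores exactly zero
  m0 <- build_matrix(sw$intra, sw$idx)
  prof0 <- expected_profile(m0, min_support = 1L, D_cap = 3L)
  z <- orientation_score(m0, prof0, "c1", "c2", "TH")
  expect_equal(z$score, 0)
  expect_error(orientation_score(m, prof, "c1", "c1", "TH"), "self")
})

test_that("orientation scores match the brute-force band-sum oracle", {
  set.seed(101)
  for (case in 1:100) {
    n_extra <- sample(2:3, 1L)
    lens <- c(1000L, sample(150:450, n_extra, replace = TRUE))
    ids <- c("c0", paste0("c", seq_len(n_extra)))
    asm <- assembly(ids, lens)
    idx <- chunk_index(asm, 100)
    sw <- scoring_world()
    p <- sw$intra
    ## random inter pairs among the extra contigs
    n_inter <- sample(5:30, 1L)
    pick <- function(k) {
      ci <- sample(ids[-1L], k, replace = TRUE)
      list(ci = ci, pos = floor(runif(k) * lens[match(ci, ids)]))
    }
    a <- pick(n_inter); b <- pick(n_inter)
    keep <- a$ci != b$ci
    p <- rbind(p, mk_pairs(a$ci[keep], a$pos[keep],
                           b$ci[keep], b$pos[keep]))
    m <- build_matrix(p, idx)
    prof <- expected_profile(m, min_support = 1L, D_cap = 3L)
    A <- ids[2L]; B <- ids[3L]
    o <- sample(c("TH", "HT", "TT", "HH"), 1L)
    got <- orientation_score(m, prof, A, B, o)
    lenv <- setNames(as.numeric(lens), ids)
    want <- oracle_join_score(as.data.frame(canonicalize_pairs(p)),
                              lenv, 100, prof$E, prof$D_max, A, B, o)
    expect_equal(got$score, want$score)
    expect_equal(got$n_cells, want$n_cells)
  }
})

test_that("score symmetry: score(A,B,o) == score(B,A,reverse(o))", {
  w <- small_world()
  m <- build_matrix(w$pairs, chunk_index(w$assembly, 10e3))
  prof <- expected_profile(m)
  ids <- w$assembly$info$id
  set.seed(5)
  for (k in 1:20) {
    ab <- sample(ids, 2L)
    for (o in c("TH", "HT", "TT", "HH")) {
      s1 <- orientation_score(m, prof, ab[1], ab[2], o)
      s2 <- orientation_score(m, prof, ab[2], ab[1],
                              reverse_orientation(o))
      expect_identical(s1$score, s2$score)
    }
  }
})

test_that("best_join tie-breaks by the fixed orientation order", {
  ## single-chunk contigs: all four orientations identical -> TH wins
  sw <- scoring_world()
  asm <- assembly(c("c0", "x", "y"), c(1000L, 100L, 100L))
  idx <- chunk_index(asm, 100)
  p <- rbind(sw$intra, mk_pairs("x", rep(0, 6), "y", rep(0, 6)))
  m <- build_matrix(p, idx)
  prof <- expected_profile(m, min_support = 1L, D_cap = 3L)
  bj <- best_join(m, prof, "x", "y")
  expect_equal(bj$orientation, "TH")
  expect_gt(bj$score, 0)
})

test_that("signal placement forces the winning orientation", {
  ## contacts between c1's high end and c2's low end -> (T, H)
  sw <- scoring_world()
  p <- rbind(sw$intra, mk_pairs("c1", rep(280, 10), "c2", rep(20, 10)))
  m <- build_matrix(p, sw$idx)
  prof <- expected_profile(m, min_support = 1L, D_cap = 3L)
  expect_equal(best_join(m, prof, "c1", "c2")$orientation, "TH")
  ## and on simulator truth: adjacent contigs recover their orientation
  w <- small_world()
  mm <- build_matrix(w$pairs, chunk_index(w$assembly, 10e3))
  pp <- expected_profile(mm)
  tr <- as.data.table(w$truth)[order(chr, g_start)]
  t1 <- tr[chr == "chr01"]
  bj <- best_join(mm, pp, t1$contig[1], t1$contig[2])
  expect_equal(bj$orientation, "TH")            # both stored forward
})

test_that("adding an in-band contact never decreases the score", {
  sw <- scoring_world()
  base <- rbind(sw$intra, mk_pairs("c1", rep(250, 3), "c2", rep(50, 3)))
  m1 <- build_matrix(base, sw$idx)
  prof <- expected_profile(m1, min_support = 1L, D_cap = 3L)
  s1 <- orientation_score(m1, prof, "c1", "c2", "TH")$score
  m2 <- build_matrix(rbind(base, mk_pairs("c1", 260, "c2", 40)), sw$idx)
  s2 <- orientation_score(m2, prof, "c1", "c2", "TH")$score
  expect_gte(s2, s1)
})

test_that("score_all enumerates candidates like exhaustive best_join", {
  ## no shared contacts -> empty
  sw <- scoring_world()
  m0 <- build_matrix(sw$intra, sw$idx)
  prof0 <- expected_profile(m0, min_support = 1L, D_cap = 3L)
  expect_equal(nrow(score_all(m0, prof0, min_pairs = 1L)), 0L)
  ## three contigs all sharing contacts -> exactly 3 join scores
  p <- rbind(sw$intra,
             mk_pairs("c0", rep(950, 6), "c1", rep(0, 6)),
             mk_pairs("c1", rep(250, 6), "c2", rep(50, 6)),
             mk_pairs("c0", rep(950, 6), "c2", rep(0, 6)))
  m <- build_matrix(p, sw$idx)
  prof <- expected_profile(m, min_support = 1L, D_cap = 3L)
  sa <- score_all(m, prof, min_pairs = 1L)
  expect_equal(nrow(sa), 3L)
  expect_true(all(diff(sa$score) <= 0))         # sorted descending
  ## equality with looping best_join over a 10-contig simulation
  w <- cached("ten_contig_world", {
    simulate_world(sim_params(n_chromosomes = 1L, chr_len = 4e5,
                              contig_min = 3e4, contig_max = 6e4,
                              n_pairs = 4e4, seed = 9L))
  })
  mm <- build_matrix(w$pairs, chunk_index(w$assembly, 10e3))
  pp <- expected_profile(mm)
  sa2 <- score_all(mm, pp, min_pairs = 5L)
  ids <- w$assembly$info$id
  inter <- mm$cells[ca != cb, .(n = sum(raw)), by = .(ca, cb)]
  for (r in seq_len(nrow(inter))) {
    A <- ids[inter$ca[r]]; B <- ids[inter$cb[r]]
    ab <- sort(c(A, B))
    row <- sa2[contig_a == ab[1] & contig_b == ab[2]]
    if (inter$n[r] < 5) {
      expect_equal(nrow(row), 0L)
      next
    }
    bj <- best_join(mm, pp, ab[1], ab[2])
    expect_equal(row$score, bj$score)
    expect_equal(row$orientation, bj$orientation)
  }
})

test_that("neighbor and random-pair scores are well separated", {
  w <- small_world()
  m <- build_matrix(w$pairs, chunk_index(w$assembly, 10e3))
  prof <- expected_profile(m)
  tr <- as.data.table(w$truth)[order(chr, g_start)]
  neigh <- c()
  for (ch in unique(tr$chr)) {
    t <- tr[chr == ch]
    for (i in seq_len(nrow(t) - 1L))
      neigh <- c(neigh, best_join(m, prof, t$contig[i],
                                  t$contig[i + 1L])$score)
  }
  set.seed(2)
  rand <- c()
  while (length(rand) < 30) {
    ab <- sample(tr$contig, 2L)
    rows <- tr[contig %in% ab]
    same_chr <- length(unique(rows$chr)) == 1L
    adjacent <- same_chr && min(abs(outer(rows$g_start, rows$g_end, "-"))) < 1
    if (!adjacent)
      rand <- c(rand, best_join(m, prof, ab[1], ab[2])$score)
  }
  expect_gte(median(neigh), 5 * median(rand))
})
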