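## Seeded simulator with full truth provenance.
##
## The simulated world: a multi-chromosome genome of i.i.d. uniform
## ACGT sequence, fragmented into contigs of a uniform length range,
## optionally corrupted by misjoined contigs (direct concatenations in
## random orientations), and Hi-C pairs whose cis separation follows a
## truncated power law s^(-alpha) with a uniform trans background.
## Every emitted pair's genome coordinates are kept as a provenance
## side channel, and a truth map records each contig part's placement.

#' Simulation parameters
#'
#' Defaults are the desk-scale preset: 20 chromosomes of 1 Mb,
#' contigs uniform on 20-100 kb, 2e6 pairs, contact-decay exponent 1
#' with a 5% trans fraction.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chr_len chromosome length in bp.
#' @param contig_min,contig_max contig length range in bp.
#' @param n_pairs number of Hi-C pairs.
#' @param alpha contact-decay exponent (`p(s) ~ s^-alpha`), > 0.
#' @param s_min minimum cis separation in bp.
#' @param trans_frac fraction of trans (uniform background) pairs,
#'   in `[0, 1)` (or exactly 1 for a pure-noise control).
#' @param mapq constant mapping quality emitted.
#' @param seed RNG seed.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_chromosomes = 20L, chr_len = 1e6,
                       contig_min = 20e3, contig_max = 100e3,
                       n_pairs = 2e6, alpha = 1, s_min = 1e3,
                       trans_frac = 0.05, mapq = 60L, seed = 1L) {
  stopifnot(contig_min >= 1, contig_min <= contig_max,
            contig_max <= chr_len, alpha > 0,
            trans_frac >= 0, trans_frac <= 1)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chr_len = chr_len, contig_min = contig_min,
                 contig_max = contig_max, n_pairs = n_pairs,
                 alpha = alpha, s_min = s_min, trans_frac = trans_frac,
                 mapq = as.integer(mapq), seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a genome
#'
#' @param params [sim_params()].
#' @param with_sequence also generate the i.i.d. uniform ACGT sequence
#'   (skip for pipeline stages that only need coordinates).
#' @return list of class `sim_genome`: `lengths` (named) and `seqs`
#'   ([Biostrings::DNAStringSet] or `NULL`).
#' @export
simulate_genome <- function(params, with_sequence = TRUE) {
  set.seed(params$seed)
  nm <- sprintf("chr%02d", seq_len(params$n_chromosomes))
  lens <- setNames(rep(params$chr_len, params$n_chromosomes), nm)
  seqs <- NULL
  if (with_sequence) {
    seqs <- Biostrings::DNAStringSet(vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), ""))
    names(seqs) <- nm
  }
  structure(list(lengths = lens, seqs = seqs), class = "sim_genome")
}

#' Fragment a genome into contigs
#'
#' Fragment lengths are uniform on `[min_len, max_len]` (the final
#' fragment of each chromosome may be shorter); contigs are shuffled
#' and renamed. The returned truth map tiles each chromosome exactly.
#'
#' @param genome `sim_genome`.
#' @param min_len,max_len fragment length range in bp.
#' @param seed RNG seed.
#' @return list with `assembly` ([assembly()]) and `truth`
#'   (`data.table(contig, part, chr, g_start, g_end, strand, c_start,
#'   c_end)`; coordinates 0-based half-open).
#' @export
fragment_genome <- function(genome, min_len = 20e3, max_len = 100e3,
                            seed = 1L) {
  stopifnot(min_len >= 1)
  set.seed(seed)
  rows <- list()
  for (chr in names(genome$lengths)) {
    L <- genome$lengths[[chr]]
    starts <- numeric(0)
    at <- 0
    while (at < L) {
      starts <- c(starts, at)
      at <- at + if (min_len >= L) L
                 else floor(runif(1, min_len, max_len + 1))
    }
    ends <- c(starts[-1L], L)
    rows[[chr]] <- data.table(chr = chr, g_start = starts, g_end = ends)
  }
  truth <- rbindlist(rows)
  truth <- truth[sample(nrow(truth))]        # shuffle contig order
  truth[, `:=`(contig = sprintf("ctg%04d", seq_len(nrow(truth))),
               part = 1L, strand = "+",
               c_start = 0, c_end = g_end - g_start)]
  seqs <- NULL
  if (!is.null(genome$seqs)) {
    seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(truth)),
      function(i) Biostrings::subseq(genome$seqs[[truth$chr[i]]],
                                     truth$g_start[i] + 1L,
                                     truth$g_end[i])))
    names(seqs) <- truth$contig
  }
  asm <- assembly(truth$contig, truth$c_end, seqs = seqs)
  list(assembly = asm,
       truth = truth[, .(contig, part, chr, g_start, g_end, strand,
                         c_start, c_end)])
}

#' Inject misjoined contigs
#'
#' Implements the benchmark misjoin scheme: `n_intra` single misjoins
#' of two same-chromosome contigs, `n_inter` single misjoins of two
#' different-chromosome contigs, and `n_double` double misjoins of any
#' three contigs, drawn without replacement, concatenated directly (no
#' gap) in random orientations. Total injected junctions =
#' `n_intra + n_inter + 2 * n_double`.
#'
#' @param asm contig [assembly()].
#' @param truth truth map from [fragment_genome()].
#' @param n_intra,n_inter,n_double counts per misjoin class.
#' @param seed RNG seed.
#' @return list with `assembly`, `truth` (multi-part rows for misjoined
#'   contigs) and `errors`
#'   (`data.table(contig, pos, class)`, one row per junction).
#' @export
introduce_misjoins <- function(asm, truth, n_intra = 10L, n_inter = 10L,
                               n_double = 5L, seed = 1L) {
  set.seed(seed)
  stopifnot(all(truth$part == 1L))
  need <- 2L * (n_intra + n_inter) + 3L * n_double
  if (need > nrow(truth)) stop("not enough contigs to inject misjoins")
  pool <- truth$contig
  pick_intra <- function() {
    tab <- truth[contig %in% pool, .N, by = chr][N >= 2L]
    if (!nrow(tab)) stop("no chromosome with 2 available contigs")
    ch <- sample(tab$chr, 1L)
    sample(truth[contig %in% pool & chr == ch]$contig, 2L)
  }
  pick_inter <- function() {
    avail <- truth[contig %in% pool]
    repeat {
      two <- sample(avail$contig, 2L)
      if (length(unique(avail[contig %in% two]$chr)) == 2L) return(two)
    }
  }
  groups <- list()
  for (i in seq_len(n_intra)) {
    g <- pick_intra(); pool <- setdiff(pool, g)
    groups[[length(groups) + 1L]] <- list(ids = g, class = "intra")
  }
  for (i in seq_len(n_inter)) {
    g <- pick_inter(); pool <- setdiff(pool, g)
    groups[[length(groups) + 1L]] <- list(ids = g, class = "inter")
  }
  for (i in seq_len(n_double)) {
    g <- sample(pool, 3L); pool <- setdiff(pool, g)
    groups[[length(groups) + 1L]] <- list(ids = g, class = "double")
  }
  lens <- asm_lengths(asm)
  new_truth <- list(); new_errors <- list()
  new_ids <- character(0); new_lens <- numeric(0)
  new_seqs <- list()
  for (k in seq_along(groups)) {
    grp <- groups[[k]]
    id <- sprintf("mis%02d_%s", k, grp$class)
    orients <- sample(c("+", "-"), length(grp$ids), replace = TRUE)
    at <- 0
    tparts <- list()
    for (j in seq_along(grp$ids)) {
      cid <- grp$ids[j]
      L <- lens[[cid]]
      tr <- truth[contig == cid]
      tparts[[j]] <- data.table(contig = id, part = j, chr = tr$chr,
                                g_start = tr$g_start, g_end = tr$g_end,
                                strand = orients[j],
                                c_start = at, c_end = at + L)
      at <- at + L
    }
    junct <- cumsum(lens[grp$ids])
    junct <- junct[-length(junct)]
    new_truth[[k]] <- rbindlist(tparts)
    new_errors[[k]] <- data.table(contig = id, pos = junct,
                                  class = grp$class)
    new_ids <- c(new_ids, id)
    new_lens <- c(new_lens, at)
    if (!is.null(asm$seqs)) {
      pieces <- lapply(seq_along(grp$ids), function(j) {
        s <- asm$seqs[[grp$ids[j]]]
        if (orients[j] == "-") Biostrings::reverseComplement(s) else s
      })
      new_seqs[[id]] <- do.call(Biostrings::xscat, pieces)
    }
  }
  used <- setdiff(truth$contig, pool)
  keep <- truth[contig %in% pool]
  ids2 <- c(pool[order(match(pool, asm$info$id))], new_ids)
  lens2 <- c(lens[setdiff(ids2, new_ids)], setNames(new_lens, new_ids))
  seqs2 <- NULL
  if (!is.null(asm$seqs)) {
    seqs2 <- c(asm$seqs[setdiff(ids2, new_ids)],
               Biostrings::DNAStringSet(new_seqs))
  }
  truth2 <- rbind(keep, rbindlist(new_truth))
  list(assembly = assembly(ids2, lens2[ids2], seqs = seqs2),
       truth = truth2, errors = rbindlist(new_errors))
}

## inverse-CDF sampler for p(s) ~ s^-alpha on [s_min, L]
.sample_powerlaw <- function(u, alpha, s_min, L) {
  if (abs(alpha - 1) < 1e-12) {
    s_min * (L / s_min)^u
  } else {
    a1 <- 1 - alpha
    (s_min^a1 + u * (L^a1 - s_min^a1))^(1 / a1)
  }
}

#' Truncated power-law separation CDF
#'
#' Analytic CDF of the cis-separation law. With
#' `placement_thinned = TRUE` (the law [simulate_hic()] realizes) the
#' density is `s^-alpha * (1 - s/L)`: drawing one end uniformly and
#' redrawing off-chromosome proposals thins separation `s` by the
#' fraction of placements that fit on the chromosome.
#'
#' @param s separations (bp).
#' @param alpha decay exponent.
#' @param s_min,L truncation bounds.
#' @param placement_thinned apply the `(1 - s/L)` placement factor
#'   (default `TRUE`); `FALSE` gives the pure truncated power law.
#' @return `P(S <= s)`.
#' @export
powerlaw_cdf <- function(s, alpha, s_min, L, placement_thinned = TRUE) {
  s <- pmin(pmax(s, s_min), L)
  ## antiderivative of t^-alpha (1 - t/L) resp. t^-alpha
  G <- if (!placement_thinned) {
    if (abs(alpha - 1) < 1e-12) function(t) log(t)
    else function(t) t^(1 - alpha) / (1 - alpha)
  } else if (abs(alpha - 1) < 1e-12) {
    function(t) log(t) - t / L
  } else if (abs(alpha - 2) < 1e-12) {
    function(t) -1 / t - log(t) / L
  } else {
    function(t) t^(1 - alpha) / (1 - alpha) -
      t^(2 - alpha) / ((2 - alpha) * L)
  }
  (G(s) - G(s_min)) / (G(L) - G(s_min))
}

#' Simulate Hi-C pairs with truth provenance
#'
#' Cis pairs (fraction `1 - trans_frac`): one end uniform on a
#' chromosome drawn proportionally to length, separation from the
#' truncated power law, random direction, redrawn while off-chromosome.
#' Trans pairs: both ends uniform on the genome. Genome positions are
#' mapped through the truth map to contig coordinates, so misjoined
#' contigs receive the union of their parts' signal and junctions get
#' no artificial depletion.
#'
#' @param genome `sim_genome`.
#' @param truth truth map (possibly with misjoins).
#' @param params [sim_params()].
#' @param seed RNG seed (defaults to `params$seed + 1`).
#' @return pairs `data.table` with canonical columns plus provenance
#'   columns `chr1, g1, chr2, g2`.
#' @export
simulate_hic <- function(genome, truth, params,
                         seed = params$seed + 1L) {
  set.seed(seed)
  lens <- genome$lengths
  chrs <- names(lens)
  n <- params$n_pairs
  n_cis <- round(n * (1 - params$trans_frac))
  n_trans <- n - n_cis
  if (length(chrs) < 2L) {        # trans impossible on one chromosome
    n_cis <- n; n_trans <- 0L
  }
  draw_chr <- function(k) sample(chrs, k, replace = TRUE,
                                 prob = lens / sum(lens))
  ## cis: one end uniform, separation from the truncated power law,
  ## random direction; off-chromosome proposals are redrawn entirely.
  ## The joint (p1, p2) density is then uniform per locus pair at a
  ## given separation — no artificial end-to-end enrichment — and the
  ## realized separation law is the power law thinned by (1 - s/L)
  ## (see powerlaw_cdf(placement_thinned = TRUE)).
  c_chr <- draw_chr(n_cis)
  c_L <- unname(lens[c_chr])
  p1 <- floor(runif(n_cis) * c_L)
  s <- round(.sample_powerlaw(runif(n_cis), params$alpha,
                              params$s_min, c_L))
  p2 <- p1 + s * sample(c(-1, 1), n_cis, replace = TRUE)
  bad <- which(p2 < 0 | p2 >= c_L)
  while (length(bad)) {
    p1[bad] <- floor(runif(length(bad)) * c_L[bad])
    s2 <- round(.sample_powerlaw(runif(length(bad)), params$alpha,
                                 params$s_min, c_L[bad]))
    p2[bad] <- p1[bad] + s2 * sample(c(-1, 1), length(bad),
                                     replace = TRUE)
    bad <- bad[p2[bad] < 0 | p2[bad] >= c_L[bad]]
  }
  ## trans: both ends uniform, on two different chromosomes
  t_chr1 <- draw_chr(n_trans); t_chr2 <- draw_chr(n_trans)
  coll <- which(t_chr1 == t_chr2)
  while (length(coll)) {
    t_chr2[coll] <- draw_chr(length(coll))
    coll <- coll[t_chr1[coll] == t_chr2[coll]]
  }
  t_p1 <- floor(runif(n_trans) * unname(lens[t_chr1]))
  t_p2 <- floor(runif(n_trans) * unname(lens[t_chr2]))
  gchr1 <- c(c_chr, t_chr1); gp1 <- c(p1, t_p1)
  gchr2 <- c(c_chr, t_chr2); gp2 <- c(p2, t_p2)
  m1 <- .genome_to_contig(gchr1, gp1, truth)
  m2 <- .genome_to_contig(gchr2, gp2, truth)
  canonicalize_pairs(data.table(
    contig1 = m1$contig, pos1 = m1$pos, mapq1 = params$mapq,
    contig2 = m2$contig, pos2 = m2$pos, mapq2 = params$mapq,
    chr1 = gchr1, g1 = gp1, chr2 = gchr2, g2 = gp2))
}

## map genome coordinates to contig coordinates through the truth map
.genome_to_contig <- function(chr, gpos, truth) {
  tr <- as.data.table(truth)[order(chr, g_start)]
  contig <- character(length(chr))
  pos <- numeric(length(chr))
  for (ch in unique(tr$chr)) {
    sel <- which(chr == ch)
    if (!length(sel)) next
    t <- tr[chr == ch]
    i <- findInterval(gpos[sel], t$g_start)
    stopifnot(all(i >= 1L), all(gpos[sel] < t$g_end[i]))
    contig[sel] <- t$contig[i]
    pos[sel] <- ifelse(t$strand[i] == "+",
                       t$c_start[i] + (gpos[sel] - t$g_start[i]),
                       t$c_start[i] + (t$g_end[i] - 1 - gpos[sel]))
  }
  list(contig = contig, pos = pos)
}

#' Full desk-scale benchmark world
#'
#' Convenience wrapper producing the complete stated world used by the
#' acceptance suite: genome, fragmented contigs, optional misjoins per
#' the 10/10/5 scheme, and pairs.
#'
#' @param params [sim_params()].
#' @param misjoins inject misjoins (default scheme: 10 intra / 10 inter
#'   / 5 double).
#' @param n_intra,n_inter,n_double misjoin counts when
#'   `misjoins = TRUE`.
#' @param with_sequence generate sequences (not needed for
#'   coordinate-only analyses).
#' @return list with `genome`, `assembly`, `truth`, `errors` (NULL when
#'   `misjoins = FALSE`) and `pairs`.
#' @export
simulate_world <- function(params = sim_params(), misjoins = FALSE,
                           n_intra = 10L, n_inter = 10L, n_double = 5L,
                           with_sequence = FALSE) {
  genome <- simulate_genome(params, with_sequence = with_sequence)
  fr <- fragment_genome(genome, params$contig_min, params$contig_max,
                        seed = params$seed)
  asm <- fr$assembly; truth <- fr$truth; errors <- NULL
  if (misjoins) {
    mj <- introduce_misjoins(asm, truth, n_intra = n_intra,
                             n_inter = n_inter, n_double = n_double,
                             seed = params$seed)
    asm <- mj$assembly; truth <- mj$truth; errors <- mj$errors
  }
  pairs <- simulate_hic(genome, truth, params)
  list(genome = genome, assembly = asm, truth = truth,
       errors = errors, pairs = pairs)
}
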