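## Shared fixtures, built in code and cached for the session.

library(data.table)

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .world_cache))
    assign(key, expr, envir = .world_cache)
  get(key, envir = .world_cache)
}

## small world: 4 chromosomes x 500 kb, 2e5 pairs
small_world <- function(seed = 7L, n_pairs = 2e5) {
  cached(sprintf("small_%d_%g", seed, n_pairs), {
    simulate_world(sim_params(n_chromosomes = 4L, chr_len = 5e5,
                              n_pairs = n_pairs, seed = seed))
  })
}

## the stated desk-scale world (20 chr x 1 Mb, 2e6 pairs), seed 1
desk_world <- function(misjoins = FALSE) {
  cached(paste0("desk_", misjoins), {
    simulate_world(sim_params(seed = 1L), misjoins = misjoins)
  })
}

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

## tiny assembly with explicit sequences
toy_assembly <- function(seqs) {
  ss <- Biostrings::DNAStringSet(seqs)
  assembly(names(seqs), Biostrings::width(ss), seqs = ss)
}

## pairs table shortcut (0-based positions, constant mapq)
mk_pairs <- function(c1, p1, c2, p2, mapq = 60L) {
  data.table(contig1 = c1, pos1 = p1, mapq1 = mapq,
             contig2 = c2, pos2 = p2, mapq2 = mapq)
}

## random paths partitioning an assembly, for AGP round-trip tests
random_paths <- function(asm, seed) {
  set.seed(seed)
  ids <- sample(asm$info$id)
  k <- sample(seq_len(length(ids)), 1L)
  grp <- sort(sample(k, length(ids), replace = TRUE))
  scaffold_paths(lapply(split(ids, grp), function(g)
    data.table(id = g, orient = sample(c("+", "-"), length(g),
                                       replace = TRUE))))
}
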