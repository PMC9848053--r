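#' Pipeline configuration
#'
#' Collects every tunable of the scaffolding run. The resolution ladder
#' must be strictly increasing (rounds proceed from fine to coarse
#' chunks); `scale` multiplies the default ladder for desk-scale data.
#'
#' @param resolutions strictly increasing bp ladder; default
#'   `c(10e3, 20e3, 50e3, 100e3, 200e3, 500e3, 1e6, 2e6, 5e6) * scale`.
#' @param scale ladder scale factor (default 1).
#' @param mapq_min mapping-quality filter (default 10).
#' @param motifs optional restriction-enzyme IUPAC motifs; when given,
#'   matrices are cut-site normalized before profile estimation and
#'   scoring.
#' @param min_support,D_cap expected-profile parameters.
#' @param min_pairs,min_score join enumeration / edge filters.
#' @param max_tip_contigs,repeat_factor,max_bubble_edges,ratio,theta
#'   graph-simplification parameters.
#' @param window,max_span,flank,min_ratio,end_guard breakpoint-detection
#'   parameters (bp; `flank`/`end_guard` default to 10 and 5 windows).
#' @param min_join_ratio post-scaffolding join-support threshold.
#' @param gap_len scaffold gap size in bp.
#' @param correct_breaks run pre-scaffolding error correction.
#' @param post_check run post-scaffolding join check.
#' @param seed integer seed recorded in the config (the pipeline itself
#'   is deterministic; the seed matters for simulation inputs).
#' @param verbose per-round logging.
#' @return list of class `scaffold_config`.
#' @export
scaffold_config <- function(resolutions = NULL, scale = 1,
                            mapq_min = 10L, motifs = NULL,
                            min_support = 8L, D_cap = 32L,
                            min_pairs = 5L, min_score = 0.1,
                            max_tip_contigs = 1L, repeat_factor = 2,
                            max_bubble_edges = 3L, ratio = 1.5,
                            theta = 0.75,
                            window = 1000L, max_span = 1e6,
                            flank = 10L * window, min_ratio = 0.1,
                            end_guard = 5L * window,
                            min_join_ratio = 0.1, gap_len = 200L,
                            correct_breaks = TRUE, post_check = TRUE,
                            seed = 1L, verbose = FALSE) {
  if (is.null(resolutions))
    resolutions <- c(10e3, 20e3, 50e3, 100e3, 200e3,
                     500e3, 1e6, 2e6, 5e6) * scale
  if (length(resolutions) && any(diff(resolutions) <= 0))
    stop("resolution ladder must be strictly increasing")
  cfg <- list(resolutions = resolutions, mapq_min = mapq_min,
              motifs = motifs, min_support = min_support, D_cap = D_cap,
              min_pairs = min_pairs, min_score = min_score,
              max_tip_contigs = max_tip_contigs,
              repeat_factor = repeat_factor,
              max_bubble_edges = max_bubble_edges, ratio = ratio,
              theta = theta, window = window, max_span = max_span,
              flank = flank, min_ratio = min_ratio,
              end_guard = end_guard, min_join_ratio = min_join_ratio,
              gap_len = gap_len, correct_breaks = correct_breaks,
              post_check = post_check, seed = as.integer(seed),
              verbose = verbose)
  class(cfg) <- "scaffold_config"
  cfg
}

#' Desk-scale pipeline configuration
#'
#' The configuration used with the bundled desk-scale simulator
#' (20 chromosomes x 1 Mb, contigs 20-100 kb): resolution ladder
#' 10/20/50/100 kb and `max_span` 5 kb. The spanning-coverage
#' statistic must stay *local*: under the simulator's scale-free
#' `s^-1` decay the pairs bridging a misjoin junction scale like
#' `max_span^2 / D` (`D` the junction's true genomic distance) while
#' flank coverage scales like `max_span * log(max_span / s_min)`, so
#' valley contrast improves as `max_span` shrinks toward the bottom of
#' the decay range. 5 kb (five windows, five times the simulator's
#' minimum separation) keeps flank coverage at tens of pairs per
#' window — far above Poisson noise — while suppressing the junction
#' floor well below the `min_ratio` threshold; the genome-scale 1 Mb
#' default spans whole desk-scale chromosomes and washes the valleys
#' out entirely.
#'
#' @param ... overrides passed to [scaffold_config()].
#' @return `scaffold_config`.
#' @export
desk_config <- function(...) {
  defaults <- list(resolutions = c(10e3, 20e3, 50e3, 100e3),
                   max_span = 5e3)
  args <- utils::modifyList(defaults, list(...))
  do.call(scaffold_config, args)
}

#' Map pair coordinates through an AGP placement
#'
#' @param pairs pairs table in component coordinates.
#' @param agp AGP as returned by [read_agp()] (`$records`), a records
#'   table, or AGP text lines.
#' @return pairs table in object coordinates, canonicalized; count
#'   conserved.
#' @export
lift_pairs <- function(pairs, agp) {
  rec <- if (is.data.frame(agp)) as.data.table(agp)
         else if (is.list(agp)) agp$records
         else read_agp(agp)$records
  w <- rec[component_type == "W"]
  if (anyDuplicated(w$component_id))
    stop("component placed more than once in AGP")
  p <- as.data.table(pairs)
  i1 <- match(p$contig1, w$component_id)
  i2 <- match(p$contig2, w$component_id)
  if (anyNA(i1) || anyNA(i2))
    stop("pair references component absent from AGP: ",
         p$contig1[which(is.na(i1))[1L]])
  map <- function(i, pos) {
    off <- w$object_beg[i] - 1
    len <- w$component_end[i] - w$component_beg[i] + 1
    ifelse(w$orient[i] == "+", off + pos, off + (len - 1 - pos))
  }
  canonicalize_pairs(data.table(
    contig1 = w$object[i1], pos1 = map(i1, p$pos1), mapq1 = p$mapq1,
    contig2 = w$object[i2], pos2 = map(i2, p$pos2), mapq2 = p$mapq2))
}

#' One scaffolding round at one resolution
#'
#' Matrix, expected profile, join scores, graph cascade and traversal at
#' the given resolution. If the expected profile cannot be estimated
#' (resolution too fine for the unit sizes) the round is skipped with a
#' warning and every unit becomes a singleton path.
#'
#' @param asm [assembly()] of the current units.
#' @param pairs pairs table in current unit coordinates.
#' @param resolution chunk size in bp.
#' @param config [scaffold_config()].
#' @return `scaffold_paths` over the current units.
#' @export
run_round <- function(asm, pairs, resolution, config = scaffold_config()) {
  idx <- chunk_index(asm, resolution)
  mat <- build_matrix(pairs, idx)
  if (!is.null(config$motifs) && !is.null(asm$seqs))
    mat <- site_normalize(mat, asm$seqs, config$motifs)
  prof <- tryCatch(
    expected_profile(mat, min_support = config$min_support,
                     D_cap = config$D_cap),
    error = function(e) {
      warning("round at resolution ", resolution, " skipped: ",
              conditionMessage(e))
      NULL
    })
  if (is.null(prof)) return(singleton_paths(asm))
  scores <- score_all(mat, prof, min_pairs = config$min_pairs)
  g <- build_graph(scores, asm, min_score = config$min_score)
  g <- simplify_graph(g, mat,
                      max_tip_contigs = config$max_tip_contigs,
                      repeat_factor = config$repeat_factor,
                      max_bubble_edges = config$max_bubble_edges,
                      ratio = config$ratio, theta = config$theta,
                      verbose = config$verbose)
  traverse(g, asm, gap_len = config$gap_len)
}

## compose: outer paths over units that are themselves paths of members
.compose_paths <- function(outer, inner) {
  members <- lapply(seq_along(outer), function(k) {
    m <- outer[[k]]
    rbindlist(lapply(seq_len(nrow(m)), function(i) {
      sub <- inner[[m$id[i]]]
      if (is.null(sub)) stop("unknown inner path: ", m$id[i])
      if (m$orient[i] == "+") sub
      else data.table(id = rev(sub$id),
                      orient = rev(ifelse(sub$orient == "+", "-", "+")))
    }))
  })
  scaffold_paths(members, names = names(outer))
}

#' Run the full hierarchical scaffolding pipeline
#'
#' Optional pre-scaffolding error correction, one scaffolding round per
#' ladder resolution (each round re-scaffolds the previous round's
#' scaffolds), optional post-scaffolding join check, and final naming of
#' scaffolds by descending length. Fully deterministic for fixed inputs
#' and configuration.
#'
#' @param asm input contig [assembly()].
#' @param pairs pairs table in contig coordinates (already mapq
#'   filtered, e.g. by [read_pairs()]).
#' @param config [scaffold_config()].
#' @return list of class `scaffold_result` with elements `paths`
#'   (final `scaffold_paths` over corrected contigs), `assembly`
#'   (corrected contig assembly), `breaks` (breakpoint report),
#'   `agp` (AGP text lines), `scaffolds` (scaffold-level assembly) and
#'   `lift` (contig correction lift table).
#' @export
hic_scaffold <- function(asm, pairs, config = scaffold_config()) {
  pairs <- canonicalize_pairs(as.data.table(pairs))
  breaks <- data.table(contig = character(), pos = numeric(),
                       kind = character(), evidence = numeric())
  lift <- NULL
  if (config$correct_breaks) {
    breaks <- detect_breakpoints(pairs, asm, window = config$window,
                                 max_span = config$max_span,
                                 flank = config$flank,
                                 min_ratio = config$min_ratio,
                                 end_guard = config$end_guard)
    if (nrow(breaks)) {
      ab <- apply_breaks(asm, breaks)
      asm <- ab$assembly
      lift <- ab$lift
      pairs <- lift_pairs_breaks(pairs, lift)
    }
    if (config$verbose)
      message(sprintf("error correction: %d breaks", nrow(breaks)))
  }
  base_asm <- asm
  cur_paths <- singleton_paths(base_asm)   # over base units
  for (round in seq_along(config$resolutions)) {
    res <- config$resolutions[round]
    cur_asm <- flatten_paths(cur_paths, base_asm, config$gap_len,
                             with_seqs = !is.null(config$motifs))
    agp <- write_agp(cur_paths, base_asm, gap_len = config$gap_len)
    cur_pairs <- lift_pairs(pairs, read_agp(agp)$records)
    if (config$verbose)
      message(sprintf("round at %g bp: %d units in", res,
                      length(cur_asm)))
    rp <- run_round(cur_asm, cur_pairs, res, config)
    cur_paths <- .compose_paths(rp, cur_paths)
    names(cur_paths) <- paste0("r", round, "_s", seq_along(cur_paths))
  }
  if (config$post_check && length(cur_paths)) {
    checks <- post_scaffold_check(cur_paths, pairs, base_asm,
                                  gap_len = config$gap_len,
                                  max_span = config$max_span,
                                  min_join_ratio = config$min_join_ratio)
    diss <- checks[dissolve == TRUE]
    if (nrow(diss)) {
      cur_paths <- dissolve_joins(cur_paths, checks)
      breaks <- rbind(breaks, data.table(
        contig = diss$contig_before, pos = diss$pos,
        kind = "post_scaffold", evidence = diss$ratio))
    }
  }
  ## final deterministic naming by descending scaffold length
  len <- path_lengths(cur_paths, base_asm, config$gap_len)
  first <- vapply(cur_paths, function(m) m$id[1L], "")
  ord <- order(-len, first)
  final <- scaffold_paths(unclass(cur_paths)[ord])
  agp <- write_agp(final, base_asm, gap_len = config$gap_len)
  structure(list(paths = final, assembly = base_asm, breaks = breaks,
                 agp = agp,
                 scaffolds = flatten_paths(final, base_asm,
                                           config$gap_len),
                 lift = lift, config = config),
            class = "scaffold_result")
}

#' @export
print.scaffold_result <- function(x, ...) {
  lens <- sort(x$scaffolds$info$length, decreasing = TRUE)
  nx <- nx_stats(lens, 50)
  cat(sprintf(paste0("scaffold_result: %d scaffolds from %d units, ",
                     "total %.3f Mb, N50 %.3f Mb (L50 %d), %d breaks\n"),
              length(x$paths), length(x$assembly),
              sum(lens) / 1e6, nx[["Nx"]] / 1e6, nx[["Lx"]],
              nrow(x$breaks)))
  invisible(x)
}

#' Write all pipeline outputs
#'
#' @param result `scaffold_result` from [hic_scaffold()].
#' @param prefix output path prefix; writes
#'   `<prefix>_scaffolds_final.agp`, `<prefix>_scaffolds_final.fa`
#'   (when sequences are available), `<prefix>_breaks.tsv` and a run
#'   summary `<prefix>.log`.
#' @return invisible vector of written paths.
#' @export
write_scaffold_result <- function(result, prefix) {
  out <- character(0)
  agp_path <- paste0(prefix, "_scaffolds_final.agp")
  writeLines(result$agp, agp_path)
  out <- c(out, agp_path)
  if (!is.null(result$scaffolds$seqs)) {
    fa <- paste0(prefix, "_scaffolds_final.fa")
    write_assembly_fasta(result$scaffolds, fa)
    out <- c(out, fa)
  }
  br <- paste0(prefix, "_breaks.tsv")
  fwrite(result$breaks, br, sep = "\t")
  out <- c(out, br)
  lg <- paste0(prefix, ".log")
  lens <- sort(result$scaffolds$info$length, decreasing = TRUE)
  n50 <- nx_stats(lens, 50); n90 <- nx_stats(lens, 90)
  writeLines(c(
    sprintf("hicscaff %s", as.character(utils::packageVersion("hicscaff"))),
    sprintf("units in: %d; scaffolds out: %d", length(result$assembly),
            length(result$paths)),
    sprintf("total bp: %.0f", sum(lens)),
    sprintf("N50: %.0f (L50 %d); N90: %.0f (L90 %d)",
            n50[["Nx"]], n50[["Lx"]], n90[["Nx"]], n90[["Lx"]]),
    sprintf("breaks: %d pre-scaffold, %d post-scaffold",
            sum(result$breaks$kind == "pre_scaffold"),
            sum(result$breaks$kind == "post_scaffold")),
    sprintf("resolution ladder: %s",
            paste(result$config$resolutions, collapse = ", "))), lg)
  out <- c(out, lg)
  invisible(out)
}
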