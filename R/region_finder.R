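# Turning window-level diversity tracks into filtered candidate target
# regions: core detection, repeat masking, copy-number/depth screening, and
# the per-subpopulation selection/inbreeding filter. Each filter sets an
# independent flag computed from the unfiltered region, so filter order does
# not matter; the pass set is the zero-flag set.

#' Panel design configuration
#'
#' Thresholds of the candidate-region pipeline. Defaults: cores are maximal
#' window runs with pi > 0.005 totalling 50-150 bp, flanked on both sides by
#' at least `min_flank_bp` of windows with pi < 1e-4; regions are discarded
#' as copy-number suspects when depth exceeds 20,000x in all (remaining)
#' samples, core pi exceeds 0.02 or the core carries more than 25 SNPs;
#' samples below 5,000x mean core depth are excluded from a region's
#' statistics; regions failing -2 < D < 2 or f < 0.25 in any subpopulation
#' are discarded.
#'
#' @param pi_core_min core window diversity floor.
#' @param pi_flank_max flank window diversity ceiling.
#' @param core_min_bp,core_max_bp core length bounds.
#' @param min_flank_bp minimum quiet flank per side (one primer footprint).
#' @param depth_ceiling per-sample depth above which a region is
#'   copy-number suspect when exceeded in all samples.
#' @param depth_floor per-sample mean core depth below which a sample is
#'   excluded from that region's statistics.
#' @param pi_ceiling,snp_ceiling core diversity and SNP-count ceilings of
#'   the copy-number screen.
#' @param tajima_bounds open interval D must lie in, per subpopulation.
#' @param f_ceiling inbreeding coefficient ceiling, per subpopulation.
#' @param fail_null_d should a subpopulation with no segregating sites (D
#'   undefined) fail the region? Conservative default `TRUE`.
#' @return a list of class `design_config`.
#' @export
design_config <- function(pi_core_min = 0.005, pi_flank_max = 1e-4,
                          core_min_bp = 50, core_max_bp = 150,
                          min_flank_bp = 30,
                          depth_ceiling = 20000, depth_floor = 5000,
                          pi_ceiling = 0.02, snp_ceiling = 25,
                          tajima_bounds = c(-2, 2), f_ceiling = 0.25,
                          fail_null_d = TRUE) {
  stopifnot(pi_core_min > 0, pi_flank_max > 0, core_min_bp <= core_max_bp,
            tajima_bounds[1] < tajima_bounds[2])
  structure(as.list(environment()), class = "design_config")
}

#' Scan a diversity track for candidate target regions
#'
#' Maximal runs of consecutive windows with `pi > pi_core_min` whose total
#' length lies within the core bounds become candidate cores. A core is kept
#' only when the adjacent windows covering at least `min_flank_bp` on each
#' side all have `pi < pi_flank_max`; cores at contig ends (missing a full
#' flank) are rejected.
#'
#' @param pi_track a `window_stats` track from [windowed_pi()] (tiled,
#'   sorted).
#' @param config a [design_config()].
#' @return data frame of class `candidate_regions`: core and flank
#'   intervals, core `pi_core`/`S_core`, and all-FALSE filter flags.
#' @export
scan_candidates <- function(pi_track, config = design_config()) {
  window_bp <- attr(pi_track, "window_bp") %||%
    as.integer(stats::median(pi_track$end - pi_track$start))
  k_flank <- as.integer(ceiling(config$min_flank_bp / window_bp))
  out <- list()
  for (ct in unique(pi_track$contig)) {
    tr <- pi_track[pi_track$contig == ct, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    hot <- tr$pi > config$pi_core_min
    r <- rle(hot)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- run_start[j]; i1 <- run_end[j]
      core_start <- tr$start[i0]; core_end <- tr$end[i1]
      core_len <- core_end - core_start
      if (core_len < config$core_min_bp || core_len > config$core_max_bp) next
      li <- (i0 - k_flank):(i0 - 1L)
      ri <- (i1 + 1L):(i1 + k_flank)
      if (i0 - k_flank < 1L || i1 + k_flank > nrow(tr)) next  # contig end
      if (any(tr$pi[li] >= config$pi_flank_max) ||
          any(tr$pi[ri] >= config$pi_flank_max)) next
      out[[length(out) + 1L]] <- data.frame(
        contig = ct, core_start = core_start, core_end = core_end,
        lflank_start = tr$start[li[1]], lflank_end = core_start,
        rflank_start = core_end, rflank_end = tr$end[ri[k_flank]],
        pi_core = sum(tr$pi[i0:i1] * window_bp) / core_len,
        S_core = sum(tr$S[i0:i1]),
        mean_dp = mean(tr$mean_dp[i0:i1], na.rm = TRUE))
    }
  }
  cand <- if (length(out)) do.call(rbind, out) else data.frame(
    contig = character(0), core_start = integer(0), core_end = integer(0),
    lflank_start = integer(0), lflank_end = integer(0),
    rflank_start = integer(0), rflank_end = integer(0),
    pi_core = numeric(0), S_core = integer(0), mean_dp = numeric(0))
  cand$locus_id <- if (nrow(cand)) {
    sprintf("%s_%d_%d", cand$contig, cand$core_start, cand$core_end)
  } else character(0)
  cand$flag_te <- logical(nrow(cand))
  cand$flag_cnv <- logical(nrow(cand))
  cand$flag_depth <- logical(nrow(cand))
  cand$flag_selection <- logical(nrow(cand))
  rownames(cand) <- NULL
  class(cand) <- c("candidate_regions", "data.frame")
  cand
}

#' Flag candidates overlapping a repeat mask
#'
#' A candidate is flagged when its core or either flank overlaps any mask
#' interval by at least 1 bp (half-open semantics: abutting intervals do not
#' overlap). Soft-mask intervals from [read_fasta()] can serve as the mask
#' when no explicit repeat annotation is available.
#'
#' @param candidates a `candidate_regions` data frame.
#' @param mask data frame with `contig`, `start`, `end` (0-based half-open).
#' @return `candidates` with `flag_te` updated.
#' @export
apply_repeat_mask <- function(candidates, mask) {
  if (nrow(candidates) == 0 || is.null(mask) || nrow(mask) == 0) {
    return(candidates)
  }
  for (ct in unique(candidates$contig)) {
    ci <- which(candidates$contig == ct)
    mi <- which(mask$contig == ct)
    if (!length(mi)) next
    q <- IRanges::IRanges(start = candidates$lflank_start[ci] + 1L,
                          end = candidates$rflank_end[ci])
    s <- IRanges::IRanges(start = mask$start[mi] + 1L, end = mask$end[mi])
    hit <- IRanges::overlapsAny(q, s, minoverlap = 1L)
    candidates$flag_te[ci] <- candidates$flag_te[ci] | hit
  }
  candidates
}

#' Copy-number and depth screening of candidate regions
#'
#' Per region: samples whose mean core depth falls below the floor are
#' excluded from the region's statistics (and counted); with the remaining
#' samples, the region is flagged copy-number suspect when depth exceeds the
#' ceiling in all of them, when core pi exceeds `pi_ceiling`, or when the
#' core carries more than `snp_ceiling` SNPs. A region with no remaining
#' samples is flagged as a depth failure. Elevated diversity and depth are
#' the signature of collapsed paralogs, so these are ceilings.
#'
#' @param candidates a `candidate_regions` data frame.
#' @param gm the [genotype_matrix()] the track was computed from.
#' @param config a [design_config()].
#' @return `candidates` with `flag_cnv`, `flag_depth`,
#'   `n_low_depth_samples`, `pi_core_used`, `S_core_used` columns updated.
#' @export
cnv_depth_filter <- function(candidates, gm, config = design_config()) {
  n <- nrow(candidates)
  candidates$n_low_depth_samples <- integer(n)
  candidates$pi_core_used <- candidates$pi_core
  candidates$S_core_used <- candidates$S_core
  for (i in seq_len(n)) {
    idx <- gm_variants_in(gm, candidates$contig[i],
                          candidates$core_start[i], candidates$core_end[i])
    if (!length(idx)) next
    dp <- gm$dp[idx, , drop = FALSE]
    sample_depth <- colMeans(dp, na.rm = TRUE)
    low <- is.finite(sample_depth) & sample_depth < config$depth_floor
    keep <- which(!low)
    candidates$n_low_depth_samples[i] <- sum(low)
    if (!length(keep)) {
      candidates$flag_depth[i] <- TRUE
      next
    }
    core_len <- candidates$core_end[i] - candidates$core_start[i]
    div <- site_pairwise_diversity(gm, idx, keep)
    ac <- gm_allele_counts(gm, idx, keep)
    S <- sum(vapply(ac, function(t) length(t) > 1, logical(1)))
    pi <- sum(div) / core_len
    candidates$pi_core_used[i] <- pi
    candidates$S_core_used[i] <- S
    all_high <- all(sample_depth[keep] > config$depth_ceiling)
    candidates$flag_cnv[i] <- all_high || pi > config$pi_ceiling ||
      S > config$snp_ceiling
  }
  candidates
}

#' Selection and inbreeding filter
#'
#' A region passes only when, in every subpopulation, Tajima's D lies
#' strictly inside `tajima_bounds` and Malecot's f is below `f_ceiling`. A
#' subpopulation where D is undefined (no segregating sites, or fewer than 4
#' haplotypes) fails the region when `fail_null_d` is set (the conservative
#' default).
#'
#' @param candidates a `candidate_regions` data frame.
#' @param gm the [genotype_matrix()] with subpopulation labels.
#' @param config a [design_config()].
#' @param subpops subpopulation labels to evaluate; defaults to all non-`NA`
#'   labels present in `gm`.
#' @return `candidates` with `flag_selection` updated and per-subpopulation
#'   `D_<label>` / `f_<label>` columns added.
#' @export
selection_filter <- function(candidates, gm, config = design_config(),
                             subpops = NULL) {
  subpops <- subpops %||% sort(unique(gm$subpop[!is.na(gm$subpop)]))
  if (length(subpops) < 2) {
    stop("selection_filter needs at least 2 labelled subpopulations",
         call. = FALSE)
  }
  for (sp in subpops) {
    candidates[[paste0("D_", sp)]] <- NA_real_
    candidates[[paste0("f_", sp)]] <- NA_real_
  }
  for (i in seq_len(nrow(candidates))) {
    fail <- FALSE
    for (sp in subpops) {
      sidx <- which(!is.na(gm$subpop) & gm$subpop == sp)
      D <- tajimas_d(gm, candidates$contig[i], candidates$core_start[i],
                     candidates$core_end[i], sidx)
      f <- malecot_f(gm, candidates$contig[i], candidates$core_start[i],
                     candidates$core_end[i], sidx)
      candidates[[paste0("D_", sp)]][i] <- as.numeric(D)
      candidates[[paste0("f_", sp)]][i] <- as.numeric(f)
      if (is.na(D)) {
        if (config$fail_null_d) fail <- TRUE
      } else if (D <= config$tajima_bounds[1] || D >= config$tajima_bounds[2]) {
        fail <- TRUE
      }
      if (!is.na(f) && f >= config$f_ceiling) fail <- TRUE
    }
    candidates$flag_selection[i] <- fail
  }
  candidates
}

#' Pass set of a flagged candidate table
#'
#' @param candidates a `candidate_regions` data frame after the filters.
#' @return the subset with all flags `FALSE`.
#' @export
candidate_pass <- function(candidates) {
  flags <- candidates[, c("flag_te", "flag_cnv", "flag_depth",
                          "flag_selection")]
  candidates[rowSums(as.matrix(flags)) == 0, , drop = FALSE]
}

#' Run the full candidate-region pipeline
#'
#' [windowed_pi()] on the genotypes, [scan_candidates()], then the repeat,
#' copy-number/depth and selection filters. Flags are independent, so the
#' result carries every flag each region earned.
#'
#' @param gm a [genotype_matrix()] with subpopulation labels.
#' @param contig_lengths named contig lengths (bp).
#' @param config a [design_config()].
#' @param repeat_mask optional mask data frame (`contig`, `start`, `end`).
#' @param window_bp diversity window size.
#' @return a flagged `candidate_regions` data frame (use
#'   [candidate_pass()] for the pass set).
#' @export
find_target_regions <- function(gm, contig_lengths, config = design_config(),
                                repeat_mask = NULL, window_bp = 50) {
  track <- windowed_pi(gm, window_bp, contig_lengths)
  cand <- scan_candidates(track, config)
  cand <- apply_repeat_mask(cand, repeat_mask)
  cand <- cnv_depth_filter(cand, gm, config)
  cand <- selection_filter(cand, gm, config)
  cand
}
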