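# Synthetic data with the statistical structure the pipeline assumes: a
# random genome carrying planted high-diversity cores with quiet flanks,
# transposable-element tracts, and collapsed-duplication decoys; a
# two-subpopulation diploid cohort with admixed individuals; annotated
# variant records with truth labels for the hard-filter rules; and
# per-amplicon read tables with primer-specific amplification biases.
#
# Everything is deterministic under the config seed. Diversity is planted
# through per-site allele frequencies (no coalescent machinery): core sites
# draw frequencies from the neutral frequency spectrum (prob ~ 1/j, folded)
# *conditioned* on each 50-bp window's expected heterozygosity falling in a
# target band — mirroring how high-diversity targets are ascertained from
# real data — which keeps Tajima's D near zero while guaranteeing that core
# windows clear the diversity floor.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 3 contigs of
#' 150 kb; 50 clean cores (80% of 150 bp, 20% of 100 bp) plus 5
#' collapsed-duplication decoy cores, each with a 200 bp site-free flank
#' zone; 10 TE tracts of 2 kb; two subpopulations of 22 diploids diverged
#' at F = 0.05 plus 6 half-admixed individuals; per-window expected
#' heterozygosity band [0.55, 1.0] (core pi about 0.013); background sites
#' at 5e-4 per bp with Beta(1, 30) frequencies; amplicon-scale depths
#' (Poisson mean 8,000x, doubled at decoys, two deliberately low-depth
#' samples at 3,000x).
#'
#' @param seed mandatory RNG seed.
#' @param n_contigs,contig_length genome layout.
#' @param n_cores,core_lengths,core_length_weights planted clean cores.
#' @param n_decoys collapsed-duplication decoy cores (their core + flanks
#'   are copied verbatim elsewhere in the genome).
#' @param decoy_psv paralogous sequence variants per decoy core (appear
#'   heterozygous in every sample).
#' @param flank_length site-free flank zone per side (bp).
#' @param window_het_band per-50bp-window expected-heterozygosity band for
#'   core site placement.
#' @param n_te,te_length transposable-element tracts (tandem 50-mer
#'   repeats).
#' @param subpop_sizes named diploid counts for the two subpopulations.
#' @param n_admixed,admix_prop admixed individuals and their ancestry
#'   proportion.
#' @param divergence Balding-Nichols F between the subpopulations.
#' @param background_rate,background_beta background site density (per bp)
#'   and Beta frequency parameters.
#' @param depth_mean,decoy_depth_factor,low_depth_samples,low_depth_mean
#'   per-call depth model.
#' @param gq_mean,gq_sd genotype-quality model.
#' @param missing_rate per-call missingness.
#' @param total_reads,bias_sd,multimap_prob,multimap_background,off_panel_rate,read_length
#'   read-table model (log-normal per-primer amplification bias).
#' @param spike_frac fraction of records spiked to violate each site
#'   hard-filter rule in [simulate_annotated_vcf()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_contigs = 3, contig_length = 150000,
                       n_cores = 50, core_lengths = c(100, 150),
                       core_length_weights = c(0.2, 0.8),
                       n_decoys = 5, decoy_psv = 6,
                       flank_length = 200,
                       window_het_band = c(0.55, 1.0),
                       n_te = 10, te_length = 2000,
                       subpop_sizes = c(Aaa = 22, Aaf = 22),
                       n_admixed = 6, admix_prop = 0.5,
                       divergence = 0.05,
                       background_rate = 5e-4,
                       background_beta = c(1, 30),
                       depth_mean = 8000, decoy_depth_factor = 2,
                       low_depth_samples = 2, low_depth_mean = 3000,
                       gq_mean = 70, gq_sd = 15,
                       missing_rate = 0.02,
                       total_reads = 1e5, bias_sd = 0.5,
                       multimap_prob = 0.9, multimap_background = 0.005,
                       off_panel_rate = 0.05, read_length = 150,
                       spike_frac = 0.05) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(missing_rate >= 0, missing_rate <= 1, admix_prop >= 0,
            admix_prop <= 1, all(core_lengths > 0), length(subpop_sizes) == 2)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a reference genome with planted features
#'
#' Random sequence with three kinds of planted features, returned together
#' with their truth intervals: clean high-diversity cores (intervals only —
#' the diversity is planted at the population stage), TE tracts (tandem
#' repeats of a random 50-mer), and decoy cores whose core + flanks are
#' copied verbatim to a second location (driving off-target and
#' copy-number tests). Core starts and lengths are aligned to the 50-bp
#' window grid.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_reference`: `genome` (a `genome_sequences`),
#'   `cores` (data frame with `locus_id`, `contig`, `start`, `end`,
#'   `type` = clean/decoy), `tes`, `copies` (decoy insertion intervals with
#'   `source_id`).
#' @export
simulate_reference <- function(config) {
  with_seed(config$seed, {
    ncontig <- config$n_contigs
    L <- config$contig_length
    contigs <- sprintf("chr%d", seq_len(ncontig))
    occupied <- lapply(contigs, function(x) cbind(start = numeric(0),
                                                  end = numeric(0)))
    names(occupied) <- contigs
    place <- function(ct, len, buffer = 300, grid = 50) {
      for (try in 1:2000) {
        s <- sample.int((L - len - 2000) %/% grid, 1) * grid + 1000
        occ <- occupied[[ct]]
        if (!nrow(occ) ||
            all(s + len + buffer <= occ[, 1] | s - buffer >= occ[, 2])) {
          occupied[[ct]] <<- rbind(occ, c(s, s + len))
          return(s)
        }
      }
      stop("cannot place a ", len, " bp feature on ", ct,
           " (genome too crowded)", call. = FALSE)
    }
    # cores (clean + decoy) with their flank zones reserved
    n_total_cores <- config$n_cores + config$n_decoys
    core_ct <- rep(contigs, length.out = n_total_cores)
    core_len <- sample(config$core_lengths, n_total_cores, replace = TRUE,
                       prob = config$core_length_weights)
    type <- c(rep("clean", config$n_cores), rep("decoy", config$n_decoys))
    fl <- config$flank_length
    starts <- integer(n_total_cores)
    for (i in seq_len(n_total_cores)) {
      s <- place(core_ct[i], core_len[i] + 2 * fl)
      starts[i] <- s + fl
    }
    cores <- data.frame(contig = core_ct, start = starts,
                        end = starts + core_len, type = type)
    cores <- cores[order(cores$contig, cores$start), ]
    cores$locus_id <- sprintf("%s_%d_%d", cores$contig, cores$start,
                              cores$end)
    rownames(cores) <- NULL
    # TE tracts
    te_ct <- rep(contigs, length.out = config$n_te)
    tes <- data.frame(contig = te_ct,
                      start = rep(NA_integer_, length(te_ct)),
                      end = rep(NA_integer_, length(te_ct)))
    motifs <- character(config$n_te)
    for (i in seq_len(config$n_te)) {
      s <- place(te_ct[i], config$te_length)
      tes$start[i] <- s; tes$end[i] <- s + config$te_length
      motifs[i] <- random_dna(50)
    }
    # decoy copy insertion sites
    decoys <- cores[cores$type == "decoy", , drop = FALSE]
    copies <- data.frame(contig = character(0), start = integer(0),
                         end = integer(0), source_id = character(0))
    if (nrow(decoys)) {
      for (i in seq_len(nrow(decoys))) {
        len <- (decoys$end[i] - decoys$start[i]) + 2 * fl
        ct <- decoys$contig[i]
        s <- place(ct, len)
        copies <- rbind(copies, data.frame(contig = ct, start = s,
                                           end = s + len,
                                           source_id = decoys$locus_id[i]))
      }
    }
    # assemble sequences
    seqs <- character(ncontig); names(seqs) <- contigs
    for (ci in seq_len(ncontig)) {
      chars <- sample(DNA_BASES, L, replace = TRUE)
      ti <- which(tes$contig == contigs[ci])
      for (i in ti) {
        tract <- strsplit(strrep(motifs[i], ceiling(config$te_length / 50)),
                          "")[[1]][seq_len(config$te_length)]
        chars[(tes$start[i] + 1L):tes$end[i]] <- tract
      }
      seqs[ci] <- paste(chars, collapse = "")
    }
    # paste decoy copies (verbatim core + flanks) after TE insertion
    for (i in seq_len(nrow(copies))) {
      src <- decoys[decoys$locus_id == copies$source_id[i], ]
      frag <- substr(seqs[src$contig], src$start - fl + 1L, src$end + fl)
      s <- seqs[copies$contig[i]]
      seqs[copies$contig[i]] <- paste0(
        substr(s, 1L, copies$start[i]), frag,
        substr(s, copies$end[i] + 1L, nchar(s)))
    }
    structure(list(genome = new_genome(seqs), cores = cores, tes = tes,
                   copies = copies, config = config),
              class = "sim_reference")
  })
}

# one folded neutral-SFS frequency: derived count j in 1..(npool-1) with
# probability ~ 1/j, random orientation
sfs_freq <- function(n, npool) {
  j <- sample.int(npool - 1L, n, replace = TRUE,
                  prob = 1 / seq_len(npool - 1L))
  p <- j / npool
  flip <- stats::runif(n) < 0.5
  p[flip] <- 1 - p[flip]
  p
}

# frequencies for one 50-bp window: add SFS sites until the expected
# heterozygosity sum enters [lo, hi]; redraw the window on overshoot
draw_core_window_freqs <- function(lo, hi, npool) {
  repeat {
    ps <- numeric(0); s <- 0
    while (s < lo) {
      p <- sfs_freq(1, npool)
      ps <- c(ps, p)
      s <- s + 2 * p * (1 - p)
    }
    if (s <= hi) return(ps)
  }
}

#' Simulate a genotyped population over a simulated reference
#'
#' Plants sites only inside the core intervals (at densities realizing the
#' window heterozygosity band) and sparse low-frequency background sites
#' outside the core flank zones. The two subpopulations draw correlated
#' frequencies from a Balding-Nichols model; admixed individuals draw each
#' allele from a subpopulation chosen by their ancestry proportion. Decoy
#' cores additionally carry paralog-collapse signals: fixed heterozygous
#' PSV sites and doubled sequencing depth. All calls are phased (the two
#' allele matrices are the haplotypes).
#'
#' @param ref a `sim_reference` from [simulate_reference()].
#' @param config optional [sim_config()]; defaults to the one inside
#'   `ref`.
#' @return a [genotype_matrix()] with subpopulation labels (`NA` for
#'   admixed samples); attribute `site_truth` maps every variant to its
#'   origin (`core` locus / `psv` / `background`).
#' @export
simulate_population <- function(ref, config = ref$config) {
  with_seed(config$seed + 1L, {
    n1 <- config$subpop_sizes[[1]]; n2 <- config$subpop_sizes[[2]]
    nadx <- config$n_admixed
    ns <- n1 + n2 + nadx
    npool <- 2L * ns
    sp_names <- names(config$subpop_sizes)
    samples <- c(sprintf("%s_%02d", sp_names[1], seq_len(n1)),
                 sprintf("%s_%02d", sp_names[2], seq_len(n2)),
                 sprintf("ADX_%02d", seq_len(nadx)))
    subpop <- c(rep(sp_names[1], n1), rep(sp_names[2], n2),
                rep(NA_character_, nadx))
    band <- config$window_het_band
    pos_l <- list(); ct_l <- list(); p_l <- list(); origin_l <- list()
    for (i in seq_len(nrow(ref$cores))) {
      co <- ref$cores[i, ]
      wstarts <- seq(co$start, co$end - 1L, by = 50L)
      for (w in wstarts) {
        ps <- draw_core_window_freqs(band[1], band[2], npool)
        offs <- sample.int(50L, length(ps))
        pos_l[[length(pos_l) + 1L]] <- w + offs - 1L
        ct_l[[length(ct_l) + 1L]] <- rep(co$contig, length(ps))
        p_l[[length(p_l) + 1L]] <- ps
        origin_l[[length(origin_l) + 1L]] <- rep(co$locus_id, length(ps))
      }
      if (co$type == "decoy" && config$decoy_psv > 0) {
        len <- co$end - co$start
        offs <- sample.int(len, config$decoy_psv)
        pos_l[[length(pos_l) + 1L]] <- co$start + offs - 1L
        ct_l[[length(ct_l) + 1L]] <- rep(co$contig, config$decoy_psv)
        p_l[[length(p_l) + 1L]] <- rep(0.5, config$decoy_psv)
        origin_l[[length(origin_l) + 1L]] <- rep(paste0("psv:", co$locus_id),
                                                 config$decoy_psv)
      }
    }
    # background sites outside core flank zones
    fl <- config$flank_length
    clens <- contig_lengths(ref$genome)
    for (ct in names(clens)) {
      n_bg <- stats::rbinom(1, clens[[ct]], config$background_rate)
      if (n_bg == 0) next
      pos <- sample.int(clens[[ct]], n_bg) - 1L
      zones <- ref$cores[ref$cores$contig == ct, , drop = FALSE]
      if (nrow(zones)) {
        excl <- vapply(pos, function(p) {
          any(p >= zones$start - fl & p < zones$end + fl)
        }, logical(1))
        pos <- pos[!excl]
      }
      if (!length(pos)) next
      pos_l[[length(pos_l) + 1L]] <- pos
      ct_l[[length(ct_l) + 1L]] <- rep(ct, length(pos))
      p_l[[length(p_l) + 1L]] <- stats::rbeta(length(pos),
                                              config$background_beta[1],
                                              config$background_beta[2])
      origin_l[[length(origin_l) + 1L]] <- rep("background", length(pos))
    }
    pos <- unlist(pos_l); ctv <- unlist(ct_l)
    p_anc <- unlist(p_l); origin <- unlist(origin_l)
    # drop duplicate positions (core + psv collisions)
    o <- order(ctv, pos)
    pos <- pos[o]; ctv <- ctv[o]; p_anc <- p_anc[o]; origin <- origin[o]
    dup <- duplicated(paste(ctv, pos))
    pos <- pos[!dup]; ctv <- ctv[!dup]; p_anc <- p_anc[!dup]
    origin <- origin[!dup]
    K <- length(pos)
    is_psv <- startsWith(origin, "psv:")
    # subpopulation frequencies (Balding-Nichols)
    Fst <- config$divergence
    c0 <- (1 - Fst) / Fst
    p1 <- stats::rbeta(K, c0 * p_anc, c0 * (1 - p_anc))
    p2 <- stats::rbeta(K, c0 * p_anc, c0 * (1 - p_anc))
    p1[is_psv] <- 0.5; p2[is_psv] <- 0.5
    draw_haps <- function(p, nind) {
      matrix(stats::rbinom(K * nind, 1L, rep(p, nind)), nrow = K)
    }
    a1 <- cbind(draw_haps(p1, n1), draw_haps(p2, n2))
    a2 <- cbind(draw_haps(p1, n1), draw_haps(p2, n2))
    if (nadx > 0) {
      adx_allele <- function() {
        anc <- matrix(stats::runif(K * nadx) < config$admix_prop, nrow = K)
        pm <- ifelse(anc, rep(p1, nadx), rep(p2, nadx))
        matrix(stats::rbinom(K * nadx, 1L, pm), nrow = K)
      }
      a1 <- cbind(a1, adx_allele())
      a2 <- cbind(a2, adx_allele())
    }
    # paralog-collapse genotypes: PSV sites heterozygous in everyone
    if (any(is_psv)) {
      a1[is_psv, ] <- 0L
      a2[is_psv, ] <- 1L
    }
    # depth: Poisson around the per-sample amplicon mean, doubled in decoy
    # cores (collapsed reads from both copies)
    decoy_ids <- ref$cores$locus_id[ref$cores$type == "decoy"]
    in_decoy <- origin %in% decoy_ids | is_psv
    sample_mean <- rep(config$depth_mean, ns)
    if (config$low_depth_samples > 0) {
      # alternate the low-depth samples between the two subpopulations
      k <- min(config$low_depth_samples, n1 + n2)
      from1 <- seq_len(min(ceiling(k / 2), n1))
      from2 <- n1 + seq_len(k - length(from1))
      sample_mean[c(from1, from2)] <- config$low_depth_mean
    }
    lam <- outer(ifelse(in_decoy, config$decoy_depth_factor, 1), sample_mean)
    dp <- matrix(stats::rpois(K * ns, lam), nrow = K)
    gq <- matrix(pmax(0, pmin(99, round(stats::rnorm(K * ns, config$gq_mean,
                                                     config$gq_sd)))),
                 nrow = K)
    # missingness
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(K * ns) < config$missing_rate, nrow = K)
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    }
    # ref/alt from the genome
    refb <- character(K); altb <- character(K)
    for (ct in unique(ctv)) {
      idx <- which(ctv == ct)
      s <- ref$genome$seq[[ct]]
      refb[idx] <- vapply(pos[idx], function(p) substr(s, p + 1, p + 1),
                          character(1))
    }
    altb <- vapply(refb, function(b) sample(setdiff(DNA_BASES, b), 1),
                   character(1))
    gm <- genotype_matrix(ctv, pos, refb, altb, a1, a2,
                          phased = matrix(TRUE, K, ns) &
                            !is.na(a1),
                          dp = dp, gq = gq, samples = samples,
                          subpop = subpop)
    attr(gm, "site_truth") <- data.frame(contig = ctv, pos = pos,
                                         origin = origin,
                                         stringsAsFactors = FALSE)
    gm
  })
}

#' Spike site annotations with known hard-filter violations
#'
#' Draws passing baseline QD/FS/ReadPosRankSum annotations for every
#' record, then spikes a disjoint fraction of records per rule with values
#' violating exactly that rule, returning truth labels so a site filter can
#' be checked for confusion-free behaviour.
#'
#' @param gm a [genotype_matrix()].
#' @param config a [sim_config()] (uses `spike_frac` and `seed`).
#' @param spike_frac override of the per-rule spike fraction.
#' @return list with `gm` (annotated) and `truth` (data frame with column
#'   `violates` in `none`/`QD`/`FS`/`ReadPosRankSum`).
#' @export
simulate_annotated_vcf <- function(gm, config, spike_frac = config$spike_frac) {
  with_seed(config$seed + 2L, {
    nv <- n_variants(gm)
    qd <- 5.2 + stats::rgamma(nv, shape = 8, rate = 0.6)       # > 5
    fs <- stats::runif(nv, 0, 40)                               # < 60
    rprs <- pmax(-7.5, pmin(7.5, stats::rnorm(nv, 0, 1.5)))     # > -8
    n_spike <- round(spike_frac * nv)
    violates <- rep("none", nv)
    if (3 * n_spike > nv) stop("spike fraction too large", call. = FALSE)
    spiked <- sample.int(nv, 3 * n_spike)
    qd_bad <- spiked[seq_len(n_spike)]
    fs_bad <- spiked[n_spike + seq_len(n_spike)]
    rprs_bad <- spiked[2 * n_spike + seq_len(n_spike)]
    qd[qd_bad] <- stats::runif(n_spike, 0, 4.9)
    fs[fs_bad] <- stats::runif(n_spike, 61, 150)
    rprs[rprs_bad] <- stats::runif(n_spike, -20, -8.1)
    violates[qd_bad] <- "QD"; violates[fs_bad] <- "FS"
    violates[rprs_bad] <- "ReadPosRankSum"
    gm$info <- data.frame(QD = round(qd, 2), FS = round(fs, 2),
                          ReadPosRankSum = round(rprs, 2))
    list(gm = gm, truth = data.frame(contig = gm$contig, pos = gm$pos,
                                     violates = violates,
                                     stringsAsFactors = FALSE))
  })
}

#' Simulate a per-amplicon read table
#'
#' Per-locus read shares are proportional to balancing factor times a
#' log-normal primer-specific amplification bias; reads are multinomially
#' assigned and placed inside their locus. Reads from decoy loci are
#' multimap-flagged with high probability (they also map to the duplicate
#' copy), other reads with a small background probability; a fraction of
#' reads falls off-panel.
#'
#' @param panel a [primer_table()] with target coordinates.
#' @param config a [sim_config()].
#' @param contig_lengths named contig lengths for placing off-panel reads.
#' @param decoy_loci locus ids whose reads are multimap-prone.
#' @param seed RNG seed (defaults to `config$seed + 3`).
#' @param total_reads total reads to simulate.
#' @param bias optional per-locus amplification bias multipliers; primer
#'   chemistry persists across runs, so pass one run's `bias` to a second
#'   call to emulate a technical replicate. Drawn log-normally when `NULL`.
#' @return list of class `sim_reads`: `alignments` (read-alignment data
#'   frame), `true_counts` (named per-locus read counts including
#'   multimap-flagged reads) and `bias` (the per-locus bias multipliers).
#' @export
simulate_read_table <- function(panel, config, contig_lengths,
                                decoy_loci = character(0),
                                seed = config$seed + 3L,
                                total_reads = config$total_reads,
                                bias = NULL) {
  with_seed(seed, {
    nl <- nrow(panel)
    if (is.null(bias)) bias <- exp(stats::rnorm(nl, 0, config$bias_sd))
    share <- panel$balancing_factor * bias
    share <- share / sum(share)
    n_off <- round(config$off_panel_rate * total_reads)
    n_on <- total_reads - n_off
    counts <- as.integer(stats::rmultinom(1, n_on, share))
    names(counts) <- panel$locus_id
    rl <- config$read_length
    rows <- vector("list", nl + 1L)
    for (i in seq_len(nl)) {
      if (counts[i] == 0) next
      lo <- panel$start[i] - 25L
      hi <- max(lo + 1L, panel$end[i] - (rl - 25L))
      starts <- lo + sample.int(hi - lo, counts[i], replace = TRUE) - 1L
      mm_p <- if (panel$locus_id[i] %in% decoy_loci) config$multimap_prob
              else config$multimap_background
      rows[[i]] <- data.frame(contig = panel$contig[i], start = starts,
                              end = starts + rl,
                              multimap = stats::runif(counts[i]) < mm_p,
                              locus = panel$locus_id[i])
    }
    if (n_off > 0) {
      ct <- sample(names(contig_lengths), n_off, replace = TRUE)
      starts <- vapply(ct, function(x) {
        sample.int(contig_lengths[[x]] - rl, 1)
      }, integer(1))
      rows[[nl + 1L]] <- data.frame(contig = ct, start = starts,
                                    end = starts + rl, multimap = FALSE,
                                    locus = NA_character_)
    }
    al <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    al <- al[sample.int(nrow(al)), , drop = FALSE]   # shuffle read order
    al <- data.frame(read_id = sprintf("r%07d", seq_len(nrow(al))),
                     contig = al$contig, start = al$start, end = al$end,
                     multimap = al$multimap, true_locus = al$locus,
                     stringsAsFactors = FALSE)
    rownames(al) <- NULL
    structure(list(alignments = al, true_counts = counts, bias = bias),
              class = "sim_reads")
  })
}
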