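# Evaluation of a sequenced panel: read-to-locus assignment, coverage
# uniformity, primer balancing factors, rarefaction of read counts, SNP
# content per amplicon, amplicon/library size statistics, and
# microhaplotype extraction.

#' Assign aligned reads to panel loci
#'
#' A read is assigned to a locus when at least half of the read interval
#' overlaps the locus interval. Multimap-flagged reads are recorded but
#' never counted; reads overlapping no locus are counted as off-panel;
#' malformed rows (end <= start) are rejected and counted. Reads are
#' conserved: assigned + off-panel + multimap-excluded + rejected = input.
#'
#' @param alignments data frame with `read_id`, `contig`, `start`, `end`,
#'   `multimap` (see [read_alignments()]).
#' @param panel a [primer_table()] with target coordinates.
#' @param min_overlap_frac assignment rule (default 0.5).
#' @return list of class `read_assignment`: `assignments` (per-read locus
#'   or `NA`), `counts` (named per-locus unique-read counts) and `tally`
#'   (assigned / off_panel / multimap / rejected).
#' @export
assign_reads <- function(alignments, panel, min_overlap_frac = 0.5) {
  if (any(is.na(panel$start))) {
    stop("panel loci need target coordinates (run in-silico PCR first)",
         call. = FALSE)
  }
  al <- alignments
  bad <- !(al$end > al$start)
  assigned <- rep(NA_character_, nrow(al))
  status <- rep("off_panel", nrow(al))
  status[bad] <- "rejected"
  for (ct in unique(al$contig)) {
    ai <- which(al$contig == ct & !bad)
    pi <- which(panel$contig == ct)
    if (!length(ai) || !length(pi)) next
    q <- IRanges::IRanges(start = al$start[ai] + 1L, end = al$end[ai])
    s <- IRanges::IRanges(start = panel$start[pi] + 1L, end = panel$end[pi])
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
    frac <- w / IRanges::width(q[qh])
    ok <- frac >= min_overlap_frac
    if (!any(ok)) next
    # best (largest-overlap) locus per read among qualifying overlaps
    o <- order(qh[ok], -w[ok])
    first <- !duplicated(qh[ok][o])
    assigned[ai[qh[ok][o][first]]] <- panel$locus_id[pi[sh[ok][o][first]]]
  }
  status[!is.na(assigned)] <- "assigned"
  is_mm <- as.logical(al$multimap) & !bad
  status[is_mm] <- "multimap"
  counted <- assigned
  counted[is_mm] <- NA_character_
  counts <- table(factor(counted, levels = panel$locus_id))
  tally <- c(assigned = sum(status == "assigned"),
             off_panel = sum(status == "off_panel"),
             multimap = sum(status == "multimap"),
             rejected = sum(status == "rejected"))
  structure(list(assignments = assigned, status = status,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 tally = tally),
            class = "read_assignment")
}

#' @export
print.read_assignment <- function(x, ...) {
  cat("read_assignment:",
      paste(sprintf("%s=%d", names(x$tally), x$tally), collapse = " "), "\n")
  invisible(x)
}

#' Coverage uniformity summary
#'
#' Per-locus read shares, the share of the most abundant locus, and the
#' Gini coefficient of the count distribution (0 = perfectly uniform).
#'
#' @param counts named per-locus read counts (all >= 0, total > 0).
#' @return list with `shares`, `top_share`, `top_locus`, `gini`.
#' @export
coverage_uniformity <- function(counts) {
  if (sum(counts) <= 0) stop("all counts are zero", call. = FALSE)
  shares <- counts / sum(counts)
  x <- sort(as.numeric(counts))
  n <- length(x)
  gini <- sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
  list(shares = shares,
       top_share = max(shares),
       top_locus = names(counts)[which.max(counts)] %||% which.max(counts),
       gini = gini)
}

#' Per-primer balancing factors
#'
#' Dilution multipliers that equalize per-amplicon read shares:
#' `factor = clamp(target_share / observed_share, lower, upper)`. Loci with
#' zero observed reads get the upper clamp and a warning.
#'
#' @param counts named per-locus counts from a test sequencing run.
#' @param target_share desired per-locus share (default uniform).
#' @param clamp_bounds allowed factor range (default `c(0.1, 2)`).
#' @return named numeric vector of balancing factors.
#' @export
balancing_factors <- function(counts, target_share = NULL,
                              clamp_bounds = c(0.1, 2)) {
  target_share <- target_share %||% (1 / length(counts))
  shares <- counts / sum(counts)
  f <- ifelse(shares > 0, target_share / shares, Inf)
  if (any(!is.finite(f))) {
    warning(sum(!is.finite(f)), " zero-count locus(i) set to the upper clamp")
  }
  stats::setNames(clamp(f, clamp_bounds[1], clamp_bounds[2]), names(counts))
}

#' Rarefaction of per-locus read counts
#'
#' Subsamples the observed read pool without replacement (multivariate
#' hypergeometric) to each depth on the grid and reports the mean and sd,
#' over replicates, of the proportion of loci reaching at least `threshold`
#' reads ("genotyped amplicons"). At the full observed depth the proportion
#' equals the observed one exactly. Depths above the observed total cannot
#' be subsampled and are reported as unsupported (`NA` with
#' `supported = FALSE`).
#'
#' @param counts named per-locus read counts.
#' @param depths read-depth grid.
#' @param threshold genotyped-amplicon read threshold (default 10).
#' @param replicates Monte-Carlo replicates per depth (default 100).
#' @param seed RNG seed (mandatory).
#' @return data frame of class `rarefaction_curve`: `depth`,
#'   `mean_genotyped`, `sd_genotyped`, `supported`; attributes `threshold`,
#'   `replicates`, `seed`.
#' @export
rarefaction <- function(counts, depths, threshold = 10, replicates = 100,
                        seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (any(depths <= 0)) stop("depths must be positive", call. = FALSE)
  counts <- as.numeric(counts)
  total <- sum(counts)
  nloc <- length(counts)
  res <- with_seed(seed, {
    lapply(depths, function(d) {
      if (d > total) {
        return(data.frame(depth = d, mean_genotyped = NA_real_,
                          sd_genotyped = NA_real_, supported = FALSE))
      }
      if (d == total) {
        obs <- mean(counts >= threshold)
        return(data.frame(depth = d, mean_genotyped = obs,
                          sd_genotyped = 0, supported = TRUE))
      }
      props <- numeric(replicates)
      for (r in seq_len(replicates)) {
        x <- rmvhyper_one(counts, d)
        props[r] <- mean(x >= threshold)
      }
      data.frame(depth = d, mean_genotyped = mean(props),
                 sd_genotyped = stats::sd(props), supported = TRUE)
    })
  })
  out <- do.call(rbind, res)
  attr(out, "threshold") <- threshold
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

# one multivariate-hypergeometric draw via sequential conditional
# hypergeometrics
rmvhyper_one <- function(counts, k) {
  n <- length(counts)
  out <- numeric(n)
  remaining <- sum(counts)
  for (i in seq_len(n)) {
    if (k <= 0) break
    if (i == n) { out[i] <- k; break }
    out[i] <- stats::rhyper(1, counts[i], remaining - counts[i], k)
    k <- k - out[i]
    remaining <- remaining - counts[i]
  }
  out
}

#' SNPs per amplicon
#'
#' Counts variants whose position falls in each locus interval (half-open);
#' variants outside every locus are reported as off-panel.
#'
#' @param gm a (typically filtered) [genotype_matrix()].
#' @param panel a [primer_table()] with target coordinates.
#' @return list with `counts` (named per-locus), `median`, `off_panel`.
#' @export
snps_per_amplicon <- function(gm, panel) {
  counts <- integer(nrow(panel))
  names(counts) <- panel$locus_id
  hit <- rep(FALSE, n_variants(gm))
  for (i in seq_len(nrow(panel))) {
    idx <- gm_variants_in(gm, panel$contig[i], panel$start[i], panel$end[i])
    counts[i] <- length(idx)
    hit[idx] <- TRUE
  }
  list(counts = counts, median = stats::median(counts),
       off_panel = sum(!hit))
}

#' Amplicon and library size statistics
#'
#' Min/median/max of the predicted amplicon lengths and of the final library
#' lengths, where the per-locus library length adds the construct overhead:
#' the adapter tails carried by the PCR1 primers plus the extra bases the
#' indexed PCR2 primers append beyond those tails (computed from the
#' supplied sequences, not hard-coded).
#'
#' @param panel a [primer_table()] with `amplicon_length` (or coordinates to
#'   derive it).
#' @param index_fwd,index_rev optional PCR2 index primer sequences whose 3'
#'   ends anneal to the tails; the overhead they add is their length minus
#'   the tail length. Omitted = no index extension.
#' @return list with `amplicon` and `library` summaries (`min`, `median`,
#'   `max`) and the per-locus `overhead`.
#' @export
amplicon_size_stats <- function(panel, index_fwd = NULL, index_rev = NULL) {
  len <- panel$amplicon_length
  if (is.null(len)) {
    if (any(is.na(panel$start)) || any(is.na(panel$end))) {
      stop("loci lack amplicon lengths and coordinates: ",
           paste(panel$locus_id[is.na(panel$start)], collapse = ", "),
           call. = FALSE)
    }
    len <- panel$end - panel$start
  }
  if (any(is.na(len))) {
    stop("loci lack amplicon lengths: ",
         paste(panel$locus_id[is.na(len)], collapse = ", "), call. = FALSE)
  }
  ext_f <- if (is.null(index_fwd)) 0 else nchar(index_fwd) - panel$fwd_tail_len
  ext_r <- if (is.null(index_rev)) 0 else nchar(index_rev) - panel$rev_tail_len
  overhead <- panel$fwd_tail_len + panel$rev_tail_len +
    pmax(ext_f, 0) + pmax(ext_r, 0)
  lib <- len + overhead
  summ <- function(x) list(min = min(x), median = stats::median(x), max = max(x))
  list(amplicon = summ(len), library = summ(lib), overhead = overhead,
       total_targeted_bp = sum(len))
}

#' Extract microhaplotypes
#'
#' For each sample and locus, the two phased allele strings across the
#' locus's variants in position order. A locus is `NA` for a sample when
#' any in-locus call is missing, or when any heterozygous call is unphased
#' (homozygous calls are unambiguous regardless of the phase flag).
#'
#' @param gm a phased [genotype_matrix()].
#' @param panel a [primer_table()] with target coordinates.
#' @return data frame: `locus_id`, `sample`, `hap1`, `hap2`, `reason`
#'   (`NA`, `"missing"` or `"unphased"`).
#' @export
extract_microhaplotypes <- function(gm, panel) {
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    idx <- gm_variants_in(gm, panel$contig[i], panel$start[i], panel$end[i])
    for (s in seq_len(n_samples(gm))) {
      a1 <- gm$a1[idx, s]; a2 <- gm$a2[idx, s]
      ph <- gm$phased[idx, s]
      hap1 <- NA_character_; hap2 <- NA_character_; reason <- NA_character_
      if (!length(idx)) {
        hap1 <- ""; hap2 <- ""
      } else if (any(is.na(a1))) {
        reason <- "missing"
      } else if (any(!ph & a1 != a2)) {
        reason <- "unphased"
      } else {
        hap1 <- paste(a1, collapse = "")
        hap2 <- paste(a2, collapse = "")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = panel$locus_id[i], sample = gm$samples[s],
        hap1 = hap1, hap2 = hap2, reason = reason)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
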