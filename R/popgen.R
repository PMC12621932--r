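# Core population-genetic statistics: windowed nucleotide diversity,
# Tajima's D, Malecot's inbreeding coefficient f, genotype r2 with windowed
# LD pruning, and method-of-moments IBD (PI_HAT).
#
# All of these are phase-free: they use allele counts only. Multiallelic
# sites contribute to pi through the full allele-pair sum; for r2, D and f
# they are collapsed to a major-vs-rest biallelic encoding.

#' Windowed nucleotide diversity
#'
#' Tiles each contig with non-overlapping windows and computes, per window,
#' the mean pairwise difference per base pair (pi), the number of segregating
#' sites (S), and the mean sequencing depth of the contributing calls. Per
#' site the mean pairwise difference over the `n` non-missing alleles is
#' `(n^2 - sum(n_i^2)) / (n (n-1))`; window pi divides the per-site sum by
#' the full window length (no accessibility correction). Sites with fewer
#' than two non-missing alleles contribute 0 and are counted as skipped.
#'
#' @param gm a [genotype_matrix()].
#' @param window_bp window size in bp (default 50).
#' @param contig_lengths named vector of contig lengths in bp.
#' @param samples optional sample subset (indices or ids).
#' @return a data frame of class `window_stats` with columns `contig`,
#'   `start`, `end`, `pi`, `S`, `mean_dp`; attribute `skipped_sites` counts
#'   sites with < 2 non-missing alleles.
#' @export
windowed_pi <- function(gm, window_bp = 50, contig_lengths, samples = NULL) {
  if (window_bp < 1) stop("window_bp must be >= 1", call. = FALSE)
  if (is.null(names(contig_lengths))) {
    stop("contig_lengths must be named", call. = FALSE)
  }
  if (is.character(samples)) samples <- match(samples, gm$samples)
  out <- vector("list", length(contig_lengths))
  skipped <- 0L
  div <- site_pairwise_diversity(gm, samples = samples)
  ac <- gm_allele_counts(gm, samples = samples)
  nall <- vapply(ac, function(t) sum(t), numeric(1))
  seg <- vapply(ac, function(t) length(t) > 1, logical(1))
  skipped <- sum(nall < 2)
  sidx <- samples %||% seq_len(n_samples(gm))
  site_dp <- rowMeans(gm$dp[, sidx, drop = FALSE], na.rm = TRUE)
  for (ci in seq_along(contig_lengths)) {
    ct <- names(contig_lengths)[ci]
    len <- contig_lengths[[ci]]
    nwin <- ceiling(len / window_bp)
    starts <- (seq_len(nwin) - 1L) * window_bp
    pi <- numeric(nwin); S <- integer(nwin); dpsum <- numeric(nwin)
    dpn <- integer(nwin)
    on_ct <- which(gm$contig == ct & gm$pos < len)
    if (length(on_ct)) {
      w <- gm$pos[on_ct] %/% window_bp + 1L
      pi <- as.numeric(rowsum_vec(div[on_ct], w, nwin))
      S <- as.integer(rowsum_vec(as.numeric(seg[on_ct]), w, nwin))
      dpsum <- rowsum_vec(ifelse(is.finite(site_dp[on_ct]), site_dp[on_ct], 0), w, nwin)
      dpn <- as.integer(rowsum_vec(as.numeric(is.finite(site_dp[on_ct])), w, nwin))
    }
    out[[ci]] <- data.frame(contig = ct, start = starts,
                            end = pmin(starts + window_bp, len),
                            pi = pi / window_bp, S = S,
                            mean_dp = ifelse(dpn > 0, dpsum / dpn, NA_real_))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "window_bp") <- window_bp
  attr(res, "skipped_sites") <- skipped
  class(res) <- c("window_stats", "data.frame")
  res
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  s <- rowsum(x, group)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Tajima's D constants
#'
#' The standard normalizing constants for `n` sampled haplotypes.
#'
#' @param n number of haplotypes (>= 4).
#' @return list with `a1`, `a2`, `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D over a region
#'
#' `D = (k - S/a1) / sqrt(e1 S + e2 S (S-1))` where `k` is the mean pairwise
#' difference count over the region and `S` the number of segregating sites.
#' The sample size used for the constants is twice the number of samples
#' with at least one non-missing call in the region. Returns `NA` (with a
#' `reason` attribute) when `S = 0` or fewer than 4 haplotypes are
#' available.
#'
#' @param gm a [genotype_matrix()].
#' @param contig,start,end region (0-based half-open).
#' @param samples optional sample subset (indices or ids).
#' @return numeric scalar `D`, with attributes `S`, `k`, `n`.
#' @export
tajimas_d <- function(gm, contig, start, end, samples = NULL) {
  idx <- gm_variants_in(gm, contig, start, end)
  if (is.character(samples)) samples <- match(samples, gm$samples)
  sidx <- samples %||% seq_len(n_samples(gm))
  called <- colSums(!is.na(gm$a1[idx, sidx, drop = FALSE])) > 0
  n <- 2L * sum(called)
  ac <- gm_allele_counts(gm, idx, sidx)
  seg <- vapply(ac, function(t) length(t) > 1, logical(1))
  S <- sum(seg)
  if (S == 0 || n < 4) {
    out <- NA_real_
    attr(out, "reason") <- if (n < 4) "fewer than 4 haplotypes" else "no segregating sites"
    attr(out, "S") <- S; attr(out, "n") <- n
    return(out)
  }
  k <- sum(site_pairwise_diversity(gm, idx, sidx))
  ct <- tajima_constants(n)
  D <- (k - S / ct$a1) / sqrt(ct$e1 * S + ct$e2 * S * (S - 1))
  attr(D, "S") <- S; attr(D, "k") <- k; attr(D, "n") <- n
  D
}

#' Malecot's inbreeding coefficient f over a region
#'
#' Ratio-of-sums estimator over polymorphic sites:
#' `f = 1 - sum(observed hets) / sum(2 p (1-p) n_genotyped)`, clamped to
#' `[-1, 1]`. Multiallelic sites are collapsed to major-vs-rest. Returns
#' `NA` when the region has no polymorphic site with at least two genotyped
#' diploids.
#'
#' @inheritParams tajimas_d
#' @return numeric scalar `f` with attribute `n_sites`.
#' @export
malecot_f <- function(gm, contig, start, end, samples = NULL) {
  idx <- gm_variants_in(gm, contig, start, end)
  if (is.character(samples)) samples <- match(samples, gm$samples)
  dos <- gm_dosage(gm, idx, samples)
  hobs_sum <- 0; hexp_sum <- 0; used <- 0L
  for (i in seq_len(nrow(dos))) {
    d <- dos[i, ]; d <- d[!is.na(d)]
    ng <- length(d)
    if (ng < 2) next
    p <- sum(d) / (2 * ng)            # frequency of the non-major allele
    if (p <= 0 || p >= 1) next
    hobs_sum <- hobs_sum + sum(d == 1)
    hexp_sum <- hexp_sum + 2 * p * (1 - p) * ng
    used <- used + 1L
  }
  if (used == 0L || hexp_sum == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no polymorphic sites"
    return(out)
  }
  f <- clamp(1 - hobs_sum / hexp_sum, -1, 1)
  attr(f, "n_sites") <- used
  f
}

#' Genotype r-squared
#'
#' Squared Pearson correlation of allele dosages over pairwise-complete
#' samples (composite, Rogers-Huff style). Returns `NA` when either vector
#' has zero variance or fewer than 2 complete pairs exist, so a degenerate
#' pair never counts as exceeding a pruning threshold.
#'
#' @param x,y dosage vectors in `{0, 1, 2, NA}`.
#' @return r^2 in `[0, 1]`, or `NA`.
#' @export
genotype_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Windowed LD pruning
#'
#' Scans moving windows of `window_snps` variants advancing by `step_snps`.
#' Within a window, variants are visited left to right and a variant is
#' removed when its r^2 with any retained earlier variant of the window
#' exceeds `r2_max`. Removal is global: once removed, a variant stays
#' removed in later windows.
#'
#' @param gm a [genotype_matrix()] (variants sorted), or a dosage matrix
#'   (variants x samples).
#' @param r2_max pruning threshold (default 0.01).
#' @param window_snps,step_snps window and step sizes in variants.
#' @return integer vector of retained variant indices.
#' @export
ld_prune <- function(gm, r2_max = 0.01, window_snps = 500, step_snps = 250) {
  dos <- if (inherits(gm, "genotype_matrix")) gm_dosage(gm) else as.matrix(gm)
  nv <- nrow(dos)
  if (nv == 0) return(integer(0))
  removed <- rep(FALSE, nv)
  starts <- seq(1L, nv, by = step_snps)
  for (s in starts) {
    idx <- s:min(s + window_snps - 1L, nv)
    for (jj in seq_along(idx)) {
      j <- idx[jj]
      if (removed[j] || jj == 1L) next
      for (i in idx[seq_len(jj - 1L)]) {
        if (removed[i]) next
        r2 <- genotype_r2(dos[i, ], dos[j, ])
        if (!is.na(r2) && r2 > r2_max) { removed[j] <- TRUE; break }
      }
    }
    if (s + window_snps - 1L >= nv) break
  }
  which(!removed)
}

#' Method-of-moments IBD estimate (PI_HAT)
#'
#' Compares observed identity-by-state (IBS) counts for a sample pair with
#' their expectations under the three IBD states given allele frequencies,
#' in the manner of the classic genome-wide relatedness estimator:
#' `Z0` from the IBS0 count, `Z1` from IBS1 after removing the IBD0
#' contribution, `Z2 = 1 - Z0 - Z1`; all three are clamped to `[0, 1]` and
#' renormalized. `PI_HAT = Z2 + Z1/2`.
#'
#' @param gm a [genotype_matrix()].
#' @param sample_a,sample_b sample ids or indices.
#' @param allele_freqs optional per-variant frequency of the non-major
#'   allele; estimated from all samples in `gm` when `NULL`.
#' @param min_sites minimum number of informative (polymorphic, genotyped in
#'   both samples) biallelic sites; below it the estimate is `NA`.
#' @return list of class `kinship_estimate` with `Z0`, `Z1`, `Z2`,
#'   `PI_HAT`, `n_sites`, or with `PI_HAT = NA` and a `reason` when
#'   underpowered.
#' @export
ibd_pi_hat <- function(gm, sample_a, sample_b, allele_freqs = NULL,
                       min_sites = 200) {
  if (is.character(sample_a)) sample_a <- match(sample_a, gm$samples)
  if (is.character(sample_b)) sample_b <- match(sample_b, gm$samples)
  dos <- gm_dosage(gm)
  if (is.null(allele_freqs)) {
    allele_freqs <- rowMeans(dos, na.rm = TRUE) / 2
  }
  da <- dos[, sample_a]; db <- dos[, sample_b]
  p <- allele_freqs
  ok <- !is.na(da) & !is.na(db) & !is.na(p) & p > 0 & p < 1
  n_inf <- sum(ok)
  if (n_inf < min_sites) {
    return(structure(list(Z0 = NA_real_, Z1 = NA_real_, Z2 = NA_real_,
                          PI_HAT = NA_real_, n_sites = n_inf,
                          reason = "too few informative sites"),
                     class = "kinship_estimate"))
  }
  da <- da[ok]; db <- db[ok]; p <- p[ok]; q <- 1 - p
  ibs <- ifelse(abs(da - db) == 2, 0L, ifelse(da == db, 2L, 1L))
  N0 <- sum(ibs == 0L); N1 <- sum(ibs == 1L)
  E0_ibd0 <- sum(2 * p^2 * q^2)
  E1_ibd0 <- sum(4 * p^3 * q + 4 * p * q^3)
  E1_ibd1 <- sum(2 * p * q)
  Z0 <- if (E0_ibd0 > 0) N0 / E0_ibd0 else 0
  Z1 <- if (E1_ibd1 > 0) (N1 - Z0 * E1_ibd0) / E1_ibd1 else 0
  Z2 <- 1 - Z0 - Z1
  z <- clamp(c(Z0, Z1, Z2), 0, 1)
  if (sum(z) == 0) z <- c(1, 0, 0) else z <- z / sum(z)
  structure(list(Z0 = z[1], Z1 = z[2], Z2 = z[3],
                 PI_HAT = z[3] + z[2] / 2, n_sites = n_inf),
            class = "kinship_estimate")
}

#' @export
print.kinship_estimate <- function(x, ...) {
  if (is.na(x$PI_HAT)) {
    cat("kinship_estimate: NA (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("kinship_estimate: PI_HAT=%.3f (Z0=%.3f Z1=%.3f Z2=%.3f, %d sites)\n",
                x$PI_HAT, x$Z0, x$Z1, x$Z2, x$n_sites))
  }
  invisible(x)
}

#' Pairwise kinship table
#'
#' [ibd_pi_hat()] for every sample pair, as a TSV-ready data frame.
#'
#' @inheritParams ibd_pi_hat
#' @return data frame with `sample_a`, `sample_b`, `Z0`, `Z1`, `Z2`,
#'   `PI_HAT`, `n_sites`.
#' @export
kinship_table <- function(gm, allele_freqs = NULL, min_sites = 200) {
  ns <- n_samples(gm)
  pairs <- utils::combn(ns, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    est <- ibd_pi_hat(gm, pairs[1, j], pairs[2, j], allele_freqs, min_sites)
    data.frame(sample_a = gm$samples[pairs[1, j]],
               sample_b = gm$samples[pairs[2, j]],
               Z0 = est$Z0, Z1 = est$Z1, Z2 = est$Z2,
               PI_HAT = est$PI_HAT, n_sites = est$n_sites)
  })
  do.call(rbind, rows)
}
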