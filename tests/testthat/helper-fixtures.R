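# Fixture builders and independent oracles used across the suite. Oracles
# are deliberately written from first principles (enumeration / textbook
# formulas) and never share code with the package internals they check.

# genotype matrix from a haplotype matrix (sites x 2N alleles, 0/1 codes);
# odd columns become a1, even columns a2
gm_from_haps <- function(H, contig = "c1", pos = NULL, phased = TRUE, ...) {
  stopifnot(ncol(H) %% 2 == 0)
  ns <- ncol(H) / 2
  a1 <- H[, seq(1, ncol(H), by = 2), drop = FALSE]
  a2 <- H[, seq(2, ncol(H), by = 2), drop = FALSE]
  nv <- nrow(H)
  genotype_matrix(rep(contig, nv), pos %||% (seq_len(nv) * 10L),
                  rep("A", nv), rep("T", nv), a1, a2,
                  phased = matrix(phased, nv, ns), ...)
}

# genotype matrix from a dosage matrix (sites x samples, 0/1/2/NA)
gm_from_dosage <- function(d, contig = "c1", pos = NULL, ...) {
  d <- as.matrix(d)
  a1 <- ifelse(is.na(d), NA_integer_, as.integer(d >= 1))
  a2 <- ifelse(is.na(d), NA_integer_, as.integer(d == 2))
  nv <- nrow(d)
  genotype_matrix(rep(contig, nv), pos %||% (seq_len(nv) * 10L),
                  rep("A", nv), rep("T", nv), a1, a2, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- oracles ---------------------------------------------------------------

# mean pairwise per-bp difference over all haplotype pairs, by enumeration
oracle_pi_from_haps <- function(H, window_len) {
  nh <- ncol(H)
  pairs <- utils::combn(nh, 2)
  tot <- 0
  for (j in seq_len(ncol(pairs))) {
    tot <- tot + sum(H[, pairs[1, j]] != H[, pairs[2, j]])
  }
  tot / ncol(pairs) / window_len
}

# Tajima's D from per-site derived-allele counts, textbook constants
oracle_tajimas_d <- function(counts, n) {
  seg <- counts > 0 & counts < n
  S <- sum(seg)
  if (S == 0 || n < 4) return(NA_real_)
  k <- sum(vapply(counts[seg], function(x) x * (n - x) / choose(n, 2),
                  numeric(1)))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# brute-force LD pruning scan with the same contract as ld_prune
oracle_ld_prune <- function(dos, r2_max, window_snps, step_snps) {
  nv <- nrow(dos)
  removed <- rep(FALSE, nv)
  for (s in seq(1, nv, by = step_snps)) {
    idx <- s:min(s + window_snps - 1, nv)
    for (j in idx) {
      if (removed[j]) next
      earlier <- idx[idx < j & !removed[idx]]
      for (i in earlier) {
        ok <- !is.na(dos[i, ]) & !is.na(dos[j, ])
        if (sum(ok) < 2) next
        if (stats::sd(dos[i, ok]) == 0 || stats::sd(dos[j, ok]) == 0) next
        if (stats::cor(dos[i, ok], dos[j, ok])^2 > r2_max) {
          removed[j] <- TRUE
          break
        }
      }
    }
    if (s + window_snps - 1 >= nv) break
  }
  which(!removed)
}

# brute-force ungapped primer matching: every offset, both strands
oracle_primer_hits <- function(primer, seqs, mismatch_fraction = 0.05) {
  k <- floor(mismatch_fraction * nchar(primer))
  pr <- strsplit(primer, "")[[1]]
  rc <- strsplit(revcomp(primer), "")[[1]]
  len <- length(pr)
  rows <- list()
  for (ct in names(seqs)) {
    sv <- strsplit(seqs[[ct]], "")[[1]]
    L <- length(sv)
    for (s in seq_len(L - len + 1)) {
      win <- sv[s:(s + len - 1)]
      mmf <- sum(win != pr)
      mmr <- sum(win != rc)
      if (mmf <= k) rows[[length(rows) + 1]] <-
          data.frame(contig = ct, start = s - 1L, end = s - 1L + len,
                     strand = "+", mismatches = mmf)
      if (mmr <= k) rows[[length(rows) + 1]] <-
          data.frame(contig = ct, start = s - 1L, end = s - 1L + len,
                     strand = "-", mismatches = mmr)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), mismatches = integer(0))
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

# small default simulation shared by end-to-end tests (kept light)
small_sim_config <- function(seed = 101) {
  sim_config(seed = seed, n_contigs = 2, contig_length = 60000,
             n_cores = 12, n_decoys = 2, n_te = 3, te_length = 1000,
             total_reads = 2e4)
}

# linear toy genetic map: `cm_per_contig` cM spread over each contig
toy_map <- function(contigs, length_bp, cm_total = 50) {
  anchors <- seq(0, length_bp, length.out = 5)
  genetic_map(contig = rep(contigs, each = length(anchors)),
              bp = rep(anchors, length(contigs)),
              cM = rep(anchors / length_bp * cm_total, length(contigs)))
}

# deterministic SD1-compatible synthetic primer panel: n loci with 17-26 bp
# locus-specific primers, 31/34 bp tails, balancing factors and target
# coordinates giving amplicons in the conventional 87-174 bp range
synth_sd1_panel <- function(n = 300, seed = 2024) {
  set.seed(seed)
  rand_dna <- function(k) paste(sample(c("A", "C", "G", "T"), k, TRUE),
                                collapse = "")
  amp_len <- sample(87:174, n, replace = TRUE)
  contig <- sort(rep_len(c("chr1", "chr2", "chr3"), n))
  start <- unlist(lapply(table(contig), function(k) {
    sort(sample.int(3e6, k)) * 100L
  }))
  primer_table(
    locus_id = sprintf("%s_%05d", contig, seq_len(n)),
    fwd_seq = vapply(sample(17:26, n, TRUE), rand_dna, character(1)),
    rev_seq = vapply(sample(17:26, n, TRUE), rand_dna, character(1)),
    fwd_tail = strrep("A", 31), rev_tail = strrep("C", 34),
    balancing_factor = round(exp(stats::runif(n, -0.7, 0.7)), 3),
    contig = contig, start = start, end = start + amp_len)
}

# simulated sample pair with known relatedness, padded with unrelated
# samples so allele frequencies are estimable from the matrix itself
sim_pair_gm <- function(n_sites, relationship, seed) {
  set.seed(seed)
  p <- pmin(pmax(rbeta(n_sites, 1, 3), 0.05), 0.95)
  g_a1 <- rbinom(n_sites, 1, p); g_a2 <- rbinom(n_sites, 1, p)
  if (relationship == "duplicate") {
    b_a1 <- g_a1; b_a2 <- g_a2
  } else if (relationship == "unrelated") {
    b_a1 <- rbinom(n_sites, 1, p); b_a2 <- rbinom(n_sites, 1, p)
  } else { # parent-offspring: one allele transmitted per site
    pick <- rbinom(n_sites, 1, 0.5)
    b_a1 <- ifelse(pick == 1, g_a1, g_a2)
    b_a2 <- rbinom(n_sites, 1, p)
  }
  ns_extra <- 20
  extra1 <- matrix(rbinom(n_sites * ns_extra, 1, rep(p, ns_extra)), n_sites)
  extra2 <- matrix(rbinom(n_sites * ns_extra, 1, rep(p, ns_extra)), n_sites)
  gm_from_haps(do.call(cbind, c(list(cbind(g_a1, g_a2, b_a1, b_a2)),
                                lapply(seq_len(ns_extra), function(i) {
                                  cbind(extra1[, i], extra2[, i])
                                }))),
               pos = seq_len(n_sites))
}
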