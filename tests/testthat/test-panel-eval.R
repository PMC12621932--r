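# Panel evaluation: read assignment, coverage balance, balancing factors,
# rarefaction with a closed-form hypergeometric check, SNP content, size
# statistics and microhaplotypes.

eval_panel <- function() {
  primer_table(locus_id = c("L1", "L2"),
               fwd_seq = c("ACGTACGTACGTACGTACGT", "TTGGCCAATTGGCCAATTGG"),
               rev_seq = c("CCGGTTAACCGGTTAACCGG", "ACACACACACACACACACAC"),
               fwd_tail = strrep("A", 31), rev_tail = strrep("C", 34),
               contig = "c1", start = c(1000, 5000), end = c(1150, 5160))
}

test_that("read assignment applies the half-overlap rule and conserves reads", {
  panel <- eval_panel()
  al <- data.frame(
    read_id = paste0("r", 1:5),
    contig = "c1",
    start = c(1010, 940, 900, 1020, 3000),   # inside; 40%; 0%; multimap; off
    end = c(1110, 1040, 1000, 1120, 3100),
    multimap = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  ra <- assign_reads(al, panel)
  expect_equal(unname(ra$counts["L1"]), 1L)
  expect_equal(unname(ra$tally),
               c(1L, 3L, 1L, 0L))   # assigned, off_panel, multimap, rejected
  expect_equal(sum(ra$tally), nrow(al))
  # a read overlapping 40% of its length is not assigned
  expect_true(is.na(ra$assignments[2]))
  # exactly 50% qualifies
  al50 <- data.frame(read_id = "r", contig = "c1", start = 950, end = 1050,
                     multimap = FALSE)
  expect_equal(unname(assign_reads(al50, panel)$counts["L1"]), 1L)
  # malformed rows are rejected and counted
  bad <- data.frame(read_id = "r", contig = "c1", start = 100, end = 100,
                    multimap = FALSE)
  expect_equal(unname(assign_reads(bad, panel)$tally["rejected"]), 1L)
})

test_that("coverage uniformity reports shares and a closed-form Gini", {
  u <- coverage_uniformity(stats::setNames(rep(10, 10), paste0("L", 1:10)))
  expect_equal(u$top_share, 0.1)
  expect_equal(u$gini, 0)
  v <- coverage_uniformity(c(one = 100, rep(0, 9)))
  expect_equal(v$top_share, 1)
  w <- coverage_uniformity(c(a = 4, b = 3, c = 2, d = 1))
  expect_equal(unname(w$shares), c(0.4, 0.3, 0.2, 0.1))
  expect_equal(w$gini, 0.25)
  expect_error(coverage_uniformity(c(0, 0)), "zero")
})

test_that("balancing factors invert observed shares with clamping", {
  counts <- c(L1 = 100, L2 = 200, L3 = 100, L4 = 0)
  expect_warning(f <- balancing_factors(counts), "zero-count")
  expect_equal(unname(f["L1"]), 0.25 / 0.25)
  expect_equal(unname(f["L2"]), 0.5)   # at 2x target -> dilute to half
  expect_equal(unname(f["L4"]), 2)     # upper clamp
  # lower clamp engages for dominant loci
  counts2 <- c(a = 1000, b = 1)
  f2 <- balancing_factors(counts2)
  expect_equal(unname(f2["a"]), 0.5005, tolerance = 1e-3)
  expect_equal(unname(f2["b"]), 2)
})

test_that("rebalancing reduces count dispersion under the bias model", {
  cfg <- sim_config(seed = 7, bias_sd = 0.5, total_reads = 2e4,
                    off_panel_rate = 0)
  panel <- eval_panel()
  panel <- panel[rep(1, 30), ]
  panel$locus_id <- sprintf("L%02d", 1:30)
  panel$start <- 1000 + (0:29) * 2000
  panel$end <- panel$start + 150
  wins <- 0
  for (trial in 1:100) {
    r1 <- simulate_read_table(panel, cfg, c(c1 = 100000), seed = 500 + trial)
    f <- balancing_factors(r1$true_counts)
    panel2 <- panel
    panel2$balancing_factor <- unname(f)
    r2 <- simulate_read_table(panel2, cfg, c(c1 = 100000), seed = 500 + trial)
    cv <- function(x) stats::sd(x) / mean(x)
    if (cv(r2$true_counts) < cv(r1$true_counts)) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("rarefaction endpoints, degenerate depths and errors behave", {
  counts <- c(L1 = 50, L2 = 5)
  rc <- rarefaction(counts, depths = c(5, 20, 55), threshold = 10,
                    replicates = 200, seed = 9)
  # at full depth the proportion equals the observed one exactly, sd 0
  expect_equal(rc$mean_genotyped[3], mean(counts >= 10))
  expect_equal(rc$sd_genotyped[3], 0)
  # a depth below the threshold cannot genotype any locus
  expect_equal(rc$mean_genotyped[1], 0)
  # depth 20 from counts (50, 5): locus 2 can never reach 10, locus 1
  # always does (at most 5 of 20 draws are non-L1); closed form = 1/2
  expect_equal(rc$mean_genotyped[2], 0.5)
  expect_error(rarefaction(counts, depths = 0, seed = 1), "positive")
  over <- rarefaction(counts, depths = 100, seed = 1)
  expect_false(over$supported)
  expect_true(is.na(over$mean_genotyped))
})

test_that("rarefaction matches the hypergeometric tail within MC error", {
  counts <- c(a = 30, b = 25, c = 5)
  depth <- 20; thr <- 10; reps <- 2000
  rc <- rarefaction(counts, depths = depth, threshold = thr,
                    replicates = reps, seed = 17)
  # marginals of the multivariate hypergeometric are hypergeometric
  exact <- mean(vapply(counts, function(k) {
    1 - stats::phyper(thr - 1, k, sum(counts) - k, depth)
  }, numeric(1)))
  mc_se <- rc$sd_genotyped / sqrt(reps)
  expect_lt(abs(rc$mean_genotyped - exact), max(3 * mc_se, 0.01))
  # determinism under seed
  rc2 <- rarefaction(counts, depths = depth, threshold = thr,
                     replicates = reps, seed = 17)
  expect_identical(rc, rc2)
})

test_that("rarefaction curves are non-decreasing in depth", {
  set.seed(23)
  counts <- stats::setNames(rpois(40, 30), paste0("L", 1:40))
  rc <- rarefaction(counts, depths = c(100, 300, 600, 900, sum(counts)),
                    threshold = 10, replicates = 300, seed = 23)
  expect_true(all(diff(rc$mean_genotyped) > -0.02))
})

test_that("SNPs per amplicon count by half-open locus intervals", {
  panel <- eval_panel()
  gm <- gm_from_dosage(matrix(1L, 4, 2), pos = c(1000L, 1100L, 1150L, 3000L))
  out <- snps_per_amplicon(gm, panel)
  # 1150 sits exactly at L1's end: excluded by half-open semantics
  expect_equal(unname(out$counts), c(2L, 0L))
  expect_equal(out$off_panel, 2)
  gm0 <- gm_from_dosage(matrix(1L, 1, 2), pos = 9000L)
  expect_equal(unname(snps_per_amplicon(gm0, panel)$counts), c(0L, 0L))
})

test_that("amplicon and library size statistics are additive arithmetic", {
  panel <- eval_panel()
  panel$amplicon_length <- c(100, 140)
  ss <- amplicon_size_stats(panel)
  expect_equal(ss$amplicon$min, 100)
  expect_equal(ss$amplicon$max, 140)
  expect_equal(ss$total_targeted_bp, 240)
  # overhead from the tails alone: 31 + 34 = 65
  expect_equal(unique(ss$overhead), 65)
  expect_equal(ss$library$min, 165)
  # index primers extend beyond the tails they anneal to
  ss2 <- amplicon_size_stats(panel, index_fwd = strrep("A", 31 + 30),
                             index_rev = strrep("C", 34 + 36))
  expect_equal(unique(ss2$overhead), 65 + 66)
  # single-locus panel: min = median = max
  ss1 <- amplicon_size_stats(panel[1, ])
  expect_equal(ss1$amplicon$min, ss1$amplicon$median)
  # a locus without length or coordinates errors, naming the locus
  p2 <- panel; p2$amplicon_length <- NULL; p2$start[2] <- NA
  expect_error(amplicon_size_stats(p2), "L2")
})

test_that("microhaplotypes follow phase and missingness rules", {
  panel <- eval_panel()[1, ]
  # two phased het sites 0|1 and 1|0 -> haplotypes "01" and "10"
  gm <- genotype_matrix(rep("c1", 2), c(1010L, 1020L), c("A", "C"),
                        c("T", "G"),
                        a1 = matrix(c(0L, 1L), 2), a2 = matrix(c(1L, 0L), 2),
                        phased = matrix(TRUE, 2, 1))
  mh <- extract_microhaplotypes(gm, panel)
  expect_equal(mh$hap1, "01")
  expect_equal(mh$hap2, "10")
  # all hom-ref locus: both haplotypes all-0 (phase flags irrelevant)
  gm0 <- genotype_matrix(rep("c1", 2), c(1010L, 1020L), c("A", "C"),
                         c("T", "G"),
                         a1 = matrix(0L, 2), a2 = matrix(0L, 2),
                         phased = matrix(FALSE, 2, 1))
  mh0 <- extract_microhaplotypes(gm0, panel)
  expect_equal(mh0$hap1, "00")
  # one unphased het -> null with reason
  gmu <- gm
  gmu$phased[2, 1] <- FALSE
  mhu <- extract_microhaplotypes(gmu, panel)
  expect_true(is.na(mhu$hap1))
  expect_equal(mhu$reason, "unphased")
  # a missing call anywhere nulls the locus
  gmm <- gm
  gmm$a1[1, 1] <- NA; gmm$a2[1, 1] <- NA
  expect_equal(extract_microhaplotypes(gmm, panel)$reason, "missing")
})
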