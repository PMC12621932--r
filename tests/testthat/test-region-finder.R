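# Candidate-region detection and the filter flags, on hand-built diversity
# tracks and genotype matrices with forced statistics.

# build a window_stats track from a pi vector (one value per 50-bp window)
track_from_pi <- function(pi, contig = "c1", window_bp = 50, S = NULL) {
  n <- length(pi)
  tr <- data.frame(contig = contig, start = (seq_len(n) - 1) * window_bp,
                   end = seq_len(n) * window_bp, pi = pi,
                   S = S %||% as.integer(pi > 0), mean_dp = NA_real_)
  attr(tr, "window_bp") <- window_bp
  class(tr) <- c("window_stats", "data.frame")
  tr
}

test_that("candidate scan detects planted cores within length bounds", {
  cfg <- design_config()
  # flat zero track: nothing
  expect_equal(nrow(scan_candidates(track_from_pi(rep(0, 20)), cfg)), 0)
  # one 100-bp run at pi = 0.01 with quiet 200-bp flanks
  pi <- c(rep(0, 4), 0.01, 0.01, rep(0, 4))
  cand <- scan_candidates(track_from_pi(pi), cfg)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$core_start, 200)
  expect_equal(cand$core_end, 300)
  expect_equal(cand$pi_core, 0.01)
  # a 200-bp run exceeds the 150-bp core ceiling
  pi <- c(rep(0, 4), rep(0.01, 4), rep(0, 4))
  expect_equal(nrow(scan_candidates(track_from_pi(pi), cfg)), 0)
  # cores at contig ends lack a flank and are rejected
  pi <- c(0.01, 0.01, rep(0, 6))
  expect_equal(nrow(scan_candidates(track_from_pi(pi), cfg)), 0)
  # a noisy flank window disqualifies the core
  pi <- c(rep(0, 3), 2e-4, 0.01, 0.01, rep(0, 4))
  expect_equal(nrow(scan_candidates(track_from_pi(pi), cfg)), 0)
})

test_that("repeat masking flags >= 1 bp overlap with half-open semantics", {
  pi <- c(rep(0, 4), 0.01, 0.01, rep(0, 4))
  cand <- scan_candidates(track_from_pi(pi), design_config())
  # mask covering the core
  m1 <- apply_repeat_mask(cand, data.frame(contig = "c1", start = 250L,
                                           end = 260L))
  expect_true(m1$flag_te)
  # mask ending exactly at the flank start: abutting, no overlap
  lf <- cand$lflank_start
  m2 <- apply_repeat_mask(cand, data.frame(contig = "c1", start = lf - 100L,
                                           end = lf))
  expect_false(m2$flag_te)
  # one bp into the flank: flagged
  m3 <- apply_repeat_mask(cand, data.frame(contig = "c1", start = lf - 100L,
                                           end = lf + 1L))
  expect_true(m3$flag_te)
  # empty mask
  expect_false(apply_repeat_mask(cand, NULL)$flag_te)
})

# a candidate data frame and genotype matrix with controllable depth/SNPs
cand_with_genotypes <- function(n_sites = 10, n_samples = 8, depth = 8000,
                                alt_count = 1) {
  H <- t(vapply(rep(alt_count, n_sites), function(x) {
    sample(c(rep(1L, x), rep(0L, 2 * n_samples - x)))
  }, integer(2 * n_samples)))
  gm <- gm_from_haps(H, pos = 200L + seq_len(n_sites) * 3L,
                     dp = matrix(depth, n_sites, n_samples))
  pi <- c(rep(0, 4), 0.01, 0.01, rep(0, 4))
  cand <- scan_candidates(track_from_pi(pi), design_config())
  list(cand = cand, gm = gm)
}

test_that("copy-number screen applies depth, diversity and SNP ceilings", {
  set.seed(5)
  # depth > 20,000 in all samples
  x <- cand_with_genotypes(depth = 25000)
  expect_true(cnv_depth_filter(x$cand, x$gm)$flag_cnv)
  # one high-depth sample does not trip the all-samples rule
  x <- cand_with_genotypes(depth = 8000)
  x$gm$dp[, 1] <- 25000
  expect_false(cnv_depth_filter(x$cand, x$gm)$flag_cnv)
  # > 25 SNPs per locus
  x <- cand_with_genotypes(n_sites = 30)
  out <- cnv_depth_filter(x$cand, x$gm)
  expect_true(out$flag_cnv)
  expect_equal(out$S_core_used, 30L)
  # core pi above 0.02: every sample heterozygous at many sites
  x <- cand_with_genotypes(n_sites = 10, alt_count = 8)
  expect_gt(cnv_depth_filter(x$cand, x$gm)$pi_core_used, 0.02)
})

test_that("low-depth samples are excluded per region, depth-fail when none remain", {
  set.seed(6)
  x <- cand_with_genotypes(depth = 8000)
  x$gm$dp[, 1:2] <- 3000
  out <- cnv_depth_filter(x$cand, x$gm)
  expect_equal(out$n_low_depth_samples, 2L)
  expect_false(out$flag_depth)
  x$gm$dp[] <- 3000
  out <- cnv_depth_filter(x$cand, x$gm)
  expect_true(out$flag_depth)
})

test_that("selection filter requires -2 < D < 2 and f < 0.25 in every subpop", {
  set.seed(8)
  # balanced intermediate-frequency sites in both subpops: D near 0, f near 0
  make_gm <- function(H1, H2) {
    H <- cbind(H1, H2)
    gm <- gm_from_haps(H, pos = 200L + seq_len(nrow(H)) * 4L)
    gm$subpop <- rep(c("A", "B"), each = ncol(H1) / 2)
    gm
  }
  # frequency-spectrum-like mix (singletons through intermediate) keeps D
  # inside the neutral band
  sfs_counts <- c(1L, 1L, 1L, 2L, 3L, 8L)
  draw_haps <- function() t(vapply(sfs_counts, function(x) {
    sample(c(rep(1L, x), rep(0L, 16 - x)))
  }, integer(16)))
  neutralish <- draw_haps()
  gm <- make_gm(neutralish, draw_haps())
  pi <- c(rep(0, 4), 0.01, 0.01, rep(0, 4))
  cand <- scan_candidates(track_from_pi(pi), design_config())
  out <- selection_filter(cand, gm)
  expect_true(abs(out$D_A) < 2 && abs(out$D_B) < 2)
  expect_false(out$flag_selection)
  # a subpopulation with no segregating sites fails (conservative default)
  gm2 <- make_gm(neutralish, matrix(0L, 6, 16))
  out2 <- selection_filter(cand, gm2)
  expect_true(out2$flag_selection)
  expect_false(selection_filter(cand, gm2,
                                design_config(fail_null_d = FALSE))$flag_selection)
  # strong heterozygote deficit in one subpop: f >= 0.25 fails
  homs <- t(replicate(6, rep(sample(c(0L, 1L)), c(8, 8))))  # all homozygous
  gm3 <- make_gm(neutralish, homs)
  out3 <- selection_filter(cand, gm3)
  expect_gte(out3$f_B, 0.25)
  expect_true(out3$flag_selection)
})

test_that("flags are independent of filter order and pass set is flag-free", {
  cfg <- small_sim_config()
  ref <- simulate_reference(cfg)
  gm <- simulate_population(ref)
  clens <- contig_lengths(ref$genome)
  track <- windowed_pi(gm, 50, clens)
  base <- scan_candidates(track, design_config())
  a <- selection_filter(cnv_depth_filter(apply_repeat_mask(base, ref$tes),
                                         gm), gm)
  b0 <- selection_filter(base, gm)
  b1 <- cnv_depth_filter(b0, gm)
  b <- apply_repeat_mask(b1, ref$tes)
  for (fl in c("flag_te", "flag_cnv", "flag_depth", "flag_selection")) {
    expect_equal(a[[fl]], b[[fl]])
  }
  pass <- candidate_pass(a)
  expect_true(all(!pass$flag_te & !pass$flag_cnv & !pass$flag_depth &
                    !pass$flag_selection))
})

test_that("the candidate pipeline is bit-identical on identical inputs", {
  cfg <- small_sim_config()
  ref <- simulate_reference(cfg)
  gm <- simulate_population(ref)
  clens <- contig_lengths(ref$genome)
  a <- find_target_regions(gm, clens, repeat_mask = ref$tes)
  b <- find_target_regions(gm, clens, repeat_mask = ref$tes)
  expect_identical(a, b)
})
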