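# The synthetic-data generators: determinism, planted-feature truth,
# diversity calibration, decoy signatures, annotation spiking and the read
# model.

test_that("every generator is deterministic under its seed", {
  cfg <- small_sim_config(77)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$genome$seq, r2$genome$seq)
  expect_identical(r1$cores, r2$cores)
  g1 <- simulate_population(r1)
  g2 <- simulate_population(r2)
  expect_identical(g1$a1, g2$a1)
  expect_identical(g1$dp, g2$dp)
  a1 <- simulate_annotated_vcf(g1, cfg)
  a2 <- simulate_annotated_vcf(g2, cfg)
  expect_identical(a1$gm$info, a2$gm$info)
  expect_identical(a1$truth, a2$truth)
  # byte-identical VCF under re-serialization
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(a1$gm, f1); write_vcf(a2$gm, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a zero-feature config yields a plain genome with empty truth", {
  cfg <- sim_config(seed = 5, n_contigs = 1, contig_length = 20000,
                    n_cores = 0, n_decoys = 0, n_te = 0)
  ref <- simulate_reference(cfg)
  expect_equal(nrow(ref$cores), 0)
  expect_equal(nrow(ref$tes), 0)
  expect_equal(nrow(ref$copies), 0)
  expect_equal(nchar(ref$genome$seq[[1]]), 20000)
  gm <- simulate_population(ref)
  # only sparse background sites remain
  expect_lt(n_variants(gm), 30)
})

test_that("each decoy plants exactly one verbatim duplicate", {
  cfg <- small_sim_config(78)
  ref <- simulate_reference(cfg)
  decoys <- ref$cores[ref$cores$type == "decoy", ]
  fl <- cfg$flank_length
  for (i in seq_len(nrow(decoys))) {
    frag <- substr(ref$genome$seq[[decoys$contig[i]]],
                   decoys$start[i] - fl + 1, decoys$end[i] + fl)
    n_occ <- sum(vapply(ref$genome$seq, function(s) {
      length(gregexpr(frag, s, fixed = TRUE)[[1]]) *
        (gregexpr(frag, s, fixed = TRUE)[[1]][1] != -1)
    }, numeric(1)))
    expect_equal(n_occ, 2)
  }
})

test_that("realized core diversity sits in the planted band", {
  cfg <- sim_config(seed = 79)
  ref <- simulate_reference(cfg)
  gm <- simulate_population(ref)
  track <- windowed_pi(gm, 50, contig_lengths(ref$genome))
  clean <- ref$cores[ref$cores$type == "clean", ]
  core_pi <- unlist(lapply(seq_len(nrow(clean)), function(i) {
    w <- track[track$contig == clean$contig[i] &
                 track$start >= clean$start[i] &
                 track$end <= clean$end[i], ]
    w$pi
  }))
  # the window band [0.55, 1.0] expected hets corresponds to mean window pi
  # of about 0.0155/50*... i.e. mean in (0.011, 0.020); sampling keeps the
  # realized mean within 20% of the band midpoint
  band_mid <- mean(cfg$window_het_band) / 50
  expect_lt(abs(mean(core_pi) - band_mid) / band_mid, 0.20)
  # flank windows are quiet
  flank_pi <- unlist(lapply(seq_len(nrow(clean)), function(i) {
    w <- track[track$contig == clean$contig[i] &
                 track$start >= clean$start[i] - 100 &
                 track$end <= clean$start[i], ]
    w$pi
  }))
  expect_true(all(flank_pi < 1e-4))
})

test_that("decoy cores carry the collapsed-duplication signature", {
  cfg <- sim_config(seed = 80)
  ref <- simulate_reference(cfg)
  gm <- simulate_population(ref)
  truth <- attr(gm, "site_truth")
  decoy_ids <- ref$cores$locus_id[ref$cores$type == "decoy"]
  in_decoy <- truth$origin %in% decoy_ids |
    truth$origin %in% paste0("psv:", decoy_ids)
  clean_ids <- ref$cores$locus_id[ref$cores$type == "clean"]
  in_clean <- truth$origin %in% clean_ids
  # roughly doubled depth
  ratio <- mean(gm$dp[in_decoy, ]) / mean(gm$dp[in_clean, ])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
  # PSV sites are heterozygous in every genotyped sample
  psv <- startsWith(truth$origin, "psv:")
  het <- gm$a1[psv, ] != gm$a2[psv, ]
  expect_true(all(het, na.rm = TRUE))
})

test_that("admixture proportion controls the ancestry of admixed alleles", {
  cfg <- sim_config(seed = 81, divergence = 0.45, n_admixed = 6,
                    admix_prop = 1)   # all alleles from subpopulation 1
  ref <- simulate_reference(cfg)
  gm <- simulate_population(ref)
  adx <- grepl("^ADX", gm$samples)
  sp1 <- !is.na(gm$subpop) & gm$subpop == "Aaa"
  sp2 <- !is.na(gm$subpop) & gm$subpop == "Aaf"
  freq <- function(cols) rowMeans(gm$a1[, cols, drop = FALSE] +
                                    gm$a2[, cols, drop = FALSE],
                                  na.rm = TRUE) / 2
  poly <- !startsWith(attr(gm, "site_truth")$origin, "psv")
  r1 <- suppressWarnings(cor(freq(adx)[poly], freq(sp1)[poly],
                             use = "complete.obs"))
  r2 <- suppressWarnings(cor(freq(adx)[poly], freq(sp2)[poly],
                             use = "complete.obs"))
  expect_gt(r1, r2 + 0.1)
})

test_that("annotation spiking is exactly recovered by the site filter", {
  cfg <- small_sim_config(82)
  ref <- simulate_reference(cfg)
  gm <- simulate_population(ref)
  # spike 0: everything passes
  ann0 <- simulate_annotated_vcf(gm, cfg, spike_frac = 0)
  out0 <- site_hard_filter(ann0$gm)
  expect_equal(n_variants(out0$gm), n_variants(gm))
  # spiked records are exactly the removed ones, rule by rule
  ann <- simulate_annotated_vcf(gm, cfg, spike_frac = 0.08)
  out <- site_hard_filter(ann$gm)
  expect_identical(out$reasons == "QD" & !is.na(out$reasons),
                   ann$truth$violates == "QD")
  expect_identical(out$reasons == "FS" & !is.na(out$reasons),
                   ann$truth$violates == "FS")
  expect_identical(is.na(out$reasons), ann$truth$violates == "none")
})

test_that("the read model respects balancing, bias and multimap labels", {
  cfg <- sim_config(seed = 83, bias_sd = 0, off_panel_rate = 0,
                    total_reads = 1e5, multimap_prob = 1)
  panel <- primer_table(locus_id = sprintf("L%02d", 1:20),
                        fwd_seq = rep("ACGTACGTACGTACGTACGT", 20),
                        rev_seq = rep("TGCATGCATGCATGCATGCA", 20),
                        contig = "c1", start = 1000 + (0:19) * 1000,
                        end = 1000 + (0:19) * 1000 + 150)
  rt <- simulate_read_table(panel, cfg, c(c1 = 50000),
                            decoy_loci = c("L01", "L02"))
  # zero bias + equal factors: counts consistent with uniform multinomial
  gof <- stats::chisq.test(rt$true_counts)
  expect_gt(gof$p.value, 0.01)
  # multimap probability 1 on decoy loci: no counted (unique) reads there
  ra <- assign_reads(rt$alignments, panel)
  expect_equal(unname(ra$counts["L01"]), 0L)
  expect_equal(unname(ra$counts["L02"]), 0L)
  expect_gt(unname(ra$counts["L03"]), 0L)
  # identical under the same seed
  rt2 <- simulate_read_table(panel, cfg, c(c1 = 50000),
                             decoy_loci = c("L01", "L02"))
  expect_identical(rt$alignments, rt2$alignments)
})
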