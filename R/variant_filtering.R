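# Post-calling filter cascades: site hard filters on quality annotations,
# per-genotype masking, variant/sample missingness filtering, and
# kinship-based sample pruning. Two profiles mirror the two sequencing
# regimes: deep amplicon data and heterogeneous-depth WGS data.

#' Filter profile
#'
#' Thresholds of the post-calling cascade. Both modes share the site hard
#' filters (QD > 5, FS < 60, ReadPosRankSum > -8, SNPs only) and the 10%
#' variant missingness ceiling. Genotype and sample thresholds differ:
#' amplicon mode retains calls with GQ >= 30 and DP >= 10 and drops samples
#' above 10% missingness; wgs mode retains GQ > 20 (strict, as the regime's
#' convention has it) and DP >= 5 and tolerates 50% sample missingness.
#'
#' @param mode `"amplicon"` or `"wgs"`.
#' @param qd_floor,fs_ceiling,rprs_floor site annotation thresholds.
#' @param gq_min,gq_strict,dp_min genotype thresholds; `gq_strict` makes the
#'   GQ bound exclusive.
#' @param variant_miss_max,sample_miss_max missingness ceilings (fractions).
#' @param pi_hat_max kinship pruning ceiling.
#' @return list of class `filter_profile`.
#' @export
filter_profile <- function(mode = c("amplicon", "wgs"),
                           qd_floor = 5, fs_ceiling = 60, rprs_floor = -8,
                           gq_min = NULL, gq_strict = NULL, dp_min = NULL,
                           variant_miss_max = 0.10, sample_miss_max = NULL,
                           pi_hat_max = 0.75) {
  mode <- match.arg(mode)
  if (mode == "amplicon") {
    gq_min <- gq_min %||% 30; gq_strict <- gq_strict %||% FALSE
    dp_min <- dp_min %||% 10; sample_miss_max <- sample_miss_max %||% 0.10
  } else {
    gq_min <- gq_min %||% 20; gq_strict <- gq_strict %||% TRUE
    dp_min <- dp_min %||% 5; sample_miss_max <- sample_miss_max %||% 0.50
  }
  structure(list(mode = mode, qd_floor = qd_floor, fs_ceiling = fs_ceiling,
                 rprs_floor = rprs_floor, gq_min = gq_min,
                 gq_strict = gq_strict, dp_min = dp_min,
                 variant_miss_max = variant_miss_max,
                 sample_miss_max = sample_miss_max, pi_hat_max = pi_hat_max),
            class = "filter_profile")
}

#' Site-level hard filter
#'
#' Keeps only SNP records (ref and every alternate a single base) whose
#' annotations satisfy QD > floor AND FS < ceiling AND ReadPosRankSum >
#' floor. An absent annotation never fails a record (pass-by-absence; the
#' annotation source leaves e.g. ReadPosRankSum undefined at sites without
#' heterozygous calls). Each removed record carries exactly one reason
#' (first failing rule in the order: not a SNP, QD, FS, ReadPosRankSum).
#'
#' @param gm a [genotype_matrix()].
#' @param profile a [filter_profile()].
#' @return list with `gm` (filtered) and `report` (data frame of stage
#'   counts, including pass-by-absence tallies).
#' @export
site_hard_filter <- function(gm, profile = filter_profile("amplicon")) {
  nv <- n_variants(gm)
  snp <- is_snp(gm)
  qd <- gm$info$QD; fs <- gm$info$FS; rprs <- gm$info$ReadPosRankSum
  fail_qd <- !is.na(qd) & qd <= profile$qd_floor
  fail_fs <- !is.na(fs) & fs >= profile$fs_ceiling
  fail_rprs <- !is.na(rprs) & rprs <= profile$rprs_floor
  reason <- rep(NA_character_, nv)
  reason[fail_rprs] <- "ReadPosRankSum"
  reason[fail_fs] <- "FS"
  reason[fail_qd] <- "QD"
  reason[!snp] <- "not_snp"
  keep <- is.na(reason)
  report <- data.frame(
    stage = "site_hard_filter",
    input = nv, retained = sum(keep), removed = sum(!keep),
    removed_not_snp = sum(reason == "not_snp", na.rm = TRUE),
    removed_qd = sum(reason == "QD", na.rm = TRUE),
    removed_fs = sum(reason == "FS", na.rm = TRUE),
    removed_rprs = sum(reason == "ReadPosRankSum", na.rm = TRUE),
    pass_by_absence = sum(keep & snp & (is.na(qd) | is.na(fs) | is.na(rprs))))
  list(gm = gm_subset(gm, variants = which(keep)), report = report,
       reasons = reason)
}

#' Genotype-level masking
#'
#' Sets sub-threshold calls to missing without removing records: in amplicon
#' mode a call needs GQ >= 30 and DP >= 10; in wgs mode GQ > 20 and
#' DP >= 5. Calls whose DP or GQ annotation is absent are retained.
#'
#' @inheritParams site_hard_filter
#' @return list with `gm` (calls masked) and `report` (`n_masked` count).
#' @export
genotype_mask <- function(gm, profile = filter_profile("amplicon")) {
  gq_bad <- if (profile$gq_strict) gm$gq <= profile$gq_min else
    gm$gq < profile$gq_min
  dp_bad <- gm$dp < profile$dp_min
  mask <- (!is.na(gq_bad) & gq_bad) | (!is.na(dp_bad) & dp_bad)
  mask <- mask & !is.na(gm$a1)
  gm$a1[mask] <- NA_integer_
  gm$a2[mask] <- NA_integer_
  gm$phased[mask] <- FALSE
  report <- data.frame(stage = "genotype_mask",
                       input = sum(!is.na(gm$a1)) + sum(mask),
                       retained = sum(!is.na(gm$a1)),
                       removed = sum(mask))
  list(gm = gm, report = report)
}

#' Missingness filter
#'
#' A single pass: first variants whose missing fraction (over all samples)
#' exceeds the ceiling are dropped, then samples whose missing fraction over
#' the retained variants exceeds the sample ceiling are dropped. No
#' iteration.
#'
#' @inheritParams site_hard_filter
#' @return list with `gm`, `report` and `removed_samples`.
#' @export
missingness_filter <- function(gm, profile = filter_profile("amplicon")) {
  nv <- n_variants(gm); ns <- n_samples(gm)
  vmiss <- rowMeans(is.na(gm$a1))
  keep_v <- vmiss <= profile$variant_miss_max
  gm2 <- gm_subset(gm, variants = which(keep_v))
  if (n_variants(gm2) > 0) {
    smiss <- colMeans(is.na(gm2$a1))
  } else {
    smiss <- rep(0, ns)
  }
  keep_s <- smiss <= profile$sample_miss_max
  removed_samples <- gm2$samples[!keep_s]
  gm3 <- gm_subset(gm2, samples = which(keep_s))
  report <- data.frame(
    stage = c("variant_missingness", "sample_missingness"),
    input = c(nv, ns),
    retained = c(sum(keep_v), sum(keep_s)),
    removed = c(sum(!keep_v), sum(!keep_s)))
  list(gm = gm3, report = report, removed_samples = removed_samples)
}

#' Kinship-based sample pruning
#'
#' Estimates PI_HAT for every sample pair, links pairs above the ceiling,
#' and greedily removes the highest-degree sample until no link remains
#' (ties: the sample with more missing data, then the lexicographically
#' later id). Pairs whose estimate is undefined (too few informative sites)
#' contribute no link and are counted.
#'
#' @param gm a [genotype_matrix()].
#' @param pi_hat_max relatedness ceiling (default 0.75).
#' @param min_sites passed to [ibd_pi_hat()].
#' @return list with `retained` / `removed` sample ids, the pairwise
#'   `kinship` table, and `n_null_pairs`.
#' @export
kinship_prune <- function(gm, pi_hat_max = 0.75, min_sites = 200) {
  if (n_samples(gm) < 2) stop("need at least 2 samples", call. = FALSE)
  kt <- kinship_table(gm, min_sites = min_sites)
  n_null <- sum(is.na(kt$PI_HAT))
  edges <- kt[!is.na(kt$PI_HAT) & kt$PI_HAT > pi_hat_max,
              c("sample_a", "sample_b"), drop = FALSE]
  miss <- colMeans(is.na(gm$a1))
  names(miss) <- gm$samples
  removed <- character(0)
  while (nrow(edges) > 0) {
    deg <- table(c(edges$sample_a, edges$sample_b))
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1) {
      m <- miss[cand]
      cand <- cand[m == max(m)]
      cand <- sort(cand, decreasing = TRUE)[1]   # lexicographically later id
    }
    removed <- c(removed, cand[1])
    edges <- edges[edges$sample_a != cand[1] & edges$sample_b != cand[1], ,
                   drop = FALSE]
  }
  list(retained = setdiff(gm$samples, removed), removed = removed,
       kinship = kt, n_null_pairs = n_null)
}

#' Full variant filter cascade
#'
#' [site_hard_filter()], then [genotype_mask()], then
#' [missingness_filter()], in the standard order. The report telescopes
#' (input = retained + removed at every stage) and states whether the
#' output is at a fixed point of the missingness stage (re-running it would
#' remove nothing further).
#'
#' @inheritParams site_hard_filter
#' @return list of class `filter_result`: `gm`, `report` (stacked stage
#'   data frame), `removed_samples`, `fixed_point`.
#' @export
filter_variants <- function(gm, profile = filter_profile("amplicon")) {
  s1 <- site_hard_filter(gm, profile)
  s2 <- genotype_mask(s1$gm, profile)
  s3 <- missingness_filter(s2$gm, profile)
  # fixed-point check: would another missingness pass remove anything?
  again <- missingness_filter(s3$gm, profile)
  fixed <- n_variants(again$gm) == n_variants(s3$gm) &&
    n_samples(again$gm) == n_samples(s3$gm)
  report <- rbind(s1$report[, c("stage", "input", "retained", "removed")],
                  s2$report[, c("stage", "input", "retained", "removed")],
                  s3$report)
  structure(list(gm = s3$gm, report = report, site_report = s1$report,
                 removed_samples = s3$removed_samples, fixed_point = fixed),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("filter_result: %d variants x %d samples retained (%s)\n",
              n_variants(x$gm), n_samples(x$gm),
              if (x$fixed_point) "at fixed point" else "not at fixed point"))
  print(x$report, row.names = FALSE)
  invisible(x)
}
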