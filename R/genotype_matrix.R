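# The genotype container every statistic and filter operates on: diploid calls
# for a set of variants x samples, with per-call depth/quality, per-call phase
# flags and the site annotations the hard filters consume.

#' Construct a genotype matrix
#'
#' The central in-memory representation of population genotypes: a set of
#' variant records (sorted by contig then position, 0-based) and diploid calls
#' for each sample, stored as two allele-index matrices. Missing genotypes are
#' `NA` in both allele matrices. Multiallelic records keep their allele
#' indices intact (`0` = ref, `1..k` = alternates).
#'
#' @param contig character vector of contig ids per variant.
#' @param pos integer vector of 0-based variant positions.
#' @param ref,alt reference allele and comma-separated alternate alleles.
#' @param a1,a2 integer matrices (variants x samples) of allele indices;
#'   `NA` marks a missing call (both must be `NA` together).
#' @param phased logical matrix; `TRUE` where the call was phased (`|`).
#' @param dp,gq numeric matrices of per-call sequencing depth and genotype
#'   quality (phred); `NA` where the annotation is absent.
#' @param info data frame of site annotations with columns `QD`, `FS`,
#'   `ReadPosRankSum`; `NA` means the annotation is absent for that record
#'   (never coerced to 0).
#' @param samples character vector of sample ids (column order of the
#'   matrices).
#' @param subpop optional character vector of subpopulation labels per sample
#'   (`NA` = unlabelled, e.g. admixed individuals).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(contig, pos, ref, alt, a1, a2,
                            phased = NULL, dp = NULL, gq = NULL,
                            info = NULL, samples = NULL, subpop = NULL) {
  nv <- length(pos)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  ns <- ncol(a1)
  if (is.null(samples)) samples <- paste0("S", seq_len(ns))
  if (is.null(phased)) phased <- matrix(FALSE, nv, ns)
  if (is.null(dp)) dp <- matrix(NA_real_, nv, ns)
  if (is.null(gq)) gq <- matrix(NA_real_, nv, ns)
  if (is.null(info)) {
    info <- data.frame(QD = rep(NA_real_, nv), FS = NA_real_,
                       ReadPosRankSum = NA_real_)
  }
  gm <- structure(list(
    contig = as.character(contig), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    a1 = a1, a2 = a2, phased = phased, dp = dp, gq = gq,
    info = info, samples = as.character(samples),
    subpop = if (is.null(subpop)) rep(NA_character_, ns) else as.character(subpop)
  ), class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  nv <- length(gm$pos); ns <- length(gm$samples)
  for (m in c("a1", "a2", "phased", "dp", "gq")) {
    if (!all(dim(gm[[m]]) == c(nv, ns))) {
      stop(sprintf("matrix '%s' must be %d x %d", m, nv, ns), call. = FALSE)
    }
  }
  if (any(xor(is.na(gm$a1), is.na(gm$a2)))) {
    stop("half-missing genotypes are not allowed (a1/a2 NA must agree)",
         call. = FALSE)
  }
  if (nv > 1) {
    o <- order(gm$contig, gm$pos)
    if (!identical(o, seq_len(nv))) {
      stop("variants must be sorted by contig then position", call. = FALSE)
    }
  }
  nalt <- n_alt(gm)
  rowmax <- suppressWarnings(apply(pmax(gm$a1, gm$a2), 1, max, na.rm = TRUE))
  bad <- which(is.finite(rowmax) & rowmax > nalt)
  if (length(bad)) {
    stop(sprintf("allele index exceeds alternate allele count at variant %d",
                 bad[1]), call. = FALSE)
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d samples\n",
              n_variants(x), n_samples(x)))
  cat(sprintf("  contigs: %s\n", paste(unique(x$contig), collapse = ", ")))
  sp <- table(x$subpop, useNA = "ifany")
  if (length(sp)) {
    cat("  subpopulations:",
        paste(sprintf("%s=%d", names(sp), sp), collapse = " "), "\n")
  }
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`.
#' @export
n_variants <- function(gm) length(gm$pos)

#' @rdname genotype_matrix
#' @export
n_samples <- function(gm) length(gm$samples)

n_alt <- function(gm) {
  ifelse(gm$alt == "" | is.na(gm$alt), 0L,
         lengths(strsplit(gm$alt, ",", fixed = TRUE)))
}

is_snp <- function(gm) {
  alt_ok <- vapply(strsplit(gm$alt, ",", fixed = TRUE),
                   function(a) length(a) > 0 && all(nchar(a) == 1L), logical(1))
  nchar(gm$ref) == 1L & alt_ok
}

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`.
#' @param variants integer or logical index of variants to keep.
#' @param samples integer, logical or character index of samples to keep.
#' @return the subsetted `genotype_matrix`.
#' @export
gm_subset <- function(gm, variants = NULL, samples = NULL) {
  if (is.null(variants)) variants <- seq_len(n_variants(gm))
  if (is.null(samples)) samples <- seq_len(n_samples(gm))
  if (is.character(samples)) samples <- match(samples, gm$samples)
  gm$contig <- gm$contig[variants]
  gm$pos <- gm$pos[variants]
  gm$ref <- gm$ref[variants]
  gm$alt <- gm$alt[variants]
  for (m in c("a1", "a2", "phased", "dp", "gq")) {
    gm[[m]] <- gm[[m]][variants, samples, drop = FALSE]
  }
  gm$info <- gm$info[variants, , drop = FALSE]
  rownames(gm$info) <- NULL
  gm$samples <- gm$samples[samples]
  gm$subpop <- gm$subpop[samples]
  gm
}

# index of variants falling in [start, end) on contig
gm_variants_in <- function(gm, contig, start, end) {
  which(gm$contig == contig & gm$pos >= start & gm$pos < end)
}

# allele-count list: per variant, table of allele index -> count over the
# selected samples (missing calls excluded)
gm_allele_counts <- function(gm, variants = NULL, samples = NULL) {
  if (is.null(variants)) variants <- seq_len(n_variants(gm))
  if (is.null(samples)) samples <- seq_len(n_samples(gm))
  if (is.character(samples)) samples <- match(samples, gm$samples)
  lapply(variants, function(v) {
    al <- c(gm$a1[v, samples], gm$a2[v, samples])
    al <- al[!is.na(al)]
    if (!length(al)) return(integer(0))
    table(al)
  })
}

# per-site mean pairwise difference: (n^2 - sum n_i^2) / (n (n-1)),
# 0 (and a skip) when fewer than 2 non-missing alleles
site_pairwise_diversity <- function(gm, variants = NULL, samples = NULL) {
  ac <- gm_allele_counts(gm, variants, samples)
  vapply(ac, function(tab) {
    n <- sum(tab)
    if (n < 2) return(0)
    (n^2 - sum(as.numeric(tab)^2)) / (n * (n - 1))
  }, numeric(1))
}

# major-vs-rest dosage encoding for biallelic-style statistics: 0/1/2 copies
# of the non-major allele, NA = missing. Major allele is the most frequent
# allele over the selected samples (ties -> lowest allele index).
gm_dosage <- function(gm, variants = NULL, samples = NULL) {
  if (is.null(variants)) variants <- seq_len(n_variants(gm))
  if (is.null(samples)) samples <- seq_len(n_samples(gm))
  if (is.character(samples)) samples <- match(samples, gm$samples)
  a1 <- gm$a1[variants, samples, drop = FALSE]
  a2 <- gm$a2[variants, samples, drop = FALSE]
  out <- matrix(NA_integer_, nrow(a1), ncol(a1))
  for (i in seq_len(nrow(a1))) {
    al <- c(a1[i, ], a2[i, ]); al <- al[!is.na(al)]
    if (!length(al)) next
    tab <- table(al)
    major <- as.integer(names(tab)[which.max(tab)])
    out[i, ] <- (a1[i, ] != major) + (a2[i, ] != major)
  }
  rownames(out) <- NULL
  colnames(out) <- gm$samples[samples]
  out
}
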