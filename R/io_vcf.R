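# VCF reading (via vcfR) and writing. Only the fields the filter cascade
# touches are interpreted: FORMAT GT/DP/GQ and INFO QD/FS/ReadPosRankSum.
# VCF positions are 1-based in the file and converted to the package's
# 0-based convention at this boundary.

#' Read a VCF into a genotype matrix
#'
#' Parses diploid genotypes with their per-call depth (`DP`) and quality
#' (`GQ`), the phase separator, and the site annotations `QD`, `FS` and
#' `ReadPosRankSum`. Annotations absent from a record are stored as `NA`
#' ("undefined"), never as 0, so downstream hard filters can apply their
#' pass-by-absence rule. Multiallelic records are retained with allele
#' indices intact.
#'
#' @param path path to a VCF (v4.x, plain or gzipped).
#' @param required_fields character vector of FORMAT/INFO keys that must be
#'   declared in the header; an absent key is an error.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, required_fields = c("GT")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  for (f in required_fields) {
    if (!any(grepl(paste0("ID=", f, "[,>]"), meta))) {
      stop("required field absent from VCF header: ", f, call. = FALSE)
    }
  }
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  nv <- nrow(fix)
  if (nv == 0) {
    return(genotype_matrix(character(0), integer(0), character(0), character(0),
                           matrix(NA_integer_, 0, 0), matrix(NA_integer_, 0, 0)))
  }
  contig <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"]) - 1L
  o <- order(contig, pos)
  if (!identical(o, seq_len(nv))) {
    stop("VCF records are not coordinate-sorted", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  if (is.null(dp)) dp <- matrix(NA_real_, nv, ncol(gt))
  if (is.null(gq)) gq <- matrix(NA_real_, nv, ncol(gt))
  qd <- suppressWarnings(vcfR::extract.info(v, element = "QD", as.numeric = TRUE))
  fs <- suppressWarnings(vcfR::extract.info(v, element = "FS", as.numeric = TRUE))
  rprs <- suppressWarnings(vcfR::extract.info(v, element = "ReadPosRankSum",
                                              as.numeric = TRUE))
  info <- data.frame(QD = qd %||% rep(NA_real_, nv),
                     FS = fs %||% rep(NA_real_, nv),
                     ReadPosRankSum = rprs %||% rep(NA_real_, nv))
  parsed <- parse_gt_strings(gt)
  genotype_matrix(contig, pos, fix[, "REF"], fix[, "ALT"],
                  parsed$a1, parsed$a2, parsed$phased, dp, gq, info,
                  samples = colnames(gt))
}

parse_gt_strings <- function(gt) {
  nv <- nrow(gt); ns <- ncol(gt)
  a1 <- matrix(NA_integer_, nv, ns)
  a2 <- matrix(NA_integer_, nv, ns)
  phased <- matrix(FALSE, nv, ns)
  flat <- as.character(gt)
  flat[is.na(flat)] <- "./."
  ph <- grepl("|", flat, fixed = TRUE)
  parts <- strsplit(flat, "[/|]")
  g1 <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1)))
  g2 <- suppressWarnings(as.integer(vapply(parts, function(p) {
    if (length(p) >= 2) p[2] else NA_character_
  }, character(1))))
  miss <- is.na(g1) | is.na(g2)
  g1[miss] <- NA_integer_; g2[miss] <- NA_integer_
  a1[] <- g1; a2[] <- g2; phased[] <- ph & !miss
  list(a1 = a1, a2 = a2, phased = phased)
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF v4.2 with GT:DP:GQ genotype fields and the QD/FS/
#' ReadPosRankSum site annotations where defined. Output formatting is fully
#' deterministic, so identical inputs produce byte-identical files.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param contig_lengths optional named vector used for `##contig` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=panelsmith",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant quality by depth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank-sum\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  writeLines(hdr, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  if (n_variants(gm) == 0) return(invisible(path))
  fmt_num <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g", digits = 6))
  info <- vapply(seq_len(n_variants(gm)), function(i) {
    kv <- c(QD = fmt_num(gm$info$QD[i]), FS = fmt_num(gm$info$FS[i]),
            ReadPosRankSum = fmt_num(gm$info$ReadPosRankSum[i]))
    kv <- kv[!is.na(kv)]
    if (!length(kv)) "." else paste(names(kv), kv, sep = "=", collapse = ";")
  }, character(1))
  for (i in seq_len(n_variants(gm))) {
    sep <- ifelse(gm$phased[i, ], "|", "/")
    gts <- ifelse(is.na(gm$a1[i, ]), "./.",
                  paste0(gm$a1[i, ], sep, gm$a2[i, ]))
    cells <- paste(gts,
                   ifelse(is.na(gm$dp[i, ]), ".", as.integer(round(gm$dp[i, ]))),
                   ifelse(is.na(gm$gq[i, ]), ".", as.integer(round(gm$gq[i, ]))),
                   sep = ":")
    writeLines(paste(c(gm$contig[i], gm$pos[i] + 1L, ".", gm$ref[i],
                       gm$alt[i], ".", ".", info[i], "GT:DP:GQ", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}
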