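# In-silico PCR: map primers to a genome allowing a mismatch fraction
# (substitutions only, no indels), pair convergent hits into predicted
# products, and flag primer pairs matching more than once.

#' Find primer binding sites
#'
#' All ungapped alignments of the primer (forward strand) and of its reverse
#' complement (reverse strand) with at most `floor(mismatch_fraction *
#' length)` substitutions. `N` in the genome counts as a mismatch.
#'
#' @param primer primer sequence over `A`, `C`, `G`, `T` (>= 10 bp).
#' @param genome a `genome_sequences` object.
#' @param mismatch_fraction allowed mismatch fraction (default 0.05: one
#'   mismatch for a 20-26 bp primer).
#' @return data frame of class `primer_hits`: `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `mismatches`.
#' @export
find_primer_hits <- function(primer, genome, mismatch_fraction = 0.05) {
  primer <- toupper(primer)
  if (nchar(primer) < 10) {
    stop("primer shorter than 10 bp is uninformative", call. = FALSE)
  }
  if (grepl("[^ACGT]", primer)) {
    stop("primer must be over A/C/G/T", call. = FALSE)
  }
  k <- floor(mismatch_fraction * nchar(primer))
  pat_f <- Biostrings::DNAString(primer)
  pat_r <- Biostrings::reverseComplement(pat_f)
  rows <- list()
  for (ct in names(genome$seq)) {
    subj <- Biostrings::DNAString(genome$seq[[ct]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_f else pat_r
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = k,
                                    with.indels = FALSE, fixed = TRUE)
      if (!length(m)) next
      st <- Biostrings::start(m)
      mm <- Biostrings::neditStartingAt(pat, subj, starting.at = st,
                                        with.indels = FALSE, fixed = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ct, start = st - 1L, end = st - 1L + nchar(primer),
        strand = strand, mismatches = as.integer(mm))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    contig = character(0), start = integer(0), end = integer(0),
    strand = character(0), mismatches = integer(0))
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("primer_hits", "data.frame")
  out
}

#' Predict PCR products from primer hits
#'
#' All convergent pairings on the same contig — a plus-strand hit of one
#' primer upstream of (and not overlapping) a minus-strand hit of the other
#' — with outer span at most `max_product`. Both primer orderings are tried,
#' since either primer may land on either strand.
#'
#' @param fwd_hits,rev_hits `primer_hits` for the forward and reverse
#'   primer.
#' @param max_product maximum outer product span in bp (default 300).
#' @return data frame of class `amplicon_products`: `contig`, `start`,
#'   `end`, `length`, `plus_primer` (which primer annealed on the plus
#'   strand), `plus_mismatches`, `minus_mismatches`.
#' @export
predict_products <- function(fwd_hits, rev_hits, max_product = 300) {
  pair_up <- function(plus, minus, label) {
    if (!nrow(plus) || !nrow(minus)) return(NULL)
    out <- list()
    for (i in seq_len(nrow(plus))) {
      j <- which(minus$contig == plus$contig[i] &
                   minus$start >= plus$end[i] &
                   minus$end - plus$start[i] <= max_product)
      if (!length(j)) next
      out[[length(out) + 1L]] <- data.frame(
        contig = plus$contig[i], start = plus$start[i], end = minus$end[j],
        length = minus$end[j] - plus$start[i], plus_primer = label,
        plus_mismatches = plus$mismatches[i],
        minus_mismatches = minus$mismatches[j])
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  res <- rbind(
    pair_up(fwd_hits[fwd_hits$strand == "+", , drop = FALSE],
            rev_hits[rev_hits$strand == "-", , drop = FALSE], "fwd"),
    pair_up(rev_hits[rev_hits$strand == "+", , drop = FALSE],
            fwd_hits[fwd_hits$strand == "-", , drop = FALSE], "rev"))
  if (is.null(res)) {
    res <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      plus_primer = character(0),
                      plus_mismatches = integer(0),
                      minus_mismatches = integer(0))
  }
  res <- res[order(res$contig, res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("amplicon_products", "data.frame")
  res
}

#' Flag panel loci with off-target products
#'
#' Runs in-silico PCR for every locus of a panel and counts the predicted
#' products (the intended target included). More than one product flags the
#' locus as having putative off-target loci; zero products flags it
#' separately as target-not-found.
#'
#' @param panel a [primer_table()].
#' @param genome a `genome_sequences` object.
#' @param mismatch_fraction see [find_primer_hits()].
#' @param max_product see [predict_products()].
#' @return data frame: `locus_id`, `n_products`, `off_target`,
#'   `target_not_found`; attribute `products` holds the per-locus product
#'   tables.
#' @export
flag_off_targets <- function(panel, genome, mismatch_fraction = 0.05,
                             max_product = 300) {
  n <- nrow(panel)
  counts <- integer(n)
  prods <- vector("list", n); names(prods) <- panel$locus_id
  for (i in seq_len(n)) {
    fh <- find_primer_hits(panel$fwd_seq[i], genome, mismatch_fraction)
    rh <- find_primer_hits(panel$rev_seq[i], genome, mismatch_fraction)
    pr <- predict_products(fh, rh, max_product)
    counts[i] <- nrow(pr)
    prods[[i]] <- pr
  }
  out <- data.frame(locus_id = panel$locus_id, n_products = counts,
                    off_target = counts > 1, target_not_found = counts == 0)
  attr(out, "products") <- prods
  out
}
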