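# FASTA reading/writing. Sequences are stored uppercase; soft-masked
# (lowercase) runs are recorded separately as 0-based half-open intervals so
# they can stand in for a repeat annotation when no explicit mask is given.

#' Read a FASTA file into a genome object
#'
#' Loads every record, uppercases the sequence, and records soft-masked
#' (lowercase) runs as a per-contig interval list. Only `A`, `C`, `G`, `T`,
#' `N` (either case) are accepted.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return an object of class `genome_sequences`: a list with `seq` (named
#'   character vector of uppercase sequences) and `softmask` (named list of
#'   data frames with 0-based half-open `start`/`end` columns).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning("empty FASTA: ", path)
    return(new_genome(character(0), list()))
  }
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0) {
    warning("empty FASTA: ", path)
    return(new_genome(character(0), list()))
  }
  ids <- vapply(recs, function(r) attr(r, "name"), character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate contig id in FASTA: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
  names(seqs) <- ids
  softmask <- vector("list", length(seqs)); names(softmask) <- ids
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    bad <- regexpr("[^ACGTNacgtn]", s)
    if (bad > 0) {
      stop(sprintf("invalid DNA letter '%s' at %s:%d", substr(s, bad, bad),
                   ids[i], bad - 1L), call. = FALSE)
    }
    softmask[[i]] <- lowercase_runs(s)
    seqs[[i]] <- toupper(s)
  }
  new_genome(seqs, softmask)
}

new_genome <- function(seqs, softmask = NULL) {
  if (is.null(softmask)) {
    softmask <- rep(list(data.frame(start = integer(0), end = integer(0))),
                    length(seqs))
    names(softmask) <- names(seqs)
  }
  structure(list(seq = seqs, softmask = softmask), class = "genome_sequences")
}

#' @export
print.genome_sequences <- function(x, ...) {
  cat(sprintf("genome_sequences: %d contig(s), %s bp total\n",
              length(x$seq), format(sum(nchar(x$seq)), big.mark = ",")))
  invisible(x)
}

#' @rdname read_fasta
#' @param genome a `genome_sequences` object.
#' @export
contig_lengths <- function(genome) {
  stats::setNames(nchar(genome$seq), names(genome$seq))
}

lowercase_runs <- function(s) {
  is_lower <- grepl("[a-z]", strsplit(s, "")[[1]])
  r <- rle(is_lower)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Write a genome object to FASTA
#'
#' Soft-mask intervals are re-emitted as lowercase so that a write/read
#' round-trip reproduces the in-memory object.
#'
#' @param genome a `genome_sequences` object.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  con <- file(path, "w"); on.exit(close(con))
  for (id in names(genome$seq)) {
    s <- genome$seq[[id]]
    sm <- genome$softmask[[id]]
    if (!is.null(sm) && nrow(sm)) {
      chars <- strsplit(s, "")[[1]]
      for (j in seq_len(nrow(sm))) {
        idx <- (sm$start[j] + 1L):sm$end[j]
        chars[idx] <- tolower(chars[idx])
      }
      s <- paste(chars, collapse = "")
    }
    writeLines(paste0(">", id), con)
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(seq(1, nchar(s), width) + width - 1, nchar(s))),
               con)
  }
  invisible(path)
}
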