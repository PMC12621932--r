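# Tabular formats: genetic map (contig / bp / cM), primer table (one row per
# locus, SD1-style column set with a configurable mapping), BED intervals and
# read-alignment tables.

#' Read a genetic map
#'
#' A genetic map is a TSV with columns `contig`, `bp`, `cM`: per-contig
#' anchors with strictly increasing physical positions and non-decreasing map
#' positions. Map positions between anchors are obtained by linear
#' interpolation; queries beyond the terminal anchors are clamped to the
#' terminal cM values.
#'
#' @param path path to the TSV (header required).
#' @return an object of class `genetic_map` (a data frame).
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "bp", "cM")
  if (!all(need %in% names(df))) {
    stop("genetic map must have columns contig, bp, cM", call. = FALSE)
  }
  genetic_map(df$contig, df$bp, df$cM)
}

#' @rdname read_genetic_map
#' @param contig,bp,cM anchor vectors.
#' @export
genetic_map <- function(contig, bp, cM) {
  df <- data.frame(contig = as.character(contig), bp = as.numeric(bp),
                   cM = as.numeric(cM))
  df <- df[order(df$contig, df$bp), , drop = FALSE]
  rownames(df) <- NULL
  for (ct in unique(df$contig)) {
    sub <- df[df$contig == ct, ]
    if (nrow(sub) < 2) {
      stop("contig '", ct, "' has fewer than 2 map anchors", call. = FALSE)
    }
    if (any(diff(sub$bp) <= 0)) {
      stop("anchor positions must be strictly increasing on ", ct, call. = FALSE)
    }
    if (any(diff(sub$cM) < 0)) {
      stop("cM must be non-decreasing with bp on ", ct, call. = FALSE)
    }
  }
  structure(df, class = c("genetic_map", "data.frame"))
}

#' Interpolate map positions
#'
#' @param map a `genetic_map`.
#' @param contig contig id (scalar).
#' @param pos physical positions (bp, 0-based; the bp scale of the anchors).
#' @return cM positions (linear between anchors, clamped beyond the ends).
#' @export
interpolate_cm <- function(map, contig, pos) {
  sub <- map[map$contig == contig, , drop = FALSE]
  if (nrow(sub) < 2) stop("no genetic map for contig ", contig, call. = FALSE)
  stats::approx(sub$bp, sub$cM, xout = pos, rule = 2, ties = "ordered")$y
}

#' @rdname read_genetic_map
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# default SD1-compatible column mapping; callers can rename
PRIMER_COLUMNS <- c(locus_id = "locus_id", fwd_seq = "fwd_seq",
                    rev_seq = "rev_seq", fwd_tail = "fwd_tail",
                    rev_tail = "rev_tail", balancing_factor = "balancing_factor",
                    contig = "contig", start = "start", end = "end")

#' Read a primer panel table
#'
#' One row per locus: locus-specific forward/reverse primer sequences, their
#' adapter tails, a dilution balancing factor, and optional target
#' coordinates (0-based half-open). The exact column names of an external
#' table can be adapted via `columns`.
#'
#' @param path path to the TSV (header required).
#' @param columns named character vector mapping internal names
#'   (`locus_id`, `fwd_seq`, `rev_seq`, `fwd_tail`, `rev_tail`,
#'   `balancing_factor`, `contig`, `start`, `end`) to the file's column
#'   names.
#' @return a data frame of class `primer_table`, with computed per-primer
#'   `fwd_len`/`rev_len` and `fwd_tail_len`/`rev_tail_len` columns.
#' @export
read_primer_table <- function(path, columns = PRIMER_COLUMNS) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- PRIMER_COLUMNS
  cols[names(columns)] <- columns
  for (k in c("locus_id", "fwd_seq", "rev_seq")) {
    if (!cols[[k]] %in% names(df)) {
      stop("primer table lacks required column: ", cols[[k]], call. = FALSE)
    }
  }
  get <- function(k, default = NA) {
    if (cols[[k]] %in% names(df)) df[[cols[[k]]]] else rep(default, nrow(df))
  }
  primer_table(locus_id = get("locus_id"),
               fwd_seq = get("fwd_seq"), rev_seq = get("rev_seq"),
               fwd_tail = get("fwd_tail", ""), rev_tail = get("rev_tail", ""),
               balancing_factor = as.numeric(get("balancing_factor", 1)),
               contig = as.character(get("contig", NA_character_)),
               start = as.numeric(get("start", NA)),
               end = as.numeric(get("end", NA)))
}

#' @rdname read_primer_table
#' @param locus_id,fwd_seq,rev_seq,fwd_tail,rev_tail,balancing_factor,contig,start,end
#'   column vectors; coordinates may be `NA` when unknown (run in-silico PCR
#'   to obtain them).
#' @export
primer_table <- function(locus_id, fwd_seq, rev_seq, fwd_tail = "",
                         rev_tail = "", balancing_factor = 1,
                         contig = NA_character_, start = NA, end = NA) {
  n <- length(locus_id)
  if (anyDuplicated(locus_id)) {
    stop("duplicate locus id: ", locus_id[duplicated(locus_id)][1], call. = FALSE)
  }
  fwd_seq <- toupper(fwd_seq); rev_seq <- toupper(rev_seq)
  for (side in list(c("forward", "fwd_seq"), c("reverse", "rev_seq"))) {
    seqs <- get(side[2])
    bad <- grepl("[^ACGT]", seqs)
    if (any(bad)) {
      stop(sprintf("%s primer of locus '%s' contains a non-ACGT character",
                   side[1], locus_id[bad][1]), call. = FALSE)
    }
  }
  if (any(!is.na(balancing_factor) & balancing_factor <= 0)) {
    stop("balancing factor must be > 0 (locus ",
         locus_id[which(balancing_factor <= 0)[1]], ")", call. = FALSE)
  }
  df <- data.frame(locus_id = as.character(locus_id),
                   fwd_seq = fwd_seq, rev_seq = rev_seq,
                   fwd_tail = toupper(rep_len(fwd_tail, n)),
                   rev_tail = toupper(rep_len(rev_tail, n)),
                   balancing_factor = rep_len(as.numeric(balancing_factor), n),
                   contig = rep_len(as.character(contig), n),
                   start = rep_len(as.numeric(start), n),
                   end = rep_len(as.numeric(end), n),
                   stringsAsFactors = FALSE)
  df$fwd_len <- nchar(df$fwd_seq)
  df$rev_len <- nchar(df$rev_seq)
  df$fwd_tail_len <- nchar(df$fwd_tail)
  df$rev_tail_len <- nchar(df$rev_tail)
  class(df) <- c("primer_table", "data.frame")
  df
}

#' @rdname read_primer_table
#' @param x a `primer_table`.
#' @export
write_primer_table <- function(x, path) {
  keep <- c("locus_id", "fwd_seq", "rev_seq", "fwd_tail", "rev_tail",
            "balancing_factor", "contig", "start", "end")
  utils::write.table(as.data.frame(x)[, keep], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write BED intervals
#'
#' Minimal BED3(+score) support; BED is 0-based half-open, matching the
#' package's internal convention, so no coordinate shift is applied.
#'
#' @param path file path.
#' @return data frame with `contig`, `start`, `end` (and further columns if
#'   present: `name`, `score`).
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  names(df)[1:3] <- c("contig", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}

#' @rdname read_bed
#' @param x data frame with `contig`, `start`, `end` and optional
#'   `name`/`score` columns.
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("contig", "start", "end", "name", "score"), names(x))
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a read-alignment table
#'
#' TSV with columns `read_id`, `contig`, `start`, `end`, `multimap`
#' (0/1): the minimal projection of an alignment needed for per-amplicon
#' read counting. Coordinates are 0-based half-open.
#'
#' @param path file path.
#' @return data frame with logical `multimap`.
#' @export
read_alignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "contig", "start", "end", "multimap")
  if (!all(need %in% names(df))) {
    stop("alignment table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$multimap <- as.logical(as.integer(df$multimap))
  df
}

#' @rdname read_alignments
#' @param x alignment data frame.
#' @export
write_alignments <- function(x, path) {
  x$multimap <- as.integer(x$multimap)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
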