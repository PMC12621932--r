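# Pseudo-random gap-filling locus selection over a genetic map, primer-dimer
# screening, and final set choice. The gap-filling scheme is this package's
# own definition: repeatedly take the largest current cM gap and place, at
# random among near-best candidates, the locus that best balances gap
# centering against SNP content.

annotate_candidate_cm <- function(candidates, map) {
  mid <- (candidates$core_start + candidates$core_end) / 2
  cm <- numeric(nrow(candidates))
  for (ct in unique(candidates$contig)) {
    ci <- which(candidates$contig == ct)
    cm[ci] <- interpolate_cm(map, ct, mid[ci])
  }
  candidates$cm <- cm
  candidates
}

#' Gap-filling marker selection
#'
#' Generates `n_sets` marker sets of size `m` each. A set starts from
#' chromosome-end sentinels (the terminal cM values of each contig's map)
#' and grows one locus at a time: find the largest current cM gap over all
#' contigs; among the unchosen candidates inside that gap score each as
#' `w_gap * (1 - |cm - mid| / (gap/2)) + w_snp * S / max(S)` and choose
#' uniformly at random among candidates within `eps` of the best score; if
#' the largest gap holds no candidate, fall through to the next largest.
#' Set `i` uses seed `seed + i - 1`, so runs are reproducible and sets
#' differ only by seed.
#'
#' @param candidates a `candidate_regions` data frame (typically the pass
#'   set), with `locus_id` and `S_core` columns.
#' @param map a [genetic_map()] covering every candidate contig.
#' @param m loci per set (default 350).
#' @param n_sets number of sets (default 10).
#' @param seed base seed (mandatory).
#' @param w_gap,w_snp score weights.
#' @param eps score tolerance of the randomized choice.
#' @return list of class `selection_run`: `sets` (list of locus-id
#'   vectors), `summaries` (per-set max/median cM gap and total SNPs),
#'   `candidates` (the annotated input), `seed`, `m`.
#' @export
gap_fill_select <- function(candidates, map, m = 350, n_sets = 10, seed,
                            w_gap = 0.7, w_snp = 0.3, eps = 0.05) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  for (ct in unique(candidates$contig)) {
    if (!any(map$contig == ct)) stop("no genetic map for contig ", ct,
                                     call. = FALSE)
  }
  candidates <- annotate_candidate_cm(candidates, map)
  ncand <- nrow(candidates)
  if (ncand < m) {
    warning(sprintf("only %d candidates for m = %d; selecting all", ncand, m))
  }
  max_snp <- max(candidates$S_core, 1)
  contigs <- unique(candidates$contig)
  sentinels <- lapply(contigs, function(ct) {
    range(map$cM[map$contig == ct])
  })
  names(sentinels) <- contigs
  sets <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    sets[[s]] <- with_seed(seed + s - 1L, {
      chosen_cm <- lapply(sentinels, function(r) sort(r))
      avail <- rep(TRUE, ncand)
      picked <- integer(0)
      while (length(picked) < min(m, ncand)) {
        gaps <- do.call(rbind, lapply(contigs, function(ct) {
          v <- chosen_cm[[ct]]
          data.frame(contig = ct, lo = v[-length(v)], hi = v[-1])
        }))
        gaps$len <- gaps$hi - gaps$lo
        gaps <- gaps[order(-gaps$len), , drop = FALSE]
        placed <- FALSE
        for (g in seq_len(nrow(gaps))) {
          inside <- which(avail & candidates$contig == gaps$contig[g] &
                            candidates$cm >= gaps$lo[g] &
                            candidates$cm <= gaps$hi[g])
          if (!length(inside)) next
          half <- gaps$len[g] / 2
          mid <- (gaps$lo[g] + gaps$hi[g]) / 2
          gap_score <- if (half > 0) {
            1 - abs(candidates$cm[inside] - mid) / half
          } else rep(1, length(inside))
          score <- w_gap * gap_score + w_snp * candidates$S_core[inside] / max_snp
          eligible <- inside[score >= max(score) - eps]
          pick <- if (length(eligible) == 1) eligible else
            eligible[sample.int(length(eligible), 1)]
          avail[pick] <- FALSE
          picked <- c(picked, pick)
          ct <- candidates$contig[pick]
          chosen_cm[[ct]] <- sort(c(chosen_cm[[ct]], candidates$cm[pick]))
          placed <- TRUE
          break
        }
        if (!placed) break  # no gap holds a candidate
      }
      candidates$locus_id[picked]
    })
  }
  summaries <- do.call(rbind, lapply(seq_len(n_sets), function(s) {
    sel <- candidates[match(sets[[s]], candidates$locus_id), ]
    st <- spacing_stats(sel)
    data.frame(set = s, seed = seed + s - 1L, n = nrow(sel),
               max_gap = st$max_gap, median_gap = st$median_gap,
               total_snps = sum(sel$S_core))
  }))
  structure(list(sets = sets, summaries = summaries,
                 candidates = candidates, seed = seed, m = m),
            class = "selection_run")
}

#' @export
print.selection_run <- function(x, ...) {
  cat(sprintf("selection_run: %d set(s) of up to %d loci (base seed %d)\n",
              length(x$sets), x$m, x$seed))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Marker spacing summary
#'
#' Gaps in cM between consecutive loci within each contig (contig ends are
#' not counted as gaps), pooled across contigs for the global summary.
#'
#' @param loci data frame with `locus_id`, `contig` and `cm` columns (e.g.
#'   annotated candidates subset to a panel).
#' @return list with `gaps` (data frame `contig`, `gap_cm`), `min_gap`,
#'   `median_gap`, `max_gap` and `loci_per_contig`.
#' @export
spacing_stats <- function(loci) {
  gaps <- do.call(rbind, lapply(unique(loci$contig), function(ct) {
    v <- sort(loci$cm[loci$contig == ct])
    if (length(v) < 2) return(NULL)
    data.frame(contig = ct, gap_cm = diff(v))
  }))
  if (is.null(gaps)) gaps <- data.frame(contig = character(0), gap_cm = numeric(0))
  list(gaps = gaps,
       min_gap = if (nrow(gaps)) min(gaps$gap_cm) else NA_real_,
       median_gap = if (nrow(gaps)) stats::median(gaps$gap_cm) else NA_real_,
       max_gap = if (nrow(gaps)) max(gaps$gap_cm) else NA_real_,
       loci_per_contig = table(loci$contig))
}

#' Screen a primer pool for dimer-prone pairs
#'
#' A heuristic stand-in for thermodynamic dimer prediction: an ordered pair
#' (A, B) is flagged when the 3' terminus of A reverse-complements a
#' subsequence of B over at least `t3` bases, or when any perfect
#' reverse-complement run of at least `t_internal` bases exists anywhere
#' between A and B. The result is the symmetric closure over unordered
#' pairs; self-pairs are screened too.
#'
#' @param primers data frame with `locus_id`, `fwd_seq`, `rev_seq` (a
#'   [primer_table()]), or a named character vector of primer sequences.
#' @param t3 3'-anchored run threshold (default 5).
#' @param t_internal internal run threshold (default 8).
#' @return data frame `primer_a`, `primer_b`, `reason` of flagged unordered
#'   pairs.
#' @export
dimer_screen <- function(primers, t3 = 5, t_internal = 8) {
  if (is.data.frame(primers)) {
    pool <- c(stats::setNames(primers$fwd_seq, paste0(primers$locus_id, "_F")),
              stats::setNames(primers$rev_seq, paste0(primers$locus_id, "_R")))
  } else {
    pool <- primers
  }
  pool <- toupper(pool)
  n <- length(pool)
  ids <- names(pool) %||% paste0("P", seq_len(n))
  rc <- revcomp(pool)
  flagged <- list()
  # 3'-anchored: revcomp of A's last t3 bases occurs in B
  tails_rc <- revcomp(substr(pool, nchar(pool) - t3 + 1L, nchar(pool)))
  # internal: A and revcomp(B) share a t_internal-mer <=> a t_internal-mer of
  # A occurs in revcomp(B); index all k-mers of rc once
  kmer_index <- new.env(hash = TRUE, parent = emptyenv())
  for (b in seq_len(n)) {
    s <- rc[b]; L <- nchar(s)
    if (L < t_internal) next
    for (p in 1:(L - t_internal + 1L)) {
      km <- substr(s, p, p + t_internal - 1L)
      assign(km, c(kmer_index[[km]], b), envir = kmer_index)
    }
  }
  for (a in seq_len(n)) {
    hit_b <- logical(n); reason <- character(n)
    # internal runs
    sa <- pool[a]; L <- nchar(sa)
    if (L >= t_internal) {
      for (p in 1:(L - t_internal + 1L)) {
        km <- substr(sa, p, p + t_internal - 1L)
        bs <- kmer_index[[km]]
        if (!is.null(bs)) {
          hit_b[bs] <- TRUE
          reason[bs][reason[bs] == ""] <- "internal"
        }
      }
    }
    # 3'-anchored runs
    three <- grepl(tails_rc[a], pool, fixed = TRUE)
    reason[three] <- ifelse(hit_b[three], "3prime+internal", "3prime")
    hit_b <- hit_b | three
    for (b in which(hit_b)) {
      key <- paste(sort(c(ids[a], ids[b])), collapse = "\r")
      if (is.null(flagged[[key]])) {
        flagged[[key]] <- data.frame(primer_a = min(ids[a], ids[b]),
                                     primer_b = max(ids[a], ids[b]),
                                     reason = reason[b])
      }
    }
  }
  if (!length(flagged)) {
    return(data.frame(primer_a = character(0), primer_b = character(0),
                      reason = character(0)))
  }
  out <- do.call(rbind, flagged)
  rownames(out) <- NULL
  out[order(out$primer_a, out$primer_b), , drop = FALSE]
}

#' Choose the final panel from a selection run
#'
#' Picks the set minimizing the maximum cM gap (ties: smaller median gap,
#' then lower seed), truncates it to `final_m` loci by iteratively removing
#' the locus whose removal least increases the maximum gap, then drops the
#' loci on `exclude` without replacement (ids not in the set are ignored
#' with a warning).
#'
#' @param run a `selection_run` from [gap_fill_select()].
#' @param final_m target panel size (default 300).
#' @param exclude locus ids to drop after truncation (e.g. loci failing
#'   amplification in practice).
#' @return data frame of class `panel_loci`: the chosen candidates with
#'   `cm`, plus attributes `set` (which set won) and `spacing`.
#' @export
choose_final_set <- function(run, final_m = 300, exclude = character(0)) {
  sm <- run$summaries
  o <- order(sm$max_gap, sm$median_gap, sm$seed)
  best <- sm$set[o[1]]
  ids <- run$sets[[best]]
  cand <- run$candidates
  sel <- cand[match(ids, cand$locus_id), , drop = FALSE]
  while (nrow(sel) > final_m) {
    best_i <- NA_integer_; best_max <- Inf
    for (i in seq_len(nrow(sel))) {
      st <- spacing_stats(sel[-i, , drop = FALSE])
      mg <- if (is.na(st$max_gap)) 0 else st$max_gap
      if (mg < best_max - 1e-12) { best_max <- mg; best_i <- i }
    }
    sel <- sel[-best_i, , drop = FALSE]
  }
  unknown <- setdiff(exclude, sel$locus_id)
  if (length(unknown)) {
    warning("exclusion ids not in the chosen set: ",
            paste(unknown, collapse = ", "))
  }
  sel <- sel[!sel$locus_id %in% exclude, , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "set") <- best
  attr(sel, "spacing") <- spacing_stats(sel)
  class(sel) <- c("panel_loci", "data.frame")
  sel
}

# fixed synthetic adapter tails of the conventional lengths (31 bp forward,
# 34 bp reverse); arbitrary sequences, not any vendor's adapters
SYNTH_FWD_TAIL <- "ACCTGTCCTAAGGTCAGATTCGCACCTGTGA"          # 31 bp
SYNTH_REV_TAIL <- "TGCAGGACCATTAGCGTCTGAACTGGACTTCAGT"       # 34 bp

#' Derive primers from candidate flanks
#'
#' A transparent stand-in for outsourced thermodynamic primer design: the
#' forward primer is the `primer_len` bases immediately left of the core and
#' the reverse primer is the reverse complement of the `primer_len` bases
#' immediately right of it, so the predicted amplicon is the core plus both
#' primer footprints.
#'
#' @param candidates a `candidate_regions` data frame (with `cm` if
#'   available).
#' @param genome a `genome_sequences` object.
#' @param primer_len locus-specific primer length in bp (17-26 in practice).
#' @param fwd_tail,rev_tail adapter tails prepended to each primer.
#' @return a [primer_table()] with target coordinates set to the predicted
#'   amplicon interval, plus `amplicon_length` and `cm` columns.
#' @export
derive_flank_primers <- function(candidates, genome, primer_len = 20,
                                 fwd_tail = SYNTH_FWD_TAIL,
                                 rev_tail = SYNTH_REV_TAIL) {
  n <- nrow(candidates)
  fwd <- character(n); rev <- character(n)
  for (i in seq_len(n)) {
    s <- genome$seq[[candidates$contig[i]]]
    a <- candidates$core_start[i]; b <- candidates$core_end[i]
    if (a - primer_len < 0 || b + primer_len > nchar(s)) {
      stop("candidate too close to contig end for a ", primer_len,
           " bp primer: ", candidates$locus_id[i], call. = FALSE)
    }
    fwd[i] <- substr(s, a - primer_len + 1L, a)           # [a-len, a)
    rev[i] <- revcomp(substr(s, b + 1L, b + primer_len))  # [b, b+len)
  }
  pt <- primer_table(locus_id = candidates$locus_id,
                     fwd_seq = fwd, rev_seq = rev,
                     fwd_tail = fwd_tail, rev_tail = rev_tail,
                     balancing_factor = 1,
                     contig = candidates$contig,
                     start = candidates$core_start - primer_len,
                     end = candidates$core_end + primer_len)
  pt$amplicon_length <- pt$end - pt$start
  if (!is.null(candidates$cm)) pt$cm <- candidates$cm
  pt
}
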